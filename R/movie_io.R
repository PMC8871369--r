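#' Write a movie to multi-page TIFF files
#'
#' One 16-bit multi-page TIFF per channel (`<channel>.tif`) plus a
#' `meta.json` carrying acquisition times, pixel size, dark offsets and
#' (for chip movies) the cross-channel column regions. Intensities are
#' clipped to the 16-bit range; writing is deterministic, so identical
#' movies give byte-identical files.
#'
#' @param movie A `pka_movie`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_movie <- function(movie, dir) {
  stopifnot(inherits(movie, "pka_movie"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in names(movie$channels)) {
    pages <- lapply(movie$channels[[ch]], function(m) {
      pmin(pmax(round(m), 0), 65535) / 65535
    })
    tiff::writeTIFF(pages, file.path(dir, paste0(ch, ".tif")),
                    bits.per.sample = 16L)
  }
  meta <- list(
    channels = names(movie$channels), t_min = movie$t_min,
    pixel_size = movie$pixel_size, dark = movie$dark,
    regions = movie$regions
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a movie written by [write_movie()]
#'
#' @param dir Directory containing `<channel>.tif` files and `meta.json`.
#' @return A `pka_movie`. Intensities are integer counts (the 16-bit
#'   quantisation of the rendered values).
#' @export
read_movie <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  channels <- lapply(setNames(meta$channels, meta$channels), function(ch) {
    pages <- tiff::readTIFF(file.path(dir, paste0(ch, ".tif")), all = TRUE)
    lapply(pages, function(p) round(p * 65535))
  })
  regions <- if (is.null(meta$regions)) NULL else
    lapply(meta$regions, as.integer)
  new_movie(channels, meta$t_min, meta$pixel_size, as.list(meta$dark),
            regions)
}

#' Serialise a ground-truth record to JSON
#'
#' @param truth The `truth` element of a [render_movie()] /
#'   [make_migration_tracks()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
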