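#' Per-cell FRET ratio time series of a movie
#'
#' Runs the standard FRET pipeline on a `pka_movie`: cells are segmented
#' by intensity thresholding of the first expression-channel frame, the
#' dark-corrected ratio map is computed for every frame, and the mean
#' ratio of each cell (after expression filtering) is reported per time
#' point.
#'
#' @param movie A `pka_movie` with `FRET_em` and `CFP` channels and an
#'   expression channel.
#' @param segment_threshold Absolute intensity threshold for segmentation
#'   (raw counts, i.e. including the dark offset).
#' @param expression_channel Channel used for segmentation and the
#'   expression filter (default `"YFP"`).
#' @param min_expression Exclusion threshold on mask-mean expression
#'   intensity (raw counts); 0 disables the filter.
#' @param min_area Minimum segmented-cell area (px).
#' @return A tibble with `cell`, `t_min`, `mean_ratio`, `n_pixels`,
#'   `excluded`, `reason`; the masks used are in `attr(, "masks")`.
#' @export
analyze_fret_movie <- function(movie, segment_threshold,
                               expression_channel = "YFP",
                               min_expression = 0, min_area = 200L) {
  stopifnot(inherits(movie, "pka_movie"))
  expr_frames <- movie$channels[[expression_channel]]
  if (is.null(expr_frames)) {
    abort(sprintf("movie has no channel '%s'", expression_channel))
  }
  masks <- threshold_segment(expr_frames[[1]], segment_threshold, min_area)
  dark_f <- movie$dark[["FRET_em"]] %||% 0
  dark_c <- movie$dark[["CFP"]] %||% 0
  out <- purrr::map_dfr(seq_along(movie$t_min), function(fi) {
    map <- fret_ratio_map(movie$channels$FRET_em[[fi]],
                          movie$channels$CFP[[fi]], masks, dark_f, dark_c)
    purrr::map_dfr(masks, function(m) {
      dplyr::mutate(
        cell_mean_ratio(map, m, expr_frames[[fi]], min_expression),
        t_min = movie$t_min[fi], .after = "cell"
      )
    })
  })
  attr(out, "masks") <- masks
  out
}

#' Per-cell maximal fractional ratio increase
#'
#' For each cell's ratio time series, the maximal percent increase of the
#' mean ratio over its `t = 0` value -- the per-cell response amplitude
#' used to measure the biosensor dynamic range under saturating
#' stimulation.
#'
#' @param ratio_series Output of [analyze_fret_movie()] (columns `cell`,
#'   `t_min`, `mean_ratio`).
#' @return A tibble with `cell`, `baseline_ratio`, `max_ratio`,
#'   `max_increase_pct`.
#' @export
max_ratio_increase <- function(ratio_series) {
  stopifnot(all(c("cell", "t_min", "mean_ratio") %in% names(ratio_series)))
  ratio_series |>
    dplyr::filter(!.data$excluded) |>
    dplyr::group_by(.data$cell) |>
    dplyr::arrange(.data$t_min, .by_group = TRUE) |>
    dplyr::summarise(
      baseline_ratio = dplyr::first(.data$mean_ratio),
      max_ratio = max(.data$mean_ratio),
      max_increase_pct = 100 * (max(.data$mean_ratio) -
        dplyr::first(.data$mean_ratio)) / dplyr::first(.data$mean_ratio),
      .groups = "drop"
    )
}

#' Per-cell binned intracellular profiles of a chip movie
#'
#' Segments each lane's cell from the expression channel and computes the
#' 20-bin intracellular ratio profile at a chosen frame, along with the
#' front-minus-rear polarity score of the binned profile.
#'
#' @param movie A chip `pka_movie` (with `regions`).
#' @param segment_threshold Segmentation threshold (raw counts).
#' @param frame Frame index at which to profile (default: last frame).
#' @param n_bins Number of bins (default 20).
#' @return A tibble with `cell`, `bin`, `position`, `mean_ratio`,
#'   `n_pixels`, `empty`; per-cell polarity scores in
#'   `attr(, "polarity")` (tibble: `cell`, `score`).
#' @export
profile_chip_movie <- function(movie, segment_threshold, frame = NULL,
                               n_bins = 20L) {
  stopifnot(inherits(movie, "pka_movie"))
  frame <- frame %||% length(movie$t_min)
  masks <- threshold_segment(movie$channels$YFP[[frame]], segment_threshold,
                             min_area = 200L)
  map <- fret_ratio_map(movie$channels$FRET_em[[frame]],
                        movie$channels$CFP[[frame]], masks,
                        movie$dark[["FRET_em"]] %||% 0,
                        movie$dark[["CFP"]] %||% 0)
  profs <- purrr::map_dfr(masks, function(m) {
    dplyr::mutate(bin_profile(map, m, n_bins), cell = m$id, .before = 1)
  })
  pol <- profs |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(
      score = mean(.data$mean_ratio[.data$position < 0.5], na.rm = TRUE) -
        mean(.data$mean_ratio[.data$position >= 0.5], na.rm = TRUE),
      .groups = "drop"
    )
  attr(profs, "polarity") <- pol
  attr(profs, "masks") <- masks
  profs
}

#' Map segmented chip cells to their lane index
#'
#' Masks from [threshold_segment()] are ordered by centroid row, which
#' does not correspond to lane order; this helper assigns each mask to the
#' cross-channel lane (movie `regions` entry) containing its centroid
#' column.
#'
#' @param masks List of masks from [threshold_segment()].
#' @param regions List of lane column-index vectors (e.g. `movie$regions`).
#' @return Integer vector: lane index per mask (NA if outside all lanes).
#' @export
lane_of_masks <- function(masks, regions) {
  vapply(masks, function(m) {
    col <- round(m$centroid[["col"]])
    hit <- which(vapply(regions, function(r) col %in% r, logical(1)))
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
}
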