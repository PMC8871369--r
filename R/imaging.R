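#' Label connected components of a binary image
#'
#' 8-connectivity labelling by iterative minimum-label propagation:
#' every foreground pixel starts with a unique label and repeatedly adopts
#' the minimum label in its 3x3 neighbourhood until a fixed point, then
#' labels are renumbered 1..n in order of component centroid (row, then
#' column). Fully deterministic.
#'
#' @param bw Logical (or 0/1 numeric) matrix.
#' @return Integer matrix of the same shape; 0 = background.
#' @export
label_components <- function(bw) {
  bw <- bw > 0
  nr <- nrow(bw); nc <- ncol(bw)
  lab <- matrix(0, nr, nc)
  lab[bw] <- seq_len(sum(bw))
  if (all(lab == 0)) return(matrix(0L, nr, nc))
  big <- sum(bw) + 1
  pad_min <- function(m) {
    p <- matrix(big, nr + 2, nc + 2)
    p[2:(nr + 1), 2:(nc + 1)] <- ifelse(m == 0, big, m)
    out <- p[2:(nr + 1), 2:(nc + 1)]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      out <- pmin(out, p[2:(nr + 1) + dr, 2:(nc + 1) + dc])
    }
    out
  }
  repeat {
    nb <- pad_min(lab)
    new <- ifelse(bw, pmin(ifelse(lab == 0, big, lab), nb), 0)
    new[new == big] <- 0
    if (identical(new, lab)) break
    lab <- new
  }
  # renumber by centroid (row, then column)
  ids <- sort(unique(lab[lab > 0]))
  cent <- t(vapply(ids, function(i) {
    w <- which(lab == i, arr.ind = TRUE)
    c(mean(w[, 1]), mean(w[, 2]))
  }, numeric(2)))
  ord <- order(cent[, 1], cent[, 2])
  out <- matrix(0L, nr, nc)
  for (k in seq_along(ord)) out[lab == ids[ord[k]]] <- k
  out
}

#' Segment cells by intensity thresholding
#'
#' Connected components (8-connectivity) of pixels strictly above
#' `threshold`; components smaller than `min_area` pixels are discarded as
#' debris. Masks are ordered by component centroid (row, then column).
#'
#' @param frame Numeric intensity matrix (e.g. the YFP expression
#'   channel).
#' @param threshold Absolute intensity threshold, >= 0.
#' @param min_area Minimum component area in pixels (default 50).
#' @return A list of masks; each mask is a list with `id`, `mask` (logical
#'   matrix), `area` (px) and `centroid` (row, col). Empty list when
#'   nothing exceeds the threshold.
#' @export
threshold_segment <- function(frame, threshold, min_area = 50L) {
  stopifnot(is.matrix(frame))
  check_scalar(threshold, "threshold", nonneg = TRUE)
  lab <- label_components(frame > threshold)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  masks <- list()
  k <- 0L
  for (i in ids) {
    m <- lab == i
    a <- sum(m)
    if (a < min_area) next
    k <- k + 1L
    w <- which(m, arr.ind = TRUE)
    masks[[k]] <- list(id = k, mask = m, area = a,
                       centroid = c(row = mean(w[, 1]), col = mean(w[, 2])))
  }
  masks
}

#' Binary erosion of a mask
#'
#' Iterated single-pixel erosion with the 8-connectivity (3x3 box)
#' structuring element; pixels outside the image count as background, so
#' masks touching the border erode from the border too.
#'
#' @param mask Logical matrix.
#' @param iterations Number of single-pixel erosion passes, >= 0.
#' @return Logical matrix, a subset of `mask`.
#' @export
erode_mask <- function(mask, iterations = 20L) {
  stopifnot(is.matrix(mask))
  if (iterations < 0) abort("`iterations` must be >= 0.")
  m <- mask > 0
  nr <- nrow(m); nc <- ncol(m)
  for (it in seq_len(iterations)) {
    if (!any(m)) break
    p <- matrix(FALSE, nr + 2, nc + 2)
    p[2:(nr + 1), 2:(nc + 1)] <- m
    keep <- p[2:(nr + 1), 2:(nc + 1)]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      keep <- keep & p[2:(nr + 1) + dr, 2:(nc + 1) + dc]
    }
    m <- keep
  }
  m
}

#' Dark-frame-corrected FRET emission-ratio map
#'
#' Per-pixel ratio `(FRET - DF_fret) / (CFP - DF_cfp)` inside the supplied
#' cell masks. Pixels outside all masks, or whose dark-corrected
#' denominator is <= 0, are set to `NA` and excluded from all downstream
#' means.
#'
#' @param fret_frame Intensity matrix of emission collected in the YFP
#'   channel under CFP excitation.
#' @param cfp_frame Intensity matrix of CFP emission (same shape).
#' @param masks List of masks from [threshold_segment()] (or a single
#'   logical matrix).
#' @param dark_fret,dark_cfp Dark-frame offset for each channel: a scalar
#'   or a matrix of the same shape.
#' @return Numeric matrix of ratios with `NA` where undefined, classed
#'   `pka_ratio_map`.
#' @export
fret_ratio_map <- function(fret_frame, cfp_frame, masks,
                           dark_fret = 0, dark_cfp = 0) {
  if (!identical(dim(fret_frame), dim(cfp_frame))) {
    abort("FRET and CFP frames must have the same shape.")
  }
  inside <- combine_masks(masks, dim(fret_frame))
  num <- fret_frame - dark_fret
  den <- cfp_frame - dark_cfp
  ratio <- matrix(NA_real_, nrow(fret_frame), ncol(fret_frame))
  ok <- inside & den > 0
  ratio[ok] <- num[ok] / den[ok]
  class(ratio) <- c("pka_ratio_map", class(ratio))
  ratio
}

combine_masks <- function(masks, dims) {
  if (is.matrix(masks)) return(masks > 0)
  out <- matrix(FALSE, dims[1], dims[2])
  for (m in masks) out <- out | m$mask
  out
}

#' Mean FRET ratio of one cell, with expression filtering
#'
#' Mean of the defined ratio pixels within a cell mask. Cells whose mean
#' expression-channel intensity falls below `min_expression` are reported
#' as excluded rather than averaged, mirroring the expression filter used
#' when biosensor levels are too low to quantify.
#'
#' @param map A ratio map from [fret_ratio_map()].
#' @param mask One mask from [threshold_segment()].
#' @param expression_frame Optional intensity matrix used for the
#'   expression filter.
#' @param min_expression Exclusion threshold on the mask-mean expression
#'   intensity.
#' @return A one-row tibble with `cell`, `mean_ratio`, `n_pixels`,
#'   `excluded` (logical) and `reason`.
#' @export
cell_mean_ratio <- function(map, mask, expression_frame = NULL,
                            min_expression = 0) {
  vals <- map[mask$mask]
  vals <- vals[is.finite(vals)]
  if (!is.null(expression_frame)) {
    expr <- mean(expression_frame[mask$mask])
    if (expr < min_expression) {
      return(tibble(cell = mask$id, mean_ratio = NA_real_,
                    n_pixels = 0L, excluded = TRUE,
                    reason = "expression below threshold"))
    }
  }
  if (length(vals) == 0) {
    return(tibble(cell = mask$id, mean_ratio = NA_real_, n_pixels = 0L,
                  excluded = TRUE, reason = "no defined ratio pixels"))
  }
  tibble(cell = mask$id, mean_ratio = mean(vals),
         n_pixels = length(vals), excluded = FALSE, reason = NA_character_)
}

#' Eroded-mask cytoplasmic intensity tracking
#'
#' Reproduces the cytoplasmic depletion readout used to quantify
#' membrane translocation: the segmentation mask of each cell is eroded by
#' `erosion_px` single-pixel passes (removing the membrane rim and its
#' neighbourhood), and the strictly positive dark-corrected pixels of the
#' tracking channel are averaged within the eroded core at every time
#' point. The series is normalised to its `t = 0` value, so the
#' "cytoplasmic intensity drop" is `1 - value`.
#'
#' Cells whose eroded core is empty (thinner than `2 * erosion_px + 1`
#' pixels) are flagged and omitted, with the reason recorded in the
#' `exclusions` attribute.
#'
#' @param movie A `pka_movie` (see [render_movie()]).
#' @param masks Masks from [threshold_segment()] on the first frame
#'   (cells are assumed stationary over the tracking window).
#' @param channel Tracking channel name (default `"mCherry"`).
#' @param erosion_px Erosion depth in pixels (default 20, i.e. 7.78 um at
#'   0.389 um/px).
#' @return A tibble with `cell`, `t_min`, `intensity`, `norm` (intensity /
#'   intensity at t = 0) and `drop` (`1 - norm`); excluded cells are
#'   listed in `attr(, "exclusions")`.
#' @export
cytoplasmic_intensity_series <- function(movie, masks, channel = "mCherry",
                                         erosion_px = 20L) {
  stopifnot(inherits(movie, "pka_movie"))
  if (erosion_px < 0) abort("`erosion_px` must be >= 0.")
  frames <- movie$channels[[channel]]
  if (is.null(frames)) abort(sprintf("movie has no channel '%s'", channel))
  dark <- movie$dark[[channel]] %||% 0
  excl <- character()
  rows <- list()
  for (m in masks) {
    core <- erode_mask(m$mask, erosion_px)
    if (!any(core)) {
      excl <- c(excl, sprintf("cell %d: eroded mask empty (cell too thin)", m$id))
      next
    }
    vals <- vapply(frames, function(fr) {
      px <- fr[core] - dark
      px <- px[px > 0]
      if (length(px) == 0) NA_real_ else mean(px)
    }, numeric(1))
    rows[[length(rows) + 1L]] <- tibble(
      cell = m$id, t_min = movie$t_min, intensity = vals,
      norm = vals / vals[1], drop = 1 - vals / vals[1]
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "exclusions") <- excl
  out
}

#' Nuclear-centroid migration tracking
#'
#' Identifies the nucleus in each frame of the nuclear-marker channel by
#' intensity thresholding within each cross-channel region of interest,
#' takes the centroid of the thresholded component, and reports the
#' y-displacement relative to `t = 0` (+y = toward the source side, i.e.
#' decreasing row index). Frames with no component above threshold are
#' flagged missing; no interpolation is performed. If a region contains
#' more than one component the largest is taken and the event is logged in
#' the `events` attribute.
#'
#' @param movie A `pka_movie`.
#' @param threshold Absolute intensity threshold for the nuclear marker.
#' @param regions List of column-index vectors, one per cross-channel ROI;
#'   defaults to the movie's own `regions`, or the whole frame.
#' @param channel Nuclear-marker channel (default `"CFP"`).
#' @param min_area Minimum nuclear component area (px).
#' @return A tibble with `cell`, `t_min`, `y_px`, `displacement_um`,
#'   `missing`; per-track events in `attr(, "events")`.
#' @export
nuclear_displacement <- function(movie, threshold, regions = NULL,
                                 channel = "CFP", min_area = 10L) {
  stopifnot(inherits(movie, "pka_movie"))
  frames <- movie$channels[[channel]]
  if (is.null(frames)) abort(sprintf("movie has no channel '%s'", channel))
  regions <- regions %||% movie$regions %||% list(seq_len(ncol(frames[[1]])))
  nr <- nrow(frames[[1]])
  events <- character()
  rows <- list()
  for (ci in seq_along(regions)) {
    cols <- regions[[ci]]
    y <- rep(NA_real_, length(frames))
    for (fi in seq_along(frames)) {
      sub <- frames[[fi]][, cols, drop = FALSE]
      lab <- label_components(sub > threshold)
      ids <- setdiff(unique(as.vector(lab)), 0L)
      ids <- ids[vapply(ids, function(i) sum(lab == i), integer(1)) >= min_area]
      if (length(ids) == 0) next
      if (length(ids) > 1) {
        areas <- vapply(ids, function(i) sum(lab == i), integer(1))
        ids <- ids[which.max(areas)]
        events <- c(events, sprintf(
          "cell %d frame %d: %s components, largest taken",
          ci, fi, length(areas)))
      }
      w <- which(lab == ids[1], arr.ind = TRUE)
      # +y toward the source side = decreasing row index
      y[fi] <- nr - mean(w[, 1])
    }
    rows[[ci]] <- tibble(
      cell = ci, t_min = movie$t_min, y_px = y,
      displacement_um = (y - y[1]) * movie$pixel_size,
      missing = is.na(y)
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "events") <- events
  out
}

#' Binned intracellular profile along the gradient axis
#'
#' Splits a cell's bounding extent along the gradient (row) axis into
#' `n_bins` equal-width bins and averages the defined ratio pixels in
#' each. Positions are normalised bin centres in \[0, 1\], with 0 at the
#' high-rapamycin (source-facing, top-row) end.
#'
#' @param map A ratio map from [fret_ratio_map()].
#' @param mask One mask from [threshold_segment()].
#' @param n_bins Number of bins (default 20).
#' @return A tibble of class `pka_binned_profile` with `bin`, `position`,
#'   `mean_ratio`, `n_pixels`, `empty`.
#' @export
bin_profile <- function(map, mask, n_bins = 20L) {
  rows_in <- which(apply(mask$mask, 1, any))
  extent <- max(rows_in) - min(rows_in) + 1L
  if (extent < n_bins) {
    abort(sprintf("mask extent along the gradient axis (%d px) is below n_bins (%d).",
                  extent, n_bins))
  }
  edges <- min(rows_in) + (extent) * (0:n_bins) / n_bins
  out <- purrr::map_dfr(seq_len(n_bins), function(b) {
    rr <- which(seq_len(nrow(mask$mask)) >= edges[b] &
                seq_len(nrow(mask$mask)) < edges[b + 1])
    if (b == n_bins) rr <- union(rr, max(rows_in))
    sel <- matrix(FALSE, nrow(mask$mask), ncol(mask$mask))
    sel[rr, ] <- TRUE
    vals <- map[sel & mask$mask]
    vals <- vals[is.finite(vals)]
    tibble(bin = b, position = (b - 0.5) / n_bins,
           mean_ratio = if (length(vals)) mean(vals) else NA_real_,
           n_pixels = length(vals), empty = length(vals) == 0L)
  })
  class(out) <- c("pka_binned_profile", class(out))
  out
}

#' @export
#' @method autoplot pka_binned_profile
autoplot.pka_binned_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$mean_ratio)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Normalised position (0 = high-rapamycin end)",
                  y = "FRET ratio") +
    ggplot2::theme_minimal()
}

#' Per-time population mean, SEM and two-group Student's t-test
#'
#' Computes per-time-point mean, SEM (sample SD with n-1 denominator over
#' sqrt(n)) and n across cells, per group when a grouping column is given,
#' and optionally a two-tailed pooled-variance Student's t-test between
#' two groups at a designated time point.
#'
#' @param df Data frame with columns `cell`, `t_min`, a value column, and
#'   optionally a group column.
#' @param value Name of the value column.
#' @param group Optional name of the grouping column (exactly two groups
#'   for the test).
#' @param test_at Optional time point (min) at which to run the t-test.
#' @return A list with `series` (tibble: group?, `t_min`, `mean`, `sem`,
#'   `n`) and `test` (one-row tibble or `NULL`). The test is refused
#'   (with a reason) when either group has fewer than 2 cells.
#' @export
population_stats <- function(df, value = "value", group = NULL,
                             test_at = NULL) {
  stopifnot(is.data.frame(df), "t_min" %in% names(df), value %in% names(df))
  gvars <- c(group, "t_min")
  series <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(gvars))) |>
    dplyr::summarise(
      mean = mean(.data[[value]], na.rm = TRUE),
      sem = stats::sd(.data[[value]], na.rm = TRUE) /
        sqrt(sum(is.finite(.data[[value]]))),
      n = sum(is.finite(.data[[value]])),
      .groups = "drop"
    )
  test <- NULL
  if (!is.null(test_at) && !is.null(group)) {
    at <- df[df$t_min == test_at, , drop = FALSE]
    gs <- unique(at[[group]])
    if (length(gs) != 2) abort("the t-test needs exactly two groups.")
    x <- at[[value]][at[[group]] == gs[1]]
    y <- at[[value]][at[[group]] == gs[2]]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) {
      test <- tibble(t_min = test_at, statistic = NA_real_, df = NA_real_,
                     p.value = NA_real_,
                     refused = TRUE, reason = "fewer than 2 cells in a group")
    } else {
      ht <- pooled_t_test(x, y)
      test <- tibble(t_min = test_at, statistic = ht$statistic,
                     df = ht$df, p.value = ht$p.value,
                     refused = FALSE, reason = NA_character_)
    }
  }
  list(series = series, test = test)
}

#' Two-tailed pooled-variance Student's t-test
#'
#' Thin wrapper around [stats::t.test()] with `var.equal = TRUE`,
#' returning a tidy one-row tibble.
#'
#' @param x,y Numeric vectors (each n >= 2).
#' @return Tibble with `statistic`, `df`, `p.value`, `mean_x`, `mean_y`.
#' @export
pooled_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("both groups need n >= 2.")
  dof <- length(x) + length(y) - 2
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    # degenerate zero-variance case: equal means give t = 0, p = 1
    t_stat <- if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf
    return(tibble(statistic = t_stat, df = dof,
                  p.value = if (t_stat == 0) 1 else 0,
                  mean_x = mean(x), mean_y = mean(y)))
  }
  ht <- t.test(x, y, var.equal = TRUE)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = ht$p.value, mean_x = mean(x), mean_y = mean(y))
}
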