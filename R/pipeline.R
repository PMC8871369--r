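#' Pipeline run configuration
#'
#' Collects everything a pipeline run needs -- the scenario, model
#' parameter overrides, analysis thresholds, output directory and seed --
#' into a fully serialisable object. Unknown keys are rejected up front so
#' that configuration typos fail before any computation.
#'
#' @param scenario_name Scenario kind (see [scenario()]).
#' @param scenario Named list of additional [scenario()] arguments
#'   (`n_cells`, `dose`, `c_source`, ...).
#' @param model Named list of model overrides: any of `K_C`, `K_A`,
#'   `alpha` ([prozone_params()]); `R_max`, `EC50`, `h`, `k_max`
#'   ([translocation_params()]); `DR`, `K_act` ([ratio_calibration()]);
#'   `R_basal`, `C_basal`, `A_tot`, `rho`.
#' @param analysis Named list: `segment_threshold`, `min_expression`,
#'   `erosion_px`, `nuclear_threshold`, `pixel_size`.
#' @param out_dir Output directory.
#' @param seed Integer seed for the run.
#' @return A list of class `pka_run_config`.
#' @export
run_config <- function(scenario_name, scenario = list(), model = list(),
                       analysis = list(), out_dir = tempfile("pka_run_"),
                       seed = 1L) {
  known_sc <- c("n_cells", "duration_min", "frame_interval_min", "dose",
                "c_source", "c_sink", "ramp_contrast", "noise", "pixel_size")
  known_model <- c("K_C", "K_A", "alpha", "R_max", "EC50", "h", "k_max",
                   "DR", "K_act", "R_basal", "C_basal", "A_tot", "rho",
                   "v0", "sigma_step", "p_up_init")
  known_an <- c("segment_threshold", "min_expression", "erosion_px",
                "nuclear_threshold", "pixel_size", "min_area")
  bad <- c(setdiff(names(scenario), known_sc),
           setdiff(names(model), known_model),
           setdiff(names(analysis), known_an))
  if (length(bad)) {
    abort(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  }
  structure(list(scenario_name = scenario_name, scenario = scenario,
                 model = model, analysis = analysis, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pka_run_config")
}

#' Read / write a run configuration as YAML
#'
#' The round trip `read_run_config(write_run_config(cfg))` is the
#' identity.
#'
#' @param cfg A [run_config()] object.
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a `pka_run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pka_run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  run_config(
    scenario_name = raw$scenario_name,
    scenario = raw$scenario %||% list(),
    model = raw$model %||% list(),
    analysis = raw$analysis %||% list(),
    out_dir = raw$out_dir %||% tempfile("pka_run_"),
    seed = raw$seed %||% 1L
  )
}

config_objects_ <- function(cfg) {
  m <- cfg$model
  take <- function(def, keys) {
    args <- m[intersect(names(m), keys)]
    if (length(args)) do.call(def, args) else def()
  }
  list(
    binding = take(prozone_params, c("K_C", "K_A", "alpha")),
    transloc = take(translocation_params, c("R_max", "EC50", "h", "k_max")),
    cal = take(ratio_calibration, c("DR", "K_act")),
    basal = compartment_totals(R_tot = m$R_basal %||% 0.1,
                               C_tot = m$C_basal %||% 0.1,
                               A_tot = m$A_tot %||% 1),
    rho = m$rho %||% 0.5,
    migration = take(migration_params, c("v0", "sigma_step", "p_up_init"))
  )
}

log_line_ <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(...))
  writeLines(msg, con)
  message(msg)
}

#' Run the full simulate-render-analyze-score pipeline
#'
#' Executes the stages appropriate for the configured scenario kind and
#' scores every analysis output against the generator's ground truth.
#' Stage failures are caught and recorded without aborting independent
#' stages; the run is idempotent for a fixed seed. All outputs (movie
#' TIFFs, ground truth JSON, series CSVs, the archived config and a
#' timestamped log) land in `cfg$out_dir`.
#'
#' Recovery metrics by scenario kind:
#' * `fsk_ibmx_saturating` -- recovered population-mean maximal ratio
#'   increase (percent) vs. the imposed dynamic range.
#' * `dish_uniform` -- per-cell depletion-curve fit: relative errors of
#'   the recovered rate `k` and plateau.
#' * `chip_gradient` / `chip_uniform` -- per-cell ratio-profile polarity
#'   sign vs. the imposed field; gradient slope recovered from the dye
#'   channel.
#' * `dmso_control`, `no_membrane_anchor_control` -- migration population
#'   series and monotonicity of the mean displacement.
#'
#' @param cfg A [run_config()] object.
#' @return A list of class `pka_run_report`: `stages` (tibble of
#'   stage/status/message), `metrics` (tibble of name/value), `outputs`
#'   (file manifest), `summaries` (list of tibbles).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pka_run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(cfg$out_dir, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)
  write_run_config(cfg, file.path(cfg$out_dir, "config.yaml"))
  log_line_(logf, "scenario=", cfg$scenario_name, " seed=", cfg$seed)

  obj <- config_objects_(cfg)
  sc <- do.call(scenario, c(list(name = cfg$scenario_name, seed = cfg$seed),
                            cfg$scenario))
  stages <- list(); metrics <- list(); outputs <- character()
  summaries <- list()
  stage <- function(name, fun) {
    res <- tryCatch(list(ok = TRUE, value = fun()),
                    error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
    stages[[length(stages) + 1L]] <<- tibble(
      stage = name, status = if (res$ok) "ok" else "error",
      message = if (res$ok) NA_character_ else res$msg
    )
    log_line_(logf, "stage ", name, ": ", if (res$ok) "ok" else res$msg)
    if (res$ok) res$value else NULL
  }
  add_metric <- function(name, value) {
    metrics[[length(metrics) + 1L]] <<- tibble(name = name, value = value)
  }

  migration_kind <- cfg$scenario_name %in%
    c("dmso_control", "no_membrane_anchor_control") ||
    (cfg$scenario_name %in% c("chip_gradient", "chip_uniform") &&
       isTRUE(cfg$scenario$migration))

  if (cfg$scenario_name %in% c("dmso_control", "no_membrane_anchor_control")) {
    sim <- stage("simulate_tracks", function() {
      make_migration_tracks(sc, obj$migration)
    })
    if (!is.null(sim)) {
      write.csv(sim$tracks, file.path(cfg$out_dir, "tracks.csv"),
                row.names = FALSE)
      write_ground_truth(sim$truth, file.path(cfg$out_dir, "ground_truth.json"))
      outputs <- c(outputs, "tracks.csv", "ground_truth.json")
      an <- stage("analyze_tracks", function() {
        population_stats(dplyr::rename(sim$tracks, value = "displacement_um"))
      })
      if (!is.null(an)) {
        summaries$displacement <- an$series
        final <- an$series[an$series$t_min == max(an$series$t_min), ]
        add_metric("final_mean_displacement_um", final$mean)
        add_metric("mean_displacement_monotone",
                   as.numeric(all(diff(an$series$mean) > 0)))
      }
    }
  } else {
    syn <- stage("render", function() {
      render_movie(sc, obj$cal, obj$transloc, obj$basal, obj$rho, obj$binding)
    })
    if (!is.null(syn)) {
      stage("write_outputs", function() {
        write_movie(syn$movie, file.path(cfg$out_dir, "movie"))
        write_ground_truth(syn$truth,
                           file.path(cfg$out_dir, "ground_truth.json"))
        TRUE
      })
      outputs <- c(outputs, "movie/", "ground_truth.json")
      thr <- cfg$analysis$segment_threshold %||% (sc$noise$dark + 250)

      if (cfg$scenario_name == "fsk_ibmx_saturating") {
        an <- stage("analyze_fret", function() {
          rs <- analyze_fret_movie(syn$movie, thr,
                                   min_expression = cfg$analysis$min_expression %||% 0)
          max_ratio_increase(rs)
        })
        if (!is.null(an)) {
          write.csv(an, file.path(cfg$out_dir, "max_ratio_increase.csv"),
                    row.names = FALSE)
          outputs <- c(outputs, "max_ratio_increase.csv")
          summaries$max_increase <- an
          rec <- mean(an$max_increase_pct)
          add_metric("recovered_dynamic_range_pct", rec)
          add_metric("imposed_dynamic_range_pct",
                     syn$truth$max_ratio_increase_pct)
          add_metric("dynamic_range_abs_error_pp",
                     abs(rec - syn$truth$max_ratio_increase_pct))
        }
      } else if (cfg$scenario_name == "dish_uniform") {
        an <- stage("analyze_depletion", function() {
          masks <- threshold_segment(syn$movie$channels$YFP[[1]], thr)
          cytoplasmic_intensity_series(syn$movie, masks,
                                       erosion_px = cfg$analysis$erosion_px %||% 20L)
        })
        if (!is.null(an)) {
          write.csv(an, file.path(cfg$out_dir, "cytoplasmic_series.csv"),
                    row.names = FALSE)
          outputs <- c(outputs, "cytoplasmic_series.csv")
          summaries$depletion <- an
          fits <- stage("fit_depletion", function() {
            an |>
              dplyr::group_by(.data$cell) |>
              dplyr::group_modify(~ glance(fit_depletion(.x))) |>
              dplyr::ungroup()
          })
          if (!is.null(fits)) {
            add_metric("median_k_rel_error",
                       stats::median(abs(fits$k - syn$truth$k) / syn$truth$k))
            add_metric("median_plateau_rel_error",
                       stats::median(abs(fits$plateau - syn$truth$plateau_drop) /
                                       syn$truth$plateau_drop))
          }
        }
      } else if (cfg$scenario_name %in% c("chip_gradient", "chip_uniform",
                                          "chip_ramp")) {
        an <- stage("profile_cells", function() {
          profile_chip_movie(syn$movie, thr)
        })
        if (!is.null(an)) {
          write.csv(an, file.path(cfg$out_dir, "bin_profiles.csv"),
                    row.names = FALSE)
          outputs <- c(outputs, "bin_profiles.csv")
          summaries$profiles <- an
          summaries$polarity <- attr(an, "polarity")
        }
        if (cfg$scenario_name != "chip_ramp") {
          slope <- stage("dye_gradient", function() {
            recover_dye_slope(syn$movie, syn$truth)
          })
          if (!is.null(slope)) {
            add_metric("dye_slope_nM_per_um", slope)
            add_metric("imposed_slope_nM_per_um", syn$truth$slope_nM_per_um)
          }
        }
      }
    }
  }

  report <- structure(list(
    stages = dplyr::bind_rows(stages),
    metrics = if (length(metrics)) dplyr::bind_rows(metrics) else
      tibble(name = character(), value = numeric()),
    outputs = outputs, summaries = summaries,
    config = cfg
  ), class = "pka_run_report")
  jsonlite::write_json(
    list(stages = report$stages, metrics = report$metrics,
         outputs = outputs),
    file.path(cfg$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  report
}

#' Recover the gradient slope from a chip movie's dye channel
#'
#' Fits the lane-interior dye intensity against image row, converts the
#' intensity slope to nM/um using the generator's intensity-to-
#' concentration calibration (gain counts/nM), and returns the recovered
#' slope with the sign convention positive-toward-source.
#'
#' @param movie A chip `pka_movie` with a `dye` channel.
#' @param truth Ground-truth record carrying `dye_gain_per_nM`.
#' @param frame Frame index (default 1).
#' @return Recovered slope (nM/um).
#' @export
recover_dye_slope <- function(movie, truth, frame = 1L) {
  dye <- movie$channels$dye[[frame]]
  cols <- unlist(movie$regions)
  dark <- movie$dark[["dye"]] %||% 0
  row_means <- rowMeans(dye[, cols, drop = FALSE]) - dark
  y_um <- (nrow(dye) - seq_len(nrow(dye))) * movie$pixel_size
  fit <- stats::lm(row_means ~ y_um)
  unname(coef(fit)[2]) / truth$dye_gain_per_nM
}

#' @export
#' @method tidy pka_run_report
tidy.pka_run_report <- function(x, ...) {
  x$metrics
}

#' @export
#' @method print pka_run_report
print.pka_run_report <- function(x, ...) {
  cat("pipeline run:", x$config$scenario_name, "seed", x$config$seed, "\n")
  print(x$stages)
  if (nrow(x$metrics)) print(x$metrics)
  invisible(x)
}
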