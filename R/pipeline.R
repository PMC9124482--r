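#' Flume configuration
#'
#' Bundles the constants of the recirculating flume and the analysis
#' options: volume, test-section cross-section, circuit length (anchored by
#' the study's frame counts), fluid defaults and the quantile convention for
#' the feeding-area radius.
#'
#' @param volume_m3 Flume volume (m^3).
#' @param cross_section_m Test-section width and height (m).
#' @param circuit_length_m Circuit length (m), see [cycle_time()].
#' @param rho_w,nu Fluid constants, see [fluid_context()].
#' @param body_diameter_m Cylinder diameter for the drag model (m).
#' @param quantile_type Quantile convention for [quartile3()].
#' @param min_confidence 2D-observation confidence cutoff.
#' @param fps Video frame rate (s^-1).
#' @return A named list of class `flume_config`.
#' @export
flume_config <- function(volume_m3 = 1.24, cross_section_m = c(0.30, 0.30),
                         circuit_length_m = circuit_length_from_anchor(),
                         rho_w = 1025, nu = 9.7e-7, body_diameter_m = 0.005,
                         quantile_type = 7, min_confidence = 0.6, fps = 60) {
  stopifnot(volume_m3 > 0, all(cross_section_m > 0), circuit_length_m > 0,
            fps > 0)
  structure(
    list(volume_m3 = volume_m3, cross_section_m = cross_section_m,
         circuit_length_m = circuit_length_m, rho_w = rho_w, nu = nu,
         body_diameter_m = body_diameter_m, quantile_type = quantile_type,
         min_confidence = min_confidence, fps = fps),
    class = "flume_config"
  )
}

#' Reconstruct a 3D track from observation files or tibbles
#'
#' Stage one of the pipeline: reads 2D observations (any mix of tibbles and
#' file paths in either CSV dialect) and DLT coefficients, triangulates
#' every point seen by at least two cameras, and optionally writes the 3D
#' track plus a provenance record.
#'
#' @param obs Observation tibble, a path, or a list of either (concatenated).
#' @param cams Named list of [camera_dlt()] or a coefficient-file path.
#' @param config A [flume_config()].
#' @param out_dir Optional output directory; writes `track3d.csv` and
#'   `provenance.json`.
#' @param units Input units of any 3D content, `"m"` or `"cm"`.
#' @param seed Recorded in the provenance (reconstruction is deterministic).
#' @return The reconstructed track tibble (see [reconstruct_track()]).
#' @export
run_reconstruct <- function(obs, cams, config = flume_config(),
                            out_dir = NULL, units = "m", seed = NULL) {
  if (is.character(cams)) cams <- read_dlt_coefficients(cams)
  if (!is.list(obs) || is.data.frame(obs)) obs <- list(obs)
  obs_tbl <- purrr::map_dfr(obs, function(o) {
    if (is.character(o)) read_observations_2d(o) else tibble::as_tibble(o)
  })
  track <- reconstruct_track(obs_tbl, cams,
                             min_confidence = config$min_confidence)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_track_3d(track, file.path(out_dir, "track3d.csv"))
    write_provenance(file.path(out_dir, "provenance.json"),
                     stage = "reconstruct", config = config, seed = seed)
  }
  track
}

#' Run the full foraging analysis on a reconstructed track
#'
#' Stage two: from a 3D track, strike annotations and a trial table,
#' computes per-strike kinematics ([strike_metrics()]), the VeDBA series
#' and its temporal mean, the per-frame length out of the burrow and its
#' third quartile, per-trial control-corrected feeding rates and the
#' feeding-area model predictions, plus a per-eel summary (mean +/- s.d.)
#' in the style the flume study reports.
#'
#' @param track 3D track tibble (`frame`, `label`, `x_m`, `y_m`, `z_m`).
#' @param strikes Strike annotation tibble (see [read_strikes()]); must
#'   carry the trial flow speed in `U_mps` unless `U` is given.
#' @param trials Trial table (see [read_trials()]); optional.
#' @param U Single flow speed overriding a `U_mps` column.
#' @param config A [flume_config()].
#' @param fps Frame rate of the track; must equal `config$fps`.
#' @param out_dir Optional output directory for the metrics CSVs and
#'   provenance record.
#' @param seed Recorded in provenance.
#' @return List of tibbles: `strike_metrics`, `vedba` (series),
#'   `vedba_mean`, `lengths` (per-frame), `length_q3`, `trial_rates`,
#'   `summary`.
#' @export
run_analyze <- function(track, strikes = NULL, trials = NULL, U = NULL,
                        config = flume_config(), fps = config$fps,
                        out_dir = NULL, seed = NULL) {
  if (!isTRUE(all.equal(fps, config$fps))) {
    stop("fps mismatch: track at ", fps, " Hz but configuration expects ",
         config$fps, " Hz", call. = FALSE)
  }
  track <- tibble::as_tibble(track)

  # per-frame polyline length out of the burrow, labels in body order
  order_labels <- intersect(c("base", paste0("body", 1:7), "spot1", "eye"),
                            unique(track$label))
  lengths <- track |>
    dplyr::filter(.data$label %in% order_labels) |>
    dplyr::mutate(label = factor(.data$label, levels = order_labels)) |>
    dplyr::arrange(.data$frame, .data$label) |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(
      length_m = if (dplyr::n() >= 3) {
        length_out_of_burrow(cbind(.data$x_m, .data$y_m, .data$z_m))
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  if (all(is.na(lengths$length_m))) {
    rlang::inform(paste("insufficient points per frame (< 3) to measure",
                        "length out of the burrow"))
  }
  q3 <- if (any(!is.na(lengths$length_m))) {
    quartile3(lengths$length_m[!is.na(lengths$length_m)],
              type = config$quantile_type)
  } else {
    NA_real_
  }

  vedba <- vedba_series(track, fps = fps)

  sm <- NULL
  if (!is.null(strikes) && nrow(strikes)) {
    strikes <- tibble::as_tibble(strikes)
    if (is.null(U)) {
      if (!"U_mps" %in% names(strikes)) {
        stop("strike table needs a `U_mps` column or a `U` argument",
             call. = FALSE)
      }
      sm <- strikes |>
        dplyr::group_by(.data$U_mps) |>
        dplyr::group_modify(~ strike_metrics(.x, .y$U_mps)) |>
        dplyr::ungroup()
    } else {
      sm <- strike_metrics(strikes, U)
    }
  } else {
    sm <- strike_metrics(
      tibble::tibble(t_init_s = numeric(), t_capture_s = numeric(),
                     eye_init_x = numeric(), eye_init_y = numeric(),
                     eye_init_z = numeric(), eye_capture_x = numeric(),
                     eye_capture_y = numeric(), eye_capture_z = numeric(),
                     prey_x = numeric(), prey_y = numeric(),
                     prey_z = numeric()),
      if (is.null(U)) 0 else U)
  }

  trial_rates <- NULL
  if (!is.null(trials) && nrow(trials)) {
    trials <- tibble::as_tibble(trials)
    rates <- trial_feeding_rate(trials$released, trials$recovered,
                                trials$U_mps, trials$control_loss_fraction,
                                circuit_length = config$circuit_length_m)
    preds <- model_feeding_rate(trials$rho_per_m3, trials$U_mps,
                                if (is.na(q3)) 0 else q3)
    trial_rates <- dplyr::bind_cols(
      trials[c("eel_id", "U_mps", "rho_per_m3")],
      rates[c("captured_adjusted", "cycle_time_s", "rate_per_min", "clamped")],
      tibble::tibble(model_F_per_min = preds$F_per_min)
    )
  }

  summary <- NULL
  if (!is.null(trial_rates)) {
    summary <- trial_rates |>
      dplyr::group_by(.data$eel_id) |>
      dplyr::summarise(
        mean_rate_per_min = mean(.data$rate_per_min),
        sd_rate_per_min = stats::sd(.data$rate_per_min),
        n_trials = dplyr::n(), .groups = "drop"
      )
  }

  out <- list(strike_metrics = sm, vedba = vedba,
              vedba_mean = mean_vedba(vedba), lengths = lengths,
              length_q3 = q3, trial_rates = trial_rates, summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(sm, file.path(out_dir, "strike_metrics.csv"))
    readr::write_csv(tibble::as_tibble(vedba), file.path(out_dir, "vedba.csv"))
    readr::write_csv(lengths, file.path(out_dir, "lengths.csv"))
    if (!is.null(trial_rates)) {
      readr::write_csv(trial_rates, file.path(out_dir, "trial_rates.csv"))
    }
    write_provenance(file.path(out_dir, "provenance.json"),
                     stage = "analyze", config = config, seed = seed)
  }
  out
}

write_provenance <- function(path, stage, config, seed = NULL) {
  jsonlite::write_json(
    list(stage = stage, seed = seed,
         config_hash = rlang::hash(config),
         config = unclass(config),
         package_version = as.character(utils::packageVersion("gardeneel")),
         r_version = as.character(getRversion()),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
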