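#' Eye-position views of a track
#'
#' Top (x-y) and side (x-z) scatter of a body point about the burrow
#' origin, the diagnostic used to visualise how far an eel extends and
#' sways under a given flow.
#'
#' @param track 3D track tibble.
#' @param label Body-point label (default `"eye"`).
#' @return A ggplot object with one panel per view.
#' @export
plot_eye_positions <- function(track, label = "eye") {
  sub <- dplyr::filter(tibble::as_tibble(track), .data$label == !!label)
  long <- dplyr::bind_rows(
    tibble::tibble(view = "top (x-y)", h = sub$x_m, v = sub$y_m),
    tibble::tibble(view = "side (x-z)", h = sub$x_m, v = sub$z_m)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$h, y = .data$v)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.5) +
    ggplot2::facet_wrap(~view) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x, upstream + (m)", y = "y / z (m)",
                  title = paste0("'", label, "' positions about the burrow"))
}

#' @exportS3Method ggplot2::autoplot
autoplot.vedba_series <- function(object, ...) {
  fps <- attr(object, "fps")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$frame / fps, y = .data$vedba)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = attr(object, "mean_vedba"),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "time (s)", y = expression(VeDBA~(m~s^-2)),
                  title = "Vectorial dynamic body acceleration")
}

#' @exportS3Method ggplot2::autoplot
autoplot.drag_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = factor(.data$segment), y = .data$force_N)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "segment (burrow to snout)", y = "drag force (N)",
                  title = paste0("Per-segment drag, scenario '",
                                 attr(object, "scenario"), "', U = ",
                                 attr(object, "U"), " m/s"))
}

#' Feeding-rate model against trial observations
#'
#' Observed per-trial feeding rates (points) with the semicircular
#' feeding-area model prediction (line) as a function of prey density.
#'
#' @param trial_rates Tibble from [run_analyze()]'s `trial_rates` (columns
#'   `rho_per_m3`, `U_mps`, `rate_per_min`, `model_F_per_min`).
#' @return A ggplot object faceted by flow speed.
#' @export
plot_feeding_model <- function(trial_rates) {
  ggplot2::ggplot(trial_rates, ggplot2::aes(x = .data$rho_per_m3)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$rate_per_min)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$model_F_per_min),
                       colour = "red") +
    ggplot2::facet_wrap(~U_mps, labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(prey~density~(m^-3)),
                  y = expression(feeding~rate~(min^-1)),
                  title = "Semicircular feeding-area model vs trials")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
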