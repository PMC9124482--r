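#' Holling disk equation (type II functional response)
#'
#' Feeding rate as a function of prey density,
#' \deqn{F = \frac{a\rho}{1 + a\rho h},}
#' with attack rate `a` (m^3 s^-1), prey density `rho` (m^-3) and handling
#' time `h` (s). Linear in density when handling time is negligible;
#' saturates at 1/h at high density.
#'
#' @param rho Prey density (m^-3), >= 0. Vectorised.
#' @param a Attack rate (m^3 s^-1), >= 0.
#' @param h Handling time (s), >= 0.
#' @return Feeding rate (prey s^-1).
#' @examples
#' disk_equation(1000, a = 0.001, h = 0.5) # 2/3
#' @export
disk_equation <- function(rho, a, h) {
  stopifnot(all(rho >= 0), a >= 0, h >= 0)
  a * rho / (1 + a * rho * h)
}

#' Fit the disk equation to density-rate observations
#'
#' Nonlinear least squares for (a, h) with the handling time bounded at
#' zero. Feeding systems observed only in the linear regime leave h nearly
#' unidentifiable; the fit then sits on the h = 0 boundary and `glance()`
#' reports `boundary_h = TRUE`.
#'
#' @param data Data frame with prey density and feeding-rate columns.
#' @param rho,rate Column names (tidy-eval) of density (m^-3) and rate
#'   (s^-1).
#' @return A `disk_fit` object with [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
fit_disk_equation <- function(data, rho = "rho", rate = "rate") {
  df <- tibble::tibble(rho = data[[rho]], rate = data[[rate]])
  stopifnot(nrow(df) >= 2)
  a0 <- max(stats::coef(stats::lm(rate ~ rho + 0, data = df))[[1]], 1e-12)
  fit <- tryCatch(
    stats::nls(rate ~ a * rho / (1 + a * rho * h), data = df,
               start = list(a = a0, h = 1e-3),
               lower = c(a = 0, h = 0), algorithm = "port",
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    est <- c(a = a0, h = 0)
    resid <- df$rate - disk_equation(df$rho, a0, 0)
    se <- c(a = NA_real_, h = NA_real_)
    linear_fallback <- TRUE
  } else {
    est <- stats::coef(fit)
    se_try <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) {
      c(a = NA_real_, h = NA_real_)
    })
    se <- se_try[names(est)]
    resid <- stats::residuals(fit)
    linear_fallback <- FALSE
  }
  structure(
    list(estimate = est, std_error = se, residuals = as.numeric(resid),
         data = df, linear_fallback = linear_fallback),
    class = "disk_fit"
  )
}

#' @export
print.disk_fit <- function(x, ...) {
  cat("<disk_fit> a =", signif(x$estimate[["a"]], 5), "m^3 s^-1, h =",
      signif(x$estimate[["h"]], 5), "s\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.disk_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "h"),
                 estimate = unname(x$estimate[c("a", "h")]),
                 std.error = unname(x$std_error[c("a", "h")]))
}

#' @exportS3Method generics::glance
glance.disk_fit <- function(x, ...) {
  tibble::tibble(
    nobs = nrow(x$data),
    sigma = sqrt(mean(x$residuals^2)),
    boundary_h = x$estimate[["h"]] <= 1e-8,
    linear_fallback = x$linear_fallback
  )
}

#' Prey flux
#'
#' Prey passing per unit cross-sectional area per unit time: the product of
#' prey density and flow speed, P = rho * U (m^-2 s^-1).
#'
#' @param rho Prey density (m^-3), >= 0.
#' @param U Flow speed (m s^-1), >= 0.
#' @return Prey flux (m^-2 s^-1).
#' @export
prey_flux <- function(rho, U) {
  stopifnot(all(rho >= 0), all(U >= 0))
  rho * U
}

#' Semicircular feeding-area model prediction
#'
#' The anchored eel is assumed to capture all prey crossing a semicircular
#' area in the cross-flow (y-z) plane, flat side on the sand bed, whose
#' radius is the third quartile L of the body length out of the burrow:
#' \deqn{F = P \cdot \frac{\pi L^2}{2}, \qquad P = \rho U,}
#' reported per minute.
#'
#' @param rho Prey density (m^-3).
#' @param U Flow speed (m s^-1).
#' @param L Feeding-area radius: Q3 of length out of the burrow (m).
#' @return Tibble with `rho_per_m3`, `U_mps`, `L_m`, `prey_flux_per_m2s`,
#'   `area_m2` (pi L^2 / 2) and `F_per_min` (nauplii min^-1). Vectorised
#'   over its arguments.
#' @examples
#' model_feeding_rate(1000, 0.10, 0.10)$F_per_min # 94.25
#' @export
model_feeding_rate <- function(rho, U, L) {
  stopifnot(all(L >= 0))
  P <- prey_flux(rho, U)
  area <- pi * L^2 / 2
  tibble::tibble(rho_per_m3 = rho, U_mps = U, L_m = L,
                 prey_flux_per_m2s = P, area_m2 = area,
                 F_per_min = 60 * P * area)
}

#' Flume water-cycle timing
#'
#' One water cycle is the time for water to circulate once around the
#' recirculating flume at the mean flow speed; each trial lasts exactly one
#' cycle, so faster flows give shorter trials. The effective circuit length
#' can be given directly or anchored by a known frame count: with
#' `frames0` video frames covering `n_trials` trials at speed `U0` and
#' `fps`, circuit_length = U0 * frames0 / (n_trials * fps).
#'
#' @param U Flow speed (m s^-1), > 0.
#' @param circuit_length Flume circuit length (m); default anchored at the
#'   study's 6720 frames for two trials at 0.10 m s^-1 and 60 fps (5.6 m).
#' @return Cycle time (s).
#' @export
cycle_time <- function(U, circuit_length = circuit_length_from_anchor()) {
  if (any(U <= 0)) stop("flow speed must be positive for cycle timing",
                        call. = FALSE)
  circuit_length / U
}

#' @param U0,frames0,n_trials,fps Anchor: frame count `frames0` spanning
#'   `n_trials` full trials at speed `U0` and frame rate `fps`.
#' @rdname cycle_time
#' @export
circuit_length_from_anchor <- function(U0 = 0.10, frames0 = 6720,
                                       n_trials = 2, fps = 60) {
  stopifnot(U0 > 0, frames0 > 0, n_trials > 0, fps > 0)
  U0 * frames0 / (n_trials * fps)
}

#' @param n_trials Number of consecutive trials covered.
#' @param fps Video frame rate (s^-1).
#' @rdname cycle_time
#' @return `frames_for_trials()`: integer frame count (rounded half to
#'   even).
#' @export
frames_for_trials <- function(U, n_trials = 2, fps = 60,
                              circuit_length = circuit_length_from_anchor()) {
  round(n_trials * fps * cycle_time(U, circuit_length))
}

#' Number of prey released for a target density
#'
#' @param rho Target prey density (m^-3).
#' @param volume Flume volume (m^3), 1.24 for the study flume.
#' @return Integer count, `round(rho * volume)`.
#' @export
released_count <- function(rho, volume = 1.24) {
  stopifnot(all(rho >= 0), all(volume >= 0))
  round(rho * volume)
}

#' Feeding rate from trial counts
#'
#' Captures are estimated as released minus recovered, corrected by the
#' mean control loss (fraction of released prey lost with no eel present,
#' <= 5% in the study's controls) and divided by the trial duration of one
#' water cycle. Corrections driving the estimate negative clamp to zero
#' with a warning.
#'
#' @param released,recovered Prey counts (recovered <= released).
#' @param U Flow speed (m s^-1) for the cycle time.
#' @param control_loss_fraction Fraction of released prey lost in controls.
#' @param circuit_length Flume circuit length (m), see [cycle_time()].
#' @return Tibble with `captured_raw`, `captured_adjusted`,
#'   `cycle_time_s`, `rate_per_min` (nauplii min^-1), `clamped`.
#' @export
trial_feeding_rate <- function(released, recovered, U,
                               control_loss_fraction = 0,
                               circuit_length = circuit_length_from_anchor()) {
  stopifnot(all(recovered >= 0), all(control_loss_fraction >= 0),
            all(control_loss_fraction <= 1))
  if (any(recovered > released)) {
    stop("recovered count exceeds released count", call. = FALSE)
  }
  raw <- released - recovered
  adj <- raw - control_loss_fraction * released
  clamped <- adj < 0
  if (any(clamped)) {
    rlang::warn(paste0(sum(clamped), " trial(s) clamped to zero captures: ",
                       "control-loss correction exceeded apparent captures"))
  }
  adj <- pmax(0, adj)
  ct <- cycle_time(U, circuit_length)
  tibble::tibble(released = released, recovered = recovered,
                 captured_raw = raw, captured_adjusted = adj,
                 cycle_time_s = ct, rate_per_min = adj / (ct / 60),
                 clamped = clamped)
}

#' The study's crossed experimental designs
#'
#' Design I crosses 5 eels x 5 prey densities (100, 200, 300, 600,
#' 1000 m^-3) x 2 flow speeds (0.10, 0.20 m s^-1) x 2 replicates; design II
#' crosses the same 5 eels x 4 flow speeds (0.10-0.25 m s^-1) x 2 densities
#' (300, 1000 m^-3) x 2 replicates, for 180 trials in total.
#'
#' @param design `"I"`, `"II"` or `"both"`.
#' @return Tibble with columns `design`, `eel_id`, `rho_per_m3`, `U_mps`,
#'   `replicate`, one row per trial.
#' @export
study_design <- function(design = c("both", "I", "II")) {
  design <- match.arg(design)
  eels <- LETTERS[1:5]
  d1 <- tidyr::expand_grid(design = "I", eel_id = eels,
                           rho_per_m3 = c(100, 200, 300, 600, 1000),
                           U_mps = c(0.10, 0.20), replicate = 1:2)
  d2 <- tidyr::expand_grid(design = "II", eel_id = eels,
                           rho_per_m3 = c(300, 1000),
                           U_mps = c(0.10, 0.15, 0.20, 0.25), replicate = 1:2)
  switch(design, I = d1, II = d2, both = dplyr::bind_rows(d1, d2))
}
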