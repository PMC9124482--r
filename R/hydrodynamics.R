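#' Fluid context for drag estimation
#'
#' Free-stream conditions used by the cylinder drag model. Defaults are
#' seawater at 25 degrees C: density 1025 kg m^-3, kinematic viscosity
#' 9.7e-7 m^2 s^-1. The flow is directed along -x (downstream) in flume
#' coordinates.
#'
#' @param U Free-stream speed (m s^-1), >= 0.
#' @param rho_w Water density (kg m^-3).
#' @param nu Kinematic viscosity (m^2 s^-1).
#' @return A `fluid_context` list.
#' @export
fluid_context <- function(U, rho_w = 1025, nu = 9.7e-7) {
  stopifnot(U >= 0, rho_w > 0, nu > 0)
  structure(list(U = U, rho_w = rho_w, nu = nu), class = "fluid_context")
}

#' Split a body polyline into cylindrical segments
#'
#' Consecutive polyline points become segments; with `n_segments` set, the
#' polyline is first resampled to arc-length-uniform vertices so the body is
#' divided into that many equal-length segments (the study used seven or
#' eight from six or seven manual points). Segment lengths are measured
#' along the body, so resampling preserves the total arc length exactly;
#' the chord between resampled vertices defines each segment's axis.
#'
#' @param polyline n x 3 matrix/data frame of ordered body points (m),
#'   burrow first.
#' @param n_segments Optional number of equal segments to resample to
#'   (1-12).
#' @param diameter Cylinder diameter (m); the study's eels are treated as
#'   0.5 cm cylinders.
#' @return A `segmented_body`: list with `start`, `end` (matrices),
#'   `lengths` (m), `diameter`.
#' @export
segment_body <- function(polyline, n_segments = NULL, diameter = 0.005) {
  P <- as_point_matrix(polyline)
  if (nrow(P) < 2L) stop("a body polyline needs >= 2 points", call. = FALSE)
  stopifnot(diameter > 0)
  arc_len <- NULL
  if (!is.null(n_segments)) {
    stopifnot(n_segments >= 1, n_segments <= 12)
    total <- sum(sqrt(rowSums(diff(P)^2)))
    P <- resample_polyline(P, n_segments + 1L)
    arc_len <- rep(total / n_segments, n_segments)
  }
  seg_len <- sqrt(rowSums(diff(P)^2))
  if (any(seg_len <= 0)) {
    stop("zero-length segment: repeated consecutive points", call. = FALSE)
  }
  if (!is.null(arc_len)) seg_len <- arc_len
  if (length(seg_len) > 12L) {
    stop("at most 12 segments are supported; resample with `n_segments`",
         call. = FALSE)
  }
  structure(
    list(start = P[-nrow(P), , drop = FALSE], end = P[-1, , drop = FALSE],
         lengths = seg_len, diameter = diameter),
    class = "segmented_body"
  )
}

#' @export
print.segmented_body <- function(x, ...) {
  cat("<segmented_body> ", length(x$lengths), " segments, arc length ",
      signif(sum(x$lengths), 5), " m, diameter ", x$diameter, " m\n", sep = "")
  invisible(x)
}

# arc-length-uniform resampling preserving total length
resample_polyline <- function(P, n_points) {
  s <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  target <- seq(0, s[length(s)], length.out = n_points)
  out <- vapply(seq_len(3), function(j) stats::approx(s, P[, j], xout = target,
                                                      ties = "ordered")$y,
                numeric(n_points))
  out
}

#' Drag coefficient of a smooth cylinder in cross-flow
#'
#' Subcritical smooth-cylinder correlation
#' \deqn{C_d(Re) = 1 + 10 \, Re^{-2/3},}
#' monotone decreasing toward 1 at high Reynolds number. Valid below the
#' drag crisis (Re < 2e5); larger Re warns. A different correlation can be
#' supplied as a function of Re.
#'
#' @param Re Reynolds number(s), > 0.
#' @param correlation Function of Re returning Cd; defaults to the built-in
#'   correlation.
#' @return Cd, dimensionless.
#' @examples
#' cylinder_cd(1000) # 1.1
#' @export
cylinder_cd <- function(Re, correlation = NULL) {
  if (any(Re <= 0)) stop("Reynolds number must be positive", call. = FALSE)
  if (any(Re > 2e5)) {
    rlang::warn("Re > 2e5: beyond the subcritical validity of the correlation")
  }
  if (is.null(correlation)) 1 + 10 * Re^(-2 / 3) else correlation(Re)
}

#' Drag force on one cylindrical segment
#'
#' Cross-flow principle: only the flow component normal to the segment axis
#' generates pressure drag; skin friction of the axial component is
#' neglected. With normal speed \eqn{U_n = U \sin\theta} (\eqn{\theta} the
#' angle between segment axis and flow direction),
#' \eqn{Re = U_n d / \nu} and
#' \deqn{F = \tfrac12 \rho_w C_d(Re) \, d\,l \, U_n^2,}
#' which is zero for a segment parallel to the flow.
#'
#' @param start,end Segment endpoints (m).
#' @param diameter Cylinder diameter (m).
#' @param fluid A [fluid_context()].
#' @param correlation Optional Cd(Re) function, see [cylinder_cd()].
#' @return Drag force (N).
#' @export
segment_drag <- function(start, end, diameter, fluid, correlation = NULL) {
  axis <- as.numeric(end) - as.numeric(start)
  l <- sqrt(sum(axis^2))
  if (l <= 0) stop("zero-length segment", call. = FALSE)
  if (fluid$U == 0) return(0)
  # flow along -x; sin(theta) is invariant to the sign of the flow axis
  cos_th <- abs(axis[1]) / l
  sin_th <- sqrt(max(0, 1 - cos_th^2))
  U_n <- fluid$U * sin_th
  if (U_n < 1e-15) return(0)
  Re <- U_n * diameter / fluid$nu
  0.5 * fluid$rho_w * cylinder_cd(Re, correlation) * diameter * l * U_n^2
}

#' Whole-body drag and drag coefficient
#'
#' Sums [segment_drag()] over all segments of a [segment_body()] and
#' normalises to a whole-body drag coefficient
#' \deqn{C_{d,\mathrm{body}} = \frac{2 F_\mathrm{total}}{\rho_w U^2 A_\mathrm{ref}},}
#' with reference area `A_ref = diameter x total arc length` by default
#' (so a straight body perpendicular to the flow recovers the single-cylinder
#' Cd exactly), or the projected frontal area (diameter x length normal to
#' the flow) with `reference = "frontal"`. At U = 0 total force is 0 and the
#' coefficient is undefined (NA, flagged).
#'
#' @param body A `segmented_body`.
#' @param fluid A [fluid_context()].
#' @param scenario Label recorded in the result (`"actual"`,
#'   `"fixed_posture_and_length"`, `"shortened_straight"`).
#' @param reference `"wetted"` (d x arc length) or `"frontal"`.
#' @param correlation Optional Cd(Re) function.
#' @return A `drag_result`: tibble of per-segment forces with attributes
#'   `total_force_N`, `body_cd`, `reference_area_m2`, `scenario`, `U`;
#'   accessors [total_drag()] and [body_cd()].
#' @export
body_drag <- function(body, fluid, scenario = "actual",
                      reference = c("wetted", "frontal"), correlation = NULL) {
  stopifnot(inherits(body, "segmented_body"), inherits(fluid, "fluid_context"))
  reference <- match.arg(reference)
  n <- length(body$lengths)
  F_seg <- vapply(seq_len(n), function(i) {
    segment_drag(body$start[i, ], body$end[i, ], body$diameter, fluid,
                 correlation)
  }, numeric(1))
  total <- sum(F_seg)
  arc <- sum(body$lengths)
  A_ref <- if (reference == "wetted") {
    body$diameter * arc
  } else {
    axis <- body$end - body$start
    sin_th <- sqrt(pmax(0, 1 - (abs(axis[, 1]) / body$lengths)^2))
    body$diameter * sum(body$lengths * sin_th)
  }
  cd <- if (fluid$U > 0 && A_ref > 0) {
    2 * total / (fluid$rho_w * fluid$U^2 * A_ref)
  } else {
    NA_real_
  }
  if (is.na(cd)) {
    rlang::inform("body_cd undefined at U = 0 (or zero reference area)")
  }
  out <- tibble::tibble(segment = seq_len(n), length_m = body$lengths,
                        force_N = F_seg)
  attr(out, "total_force_N") <- total
  attr(out, "body_cd") <- cd
  attr(out, "reference_area_m2") <- A_ref
  attr(out, "scenario") <- scenario
  attr(out, "U") <- fluid$U
  class(out) <- c("drag_result", class(out))
  out
}

#' @export
print.drag_result <- function(x, ...) {
  NextMethod()
  cat("# scenario: ", attr(x, "scenario"), ", U = ", attr(x, "U"),
      " m s^-1, total = ", signif(attr(x, "total_force_N"), 5),
      " N, body Cd = ", signif(attr(x, "body_cd"), 5), "\n", sep = "")
  invisible(x)
}

#' @rdname body_drag
#' @param x A `drag_result`.
#' @export
total_drag <- function(x) attr(x, "total_force_N")

#' @rdname body_drag
#' @export
body_cd <- function(x) attr(x, "body_cd")

#' Counterfactual posture scenarios
#'
#' Transforms the posture observed at low flow speed into the two
#' counterfactuals evaluated at high flow: scenario
#' `"fixed_posture_and_length"` keeps the low-speed geometry unchanged (the
#' eel neither bends nor shortens), and `"shortened_straight"` replaces the
#' body with a straight one of the length actually observed at the high
#' speed, oriented along the low-speed body's mean axis (burrow to snout
#' direction; falls back to vertical when degenerate) or vertically with
#' `orientation = "vertical"`.
#'
#' @param body_lowU `segmented_body` observed at the low flow speed.
#' @param scenario One of `"fixed_posture_and_length"`,
#'   `"shortened_straight"`.
#' @param length_highU Arc length out of the burrow observed at the high
#'   speed (m); required for the shortened-straight scenario.
#' @param orientation Axis of the straight counterfactual body.
#' @return A `segmented_body` to evaluate with [body_drag()] at the high
#'   flow speed.
#' @export
scenario_transform <- function(body_lowU,
                               scenario = c("fixed_posture_and_length",
                                            "shortened_straight"),
                               length_highU = NULL,
                               orientation = c("mean_axis", "vertical")) {
  scenario <- match.arg(scenario)
  orientation <- match.arg(orientation)
  stopifnot(inherits(body_lowU, "segmented_body"))
  if (scenario == "fixed_posture_and_length") return(body_lowU)
  if (is.null(length_highU) || length_highU <= 0) {
    stop("`length_highU` > 0 is required for the shortened-straight scenario",
         call. = FALSE)
  }
  axis <- c(0, 0, 1)
  if (orientation == "mean_axis") {
    snout <- body_lowU$end[nrow(body_lowU$end), ]
    root <- body_lowU$start[1, ]
    v <- snout - root
    if (sqrt(sum(v^2)) > 1e-9) axis <- v / sqrt(sum(v^2))
  }
  n_seg <- length(body_lowU$lengths)
  pts <- outer(seq(0, length_highU, length.out = n_seg + 1L), axis) +
    matrix(body_lowU$start[1, ], n_seg + 1L, 3, byrow = TRUE)
  segment_body(pts, diameter = body_lowU$diameter)
}

#' Average drag over posture frames
#'
#' The study evaluated drag on 10 posture frames per condition and averaged;
#' this helper maps [body_drag()] over a list of bodies and returns one row
#' per frame plus the across-frame means.
#'
#' @param bodies List of `segmented_body` (one per frame).
#' @param fluid A [fluid_context()].
#' @param ... Passed to [body_drag()].
#' @return Tibble with per-frame `total_force_N` and `body_cd`, with
#'   attributes `mean_force_N`, `mean_body_cd`.
#' @export
frame_average_drag <- function(bodies, fluid, ...) {
  rows <- purrr::imap(bodies, function(b, i) {
    dr <- body_drag(b, fluid, ...)
    tibble::tibble(frame = i, total_force_N = total_drag(dr),
                   body_cd = body_cd(dr))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "mean_force_N") <- mean(out$total_force_N)
  attr(out, "mean_body_cd") <- mean(out$body_cd)
  out
}
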