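#' Body length outside the burrow
#'
#' Arc length of an ordered body polyline from the burrow origin to the
#' snout: the sum of Euclidean segment lengths. A single point has length 0.
#'
#' @param polyline n x 3 matrix or data frame of ordered 3D points (m),
#'   first vertex at the burrow origin.
#' @return Length in metres.
#' @examples
#' length_out_of_burrow(rbind(c(0, 0, 0), c(0, 0, 0.12)))
#' @export
length_out_of_burrow <- function(polyline) {
  P <- as_point_matrix(polyline)
  if (nrow(P) == 0L) stop("empty polyline", call. = FALSE)
  if (nrow(P) == 1L) return(0)
  sum(sqrt(rowSums(diff(P)^2)))
}

#' Third quartile of a length series
#'
#' 75th percentile with linear interpolation between order statistics
#' (position h = (n - 1) p + 1), the convention used as the feeding-area
#' radius: a value between the average and the maximum body extension.
#'
#' @param x Numeric series (m), nonempty.
#' @param type Quantile convention, passed to [stats::quantile()].
#' @return The third quartile (m).
#' @export
quartile3 <- function(x, type = 7) {
  if (!length(x) || anyNA(x)) stop("nonempty series without NA required",
                                   call. = FALSE)
  unname(stats::quantile(x, 0.75, type = type))
}

#' Eye position in polar coordinates about the burrow
#'
#' Converts per-frame positions of one body point to polar coordinates about
#' the burrow origin: radius (m), azimuth (deg, angle of (x, y) from the +x
#' upstream axis) and elevation (deg, above the x-y sand-bed plane). A point
#' at the origin has undefined azimuth, emitted as 0 with `origin_flag`.
#'
#' @param track Tibble with columns `frame`, `label`, `x_m`, `y_m`, `z_m`.
#' @param label Body-point label to convert (default `"eye"`).
#' @return Tibble `frame`, `r_m`, `azimuth_deg`, `elevation_deg`,
#'   `origin_flag`.
#' @export
eye_polar <- function(track, label = "eye") {
  track <- tibble::as_tibble(track)
  sub <- dplyr::filter(track, .data$label == !!label)
  if (!nrow(sub)) stop("label '", label, "' not present in track",
                       call. = FALSE)
  r <- sqrt(sub$x_m^2 + sub$y_m^2 + sub$z_m^2)
  rxy <- sqrt(sub$x_m^2 + sub$y_m^2)
  at_origin <- r < 1e-12
  az <- ifelse(rxy < 1e-12, 0, atan2(sub$y_m, sub$x_m) * 180 / pi)
  el <- ifelse(at_origin, 0, atan2(sub$z_m, rxy) * 180 / pi)
  tibble::tibble(frame = sub$frame, r_m = r, azimuth_deg = az,
                 elevation_deg = el, origin_flag = at_origin)
}

#' Strike kinematics in earth and water frames
#'
#' From per-strike annotations (initiation and capture times, eye positions,
#' prey capture position) and the flow speed, computes strike distance
#' (eye displacement, m), strike time (s), strike speed in the earth frame
#' (distance / time) and in the water frame (the frame drifting downstream
#' with the flow, velocity (-U, 0, 0) since +x is upstream), and the
#' reactive distance: the eye-to-prey distance at strike initiation, with
#' the prey back-advected upstream from its capture position by U times the
#' strike time.
#'
#' @param strikes Tibble with columns `t_init_s`, `t_capture_s`,
#'   `eye_init_x/y/z`, `eye_capture_x/y/z`, `prey_x/y/z` (m). Any other
#'   columns (e.g. `eel_id`) are preserved.
#' @param U Flow speed (m s^-1), >= 0.
#' @return The input tibble with columns `strike_time_s`,
#'   `strike_distance_m`, `strike_speed_earth_mps`, `strike_speed_water_mps`,
#'   `reactive_distance_m` appended.
#' @export
strike_metrics <- function(strikes, U) {
  stopifnot(is.numeric(U), U >= 0)
  s <- tibble::as_tibble(strikes)
  dt <- s$t_capture_s - s$t_init_s
  if (any(dt <= 0)) stop("strike_time must be positive (t_capture > t_init)",
                         call. = FALSE)
  dx <- s$eye_capture_x - s$eye_init_x
  dy <- s$eye_capture_y - s$eye_init_y
  dz <- s$eye_capture_z - s$eye_init_z
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  # water frame: subtract the drift displacement (-U*dt, 0, 0)
  dist_w <- sqrt((dx + U * dt)^2 + dy^2 + dz^2)
  # prey advects downstream (-x); at initiation it was upstream of capture
  px <- s$prey_x + U * dt
  rd <- sqrt((px - s$eye_init_x)^2 + (s$prey_y - s$eye_init_y)^2 +
               (s$prey_z - s$eye_init_z)^2)
  dplyr::mutate(s,
    strike_time_s = dt,
    strike_distance_m = dist,
    strike_speed_earth_mps = dist / dt,
    strike_speed_water_mps = dist_w / dt,
    reactive_distance_m = rd
  )
}

#' Reactive distance only
#'
#' Convenience wrapper around [strike_metrics()] returning just the reactive
#' distance column.
#'
#' @inheritParams strike_metrics
#' @return Numeric vector of reactive distances (m).
#' @export
reactive_distance <- function(strikes, U) {
  strike_metrics(strikes, U)$reactive_distance_m
}

#' Vectorial dynamic body acceleration from a 3D track
#'
#' Instantaneous triaxial acceleration from the three-point second-order
#' finite-difference stencil
#' \deqn{a_i = (p_i - 2 p_{i+1} + p_{i+2}) \cdot \mathrm{fps}^2,}
#' recorded at index i, and the per-frame vectorial dynamic body
#' acceleration \eqn{\mathrm{VeDBA} = \sqrt{a_x^2 + a_y^2 + a_z^2}}, a proxy
#' for locomotor energy expenditure. The series is 2 frames shorter than the
#' track. Requires contiguous frames at uniform `fps` unless
#' `interpolate_gaps` linearly fills missing frames (flagged per filled
#' frame).
#'
#' @param track Tibble with columns `frame`, `label`, `x_m`, `y_m`, `z_m`,
#'   or an n x 3 matrix of positions at uniform sampling.
#' @param label Body-point label used for the acceleration; the first black
#'   spot is nearest the body centre and preferred over the eye when present.
#' @param fps Sampling rate (frames s^-1), 60 for the study videos.
#' @param interpolate_gaps Linearly interpolate missing frames instead of
#'   erroring.
#' @return A tibble of class `vedba_series` with columns `frame`, `a_x`,
#'   `a_y`, `a_z` (m s^-2), `vedba` (m s^-2) and, when gaps were filled,
#'   `interpolated`; the temporal mean is in `attr(, "mean_vedba")`.
#' @export
vedba_series <- function(track, label = NULL, fps = 60,
                         interpolate_gaps = FALSE) {
  stopifnot(fps > 0)
  if (is.matrix(track)) {
    P <- as_point_matrix(track)
    frames <- seq_len(nrow(P)) - 1L
    interp <- rep(FALSE, nrow(P))
  } else {
    track <- tibble::as_tibble(track)
    if (is.null(label)) {
      labs <- unique(track$label)
      label <- if ("spot1" %in% labs) "spot1" else labs[[1]]
      if (label != "spot1") {
        rlang::warn(paste0("first black spot track absent; using '", label,
                           "' for VeDBA"))
      }
    }
    sub <- dplyr::arrange(dplyr::filter(track, .data$label == !!label),
                          .data$frame)
    if (!nrow(sub)) stop("label '", label, "' not present", call. = FALSE)
    frames <- sub$frame
    P <- cbind(sub$x_m, sub$y_m, sub$z_m)
    if (any(diff(frames) != 1L)) {
      if (!interpolate_gaps) {
        stop("track has frame gaps; set `interpolate_gaps = TRUE` to fill ",
             "them linearly", call. = FALSE)
      }
      full <- seq(min(frames), max(frames))
      Pi <- apply(P, 2, function(col) stats::approx(frames, col, xout = full)$y)
      interp <- !(full %in% frames)
      frames <- full
      P <- Pi
    } else {
      interp <- rep(FALSE, length(frames))
    }
  }
  n <- nrow(P)
  if (n < 3L) stop("VeDBA needs >= 3 frames, got ", n, call. = FALSE)
  acc <- (P[1:(n - 2), , drop = FALSE] - 2 * P[2:(n - 1), , drop = FALSE] +
            P[3:n, , drop = FALSE]) * fps^2
  out <- tibble::tibble(
    frame = frames[1:(n - 2)],
    a_x = acc[, 1], a_y = acc[, 2], a_z = acc[, 3],
    vedba = sqrt(rowSums(acc^2))
  )
  if (any(interp)) out$interpolated <- interp[1:(n - 2)]
  attr(out, "mean_vedba") <- mean(out$vedba)
  attr(out, "fps") <- fps
  class(out) <- c("vedba_series", class(out))
  out
}

#' @export
print.vedba_series <- function(x, ...) {
  NextMethod()
  cat("# mean VeDBA:", signif(attr(x, "mean_vedba"), 6), "m s^-2 at",
      attr(x, "fps"), "Hz\n")
  invisible(x)
}

#' Mean VeDBA of a series
#'
#' @param x A `vedba_series`.
#' @return Temporal mean VeDBA (m s^-2).
#' @export
mean_vedba <- function(x) {
  stopifnot(inherits(x, "vedba_series"))
  attr(x, "mean_vedba")
}

#' Successful strike rate
#'
#' Prey captured during a trial divided by the number of strikes; may exceed
#' 1 when single strikes capture several prey.
#'
#' @param captured Prey captured (>= 0; may be a trial-averaged real).
#' @param strikes Number of strikes (> 0).
#' @return The ratio.
#' @export
successful_strike_rate <- function(captured, strikes) {
  stopifnot(all(captured >= 0))
  if (any(strikes <= 0)) stop("strike count must be positive", call. = FALSE)
  captured / strikes
}

#' Detect candidate strikes from eye speed
#'
#' Optional plumbing, not part of the study protocol (strikes there were
#' annotated visually): flags runs of at least `min_frames` frames where the
#' eye speed exceeds `factor` times its rolling median.
#'
#' @param track Tibble track (see [vedba_series()]).
#' @param label Body-point label (default `"eye"`).
#' @param fps Sampling rate (Hz).
#' @param factor Speed threshold as a multiple of the rolling median.
#' @param min_frames Minimum run length.
#' @param window Rolling-median window (frames, odd); wide enough that a
#'   lunge plus its return occupies a minority of the window.
#' @return Tibble with `t_init_s`, `t_capture_s` and frame bounds per
#'   candidate event.
#' @export
detect_strikes <- function(track, label = "eye", fps = 60, factor = 3,
                           min_frames = 3, window = 121) {
  sub <- dplyr::arrange(dplyr::filter(tibble::as_tibble(track),
                                      .data$label == !!label), .data$frame)
  if (nrow(sub) < min_frames + 1) {
    return(tibble::tibble(frame_init = integer(), frame_capture = integer(),
                          t_init_s = numeric(), t_capture_s = numeric()))
  }
  P <- cbind(sub$x_m, sub$y_m, sub$z_m)
  speed <- c(sqrt(rowSums(diff(P)^2)) * fps, 0)
  med <- stats::runmed(speed, k = min(window, 2 * (nrow(sub) %/% 2) - 1))
  hot <- speed > factor * pmax(med, 1e-9)
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_frames
  tibble::tibble(
    frame_init = sub$frame[starts[keep]],
    frame_capture = sub$frame[ends[keep]],
    t_init_s = sub$frame[starts[keep]] / fps,
    t_capture_s = sub$frame[ends[keep]] / fps
  )
}
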