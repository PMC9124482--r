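# Synthetic flume scenes with known ground truth: a swaying anchored eel
# polyline with strike lunges, prey advected at the flow speed, noisy
# multi-camera projections and Poisson trial counts. Every generator is a
# pure function of (parameters, seed); the RNG state of the caller is
# restored on exit.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# circular-arc posture: arc length L, tangent tilting from vertical (+z)
# toward downstream (-x) by `bend` radians at the snout; bend -> 0 is a
# straight vertical body
arc_posture <- function(s, L, bend) {
  if (bend < 1e-9) {
    cbind(x = 0 * s, y = 0 * s, z = s)
  } else {
    R <- L / bend
    th <- bend * s / L
    cbind(x = -R * (1 - cos(th)), y = 0 * s, z = R * sin(th))
  }
}

#' Body length observed at a given flow speed
#'
#' Lookup (with linear interpolation) of the emulated length out of the
#' burrow as a function of flow speed. The default table makes the body
#' shorten as the flow strengthens, mirroring the qualitative trend of the
#' flume observations; it is a configuration table, not a fitted quantity.
#'
#' @param U Flow speed (m s^-1).
#' @param table Data frame with columns `U_mps`, `length_m`.
#' @return Length out of the burrow (m).
#' @export
eel_length_for_speed <- function(U, table = default_length_table()) {
  stats::approx(table$U_mps, table$length_m, xout = U, rule = 2)$y
}

#' @rdname eel_length_for_speed
#' @export
default_length_table <- function() {
  tibble::tibble(U_mps = c(0.10, 0.15, 0.20, 0.25),
                 length_m = c(0.14, 0.12, 0.10, 0.08))
}

#' Simulate a swaying, striking garden eel track
#'
#' Generates a 60 Hz track of an 8-point body polyline anchored at the
#' burrow origin: a circular-arc base posture of arc length `base_length`
#' bending downstream by `bend` radians, sinusoidal lateral sway whose
#' amplitude grows quadratically from the burrow (zero) to the snout
#' (`sway_amplitude`), and strike lunges at Poisson times: the head darts
#' straight at `strike_speed` toward a sampled prey position and returns
#' along the same path. Polyline order from the burrow: `base`,
#' `body1`..`body5`, `spot1`, `eye`.
#'
#' @param base_length Arc length out of the burrow (m).
#' @param sway_amplitude Lateral sway amplitude at the snout (m).
#' @param sway_freq Sway frequency (Hz).
#' @param strike_rate Poisson rate of strikes (s^-1).
#' @param strike_speed Lunge speed (m s^-1).
#' @param bend Downstream bend of the base posture at the snout (rad).
#' @param fps Frame rate (s^-1).
#' @param duration Track duration (s).
#' @param seed RNG seed; identical seeds give identical tracks.
#' @return List with `track` (tibble `frame`, `label`, `x_m`, `y_m`,
#'   `z_m`), `strikes` (ground-truth tibble in the [read_strikes()] schema),
#'   `length_series` (per-frame arc length, m) and `params`.
#' @export
gen_eel_track <- function(base_length = 0.12, sway_amplitude = 0.01,
                          sway_freq = 1, strike_rate = 0.2,
                          strike_speed = 0.2, bend = 0.6, fps = 60,
                          duration = 10, seed = 1) {
  stopifnot(base_length >= 0, sway_amplitude >= 0, sway_freq >= 0,
            strike_rate >= 0, strike_speed >= 0, fps > 0, duration > 0)
  with_seed(seed, {
    n <- floor(duration * fps) + 1L
    t <- (seq_len(n) - 1L) / fps
    labels <- c("base", paste0("body", 1:5), "spot1", "eye")
    s_frac <- seq(0, 1, length.out = 8L)
    base <- arc_posture(s_frac * base_length, base_length, bend)

    # Poisson strike schedule; lunge target sampled in the upstream-facing
    # hemisphere within half a body length of the eye's rest position
    strikes <- list()
    if (strike_rate > 0 && strike_speed > 0) {
      t_cur <- 0
      eye_rest <- base[8L, ]
      repeat {
        t_cur <- t_cur + stats::rexp(1, strike_rate)
        if (t_cur > duration - 1) break
        dir <- c(abs(stats::rnorm(1)), stats::rnorm(1), stats::rnorm(1))
        dir <- dir / sqrt(sum(dir^2))
        reach <- stats::runif(1, 0.1, 0.5) * max(base_length, 0.05)
        target <- eye_rest + dir * reach
        dur <- reach / strike_speed
        strikes[[length(strikes) + 1L]] <- list(
          t_init = t_cur, t_capture = t_cur + dur, target = target)
        t_cur <- t_cur + 2 * dur + 0.2   # lunge + return + refractory
      }
    }

    sway <- sway_amplitude * sin(2 * pi * sway_freq * t)
    # per-frame positions: base posture + lateral sway + strike displacement
    pos <- array(0, dim = c(n, 8L, 3L))
    for (k in 1:8) {
      pos[, k, 1] <- base[k, 1]
      pos[, k, 2] <- base[k, 2] + sway * s_frac[k]^2
      pos[, k, 3] <- base[k, 3]
    }
    for (st in strikes) {
      dur <- st$t_capture - st$t_init
      # triangular ramp: out during [t_init, t_capture], back during the
      # same duration after capture
      phase <- pmax(0, pmin((t - st$t_init) / dur, 2 - (t - st$t_init) / dur))
      offset <- st$target - base[8L, ]
      # head-weighted displacement: eye full, spot1 60%, body5 30%
      w <- c(0, 0, 0, 0, 0, 0.3, 0.6, 1)
      for (k in which(w > 0)) {
        for (j in 1:3) {
          pos[, k, j] <- pos[, k, j] + phase * w[k] * offset[j]
        }
      }
    }

    track <- tibble::tibble(
      frame = rep(seq_len(n) - 1L, each = 8L),
      label = rep(labels, times = n),
      x_m = as.numeric(t(pos[, , 1])),
      y_m = as.numeric(t(pos[, , 2])),
      z_m = as.numeric(t(pos[, , 3]))
    )
    length_series <- vapply(seq_len(n), function(i) {
      length_out_of_burrow(pos[i, , ])
    }, numeric(1))
    strike_tbl <- if (length(strikes)) {
      purrr::map_dfr(strikes, function(st) {
        i0 <- which.min(abs(t - st$t_init))
        i1 <- which.min(abs(t - st$t_capture))
        tibble::tibble(
          t_init_s = st$t_init, t_capture_s = st$t_capture,
          eye_init_x = pos[i0, 8, 1], eye_init_y = pos[i0, 8, 2],
          eye_init_z = pos[i0, 8, 3],
          eye_capture_x = pos[i1, 8, 1], eye_capture_y = pos[i1, 8, 2],
          eye_capture_z = pos[i1, 8, 3],
          prey_x = st$target[1], prey_y = st$target[2], prey_z = st$target[3]
        )
      })
    } else {
      tibble::tibble(t_init_s = numeric(), t_capture_s = numeric(),
                     eye_init_x = numeric(), eye_init_y = numeric(),
                     eye_init_z = numeric(), eye_capture_x = numeric(),
                     eye_capture_y = numeric(), eye_capture_z = numeric(),
                     prey_x = numeric(), prey_y = numeric(),
                     prey_z = numeric())
    }
    list(track = track, strikes = strike_tbl, length_series = length_series,
         params = list(base_length = base_length,
                       sway_amplitude = sway_amplitude,
                       sway_freq = sway_freq, strike_rate = strike_rate,
                       strike_speed = strike_speed, bend = bend, fps = fps,
                       duration = duration, seed = seed))
  })
}

#' Simulate advected prey particles
#'
#' Seeds non-swimming tracer particles as a spatial Poisson process of
#' density `rho` in a box spanning `x_span` upstream of the burrow plane and
#' the test-section cross-section, then advects them downstream at
#' (-U, 0, 0). A particle initially at x0 > 0 crosses the burrow plane
#' x = 0 at time x0 / U, so the number of crossings in `T` has mean
#' rho * U * A * T (prey flux times area times time) whenever
#' `x_span >= U * T`.
#'
#' @param rho Prey density (m^-3).
#' @param U Flow speed (m s^-1).
#' @param y_range,z_range Cross-section extents (m); defaults are the
#'   0.30 x 0.30 m test section centred on the burrow.
#' @param x_span Upstream seeding span (m); enlarged automatically to cover
#'   `U * T`.
#' @param T_s Observation window (s).
#' @param jitter_sd Optional per-step isotropic swimming jitter (m, per
#'   sqrt(s)); 0 for pure tracers.
#' @param seed RNG seed.
#' @return List with `particles` (tibble `id`, `x0`, `y0`, `z0`,
#'   `t_cross_s`), `n_crossings` (count crossing x = 0 within `T_s`) and
#'   `expected_crossings` (rho * U * A * T).
#' @export
gen_prey_particles <- function(rho, U, y_range = c(-0.15, 0.15),
                               z_range = c(0, 0.30), x_span = NULL,
                               T_s = 56, jitter_sd = 0, seed = 1) {
  stopifnot(rho >= 0, U >= 0, T_s > 0)
  A <- diff(y_range) * diff(z_range)
  with_seed(seed, {
    span <- max(if (is.null(x_span)) 0 else x_span, U * T_s)
    if (span <= 0 || rho == 0) {
      return(list(particles = tibble::tibble(id = integer(), x0 = numeric(),
                                             y0 = numeric(), z0 = numeric(),
                                             t_cross_s = numeric()),
                  n_crossings = 0L, expected_crossings = rho * U * A * T_s))
    }
    n <- stats::rpois(1, rho * A * span)
    x0 <- stats::runif(n, 0, span)
    y0 <- stats::runif(n, y_range[1], y_range[2])
    z0 <- stats::runif(n, z_range[1], z_range[2])
    if (jitter_sd > 0) {
      y0 <- y0 + stats::rnorm(n, 0, jitter_sd * sqrt(T_s))
      z0 <- z0 + stats::rnorm(n, 0, jitter_sd * sqrt(T_s))
    }
    t_cross <- if (U > 0) x0 / U else rep(Inf, n)
    particles <- tibble::tibble(id = seq_len(n), x0 = x0, y0 = y0, z0 = z0,
                                t_cross_s = t_cross)
    list(particles = particles,
         n_crossings = sum(t_cross <= T_s),
         expected_crossings = rho * U * A * T_s)
  })
}

#' A synthetic three-camera rig
#'
#' Builds three pinhole cameras converted to DLT form, arranged like the
#' flume recording setup: two side by side and a third above them, all on
#' one side of the test section and focused on the eel above the burrow.
#'
#' @param distance Camera distance from the burrow (m).
#' @param look_at Fixation point (m).
#' @param f Focal length (px).
#' @return Named list of three [camera_dlt()].
#' @export
make_camera_rig <- function(distance = 0.9, look_at = c(0, 0, 0.08),
                            f = 1500) {
  list(
    cam1 = camera_pinhole(c(0.25, -distance, 0.15), look_at, f = f,
                          camera_id = "cam1"),
    cam2 = camera_pinhole(c(-0.25, -distance, 0.15), look_at, f = f,
                          camera_id = "cam2"),
    cam3 = camera_pinhole(c(0, -distance, 0.45), look_at, f = f,
                          camera_id = "cam3")
  )
}

#' Project a 3D track through cameras with pixel noise
#'
#' Applies [dlt_project()] to every (frame, label) position for each camera
#' and adds isotropic Gaussian pixel noise, producing observations in the
#' plain 2D dialect with unit confidence.
#'
#' @param track Track tibble (`frame`, `label`, `x_m`, `y_m`, `z_m`).
#' @param cams List of [camera_dlt()].
#' @param pixel_noise_sd Gaussian pixel noise s.d. (px).
#' @param seed RNG seed.
#' @return Tibble `camera_id`, `frame`, `label`, `u`, `v`, `confidence`.
#' @export
gen_camera_obs <- function(track, cams, pixel_noise_sd = 0, seed = 1) {
  track <- tibble::as_tibble(track)
  with_seed(seed, {
    obs <- purrr::map_dfr(cams, function(cam) {
      uv <- tryCatch(
        dlt_project(cam, cbind(track$x_m, track$y_m, track$z_m)),
        error = function(e) {
          stop("projection failed for camera '", cam$camera_id, "': ",
               conditionMessage(e), call. = FALSE)
        }
      )
      tibble::tibble(camera_id = cam$camera_id, frame = track$frame,
                     label = track$label, u = uv$u, v = uv$v,
                     confidence = 1)
    })
    if (pixel_noise_sd > 0) {
      obs$u <- obs$u + stats::rnorm(nrow(obs), 0, pixel_noise_sd)
      obs$v <- obs$v + stats::rnorm(nrow(obs), 0, pixel_noise_sd)
    }
    obs
  })
}

#' Simulate trial prey counts from the feeding-area forward model
#'
#' Forward model of a single flume trial: `released = round(rho * volume)`
#' prey are released; captures are Poisson with mean equal to the
#' semicircular feeding-area prediction rho * U * (pi L^2 / 2) * T; control
#' losses are Binomial(released, control_loss); recovery is what remains.
#'
#' @param rho Prey density (m^-3).
#' @param U Flow speed (m s^-1).
#' @param L Feeding-area radius (m).
#' @param T_s Trial duration (s), one water cycle.
#' @param control_loss Per-prey loss probability with no eel present.
#' @param volume Flume volume (m^3).
#' @param seed RNG seed.
#' @return Tibble with `released`, `captures`, `control_losses`,
#'   `recovered`, `mean_captures`.
#' @export
gen_trial_counts <- function(rho, U, L, T_s, control_loss = 0,
                             volume = 1.24, seed = 1) {
  stopifnot(rho >= 0, U >= 0, L >= 0, T_s >= 0,
            control_loss >= 0, control_loss <= 1)
  released <- released_count(rho, volume)
  mu <- rho * U * (pi * L^2 / 2) * T_s
  if (mu > released) {
    stop("unphysical parameters: expected captures (", signif(mu, 4),
         ") exceed released prey (", released, ")", call. = FALSE)
  }
  with_seed(seed, {
    captures <- stats::rpois(1, mu)
    losses <- stats::rbinom(1, released, control_loss)
    recovered <- max(0L, released - captures - losses)
    tibble::tibble(released = released, captures = captures,
                   control_losses = losses, recovered = recovered,
                   mean_captures = mu)
  })
}
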