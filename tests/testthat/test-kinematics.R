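test_that("length out of the burrow is the polyline arc length", {
  expect_equal(length_out_of_burrow(rbind(c(0, 0, 0), c(0, 0, 0.12))), 0.12)
  expect_equal(
    length_out_of_burrow(rbind(c(0, 0, 0), c(0, 0, 0.05), c(0.02, 0, 0.09))),
    0.05 + sqrt(0.02^2 + 0.04^2),
    tolerance = 1e-12
  )
  expect_equal(length_out_of_burrow(rbind(c(0, 0, 0))), 0)
  expect_error(length_out_of_burrow(matrix(numeric(0), ncol = 3)), "empty")
})

test_that("quartile3 interpolates order statistics and bounds hold", {
  expect_equal(quartile3(c(0.08, 0.10, 0.12, 0.14)), 0.125)
  expect_equal(quartile3(rep(0.1, 10)), 0.1)
  expect_equal(quartile3(0.07), 0.07)
  expect_error(quartile3(numeric(0)), "nonempty")
  for (s in 1:25) {
    x <- gardeneel:::with_seed(s, runif(sample(3:50, 1), 0, 0.3))
    q <- quartile3(x)
    expect_gte(q, min(x))
    expect_lte(q, max(x))
    expect_gte(q, stats::median(x))
  }
})

test_that("polar conversion of the eye about the burrow", {
  tr <- tibble::tibble(frame = 0:2, label = "eye",
                       x_m = c(0.03, 0, 0.05), y_m = c(0.04, 0, 0),
                       z_m = c(0, 0.1, 0))
  p <- eye_polar(tr)
  expect_equal(p$r_m, c(0.05, 0.1, 0.05))
  expect_equal(p$azimuth_deg[1], 53.13010, tolerance = 1e-6)
  expect_equal(p$elevation_deg, c(0, 90, 0))
  expect_false(any(p$origin_flag))

  o <- eye_polar(tibble::tibble(frame = 0, label = "eye", x_m = 0, y_m = 0,
                                z_m = 0))
  expect_true(o$origin_flag)
  expect_equal(o$azimuth_deg, 0)
  expect_error(eye_polar(tr, "spot1"), "not present")
})

test_that("strike metrics in earth and water frames, and reactive distance", {
  ev <- tibble::tibble(t_init_s = 0, t_capture_s = 0.25,
                       eye_init_x = 0.05, eye_init_y = 0, eye_init_z = 0.10,
                       eye_capture_x = 0.02, eye_capture_y = 0.01,
                       eye_capture_z = 0.08,
                       prey_x = 0.02, prey_y = 0.01, prey_z = 0.08)
  m <- strike_metrics(ev, U = 0.2)
  expect_equal(m$strike_time_s, 0.25)
  expect_equal(m$strike_distance_m, sqrt(0.0014), tolerance = 1e-9)
  expect_equal(m$strike_speed_earth_mps, sqrt(0.0014) / 0.25,
               tolerance = 1e-9)
  expect_equal(m$strike_speed_water_mps, 0.12, tolerance = 1e-9)
  expect_equal(m$reactive_distance_m, 0.03, tolerance = 1e-9)
  expect_equal(reactive_distance(ev, 0.2), 0.03, tolerance = 1e-9)

  # zero displacement: pure drift of the water frame
  ev0 <- ev
  ev0$t_capture_s <- 0.5
  ev0[c("eye_capture_x", "eye_capture_y", "eye_capture_z")] <-
    ev0[c("eye_init_x", "eye_init_y", "eye_init_z")]
  m0 <- strike_metrics(ev0, U = 0.1)
  expect_equal(m0$strike_distance_m, 0)
  expect_equal(m0$strike_speed_earth_mps, 0)
  expect_equal(m0$strike_speed_water_mps, 0.1)

  # pure streamwise offset: eye at the capture point, U t upstream at init
  ev1 <- ev
  ev1$t_capture_s <- 0.1
  ev1[c("prey_x", "prey_y", "prey_z")] <-
    ev1[c("eye_init_x", "eye_init_y", "eye_init_z")]
  expect_equal(strike_metrics(ev1, 0.25)$reactive_distance_m, 0.025,
               tolerance = 1e-12)

  bad <- ev
  bad$t_capture_s <- 0
  expect_error(strike_metrics(bad, 0.2), "positive")
})

test_that("earth and water frames coincide at U = 0 for random events", {
  for (s in 1:30) {
    ev <- gardeneel:::with_seed(s, tibble::tibble(
      t_init_s = 0, t_capture_s = runif(1, 0.05, 0.5),
      eye_init_x = rnorm(1, 0, 0.05), eye_init_y = rnorm(1, 0, 0.05),
      eye_init_z = runif(1, 0.02, 0.15),
      eye_capture_x = rnorm(1, 0, 0.05), eye_capture_y = rnorm(1, 0, 0.05),
      eye_capture_z = runif(1, 0.02, 0.15),
      prey_x = rnorm(1, 0, 0.05), prey_y = rnorm(1, 0, 0.05),
      prey_z = runif(1, 0.02, 0.15)))
    m <- strike_metrics(ev, 0)
    expect_equal(m$strike_speed_water_mps, m$strike_speed_earth_mps)
    expect_equal(m$reactive_distance_m,
                 sqrt((ev$prey_x - ev$eye_init_x)^2 +
                        (ev$prey_y - ev$eye_init_y)^2 +
                        (ev$prey_z - ev$eye_init_z)^2))
  }
})

test_that("VeDBA: exact second differences, drift invariance, sinusoid
           closed form", {
  fps <- 60
  t <- seq(0, 2, by = 1 / fps)
  # constant velocity: annihilated by the stencil
  lin <- cbind(0.01 * t, -0.02 * t, 0.05 + 0.001 * t)
  v <- vedba_series(lin, fps = fps)
  expect_equal(mean_vedba(v), 0)
  expect_equal(nrow(v), length(t) - 2)

  # quadratic in x: exactly 2 m s^-2 at every frame
  quad <- cbind(0.5 * 2 * t^2, 0, 0)
  vq <- vedba_series(quad, fps = fps)
  expect_vector_equal(vq$a_x, rep(2, nrow(vq)), 1e-8)
  expect_equal(mean_vedba(vq), 2, tolerance = 1e-9)

  # sinusoid: mean |a| = (2/pi) A (2 pi f)^2
  t10 <- seq(0, 10, by = 1 / fps)
  sine <- cbind(0.01 * sin(2 * pi * t10), 0, 0)
  vs <- vedba_series(sine, fps = fps)
  target <- (2 / pi) * 0.01 * (2 * pi)^2
  expect_lt(abs(mean_vedba(vs) - target) / target, 0.005)

  # adding a constant-velocity drift changes nothing
  drift <- sine + cbind(0.03 * t10, 0.01 * t10, -0.02 * t10)
  expect_equal(mean_vedba(vedba_series(drift, fps = fps)), mean_vedba(vs),
               tolerance = 1e-9)

  expect_error(vedba_series(sine[1:2, ], fps = fps), ">= 3")
})

test_that("VeDBA converges to the analytic second derivative as O(fps^-2)", {
  A <- 0.01; f <- 2
  err_at <- function(fps) {
    tt <- seq(0, 5, by = 1 / fps)
    v <- vedba_series(cbind(A * sin(2 * pi * f * tt), 0, 0), fps = fps)
    truth <- A * (2 * pi * f)^2 * abs(sin(2 * pi * f * (v$frame + 1) / fps))
    max(abs(v$vedba - truth))
  }
  e1 <- err_at(30); e2 <- err_at(60)
  expect_lt(e2, e1)            # finer sampling is more accurate
  expect_gt(e1 / e2, 3)        # ~4x per halving of the step
})

test_that("VeDBA track plumbing: label choice, gaps, frame bookkeeping", {
  sim <- gen_eel_track(duration = 1, strike_rate = 0, seed = 2)
  v <- vedba_series(sim$track, fps = 60)  # silently picks spot1
  expect_s3_class(v, "vedba_series")
  gap <- sim$track[!(sim$track$frame %in% 10:12 & sim$track$label == "spot1"), ]
  expect_error(vedba_series(gap, label = "spot1", fps = 60), "gaps")
  vi <- vedba_series(gap, label = "spot1", fps = 60, interpolate_gaps = TRUE)
  expect_true(any(vi$interpolated))
  eye_only <- sim$track[sim$track$label == "eye", ]
  expect_warning(vedba_series(eye_only, fps = 60), "spot")
})

test_that("successful strike rate handles ratios above one and zero strikes", {
  expect_equal(successful_strike_rate(12, 10), 1.2)
  expect_equal(successful_strike_rate(0, 10), 0)
  expect_equal(successful_strike_rate(9.5, 10), 0.95)
  expect_error(successful_strike_rate(5, 0), "positive")
})

test_that("speed-threshold strike detector flags simulated lunges", {
  sim <- gen_eel_track(duration = 10, strike_rate = 1, sway_amplitude = 0.002,
                       seed = 11)
  det <- detect_strikes(sim$track, fps = 60)
  expect_gt(nrow(det), 0)
  # every detection overlaps a true strike window (lunge out + return)
  overlaps <- vapply(det$t_init_s, function(t0) {
    any(t0 >= sim$strikes$t_init_s - 0.1 &
          t0 <= 2 * sim$strikes$t_capture_s - sim$strikes$t_init_s + 0.1)
  }, logical(1))
  expect_true(all(overlaps))
})
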