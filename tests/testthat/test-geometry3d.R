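test_that("dlt_project evaluates the 11-coefficient map", {
  cam <- camera_dlt(c(1, 0, 0, 0, 0, 1, rep(0, 5)), "ident")
  expect_equal(as.numeric(dlt_project(cam, c(2, 3, 5))), c(2, 3))

  cam2 <- camera_dlt(c(2, 0, 0, 1, 0, 2, 0, 1, 0, 0, 1), "scaled")
  expect_equal(as.numeric(dlt_project(cam2, c(1, 1, 1))), c(1.5, 1.5))

  # D = L9 X + 1 = 0 at X = -1
  cam3 <- camera_dlt(c(1, 0, 0, 0, 0, 1, 0, 0, 1, 0, 0), "sing")
  expect_error(dlt_project(cam3, c(-1, 0, 0)), "denominator")
})

test_that("camera_dlt validates its coefficient vector", {
  expect_error(camera_dlt(1:10), "11")
  expect_error(camera_dlt(c(1:10, NA)), "11")
})

test_that("calibration from a noiseless cube is exact and preconditions hold", {
  cube <- as.matrix(expand.grid(x = c(0, 0.2), y = c(0, 0.2), z = c(0, 0.2)))
  cam <- camera_pinhole(c(0.4, -0.9, 0.3), look_at = c(0.1, 0.1, 0.1))
  uv <- dlt_project(cam, cube)
  fit <- dlt_calibrate(cube, uv, "refit")
  expect_lt(fit$rms_px, 1e-8)
  expect_vector_equal(as.matrix(dlt_project(fit, cube)), as.matrix(uv), 1e-7)

  expect_error(dlt_calibrate(cube[1:5, ], uv[1:5, ]), "at least 6")
  # 8 coplanar points (z = 0) are degenerate
  flat <- cbind(cube[, 1:2], 0)
  expect_error(dlt_calibrate(flat, dlt_project(cam, flat)), "coplanar")
})

test_that("calibration under pixel noise reports a plausible RMS", {
  cube <- as.matrix(expand.grid(x = c(0, 0.2), y = c(0, 0.2), z = c(0, 0.2)))
  grid <- as.matrix(expand.grid(x = c(0.05, 0.15), y = c(0.05, 0.15),
                                z = c(0.05, 0.15)))
  pts <- rbind(cube, grid)
  cam <- camera_pinhole(c(0.4, -0.9, 0.3), look_at = c(0.1, 0.1, 0.1))
  uv <- as.matrix(dlt_project(cam, pts))
  rms <- vapply(1:100, function(s) {
    set.seed(s)
    fit <- dlt_calibrate(pts, uv + rnorm(length(uv), 0, 0.5))
    fit$rms_px
  }, numeric(1))
  expect_true(all(rms > 0.2 & rms < 1.0))
})

test_that("triangulation recovers points from orthogonal axis-aligned views", {
  camA <- camera_dlt(c(1, 0, 0, 0, 0, 1, rep(0, 5)), "xy")  # sees (X, Y)
  camB <- camera_dlt(c(1, 0, 0, 0, 0, 0, 1, rep(0, 4)), "xz")  # sees (X, Z)
  r <- dlt_reconstruct(list(camA, camB), rbind(c(2, 3), c(2, 5)))
  expect_equal(r$point, c(2, 3, 5))
  expect_lt(r$rms_px, 1e-9)
  expect_false(r$low_confidence)

  expect_error(dlt_reconstruct(list(camA), rbind(c(2, 3))), ">= 2")
})

test_that("noisy 3-camera reconstruction lands within 5 mm at flume scale", {
  rig <- make_camera_rig()
  p <- c(0.03, -0.02, 0.12)
  uv <- t(vapply(rig, function(cm) as.numeric(dlt_project(cm, p)), numeric(2)))
  err <- vapply(1:100, function(s) {
    set.seed(s)
    r <- dlt_reconstruct(rig, uv + rnorm(6, 0, 0.3))
    sqrt(sum((r$point - p)^2))
  }, numeric(1))
  expect_lt(max(err), 0.005)
})

test_that("noiseless round trips and residual behaviour with a third view", {
  for (s in 1:20) {
    rig <- random_rig(s)
    p <- gardeneel:::with_seed(1000 + s, {
      c(runif(1, -0.1, 0.1), runif(1, -0.1, 0.1), runif(1, 0.02, 0.2))
    })
    uv <- t(vapply(rig, function(cm) as.numeric(dlt_project(cm, p)),
                   numeric(2)))
    r2 <- dlt_reconstruct(rig[1:2], uv[1:2, ])
    r3 <- dlt_reconstruct(rig, uv)
    expect_lt(sqrt(sum((r3$point - p)^2)), 1e-6)
    # a consistent third view cannot worsen the reprojection residual
    expect_lte(r3$rms_px, r2$rms_px + 1e-9)
  }
})

test_that("near-parallel rays are flagged low confidence", {
  cam1 <- camera_pinhole(c(0, -0.9, 0.1), camera_id = "a")
  cam2 <- camera_pinhole(c(1e-8, -0.9, 0.1), camera_id = "b")  # ~same ray
  p <- c(0.02, 0.01, 0.1)
  uv <- rbind(as.numeric(dlt_project(cam1, p)),
              as.numeric(dlt_project(cam2, p)))
  r <- dlt_reconstruct(list(cam1, cam2), uv)
  expect_true(r$low_confidence)
})

test_that("reconstruct_track triangulates labels seen by >= 2 cameras and drops
           low-confidence observations", {
  rig <- make_camera_rig()
  sim <- gen_eel_track(duration = 0.5, strike_rate = 0, seed = 3)
  obs <- gen_camera_obs(sim$track, rig, pixel_noise_sd = 0, seed = 1)
  # one camera's eye observations made untrustworthy in frame 0
  obs$confidence[obs$camera_id == "cam1" & obs$frame == 0 &
                   obs$label == "eye"] <- 0.1
  expect_message(tk <- reconstruct_track(obs, rig), "low-confidence")
  expect_equal(tk$n_views[tk$frame == 0 & tk$label == "eye"], 2L)
  truth <- sim$track[order(sim$track$frame, sim$track$label), ]
  tk <- tk[order(tk$frame, tk$label), ]
  expect_vector_equal(tk$x_m, truth$x_m, 1e-6)
  expect_vector_equal(tk$z_m, truth$z_m, 1e-6)

  bad <- obs[obs$camera_id != "cam3", ]
  bad$camera_id <- sub("cam1", "camX", bad$camera_id)
  expect_error(reconstruct_track(bad, rig), "camX")
})
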