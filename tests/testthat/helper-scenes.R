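# shared fixtures, built in code

# frame-0 posture polyline of a simulated eel (8 x 3 matrix)
posture_polyline <- function(base_length = 0.12, bend = 0.6) {
  sim <- gen_eel_track(base_length = base_length, sway_amplitude = 0,
                       strike_rate = 0, bend = bend, duration = 0.1, seed = 1)
  f0 <- sim$track[sim$track$frame == 0, ]
  cbind(f0$x_m, f0$y_m, f0$z_m)
}

# a well-conditioned random camera rig around the flume test section
random_rig <- function(seed) {
  r <- gardeneel:::with_seed(seed, {
    list(d = runif(1, 0.6, 1.2), f = runif(1, 1000, 2000),
         la = c(runif(1, -0.05, 0.05), runif(1, -0.05, 0.05),
                runif(1, 0.05, 0.15)))
  })
  make_camera_rig(distance = r$d, look_at = r$la, f = r$f)
}

expect_vector_equal <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b)), tol)
}

scratch_file <- function(name) file.path(tempdir(), name)
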