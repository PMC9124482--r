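test_that("segment_body splits polylines and preserves arc length when
           resampling", {
  straight <- cbind(0, 0, seq(0, 0.1, length.out = 8))
  b <- segment_body(straight)
  expect_length(b$lengths, 7)
  expect_vector_equal(b$lengths, rep(0.1 / 7, 7), 1e-12)

  tri <- rbind(c(0, 0, 0), c(0, 0, 0.05), c(0.02, 0, 0.09))
  b2 <- segment_body(tri)
  expect_equal(b2$lengths, c(0.05, sqrt(0.02^2 + 0.04^2)), tolerance = 1e-12)

  b8 <- segment_body(tri, n_segments = 8)
  expect_length(b8$lengths, 8)
  expect_lt(abs(sum(b8$lengths) - sum(b2$lengths)), 1e-9)

  expect_error(segment_body(rbind(c(0, 0, 0))), ">= 2")
})

test_that("cylinder Cd correlation: values, monotonicity, validity range", {
  expect_equal(cylinder_cd(1000), 1.1)
  expect_equal(cylinder_cd(8), 3.5)
  Re <- 10^seq(0, 5, by = 0.25)
  cd <- cylinder_cd(Re)
  expect_true(all(diff(cd) < 0))
  expect_lt(cylinder_cd(1e5), 1.01)       # asymptote toward 1
  expect_error(cylinder_cd(0), "positive")
  expect_warning(cylinder_cd(3e5), "subcritical")
  expect_equal(cylinder_cd(500, correlation = function(Re) 1.2), 1.2)
})

test_that("segment drag matches the single-cylinder closed form", {
  fl <- fluid_context(0.10, rho_w = 1025, nu = 1e-6)
  # vertical 0.10 m segment, d = 5 mm: Re = 500
  F_vert <- segment_drag(c(0, 0, 0), c(0, 0, 0.10), 0.005, fl)
  Cd500 <- 1 + 10 * 500^(-2 / 3)
  expect_equal(F_vert, 0.5 * 1025 * Cd500 * 0.005 * 0.10 * 0.10^2,
               tolerance = 1e-12)
  expect_equal(F_vert, 2.969e-3, tolerance = 1e-3)

  # parallel to the flow: no normal component, no drag
  expect_equal(segment_drag(c(0, 0, 0), c(0.1, 0, 0), 0.005, fl), 0)

  # 45 degrees: U_n = U / sqrt(2), independent recomputation
  F_45 <- segment_drag(c(0, 0, 0), c(0.1, 0, 0.1) / sqrt(2), 0.005, fl)
  U_n <- 0.10 / sqrt(2)
  Re <- U_n * 0.005 / 1e-6
  expect_equal(F_45, 0.5 * 1025 * (1 + 10 * Re^(-2 / 3)) * 0.005 * 0.1 * U_n^2,
               tolerance = 1e-12)
  expect_equal(F_45, 1.54e-3, tolerance = 5e-3)

  expect_error(segment_drag(c(0, 0, 0), c(0, 0, 0), 0.005, fl), "zero-length")
})

test_that("whole-body drag: additivity, Cd consistency, U scaling", {
  fl <- fluid_context(0.10, nu = 1e-6)
  straight <- cbind(0, 0, seq(0, 0.1, length.out = 9))
  d8 <- body_drag(segment_body(straight), fl)
  one <- body_drag(segment_body(rbind(c(0, 0, 0), c(0, 0, 0.1))), fl)
  expect_equal(total_drag(d8), total_drag(one), tolerance = 1e-13)
  expect_equal(body_cd(d8), cylinder_cd(500), tolerance = 1e-12)
  expect_equal(sum(d8$force_N), total_drag(d8))

  # doubling U: closed-form force ratio 4 Cd(1000)/Cd(500)
  d2 <- body_drag(segment_body(straight), fluid_context(0.20, nu = 1e-6))
  expect_equal(total_drag(d2) / total_drag(d8),
               4 * cylinder_cd(1000) / cylinder_cd(500), tolerance = 1e-12)

  expect_message(d0 <- body_drag(segment_body(straight), fluid_context(0)),
                 "U = 0")
  expect_equal(total_drag(d0), 0)
  expect_true(is.na(body_cd(d0)))
})

test_that("splitting segments is drag-neutral and drag grows with U", {
  poly <- posture_polyline(0.14, bend = 0.8)
  for (s in 1:10) {
    U <- gardeneel:::with_seed(s, runif(1, 0.05, 0.3))
    fl <- fluid_context(U)
    coarse <- body_drag(segment_body(poly), fl)
    # arc-length resampling to more segments keeps every sub-segment
    # collinear within the original legs only for straight bodies; use an
    # explicitly collinear split here
    seg <- rbind(poly[1, ], poly[2, ])
    k <- 5
    fine <- sapply(seq(0, 1, length.out = k + 1),
                   function(a) seg[1, ] + a * (seg[2, ] - seg[1, ]))
    F1 <- segment_drag(seg[1, ], seg[2, ], 0.005, fl)
    Fk <- sum(vapply(seq_len(k), function(i) {
      segment_drag(fine[, i], fine[, i + 1], 0.005, fl)
    }, numeric(1)))
    expect_equal(Fk, F1, tolerance = 1e-12)
    invisible(coarse)
  }
  U_grid <- seq(0.02, 0.3, by = 0.02)
  forces <- vapply(U_grid, function(U) {
    total_drag(body_drag(segment_body(poly), fluid_context(U)))
  }, numeric(1))
  expect_true(all(diff(forces) > 0))
})

test_that("frame-averaged drag lies within the per-frame range", {
  bodies <- lapply(1:10, function(s) {
    segment_body(posture_polyline(0.1 + 0.004 * s, bend = 0.05 * s))
  })
  fa <- frame_average_drag(bodies, fluid_context(0.15))
  expect_equal(nrow(fa), 10)
  m <- attr(fa, "mean_force_N")
  expect_gte(m, min(fa$total_force_N))
  expect_lte(m, max(fa$total_force_N))
})

test_that("counterfactual scenarios: identity, construction, and dominance
           over observed high-flow postures", {
  low <- segment_body(posture_polyline(0.14, bend = 0.3))
  s1 <- scenario_transform(low, "fixed_posture_and_length")
  expect_identical(s1, low)

  s2 <- scenario_transform(low, "shortened_straight", length_highU = 0.06)
  expect_equal(sum(s2$lengths), 0.06, tolerance = 1e-12)
  # straight: all segment axes parallel
  ax <- (s2$end - s2$start) / s2$lengths
  expect_lt(max(abs(sweep(ax, 2, ax[1, ]))), 1e-9)

  s2v <- scenario_transform(low, "shortened_straight", length_highU = 0.06,
                            orientation = "vertical")
  expect_vector_equal(s2v$end[nrow(s2v$end), ],
                      c(low$start[1, 1:2], 0.06), 1e-12)

  expect_error(scenario_transform(low, "shortened_straight"), "length_highU")
  expect_error(scenario_transform(low, "smoothed"), "'arg'")

  # keeping the long, straighter low-flow posture at high flow always costs
  # at least as much drag as the actual bent, shortened posture
  fl <- fluid_context(0.25)
  worse <- vapply(1:100, function(s) {
    par <- gardeneel:::with_seed(s, list(
      L_low = runif(1, 0.10, 0.16), L_high = runif(1, 0.05, 0.09),
      b_low = runif(1, 0, 0.5), b_extra = runif(1, 0.1, 1.0)))
    low_b <- segment_body(posture_polyline(par$L_low, par$b_low))
    high_b <- segment_body(posture_polyline(par$L_high,
                                            par$b_low + par$b_extra))
    total_drag(body_drag(scenario_transform(low_b,
                                            "fixed_posture_and_length"),
                         fl)) >=
      total_drag(body_drag(high_b, fl))
  }, logical(1))
  expect_true(all(worse))
})
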