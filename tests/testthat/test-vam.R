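test_that("hysteresis loop construction floors SE values and checks bases", {
  tt <- seq(0, 30, by = 1)
  se <- sin(tt / 5) - 0.2               # dips negative
  ge <- pmax(se, 0)^1.5
  loop <- build_vhl(tt, ge, tt, se)
  expect_true(all(loop$x >= 0))
  # ge = se^(3/2) pointwise degenerates to a line with zero area
  expect_equal(compute_mti(loop), 0, tolerance = 1e-12)
  expect_error(build_vhl(tt, ge, tt + 0.5, se), "time base")
})

test_that("the loop from one-frame-shifted gamma curves is a simple loop", {
  tt <- (0:59) * 1.5
  ge <- gamma_variate(tt, 1, 18, 3, 1.8)
  se <- gamma_variate(tt, 0.4, 19.5, 3, 1.8)
  # restrict to bolus frames so the polygon has no duplicated rest points
  keep <- ge > 1e-6 | se > 1e-6
  loop <- build_vhl(tt, ge, tt, se, window = which(keep))
  # non-self-intersecting: signed area magnitude equals the ear-clipped
  # unsigned area (a figure-eight would partially cancel)
  x <- loop$x; y <- loop$y
  expect_equal(abs(compute_mti(list(x = x, y = y))),
               abs(signed_area_oracle(x, y)), tolerance = 1e-9)
})

test_that("Q_max is the GE-peak over the 3/2-power SE-peak", {
  expect_equal(compute_qmax(c(0, 10, 2), c(0, 4^(2 / 3), 1)), 2.5,
               tolerance = 1e-9)
  ge <- gamma_variate((0:59) * 1.5, 1, 12, 3, 1.5)
  q1 <- compute_qmax(ge, ge)
  expect_equal(compute_qmax(2 * ge, ge), 2 * q1, tolerance = 1e-12)
  # identical curves with peak < 1: p / p^(3/2) > 1
  expect_gt(compute_qmax(0.5 * ge / max(ge), 0.5 * ge / max(ge)), 1)
  expect_true(is.na(compute_qmax(ge, rep(0, length(ge)))))
})

test_that("MTI returns +2*pi on the clockwise 2x1 ellipse", {
  t <- seq(0, 2 * pi, length.out = 101)[-101]
  loop <- list(x = 2 * cos(t), y = sin(-t))
  area <- compute_mti(loop)
  # shoelace on the sampled polygon: pi*a*b * sampling factor, ~ +2 pi
  expect_equal(area, 2 * pi, tolerance = 0.01)
  expect_gt(area, 0)
  # reversing traversal flips the sign exactly
  rev_loop <- list(x = rev(loop$x), y = rev(loop$y))
  expect_equal(compute_mti(rev_loop), -area, tolerance = 1e-12)
  expect_error(compute_mti(list(x = c(0, 1), y = c(0, 1))), "3 points")
})

test_that("MTI agrees with the triangulation oracle on 100 random polygons", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(6:14, 1)
    # jittered equally spaced angles: gaps stay < pi, so the origin lies in
    # the kernel and the angle-sorted polygon is simple
    ang <- (0:(n - 1)) * 2 * pi / n + runif(n, 0, 1.8 * pi / n)
    rad <- runif(n, 0.5, 2)
    x <- rad * cos(ang); y <- rad * sin(ang)
    if (runif(1) < 0.5) { x <- rev(x); y <- rev(y) }
    expect_equal(compute_mti(list(x = x, y = y)), signed_area_oracle(x, y),
                 tolerance = 1e-9)
  }
})

test_that("MTI is additive over a decomposition into simple sub-loops", {
  # unit square split into two rectangles along x = 0.4 (all clockwise)
  sq <- list(x = c(0, 0, 1, 1), y = c(0, 1, 1, 0))
  left <- list(x = c(0, 0, 0.4, 0.4), y = c(0, 1, 1, 0))
  right <- list(x = c(0.4, 0.4, 1, 1), y = c(0, 1, 1, 0))
  expect_equal(compute_mti(sq),
               compute_mti(left) + compute_mti(right), tolerance = 1e-12)
  expect_equal(compute_mti(sq), 1, tolerance = 1e-12)
})

test_that("microvessel density and vessel size follow the adopted parses", {
  mvd <- compute_mvd(qmax = 2.5, cbv = 0.04, adc = 1.0e-3)
  expect_equal(mvd, 2.18e3, tolerance = 0.005)
  # linear in Q_max; cube-root in CBV
  expect_equal(compute_mvd(5, 0.04, 1e-3), 2 * mvd, tolerance = 1e-12)
  expect_equal(compute_mvd(2.5, 8 * 0.04, 1e-3), 2 * mvd, tolerance = 1e-12)
  expect_true(is.na(compute_mvd(2.5, 0.04, 0)))

  vsi <- compute_vsi(cbv = 0.04, adc = 1.0e-3, qmax = 2.5)
  expect_equal(vsi, 1.39e-3, tolerance = 0.005)  # mm, ~1.4 um
  expect_equal(compute_vsi(0.04, 1e-3, 2.5 * 4^(1 / 3)) * 2,
               vsi, tolerance = 1e-9)            # ~ Qmax^(-3/2)
  expect_equal(compute_vsi(4 * 0.04, 1e-3, 2.5), 2 * vsi, tolerance = 1e-12)
  expect_true(is.na(compute_vsi(0.04, 1e-3, 0)))
})

test_that("mapped MTI sign matches the simulated loop orientation", {
  for (fix in list(list(label = "IDHwt", seed = 7),
                   list(label = "IDHmut", seed = 13))) {
    m <- small_mapped(label = fix$label, seed = fix$seed)
    b <- small_bundle(label = fix$label, seed = fix$seed)
    tm <- b$gt$tumor_mask
    ok <- m$MTI$valid[tm]
    expect_equal(mean(sign(m$MTI$data[tm][ok]) ==
                        b$gt$maps$loop_orientation[tm][ok]), 1)
  }
})
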