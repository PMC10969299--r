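test_that("hybrid GESE series splits into consistent GE and SE series", {
  b <- small_bundle(protocol = "site_B_hybrid")
  sp <- split_gese(b$dsc)
  expect_equal(dim(sp$ge$signal)[4], 80L)
  expect_equal(dim(sp$se$signal)[4], 80L)
  expect_lt(sp$ge$echo_time, sp$se$echo_time)
  expect_equal(sp$ge$frame_interval, sp$se$frame_interval)
  # split then merge is the identity
  back <- merge_gese(sp$ge, sp$se)
  expect_identical(back$ge_signal, b$dsc$ge_signal)
  expect_identical(back$se_signal, b$dsc$se_signal)
  expect_error(split_gese(sp$ge), "hybrid")
})

test_that("signal-to-concentration conversion inverts the exponential model", {
  dm <- c(2, 2, 2)
  nt <- 50; te <- 30
  c_true <- 3.5
  sig <- array(0, c(dm, nt))
  curve <- c(rep(0, 10), rep(c_true, nt - 10))
  for (k in 1:nt) sig[, , , k] <- 800 * exp(-(te / 1000) * curve[k])
  ser <- structure(list(signal = sig, frame_interval = 1.5, echo_time = te,
                        echo_kind = "GE", baseline_window = 1:8,
                        spacing = c(1, 1, 1)), class = "dynamic_series")
  cv <- signal_to_delta_r2(ser)
  expect_equal(max(abs(cv$dr2[, 11:nt] - c_true)), 0, tolerance = 1e-10)
  expect_equal(max(abs(cv$dr2[, 1:10])), 0, tolerance = 1e-10)
  # flat series -> identically zero concentration
  sig0 <- array(800, c(dm, nt))
  ser0 <- ser; ser0$signal <- sig0
  expect_equal(max(abs(signal_to_delta_r2(ser0)$dr2)), 0)
})

test_that("baseline noise propagates into a small concentration offset", {
  set.seed(3)
  nt <- 60; te <- 30
  tt <- (0:(nt - 1)) * 1.5
  peak_dr2 <- 4
  dr2 <- gamma_variate(tt, 1, 15, 3, 1.5) / max(gamma_variate(tt, 1, 15, 3, 1.5)) * peak_dr2
  off <- replicate(200, {
    sig <- 800 * exp(-(te / 1000) * dr2) * (1 + rnorm(nt, 0, 0.01))
    base <- mean(sig[1:5])
    mean(-log(sig[1:5] / base) / (te / 1000))
  })
  expect_lt(max(abs(off)), 0.05 * peak_dr2)
})

test_that("gamma-variate fit recovers noise-free generator parameters", {
  tt <- seq(0, 60, by = 0.5)
  y <- gamma_variate(tt, K = 1, t0 = 10, alpha = 3, b = 1.5)
  f <- fit_first_pass(tt, y)
  expect_true(f$valid)
  expect_equal(c(f$K, f$t0, f$alpha, f$b), c(1, 10, 3, 1.5), tolerance = 1e-4)
  # analytic mode of the fitted curve: t0 + alpha * b
  expect_equal(f$t0 + f$alpha * f$b, 14.5, tolerance = 1e-3)
  # flat curve: flagged invalid without an exception
  expect_false(fit_first_pass(tt, rep(0, length(tt)))$valid)
  expect_false(fit_first_pass(tt, rep(1e-9, length(tt)))$valid)
})

test_that("gamma-fit oracle holds over 50 random noiseless draws", {
  set.seed(42)
  tt <- (0:59) * 1.5
  for (i in 1:50) {
    K <- runif(1, 0.5, 5); t0 <- runif(1, 8, 16)
    al <- runif(1, 1.5, 4); b <- runif(1, 0.8, 3)
    f <- fit_first_pass(tt, gamma_variate(tt, K, t0, al, b))
    expect_true(f$valid)
    expect_lt(max(abs(c(f$K - K, f$t0 - t0, f$alpha - al, f$b - b) /
                        c(K, t0, al, b))), 1e-3)
  }
})

test_that("AIF selection finds the designated arterial region", {
  b <- small_bundle()
  curves <- signal_to_delta_r2(b$dsc$ge, mask = b$gt$brain_mask)
  aif <- select_aif(curves, b$gt$brain_mask)
  expect_true(all(b$gt$arterial_mask[aif$voxel_idx]))
  expect_gte(length(aif$voxel_idx), 5L)
  # deterministic for fixed input
  aif2 <- select_aif(curves, b$gt$brain_mask)
  expect_identical(aif$voxel_idx, aif2$voxel_idx)
  expect_identical(aif$values, aif2$values)
  # top_n = 1 on identical arterial voxels equals a single fitted curve
  a1 <- select_aif(curves, b$gt$brain_mask, top_n = 1L)
  i <- a1$picked[1]
  expect_equal(a1$values,
               gamma_variate(curves$times, a1$fits$K[i], a1$fits$t0[i],
                             a1$fits$alpha[i], a1$fits$b[i]))
  expect_error(select_aif(curves, array(FALSE, dim(b$gt$brain_mask))),
               "100")
})

test_that("CBV is the first-pass area ratio and is scale-invariant", {
  tt <- (0:59) * 1.5
  a <- gamma_variate(tt, 2, 12, 2.5, 1.2)
  fa <- fit_first_pass(tt, a)
  aif <- list(times = tt, values = a, area = fa$area)
  class(aif) <- "aif_result"
  f_half <- fit_first_pass(tt, 0.5 * a)
  expect_equal(compute_cbv(f_half, aif), 0.5, tolerance = 1e-6)
  expect_equal(compute_cbv(fa, aif), 1, tolerance = 1e-9)
  expect_equal(compute_micro_cbv(f_half, aif), 0.5, tolerance = 1e-6)
  # global signal scaling cancels in the ratio: scale both curves x3
  fa3 <- fit_first_pass(tt, 3 * a)
  f_half3 <- fit_first_pass(tt, 1.5 * a)
  aif3 <- aif; aif3$area <- fa3$area
  expect_equal(compute_cbv(f_half3, aif3), 0.5, tolerance = 1e-6)
  bad <- aif; bad$area <- 0
  expect_error(compute_cbv(f_half, bad), "zero")
})

test_that("SVD deconvolution returns a unit spike for a delayed AIF copy", {
  tt <- (0:59) * 1.5
  a <- gamma_variate(tt, 1, 12, 3, 1.5); a <- a / max(a) * 10
  tis <- c(rep(0, 3), a[1:57])           # AIF delayed by 3 frames
  r <- compute_cbf(tis, a, lambda = 1e-3)
  expect_equal(r$cbf, 1, tolerance = 0.05)
  expect_equal(compute_cbf(rep(0, 60), a)$cbf, 0)
  r1 <- compute_cbf(tis, a, lambda = 1)   # truncate everything
  expect_equal(r1$cbf, 0)
  expect_false(r1$valid)
})

test_that("microvascular CBV uses spin-echo data with its own AIF", {
  m <- small_mapped()
  # SE AIF voxels are selected from SE curves only, inside the arterial region
  b <- small_bundle()
  expect_true(all(b$gt$arterial_mask[m$aif_se$voxel_idx]))
  tm <- m$tumor_mask
  gt <- b$gt
  ratio <- m$uCBV$data[tm] / m$CBV$data[tm]
  expect_equal(ratio, gt$maps$mcbv[tm] / gt$maps$cbv[tm], tolerance = 1e-6)
})

test_that("a linear post-bolus drift of 10% of peak moves CBV by < 2%", {
  tt <- (0:59) * 1.5
  base <- gamma_variate(tt, 1, 12, 3, 1.5)
  f0 <- fit_first_pass(tt, base)
  drift <- pmax(0, tt - 20); drift <- drift / max(drift) * 0.10 * max(base)
  f1 <- fit_first_pass(tt, base + drift)
  expect_lt(abs(f1$area - f0$area) / f0$area, 0.02)
})
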