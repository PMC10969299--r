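as_vol <- function(x) array(x, c(2, 2, 2))

test_that("OEF is the rate difference over the susceptibility coupling", {
  k <- physio_constants()$k
  expect_equal(k, 316.8, tolerance = 1e-3)   # (4/3) pi gamma dchi Hct B0
  oef <- compute_oef(as_vol(12 + 5.07), as_vol(12), as_vol(0.04))
  expect_equal(unique(as.vector(oef$data)), 0.40, tolerance = 1e-3)
  # R2* = R2 -> OEF 0
  expect_equal(unique(as.vector(
    compute_oef(as_vol(14), as_vol(14), as_vol(0.05))$data)), 0)
  # doubling CBV halves OEF
  o1 <- compute_oef(as_vol(15), as_vol(12), as_vol(0.03))$data[1]
  o2 <- compute_oef(as_vol(15), as_vol(12), as_vol(0.06))$data[1]
  expect_equal(o1 / o2, 2, tolerance = 1e-9)
  # CBV = 0 voxels are flagged invalid, not infinite
  cbv <- as_vol(0.04); cbv[1, 1, 1] <- 0
  o3 <- compute_oef(as_vol(15), as_vol(12), cbv)
  expect_false(o3$valid[1, 1, 1])
  expect_true(is.finite(o3$data[1, 1, 1]))
  # out-of-range quotients clamp to [0, 1] and flag
  o4 <- compute_oef(as_vol(200), as_vol(12), as_vol(0.01))
  expect_equal(unique(as.vector(o4$data)), 1)
  expect_false(any(o4$valid))
})

test_that("CMRO2 reduces to Fick's principle under the adopted coupling", {
  cns <- physio_constants()
  r2s <- as_vol(12 + 5.07); r2 <- as_vol(12); cbv <- as_vol(0.04)
  cbf <- as_vol(50)
  cm <- compute_cmro2(cbf, cbv, r2s, r2, consts = cns)
  oef <- compute_oef(r2s, r2, cbv, consts = cns)
  expect_equal(cm$data, cns$Ca * 50 * oef$data, tolerance = 1e-12)
  # direct product oracle: CBF 50, OEF 0.4, Ca 8.68 -> 173.6
  expect_equal(unique(as.vector(cm$data)), 8.68 * 50 * 0.4, tolerance = 1e-2)
  expect_equal(8.68 * 50 * 0.4, 173.6, tolerance = 1e-12)
  # OEF 0 -> CMRO2 0
  cm0 <- compute_cmro2(cbf, cbv, r2, r2, consts = cns)
  expect_equal(unique(as.vector(cm0$data)), 0)
})

test_that("capillary oxygen tension follows the dissociation model", {
  cns <- physio_constants()
  # OEF = 1: the power term is 1, so capiPO2 equals P50 = 27 mmHg
  expect_equal(unique(as.vector(compute_capipo2(as_vol(1))$data)), 27)
  # OEF = 0.5 -> 27 * 3^(1/2.7)
  expect_equal(unique(as.vector(compute_capipo2(as_vol(0.5))$data)),
               27 * 3^(1 / 2.7), tolerance = 1e-12)
  expect_equal(27 * 3^(1 / 2.7), 40.6, tolerance = 1e-2)
  # strictly decreasing in OEF on (0, 1]
  grid <- seq(0.05, 1, by = 0.05)
  vals <- vapply(grid, function(o)
    compute_capipo2(array(o, c(1, 1, 1)))$data[1], 0)
  expect_true(all(diff(vals) < 0))
  # OEF -> 0 voxels are flagged (the tension diverges)
  o <- as_vol(0.5); o[1, 1, 1] <- 0
  cp <- compute_capipo2(o)
  expect_false(cp$valid[1, 1, 1])
})

test_that("mitochondrial tension is the capillary tension minus demand/L", {
  capi <- as_vol(40.6); cm <- as_vol(8.8)
  mito <- compute_mitopo2(capi, cm)
  expect_equal(unique(as.vector(mito$data)), 40.6 - 8.8 / 4.4,
               tolerance = 1e-12)
  # CMRO2 = 0 -> mitoPO2 = capiPO2
  expect_equal(compute_mitopo2(capi, as_vol(0))$data, capi)
  # demand exceeding supply clamps to 0 and flags
  m2 <- compute_mitopo2(as_vol(5), as_vol(100))
  expect_equal(unique(as.vector(m2$data)), 0)
  expect_false(any(m2$valid))
})

test_that("mitoPO2 never exceeds capiPO2 where CMRO2 is nonnegative", {
  m <- small_mapped()
  v <- m$capiPO2$valid & m$mitoPO2$valid & m$CMRO2$data >= 0
  expect_true(all(m$mitoPO2$data[v] <= m$capiPO2$data[v] + 1e-9))
})

test_that("forward qBOLD model and OEF inversion round-trip to 1e-6", {
  cns <- physio_constants()
  set.seed(5)
  oef <- runif(50, 0.1, 0.9); cbv <- runif(50, 0.01, 0.15)
  r2 <- runif(50, 10, 14)
  r2star <- r2 + cns$k * cbv * oef
  back <- (r2star - r2) / (cns$k * cbv)
  expect_lt(max(abs(back - oef) / oef), 1e-6)
})

test_that("oxygen maps are invariant to a common raw-signal rescaling", {
  b <- small_bundle()
  b2 <- b
  for (f in c("ge_echo", "se_echo"))
    b2[[f]]$volumes <- lapply(b2[[f]]$volumes, function(v) 2.5 * v)
  b2$dsc$ge$signal <- 2.5 * b2$dsc$ge$signal
  b2$dsc$se$signal <- 2.5 * b2$dsc$se$signal
  b2$dwi$s0 <- 2.5 * b2$dwi$s0; b2$dwi$s1000 <- 2.5 * b2$dwi$s1000
  m1 <- small_mapped(); m2 <- map_patient(b2)
  tm <- m1$tumor_mask
  for (map in c("OEF", "CMRO2", "capiPO2", "mitoPO2"))
    expect_equal(m2[[map]]$data[tm], m1[[map]]$data[tm], tolerance = 1e-8)
})
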