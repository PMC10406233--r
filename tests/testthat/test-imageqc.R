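noise_vol <- function(dims = c(16, 16, 12), T = 1, sd = 1, seed = 1,
                      voxel = c(3, 3, 3)) {
  set.seed(seed)
  vol4d(array(rnorm(prod(dims) * T, sd = sd), c(dims, T)), voxel_mm = voxel)
}

full_mask <- function(vol) brain_mask(array(TRUE, spatial_dims(vol)),
                                      vol$voxel_mm)

test_that("TSNR is mean over sd and handles degenerate voxels", {
  d <- c(4, 4, 2)
  a <- array(0, c(d, 4))
  a[1, 1, 1, ] <- c(90, 110, 90, 110)        # mean 100, sd ~11.55
  a[2, 1, 1, ] <- 50                          # constant: undefined
  a[3, 1, 1, ] <- c(1, 2, 3, 4)
  v <- vol4d(a)
  m <- brain_mask(array(c(TRUE, TRUE, TRUE, rep(FALSE, prod(d) - 3)), d))
  ts <- tsnr(v, m)
  expect_equal(ts$map[1, 1, 1], 100 / sd(c(90, 110, 90, 110)))
  expect_true(is.na(ts$map[2, 1, 1]))
  expect_equal(ts$n_undefined, 1L)
  expect_equal(ts$mean_in_mask,
               mean(c(100 / sd(c(90, 110, 90, 110)), 2.5 / sd(1:4))))

  # scale invariance
  v2 <- v; v2$values <- v$values * 3.7
  expect_equal(tsnr(v2, m)$mean_in_mask, ts$mean_in_mask)
  expect_error(tsnr(vol4d(a[, , , 1, drop = FALSE]), m), "2 time points")
})

test_that("doubling thermal noise roughly halves phantom TSNR", {
  # noise-dominated phantom (no network signal)
  b1 <- simulate_subject(small_spec(thermal_sigma = 1, signal_amp = 0))
  b2 <- simulate_subject(small_spec(thermal_sigma = 2, signal_amp = 0))
  t1 <- tsnr(b1$volume, b1$brain_mask)
  t2 <- tsnr(b2$volume, b2$brain_mask)
  expect_gt(t2$mean_in_mask / t1$mean_in_mask, 0.4)
  expect_lt(t2$mean_in_mask / t1$mean_in_mask, 0.6)
})

test_that("smoothness estimation recovers a known Gaussian blur", {
  v <- noise_vol(c(48, 48, 40), seed = 3)
  m <- full_mask(v)
  blurred <- gaussian_blur(v, m, fwhm_mm = 8)
  est <- estimate_fwhm(vol3d(blurred$values[, , , 1], v$voxel_mm), m)
  expect_lt(abs(est$combined_mm - 8) / 8, 0.10)
  expect_equal(est$combined_mm, prod(est$fwhm_mm)^(1 / 3))

  # spatially independent noise is reported as rougher than any kernel
  est0 <- estimate_fwhm(vol3d(v$values[, , , 1], v$voxel_mm), m)
  expect_lt(est0$combined_mm, 3)

  # a perfectly uniform image has no defined smoothness
  u <- vol3d(array(1, c(8, 8, 8)))
  expect_error(estimate_fwhm(u, full_mask(u)), "zero spatial variance")
})

test_that("smoothness estimate agrees with a direct autocorrelation fit", {
  # oracle: fit the neighbour correlation rho = exp(-dx^2 / (4 s^2)) directly
  v <- noise_vol(c(48, 48, 40), seed = 9)
  m <- full_mask(v)
  blurred <- gaussian_blur(v, m, fwhm_mm = 7)$values[, , , 1]
  x <- as.vector(blurred)
  a <- blurred[-1, , ]; b <- blurred[-48, , ]
  rho <- cor(as.vector(a), as.vector(b))
  s <- 3 / (2 * sqrt(-log(rho)))          # mm
  oracle_fwhm <- 2 * sqrt(2 * log(2)) * s
  est <- estimate_fwhm(vol3d(blurred, c(3, 3, 3)), m)
  expect_lt(abs(est$fwhm_mm[1] - oracle_fwhm) / oracle_fwhm, 0.05)
})

test_that("iterative blurring converges to the target smoothness", {
  v <- noise_vol(c(32, 32, 24), seed = 5)
  m <- full_mask(v)
  out <- blur_to_fwhm(v, m, target_mm = 8, tol_frac = 0.05)
  expect_lt(abs(attr(out, "fwhm_mm") - 8) / 8, 0.05)

  # already at target: no iterations, volume unchanged
  out2 <- blur_to_fwhm(out, m, target_mm = attr(out, "fwhm_mm"))
  expect_equal(attr(out2, "n_iter"), 0L)
  expect_equal(out2$values, out$values)

  # smoothing only ever increases the estimate
  v2 <- gaussian_blur(v, m, 4)
  f1 <- estimate_fwhm(v2, m)$combined_mm
  v3 <- gaussian_blur(v2, m, 4)
  expect_gt(estimate_fwhm(v3, m)$combined_mm, f1)

  # refuse a target below the current smoothness
  expect_error(blur_to_fwhm(out, m, target_mm = 4), "already smoother")
})

test_that("Dice overlap follows its closed form and symmetry", {
  d <- c(10, 10, 5)
  a <- array(FALSE, d); b <- array(FALSE, d)
  a[1:100] <- TRUE                      # |A| = 100
  b[41:100] <- TRUE                     # 60 voxels inside A
  b[101:120] <- TRUE                    # 20 outside -> |B| = 80, overlap 60
  ma <- brain_mask(a); mb <- brain_mask(b)
  expect_equal(dice(ma, mb), 120 / 180)
  expect_equal(dice(mb, ma), dice(ma, mb))
  expect_equal(dice(ma, ma), 1)
  # disjoint masks
  c_ <- array(FALSE, d); c_[200:250] <- TRUE
  expect_equal(dice(ma, brain_mask(c_)), 0)
  # removing overlap voxels monotonically lowers Dice
  vals <- vapply(c(60, 40, 20), function(k) {
    bb <- array(FALSE, d); bb[21:(20 + k)] <- TRUE; bb[101:180] <- TRUE
    dice(ma, brain_mask(bb))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(dice(brain_mask(array(FALSE, d)), brain_mask(array(FALSE, d))),
               "empty")
})

test_that("FCS equals the brute-force mean pairwise correlation up to one scalar", {
  set.seed(12)
  for (rep in 1:3) {
    Y <- matrix(rnorm(20 * 8), 20, 8)
    res <- fcs(Y)
    # brute force: mean over j (including self) of cor(v, j)
    C <- cor(Y)
    brute <- rowMeans(C)
    scale_fac <- sd(res$scaled_global)
    expect_lt(max(abs(res$map - brute / scale_fac)) / max(abs(res$map)),
              1e-10)
    expect_equal(cor(res$map, brute, method = "spearman"), 1)
  }
})

test_that("shared time courses and global spikes inflate FCS", {
  # identical series -> FCS 1 everywhere
  Y <- matrix(rep(rnorm(15), 6), 15, 6)
  expect_equal(fcs(Y)$map, rep(1, 6), tolerance = 1e-12)

  # global multiplicative spikes raise mean FCS over the spike-free twin
  sp0 <- small_spec(network_weight = 0, signal_amp = 0)
  sp1 <- small_spec(network_weight = 0, signal_amp = 0,
                    spike_times = c(15, 35, 55), spike_gain = 0.08)
  b0 <- simulate_subject(sp0); b1 <- simulate_subject(sp1)
  f0 <- fcs(vol_matrix(b0$volume, b0$brain_mask))
  f1 <- fcs(vol_matrix(b1$volume, b1$brain_mask))
  expect_gt(f1$mean_in_mask, f0$mean_in_mask)
})

test_that("the flip check fires on mirrored anatomy and not otherwise", {
  # an asymmetric 'anatomy': bright blob off-centre along L-R
  d <- c(20, 16, 12)
  idx <- expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3])
  blob <- exp(-((idx$i - 6)^2 / 8 + (idx$j - 8)^2 / 10 + (idx$k - 6)^2 / 6))
  blob2 <- 0.6 * exp(-((idx$i - 14)^2 / 20 + (idx$j - 10)^2 / 10 +
                         (idx$k - 7)^2 / 6))
  t1 <- vol3d(array(blob + blob2, d))
  m <- brain_mask(array(TRUE, d))

  # identical images: not flipped
  fr <- check_lr_flip(t1, t1, m)
  expect_false(fr$flipped)
  expect_equal(fr$cost_original, -1)

  # EPI constructed as the L-R mirror of the T1: flip detected
  epi_flipped <- flip_axis(t1, 1)
  epi_flipped$orientation <- t1$orientation   # same grid, mirrored content
  epi_flipped$origin_mm <- t1$origin_mm
  fr <- check_lr_flip(epi_flipped, t1, m)
  expect_true(fr$flipped)

  # perfectly symmetric input: tie goes to not flipped
  sym <- vol3d(array(exp(-((idx$i - 10.5)^2 / 9 + (idx$j - 8)^2 / 10 +
                             (idx$k - 6)^2 / 6)), d))
  fr <- check_lr_flip(sym, sym, m)
  expect_false(fr$flipped)
})
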