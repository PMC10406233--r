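random_nuisance <- function(T, n = 9, seed = 1) {
  set.seed(seed)
  stats::setNames(lapply(seq_len(n), function(i) rnorm(T)),
                  paste0("nuis_", seq_len(n)))
}

# place residuals back on the full time grid (zeros at censored rows)
inflate_rows <- function(vals, kept, T) {
  out <- matrix(0, T, ncol(vals)); out[kept, ] <- vals; out
}

test_that("design columns follow the documented arithmetic", {
  # 9 nuisance + 9 derivatives + order-2 polynomial, no band -> 21 columns
  des <- build_design(140, 2, random_nuisance(140), poly_order = 2)
  expect_equal(ncol(des$X), 21L)
  expect_equal(sum(des$category == "polynomial"), 3L)
  expect_equal(sum(des$category == "nuisance"), 9L)
  expect_equal(sum(des$category == "derivative"), 9L)

  # T=100, TR=2, band 0.01-0.1 Hz: stop frequencies k/200 for k in {1, 21..50},
  # sine+cosine each except Nyquist (k=50, cosine only) -> 61 columns
  des <- build_design(100, 2, poly_order = 0, band_hz = c(0.01, 0.1))
  expect_equal(sum(des$category == "bandpass_stop"), 61L)

  # a band covering (0, Nyquist) leaves no stop-band columns
  des <- build_design(100, 2, poly_order = 0, band_hz = c(0.004, 0.25))
  expect_equal(sum(des$category == "bandpass_stop"), 0L)

  expect_error(build_design(100, 2, band_hz = c(0.3, 0.4)), "Nyquist")
})

test_that("derivatives are backward differences with a leading zero", {
  x <- cumsum(rnorm(30))
  des <- build_design(30, 2, list(a = x), poly_order = 0)
  expect_equal(des$X[, "d_a"], c(0, diff(x)))
})

test_that("residual degrees of freedom reproduce the run-length arithmetic", {
  # 140 retained points, 21-column full-rank design, no band -> 119
  expect_equal(residual_dof(build_design(140, 2, random_nuisance(140))), 119L,
               ignore_attr = TRUE)
  # 720 points, same design -> 699
  expect_equal(residual_dof(build_design(720, 2, random_nuisance(720))), 699L,
               ignore_attr = TRUE)
  # truly empty design, no censoring: dof = number of time points
  des <- build_design(100, 2)
  des$X <- des$X[, 0, drop = FALSE]; des$category <- character(0)
  expect_equal(residual_dof(des), 100L, ignore_attr = TRUE)
})

test_that("a saturated design reports zero dof with the over-determined flag", {
  des <- build_design(30, 2, random_nuisance(30, n = 20), poly_order = 2,
                      band_hz = c(0.01, 0.1))
  cm <- tibble::tibble(t = 1:30, keep = c(rep(TRUE, 25), rep(FALSE, 5)))
  dof <- residual_dof(des, cm)
  expect_equal(as.integer(dof), 0L)
  expect_true(isTRUE(attr(dof, "over_determined")))
})

test_that("dof bookkeeping holds under censoring: dof + rank = retained rows", {
  set.seed(4)
  for (i in 1:5) {
    T <- 60
    keep <- runif(T) > 0.2
    cm <- tibble::tibble(t = 1:T, keep = keep)
    des <- build_design(T, 2, random_nuisance(T, n = 4, seed = i),
                        band_hz = c(0.02, 0.2), mask = cm)
    g <- glance(des)
    expect_equal(g$dof + g$rank, sum(keep))
  }
})

test_that("censoring additional rows never increases dof", {
  des <- build_design(80, 2, random_nuisance(80, n = 5), band_hz = c(0.01, 0.1))
  keep <- rep(TRUE, 80)
  last <- residual_dof(des)
  set.seed(11)
  for (k in 1:20) {
    keep[sample(which(keep), 2)] <- FALSE
    cur <- residual_dof(des, tibble::tibble(t = 1:80, keep = keep))
    expect_lte(as.integer(cur), as.integer(last))
    expect_gte(as.integer(cur), as.integer(last) - 2L)
    last <- cur
  }
})

test_that("projection annihilates the design span and nothing more", {
  T <- 64
  nuis <- random_nuisance(T, n = 3, seed = 2)
  des <- build_design(T, 2, nuis, poly_order = 2, band_hz = c(0.05, 0.2))

  # a series equal to a design column leaves a zero residual
  res <- project_nuisance(nuis$nuis_2, des)
  expect_lt(max(abs(res$values)), 1e-8)

  # residuals are orthogonal to every design column on retained rows
  set.seed(3)
  res <- project_nuisance(matrix(rnorm(T * 4), T, 4), des)
  Xk <- des$X[des$keep, ]
  dots <- crossprod(Xk, res$values)
  norms <- outer(sqrt(colSums(Xk^2)), sqrt(colSums(res$values^2)))
  expect_lt(max(abs(dots) / pmax(norms, 1e-12)), 1e-8)

  # projection is idempotent
  res2 <- project_nuisance(inflate_rows(res$values, res$kept, T), des)
  expect_lt(max(abs(res2$values - res$values)) /
              max(abs(res$values)), 1e-10)
})

test_that("stop-band sinusoids are removed and pass-band ones survive", {
  T <- 100; tr <- 2
  des <- build_design(T, tr, poly_order = 0, band_hz = c(0.01, 0.1))
  tt <- (seq_len(T) - 1) * tr

  # out-of-band DFT frequency (k=30 -> 0.15 Hz): annihilated
  x_out <- sin(2 * pi * (30 / (T * tr)) * tt + 0.7)
  res <- project_nuisance(x_out, des)
  expect_lt(sum(res$values^2), 1e-10 * sum(x_out^2))

  # in-band DFT frequency (k=10 -> 0.05 Hz) with a constant-only design:
  # residual equals the series minus its mean
  des0 <- build_design(T, tr, poly_order = 0)
  x_in <- sin(2 * pi * (10 / (T * tr)) * tt + 0.3)
  res <- project_nuisance(x_in, des0)
  expect_equal(as.vector(res$values), x_in - mean(x_in), tolerance = 1e-10)

  # and the full band-stop design leaves the in-band sinusoid intact
  res <- project_nuisance(x_in, des)
  expect_gt(sum(res$values^2), 0.99 * sum((x_in - mean(x_in))^2))
})

test_that("total residual power at stop-band DFT frequencies is negligible", {
  T <- 96; tr <- 2.5
  des <- build_design(T, tr, random_nuisance(T, n = 2, seed = 6),
                      poly_order = 2, band_hz = c(0.02, 0.1))
  set.seed(7)
  y <- rnorm(T)
  res <- project_nuisance(y, des)
  sp <- Mod(stats::fft(as.vector(res$values)))^2
  freqs <- (seq_len(T) - 1) / (T * tr)
  stop_bins <- freqs > 0 & freqs <= 1 / (2 * tr) &
    (freqs < 0.02 - 1e-9 | freqs > 0.1 + 1e-9)
  expect_lt(sum(sp[stop_bins]), 1e-10 * sum(y^2))
})

test_that("nuisance extraction averages masks and honours the GSR toggle", {
  b <- small_subject()
  # a uniform volume returns its own time course as the global mean
  d <- dim(b$volume$values)
  f <- sin(seq_len(d[4]))
  uni <- vol4d(array(rep(f, each = prod(d[1:3])), d))
  ser <- extract_nuisance_series(uni, list(global = b$brain_mask),
                                 motion = NULL, wm = FALSE, csf = FALSE,
                                 motion_params = FALSE)
  expect_equal(ser$global, f)

  masks <- list(global = b$brain_mask, wm = b$wm_mask, csf = b$csf_mask)
  ser <- extract_nuisance_series(b$volume, masks, b$motion)
  expect_equal(length(ser), 9L)

  # GSR off -> 8 series (WM, CSF, 6 motion)
  ser <- extract_nuisance_series(b$volume, masks, b$motion, global = FALSE)
  expect_equal(length(ser), 8L)
  expect_false("global" %in% names(ser))

  # the white-matter compartment carries no network signal
  r <- abs(cor(ser$wm, b$truth$network_tcs))
  expect_true(all(r < 0.25))

  empty <- brain_mask(array(FALSE, d[1:3]))
  expect_error(extract_nuisance_series(b$volume, list(global = empty)),
               "empty")
})
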