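#' Temporal signal-to-noise ratio
#'
#' Per-voxel mean over time divided by standard deviation over time
#' (denominator T - 1), computed on the original, un-regressed series.
#' Zero-variance voxels are undefined, counted, and excluded from the
#' in-mask summary. TSNR drops with head motion, coil spiking and thermal
#' noise, so the in-mask mean compared across subjects at one site is a
#' cheap artifact screen.
#'
#' @param volume a [vol4d].
#' @param mask a [brain_mask] on the same grid.
#' @return A `tsnr_result`: list with `map` (3D array, NA where undefined),
#'   `mean_in_mask`, `n_undefined`.
#' @export
tsnr <- function(volume, mask) {
  if (n_timepoints(volume) < 2L) stop("TSNR needs at least 2 time points", call. = FALSE)
  Y <- vol_matrix(volume, mask)          # T x V
  mu <- colMeans(Y)
  sdv <- apply(Y, 2, stats::sd)
  val <- ifelse(sdv > 0, mu / sdv, NA_real_)
  map <- array(NA_real_, spatial_dims(volume))
  map[mask$values] <- val
  structure(list(map = map,
                 mean_in_mask = mean(val, na.rm = TRUE),
                 n_undefined = sum(sdv == 0)),
            class = "tsnr_result")
}

#' @export
print.tsnr_result <- function(x, ...) {
  cat(sprintf("<tsnr_result> mean in-mask TSNR %.2f (%d undefined voxels)\n",
              x$mean_in_mask, x$n_undefined))
  invisible(x)
}

#' Spatial smoothness (FWHM) estimation
#'
#' Estimates the full width at half maximum of the effective spatial
#' smoothing kernel in each cardinal direction from the variance of first
#' spatial differences, assuming a Gaussian spatial autocorrelation. With
#' sigma2 the spatial variance of in-mask values and sigma_d2 the variance
#' of differences between in-mask neighbours along direction d (voxel size
#' delta_d):
#' \deqn{FWHM_d = \Delta_d \sqrt{\frac{-2\ln 2}{\ln(1 - \sigma_\Delta^2 / 2\sigma^2)}}}
#' For 4D input each time point is treated as an independent noise image
#' (after per-voxel linear detrending when `detrend = TRUE`) and the
#' per-direction estimates are averaged over time. When the measured
#' roughness reaches or exceeds that of spatially independent noise
#' (sigma_d2 >= 2 sigma2) the direction's FWHM is reported as 0; estimates
#' below about one voxel are therefore not meaningful, and the estimator is
#' intended for data at least as smooth as the grid.
#'
#' @param volume a [vol4d] or [vol3d].
#' @param mask a [brain_mask] on the same grid.
#' @param detrend for 4D input, remove a per-voxel linear trend first
#'   (default TRUE).
#' @return An `fwhm_result`: list with `fwhm_mm` (length 3) and
#'   `combined_mm` (geometric mean).
#' @export
estimate_fwhm <- function(volume, mask, detrend = TRUE) {
  check_same_grid(volume, mask)
  vols <- if (inherits(volume, "vol3d")) {
    list(volume$values)
  } else {
    Y <- vol_matrix(volume, mask)
    if (detrend && nrow(Y) >= 3L) {
      tt <- seq_len(nrow(Y))
      Y <- stats::resid(stats::lm.fit(cbind(1, tt), Y))
    }
    d3 <- spatial_dims(volume)
    lapply(seq_len(nrow(Y)), function(t) {
      a <- array(NA_real_, d3)
      a[mask$values] <- Y[t, ]
      a
    })
  }
  member <- mask$values
  if (inherits(volume, "vol3d")) {
    # restrict to mask, leave out-of-mask as NA
    vols <- lapply(vols, function(a) { a[!member] <- NA_real_; a })
  }
  ests <- vapply(vols, function(a) fwhm_one_volume(a, member, volume$voxel_mm),
                 numeric(3))
  fwhm <- rowMeans(ests, na.rm = TRUE)
  if (any(!is.finite(fwhm))) {
    stop("smoothness undefined: zero spatial variance within the mask", call. = FALSE)
  }
  structure(list(fwhm_mm = fwhm, combined_mm = prod(fwhm)^(1 / 3)),
            class = "fwhm_result")
}

fwhm_one_volume <- function(a, member, voxel_mm) {
  vals <- a[member]
  s2 <- stats::var(vals)
  if (!is.finite(s2) || s2 <= 0) return(rep(NA_real_, 3))
  out <- numeric(3)
  d <- dim(a)
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2L) { out[ax] <- NA_real_; next }
    hi <- slice_shift(a, ax, -1L); hi_m <- slice_shift(member, ax, -1L)
    lo <- slice_shift(a, ax, 1L);  lo_m <- slice_shift(member, ax, 1L)
    pair <- hi_m & lo_m
    if (sum(pair) < 2L) { out[ax] <- NA_real_; next }
    dv <- (hi[pair] - lo[pair])
    sd2 <- stats::var(dv)
    arg <- 1 - sd2 / (2 * s2)
    out[ax] <- if (arg <= 0) 0 else
      voxel_mm[ax] * sqrt(-2 * log(2) / log(arg))
  }
  out
}

# Neighbour slabs along one axis: shift = -1 drops the first slice,
# shift = 1 drops the last, so hi/lo pairs are offset by one voxel.
slice_shift <- function(a, ax, shift) {
  d <- dim(a)
  idx <- rep(list(quote(expr = )), 3)
  idx[[ax]] <- if (shift < 0) 2:d[ax] else 1:(d[ax] - 1)
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

#' @export
print.fwhm_result <- function(x, ...) {
  cat(sprintf("<fwhm_result> x %.2f, y %.2f, z %.2f mm; combined %.2f mm\n",
              x$fwhm_mm[1], x$fwhm_mm[2], x$fwhm_mm[3], x$combined_mm))
  invisible(x)
}

#' Masked Gaussian blur of a 3D or 4D volume
#'
#' Separable FFT convolution with a Gaussian kernel, renormalised by the
#' blurred mask so that signal does not bleed across the mask boundary.
#'
#' @param volume a [vol4d] or [vol3d].
#' @param mask a [brain_mask].
#' @param fwhm_mm kernel FWHM in mm (scalar, isotropic).
#' @return Object of the same class with smoothed in-mask values
#'   (out-of-mask voxels unchanged).
#' @export
gaussian_blur <- function(volume, mask, fwhm_mm) {
  check_same_grid(volume, mask)
  stopifnot(fwhm_mm > 0)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d3 <- spatial_dims(volume)
  K <- gauss_kernel_fft(d3, volume$voxel_mm, sigma_mm)
  member <- mask$values
  mnorm <- Re(stats::fft(stats::fft(array(as.numeric(member), d3)) * K,
                         inverse = TRUE)) / prod(d3)
  blur_one <- function(a) {
    src <- a; src[!member] <- 0
    num <- Re(stats::fft(stats::fft(src) * K, inverse = TRUE)) / prod(d3)
    out <- a
    out[member] <- num[member] / mnorm[member]
    out
  }
  if (inherits(volume, "vol3d")) {
    volume$values <- blur_one(volume$values)
  } else {
    for (t in seq_len(n_timepoints(volume))) {
      volume$values[, , , t] <- blur_one(volume$values[, , , t])
    }
  }
  volume
}

gauss_kernel_fft <- function(d3, voxel_mm, sigma_mm) {
  axes <- lapply(1:3, function(ax) {
    n <- d3[ax]
    x <- (seq_len(n) - 1)
    x <- pmin(x, n - x) * voxel_mm[ax]   # circular distance
    k <- exp(-x^2 / (2 * sigma_mm^2))
    k / sum(k)
  })
  kern <- outer(outer(axes[[1]], axes[[2]]), axes[[3]])
  dim(kern) <- d3
  stats::fft(kern)
}

#' Iteratively smooth a volume to a target smoothness
#'
#' Multi-site data arrive at different intrinsic smoothness; rather than
#' adding a fixed blur, each dataset is smoothed just enough to land at a
#' common target FWHM. Each iteration estimates the current combined FWHM
#' and, if short of the target, applies a Gaussian whose width fills the
#' quadrature gap \eqn{\sigma_{step}^2 = \sigma_{target}^2 - \sigma_{cur}^2}.
#'
#' @param volume a [vol4d] or [vol3d].
#' @param mask a [brain_mask].
#' @param target_mm target combined FWHM in mm (default 8).
#' @param tol_frac relative tolerance for convergence (default 0.05).
#' @param max_iter maximum iterations (default 10; warning if reached).
#' @return The smoothed volume, with attributes `fwhm_mm` (final combined
#'   estimate) and `n_iter`.
#' @export
blur_to_fwhm <- function(volume, mask, target_mm = 8, tol_frac = 0.05,
                         max_iter = 10) {
  cur <- estimate_fwhm(volume, mask)$combined_mm
  if (cur > target_mm * (1 + tol_frac)) {
    stop(sprintf(paste0("data are already smoother (combined FWHM %.2f mm) ",
                        "than the target %.2f mm"), cur, target_mm),
         call. = FALSE)
  }
  iter <- 0L
  while (abs(cur - target_mm) > tol_frac * target_mm && iter < max_iter) {
    # fill the quadrature gap between current and target width
    gap2 <- target_mm^2 - max(cur, 0)^2
    if (gap2 <= 0) break
    volume <- gaussian_blur(volume, mask, sqrt(gap2))
    cur <- estimate_fwhm(volume, mask)$combined_mm
    iter <- iter + 1L
  }
  if (abs(cur - target_mm) > tol_frac * target_mm) {
    warning(sprintf("blur_to_fwhm stopped at %.2f mm after %d iterations",
                    cur, iter), call. = FALSE)
  }
  attr(volume, "fwhm_mm") <- cur
  attr(volume, "n_iter") <- iter
  volume
}

#' Dice overlap of two masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}, in [0, 1]. Used to audit EPI-to-T1 and
#' T1-to-template alignment via whole-brain mask overlap.
#'
#' @param a,b [brain_mask] objects on the same grid.
#' @return Scalar Dice coefficient.
#' @export
dice <- function(a, b) {
  check_same_grid(a, b)
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0L) stop("both masks are empty", call. = FALSE)
  2 * sum(a$values & b$values) / (na + nb)
}

#' Functional connectivity strength (FCS)
#'
#' The average correlation of each voxel with all brain voxels, computed
#' through its algebraic identity: the correlation of each voxel's series
#' with the scaled global signal (every in-mask series divided by its own
#' standard deviation, then averaged over the brain). A loose RF coil
#' element produces spikes simultaneously across large parts of the image,
#' inflating FCS even when TSNR barely moves. The map includes the
#' self-correlation term (an O(1/V) offset relative to "all other voxels").
#'
#' @param x a [vol4d] of residual (post-regression) data, or a T x V numeric
#'   matrix of series.
#' @param mask a [brain_mask]; required when `x` is a volume.
#' @return An `fcs_result`: list with `map` (3D when input was a volume,
#'   else a vector), `mean_in_mask`, `scaled_global` (length-T series),
#'   `n_zero_var`.
#' @export
fcs <- function(x, mask = NULL) {
  if (inherits(x, "vol4d")) {
    stopifnot(!is.null(mask))
    Y <- vol_matrix(x, mask)
  } else {
    Y <- as.matrix(x)
  }
  if (nrow(Y) < 3L) stop("FCS needs at least 3 time points", call. = FALSE)
  sdv <- apply(Y, 2, stats::sd)
  ok <- sdv > 0
  if (!any(ok)) stop("all voxels have zero variance", call. = FALSE)
  scaled <- sweep(Y[, ok, drop = FALSE], 2, sdv[ok], `/`)
  g <- rowMeans(scaled)
  r <- as.vector(stats::cor(Y[, ok, drop = FALSE], g))
  vals <- rep(NA_real_, ncol(Y))
  vals[ok] <- r
  map <- if (inherits(x, "vol4d")) {
    m <- array(NA_real_, spatial_dims(x)); m[mask$values] <- vals; m
  } else vals
  structure(list(map = map, mean_in_mask = mean(r),
                 scaled_global = g, n_zero_var = sum(!ok)),
            class = "fcs_result")
}

#' @export
print.fcs_result <- function(x, ...) {
  cat(sprintf("<fcs_result> mean in-mask FCS %.3f (%d zero-variance voxels)\n",
              x$mean_in_mask, x$n_zero_var))
  invisible(x)
}

#' Left-right flip check
#'
#' An accidental left-right flip of either the functional or the structural
#' image is invisible in a near-symmetric brain unless the two are compared:
#' the alignment cost between the EPI and the T1 is evaluated as-is and with
#' the T1 mirrored about the mid-sagittal plane (the grid axis mapped to L-R
#' by the orientation code). Inputs must already be aligned and resampled to
#' one grid; only an exhaustive integer-voxel translation search (within
#' `max_shift_mm` per axis) is performed for each candidate, mimicking a
#' final registration polish. If the mirrored cost is lower by more than
#' `margin`, one of the images is likely flipped. Ties favour "not flipped".
#'
#' @param epi a [vol3d] (e.g. mean functional image).
#' @param t1 a [vol3d] structural image on the same grid.
#' @param mask a [brain_mask].
#' @param margin minimum cost improvement to call a flip (default 0.005).
#' @param max_shift_mm translation search range per axis (default 10 mm).
#' @return A `flip_result`: list with `cost_original`, `cost_flipped`,
#'   `flipped`, `margin`. Costs are negative Pearson correlations (lower is
#'   better).
#' @export
check_lr_flip <- function(epi, t1, mask, margin = 0.005, max_shift_mm = 10) {
  check_same_grid(epi, t1)
  check_same_grid(epi, mask)
  lr_axis <- which(vapply(strsplit(epi$orientation, "")[[1]],
                          function(l) ORIENT_AXES[[l]] == 1L, logical(1)))
  t1_flip <- flip_axis(t1, lr_axis)
  cost_orig <- best_translation_cost(epi$values, t1$values, mask$values,
                                     epi$voxel_mm, max_shift_mm)
  cost_flip <- best_translation_cost(epi$values, t1_flip$values, mask$values,
                                     epi$voxel_mm, max_shift_mm)
  structure(list(cost_original = cost_orig, cost_flipped = cost_flip,
                 flipped = cost_flip < cost_orig - margin, margin = margin),
            class = "flip_result")
}

#' @export
print.flip_result <- function(x, ...) {
  cat(sprintf("<flip_result> cost original %.4f, mirrored %.4f -> %s\n",
              x$cost_original, x$cost_flipped,
              if (x$flipped) "LIKELY FLIPPED" else "not flipped"))
  invisible(x)
}

best_translation_cost <- function(a, b, member, voxel_mm, max_shift_mm) {
  shifts <- lapply(1:3, function(ax) {
    s <- floor(max_shift_mm / voxel_mm[ax])
    seq.int(-s, s)
  })
  best <- Inf
  for (dx in shifts[[1]]) for (dy in shifts[[2]]) for (dz in shifts[[3]]) {
    bs <- shift_array(b, c(dx, dy, dz))
    v <- member & is.finite(bs)
    if (sum(v) < 10L) next
    av <- a[v]; bv <- bs[v]
    if (stats::sd(av) == 0 || stats::sd(bv) == 0) next
    cost <- -stats::cor(av, bv)
    if (cost < best) best <- cost
  }
  if (!is.finite(best)) stop("no valid overlap in translation search", call. = FALSE)
  best
}

shift_array <- function(a, by) {
  d <- dim(a)
  out <- array(NA_real_, d)
  src <- dst <- list()
  for (ax in 1:3) {
    s <- by[ax]
    if (abs(s) >= d[ax]) return(out)
    if (s >= 0) { dst[[ax]] <- (1 + s):d[ax]; src[[ax]] <- 1:(d[ax] - s) }
    else        { dst[[ax]] <- 1:(d[ax] + s); src[[ax]] <- (1 - s):d[ax] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}
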