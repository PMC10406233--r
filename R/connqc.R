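#' Fisher-Z transform of correlation coefficients
#'
#' `fisher_z()` is atanh with r clipped to +/-(1 - 1e-7) so perfect
#' correlations stay finite; `inv_fisher_z()` is tanh.
#'
#' @param r,z numeric.
#' @return numeric of the same shape.
#' @export
fisher_z <- function(r) atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))

#' @rdname fisher_z
#' @export
inv_fisher_z <- function(z) tanh(z)

#' Seed region specification
#'
#' A spherical seed in world (template) coordinates. Voxel membership is
#' decided by the Euclidean distance from the voxel centre to the seed
#' centre in mm. Printed coordinate triplets from different conventions can
#' be mapped by flipping signs before construction; the package interprets
#' `center_mm` on the world axes L-R (+R), P-A (+A), I-S (+S).
#'
#' @param name seed label.
#' @param center_mm length-3 world coordinate (mm).
#' @param radius_mm sphere radius (mm), > 0; default 4.
#' @return A `seed_spec` list.
#' @export
seed_spec <- function(name, center_mm, radius_mm = 4) {
  stopifnot(length(center_mm) == 3L, radius_mm > 0)
  structure(list(name = name, center_mm = as.numeric(center_mm),
                 radius_mm = radius_mm),
            class = "seed_spec")
}

#' The four review seeds
#'
#' Posterior cingulate (default mode), left primary motor, left auditory and
#' left primary visual seeds, 4 mm radius, for visual review of the
#' corresponding canonical networks.
#'
#' @return A named list of [seed_spec] objects.
#' @export
default_seeds <- function() {
  list(
    pcc = seed_spec("posterior_cingulate", c(0, 50, 31)),
    motor = seed_spec("left_motor", c(36, 20, 60)),
    auditory = seed_spec("left_auditory", c(43, 25, 14)),
    visual = seed_spec("left_visual", c(30, 87, 9))
  )
}

#' Seed-based correlation map
#'
#' Averages the (residual) signal over the seed sphere and correlates the
#' seed time course with every in-mask voxel.
#'
#' @param volume a [vol4d] of residual data.
#' @param mask a [brain_mask].
#' @param seed a [seed_spec].
#' @param kept optional integer vector of retained time points (censored
#'   points excluded from the correlation); default all.
#' @return 3D array of Pearson r (NA outside the mask and at zero-variance
#'   voxels), with attribute `n_seed_voxels`.
#' @export
seed_map <- function(volume, mask, seed, kept = NULL) {
  check_same_grid(volume, mask)
  idx <- which(mask$values, arr.ind = TRUE)
  xyz <- voxel_coords_mm(volume, idx)
  d2 <- (xyz[, 1] - seed$center_mm[1])^2 + (xyz[, 2] - seed$center_mm[2])^2 +
    (xyz[, 3] - seed$center_mm[3])^2
  in_seed <- d2 <= seed$radius_mm^2
  if (!any(in_seed)) {
    stop("seed '", seed$name, "' does not intersect the mask", call. = FALSE)
  }
  Y <- vol_matrix(volume, mask)
  if (!is.null(kept)) Y <- Y[kept, , drop = FALSE]
  sc <- rowMeans(Y[, in_seed, drop = FALSE])
  sdv <- apply(Y, 2, stats::sd)
  r <- rep(NA_real_, ncol(Y))
  r[sdv > 0] <- as.vector(stats::cor(Y[, sdv > 0, drop = FALSE], sc))
  map <- array(NA_real_, spatial_dims(volume))
  map[mask$values] <- r
  attr(map, "n_seed_voxels") <- sum(in_seed)
  map
}

#' Parcellated functional connectivity matrix
#'
#' Region-mean time courses are correlated pairwise (Pearson) over the
#' retained time points; optionally Fisher-Z transformed. A region whose
#' mean series has zero variance yields undefined (NA) edges, which are
#' counted and propagated.
#'
#' @param x a [vol4d] (with `parc`) or a T x R matrix of region series
#'   (columns named by region id).
#' @param parc a [parcellation]; required when `x` is a volume.
#' @param fisher_z apply the Fisher-Z transform (default TRUE).
#' @param kept optional integer vector of retained time points.
#' @return An `fc_matrix`: list with `values` (R x R symmetric), `fisher_z`,
#'   `region_ids`, `n_undefined_edges`.
#' @export
fc_matrix <- function(x, parc = NULL, fisher_z = TRUE, kept = NULL) {
  S <- if (inherits(x, "vol4d")) {
    stopifnot(!is.null(parc))
    roi_series(x, parc)
  } else {
    as.matrix(x)
  }
  if (is.null(colnames(S))) colnames(S) <- as.character(seq_len(ncol(S)))
  if (!is.null(kept)) S <- S[kept, , drop = FALSE]
  if (ncol(S) < 2L) stop("need at least 2 regions", call. = FALSE)
  if (nrow(S) < 3L) stop("need at least 3 retained time points", call. = FALSE)
  sdv <- apply(S, 2, stats::sd)
  R <- suppressWarnings(stats::cor(S))
  R[sdv == 0, ] <- NA_real_
  R[, sdv == 0] <- NA_real_
  diag(R) <- 1
  vals <- if (fisher_z) {
    z <- fisher_z(R); diag(z) <- 0; z
  } else R
  new_fc_matrix(vals, fisher_z, colnames(S))
}

new_fc_matrix <- function(values, fisher_z, region_ids) {
  ut <- upper.tri(values)
  structure(list(values = values, fisher_z = fisher_z,
                 region_ids = region_ids,
                 n_undefined_edges = sum(is.na(values[ut]))),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  n <- nrow(x$values)
  cat(sprintf("<fc_matrix> %d regions, %d edges%s%s\n", n, n * (n - 1) / 2,
              if (x$fisher_z) ", Fisher-Z" else ", r",
              if (x$n_undefined_edges)
                sprintf(", %d undefined", x$n_undefined_edges) else ""))
  invisible(x)
}

#' Edge vector of an FC matrix (upper triangle, no diagonal)
#' @param fc an `fc_matrix`.
#' @return numeric vector of edge values.
#' @export
fc_edges <- function(fc) fc$values[upper.tri(fc$values)]

#' Group-average functional connectivity matrix
#'
#' Edgewise mean over subjects, computed in Fisher-Z space. Undefined edges
#' are excluded per edge, with contribution counts recorded. Optionally a
#' leave-one-out mean for a chosen subject.
#'
#' @param matrices list of `fc_matrix` objects with identical regions and
#'   Fisher-Z state (must be Fisher-Z).
#' @param leave_out optional index of a subject to exclude from the mean.
#' @return An `fc_matrix` (the mean), with attribute `n_per_edge`.
#' @export
group_mean_fc <- function(matrices, leave_out = NULL) {
  if (length(matrices) < 2L) stop("need at least 2 matrices", call. = FALSE)
  ids <- matrices[[1]]$region_ids
  for (m in matrices) {
    if (!identical(m$region_ids, ids)) stop("matrices have different regions", call. = FALSE)
    if (!m$fisher_z) stop("group mean is computed in Fisher-Z space; transform first",
                          call. = FALSE)
  }
  use <- if (is.null(leave_out)) seq_along(matrices) else
    setdiff(seq_along(matrices), leave_out)
  arr <- simplify2array(lapply(matrices[use], function(m) m$values))
  mean_v <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  n_per <- apply(arr, c(1, 2), function(v) sum(!is.na(v)))
  mean_v[n_per == 0] <- NA_real_
  out <- new_fc_matrix(mean_v, TRUE, ids)
  attr(out, "n_per_edge") <- n_per
  out
}

#' Similarity of a subject's FC matrix to the group mean
#'
#' Pearson correlation and Euclidean distance ("dissimilarity") between the
#' subject's and the group's edge vectors (upper triangle, diagonal
#' excluded). High-quality subjects resemble the group mean; subjects with
#' few residual degrees of freedom or artifacts drift away from it.
#'
#' @param subject,group `fc_matrix` objects over the same regions.
#' @return One-row tibble: `pearson`, `dissimilarity`, `n_edges`.
#' @export
fc_similarity <- function(subject, group) {
  if (!identical(subject$region_ids, group$region_ids)) {
    stop("matrices have different regions", call. = FALSE)
  }
  a <- fc_edges(subject); b <- fc_edges(group)
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero-variance edge vector", call. = FALSE)
  }
  tibble::tibble(pearson = stats::cor(a, b),
                 dissimilarity = sqrt(sum((a - b)^2)),
                 n_edges = sum(ok))
}

#' Per-subject similarity to the group mean across a cohort
#'
#' @param matrices list of Fisher-Z `fc_matrix` objects.
#' @param leave_one_out exclude each subject from its own group mean
#'   (default FALSE: the literal group average).
#' @return Tibble with one row per subject: `subject`, `pearson`,
#'   `dissimilarity`.
#' @export
cohort_similarity <- function(matrices, leave_one_out = FALSE) {
  grand <- if (leave_one_out) NULL else group_mean_fc(matrices)
  purrr::map_dfr(seq_along(matrices), function(i) {
    g <- if (leave_one_out) group_mean_fc(matrices, leave_out = i) else grand
    dplyr::mutate(fc_similarity(matrices[[i]], g), subject = i,
                  .before = 1)
  })
}

#' QC-FC: correlation of connectivity with motion across subjects
#'
#' For every edge, the Pearson correlation across subjects between the
#' (Fisher-Z) edge value and the subject's mean volume-to-volume motion. A
#' clean pipeline leaves these correlations centred on zero; residual motion
#' artifact shifts them. The distance dependence — the correlation of the
#' per-edge QC-FC values with inter-node Euclidean distance — diagnoses the
#' short-range inflation typical of motion. Its 95% CI uses the Fisher-Z
#' interval with n = number of edges; edges are treated as independent,
#' which is anti-conservative, but matches how such intervals are commonly
#' reported.
#'
#' @param matrices list of Fisher-Z `fc_matrix` objects (>= 3 subjects).
#' @param mean_enorms numeric vector of per-subject mean motion (mm).
#' @param centroids matrix/data frame of per-region world coordinates (R x
#'   3, in region order), or NULL to skip distance dependence.
#' @param bins number of histogram bins on [-1, 1] (default 101).
#' @return A `qcfc_result`: list with `edge_r`, `edge_index` (i, j), `mean_r`,
#'   `histogram` (tibble `mid`, `count`), `distance_mm`,
#'   `distance_dependence_r`, `distance_ci95`, `n_excluded_edges`,
#'   `n_subjects`.
#' @export
qcfc <- function(matrices, mean_enorms, centroids = NULL, bins = 101) {
  n <- length(matrices)
  if (n < 3L) stop("QC-FC needs at least 3 subjects", call. = FALSE)
  stopifnot(length(mean_enorms) == n)
  if (!all(is.finite(mean_enorms)) || stats::sd(mean_enorms) == 0) {
    stop("mean_enorms must be finite with nonzero variance", call. = FALSE)
  }
  for (m in matrices) if (!m$fisher_z) {
    stop("QC-FC is computed on Fisher-Z matrices", call. = FALSE)
  }
  E <- do.call(rbind, lapply(matrices, fc_edges))   # subjects x edges
  ok_edge <- apply(E, 2, function(v) all(is.finite(v)) && stats::sd(v) > 0)
  edge_r <- rep(NA_real_, ncol(E))
  edge_r[ok_edge] <- as.vector(stats::cor(E[, ok_edge, drop = FALSE],
                                          mean_enorms))
  R <- nrow(matrices[[1]]$values)
  ij <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  br <- seq(-1, 1, length.out = bins + 1)
  h <- graphics::hist(edge_r[ok_edge], breaks = br, plot = FALSE)

  dist_mm <- dd_r <- ci <- NULL
  if (!is.null(centroids)) {
    C <- as.matrix(centroids)
    stopifnot(nrow(C) == R, ncol(C) == 3L)
    dist_mm <- sqrt(rowSums((C[ij[, 1], ] - C[ij[, 2], ])^2))
    use <- ok_edge
    dd_r <- stats::cor(edge_r[use], dist_mm[use])
    n_e <- sum(use)
    zz <- atanh(dd_r)
    half <- 1.96 / sqrt(n_e - 3)
    ci <- tanh(c(zz - half, zz + half))
  }
  structure(list(edge_r = edge_r, edge_index = ij, mean_r = mean(edge_r[ok_edge]),
                 histogram = tibble::tibble(mid = h$mids, count = h$counts),
                 distance_mm = dist_mm, distance_dependence_r = dd_r,
                 distance_ci95 = ci, n_excluded_edges = sum(!ok_edge),
                 n_subjects = n),
            class = "qcfc_result")
}

#' @export
print.qcfc_result <- function(x, ...) {
  cat(sprintf("<qcfc_result> %d subjects, %d edges; mean QC-FC %.4f\n",
              x$n_subjects, length(x$edge_r), x$mean_r))
  if (!is.null(x$distance_dependence_r)) {
    cat(sprintf("  distance dependence r = %.4f (95%% CI %.4f, %.4f)\n",
                x$distance_dependence_r, x$distance_ci95[1], x$distance_ci95[2]))
  }
  invisible(x)
}

#' Censoring-threshold / band-pass sweep over a cohort
#'
#' Re-runs censoring, design construction, censored nuisance projection,
#' FC-matrix estimation and group-mean similarity for every combination of
#' censoring threshold and band option, from region-level series. This is
#' the engine behind choosing a censoring threshold: it exposes how the
#' degrees of freedom, and with them the similarity of each subject's
#' connectivity to the group mean, move as the threshold tightens or the
#' stop-band projection is dropped.
#'
#' @param subjects list of per-subject inputs, each a list with elements
#'   `roi` (T x R region series), `nuisance` (named list of length-T
#'   series), `motion` (a [motion_trace]).
#' @param thresholds numeric censoring thresholds (mm).
#' @param bands list of band options (each a length-2 numeric or NULL).
#' @param tr_s repetition time (s).
#' @param poly_order polynomial drift order (default 2).
#' @return A `sweep_table` tibble with one row per (threshold, band,
#'   subject): `threshold_mm`, `band`, `subject`, `mean_enorm_mm`,
#'   `n_good`, `dof`, `pearson`, `dissimilarity`. The per-cell Fisher-Z
#'   matrices are attached as attribute `matrices` (a nested list keyed by
#'   cell label).
#' @export
threshold_sweep <- function(subjects, thresholds, bands = list(NULL),
                            tr_s, poly_order = 2) {
  enorms <- lapply(subjects, function(s) compute_enorm(s$motion))
  rows <- list()
  mats_by_cell <- list()
  for (thr in thresholds) {
    for (b in bands) {
      band_lab <- if (is.null(b)) "none" else
        sprintf("%g-%g", b[1], b[2])
      cell <- sprintf("thr%g_band_%s", thr, band_lab)
      mats <- vector("list", length(subjects))
      meta <- vector("list", length(subjects))
      for (i in seq_along(subjects)) {
        s <- subjects[[i]]
        cm <- censor_mask(enorms[[i]], thr)
        des <- build_design(nrow(s$roi), tr_s, s$nuisance,
                            poly_order = poly_order, band_hz = b, mask = cm)
        resid <- project_nuisance(s$roi, des)
        mats[i] <- list(if (resid$dof >= 3L) {
          fc_matrix(resid$values, fisher_z = TRUE)
        } else NULL)
        ms <- motion_summary(enorms[[i]], cm, tr_s)
        meta[[i]] <- tibble::tibble(
          threshold_mm = thr, band = band_lab, subject = i,
          mean_enorm_mm = ms$mean_enorm_mm, n_good = ms$n_good,
          dof = resid$dof
        )
      }
      usable <- !vapply(mats, is.null, logical(1))
      sim <- tibble::tibble(subject = seq_along(subjects),
                            pearson = NA_real_, dissimilarity = NA_real_)
      if (sum(usable) >= 2L) {
        cs <- cohort_similarity(mats[usable])
        sim$pearson[which(usable)[cs$subject]] <- cs$pearson
        sim$dissimilarity[which(usable)[cs$subject]] <- cs$dissimilarity
      }
      cell_tab <- dplyr::left_join(dplyr::bind_rows(meta), sim, by = "subject")
      rows[[cell]] <- cell_tab
      mats_by_cell[[cell]] <- mats
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "matrices") <- mats_by_cell
  class(out) <- c("sweep_table", class(out))
  out
}

#' Summarise a threshold sweep per cell
#'
#' For each (threshold, band) cell: the R-squared of subject similarity on
#' mean motion, the mean QC-FC, and the count of subjects excluded under the
#' degrees-of-freedom and good-seconds cutoffs.
#'
#' @param sweep a `sweep_table` from [threshold_sweep()].
#' @param mean_enorms per-subject mean motion used for QC-FC (defaults to
#'   the values in the table).
#' @param config a [run_config] supplying `dof_cutoff` and
#'   `min_good_seconds`; `tr_s` converts `n_good` to seconds.
#' @return Tibble with one row per cell: `threshold_mm`, `band`,
#'   `r2_similarity_motion`, `mean_qcfc`, `n_low_dof`, `n_short`,
#'   `median_dof`.
#' @export
sweep_summary <- function(sweep, config, mean_enorms = NULL) {
  mats_by_cell <- attr(sweep, "matrices")
  sweep |>
    dplyr::group_by(.data$threshold_mm, .data$band) |>
    dplyr::group_modify(function(df, key) {
      ok <- is.finite(df$pearson) & is.finite(df$mean_enorm_mm)
      r2 <- if (sum(ok) >= 3L && stats::sd(df$mean_enorm_mm[ok]) > 0 &&
                stats::sd(df$pearson[ok]) > 0) {
        stats::cor(df$pearson[ok], df$mean_enorm_mm[ok])^2
      } else NA_real_
      cell <- sprintf("thr%g_band_%s", key$threshold_mm, key$band)
      mats <- mats_by_cell[[cell]]
      usable <- !vapply(mats, is.null, logical(1))
      me <- if (is.null(mean_enorms)) df$mean_enorm_mm else mean_enorms
      mq <- if (sum(usable) >= 3L && stats::sd(me[usable]) > 0) {
        qcfc(mats[usable], me[usable])$mean_r
      } else NA_real_
      tibble::tibble(
        r2_similarity_motion = r2,
        mean_qcfc = mq,
        n_low_dof = sum(df$dof < config$dof_cutoff),
        n_short = sum(df$n_good * config$tr_s < config$min_good_seconds),
        median_dof = stats::median(df$dof)
      )
    }) |>
    dplyr::ungroup()
}
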