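#' Assemble the per-subject QC record
#'
#' Runs the whole subject-level pipeline — motion series, censoring, design
#' and degrees-of-freedom accounting, TSNR, smoothness, FCS on residual
#' data, optional mask-overlap Dice and left-right flip check — and collects
#' one row of metrics.
#'
#' @param volume a [vol4d] functional series.
#' @param motion a [motion_trace].
#' @param masks named list of [brain_mask] objects (`global`, `wm`, `csf`);
#'   `global` doubles as the analysis mask.
#' @param config a [run_config].
#' @param subject_id subject label.
#' @param t1 optional [vol3d] structural image for the flip check (mean EPI
#'   is compared against it).
#' @param t1_mask,template_mask optional [brain_mask]s for the Dice overlap
#'   metrics (EPI-vs-T1 and T1-vs-template).
#' @param parcellation optional [parcellation]; adds an FC matrix to the
#'   result.
#' @return A `subject_qc` list: `qc` (one-row tibble of metrics), `censor`,
#'   `design`, `residuals`, `fc` (or NULL).
#' @export
subject_qc <- function(volume, motion, masks, config, subject_id = "sub-01",
                       t1 = NULL, t1_mask = NULL, template_mask = NULL,
                       parcellation = NULL) {
  mask <- masks$global
  en <- compute_enorm(motion)
  cm <- censor_mask(en, config$censor_threshold_mm)
  ms <- motion_summary(en, cm, config$tr_s)

  nuis <- extract_nuisance_series(
    volume, masks, motion,
    global = config$nuisance$global, wm = config$nuisance$wm,
    csf = config$nuisance$csf, motion_params = config$nuisance$motion)
  des <- build_design(n_timepoints(volume), config$tr_s, nuis,
                      poly_order = config$poly_order,
                      band_hz = config$band_hz, mask = cm,
                      derivatives = config$nuisance$derivatives)
  dof <- residual_dof(des)
  ts <- tsnr(volume, mask)
  fw <- estimate_fwhm(volume, mask)

  resid <- project_nuisance(vol_matrix(volume, mask), des)
  fcs_mean <- if (resid$dof >= 3L) fcs(resid$values)$mean_in_mask else NA_real_

  dice_e2a <- if (!is.null(t1_mask)) dice(mask, t1_mask) else NA_real_
  dice_a2t <- if (!is.null(t1_mask) && !is.null(template_mask)) {
    dice(t1_mask, template_mask)
  } else NA_real_
  flip <- if (!is.null(t1)) {
    mean_epi <- vol3d(apply(volume$values, 1:3, mean), volume$voxel_mm,
                      volume$origin_mm, volume$orientation)
    check_lr_flip(mean_epi, t1, mask)
  } else NULL

  fc <- if (!is.null(parcellation) && resid$dof >= 3L) {
    fc_matrix(volume, parcellation, fisher_z = TRUE, kept = resid$kept)
  } else NULL

  qc <- tibble::tibble(
    subject_id = subject_id,
    matrix_size = spatial_dims(volume)[1],
    voxel_size_mm = volume$voxel_mm[1],
    tr_s = config$tr_s,
    oblique = isTRUE(attr(volume, "oblique")),
    n_timepoints = n_timepoints(volume),
    mean_enorm_mm = ms$mean_enorm_mm,
    max_enorm_mm = ms$max_enorm_mm,
    n_good = ms$n_good,
    good_seconds = ms$good_seconds,
    dof = as.integer(dof),
    tsnr_mean = ts$mean_in_mask,
    fwhm_x_mm = fw$fwhm_mm[1], fwhm_y_mm = fw$fwhm_mm[2],
    fwhm_z_mm = fw$fwhm_mm[3], fwhm_combined_mm = fw$combined_mm,
    dice_e2a = dice_e2a, dice_a2t = dice_a2t,
    fcs_mean = fcs_mean,
    flip_flag = if (is.null(flip)) NA else flip$flipped
  )
  structure(list(qc = qc, censor = cm, design = des, residuals = resid,
                 fc = fc),
            class = "subject_qc")
}

CRITERIA_IDS <- c("A", "B", "C", "D", "E", "F", "G", "H")

#' Evaluate the subject inclusion criteria
#'
#' Applies the quantitative exclusion rules to a row of QC metrics:
#' \describe{
#'   \item{A}{fail when fewer than `dof_cutoff` residual degrees of freedom
#'     remain after censoring, nuisance regression and band-pass (strict
#'     "fewer than").}
#'   \item{B}{fail when fewer than `min_good_seconds` of data survive
#'     censoring (strict; exactly at the cutoff passes).}
#'   \item{C}{maximum volume-to-volume motion above `max_enorm_mm` marks the
#'     subject *uncertain* (flag for review) rather than excluded — a large
#'     but isolated movement can be censored away; set
#'     `exclude_on_max_enorm = TRUE` to make it exclusionary.}
#'   \item{D}{uncertain when the left-right flip check fired.}
#'   \item{E}{fail when the subject's mean TSNR or mean FCS is a robust
#'     outlier within its site group: |value - site median| > k * MAD
#'     (default k = 4). Needs site statistics; not evaluable for a lone
#'     subject.}
#'   \item{F, G, H}{qualitative (field-of-view coverage, anatomical
#'     abnormality, unfixable misalignment): emitted as "not-evaluable" for
#'     manual entry.}
#' }
#' Missing metrics make the corresponding criterion "not-evaluable".
#'
#' @param qc one-row tibble of subject metrics (from [subject_qc()]).
#' @param config a [run_config].
#' @param site_stats optional one-row tibble with `tsnr_median`, `tsnr_mad`,
#'   `fcs_median`, `fcs_mad` for the subject's site group.
#' @param mad_k robust outlier multiplier for criterion E (default 4).
#' @param exclude_on_max_enorm make criterion C exclusionary (default
#'   FALSE).
#' @return Tibble with columns `criterion`, `status` (one of `"pass"`,
#'   `"fail"`, `"uncertain"`, `"not-evaluable"`).
#' @export
evaluate_criteria <- function(qc, config, site_stats = NULL, mad_k = 4,
                              exclude_on_max_enorm = FALSE) {
  st <- function(cond, when_true = "fail") {
    if (is.na(cond)) "not-evaluable" else if (cond) when_true else "pass"
  }
  a <- st(qc$dof < config$dof_cutoff)
  b <- st(qc$good_seconds < config$min_good_seconds)
  c_ <- st(qc$max_enorm_mm > config$max_enorm_mm,
           if (exclude_on_max_enorm) "fail" else "uncertain")
  d <- if (is.na(qc$flip_flag)) "not-evaluable" else
    if (qc$flip_flag) "uncertain" else "pass"
  e <- if (is.null(site_stats) || is.na(qc$tsnr_mean)) {
    "not-evaluable"
  } else {
    tsnr_out <- site_stats$tsnr_mad > 0 &&
      abs(qc$tsnr_mean - site_stats$tsnr_median) > mad_k * site_stats$tsnr_mad
    fcs_out <- !is.na(qc$fcs_mean) && site_stats$fcs_mad > 0 &&
      abs(qc$fcs_mean - site_stats$fcs_median) > mad_k * site_stats$fcs_mad
    if (tsnr_out || fcs_out) "fail" else "pass"
  }
  tibble::tibble(
    criterion = CRITERIA_IDS,
    status = c(a, b, c_, d, e, "not-evaluable", "not-evaluable",
               "not-evaluable")
  )
}

#' Evaluate criteria across a cohort and summarise exclusions
#'
#' `cohort_criteria()` evaluates every subject's flags, computing the
#' site-grouped robust statistics needed by criterion E from the cohort
#' itself. `cohort_summary()` counts subjects per criterion and status;
#' counts are column sums of the per-subject flag table.
#'
#' @param qc_table tibble with one row per subject (columns of
#'   [subject_qc()]'s `qc`, plus optionally `site`; a single site is assumed
#'   when absent).
#' @param config a [run_config].
#' @param ... passed to [evaluate_criteria()].
#' @return `cohort_criteria()`: tibble `subject_id`, `criterion`, `status`.
#'   `cohort_summary()`: tibble `criterion`, `n_fail`, `n_uncertain`,
#'   `n_pass`, `n_not_evaluable`.
#' @export
cohort_criteria <- function(qc_table, config, ...) {
  if (nrow(qc_table) == 0L) stop("empty cohort", call. = FALSE)
  if (!"site" %in% names(qc_table)) qc_table$site <- "all"
  stats_by_site <- qc_table |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(
      tsnr_median = stats::median(.data$tsnr_mean, na.rm = TRUE),
      tsnr_mad = stats::mad(.data$tsnr_mean, na.rm = TRUE),
      fcs_median = stats::median(.data$fcs_mean, na.rm = TRUE),
      fcs_mad = stats::mad(.data$fcs_mean, na.rm = TRUE),
      .groups = "drop")
  purrr::map_dfr(seq_len(nrow(qc_table)), function(i) {
    row <- qc_table[i, ]
    ss <- stats_by_site[stats_by_site$site == row$site, ]
    dplyr::mutate(evaluate_criteria(row, config, site_stats = ss, ...),
                  subject_id = row$subject_id, .before = 1)
  })
}

#' @rdname cohort_criteria
#' @param flags output of `cohort_criteria()`.
#' @export
cohort_summary <- function(flags) {
  flags |>
    dplyr::count(.data$criterion, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L) |>
    dplyr::rename_with(~ paste0("n_", gsub("-", "_", .x)),
                       -"criterion") |>
    dplyr::arrange(.data$criterion)
}

#' Write cohort QC outputs
#'
#' The per-subject table as CSV (one row per subject) and a nested JSON
#' record (per-subject metrics plus flags), with deterministic subject
#' ordering.
#'
#' @param qc_table per-subject metric tibble.
#' @param flags per-subject criteria flags (from [cohort_criteria()]).
#' @param dir output directory.
#' @return Paths of the two files, invisibly.
#' @export
write_cohort_report <- function(qc_table, flags, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  qc_table <- dplyr::arrange(qc_table, .data$subject_id)
  csv <- file.path(dir, "cohort_qc.csv")
  utils::write.csv(qc_table, csv, row.names = FALSE)
  js <- file.path(dir, "cohort_qc.json")
  per_subject <- lapply(qc_table$subject_id, function(sid) {
    list(metrics = as.list(qc_table[qc_table$subject_id == sid, ]),
         criteria = as.list(stats::setNames(
           flags$status[flags$subject_id == sid],
           flags$criterion[flags$subject_id == sid])))
  })
  names(per_subject) <- qc_table$subject_id
  jsonlite::write_json(per_subject, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv, json = js))
}

#' Export static review montages
#'
#' One PNG panel per subject showing three orthogonal mid-slices, with the
#' intensity window fixed across the cohort at robust (2nd/98th) percentiles
#' so identical voxel values render identically in every panel — a static
#' stand-in for scrolling concatenated volumes as a movie.
#'
#' @param volumes named list of [vol3d] (or [vol4d], in which case the first
#'   volume is shown) on one grid.
#' @param dir output directory.
#' @param width,height panel size in pixels.
#' @return Tibble `subject`, `path` in deterministic (input) order.
#' @export
export_montage <- function(volumes, dir, width = 480, height = 180) {
  if (!length(volumes)) stop("no volumes to export", call. = FALSE)
  vols3 <- lapply(volumes, function(v) {
    if (inherits(v, "vol4d")) {
      vol3d(v$values[, , , 1], v$voxel_mm, v$origin_mm, v$orientation)
    } else v
  })
  for (v in vols3[-1]) check_same_grid(vols3[[1]], v)
  all_vals <- unlist(lapply(vols3, function(v) as.vector(v$values)))
  win <- stats::quantile(all_vals, c(0.02, 0.98), na.rm = TRUE, names = FALSE)
  if (win[1] == win[2]) win[2] <- win[1] + 1
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- names(vols3)
  if (is.null(nm)) nm <- sprintf("subject_%03d", seq_along(vols3))
  paths <- character(length(vols3))
  for (i in seq_along(vols3)) {
    a <- pmin(pmax(vols3[[i]]$values, win[1]), win[2])
    d <- dim(a)
    paths[i] <- file.path(dir, paste0(nm[i], ".png"))
    grDevices::png(paths[i], width = width, height = height)
    graphics::par(mfrow = c(1, 3), mar = c(0.5, 0.5, 0.5, 0.5))
    graphics::image(a[ceiling(d[1] / 2), , ], zlim = win, axes = FALSE,
                    col = grDevices::gray.colors(128, 0, 1), useRaster = TRUE)
    graphics::image(a[, ceiling(d[2] / 2), ], zlim = win, axes = FALSE,
                    col = grDevices::gray.colors(128, 0, 1), useRaster = TRUE)
    graphics::image(a[, , ceiling(d[3] / 2)], zlim = win, axes = FALSE,
                    col = grDevices::gray.colors(128, 0, 1), useRaster = TRUE)
    grDevices::dev.off()
  }
  tibble::tibble(subject = nm, path = paths)
}
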