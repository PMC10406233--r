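#' Specification of a synthetic resting-state subject
#'
#' The phantom emulates the data properties the QC metrics assume: a small
#' set of spatial networks sharing low-frequency (< 0.1 Hz) time courses,
#' Gaussian thermal noise, optional global multiplicative spikes (the RF
#' coil-artifact signature: a simultaneous excursion across the whole
#' image), and a rigid-body motion trace with controllable mean
#' volume-to-volume motion, spike events and drift. It makes no attempt at
#' EPI physics — no field distortion, slice timing or spin history, and no
#' image-space resampling of motion.
#'
#' @param grid_dims length-3 positive integers, grid size in voxels.
#' @param voxel_size_mm length-3 positive voxel sizes (mm).
#' @param n_timepoints number of volumes T.
#' @param tr_s repetition time (s).
#' @param n_networks number of networks.
#' @param network_freq_band_hz frequency band of the network time courses;
#'   must lie within (0, Nyquist). Default (0.01, 0.08) Hz so network signal
#'   survives a 0.01-0.1 Hz pass band.
#' @param thermal_sigma s.d. of additive Gaussian thermal noise (signal
#'   units; baseline signal is `baseline`).
#' @param spike_times volume indices (1-based) of global signal spikes.
#' @param spike_gain multiplicative gain of a global spike: in-mask voxels
#'   are scaled by `1 + spike_gain` at `spike_times`.
#' @param motion_mean_enorm_mm target mean volume-to-volume motion of the
#'   baseline (spike-free) trace.
#' @param motion_spike_times volume indices (>= 2) of motion spikes.
#' @param motion_spike_amp_mm amplitude of each motion spike (single-axis
#'   translation step, so the injected volume-to-volume excursion equals
#'   this exactly in the noise-free case).
#' @param seed integer seed; one seed drives every random stream of the
#'   subject via fixed offsets (see [simulate_subject()]).
#' @param n_regions number of parcellation regions carved out of the
#'   cortical compartment.
#' @param network_weight weight in [0, 1] of the shared network component in
#'   each region's time course (1 = regions reproduce their network's time
#'   course exactly).
#' @param baseline baseline signal level (arbitrary units).
#' @param signal_amp amplitude of the network fluctuation (signal units).
#' @param wm_frac,csf_frac radii of the white-matter and CSF compartments as
#'   fractions of the mask radius (0 removes the compartment, leaving the
#'   whole mask cortical).
#' @param seed_anatomy optional separate seed for the anatomy (mask, region
#'   layout); [simulate_cohort()] sets one value for all subjects so the
#'   cohort shares a template-space anatomy.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_dims = c(20, 20, 16),
                         voxel_size_mm = c(3, 3, 3),
                         n_timepoints = 150, tr_s = 2,
                         n_networks = 3,
                         network_freq_band_hz = c(0.01, 0.08),
                         thermal_sigma = 1,
                         spike_times = integer(0), spike_gain = 0,
                         motion_mean_enorm_mm = 0.05,
                         motion_spike_times = integer(0),
                         motion_spike_amp_mm = 0,
                         seed = 1L,
                         n_regions = 9, network_weight = 0.8,
                         baseline = 100, signal_amp = 4,
                         wm_frac = 0.35, csf_frac = 0.18,
                         seed_anatomy = NULL) {
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 4),
            length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            n_timepoints >= 2, tr_s > 0, n_networks >= 1,
            thermal_sigma >= 0, spike_gain >= 0,
            motion_mean_enorm_mm >= 0, motion_spike_amp_mm >= 0,
            n_regions >= n_networks, network_weight >= 0, network_weight <= 1,
            baseline > 0, signal_amp >= 0)
  nyq <- 1 / (2 * tr_s)
  b <- network_freq_band_hz
  if (length(b) != 2L || b[1] <= 0 || b[2] <= b[1] || b[2] >= nyq) {
    stop("network_freq_band_hz must lie within (0, Nyquist = ",
         format(nyq), " Hz)", call. = FALSE)
  }
  check_indices <- function(idx, lo, what) {
    idx <- as.integer(idx)
    if (length(idx) && (any(idx < lo) || any(idx > n_timepoints))) {
      stop(what, " indices must lie in [", lo, ", ", n_timepoints, "]",
           call. = FALSE)
    }
    idx
  }
  spike_times <- check_indices(spike_times, 1L, "spike")
  motion_spike_times <- check_indices(motion_spike_times, 2L, "motion spike")
  structure(as.list(environment())[c(
    "grid_dims", "voxel_size_mm", "n_timepoints", "tr_s", "n_networks",
    "network_freq_band_hz", "thermal_sigma", "spike_times", "spike_gain",
    "motion_mean_enorm_mm", "motion_spike_times", "motion_spike_amp_mm",
    "seed", "n_regions", "network_weight", "baseline", "signal_amp",
    "wm_frac", "csf_frac", "seed_anatomy")], class = "phantom_spec")
}

# chi_6 mean / sqrt(6): ratio between the mean volume-to-volume norm of a
# 6-axis Gaussian innovation and its per-axis-combined RMS
CHI6_MEAN_FACTOR <- sqrt(2) * gamma(3.5) / gamma(3) / sqrt(6)

#' Simulate a rigid-body motion trace
#'
#' A Gaussian random-walk across the six parameters whose volume-to-volume
#' Euclidean norm has mean `baseline_sigma_mm * 0.959` (exact chi-6 factor),
#' plus optional translation steps of exactly `spike_amp_mm` at
#' `spike_times` and an optional linear drift. In the noise-free case the
#' injected excursions appear in the motion series exactly.
#'
#' @param n_timepoints number of volumes (>= 2).
#' @param tr_s repetition time (s).
#' @param baseline_sigma_mm RMS of the volume-to-volume parameter-difference
#'   norm for the baseline random walk (0 gives an all-zero trace).
#' @param spike_times volume indices (>= 2) of injected translation steps.
#' @param spike_amp_mm step amplitude (mm), applied along the first
#'   translation axis.
#' @param seed integer seed.
#' @param drift_mm total linear drift over the run on the second translation
#'   axis (default 0).
#' @return A [motion_trace].
#' @export
simulate_motion_trace <- function(n_timepoints, tr_s, baseline_sigma_mm = 0,
                                  spike_times = integer(0), spike_amp_mm = 0,
                                  seed = 1L, drift_mm = 0) {
  T <- as.integer(n_timepoints)
  stopifnot(T >= 2L, baseline_sigma_mm >= 0, spike_amp_mm >= 0)
  spike_times <- as.integer(spike_times)
  if (length(spike_times) && (any(spike_times < 2L) || any(spike_times > T))) {
    stop("motion spike indices must lie in [2, ", T, "]", call. = FALSE)
  }
  set.seed(as.integer(seed))
  innov <- matrix(stats::rnorm(T * 6, sd = baseline_sigma_mm / sqrt(6)), T, 6)
  innov[1, ] <- 0
  if (drift_mm != 0) innov[-1, 5] <- innov[-1, 5] + drift_mm / (T - 1)
  innov[spike_times, 4] <- innov[spike_times, 4] + spike_amp_mm
  motion_trace(apply(innov, 2, cumsum), tr_s)
}

#' Simulate one synthetic subject
#'
#' Builds an ellipsoidal brain mask with a central white-matter sphere and a
#' CSF shell around it; partitions the remaining "cortical" voxels into
#' `n_regions` contiguous regions (nearest seeded centre); assigns regions
#' to networks round-robin; draws band-limited network and region-private
#' time courses as sums of sinusoids; and synthesises the 4D volume as
#' baseline + network signal + thermal noise, with global multiplicative
#' spikes applied to every in-mask voxel at `spike_times`. The motion trace
#' is generated from the spec's motion fields. Every random stream derives
#' from `spec$seed` with a fixed offset (+1 motion, +2 anatomy, +3 time
#' courses, +4 noise), so identical specs give bit-identical bundles.
#'
#' @param spec a [phantom_spec].
#' @param coupling optional motion-FC coupling: a list with `edges` (matrix
#'   of region-index pairs, one row per edge) and `slope` (correlation per
#'   mm of mean motion). Each coupled edge's region time courses are mixed
#'   so their true correlation equals `slope * motion_mean_enorm_mm`
#'   (clamped to 0.9).
#' @return A `subject_bundle`: list with `volume` ([vol4d]), `motion`
#'   ([motion_trace]), `brain_mask`, `wm_mask`, `csf_mask` ([brain_mask]),
#'   `parcellation` ([parcellation]), and `truth` (network assignment,
#'   network and region time courses, true region-correlation matrix,
#'   injected spike times, the spec itself).
#' @export
simulate_subject <- function(spec, coupling = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_dims
  T <- spec$n_timepoints

  baseline_sigma <- spec$motion_mean_enorm_mm / CHI6_MEAN_FACTOR
  motion <- simulate_motion_trace(T, spec$tr_s, baseline_sigma,
                                  spec$motion_spike_times,
                                  spec$motion_spike_amp_mm,
                                  seed = spec$seed + 1L)

  anat <- phantom_anatomy(spec)
  tcs <- phantom_timecourses(spec, coupling)

  set.seed(spec$seed + 4L)
  flat <- matrix(0, prod(d), T)
  in_mask <- as.vector(anat$mask)
  n_in <- sum(in_mask)
  flat[in_mask, ] <- spec$baseline
  gray <- which(as.vector(anat$labels) > 0L)
  lab_gray <- as.vector(anat$labels)[gray]
  flat[gray, ] <- flat[gray, ] +
    spec$signal_amp * t(tcs$region_tcs[, lab_gray, drop = FALSE])
  if (spec$thermal_sigma > 0) {
    flat[in_mask, ] <- flat[in_mask, ] +
      matrix(stats::rnorm(n_in * T, sd = spec$thermal_sigma), n_in, T)
  }
  if (length(spec$spike_times)) {
    flat[in_mask, spec$spike_times] <-
      flat[in_mask, spec$spike_times, drop = FALSE] * (1 + spec$spike_gain)
  }

  vol <- vol4d(array(flat, c(d, T)), spec$voxel_size_mm)
  mk_mask <- function(m) brain_mask(m, spec$voxel_size_mm)
  structure(list(
    volume = vol,
    motion = motion,
    brain_mask = mk_mask(anat$mask),
    wm_mask = mk_mask(anat$wm),
    csf_mask = mk_mask(anat$csf),
    parcellation = parcellation(anat$labels, spec$voxel_size_mm),
    truth = list(region_network = tcs$region_network,
                 network_tcs = tcs$network_tcs,
                 region_tcs = tcs$region_tcs,
                 true_fc = stats::cor(tcs$region_tcs),
                 spike_times = spec$spike_times,
                 motion_spike_times = spec$motion_spike_times,
                 spec = spec)
  ), class = "subject_bundle")
}

# ellipsoidal brain with central WM sphere, CSF shell, cortical regions
phantom_anatomy <- function(spec) {
  d <- spec$grid_dims
  ctr <- (d + 1) / 2
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3]), KEEP.OUT.ATTRS = FALSE))
  u <- sweep(sweep(idx, 2, ctr), 2, 0.45 * d, `/`)
  r2 <- rowSums(u^2)
  mask <- array(r2 <= 1, d)
  wm <- array(r2 <= spec$wm_frac^2, d)
  csf <- array(r2 > spec$wm_frac^2 & r2 <= (spec$wm_frac + spec$csf_frac)^2, d)
  gray <- mask & !wm & !csf
  gv <- which(as.vector(gray))
  if (length(gv) < spec$n_regions) stop("grid too small for n_regions", call. = FALSE)
  # cohorts share one anatomy (template space): seed_anatomy overrides
  set.seed(if (is.null(spec$seed_anatomy)) spec$seed + 2L else spec$seed_anatomy)
  centers <- idx[sample(gv, spec$n_regions), , drop = FALSE]
  dmat <- outer(rowSums(idx[gv, ]^2), rep(1, spec$n_regions)) -
    2 * idx[gv, ] %*% t(centers) +
    outer(rep(1, length(gv)), rowSums(centers^2))
  assign <- max.col(-dmat, ties.method = "first")
  labels <- array(0L, d)
  labels[gv] <- assign
  list(mask = mask, wm = wm, csf = csf, labels = labels)
}

# band-limited sinusoid mixtures for networks and regions
phantom_timecourses <- function(spec, coupling) {
  T <- spec$n_timepoints
  set.seed(spec$seed + 3L)
  draw_tc <- function() {
    f <- stats::runif(4, spec$network_freq_band_hz[1],
                      spec$network_freq_band_hz[2])
    ph <- stats::runif(4, 0, 2 * pi)
    tt <- (seq_len(T) - 1) * spec$tr_s
    x <- rowSums(vapply(1:4, function(m) sin(2 * pi * f[m] * tt + ph[m]),
                        numeric(T)))
    (x - mean(x)) / stats::sd(x)
  }
  network_tcs <- vapply(seq_len(spec$n_networks), function(k) draw_tc(),
                        numeric(T))
  region_network <- rep(seq_len(spec$n_networks),
                        length.out = spec$n_regions)
  w <- sqrt(spec$network_weight)
  region_tcs <- vapply(seq_len(spec$n_regions), function(r) {
    x <- w * network_tcs[, region_network[r]] +
      sqrt(1 - spec$network_weight) * draw_tc()
    x / stats::sd(x)
  }, numeric(T))
  if (!is.null(coupling)) {
    edges <- matrix(as.integer(coupling$edges), ncol = 2)
    if (any(edges < 1) || any(edges > spec$n_regions)) {
      stop("coupling references a nonexistent region (have ",
           spec$n_regions, ")", call. = FALSE)
    }
    lam <- min(coupling$slope * spec$motion_mean_enorm_mm, 0.9)
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1]; j <- edges[e, 2]
      region_tcs[, j] <- sqrt(1 - lam^2) * region_tcs[, j] +
        lam * region_tcs[, i]
      region_tcs[, j] <- region_tcs[, j] / stats::sd(region_tcs[, j])
    }
  }
  list(network_tcs = network_tcs, region_tcs = region_tcs,
       region_network = region_network)
}

#' @export
print.subject_bundle <- function(x, ...) {
  s <- x$truth$spec
  cat(sprintf(paste0("<subject_bundle> %s grid, %d time points, %d networks,",
                     " %d regions, seed %d\n"),
              paste(s$grid_dims, collapse = "x"), s$n_timepoints,
              s$n_networks, s$n_regions, s$seed))
  invisible(x)
}

#' Simulate a cohort of synthetic subjects
#'
#' Per-subject target mean motion is taken from `motion_levels`; per-subject
#' motion spikes may be supplied to emulate intermittent movers. When
#' `qcfc_coupling` is given, the designated true-FC edges vary linearly with
#' the subject's target mean motion with the stated slope (injected at the
#' time-course level, giving an analytic target for QC-FC recovery).
#' Subject i draws its streams from `seed + 101 * i`.
#'
#' @param n_subjects number of subjects.
#' @param base_spec a [phantom_spec] supplying everything except motion and
#'   seed.
#' @param motion_levels length-`n_subjects` target mean motion values (mm).
#' @param qcfc_coupling NULL or list(`edges`, `slope`) as in
#'   [simulate_subject()].
#' @param seed cohort seed.
#' @param motion_spike_times NULL, or a list of per-subject spike-index
#'   vectors.
#' @param motion_spike_amp_mm motion spike amplitude (mm).
#' @param light if TRUE, drop each subject's 4D volume after extracting the
#'   region series and nuisance series (memory-friendly cohorts for sweep
#'   analyses); the dropped volume is replaced by NULL and a `sweep_input`
#'   element is added.
#' @return A `cohort` list: `subjects` (list of `subject_bundle`), `truth`
#'   (motion levels, coupling, seed).
#' @export
simulate_cohort <- function(n_subjects, base_spec, motion_levels,
                            qcfc_coupling = NULL, seed = 1L,
                            motion_spike_times = NULL,
                            motion_spike_amp_mm = 0, light = FALSE) {
  stopifnot(inherits(base_spec, "phantom_spec"))
  if (length(motion_levels) != n_subjects) {
    stop("motion_levels must have length n_subjects", call. = FALSE)
  }
  if (!is.null(motion_spike_times)) {
    stopifnot(length(motion_spike_times) == n_subjects)
  }
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sp <- base_spec
    sp$motion_mean_enorm_mm <- motion_levels[i]
    sp$seed <- as.integer(seed + 101L * i)
    # one template-space anatomy for the whole cohort
    if (is.null(sp$seed_anatomy)) sp$seed_anatomy <- as.integer(seed + 2L)
    if (!is.null(motion_spike_times)) {
      sp$motion_spike_times <- as.integer(motion_spike_times[[i]])
      sp$motion_spike_amp_mm <- motion_spike_amp_mm
    }
    b <- simulate_subject(sp, coupling = qcfc_coupling)
    if (light) {
      b$sweep_input <- bundle_sweep_input(b)
      b$volume <- NULL
    }
    subjects[[i]] <- b
  }
  structure(list(subjects = subjects,
                 truth = list(motion_levels = motion_levels,
                              coupling = qcfc_coupling, seed = seed)),
            class = "cohort")
}

#' Sweep input from a subject bundle
#'
#' Extracts the pieces [threshold_sweep()] needs: region-mean series, the
#' nuisance series (global, WM, CSF means and the six motion parameters),
#' and the motion trace.
#'
#' @param bundle a `subject_bundle` (with its volume still present).
#' @return list(`roi`, `nuisance`, `motion`).
#' @export
bundle_sweep_input <- function(bundle) {
  list(
    roi = roi_series(bundle$volume, bundle$parcellation),
    nuisance = extract_nuisance_series(
      bundle$volume,
      masks = list(global = bundle$brain_mask, wm = bundle$wm_mask,
                   csf = bundle$csf_mask),
      motion = bundle$motion),
    motion = bundle$motion
  )
}

#' Write a subject bundle to disk
#'
#' NIfTI-1 volume, masks and parcellation; a whitespace-delimited 6-column
#' motion file; and a JSON ground-truth record.
#'
#' @param bundle a `subject_bundle`.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_subject_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(bundle$volume, file.path(dir, "bold.nii.gz"))
  write_volume(bundle$brain_mask, file.path(dir, "mask_brain.nii.gz"))
  write_volume(bundle$wm_mask, file.path(dir, "mask_wm.nii.gz"))
  write_volume(bundle$csf_mask, file.path(dir, "mask_csf.nii.gz"))
  write_volume(bundle$parcellation, file.path(dir, "parcellation.nii.gz"))
  write_motion(bundle$motion, file.path(dir, "motion.txt"))
  tr <- bundle$truth
  jsonlite::write_json(
    list(region_network = tr$region_network,
         true_fc = tr$true_fc, spike_times = tr$spike_times,
         motion_spike_times = tr$motion_spike_times,
         spec = unclass(tr$spec)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
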