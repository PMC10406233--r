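# Shared fixtures, built in code. Expensive cohorts are memoised so several
# test files can reuse them within one run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

small_spec <- function(...) {
  phantom_spec(grid_dims = c(14, 14, 10), n_timepoints = 80, tr_s = 2,
               n_networks = 2, n_regions = 6, seed = 7L, ...)
}

small_subject <- function() memo("small_subject", simulate_subject(small_spec()))

# 40-subject cohort whose dissimilarity is driven by censoring-induced
# degrees-of-freedom loss: low baseline motion plus per-subject motion
# spikes of 0.28 mm (censored at 0.2 mm, kept at 0.4 and 1.0 mm)
mechanism_cohort <- function() {
  memo("mechanism_cohort", {
    n <- 40
    base <- phantom_spec(grid_dims = c(16, 16, 12), n_timepoints = 150,
                         tr_s = 2, n_networks = 3, n_regions = 9,
                         thermal_sigma = 1.5, seed = 11L)
    n_spikes <- round(seq(0, 24, length.out = n))
    spike_times <- lapply(seq_len(n), function(i) {
      if (n_spikes[i] == 0) integer(0) else
        unique(round(seq(6, 144, length.out = n_spikes[i])))
    })
    simulate_cohort(n, base, motion_levels = rep(0.03, n),
                    seed = 11L, motion_spike_times = spike_times,
                    motion_spike_amp_mm = 0.28, light = TRUE)
  })
}

# 40-subject null cohort: motion varies across subjects but is uncoupled
# from connectivity
null_cohort <- function() {
  memo("null_cohort", {
    n <- 40
    base <- phantom_spec(grid_dims = c(16, 16, 12), n_timepoints = 150,
                         tr_s = 2, n_networks = 3, n_regions = 9,
                         thermal_sigma = 1.5, seed = 23L)
    simulate_cohort(n, base, motion_levels = seq(0.02, 0.25, length.out = n),
                    seed = 23L, light = TRUE)
  })
}

# Fisher-Z FC matrices + measured mean motion for a light cohort processed
# at one threshold/band
cohort_fc <- function(cohort, threshold_mm = 0.4, band = c(0.01, 0.1)) {
  tr_s <- cohort$subjects[[1]]$truth$spec$tr_s
  mats <- list(); enorms <- numeric(0)
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]$sweep_input
    en <- compute_enorm(s$motion)
    cm <- censor_mask(en, threshold_mm)
    des <- build_design(nrow(s$roi), tr_s, s$nuisance, poly_order = 2,
                        band_hz = band, mask = cm)
    resid <- project_nuisance(s$roi, des)
    mats[[i]] <- fc_matrix(resid$values, fisher_z = TRUE)
    enorms[i] <- motion_summary(en, cm, tr_s)$mean_enorm_mm
  }
  list(mats = mats, enorms = enorms,
       centroids = as.matrix(region_centroids(
         cohort$subjects[[1]]$parcellation)[, c("x_mm", "y_mm", "z_mm")]))
}
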