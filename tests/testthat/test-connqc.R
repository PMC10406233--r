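test_that("Fisher-Z is odd, order-preserving and clipped", {
  r <- c(-0.99, -0.5, 0, 0.3, 0.8)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_true(is.finite(fisher_z(1)))
  expect_equal(inv_fisher_z(fisher_z(0.6)), 0.6, tolerance = 1e-12)
})

test_that("a 4 mm seed on a 3 mm grid selects the 7-voxel face-neighbour sphere", {
  b <- small_subject()
  # centre the seed on an in-mask voxel centre
  ctr_idx <- c(7, 7, 5)
  ctr_mm <- voxel_coords_mm(b$volume, matrix(ctr_idx, 1))
  map <- seed_map(b$volume, b$brain_mask, seed_spec("test", ctr_mm, 4))
  expect_equal(attr(map, "n_seed_voxels"), 7L)
  expect_error(seed_map(b$volume, b$brain_mask,
                        seed_spec("far", c(500, 500, 500), 4)),
               "does not intersect")
})

test_that("seed maps recover the phantom network in the noiseless limit", {
  sp <- phantom_spec(grid_dims = c(12, 12, 8), n_timepoints = 60,
                     n_networks = 2, n_regions = 2, network_weight = 1,
                     thermal_sigma = 0, wm_frac = 0, csf_frac = 0, seed = 13)
  b <- simulate_subject(sp)
  idx <- which(b$parcellation$values == 1L, arr.ind = TRUE)
  ctr <- colMeans(voxel_coords_mm(b$volume, idx))
  # use the in-region voxel nearest the centroid as the seed centre
  d2 <- rowSums(sweep(voxel_coords_mm(b$volume, idx), 2, ctr)^2)
  seed_mm <- voxel_coords_mm(b$volume, idx[which.min(d2), , drop = FALSE])
  map <- seed_map(b$volume, b$brain_mask, seed_spec("net1", seed_mm, 4))
  in1 <- b$parcellation$values == 1L
  in2 <- b$parcellation$values == 2L
  expect_true(all(abs(map[in1] - 1) < 1e-6))
  expect_true(max(abs(map[in2]), na.rm = TRUE) <
                min(map[in1]) + 1e-6)
})

test_that("FC matrices match brute-force pairwise correlation", {
  set.seed(21)
  S <- matrix(rnorm(30 * 4), 30, 4)
  fc <- fc_matrix(S, fisher_z = FALSE)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(fc$values[i, j], cor(S[, i], S[, j]), tolerance = 1e-12)
  }
  fz <- fc_matrix(S, fisher_z = TRUE)
  expect_equal(fc_edges(fz), atanh(fc_edges(fc)), tolerance = 1e-12)

  # shared time course -> r = 1, Fisher-Z finite; orthogonal -> 0
  x <- rnorm(30)
  fc2 <- fc_matrix(cbind(a = x, b = x), fisher_z = TRUE)
  expect_true(is.finite(fc2$values[1, 2]))
  expect_gt(fc2$values[1, 2], 5)
  tt <- seq_len(32)
  orth <- cbind(sin(2 * pi * tt / 8), cos(2 * pi * tt / 8))
  expect_equal(fc_matrix(orth, fisher_z = TRUE)$values[1, 2], 0,
               tolerance = 1e-10)

  # zero-variance region -> undefined edges, counted
  fc3 <- fc_matrix(cbind(a = x, b = rep(1, 30), c = rnorm(30)))
  expect_equal(fc3$n_undefined_edges, 2L)
})

test_that("estimated FC recovers the phantom's true correlation structure", {
  sp <- phantom_spec(grid_dims = c(14, 14, 10), n_timepoints = 300,
                     n_networks = 3, n_regions = 9, thermal_sigma = 1,
                     seed = 17)
  b <- simulate_subject(sp)
  est <- fc_matrix(b$volume, b$parcellation, fisher_z = FALSE)
  expect_lt(max(abs(est$values - b$truth$true_fc)), 0.15)
})

test_that("group means average in Z space and tolerate sign cancelation", {
  S <- matrix(rnorm(40 * 5), 40, 5)
  m1 <- fc_matrix(S); m2 <- fc_matrix(S)
  g <- group_mean_fc(list(m1, m2))
  expect_equal(g$values, m1$values, tolerance = 1e-12)

  m3 <- m1; m3$values <- -m1$values
  g2 <- group_mean_fc(list(m1, m3))
  expect_true(all(abs(fc_edges(g2)) < 1e-12))

  expect_error(group_mean_fc(list(m1)), "at least 2")
  raw <- fc_matrix(S, fisher_z = FALSE)
  expect_error(group_mean_fc(list(raw, raw)), "Fisher-Z")
})

test_that("similarity to the group mean follows its closed forms", {
  set.seed(33)
  S <- matrix(rnorm(50 * 6), 50, 6)
  m <- fc_matrix(S)
  sim <- fc_similarity(m, m)
  expect_equal(sim$pearson, 1)
  expect_equal(sim$dissimilarity, 0)

  # constant offset on every edge: pearson 1, dissimilarity = offset*sqrt(E)
  off <- m; off$values <- m$values + 0.25; diag(off$values) <- 0
  sim <- fc_similarity(off, m)
  expect_equal(sim$pearson, 1, tolerance = 1e-12)
  expect_equal(sim$dissimilarity, 0.25 * sqrt(choose(6, 2)),
               tolerance = 1e-12)

  # increasing noise degrades pearson and inflates dissimilarity
  set.seed(34)
  sims <- purrr::map_dfr(c(0.05, 0.3, 1), function(s) {
    noisy <- m
    noisy$values <- m$values + matrix(rnorm(36, sd = s), 6, 6)
    noisy$values <- (noisy$values + t(noisy$values)) / 2; diag(noisy$values) <- 0
    fc_similarity(noisy, m)
  })
  expect_true(all(diff(sims$pearson) < 0))
  expect_true(all(diff(sims$dissimilarity) > 0))
})

test_that("leave-one-out and include-all similarity agree closely at n=40", {
  fcres <- memo("null_fc_04", cohort_fc(null_cohort(), 0.4, c(0.01, 0.1)))
  inc <- cohort_similarity(fcres$mats)
  loo <- cohort_similarity(fcres$mats, leave_one_out = TRUE)
  expect_gt(cor(inc$pearson, loo$pearson), 0.99)
})

test_that("QC-FC is near zero without coupling and flags coupled edges", {
  fcres <- memo("null_fc_04", cohort_fc(null_cohort(), 0.4, c(0.01, 0.1)))
  q <- qcfc(fcres$mats, fcres$enorms, fcres$centroids)
  expect_lt(abs(q$mean_r), 0.1)
  expect_lt(q$distance_ci95[1], 0)
  expect_gt(q$distance_ci95[2], 0)
  expect_equal(sum(q$histogram$count),
               length(q$edge_r) - q$n_excluded_edges)

  # coupling on edge (1, 2): its QC-FC lands in the top decile
  base <- phantom_spec(grid_dims = c(12, 12, 8), n_timepoints = 150,
                       n_networks = 3, n_regions = 9, network_weight = 0.8,
                       thermal_sigma = 1, seed = 41)
  co <- simulate_cohort(40, base,
                        motion_levels = seq(0.02, 0.5, length.out = 40),
                        qcfc_coupling = list(edges = rbind(c(1, 2)),
                                             slope = 1.2),
                        seed = 41, light = TRUE)
  mats <- lapply(co$subjects, function(s) {
    fc_matrix(s$sweep_input$roi, fisher_z = TRUE)
  })
  q2 <- qcfc(mats, co$truth$motion_levels)
  target <- q2$edge_r[q2$edge_index[, 1] == 1 & q2$edge_index[, 2] == 2]
  expect_gt(target, 0)
  expect_gte(target, quantile(q2$edge_r, 0.9, na.rm = TRUE))

  # contracts
  expect_error(qcfc(mats[1:2], co$truth$motion_levels[1:2]), "3 subjects")
  expect_error(qcfc(mats[1:3], rep(0.1, 3)), "variance")
})

test_that("QC-FC is invariant to constant shifts of the motion summary", {
  fcres <- memo("null_fc_04", cohort_fc(null_cohort(), 0.4, c(0.01, 0.1)))
  q1 <- qcfc(fcres$mats, fcres$enorms)
  q2 <- qcfc(fcres$mats, fcres$enorms + 5)
  expect_equal(q1$edge_r, q2$edge_r, tolerance = 1e-12)
})

test_that("coupling-slope recovery: regressing edge z on motion finds the slope", {
  base <- phantom_spec(grid_dims = c(12, 12, 8), n_timepoints = 300,
                       n_networks = 3, n_regions = 9, network_weight = 0.8,
                       thermal_sigma = 0.5, seed = 47)
  slope <- 0.8
  co <- simulate_cohort(40, base,
                        motion_levels = seq(0.02, 0.5, length.out = 40),
                        qcfc_coupling = list(edges = rbind(c(1, 2)),
                                             slope = slope),
                        seed = 47, light = TRUE)
  z12 <- vapply(co$subjects, function(s) {
    fc_matrix(s$sweep_input$roi, fisher_z = TRUE)$values[1, 2]
  }, numeric(1))
  fit <- lm(z12 ~ co$truth$motion_levels)
  est <- coef(summary(fit))[2, ]
  # z ~ r for small r, so the fitted slope approximates the injected one
  expect_lt(abs(est["Estimate"] - slope), 2 * est["Std. Error"] + 0.15)
})

test_that("the threshold sweep exposes dof monotonicity and band-column loss", {
  co <- mechanism_cohort()
  inputs <- lapply(co$subjects[seq(1, 40, by = 8)],
                   function(s) s$sweep_input)
  sw <- threshold_sweep(inputs, thresholds = c(0.2, 0.4, 1.0),
                        bands = list(c(0.01, 0.1), NULL), tr_s = 2)
  med <- sw |>
    dplyr::filter(.data$band != "none") |>
    dplyr::group_by(.data$threshold_mm) |>
    dplyr::summarise(m = median(.data$dof))
  expect_true(all(diff(med$m[order(med$threshold_mm)]) >= 0))

  # removing the band raises every subject's dof by the number of
  # independent stop-band columns in that subject's retained design
  for (thr in c(0.4, 1.0)) {
    with_band <- dplyr::filter(sw, .data$threshold_mm == thr,
                               .data$band != "none")
    no_band <- dplyr::filter(sw, .data$threshold_mm == thr,
                             .data$band == "none")
    expect_true(all(no_band$dof > with_band$dof))
  }
})
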