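test_that("transition counts follow the sliding window within replicas", {
  expect_equal(count_transitions(c(1, 1, 2, 2), 1),
               rbind(c(1, 1), c(0, 1)))
  # two replicas: no cross-replica pair is counted
  expect_equal(count_transitions(c(1, 2, 2, 1), 1,
                                 trajectory = c(1, 1, 2, 2)),
               rbind(c(0, 1), c(1, 0)))
  # lag 2 on a 3-frame replica: single 1 -> 1 transition
  expect_equal(count_transitions(c(1, 2, 1), 2), rbind(c(1, 0), c(0, 0)))
  expect_warning(count_transitions(c(1, 2), 5), "shorter than the lag")
  expect_error(count_transitions(c(1, 2), 0), ">= 1")
})

test_that("the symmetrized estimator reproduces hand-computed P", {
  tm1 <- transition_matrix(rbind(c(8, 2), c(2, 8)))
  expect_equal(tm1$P, rbind(c(0.8, 0.2), c(0.2, 0.8)))

  tm2 <- transition_matrix(rbind(c(6, 2), c(4, 8)))
  expect_equal(tm2$P, rbind(c(12 / 18, 6 / 18), c(6 / 22, 16 / 22)))

  # rows sum to one for arbitrary counts
  set.seed(30)
  C <- matrix(rpois(25, 4), 5)
  tm3 <- transition_matrix(C)
  expect_equal(rowSums(tm3$P), rep(1, nrow(tm3$P)), tolerance = 1e-12)
})

test_that("detailed balance holds exactly by construction", {
  set.seed(31)
  C <- matrix(rpois(64, 3), 8)
  tm <- transition_matrix(C)
  flux <- diag(tm$pi) %*% tm$P
  expect_lt(max(abs(flux - t(flux))), 1e-12)
})

test_that("ergodic trimming isolates the largest connected component", {
  C <- rbind(c(5, 3, 0), c(4, 6, 0), c(0, 0, 7))
  tm <- transition_matrix(C)
  expect_equal(tm$kept_states, 1:2)
  expect_equal(tm$trimmed_states, 3L)
  expect_equal(dim(tm$P), c(2, 2))
})

test_that("implied timescales follow the closed form and exclude lambda=1", {
  # symmetric counts with lambda_2 = exp(-1) at lag 1
  e <- exp(-1)
  C <- 50 * rbind(c(1 + e, 1 - e), c(1 - e, 1 + e))
  tm <- transition_matrix(C, lag_frames = 1)
  expect_equal(tm$eigenvalues, c(1, e), tolerance = 1e-12)
  expect_equal(-1 / log(tm$eigenvalues[2]), 1, tolerance = 1e-12)

  set.seed(32)
  labels <- sample(1:3, 3000, replace = TRUE,
                   prob = c(0.5, 0.3, 0.2))
  its <- implied_timescales(labels, c(1, 2), n_timescales = 2)
  expect_true(all(its$timescale_index >= 2))
  expect_true(all(is.finite(its$timescale_frames)))
})

test_that("timescales are invariant to reversing every replica", {
  set.seed(33)
  spec <- quick_spec(n_states = 2,
                     trans_mat = rbind(c(0.9, 0.1), c(0.1, 0.9)),
                     tilt_deg = c(0, 8), n_frames = 2000, replicas = 2,
                     seed = 5)
  gen <- generate_ensembles(spec)
  labels <- unlist(gen$truth$states$A)
  traj <- rep(1:2, each = 2000)
  rev_labels <- unlist(lapply(gen$truth$states$A, rev))
  f <- implied_timescales(labels, c(1, 3), traj)
  r <- implied_timescales(rev_labels, c(1, 3), traj)
  expect_equal(f$timescale_frames, r$timescale_frames, tolerance = 1e-12)
})

test_that("PCCA+ separates nearly uncoupled blocks exactly", {
  eps <- 0.01
  C <- rbind(c(100, 50, eps * 100, eps * 100),
             c(50, 100, eps * 100, eps * 100),
             c(eps * 100, eps * 100, 100, 50),
             c(eps * 100, eps * 100, 50, 100))
  tm <- transition_matrix(C)
  macro <- pcca_coarse_grain(tm, 2)
  m <- macro$micro_to_macro
  expect_equal(m[1], m[2])
  expect_equal(m[3], m[4])
  expect_false(m[1] == m[3])
})

test_that("n_macro equal to n_micro is the identity coarse-graining", {
  set.seed(34)
  C <- matrix(rpois(16, 5) + 1, 4)
  tm <- transition_matrix(C)
  macro <- suppressWarnings(pcca_coarse_grain(tm, 4))
  expect_equal(sort(unique(macro$micro_to_macro)), 1:4)
  expect_equal(length(unique(macro$micro_to_macro)), 4)
})

test_that("macro-state recovery on a planted three-state ensemble", {
  spec <- quick_spec(n_frames = 2500, replicas = 2, seed = 51)
  gen <- generate_ensembles(spec)
  pocket <- tail(spec$domain_map$domains$SH2, 24)
  fc <- combine_features(com_pair_distances(gen$A, pocket),
                         com_pair_distances(gen$B, pocket))
  m <- fit_pca(fc)
  proj <- project_pca(m, fc)
  micro <- cluster_microstates(proj, n_micro = 60)
  traj <- paste(fc$info$system, fc$info$replica, sep = "/")
  tm <- transition_matrix(count_transitions(micro$labels, 5, traj),
                          lag_frames = 5)
  macro <- pcca_coarse_grain(tm, 3, microstates = micro,
                             system = fc$info$system)
  hidden <- c(unlist(gen$truth$states$A), unlist(gen$truth$states$B))
  ari <- mclust::adjustedRandIndex(macro$frame_labels, hidden)
  expect_gt(ari, 0.9)
  # occupancy fractions sum to one per system
  expect_equal(unname(rowSums(macro$occupancy)), c(1, 1),
               tolerance = 1e-12)
})

test_that("occupancy reflects a state visited by only one system", {
  labels <- c(rep(1, 50), rep(2, 50), rep(1, 100))
  system <- c(rep("a", 100), rep("b", 100))
  occ <- macrostate_occupancy(labels, system)
  expect_equal(occ["a", ], c(M1 = 0.5, M2 = 0.5))
  expect_equal(occ["b", ], c(M1 = 1, M2 = 0))
})

test_that("macro-state averages reproduce degenerate structures", {
  frames <- lapply(1:4, function(i) build_ideal_helix(10))
  ens <- mini_ensemble(frames)
  avg <- macrostate_average_structure(ens, rep(1, 4), 1)
  expect_equal(avg, as.numeric(t(frames[[1]])), tolerance = 1e-8)
  expect_error(macrostate_average_structure(ens, rep(1, 4), 2),
               "no frames")

  # zero-noise synthetic state mean is recovered exactly
  spec <- quick_spec(sigma = 0, n_frames = 60, replicas = 1)
  gen <- generate_ensembles(spec)
  s <- gen$truth$states$A[[1]]
  k <- s[1]
  avg2 <- macrostate_average_structure(gen$A, s, k)
  ca <- ca_indices(gen$A$topology)
  cols <- as.integer(rbind(3 * ca - 2, 3 * ca - 1, 3 * ca))
  expect_equal(avg2[cols], as.numeric(t(gen$truth$state_means_A[[k]])),
               tolerance = 1e-8)
})

test_that("micro-state assignment is consistent with its centers", {
  set.seed(36)
  blobs <- rbind(matrix(rnorm(200, 0, 0.1), 100, 2),
                 matrix(rnorm(200, 5, 0.1), 100, 2),
                 matrix(rnorm(200, 10, 0.1), 100, 2))
  micro <- cluster_microstates(blobs, n_micro = 3)
  expect_equal(length(unique(micro$labels)), 3)
  # well-separated blobs are recovered exactly
  expect_equal(length(unique(micro$labels[1:100])), 1)
  expect_equal(length(unique(micro$labels[101:200])), 1)
  # duplicate points land in one micro-state
  expect_equal(micro$labels[1], assign_to_centers(blobs[1, , drop = FALSE],
                                                  micro$centers))
  relab <- assign_to_centers(blobs, micro$centers)
  expect_gte(mean(relab == micro$labels), 0.99)
  expect_error(cluster_microstates(blobs[1:2, ], n_micro = 3),
               "n_micro")
})
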