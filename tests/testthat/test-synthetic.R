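test_that("spec validation catches malformed transition matrices", {
  expect_error(quick_spec(trans_mat = matrix(c(0.9, 0.3, 0.1, 0.8), 2),
                          n_states = 2),
               "sum to 1")
  # absorbing chain rejected unless explicitly allowed
  Tabs <- rbind(c(1, 0), c(0.1, 0.9))
  expect_error(quick_spec(trans_mat = Tabs, n_states = 2),
               "irreducible")
  expect_s3_class(quick_spec(trans_mat = Tabs, n_states = 2,
                             allow_absorbing = TRUE),
                  "synthetic_spec")
})

test_that("hidden-state occupancy matches the stationary distribution", {
  Tsym <- rbind(c(0.95, 0.05), c(0.05, 0.95))
  spec <- quick_spec(n_states = 2, trans_mat = Tsym, replicas = 1,
                     n_frames = 10000, tilt_deg = c(0, 6), seed = 3)
  gen <- generate_ensembles(spec)
  occ <- mean(unlist(gen$truth$states$A) == 1)
  expect_equal(occ, 0.5, tolerance = 0.04)   # 0.5 +/- 0.02 absolute
  expect_lt(abs(occ - 0.5), 0.02)
})

test_that("state dwell times are geometric with mean 1/(1 - T_kk)", {
  Tm <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  spec <- quick_spec(n_states = 2, trans_mat = Tm, replicas = 1,
                     n_frames = 20000, tilt_deg = c(0, 6), seed = 8)
  gen <- generate_ensembles(spec)
  s <- unlist(gen$truth$states$A)
  runs <- rle(s)$lengths
  runs <- runs[-c(1, length(runs))]        # interior dwells only
  expect_equal(mean(runs), 10, tolerance = 0.1)
})

test_that("zero noise reproduces the state means exactly", {
  spec <- quick_spec(sigma = 0, n_frames = 50, replicas = 1)
  gen <- generate_ensembles(spec)
  s <- gen$truth$states$A[[1]]
  ca <- ca_indices(gen$A$topology)
  cols <- as.integer(rbind(3 * ca - 2, 3 * ca - 1, 3 * ca))
  for (f in c(1, 25, 50)) {
    want <- as.numeric(t(gen$truth$state_means_A[[s[f]]]))
    expect_equal(gen$A$replicas[[1]][f, cols], want, tolerance = 1e-12)
  }
})

test_that("generation is deterministic given the seed", {
  g1 <- generate_ensembles(quick_spec(n_frames = 200, seed = 99))
  g2 <- generate_ensembles(quick_spec(n_frames = 200, seed = 99))
  expect_identical(g1$A$replicas, g2$A$replicas)
  expect_identical(g1$B$replicas, g2$B$replicas)
  expect_identical(g1$truth$states, g2$truth$states)
  g3 <- generate_ensembles(quick_spec(n_frames = 200, seed = 100))
  expect_false(identical(g1$A$replicas, g3$A$replicas))
})

test_that("planted rigid pairs are quieter than the inter-domain bulk", {
  spec <- quick_spec(n_frames = 1500, seed = 21)
  gen <- generate_ensembles(spec)
  dm <- spec$domain_map$domains
  pairs <- select_interdomain_ca_pairs(gen$A, gen$B, dm$CCD, dm$DBD)
  fm <- combine_features(ca_pair_distances(gen$A, pairs),
                         ca_pair_distances(gen$B, pairs))
  tab <- pair_variability(fm)
  key <- paste(tab$res_i, tab$res_j)
  planted <- key %in% paste(spec$rigid_pairs$res_i, spec$rigid_pairs$res_j)
  expect_gt(sum(planted), 0)
  thresh <- quantile(tab$sd[!planted], 0.05)
  expect_true(all(tab$sd[planted] < thresh))
})

test_that("ideal helices recover their construction axis", {
  h <- build_ideal_helix(12, axis = c(0, 0, 1))
  ens <- mini_ensemble(h)
  expect_equal(helix_global_tilt(ens, 1:12)$tilt_deg, 0,
               tolerance = 1e-6)
  hx <- build_ideal_helix(12, axis = c(1, 0, 0))
  expect_equal(helix_global_tilt(mini_ensemble(hx), 1:12)$tilt_deg, 90,
               tolerance = 1e-6)
  # axis rotated 30 degrees from z within the xz-plane
  ax <- c(sin(pi / 6), 0, cos(pi / 6))
  h30 <- build_ideal_helix(12, axis = ax)
  expect_equal(helix_global_tilt(mini_ensemble(h30), 1:12)$tilt_deg, 30,
               tolerance = 1)
  expect_error(build_ideal_helix(12, axis = c(0, 0, 0)), "non-zero")
  expect_error(build_ideal_helix(3), "at least 4")
})

test_that("planted hydrogen-bond geometry drives the detector", {
  spec <- quick_spec(n_frames = 40, replicas = 1, seed = 6)
  gen <- generate_ensembles(spec)
  rec <- detect_hbonds(gen$A, min_freq = 0)
  key <- paste(rec$bonds$donor_res, rec$bonds$acceptor_res)
  planted_key <- paste(spec$hbond_triplets$donor,
                       spec$hbond_triplets$acceptor)
  expect_true(all(planted_key %in% key))
  for (b in seq_along(planted_key)) {
    j <- match(planted_key[b], key)
    expect_equal(rec$presence[, j], gen$truth$presence$A[[1]][, b])
  }
})

test_that("planted per-state bond probability is recovered empirically", {
  probs <- rbind(rep(0.7, 3), c(0.85, 0.85, 0.15), c(0.15, 0.8, 0.8))
  spec <- quick_spec(n_frames = 3000, replicas = 1, seed = 13,
                     hbond_probs = probs)
  gen <- generate_ensembles(spec)
  s <- gen$truth$states$A[[1]]
  pres <- gen$truth$presence$A[[1]][, 1]
  for (k in 1:3) {
    nk <- sum(s == k)
    if (nk < 500) next
    expect_equal(mean(pres[s == k]), 0.7, tolerance = 0.08)
  }
})

test_that("plant_hbond_geometry places ideal and broken geometries", {
  top <- topology(data.frame(
    eleno = 1:3, elety = c("ND", "HD", "OA"),
    element = c("N", "H", "O"), resno = c(1, 1, 2), resname = "ALA",
    chain = "A", hpar = c(NA, 1L, NA)))
  frame <- as.numeric(t(rbind(c(0, 0, 0), c(1, 0, 0), c(6, 0, 0))))
  on_ <- plant_hbond_geometry(frame, c(1, 2, 3), TRUE)
  expect_equal(on_[4:6], c(6 - 1.9, 0, 0))
  off <- plant_hbond_geometry(frame, c(1, 2, 3), FALSE)
  expect_equal(off[4:6], c(6 - 4.5, 0, 0))
})
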