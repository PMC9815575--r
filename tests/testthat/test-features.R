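test_that("COM pair distances follow mass-weighted geometry", {
  # two single-atom residues at a 3-4-5 triangle
  ens <- mini_ensemble(rbind(c(0, 0, 0), c(3, 4, 0)))
  fm <- com_pair_distances(ens, 1:2)
  expect_equal(unname(fm$values[1, 1]), 5)

  # carbon at z = 0 and oxygen at z = 2 within one residue:
  # COM z = 16*2 / (12 + 16); measured against a point probe at origin
  at <- data.frame(eleno = 1:3,
                   elety = c("C1", "O1", "CA"),
                   element = c("C", "O", "C"),
                   resno = c(1, 1, 2), resname = "UNK", chain = "A")
  at$mass <- c(12, 16, 12)
  top <- topology(at)
  coords <- rbind(c(0, 0, 0), c(0, 0, 2), c(0, 0, 0))
  fm2 <- com_pair_distances(mini_ensemble(list(coords), top = top), 1:2)
  expect_equal(unname(fm2$values[1, 1]), 32 / 28, tolerance = 1e-12)

  # n residues give n(n-1)/2 columns
  set.seed(1)
  ens12 <- mini_ensemble(matrix(rnorm(36), 12, 3))
  expect_equal(ncol(com_pair_distances(ens12, 1:12)$values), 66)
  expect_error(com_pair_distances(ens12, c(1, 99)), "unknown residue")
})

test_that("COM distances of single-CA residues equal CA distances", {
  set.seed(2)
  coords <- matrix(rnorm(30, sd = 5), 10, 3)
  ens <- mini_ensemble(coords)
  fm <- com_pair_distances(ens, 1:10)
  fm_ca <- ca_pair_distances(ens, fm$pairs)
  expect_equal(fm$values, fm_ca$values)
})

test_that("inter-domain pair selection applies cutoff and intersection", {
  # two static 2-residue domains; one cross pair at 8 A, others beyond
  coords <- rbind(c(0, 0, 0), c(0, 0, 30), c(8, 0, 0), c(8, 0, 40))
  ens <- mini_ensemble(coords)
  sel <- select_interdomain_ca_pairs(ens, ens, 1:2, 3:4, stride = 1)
  expect_equal(sel, data.frame(res_i = 1L, res_j = 3L))

  # closest approach 12 A in both systems -> empty, not an error
  far <- mini_ensemble(rbind(c(0, 0, 0), c(0, 0, 30),
                             c(12, 0, 0), c(12, 0, 40)))
  sel2 <- select_interdomain_ca_pairs(far, far, 1:2, 3:4, stride = 1)
  expect_equal(nrow(sel2), 0)

  # pair within 10 A in one system only is excluded by the
  # intersection rule
  sel3 <- select_interdomain_ca_pairs(ens, far, 1:2, 3:4, stride = 1)
  expect_equal(nrow(sel3), 0)
})

test_that("RMSD handles identity, rotation, and the unfit closed form", {
  set.seed(3)
  ref <- matrix(rnorm(42, sd = 4), 14, 3)
  ens <- mini_ensemble(list(ref))
  expect_equal(rmsd_series(ens, as.numeric(t(ref))), 0,
               tolerance = 1e-6)

  tr <- random_rigid_transform()
  rot <- ref %*% t(tr$R) + matrix(tr$t, 14, 3, byrow = TRUE)
  expect_equal(rmsd_series(mini_ensemble(list(rot)),
                           as.numeric(t(ref))), 0, tolerance = 1e-6)

  # +1 A x-shift on half the atoms, no superposition -> sqrt(0.5)
  shifted <- ref
  shifted[1:7, 1] <- shifted[1:7, 1] + 1     # half of the 14 atoms
  r <- rmsd_series(mini_ensemble(list(shifted)), as.numeric(t(ref)),
                   fit = FALSE)
  expect_equal(r, sqrt(7 / 14), tolerance = 1e-12)
})

test_that("pairwise RMSD is symmetric and matches per-pair calls", {
  set.seed(4)
  frames <- lapply(1:3, function(i) matrix(rnorm(30, sd = 3), 10, 3))
  ens <- mini_ensemble(frames)
  m <- pairwise_rmsd(ens)
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(0, 3))
  for (i in 1:2) for (j in (i + 1):3) {
    direct <- rmsd_series(mini_ensemble(frames[j]),
                          as.numeric(t(frames[[i]])))
    expect_equal(m[i, j], direct, tolerance = 1e-8)
  }
  # identical frames give the zero matrix
  same <- mini_ensemble(list(frames[[1]], frames[[1]]))
  expect_equal(max(pairwise_rmsd(same)), 0, tolerance = 1e-6)
})

test_that("RMSF vanishes for static trajectories and scales as sigma*sqrt(3)", {
  base <- build_ideal_helix(40)
  static <- mini_ensemble(lapply(1:5, function(i) base))
  expect_equal(max(rmsf_per_residue(static)$rmsf_mean), 0,
               tolerance = 1e-6)

  set.seed(7)
  sigma <- 0.3
  top <- bead_topology(40)
  reps <- lapply(1:2, function(r) {
    t(vapply(1:1500, function(f)
      as.numeric(t(base + matrix(rnorm(120, sd = sigma), 40, 3))),
      numeric(120)))
  })
  ens <- ensemble_set("jitter", top, reps, 1)
  out <- rmsf_per_residue(ens)
  expect_equal(mean(out$rmsf_mean), sigma * sqrt(3), tolerance = 0.05)
  expect_false(attr(out, "single_replica"))

  single <- ensemble_set("one", top, reps[1], 1)
  out1 <- rmsf_per_residue(single)
  expect_true(attr(out1, "single_replica"))
  expect_equal(out1$rmsf_se, rep(0, 40))
})

test_that("backbone dihedrals are recovered and classified", {
  phi <- c(NA, -60, -120, 60)     # residue 1 phi undefined
  psi <- c(-45, -45, 130, 60)
  ens <- build_backbone(phi = c(-57, phi[-1]), psi = psi)
  pp <- phi_psi(ens, 2:4)
  expect_equal(pp[["2"]]$phi, -60, tolerance = 1e-6)
  expect_equal(pp[["2"]]$psi, -45, tolerance = 1e-6)
  expect_equal(pp[["3"]]$phi, -120, tolerance = 1e-6)
  expect_equal(pp[["3"]]$psi, 130, tolerance = 1e-6)

  first <- phi_psi(ens, 1)[["1"]]
  expect_true(is.na(first$phi))          # chain start: no preceding C
  last <- phi_psi(ens, 4)[["4"]]
  expect_true(is.na(last$psi))           # chain end: no following N

  expect_equal(classify_ramachandran(c(-60, -120, 60), c(-45, 130, 60)),
               c("alpha", "beta", "other"))
})

test_that("helix tilt against opposite reference axes sums to 180", {
  set.seed(9)
  for (i in 1:5) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    h <- build_ideal_helix(10, axis = ax)
    ens <- mini_ensemble(h)
    up <- helix_global_tilt(ens, 1:10, ref_axis = c(0, 0, 1))$tilt_deg
    dn <- helix_global_tilt(ens, 1:10, ref_axis = c(0, 0, -1))$tilt_deg
    expect_equal(up + dn, 180, tolerance = 1e-6)
  }
  expect_error(helix_global_tilt(mini_ensemble(build_ideal_helix(5)),
                                 1:3), "at least 4")
})

test_that("distance features are invariant to rigid motion per frame", {
  spec <- quick_spec(n_frames = 30, replicas = 1, seed = 17)
  gen <- generate_ensembles(spec)
  set.seed(31)
  moved <- apply_rigid(gen$A)
  pocket <- tail(spec$domain_map$domains$SH2, 8)
  f0 <- com_pair_distances(gen$A, pocket)
  f1 <- com_pair_distances(moved, pocket)
  expect_equal(f0$values, f1$values, tolerance = 1e-8)

  r0 <- detect_hbonds(gen$A, min_freq = 0)
  r1 <- detect_hbonds(moved, min_freq = 0)
  expect_equal(r0$presence, r1$presence)
})

test_that("two-sample tests behave at the extremes and under power", {
  x <- c(1, 2, 3, 4, 5)
  same <- compare_distributions(x, x)
  expect_equal(same$ks_stat, 0)

  disjoint <- compare_distributions(1:50, 101:150)
  expect_equal(disjoint$ks_stat, 1)

  set.seed(12)
  strong <- compare_distributions(rnorm(1000), rnorm(1000, mean = 1))
  expect_lt(strong$ks_pvalue, 1e-3)
  expect_lt(strong$t_pvalue, 1e-3)

  degen <- compare_distributions(rep(2, 5), rep(2, 5))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$t_stat))
  expect_error(compare_distributions(1, 1:5), "size >= 2")
})
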