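# Geometric featurization: COM pair distances, inter-domain CA pairs,
# helix global tilt (Sugeta-Miyazawa local axes), RMSD/RMSF, backbone
# dihedrals and two-sample distribution tests.

#' Feature matrix container
#'
#' @param values frames x features numeric matrix (Angstrom or degrees).
#' @param labels character vector, one label per column.
#' @param info per-frame provenance data.frame (`system`, `replica`,
#'   `frame`).
#' @param pairs optional data.frame of residue pairs backing the columns.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, info, pairs = NULL) {
  values <- as.matrix(values)
  if (length(labels) != ncol(values))
    stop("label count (", length(labels), ") != column count (",
         ncol(values), ")")
  if (nrow(info) != nrow(values))
    stop("provenance rows != frame count")
  if (!all(is.finite(values))) stop("feature values must be finite")
  colnames(values) <- labels
  structure(list(values = values, labels = labels, info = info,
                 pairs = pairs), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$values), "frames x", ncol(x$values),
      "features\n")
  invisible(x)
}

#' Stack feature matrices from several systems
#' @param ... `feature_matrix` objects with identical labels.
#' @return A combined `feature_matrix`.
#' @export
combine_features <- function(...) {
  fms <- list(...)
  labs <- fms[[1]]$labels
  for (fm in fms[-1])
    if (!identical(fm$labels, labs)) stop("feature labels do not match")
  feature_matrix(do.call(rbind, lapply(fms, `[[`, "values")), labs,
                 do.call(rbind, lapply(fms, `[[`, "info")),
                 pairs = fms[[1]]$pairs)
}

# per-frame center of mass of one residue: frames x 3
residue_com <- function(ensemble, resno) {
  top <- ensemble$topology
  idx <- which(top$atoms$resno == resno)
  if (!length(idx)) stop("unknown residue id: ", resno)
  w <- top$atoms$mass[idx]
  w <- w / sum(w)
  xyz <- all_xyz(ensemble)
  out <- matrix(0, nrow(xyz), 3)
  for (d in 1:3) {
    cols <- 3 * (idx - 1) + d
    out[, d] <- xyz[, cols, drop = FALSE] %*% w
  }
  out
}

#' Residue center-of-mass pair distances
#'
#' One column per unordered residue pair (i < j), mass-weighted over
#' each residue's atoms.
#'
#' @param ensemble an [ensemble_set()].
#' @param residue_set residue numbers (n >= 2).
#' @return A [feature_matrix()] with `n (n - 1) / 2` columns labelled
#'   `"i-j"`.
#' @export
com_pair_distances <- function(ensemble, residue_set) {
  residue_set <- sort(unique(as.integer(residue_set)))
  if (length(residue_set) < 2) stop("need at least two residues")
  coms <- lapply(residue_set, function(r) residue_com(ensemble, r))
  n <- length(residue_set)
  cols <- vector("list", n * (n - 1) / 2)
  labs <- character(length(cols))
  pairs <- matrix(0L, length(cols), 2)
  k <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    k <- k + 1
    cols[[k]] <- sqrt(rowSums((coms[[i]] - coms[[j]])^2))
    labs[k] <- paste0(residue_set[i], "-", residue_set[j])
    pairs[k, ] <- c(residue_set[i], residue_set[j])
  }
  feature_matrix(do.call(cbind, cols), labs, frame_info(ensemble),
                 pairs = data.frame(res_i = pairs[, 1], res_j = pairs[, 2]))
}

#' CA-CA distances for an explicit list of residue pairs
#'
#' @param ensemble an [ensemble_set()].
#' @param pairs data.frame with columns `res_i`, `res_j`.
#' @return A [feature_matrix()].
#' @export
ca_pair_distances <- function(ensemble, pairs) {
  top <- ensemble$topology
  xyz <- all_xyz(ensemble)
  ci <- ca_indices(top, pairs$res_i)
  cj <- ca_indices(top, pairs$res_j)
  vals <- matrix(0, nrow(xyz), nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    d <- xyz[, atom2xyz_idx(ci[k]), drop = FALSE] -
      xyz[, atom2xyz_idx(cj[k]), drop = FALSE]
    vals[, k] <- sqrt(rowSums(d^2))
  }
  feature_matrix(vals, paste0(pairs$res_i, "-", pairs$res_j),
                 frame_info(ensemble),
                 pairs = data.frame(res_i = pairs$res_i, res_j = pairs$res_j))
}

#' Select inter-domain CA pairs within a contact cutoff in both systems
#'
#' A pair (r1 in `domain1`, r2 in `domain2`) qualifies in one system if
#' its CA-CA distance falls below `cutoff` in at least one analyzed
#' frame; the returned set is the intersection of the two systems'
#' qualifying pairs. The criterion is evaluated on a strided frame
#' subset for speed; the any-frame rule is exact on that subset.
#'
#' @param ensemble_a,ensemble_b the two [ensemble_set()]s.
#' @param domain1,domain2 residue number vectors.
#' @param cutoff contact cutoff in Angstrom (default 10, i.e. 1 nm).
#' @param stride frame stride for the scan.
#' @return data.frame with columns `res_i` (domain1), `res_j`
#'   (domain2); zero rows if no pair qualifies.
#' @export
select_interdomain_ca_pairs <- function(ensemble_a, ensemble_b,
                                        domain1, domain2, cutoff = 10,
                                        stride = 10) {
  qualify <- function(ens) {
    ci <- ca_indices(ens$topology, domain1)
    cj <- ca_indices(ens$topology, domain2)
    xyz <- all_xyz(ens)
    xyz <- xyz[seq(1, nrow(xyz), by = stride), , drop = FALSE]
    hit <- matrix(FALSE, length(ci), length(cj))
    for (f in seq_len(nrow(xyz))) {
      a <- matrix(xyz[f, atom2xyz_idx(ci)], ncol = 3, byrow = TRUE)
      b <- matrix(xyz[f, atom2xyz_idx(cj)], ncol = 3, byrow = TRUE)
      d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
        outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
      hit <- hit | (d2 < cutoff^2)
    }
    hit
  }
  hits <- qualify(ensemble_a) & qualify(ensemble_b)
  idx <- which(hits, arr.ind = TRUE)
  out <- data.frame(res_i = domain1[idx[, 1]], res_j = domain2[idx[, 2]])
  out <- out[order(out$res_i, out$res_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Sugeta-Miyazawa local helix axes: for each window of 4 consecutive CA
# atoms, the axis is the cross product of successive bond-vector
# differences, oriented along the chain.
helix_axes_frame <- function(p) {
  n <- nrow(p)
  b <- p[-1, , drop = FALSE] - p[-n, , drop = FALSE]
  axes <- matrix(0, n - 3, 3)
  for (j in seq_len(n - 3)) {
    d1 <- b[j, ] - b[j + 1, ]
    d2 <- b[j + 1, ] - b[j + 2, ]
    ax <- cross3(d1, d2)
    nrm <- vec_norm(ax)
    if (nrm < 1e-12) { axes[j, ] <- NA_real_; next }
    ax <- ax / nrm
    if (sum(ax * (p[j + 3, ] - p[j, ])) < 0) ax <- -ax
    axes[j, ] <- ax
  }
  axes[stats::complete.cases(axes), , drop = FALSE]
}

#' Global helix tilt per frame
#'
#' Local helix axes are built from sliding windows of four consecutive
#' CA atoms (Sugeta-Miyazawa construction); the global axis is the
#' normalized mean of the local axes and the tilt is its angle to
#' `ref_axis`, in degrees within \[0, 180\]. The ensemble is assumed to
#' be aligned to a common reference structure.
#'
#' @param ensemble an [ensemble_set()].
#' @param helix_residues residues of the helix (>= 4 CA atoms).
#' @param ref_axis reference direction (default z).
#' @return Object of class `helix_tilt` with per-frame `tilt_deg` and
#'   frame provenance.
#' @export
helix_global_tilt <- function(ensemble, helix_residues,
                              ref_axis = c(0, 0, 1)) {
  if (length(helix_residues) < 4)
    stop("helix needs at least 4 CA residues")
  ref <- unit_vec(ref_axis)
  ca <- ca_indices(ensemble$topology, helix_residues)
  xyz <- all_xyz(ensemble)
  cols <- atom2xyz_idx(ca)
  tilt <- vapply(seq_len(nrow(xyz)), function(f) {
    p <- matrix(xyz[f, cols], ncol = 3, byrow = TRUE)
    axes <- helix_axes_frame(p)
    g <- unit_vec(colMeans(axes))
    acos(max(-1, min(1, sum(g * ref)))) * 180 / pi
  }, numeric(1))
  structure(list(tilt_deg = tilt, ref_axis = ref,
                 residues = helix_residues, info = frame_info(ensemble)),
            class = "helix_tilt")
}

#' Per-frame RMSD to a reference structure
#'
#' With `fit = TRUE` (default) each frame is optimally superposed onto
#' the reference over `selection` before the deviation is measured.
#'
#' @param ensemble an [ensemble_set()].
#' @param reference_xyz numeric 3N reference coordinates (full
#'   topology).
#' @param selection atom indices used both for fitting and measuring
#'   (default: all CA atoms).
#' @param fit superpose before measuring?
#' @return Numeric vector of per-frame RMSD in Angstrom.
#' @export
rmsd_series <- function(ensemble, reference_xyz, selection = NULL,
                        fit = TRUE) {
  top <- ensemble$topology
  selection <- selection %||% which(top$atoms$elety == "CA")
  if (!length(selection)) stop("empty selection")
  if (length(reference_xyz) != 3L * top$n_atoms)
    stop("reference length does not match topology")
  cols <- atom2xyz_idx(selection)
  xyz <- all_xyz(ensemble)
  rmsd_to_ref(reference_xyz[cols], xyz[, cols, drop = FALSE], fit)
}

# full-precision RMSD of each row of `mob` (frames x 3n) to `ref`
rmsd_to_ref <- function(ref, mob, fit = TRUE) {
  if (fit) {
    k <- length(ref)
    mob <- bio3d::fit.xyz(fixed = ref, mobile = mob,
                          fixed.inds = seq_len(k),
                          mobile.inds = seq_len(k))
    mob <- matrix(mob, ncol = k)
  }
  dev <- sweep(mob, 2, ref)
  sqrt(rowSums(dev^2) / (length(ref) / 3))
}

#' Pairwise RMSD matrix over strided frames
#'
#' @param ensemble an [ensemble_set()].
#' @param stride keep every `stride`-th frame.
#' @param selection atom indices (default: all CA atoms).
#' @return Symmetric matrix of superposed RMSD values, zero diagonal.
#' @export
pairwise_rmsd <- function(ensemble, stride = 1L, selection = NULL) {
  top <- ensemble$topology
  selection <- selection %||% which(top$atoms$elety == "CA")
  cols <- atom2xyz_idx(selection)
  xyz <- all_xyz(ensemble)[, cols, drop = FALSE]
  xyz <- xyz[seq(1, nrow(xyz), by = stride), , drop = FALSE]
  n <- nrow(xyz)
  if (n < 2) stop("need at least 2 sampled frames")
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    r <- rmsd_to_ref(xyz[i, ], xyz[(i + 1):n, , drop = FALSE])
    m[i, (i + 1):n] <- r
    m[(i + 1):n, i] <- r
  }
  m
}

#' Per-residue RMSF averaged over replicas
#'
#' Each replica is superposed (CA atoms) onto its own first frame, the
#' per-CA root-mean-square fluctuation about the replica mean is
#' computed, and mean and standard error over replicas are reported.
#' With a single replica the standard error is reported as 0 and
#' flagged.
#'
#' @param ensemble an [ensemble_set()].
#' @return data.frame with `resno`, `rmsf_mean`, `rmsf_se`; attribute
#'   `single_replica` flags the degenerate case.
#' @export
rmsf_per_residue <- function(ensemble) {
  top <- ensemble$topology
  ca <- which(top$atoms$elety == "CA")
  cols <- atom2xyz_idx(ca)
  per_rep <- lapply(ensemble$replicas, function(m) {
    fitted <- bio3d::fit.xyz(fixed = m[1, ], mobile = m,
                             fixed.inds = cols, mobile.inds = cols)
    bio3d::rmsf(fitted[, cols, drop = FALSE])
  })
  mat <- do.call(cbind, per_rep)
  nrep <- ncol(mat)
  se <- if (nrep > 1) apply(mat, 1, sd) / sqrt(nrep) else rep(0, nrow(mat))
  out <- data.frame(resno = top$atoms$resno[ca],
                    rmsf_mean = rowMeans(mat), rmsf_se = se)
  attr(out, "single_replica") <- nrep == 1
  out
}

#' Backbone phi/psi dihedrals for selected residues
#'
#' Requires full backbone atoms (N, CA, C) for each residue and its
#' neighbours. Chain-terminal residues with an undefined angle are
#' reported as `NA`.
#'
#' @param ensemble an [ensemble_set()].
#' @param residues residue numbers.
#' @return list of per-residue data.frames with per-frame `phi`, `psi`
#'   in degrees.
#' @export
phi_psi <- function(ensemble, residues) {
  top <- ensemble$topology
  xyz <- all_xyz(ensemble)
  get_idx <- function(resno, elety) {
    i <- which(top$atoms$resno == resno & top$atoms$elety == elety)
    if (length(i) == 1) i else NA_integer_
  }
  out <- lapply(residues, function(r) {
    iN <- get_idx(r, "N"); iCA <- get_idx(r, "CA"); iC <- get_idx(r, "C")
    iCprev <- get_idx(r - 1, "C"); iNnext <- get_idx(r + 1, "N")
    if (is.na(iN) || is.na(iCA) || is.na(iC))
      stop("residue ", r, " lacks full backbone (N, CA, C)")
    nfr <- nrow(xyz)
    phi <- rep(NA_real_, nfr)
    psi <- rep(NA_real_, nfr)
    for (f in seq_len(nfr)) {
      pt <- function(i) xyz[f, atom2xyz_idx(i)]
      if (!is.na(iCprev))
        phi[f] <- dihedral_angle(rbind(pt(iCprev), pt(iN), pt(iCA), pt(iC)))
      if (!is.na(iNnext))
        psi[f] <- dihedral_angle(rbind(pt(iN), pt(iCA), pt(iC), pt(iNnext)))
    }
    data.frame(phi = phi, psi = psi)
  })
  names(out) <- as.character(residues)
  out
}

#' Classify (phi, psi) pairs into Ramachandran regions
#'
#' Rectangular region defaults: alpha phi in \[-100, -30\], psi in
#' \[-80, -5\]; beta phi in \[-180, -45\], psi in \[90, 180\] or
#' \[-180, -150\]. Anything else is "other".
#'
#' @param phi,psi angles in degrees.
#' @param regions optional list overriding the rectangles; each entry is
#'   a list of `rbind(c(phi_lo, phi_hi, psi_lo, psi_hi), ...)` rows.
#' @return Character vector in `c("alpha", "beta", "other")` (`NA` in,
#'   `NA` out).
#' @export
classify_ramachandran <- function(phi, psi, regions = NULL) {
  regions <- regions %||% list(
    alpha = rbind(c(-100, -30, -80, -5)),
    beta = rbind(c(-180, -45, 90, 180), c(-180, -45, -180, -150)))
  out <- rep("other", length(phi))
  out[is.na(phi) | is.na(psi)] <- NA_character_
  for (nm in names(regions)) {
    rects <- regions[[nm]]
    inside <- rep(FALSE, length(phi))
    for (r in seq_len(nrow(rects))) {
      inside <- inside | (!is.na(phi) & !is.na(psi) &
                            phi >= rects[r, 1] & phi <= rects[r, 2] &
                            psi >= rects[r, 3] & psi <= rects[r, 4])
    }
    out[inside & out == "other"] <- nm
  }
  out
}

#' Two-sample distribution comparison (Welch t and Kolmogorov-Smirnov)
#'
#' @param sample_a,sample_b numeric samples (size >= 2 each).
#' @return Object of class `distribution_test` with `t_stat`,
#'   `t_pvalue`, `ks_stat`, `ks_pvalue`, sample sizes and a
#'   `degenerate` flag set when both samples are constant and identical
#'   (t undefined).
#' @export
compare_distributions <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("both samples must have size >= 2")
  ks <- suppressWarnings(ks.test(sample_a, sample_b))
  degenerate <- sd(sample_a) == 0 && sd(sample_b) == 0
  if (degenerate) {
    tt <- list(statistic = NA_real_, p.value = NA_real_)
  } else {
    tt <- t.test(sample_a, sample_b, var.equal = FALSE)
  }
  structure(list(t_stat = unname(tt$statistic), t_pvalue = tt$p.value,
                 ks_stat = unname(ks$statistic), ks_pvalue = ks$p.value,
                 n_a = length(sample_a), n_b = length(sample_b),
                 degenerate = degenerate),
            class = "distribution_test")
}

#' @export
print.distribution_test <- function(x, ...) {
  cat("two-sample test: t =", signif(x$t_stat, 4),
      "(p =", signif(x$t_pvalue, 3), "), KS D =", signif(x$ks_stat, 4),
      "(p =", signif(x$ks_pvalue, 3), ")\n")
  invisible(x)
}
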