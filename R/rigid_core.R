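# Rigid-core analysis: rank inter-domain CA pair distances by their
# variability across all frames of all replicas of both systems.

#' Per-pair distance variability over the pooled frame set
#'
#' Mean and population (N) standard deviation per feature column over
#' the combined frames, with ascending-deviation ranks. Ties are
#' broken by (res_i, res_j) order when pair metadata is available.
#'
#' @param fm a [feature_matrix()] of pair distances pooled over both
#'   systems (see [combine_features()]).
#' @return data.frame (`pair_variability`) with `label`, optional
#'   `res_i`/`res_j`, `mean`, `sd`, `rank`.
#' @export
pair_variability <- function(fm) {
  X <- fm$values
  if (nrow(X) < 2) stop("need at least 2 frames")
  mu <- colMeans(X)
  sdev <- sqrt(colMeans(sweep(X, 2, mu)^2))   # population form
  out <- data.frame(label = fm$labels, mean = mu, sd = sdev,
                    row.names = NULL)
  if (!is.null(fm$pairs)) {
    out$res_i <- fm$pairs$res_i
    out$res_j <- fm$pairs$res_j
    ord <- order(out$sd, out$res_i, out$res_j)
  } else {
    ord <- order(out$sd, out$label)
  }
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(nrow(out))
  class(out) <- c("pair_variability", "data.frame")
  out
}

#' Select the least-deviating ("rigid core") pairs
#'
#' @param table a [pair_variability()] table.
#' @param k number of pairs to keep (default 200, the size used for
#'   full-protein inter-domain analyses).
#' @return The k lowest-deviation rows, in rank order.
#' @export
rigid_core_selection <- function(table, k = 200) {
  if (k > nrow(table)) stop("k exceeds the table size")
  out <- table[order(table$rank), , drop = FALSE][seq_len(k), ,
                                                  drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Residue-level rigid-core membership
#'
#' Residues appearing in at least `m` selected pairs.
#'
#' @param selection output of [rigid_core_selection()] (needs
#'   `res_i`/`res_j`).
#' @param m minimum number of selected pairs a residue must appear in.
#' @return data.frame with `resno` and `n_pairs`.
#' @export
rigid_core_residues <- function(selection, m = 2) {
  if (is.null(selection$res_i)) stop("selection lacks residue columns")
  tab <- table(c(selection$res_i, selection$res_j))
  keep <- tab[tab >= m]
  data.frame(resno = as.integer(names(keep)),
             n_pairs = as.integer(keep), row.names = NULL)
}

#' Per-macro-state distance distributions and their overlap
#'
#' For each named atom pair, computes the per-macro-state distance
#' samples, a histogram per state, and a pairwise distribution-overlap
#' score `1 - KS statistic` across states. States with fewer than 10
#' frames are flagged.
#'
#' @param atom_pairs data.frame with columns `res_i`, `atom_i`,
#'   `res_j`, `atom_j`.
#' @param ensemble an [ensemble_set()].
#' @param macro_labels per-frame macro labels aligned with the
#'   ensemble.
#' @param breaks histogram breaks passed to [graphics::hist()]
#'   semantics via [base::cut()]; default 30 equal bins.
#' @return list per pair with `samples` (per state), `histograms`,
#'   `overlap` (symmetric matrix), `min_overlap`, `flagged_states`.
#' @export
conserved_distance_profiles <- function(atom_pairs, ensemble,
                                        macro_labels, breaks = 30) {
  xyz <- all_xyz(ensemble)
  if (length(macro_labels) != nrow(xyz))
    stop("macro labels not aligned with the ensemble frames")
  states <- sort(unique(macro_labels[!is.na(macro_labels)]))
  out <- lapply(seq_len(nrow(atom_pairs)), function(p) {
    i <- atom_index(ensemble$topology, atom_pairs$res_i[p],
                    atom_pairs$atom_i[p])
    j <- atom_index(ensemble$topology, atom_pairs$res_j[p],
                    atom_pairs$atom_j[p])
    d <- sqrt(rowSums((xyz[, atom2xyz_idx(i), drop = FALSE] -
                         xyz[, atom2xyz_idx(j), drop = FALSE])^2))
    samples <- lapply(states, function(s)
      d[!is.na(macro_labels) & macro_labels == s])
    names(samples) <- paste0("M", states)
    flagged <- states[vapply(samples, length, integer(1)) < 10]
    brk <- seq(min(d), max(d), length.out = breaks + 1)
    hists <- lapply(samples, function(s)
      if (length(s)) tabulate(findInterval(s, brk, all.inside = TRUE),
                              nbins = breaks) else rep(0L, breaks))
    ov <- diag(1, length(states))
    if (length(states) > 1) {
      for (a in 1:(length(states) - 1)) for (b in (a + 1):length(states)) {
        if (length(samples[[a]]) < 2 || length(samples[[b]]) < 2) {
          ov[a, b] <- ov[b, a] <- NA_real_
        } else {
          ks <- suppressWarnings(ks.test(samples[[a]], samples[[b]]))
          ov[a, b] <- ov[b, a] <- 1 - unname(ks$statistic)
        }
      }
    }
    dimnames(ov) <- list(names(samples), names(samples))
    list(pair = atom_pairs[p, ], samples = samples, breaks = brk,
         histograms = hists, overlap = ov,
         min_overlap = min(ov, na.rm = TRUE), flagged_states = flagged)
  })
  names(out) <- paste0(atom_pairs$res_i, ":", atom_pairs$atom_i, "-",
                       atom_pairs$res_j, ":", atom_pairs$atom_j)
  out
}
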