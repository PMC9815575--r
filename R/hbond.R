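# Hydrogen-bond network analysis: geometric (Baker-Hubbard style)
# per-frame detection, per-macro-state occurrence rates, conserved
# bonds, and the differential (+/-50 percent) network against a
# reference macro-state.

#' Detect hydrogen bonds with a geometric distance/angle criterion
#'
#' A donor-H...acceptor triplet counts as bonded in a frame when the
#' H...acceptor distance is at most `dist_cutoff` and the
#' donor-H...acceptor angle is at least `angle_cutoff`. Donors are
#' N/O heavy atoms with a covalently bonded hydrogen (from the
#' topology's `hpar` map); acceptors are N/O atoms. Salt bridges
#' between amine and carboxylate groups satisfy the same geometric
#' rule and are reported as hydrogen bonds. Bonds are kept when their
#' overall frame frequency reaches `min_freq`.
#'
#' @param ensemble an [ensemble_set()] whose topology includes
#'   hydrogens with assigned parents.
#' @param dist_cutoff H...acceptor cutoff, Angstrom (default 2.5).
#' @param angle_cutoff donor-H...acceptor cutoff, degrees (default
#'   120).
#' @param min_freq minimum overall frequency (default 0.1).
#' @param exclude_same_residue drop donor/acceptor pairs within one
#'   residue (default TRUE).
#' @return Object of class `hbond_records`: `bonds` (data.frame with
#'   donor/acceptor residue and atom plus `freq`), `presence`
#'   (frames x bonds logical matrix), `info` (frame provenance).
#' @export
detect_hbonds <- function(ensemble, dist_cutoff = 2.5,
                          angle_cutoff = 120, min_freq = 0.1,
                          exclude_same_residue = TRUE) {
  top <- ensemble$topology
  at <- top$atoms
  hyd <- which(at$element == "H" & !is.na(at$hpar))
  if (!length(hyd))
    stop("topology has no hydrogens with assigned donors; hydrogen ",
         "bonds cannot be detected on a heavy-atom-only model")
  acc <- which(at$element %in% c("N", "O"))
  xyz <- all_xyz(ensemble)
  nfr <- nrow(xyz)
  bonds <- list()
  presence <- list()
  for (h in hyd) {
    d <- at$hpar[h]
    hx <- xyz[, atom2xyz_idx(h), drop = FALSE]
    dx <- xyz[, atom2xyz_idx(d), drop = FALSE]
    for (a in acc) {
      if (a == d || a == h) next
      if (exclude_same_residue && at$resno[a] == at$resno[d]) next
      ax <- xyz[, atom2xyz_idx(a), drop = FALSE]
      ha <- ax - hx
      dha <- sqrt(rowSums(ha^2))
      close_enough <- dha <= dist_cutoff
      if (!any(close_enough)) next
      hd <- dx - hx
      cosang <- rowSums(ha * hd) /
        (dha * sqrt(rowSums(hd^2)))
      ang <- acos(pmax(-1, pmin(1, cosang))) * 180 / pi
      present <- close_enough & ang >= angle_cutoff
      freq <- mean(present)
      if (any(present) && freq >= min_freq) {
        bonds[[length(bonds) + 1]] <- data.frame(
          donor_res = at$resno[d], donor_atom = at$elety[d],
          hydrogen_atom = at$elety[h],
          acceptor_res = at$resno[a], acceptor_atom = at$elety[a],
          freq = freq, stringsAsFactors = FALSE)
        presence[[length(presence) + 1]] <- present
      }
    }
  }
  bonds <- if (length(bonds)) do.call(rbind, bonds) else
    data.frame(donor_res = integer(), donor_atom = character(),
               hydrogen_atom = character(), acceptor_res = integer(),
               acceptor_atom = character(), freq = numeric())
  pres <- if (length(presence)) do.call(cbind, presence) else
    matrix(FALSE, nfr, 0)
  structure(list(bonds = bonds, presence = pres,
                 info = frame_info(ensemble)),
            class = "hbond_records")
}

#' @export
print.hbond_records <- function(x, ...) {
  cat("hbond_records:", nrow(x$bonds), "bonds over", nrow(x$presence),
      "frames\n")
  invisible(x)
}

#' Merge hydrogen-bond records from several ensembles
#'
#' Bonds are keyed by (donor residue, donor atom, acceptor residue,
#' acceptor atom) so rotamer-equivalent hydrogens aggregate; a bond
#' absent from one ensemble contributes all-FALSE presence there.
#'
#' @param ... `hbond_records` objects over the same topology.
#' @return A combined `hbond_records`.
#' @export
combine_hbonds <- function(...) {
  recs <- list(...)
  key <- function(b) paste(b$donor_res, b$donor_atom, b$acceptor_res,
                           b$acceptor_atom, sep = "|")
  keys <- unique(unlist(lapply(recs, function(r) key(r$bonds))))
  info <- do.call(rbind, lapply(recs, `[[`, "info"))
  nfr <- vapply(recs, function(r) nrow(r$presence), integer(1))
  pres <- matrix(FALSE, sum(nfr), length(keys))
  bonds <- NULL
  off <- 0
  for (r in recs) {
    kk <- key(r$bonds)
    for (b in seq_along(kk)) {
      j <- match(kk[b], keys)
      pres[off + seq_len(nrow(r$presence)), j] <- r$presence[, b]
      if (is.null(bonds)) bonds <- r$bonds[0, ]
    }
    bonds <- rbind(bonds, r$bonds[!kk %in% key(bonds), , drop = FALSE])
    off <- off + nrow(r$presence)
  }
  bonds <- bonds[match(keys, key(bonds)), , drop = FALSE]
  bonds$freq <- colMeans(pres)
  rownames(bonds) <- NULL
  structure(list(bonds = bonds, presence = pres, info = info),
            class = "hbond_records")
}

#' Hydrogen-bond occurrence rate per macro-state
#'
#' @param records an [detect_hbonds()] result (possibly
#'   [combine_hbonds()]-merged).
#' @param macro_labels per-frame macro-state labels aligned with the
#'   records' frames (NA frames are dropped).
#' @return matrix bonds x macro-states of occurrence rates in
#'   \[0, 1\]; bond metadata attached as attribute `bonds`.
#' @export
hbond_rates_by_state <- function(records, macro_labels) {
  if (length(macro_labels) != nrow(records$presence))
    stop("macro labels not aligned with the hbond frames")
  keep <- !is.na(macro_labels)
  labs <- macro_labels[keep]
  pres <- records$presence[keep, , drop = FALSE]
  states <- sort(unique(labs))
  if (!length(states)) stop("no labelled frames")
  rates <- vapply(states, function(s)
    colMeans(pres[labs == s, , drop = FALSE]), numeric(ncol(pres)))
  rates <- matrix(rates, nrow = ncol(pres))
  dimnames(rates) <- list(NULL, paste0("M", states))
  attr(rates, "bonds") <- records$bonds
  attr(rates, "states") <- states
  rates
}

#' Differential hydrogen-bond network against a reference macro-state
#'
#' A bond is gained in state M when `rate_M >= up * rate_ref` (and
#' `rate_M >= min_rate`), and lost when `rate_M <= down * rate_ref`
#' (and `rate_ref >= min_rate`). The default thresholds implement the
#' "at least 50 percent higher / lower rate" rule; `min_rate`
#' suppresses ratios of near-zero rates.
#'
#' @param rate_table bonds x states rate matrix from
#'   [hbond_rates_by_state()].
#' @param ref_state reference macro-state id (matched against the
#'   `states` attribute or column index).
#' @param up,down ratio thresholds (defaults 1.5 and 0.5).
#' @param min_rate rate floor (default 0.05).
#' @return Object of class `differential_hbond_network`: `gained` and
#'   `lost` data.frames (`bond`, `state`, `rate`, `ref_rate`),
#'   thresholds, and the reference state.
#' @export
differential_hbond_network <- function(rate_table, ref_state,
                                       up = 1.5, down = 0.5,
                                       min_rate = 0.05) {
  states <- attr(rate_table, "states") %||% seq_len(ncol(rate_table))
  ri <- match(ref_state, states)
  if (is.na(ri)) stop("ref_state not present in the rate table")
  ref <- rate_table[, ri]
  gained <- list(); lost <- list()
  for (si in seq_along(states)) {
    if (si == ri) next
    r <- rate_table[, si]
    g <- which(r >= up * ref & r >= min_rate)
    l <- which(r <= down * ref & ref >= min_rate)
    if (length(g)) gained[[length(gained) + 1]] <- data.frame(
      bond = g, state = states[si], rate = r[g], ref_rate = ref[g])
    if (length(l)) lost[[length(lost) + 1]] <- data.frame(
      bond = l, state = states[si], rate = r[l], ref_rate = ref[l])
  }
  empty <- data.frame(bond = integer(), state = integer(),
                      rate = numeric(), ref_rate = numeric())
  structure(list(
    gained = if (length(gained)) do.call(rbind, gained) else empty,
    lost = if (length(lost)) do.call(rbind, lost) else empty,
    ref_state = ref_state, up = up, down = down, min_rate = min_rate,
    bonds = attr(rate_table, "bonds")),
    class = "differential_hbond_network")
}

#' @export
print.differential_hbond_network <- function(x, ...) {
  cat("differential_hbond_network vs M", x$ref_state, ": ",
      nrow(x$gained), " gained, ", nrow(x$lost), " lost\n", sep = "")
  invisible(x)
}

#' Bonds conserved across all macro-states
#'
#' @param rate_table bonds x states rate matrix.
#' @param floor minimum rate required in every state (default 0.5).
#' @return Integer indices of conserved bonds (rows of the rate
#'   table).
#' @export
conserved_hbonds <- function(rate_table, floor = 0.5) {
  if (ncol(rate_table) < 2) stop("need at least 2 macro-states")
  which(apply(rate_table >= floor, 1, all))
}
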