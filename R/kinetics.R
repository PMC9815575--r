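# Kinetic coarse-graining: micro-state clustering on the 2-D landscape,
# lag-dependent transition counts, the symmetrized reversible MSM
# estimator, implied timescales and PCCA+ macro-states.

#' Cluster projected frames into micro-states
#'
#' Deterministic agglomerative (Ward) clustering of the 2-D PC
#' coordinates. When the frame count exceeds `max_fit_frames` the
#' hierarchy is built on an evenly spaced subset and all frames are
#' then assigned to the nearest cluster center (member mean), which is
#' also how new data are assigned.
#'
#' @param projection frames x d coordinate matrix (from
#'   [project_pca()]).
#' @param n_micro number of micro-states.
#' @param linkage hclust linkage; `"ward"` maps to `"ward.D2"`.
#' @param max_fit_frames hierarchy size cap.
#' @return Object of class `microstate_model` with per-frame `labels`,
#'   `centers` and `n_micro`.
#' @export
cluster_microstates <- function(projection, n_micro = 300,
                                linkage = "ward",
                                max_fit_frames = 5000) {
  proj <- as.matrix(projection)
  nfr <- nrow(proj)
  if (nfr < n_micro)
    stop("frames (", nfr, ") < n_micro (", n_micro, ")")
  method <- if (linkage == "ward") "ward.D2" else linkage
  fit_idx <- if (nfr > max_fit_frames)
    round(seq(1, nfr, length.out = max_fit_frames)) else seq_len(nfr)
  sub <- proj[fit_idx, , drop = FALSE]
  hc <- hclust(dist(sub), method = method)
  sub_lab <- cutree(hc, k = n_micro)
  centers <- do.call(rbind, lapply(seq_len(n_micro), function(k)
    colMeans(sub[sub_lab == k, , drop = FALSE])))
  labels <- assign_to_centers(proj, centers)
  structure(list(labels = labels, centers = centers, n_micro = n_micro,
                 info = attr(projection, "info")),
            class = "microstate_model")
}

#' Assign coordinates to the nearest micro-state center
#' @param projection frames x d matrix.
#' @param centers n_micro x d center matrix.
#' @return Integer labels in 1..n_micro.
#' @export
assign_to_centers <- function(projection, centers) {
  proj <- as.matrix(projection)
  d2 <- outer(rowSums(proj^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(proj)), rowSums(centers^2)) -
    2 * proj %*% t(centers)
  max.col(-d2, ties.method = "first")
}

#' @export
print.microstate_model <- function(x, ...) {
  cat("microstate_model:", x$n_micro, "micro-states over",
      length(x$labels), "frames\n")
  invisible(x)
}

#' Count micro-state transitions at a lag
#'
#' Sliding-window counts (every frame is a window start) strictly
#' within each trajectory segment; replica and system boundaries are
#' never crossed. A segment shorter than the lag contributes nothing
#' (with a warning).
#'
#' @param labels integer micro-state labels (1-based).
#' @param lag_frames lag in frames (>= 1).
#' @param trajectory factor/vector marking the trajectory (system x
#'   replica) each frame belongs to; a single trajectory is assumed
#'   when NULL.
#' @param n_states number of states (default `max(labels)`).
#' @return n x n count matrix C, `C[i, j]` = observed i -> j
#'   transitions.
#' @export
count_transitions <- function(labels, lag_frames, trajectory = NULL,
                              n_states = NULL) {
  lag_frames <- as.integer(lag_frames)
  if (lag_frames < 1) stop("lag must be >= 1 frame")
  n_states <- n_states %||% max(labels)
  trajectory <- trajectory %||% rep(1L, length(labels))
  C <- matrix(0, n_states, n_states)
  for (tr in unique(trajectory)) {
    l <- labels[trajectory == tr]
    if (length(l) <= lag_frames) {
      warning("trajectory ", tr, " shorter than the lag; skipped")
      next
    }
    i <- l[seq_len(length(l) - lag_frames)]
    j <- l[(lag_frames + 1):length(l)]
    tab <- table(factor(i, levels = seq_len(n_states)),
                 factor(j, levels = seq_len(n_states)))
    C <- C + unclass(tab)
  }
  dimnames(C) <- NULL
  C
}

#' Reversible transition matrix from a count matrix
#'
#' Uses the symmetrized estimator
#' `P_ij = (C_ij + C_ji) / sum_k (C_ik + C_ki)` after trimming to the
#' largest connected component of the symmetrized count graph. The
#' stationary distribution `pi_i` is proportional to the row sums of
#' `C + t(C)`, so detailed balance `pi_i P_ij = pi_j P_ji` holds
#' exactly by construction.
#'
#' @param C square count matrix.
#' @param lag_frames,lag_ns the lag the counts were taken at (stored
#'   for timescale conversion; default 1 frame).
#' @return Object of class `transition_model`: `P`, `pi`, `C`,
#'   `kept_states` (indices into the original state set),
#'   `trimmed_states`, `eigenvalues`, `lag_frames`, `lag_ns`.
#' @export
transition_matrix <- function(C, lag_frames = 1, lag_ns = NULL) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop("count matrix must be square")
  S <- C + t(C)
  g <- igraph::graph_from_adjacency_matrix(S > 0, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  active <- rowSums(S) > 0
  sizes <- vapply(seq_len(comp$no), function(k)
    sum(active & comp$membership == k), integer(1))
  keep <- which(active & comp$membership == which.max(sizes))
  trimmed <- setdiff(seq_len(nrow(C)), keep)
  if (!length(keep)) stop("count matrix has no observed transitions")
  Ck <- C[keep, keep, drop = FALSE]
  Sk <- Ck + t(Ck)
  rs <- rowSums(Sk)
  P <- Sk / rs
  pi <- rs / sum(Sk)
  # spectrum via the symmetric similarity transform (real by
  # reversibility)
  A <- diag(sqrt(pi)) %*% P %*% diag(1 / sqrt(pi))
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE)
  structure(list(P = P, pi = pi, C = Ck, kept_states = keep,
                 trimmed_states = trimmed,
                 eigenvalues = ev$values, eigenvectors_sym = ev$vectors,
                 lag_frames = lag_frames, lag_ns = lag_ns),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat("transition_model:", nrow(x$P), "states (",
      length(x$trimmed_states), "trimmed ), lag", x$lag_frames,
      "frames\n")
  invisible(x)
}

# right eigenvectors of P (columns), from the symmetric eigenproblem
right_eigenvectors <- function(tm, m) {
  V <- tm$eigenvectors_sym[, seq_len(m), drop = FALSE] / sqrt(tm$pi)
  V[, 1] <- 1
  V
}

#' Implied relaxation timescales over a list of lags
#'
#' For each lag, counts are re-estimated, the reversible transition
#' matrix is built and the timescales `t_i = -lag / log(lambda_i)` are
#' reported for eigenvalues in (0, 1).
#'
#' @param labels,trajectory as in [count_transitions()].
#' @param lag_list integer lags in frames (>= 2 values).
#' @param n_timescales how many timescales to keep per lag.
#' @param dt_ns frame interval for the ns conversion (optional).
#' @return data.frame with `lag_frames`, `timescale_index`,
#'   `timescale_frames` and, when `dt_ns` is given, `lag_ns` /
#'   `timescale_ns`.
#' @export
implied_timescales <- function(labels, lag_list, trajectory = NULL,
                               n_timescales = 5, dt_ns = NULL) {
  if (length(lag_list) < 2) stop("provide at least 2 lags")
  rows <- list()
  for (lag in lag_list) {
    C <- count_transitions(labels, lag, trajectory)
    tm <- transition_matrix(C, lag_frames = lag)
    lam <- tm$eigenvalues
    lam <- lam[-1]                       # lambda_1 = 1 excluded
    lam <- lam[lam > 0 & lam < 1]
    ts <- -lag / log(lam)
    nk <- min(n_timescales, length(ts))
    if (nk == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      lag_frames = lag, timescale_index = seq_len(nk) + 1L,
      timescale_frames = ts[seq_len(nk)])
  }
  out <- do.call(rbind, rows)
  if (!is.null(dt_ns)) {
    out$lag_ns <- out$lag_frames * dt_ns
    out$timescale_ns <- out$timescale_frames * dt_ns
  }
  out
}

# PCCA+ inner-simplex vertex search (Weber/Deuflhard): pick the m rows
# of the eigenvector matrix that span the membership simplex.
pcca_vertices <- function(X) {
  m <- ncol(X)
  idx <- integer(m)
  idx[1] <- which.max(rowSums(X^2))
  ortho <- sweep(X, 2, X[idx[1], ])
  for (j in seq_len(m - 1)) {
    idx[j + 1] <- which.max(rowSums(ortho^2))
    v <- ortho[idx[j + 1], ]
    nv <- vec_norm(v)
    if (nv < 1e-12) break
    v <- v / nv
    ortho <- ortho - (ortho %*% v) %*% t(v)
  }
  idx
}

#' Coarse-grain micro-states into macro-states with PCCA+
#'
#' Spectral memberships are built from the leading `n_macro` right
#' eigenvectors of the reversible transition matrix (inner-simplex
#' vertex construction); crisp assignment takes the maximum membership,
#' ties broken towards the lower macro index. Macro-states are
#' renumbered by descending occupancy (stationary weight, or frame
#' counts when micro labels are supplied). Micro-states trimmed during
#' estimation map to `NA`.
#'
#' @param tm a [transition_matrix()] model.
#' @param n_macro requested number of macro-states.
#' @param microstates optional [cluster_microstates()] model (or
#'   integer frame labels) used to attach per-frame macro labels.
#' @param system optional per-frame system labels for occupancy.
#' @return Object of class `macrostate_model`: `micro_to_macro` (over
#'   the original micro-state indexing, `NA` for trimmed states),
#'   `membership` (micro x macro), `frame_labels`, `occupancy`
#'   (per-system fractions), `n_macro`.
#' @export
pcca_coarse_grain <- function(tm, n_macro, microstates = NULL,
                              system = NULL) {
  n <- nrow(tm$P)
  if (n_macro > n) stop("n_macro exceeds the number of micro-states")
  gap_support <- sum(tm$eigenvalues > 0.9 * tm$eigenvalues[2])
  if (n_macro > max(gap_support, 2))
    warning("requested n_macro exceeds the apparent spectral gap ",
            "support; computing anyway")
  if (n_macro == n) {
    chi <- diag(n)
    crisp <- seq_len(n)
  } else {
    X <- right_eigenvectors(tm, n_macro)
    vert <- pcca_vertices(X)
    A <- solve(X[vert, , drop = FALSE])
    chi <- X %*% A
    crisp <- max.col(chi, ties.method = "first")
  }
  # order macro-states by descending stationary mass for stable naming
  mass <- vapply(seq_len(n_macro), function(k) sum(tm$pi[crisp == k]),
                 numeric(1))
  remap <- integer(n_macro)
  remap[order(-mass)] <- seq_len(n_macro)
  crisp <- remap[crisp]
  chi <- chi[, order(-mass), drop = FALSE]

  n_total <- length(tm$kept_states) + length(tm$trimmed_states)
  micro_to_macro <- rep(NA_integer_, n_total)
  micro_to_macro[tm$kept_states] <- crisp

  frame_labels <- NULL
  occupancy <- NULL
  micro_labels <- if (inherits(microstates, "microstate_model"))
    microstates$labels else microstates
  if (!is.null(micro_labels)) {
    frame_labels <- micro_to_macro[micro_labels]
    if (!is.null(system)) occupancy <- macrostate_occupancy(frame_labels,
                                                           system, n_macro)
  }
  structure(list(micro_to_macro = micro_to_macro, membership = chi,
                 frame_labels = frame_labels, occupancy = occupancy,
                 n_macro = n_macro),
            class = "macrostate_model")
}

#' @export
print.macrostate_model <- function(x, ...) {
  cat("macrostate_model:", x$n_macro, "macro-states\n")
  invisible(x)
}

#' Per-system macro-state occupancy fractions
#'
#' @param macro_labels per-frame macro-state labels (NA allowed;
#'   excluded from the fractions).
#' @param system per-frame system labels.
#' @param n_macro number of macro-states.
#' @return matrix systems x macro-states; rows sum to 1.
#' @export
macrostate_occupancy <- function(macro_labels, system,
                                 n_macro = max(macro_labels,
                                               na.rm = TRUE)) {
  if (length(macro_labels) != length(system))
    stop("labels and system vector lengths differ")
  systems <- unique(system)
  occ <- t(vapply(systems, function(s) {
    l <- macro_labels[system == s & !is.na(macro_labels)]
    tabulate(l, nbins = n_macro) / length(l)
  }, numeric(n_macro)))
  rownames(occ) <- as.character(systems)
  colnames(occ) <- paste0("M", seq_len(n_macro))
  occ
}

#' Mean structure of a macro-state
#'
#' Member frames are superposed (CA atoms) onto the first member frame
#' and averaged.
#'
#' @param ensemble an [ensemble_set()].
#' @param macro_labels per-frame labels aligned with the ensemble's
#'   frames.
#' @param state macro-state id.
#' @return numeric 3N mean coordinate vector.
#' @export
macrostate_average_structure <- function(ensemble, macro_labels, state) {
  xyz <- all_xyz(ensemble)
  if (length(macro_labels) != nrow(xyz))
    stop("macro labels not aligned with the ensemble frames")
  members <- which(!is.na(macro_labels) & macro_labels == state)
  if (!length(members)) stop("macro-state ", state, " has no frames")
  sel <- atom2xyz_idx(which(ensemble$topology$atoms$elety == "CA"))
  sub <- xyz[members, , drop = FALSE]
  fitted <- bio3d::fit.xyz(fixed = sub[1, ], mobile = sub,
                           fixed.inds = sel, mobile.inds = sel)
  colMeans(fitted)
}
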