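# REDAN: perturbation-relative-entropy residue network. Per-pair CA
# distance distributions are estimated for the two systems on a shared
# histogram support, PRE = (D_KL(P||Q) + D_KL(Q||P)) / 2 is computed,
# pairs in persistent contact (maximum observed distance < 10 A) become
# edges weighted 1/PRE, and allosteric pathways are extracted as
# minimal-weight paths.

#' Regularized histogram density estimate
#'
#' Fixed-width histogram with a per-bin pseudocount, renormalized so
#' the density integrates to 1 over the support.
#'
#' @param samples numeric samples (a warning is issued below 50).
#' @param bin_width bin width in Angstrom (default 0.1).
#' @param support `c(lo, hi)`; default: sample range padded by one bin.
#' @param pseudocount per-bin count added before normalization;
#'   default `1 / length(samples)`.
#' @return list with `breaks`, `mids`, `density`, `bin_width`, `n`.
#' @export
estimate_density <- function(samples, bin_width = 0.1, support = NULL,
                             pseudocount = NULL) {
  if (length(samples) < 50)
    warning("density estimated from fewer than 50 samples")
  support <- support %||% (range(samples) + c(-bin_width, bin_width))
  if (diff(support) <= 0) stop("zero-width support")
  if (min(samples) < support[1] || max(samples) > support[2])
    stop("support does not cover the samples")
  pseudocount <- pseudocount %||% (1 / length(samples))
  nbins <- max(1L, ceiling(diff(support) / bin_width))
  breaks <- support[1] + bin_width * (0:nbins)
  counts <- tabulate(findInterval(samples, breaks, all.inside = TRUE),
                     nbins = nbins)
  w <- counts + pseudocount
  dens <- w / (sum(w) * bin_width)
  list(breaks = breaks, mids = breaks[-1] - bin_width / 2,
       density = dens, bin_width = bin_width, n = length(samples))
}

#' Perturbation relative entropy of two densities
#'
#' Symmetrized Kullback-Leibler divergence
#' `PRE = (D_KL(p||q) + D_KL(q||p)) / 2` evaluated as a discrete sum
#' over the shared histogram support, in nats.
#'
#' @param p,q density vectors on the same bins (strictly positive;
#'   estimate them with a pseudocount, see [estimate_density()]).
#' @param bin_width shared bin width.
#' @return Non-negative PRE in nats.
#' @export
pre_score <- function(p, q, bin_width) {
  if (length(p) != length(q))
    stop("densities must share one support")
  if (any(p <= 0) || any(q <= 0))
    stop("densities contain zero bins; re-estimate with a pseudocount")
  dkl_pq <- sum(p * log(p / q)) * bin_width
  dkl_qp <- sum(q * log(q / p)) * bin_width
  (dkl_pq + dkl_qp) / 2
}

# Shared-support densities and PRE for two samples.
pre_from_samples <- function(a, b, bin_width = 0.1, pseudocount = NULL) {
  support <- range(c(a, b)) + c(-bin_width, bin_width)
  pc <- pseudocount %||% (1 / max(length(a), length(b)))
  da <- suppressWarnings(estimate_density(a, bin_width, support, pc))
  db <- suppressWarnings(estimate_density(b, bin_width, support, pc))
  pre_score(da$density, db$density, bin_width)
}

#' Build the PRE residue network from two ensembles
#'
#' Nodes are residues (CA atoms). Two residues are joined by an edge
#' when the largest CA-CA distance observed over all analyzed frames of
#' both systems stays below `cutoff` (optionally a percentile of the
#' observed distances for robustness). Each edge carries the PRE of the
#' pair's distance distributions in the two systems and the weight
#' `1 / max(PRE, floor)`.
#'
#' @param ensemble_a,ensemble_b the reference (P) and perturbed (Q)
#'   [ensemble_set()]s, sharing residue numbering.
#' @param residues residue subset (default: all residues).
#' @param cutoff contact cutoff in Angstrom (default 10).
#' @param bin_width,pseudocount density estimation parameters.
#' @param contact_quantile quantile of the pooled per-pair distances
#'   used as the "longest possible distance" (default 1 = maximum).
#' @param pre_floor lower bound on PRE when forming weights.
#' @param stride frame stride for the analysis.
#' @return Object of class `pre_graph`: `edges` (data.frame `res_i`,
#'   `res_j`, `pre`, `weight`), `residues`, parameters.
#' @export
build_pre_graph <- function(ensemble_a, ensemble_b, residues = NULL,
                            cutoff = 10, bin_width = 0.1,
                            pseudocount = NULL, contact_quantile = 1,
                            pre_floor = 1e-6, stride = 1L) {
  residues <- residues %||% ensemble_a$topology$residues$resno
  grab <- function(ens) {
    ca <- ca_indices(ens$topology, residues)
    xyz <- all_xyz(ens)
    xyz <- xyz[seq(1, nrow(xyz), by = stride), atom2xyz_idx(ca),
               drop = FALSE]
    xyz
  }
  xa <- grab(ensemble_a)
  xb <- grab(ensemble_b)
  n <- length(residues)
  edges <- list()
  col3 <- function(x, i) x[, (3 * i - 2):(3 * i), drop = FALSE]
  for (i in seq_len(n - 1)) {
    ja <- col3(xa, i); jb <- col3(xb, i)
    for (j in (i + 1):n) {
      da <- sqrt(rowSums((ja - col3(xa, j))^2))
      db <- sqrt(rowSums((jb - col3(xb, j))^2))
      longest <- if (contact_quantile >= 1) max(da, db) else
        stats::quantile(c(da, db), contact_quantile, names = FALSE)
      if (longest >= cutoff) next
      pre <- pre_from_samples(da, db, bin_width, pseudocount)
      edges[[length(edges) + 1]] <- c(residues[i], residues[j], pre)
    }
  }
  if (length(edges)) {
    em <- do.call(rbind, edges)
    edges <- data.frame(res_i = as.integer(em[, 1]),
                        res_j = as.integer(em[, 2]), pre = em[, 3])
    edges$weight <- 1 / pmax(edges$pre, pre_floor)
  } else {
    edges <- data.frame(res_i = integer(), res_j = integer(),
                        pre = numeric(), weight = numeric())
  }
  structure(list(edges = edges, residues = residues, cutoff = cutoff,
                 bin_width = bin_width, pre_floor = pre_floor,
                 contact_quantile = contact_quantile),
            class = "pre_graph")
}

#' @export
print.pre_graph <- function(x, ...) {
  cat("pre_graph:", length(x$residues), "residues,", nrow(x$edges),
      "contact edges\n")
  invisible(x)
}

# Deterministic Dijkstra over an edge list; ties broken by fewer hops,
# then by lexicographic residue sequence.
dijkstra_path <- function(edges, nodes, source, target) {
  n <- length(nodes)
  id <- setNames(seq_len(n), as.character(nodes))
  s <- id[as.character(source)]; t <- id[as.character(target)]
  if (is.na(s) || is.na(t)) stop("source or target not in the graph")
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    a <- id[as.character(edges$res_i[e])]
    b <- id[as.character(edges$res_j[e])]
    w <- edges$weight[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  dist <- rep(Inf, n); hops <- rep(Inf, n)
  prev <- rep(NA_integer_, n); done <- rep(FALSE, n)
  dist[s] <- 0; hops[s] <- 0
  path_key <- function(v) {
    p <- integer(0)
    while (!is.na(v)) { p <- c(nodes[v], p); v <- prev[v] }
    paste(p, collapse = ",")
  }
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[order(dist[cand], hops[cand])][1]
    done[u] <- TRUE
    if (u == t) break
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1]; w <- nb[r, 2]
      nd <- dist[u] + w; nh <- hops[u] + 1
      better <- nd < dist[v] - 1e-15 ||
        (abs(nd - dist[v]) <= 1e-15 && nh < hops[v]) ||
        (abs(nd - dist[v]) <= 1e-15 && nh == hops[v] && !is.na(prev[v]) &&
           nodes[u] < nodes[prev[v]])
      if (better) { dist[v] <- nd; hops[v] <- nh; prev[v] <- u }
    }
  }
  if (!is.finite(dist[t])) return(NULL)
  p <- integer(0); v <- t
  while (!is.na(v)) { p <- c(v, p); v <- prev[v] }
  list(residues = nodes[p], total_weight = dist[t])
}

#' Extract minimal-weight allosteric pathway(s)
#'
#' Dijkstra's algorithm on the 1/PRE-weighted contact graph; the path
#' with the smallest total weight is the proposed allosteric route.
#' `k_paths > 1` returns additional loopless alternatives
#' (Yen-style, via igraph).
#'
#' @param graph a [build_pre_graph()] result.
#' @param source,target residue numbers.
#' @param k_paths number of pathways to return.
#' @return list of `allosteric_path` objects: `residues` (ordered
#'   source to target), `total_weight`, `edge_pre` (per step).
#' @export
shortest_allosteric_path <- function(graph, source, target,
                                     k_paths = 1) {
  edges <- graph$edges
  if (!nrow(edges)) stop("graph has no edges")
  nodes <- sort(unique(c(edges$res_i, edges$res_j)))
  if (!(source %in% nodes) || !(target %in% nodes))
    stop("source or target residue has no contact edges")
  ig <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$res_i),
               to = as.character(edges$res_j), weight = edges$weight),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes)))
  comp <- igraph::components(ig)
  if (comp$membership[as.character(source)] !=
      comp$membership[as.character(target)])
    stop("source and target lie in disconnected components of the ",
         "PRE graph")
  edge_lookup <- function(a, b) {
    hit <- (edges$res_i == a & edges$res_j == b) |
      (edges$res_i == b & edges$res_j == a)
    edges$pre[which(hit)[1]]
  }
  wrap <- function(res_seq) {
    res_seq <- as.integer(res_seq)
    pre <- vapply(seq_len(length(res_seq) - 1), function(k)
      edge_lookup(res_seq[k], res_seq[k + 1]), numeric(1))
    structure(list(residues = res_seq, total_weight = sum(1 / pmax(
      pre, graph$pre_floor)), edge_pre = pre),
      class = "allosteric_path")
  }
  if (k_paths == 1) {
    p <- dijkstra_path(edges, nodes, source, target)
    return(list(wrap(p$residues)))
  }
  ks <- igraph::k_shortest_paths(ig, from = as.character(source),
                                 to = as.character(target), k = k_paths)
  lapply(ks$vpaths, function(vp) wrap(names(vp)))
}

#' @export
print.allosteric_path <- function(x, ...) {
  cat("allosteric_path (", length(x$residues), " residues, weight ",
      signif(x$total_weight, 4), "):\n  ",
      paste(x$residues, collapse = " -> "), "\n", sep = "")
  invisible(x)
}
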