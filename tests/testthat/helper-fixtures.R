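# Shared fixtures: bead topologies, miniature ensembles, a backbone
# builder with prescribed dihedrals, and a brute-force shortest-path
# oracle.

bead_topology <- function(n, resno = seq_len(n)) {
  topology(data.frame(
    eleno = seq_len(n), elety = "CA", element = "C", resno = resno,
    resname = "ALA", chain = "A", stringsAsFactors = FALSE))
}

# ensemble from a list of n_atoms x 3 coordinate matrices (frames)
mini_ensemble <- function(frames, top = NULL, dt_ns = 1,
                          system = "toy") {
  if (is.matrix(frames)) frames <- list(frames)
  n <- nrow(frames[[1]])
  top <- top %||% bead_topology(n)
  xyz <- do.call(rbind, lapply(frames, function(f) as.numeric(t(f))))
  ensemble_set(system, top, list(xyz), dt_ns)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_rigid_transform <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  ct <- cos(th); st <- sin(th)
  R <- outer(ax, ax) * (1 - ct) + diag(3) * ct +
    matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0),
           3, 3) * st
  list(R = R, t = rnorm(3, sd = 5))
}

apply_rigid <- function(ensemble, per_frame = TRUE) {
  reps <- lapply(ensemble$replicas, function(m) {
    out <- m
    tr <- random_rigid_transform()
    for (f in seq_len(nrow(m))) {
      if (per_frame) tr <- random_rigid_transform()
      p <- matrix(m[f, ], ncol = 3, byrow = TRUE)
      out[f, ] <- as.numeric(t(p %*% t(tr$R) +
                                 matrix(tr$t, nrow(p), 3, byrow = TRUE)))
    }
    out
  })
  ensemble_set(ensemble$system, ensemble$topology, reps, ensemble$dt_ns)
}

# NeRF-style placement: position d such that |cd| = r, angle bcd =
# theta (deg) and dihedral abcd = phi (deg)
nerf_place <- function(a, b, c, r, theta, phi) {
  th <- theta * pi / 180
  ph <- pi - phi * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- c(bc[2] * (a - b)[3] - bc[3] * (a - b)[2],
         bc[3] * (a - b)[1] - bc[1] * (a - b)[3],
         bc[1] * (a - b)[2] - bc[2] * (a - b)[1])
  n <- -n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# backbone (N, CA, C per residue) with prescribed phi/psi, ideal
# geometry, omega = 180
build_backbone <- function(phi, psi) {
  nres <- length(phi)
  coords <- list()
  atoms <- list()
  # residue 1: fixed initial triad
  pN <- c(0, 0, 0); pCA <- c(1.46, 0, 0)
  pC <- pCA + 1.52 * c(cos(pi - 111 * pi / 180),
                       sin(pi - 111 * pi / 180), 0)
  add <- function(resno, elety, p) {
    atoms[[length(atoms) + 1]] <<- data.frame(
      elety = elety, element = substr(elety, 1, 1), resno = resno,
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1]] <<- p
  }
  add(1, "N", pN); add(1, "CA", pCA); add(1, "C", pC)
  prevN <- pN; prevCA <- pCA; prevC <- pC
  for (i in seq_len(nres - 1) + 1) {
    # psi of residue i-1 sets N_i; omega sets CA_i; phi of residue i
    # sets C_i
    pN <- nerf_place(prevN, prevCA, prevC, 1.33, 116, psi[i - 1])
    pCA <- nerf_place(prevCA, prevC, pN, 1.46, 122, 180)
    pC <- nerf_place(prevC, pN, pCA, 1.52, 111, phi[i])
    add(i, "N", pN); add(i, "CA", pCA); add(i, "C", pC)
    prevN <- pN; prevCA <- pCA; prevC <- pC
  }
  at <- do.call(rbind, atoms)
  at$eleno <- seq_len(nrow(at))
  at$resname <- "ALA"; at$chain <- "A"
  top <- topology(at)
  m <- do.call(rbind, coords)
  mini_ensemble(list(m), top = top)
}

# exhaustive minimal-weight simple path for small graphs
brute_force_path <- function(edges, source, target) {
  nodes <- sort(unique(c(edges$res_i, edges$res_j)))
  wfun <- function(a, b) {
    hit <- (edges$res_i == a & edges$res_j == b) |
      (edges$res_i == b & edges$res_j == a)
    if (any(hit)) min(edges$weight[hit]) else NA_real_
  }
  best <- list(weight = Inf, path = NULL)
  recurse <- function(path, w) {
    last <- path[length(path)]
    if (last == target) {
      if (w < best$weight) best <<- list(weight = w, path = path)
      return(invisible())
    }
    for (v in nodes[!(nodes %in% path)]) {
      ew <- wfun(last, v)
      if (!is.na(ew)) recurse(c(path, v), w + ew)
    }
  }
  recurse(source, 0)
  best
}

# small synthetic spec for fast tests
quick_spec <- function(...) {
  do.call(synthetic_spec,
          utils::modifyList(list(n_frames = 600, replicas = 2,
                                 seed = 42), list(...)))
}
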