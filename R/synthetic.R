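# Synthetic two-system ensemble generator with planted ground truth.
#
# The model protein is a bead-per-residue four-domain fold: three ideal
# alpha helices (CCD, DBD, SH2) and one extended strand (LD) arranged as
# a bundle. Hidden metastable states evolve by a Markov chain; each
# state displaces a mobile sub-domain, tilts a helix, and sets
# hydrogen-bond formation probabilities. System B additionally carries
# an alternating mean displacement along a planted path of strand
# residues, so the perturbation relative entropy is elevated exactly on
# consecutive path pairs. A set of rigid inter-domain residue pairs
# receives strongly reduced positional noise.

#' Ideal helix CA coordinates
#'
#' Builds a regular helix (default: alpha-helix geometry, 1.5 A rise,
#' 100 degree twist, 2.3 A radius) whose geometric axis points along
#' `axis`.
#'
#' @param n_res number of residues (>= 4).
#' @param rise_per_res axial rise per residue, Angstrom.
#' @param twist_per_res rotation per residue, degrees.
#' @param radius helix radius, Angstrom.
#' @param axis axis direction (any non-zero 3-vector; normalized).
#' @param phase_deg phase of the first residue, degrees.
#' @return n_res x 3 matrix of CA coordinates (axis through the origin).
#' @export
build_ideal_helix <- function(n_res, rise_per_res = 1.5,
                              twist_per_res = 100, radius = 2.3,
                              axis = c(0, 0, 1), phase_deg = 0) {
  if (n_res < 4) stop("a helix needs at least 4 residues")
  if (vec_norm(axis) == 0) stop("`axis` must be a non-zero vector")
  j <- seq_len(n_res) - 1
  ang <- (phase_deg + twist_per_res * j) * pi / 180
  m <- cbind(radius * cos(ang), radius * sin(ang), rise_per_res * j)
  R <- rotation_between(c(0, 0, 1), axis)
  m %*% t(R)
}

# Base CA geometry: helices/strand laid out on the corners of a square
# of side `bundle_sep`; chain direction alternates up/down so domain
# boundaries stay spatially close.
build_base_structure <- function(n_residues, bundle_sep = 8) {
  if (n_residues < 16) stop("need at least 16 residues (4 per domain)")
  sizes <- rep(n_residues %/% 4, 4)
  sizes[seq_len(n_residues %% 4)] <- sizes[seq_len(n_residues %% 4)] + 1
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  offsets <- rbind(c(0, 0), c(bundle_sep, 0),
                   c(bundle_sep, bundle_sep), c(0, bundle_sep))
  up <- c(TRUE, FALSE, TRUE, FALSE)
  is_strand <- c(FALSE, FALSE, TRUE, FALSE)  # LD is an extended strand
  coords <- matrix(0, n_residues, 3)
  helix_height <- function(n) (n - 1) * 1.5
  for (k in 1:4) {
    idx <- starts[k]:ends[k]
    n <- length(idx)
    if (is_strand[k]) {
      z <- (seq_len(n) - 1) * 3.8
      seg <- cbind(0, 0, z)
    } else {
      seg <- build_ideal_helix(n)
    }
    if (!up[k]) seg[, 3] <- max(seg[, 3]) - seg[, 3]
    seg[, 1] <- seg[, 1] + offsets[k, 1]
    seg[, 2] <- seg[, 2] + offsets[k, 2]
    coords[idx, ] <- seg
  }
  dmap <- domain_map(list(CCD = starts[1]:ends[1], DBD = starts[2]:ends[2],
                          LD = starts[3]:ends[3], SH2 = starts[4]:ends[4]))
  list(coords = coords, domain_map = dmap, strand_dir = c(0, 0, 1))
}

#' Specification for a synthetic two-system benchmark ensemble
#'
#' Defines the study conditions for the validation ensembles: hidden
#' Markov kinetics over `n_states` metastable states, per-state mean
#' structures, planted rigid inter-domain pairs, a planted allosteric
#' path (system B only), per-state hydrogen-bond probabilities and a
#' state-dependent helix tilt. All randomness downstream flows from
#' `seed`.
#'
#' @param n_residues chain length (>= 16; split into 4 domains).
#' @param n_states number of metastable states K (>= 2).
#' @param trans_mat K x K row-stochastic transition matrix applied per
#'   frame; default: 0.97 self-transition, remainder spread uniformly.
#' @param replicas,n_frames replicas per system and frames per replica.
#' @param dt_ns frame interval, ns.
#' @param sigma isotropic positional noise per residue, Angstrom.
#' @param sigma_rigid noise for residues in planted rigid pairs.
#' @param bundle_sep distance between neighbouring domain axes, Angstrom.
#' @param state_shift x-displacement of the mobile sub-domain per state
#'   index, Angstrom (state k shifts by (k-1)*state_shift).
#' @param mobile_residues residues displaced per state (default: the
#'   C-terminal 60 percent of SH2).
#' @param tilt_residues helix segment tilted per state (default: the
#'   N-terminal half of CCD).
#' @param tilt_deg per-state tilt angles, degrees (length K).
#' @param n_rigid_seeds number of closest CCD-DBD pairs used to seed the
#'   planted rigid interface.
#' @param path_residues ordered planted path (default: interior of the
#'   LD strand).
#' @param path_delta mean shift of consecutive path pair distances
#'   between systems A and B, Angstrom.
#' @param hbond_triplets data.frame with columns `donor`, `acceptor`
#'   (residue numbers) or NULL for defaults.
#' @param hbond_probs bonds x K matrix of per-state formation
#'   probabilities, or NULL for defaults.
#' @param allow_absorbing permit reducible transition matrices.
#' @param seed integer RNG seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_residues = 120, n_states = 3,
                           trans_mat = NULL, replicas = 3,
                           n_frames = 5000, dt_ns = 1, sigma = 0.4,
                           sigma_rigid = 0.04, bundle_sep = 8,
                           state_shift = 3.5, mobile_residues = NULL,
                           tilt_residues = NULL, tilt_deg = NULL,
                           n_rigid_seeds = 12, path_residues = NULL,
                           path_delta = 2, hbond_triplets = NULL,
                           hbond_probs = NULL, allow_absorbing = FALSE,
                           seed = 1) {
  K <- as.integer(n_states)
  if (K < 2) stop("n_states must be >= 2")
  stopifnot_scalar_number(sigma, "sigma")
  if (sigma < 0) stop("`sigma` must be >= 0")
  if (is.null(trans_mat)) {
    trans_mat <- matrix(0.03 / (K - 1), K, K)
    diag(trans_mat) <- 0.97
  }
  trans_mat <- as.matrix(trans_mat)
  if (nrow(trans_mat) != K || ncol(trans_mat) != K)
    stop("trans_mat must be K x K")
  if (any(abs(rowSums(trans_mat) - 1) > 1e-12))
    stop("rows of trans_mat must sum to 1 (tolerance 1e-12)")
  if (any(trans_mat < 0)) stop("trans_mat entries must be >= 0")
  if (!allow_absorbing) {
    g <- igraph::graph_from_adjacency_matrix(trans_mat > 0, mode = "directed")
    if (igraph::components(g, mode = "strong")$no > 1)
      stop("trans_mat is not irreducible (absorbing/disconnected chain); ",
           "set allow_absorbing = TRUE to permit this")
  }

  base <- build_base_structure(n_residues, bundle_sep)
  dmap <- base$domain_map
  dom <- dmap$domains

  mobile_residues <- mobile_residues %||% {
    sh2 <- dom$SH2
    tail(sh2, max(4, round(length(sh2) * 0.6)))
  }
  tilt_residues <- tilt_residues %||% {
    ccd <- dom$CCD
    head(ccd, max(4, length(ccd) %/% 2))
  }
  tilt_deg <- tilt_deg %||% (6 * (seq_len(K) - 1))
  if (length(tilt_deg) != K) stop("tilt_deg must have one angle per state")
  path_residues <- path_residues %||% {
    ld <- dom$LD
    if (length(ld) < 8) stop("LD domain too short for a default path")
    ld[3:(length(ld) - 2)]
  }

  # rigid interface: closest static CCD-DBD pairs in the base geometry
  cand_a <- setdiff(dom$CCD, union(tilt_residues, path_residues))
  cand_b <- setdiff(dom$DBD, path_residues)
  dmat <- as.matrix(dist(base$coords))
  sub <- dmat[cand_a, cand_b, drop = FALSE]
  ord <- order(sub)[seq_len(min(n_rigid_seeds, length(sub)))]
  seed_pairs <- cbind(cand_a[(ord - 1) %% nrow(sub) + 1],
                      cand_b[(ord - 1) %/% nrow(sub) + 1])
  rigid_residues <- sort(unique(as.integer(seed_pairs)))
  ra <- intersect(rigid_residues, cand_a)
  rb <- intersect(rigid_residues, cand_b)
  # ground truth uses the same 10 A contact range as pair selection
  rp <- expand.grid(res_i = ra, res_j = rb)
  rp <- rp[dmat[cbind(rp$res_i, rp$res_j)] < 10, , drop = FALSE]
  rigid_pairs <- rp[order(rp$res_i, rp$res_j), , drop = FALSE]
  rownames(rigid_pairs) <- NULL

  overlap <- intersect(path_residues,
                       c(rigid_residues, mobile_residues, tilt_residues))
  if (length(overlap))
    stop("path residues overlap other planted sets: ",
         paste(overlap, collapse = ", "))

  # default H-bond triplets live on static helix faces (i, i+4 contacts)
  if (is.null(hbond_triplets)) {
    sh2_static <- setdiff(dom$SH2, mobile_residues)
    dbd_static <- setdiff(dom$DBD, rigid_residues)
    donors <- c(if (length(sh2_static) >= 2) sh2_static[2],
                if (length(sh2_static) >= 4) sh2_static[4],
                if (length(dbd_static) >= 7)
                  dbd_static[length(dbd_static) - 6])
    donors <- donors[donors + 4 <= n_residues]
    if (!length(donors))
      stop("no room for default hbond triplets; supply hbond_triplets")
    # i/i+4 helix contacts on static faces
    hbond_triplets <- data.frame(donor = donors, acceptor = donors + 4)
  }
  hbond_triplets <- as.data.frame(hbond_triplets)
  if (is.null(hbond_probs)) {
    hbond_probs <- rbind(rep(0.9, K),
                         c(rep(0.85, K - 1), 0.15),
                         c(0.15, rep(0.8, K - 1)))
    hbond_probs <- hbond_probs[seq_len(nrow(hbond_triplets)), , drop = FALSE]
  }
  hbond_probs <- as.matrix(hbond_probs)
  if (nrow(hbond_probs) != nrow(hbond_triplets) || ncol(hbond_probs) != K)
    stop("hbond_probs must be (number of triplets) x K")
  if (any(hbond_probs < 0 | hbond_probs > 1))
    stop("hbond_probs must lie in [0, 1]")

  # per-state mean CA structures, system A
  means_A <- vector("list", K)
  tilt_center <- colMeans(base$coords[tilt_residues, , drop = FALSE])
  for (k in seq_len(K)) {
    m <- base$coords
    if (tilt_deg[k] != 0) {
      R <- rotation_axis_angle(c(1, 0, 0), tilt_deg[k] * pi / 180)
      seg <- m[tilt_residues, , drop = FALSE]
      m[tilt_residues, ] <- sweep(sweep(seg, 2, tilt_center) %*% t(R),
                                  2, tilt_center, `+`)
    }
    m[mobile_residues, 1] <- m[mobile_residues, 1] + (k - 1) * state_shift
    means_A[[k]] <- m
  }
  # system B: alternating displacement of path residues along the strand
  disp <- (path_delta / 2) * base$strand_dir
  sgn <- rep_len(c(1, -1), length(path_residues))
  means_B <- lapply(means_A, function(m) {
    m[path_residues, ] <- m[path_residues, ] +
      outer(sgn, c(1, 1, 1)) * matrix(disp, length(path_residues), 3,
                                      byrow = TRUE)
    m
  })

  # invariant: consecutive path residues within 10 A in every state mean
  for (mm in c(means_A, means_B)) {
    p <- mm[path_residues, , drop = FALSE]
    gaps <- sqrt(rowSums((p[-1, , drop = FALSE] -
                            p[-nrow(p), , drop = FALSE])^2))
    if (any(gaps >= 10))
      stop("consecutive path residues exceed 10 A in a state mean ",
           "(max gap ", round(max(gaps), 2), " A)")
  }
  # H-bond donor-acceptor CA separation must admit both geometries
  for (mm in c(means_A, means_B)) {
    da <- sqrt(rowSums((mm[hbond_triplets$donor, , drop = FALSE] -
                          mm[hbond_triplets$acceptor, , drop = FALSE])^2))
    if (any(da <= 5))
      stop("hbond donor/acceptor residues too close (need > 5 A CA-CA)")
  }

  sigma_res <- rep(sigma, n_residues)
  sigma_res[rigid_residues] <- min(sigma_rigid, sigma)

  structure(list(
    n_residues = n_residues, n_states = K, trans_mat = trans_mat,
    replicas = replicas, n_frames = n_frames, dt_ns = dt_ns,
    sigma = sigma, sigma_res = sigma_res, domain_map = dmap,
    base_coords = base$coords, means_A = means_A, means_B = means_B,
    mobile_residues = mobile_residues, state_shift = state_shift,
    tilt_residues = tilt_residues, tilt_deg = tilt_deg,
    rigid_residues = rigid_residues, rigid_pairs = rigid_pairs,
    path_residues = path_residues, path_delta = path_delta,
    hbond_triplets = hbond_triplets, hbond_probs = hbond_probs,
    seed = as.integer(seed)), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("synthetic_spec:", x$n_residues, "residues,", x$n_states,
      "states,", x$replicas, "replicas x", x$n_frames, "frames\n")
  invisible(x)
}

# stationary distribution of a row-stochastic matrix
stationary_distribution <- function(T_) {
  e <- eigen(t(T_))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

sample_markov_chain <- function(T_, n, pi0 = NULL) {
  K <- nrow(T_)
  pi0 <- pi0 %||% stationary_distribution(T_)
  cum0 <- cumsum(pi0)
  cumT <- t(apply(T_, 1, cumsum))
  s <- integer(n)
  u <- runif(n)
  s[1] <- findInterval(u[1], cum0, left.open = TRUE) + 1L
  for (t in 2:n)
    s[t] <- findInterval(u[t], cumT[s[t - 1], ], left.open = TRUE) + 1L
  s
}

# Topology for the synthetic bead model: CA per residue, plus explicit
# donor N / hydrogen / acceptor O pseudo-atoms for the planted bonds.
synthetic_topology <- function(spec) {
  n <- spec$n_residues
  donors <- spec$hbond_triplets$donor
  acceptors <- spec$hbond_triplets$acceptor
  rows <- list()
  for (r in seq_len(n)) {
    rows[[length(rows) + 1]] <- data.frame(
      elety = "CA", element = "C", resno = r, stringsAsFactors = FALSE)
    if (r %in% donors) {
      rows[[length(rows) + 1]] <- data.frame(
        elety = c("ND", "HD"), element = c("N", "H"), resno = r,
        stringsAsFactors = FALSE)
    }
    if (r %in% acceptors) {
      rows[[length(rows) + 1]] <- data.frame(
        elety = "OA", element = "O", resno = r, stringsAsFactors = FALSE)
    }
  }
  at <- do.call(rbind, rows)
  at$eleno <- seq_len(nrow(at))
  at$resname <- "ALA"
  at$chain <- "A"
  at$hpar <- NA_integer_
  hyd <- which(at$elety == "HD")
  for (h in hyd) at$hpar[h] <- which(at$elety == "ND" & at$resno == at$resno[h])
  topology(at)
}

#' Impose or remove an ideal hydrogen-bond geometry in one frame
#'
#' Places the hydrogen on the donor-acceptor axis so that, when
#' `present`, the H...acceptor distance is 1.9 A with a 180 degree
#' donor-H...acceptor angle; when absent, the H...acceptor distance is
#' set to 4.5 A (outside any standard geometric criterion).
#'
#' @param frame_coords numeric 3N coordinate vector (x1,y1,z1,...).
#' @param triplet integer vector `c(donor, hydrogen, acceptor)` of atom
#'   indices.
#' @param present logical flag.
#' @return Modified coordinate vector.
#' @export
plant_hbond_geometry <- function(frame_coords, triplet, present) {
  d <- frame_coords[atom2xyz_idx(triplet[1])]
  a <- frame_coords[atom2xyz_idx(triplet[3])]
  u <- unit_vec(d - a)
  len <- if (isTRUE(present)) 1.9 else 4.5
  frame_coords[atom2xyz_idx(triplet[2])] <- a + len * u
  frame_coords
}

#' Generate the two synthetic ensembles and their ground truth
#'
#' Frames are drawn as state mean plus isotropic Gaussian noise, with
#' the hidden state evolving by the planted transition matrix once per
#' frame; replicas start from independent draws of the stationary
#' distribution. System B carries the planted path displacement. All
#' randomness flows from `spec$seed`; equal specs give identical output.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `A` and `B` ([ensemble_set()]s) and
#'   `truth` (hidden states, planted rigid pairs/path/H-bond
#'   probabilities, per-frame bond presence, state means).
#' @export
generate_ensembles <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("`spec` must be a synthetic_spec")
  set.seed(spec$seed)
  top <- synthetic_topology(spec)
  n_res <- spec$n_residues
  nb <- nrow(spec$hbond_triplets)
  # column index maps from residue CA coordinates to the atom table
  ca_idx <- ca_indices(top)
  atoms <- top$atoms
  d_idx <- vapply(spec$hbond_triplets$donor,
                  function(r) atom_index(top, r, "ND"), integer(1))
  h_idx <- vapply(spec$hbond_triplets$donor,
                  function(r) atom_index(top, r, "HD"), integer(1))
  a_idx <- vapply(spec$hbond_triplets$acceptor,
                  function(r) atom_index(top, r, "OA"), integer(1))

  sig3 <- rep(spec$sigma_res, each = 3)
  make_system <- function(means) {
    mean_mat <- do.call(rbind, lapply(means, mat_to_xyz))  # K x 3n
    reps <- vector("list", spec$replicas)
    states <- vector("list", spec$replicas)
    presence <- vector("list", spec$replicas)
    for (r in seq_len(spec$replicas)) {
      s <- sample_markov_chain(spec$trans_mat, spec$n_frames)
      noise <- matrix(rnorm(spec$n_frames * 3L * n_res), spec$n_frames) *
        matrix(sig3, spec$n_frames, 3L * n_res, byrow = TRUE)
      ca_xyz <- mean_mat[s, , drop = FALSE] + noise
      xyz <- matrix(0, spec$n_frames, 3L * top$n_atoms)
      # CA, donor-N and acceptor-O atoms sit on the residue bead
      for (j in seq_len(top$n_atoms)) {
        if (atoms$elety[j] == "HD") next
        res <- atoms$resno[j]
        xyz[, atom2xyz_idx(j)] <- ca_xyz[, atom2xyz_idx(res)]
      }
      pres <- matrix(FALSE, spec$n_frames, nb)
      for (b in seq_len(nb)) {
        p <- spec$hbond_probs[b, s]
        pres[, b] <- runif(spec$n_frames) < p
        dmat <- xyz[, atom2xyz_idx(d_idx[b]), drop = FALSE]
        amat <- xyz[, atom2xyz_idx(a_idx[b]), drop = FALSE]
        dv <- dmat - amat
        dn <- sqrt(rowSums(dv^2))
        len <- ifelse(pres[, b], 1.9, 4.5)
        xyz[, atom2xyz_idx(h_idx[b])] <- amat + dv / dn * len
      }
      reps[[r]] <- xyz
      states[[r]] <- s
      presence[[r]] <- pres
    }
    list(reps = reps, states = states, presence = presence)
  }

  sysA <- make_system(spec$means_A)
  sysB <- make_system(spec$means_B)
  ens_A <- ensemble_set("system_A", top, sysA$reps, spec$dt_ns)
  ens_B <- ensemble_set("system_B", top, sysB$reps, spec$dt_ns)
  truth <- list(
    states = list(A = sysA$states, B = sysB$states),
    presence = list(A = sysA$presence, B = sysB$presence),
    trans_mat = spec$trans_mat,
    stationary = stationary_distribution(spec$trans_mat),
    rigid_pairs = spec$rigid_pairs, rigid_residues = spec$rigid_residues,
    path_residues = spec$path_residues, path_delta = spec$path_delta,
    hbond_triplets = spec$hbond_triplets, hbond_probs = spec$hbond_probs,
    tilt_residues = spec$tilt_residues, tilt_deg = spec$tilt_deg,
    mobile_residues = spec$mobile_residues,
    state_means_A = spec$means_A, state_means_B = spec$means_B,
    domain_map = spec$domain_map,
    hbond_atom_idx = cbind(donor = d_idx, hydrogen = h_idx,
                           acceptor = a_idx))
  list(A = ens_A, B = ens_B, truth = truth)
}
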