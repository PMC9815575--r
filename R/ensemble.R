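#' Multi-replica trajectory ensemble for one system
#'
#' Coordinates are stored in Angstrom, bio3d xyz convention: each
#' replica is a frames x (3 * n_atoms) matrix with columns ordered
#' x1, y1, z1, x2, ... Frames are assumed evenly spaced.
#'
#' @param system system label, e.g. `"wild_type"` or `"D170A"`.
#' @param topology a [topology()] shared by all replicas.
#' @param replicas list of frames x (3 * n_atoms) coordinate matrices.
#' @param dt_ns frame interval in nanoseconds (> 0).
#' @return Object of class `ensemble_set`.
#' @export
ensemble_set <- function(system, topology, replicas, dt_ns) {
  stopifnot_scalar_number(dt_ns, "dt_ns", positive = TRUE)
  if (!inherits(topology, "topology")) stop("`topology` must be a topology")
  if (!length(replicas)) stop("at least one replica is required")
  nc <- 3L * topology$n_atoms
  for (i in seq_along(replicas)) {
    m <- replicas[[i]]
    if (!is.matrix(m) || ncol(m) != nc)
      stop("replica ", i, ": expected ", nc, " coordinate columns, got ",
           if (is.matrix(m)) ncol(m) else "a non-matrix")
    if (!all(is.finite(m)))
      stop("replica ", i, " contains non-finite coordinates")
  }
  structure(list(system = system, topology = topology,
                 replicas = replicas, dt_ns = dt_ns),
            class = "ensemble_set")
}

#' @export
print.ensemble_set <- function(x, ...) {
  nf <- vapply(x$replicas, nrow, integer(1))
  cat("ensemble_set '", x$system, "': ", length(nf), " replica(s), ",
      sum(nf), " frames (", x$dt_ns, " ns/frame, ",
      sum(nf) * x$dt_ns, " ns total)\n", sep = "")
  invisible(x)
}

#' Total number of frames across replicas
#' @param ensemble an [ensemble_set()].
#' @return Integer frame count.
#' @export
n_frames <- function(ensemble) {
  sum(vapply(ensemble$replicas, nrow, integer(1)))
}

#' Per-frame provenance (system, replica, frame index)
#' @param ensemble an [ensemble_set()].
#' @return data.frame with columns `system`, `replica`, `frame`.
#' @export
frame_info <- function(ensemble) {
  nf <- vapply(ensemble$replicas, nrow, integer(1))
  data.frame(system = ensemble$system,
             replica = rep(seq_along(nf), nf),
             frame = unlist(lapply(nf, seq_len), use.names = FALSE))
}

# Stack all replicas into one frames x 3N matrix (replica order kept).
all_xyz <- function(ensemble) do.call(rbind, ensemble$replicas)

#' Load an ensemble from trajectory files
#'
#' Supported formats: CHARMM/NAMD DCD (`.dcd`, read with bio3d) and
#' multi-model PDB (`.pdb`). Coordinates are converted to Angstrom on
#' load; trajectories written in nanometres are rescaled with
#' `unit = "nm"`.
#'
#' @param topology a [topology()].
#' @param trajectory_paths character vector, one file per replica.
#' @param frame_interval_ns time between stored frames, ns.
#' @param stride keep every `stride`-th frame; the frame interval is
#'   rescaled accordingly.
#' @param unit `"angstrom"` (default) or `"nm"`.
#' @param system system label.
#' @return An [ensemble_set()].
#' @export
load_ensemble <- function(topology, trajectory_paths, frame_interval_ns,
                          stride = 1L, unit = c("angstrom", "nm"),
                          system = "system") {
  unit <- match.arg(unit)
  stride <- as.integer(stride)
  if (stride < 1) stop("`stride` must be >= 1")
  scale <- if (unit == "nm") 10 else 1
  nc <- 3L * topology$n_atoms
  replicas <- lapply(trajectory_paths, function(p) {
    ext <- tolower(tools::file_ext(p))
    m <- switch(ext,
      dcd = unclass(bio3d::read.dcd(p, verbose = FALSE)),
      pdb = {
        pdb <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
        unclass(pdb$xyz)
      },
      stop("unsupported trajectory format: .", ext,
           " (supported: .dcd, .pdb multi-model)"))
    m <- as.matrix(m)
    if (ncol(m) != nc)
      stop("atom-count mismatch in ", p, ": trajectory has ", ncol(m) / 3,
           " atoms, topology has ", topology$n_atoms)
    m <- m[seq(1, nrow(m), by = stride), , drop = FALSE] * scale
    dimnames(m) <- NULL
    m
  })
  ensemble_set(system, topology, replicas, frame_interval_ns * stride)
}

#' Discard the leading equilibration segment of every replica
#'
#' Drops `floor(discard_ns / dt_ns)` leading frames from each replica
#' and records the total retained simulation time.
#'
#' @param ensemble an [ensemble_set()].
#' @param discard_ns equilibration time to discard (>= 0).
#' @return The trimmed [ensemble_set()]; `retained_time_ns()` reports
#'   the per-replica and total retained time.
#' @export
discard_equilibration <- function(ensemble, discard_ns) {
  stopifnot_scalar_number(discard_ns, "discard_ns")
  if (discard_ns < 0) stop("`discard_ns` must be >= 0")
  n_drop <- floor(discard_ns / ensemble$dt_ns)
  replicas <- lapply(seq_along(ensemble$replicas), function(i) {
    m <- ensemble$replicas[[i]]
    if (n_drop >= nrow(m))
      stop("discard_ns (", discard_ns, " ns) >= length of replica ", i,
           " (", nrow(m) * ensemble$dt_ns, " ns)")
    m[(n_drop + 1):nrow(m), , drop = FALSE]
  })
  out <- ensemble_set(ensemble$system, ensemble$topology, replicas,
                      ensemble$dt_ns)
  out
}

#' Retained simulation time of an ensemble
#' @param ensemble an [ensemble_set()].
#' @return list with `per_replica_ns` and `total_ns`.
#' @export
retained_time_ns <- function(ensemble) {
  per <- vapply(ensemble$replicas, nrow, integer(1)) * ensemble$dt_ns
  list(per_replica_ns = per, total_ns = sum(per))
}

#' Write an ensemble as a PDB topology plus one DCD per replica
#'
#' The PDB carries the topology with first-frame coordinates; each
#' replica is written as a CHARMM-format DCD (Angstrom, float32).
#'
#' @param ensemble an [ensemble_set()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default: the system label).
#' @return list with `pdb` path and `trajectories` paths.
#' @export
write_ensemble <- function(ensemble, dir, prefix = NULL) {
  prefix <- prefix %||% ensemble$system
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  top <- ensemble$topology
  pdb_path <- file.path(dir, paste0(prefix, ".pdb"))
  bio3d::write.pdb(file = pdb_path, xyz = ensemble$replicas[[1]][1, ],
                   resno = top$atoms$resno, resid = top$atoms$resname,
                   eleno = top$atoms$eleno, elety = top$atoms$elety,
                   chain = top$atoms$chain, elesy = top$atoms$element)
  traj <- vapply(seq_along(ensemble$replicas), function(i) {
    p <- file.path(dir, sprintf("%s_rep%02d.dcd", prefix, i))
    write_dcd(ensemble$replicas[[i]], p)
    p
  }, character(1))
  list(pdb = pdb_path, trajectories = traj)
}

#' Write a coordinate matrix as a CHARMM-format DCD file
#'
#' Minimal single-precision writer (no unit cell); round-trips through
#' DCD readers to float32 precision (~1e-6 A relative).
#'
#' @param xyz frames x (3 * n_atoms) matrix in Angstrom.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(xyz, path) {
  if (!is.matrix(xyz) || ncol(xyz) %% 3 != 0)
    stop("`xyz` must be a frames x 3N matrix")
  nf <- nrow(xyz)
  natom <- ncol(xyz) %/% 3L
  con <- file(path, "wb")
  on.exit(close(con))
  wrec <- function(writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
    writer()
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[10] <- readBin(writeBin(1.0, raw(), size = 4, endian = "little"),
                        "integer", size = 4, endian = "little")
  icntrl[20] <- 24L
  wrec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl, con, size = 4, endian = "little")
  }, 84)
  title <- formatC("written by allopath", width = -80)
  wrec(function() {
    writeBin(1L, con, size = 4, endian = "little")
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84)
  wrec(function() writeBin(as.integer(natom), con, size = 4,
                           endian = "little"), 4)
  xi <- seq(1, 3 * natom, by = 3)
  for (f in seq_len(nf)) {
    fr <- xyz[f, ]
    for (d in 0:2)
      local({
        v <- fr[xi + d]
        wrec(function() writeBin(as.numeric(v), con, size = 4,
                                 endian = "little"), 4 * natom)
      })
  }
  invisible(path)
}
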