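# Small geometry and bookkeeping helpers shared across modules.

# Standard atomic masses (amu) for the elements that occur in protein
# topologies; anything else falls back to bio3d's lookup.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971
)

element_mass <- function(element) {
  el <- toupper(trimws(element))
  m <- .element_masses[el]
  miss <- is.na(m)
  if (any(miss)) {
    m[miss] <- vapply(el[miss], function(e) {
      out <- tryCatch(bio3d::atom2mass(e), error = function(err) NA_real_)
      out
    }, numeric(1))
  }
  if (anyNA(m)) {
    stop("cannot assign a mass to element(s): ",
         paste(unique(el[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' @noRd
vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stop("zero-length vector cannot be normalized")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation matrix taking unit vector `from` onto unit vector `to`
# (Rodrigues). Degenerate antiparallel case handled via an arbitrary
# perpendicular axis.
rotation_between <- function(from, to) {
  f <- unit_vec(from); t <- unit_vec(to)
  v <- cross3(f, t)
  c_ <- sum(f * t)
  if (vec_norm(v) < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to f
    p <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- unit_vec(cross3(f, p))
    return(rotation_axis_angle(axis, pi))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * (1 / (1 + c_))
}

rotation_axis_angle <- function(axis, theta) {
  a <- unit_vec(axis)
  ct <- cos(theta); st <- sin(theta)
  outer(a, a) * (1 - ct) + diag(3) * ct +
    matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3) * st
}

# Dihedral angle (degrees, in (-180, 180]) defined by four points given
# as rows of a 4 x 3 matrix.
dihedral_angle <- function(p) {
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit_vec(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Angle (degrees) at vertex b of the triangle a-b-c.
vertex_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (vec_norm(u) * vec_norm(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# xyz frame helpers: frames are stored bio3d-style as rows of length
# 3*n_atoms ordered x1,y1,z1,x2,...
xyz_to_mat <- function(frame) matrix(frame, ncol = 3, byrow = TRUE)
mat_to_xyz <- function(m) as.numeric(t(m))
atom2xyz_idx <- function(atom_idx) {
  as.integer(rbind(3 * atom_idx - 2, 3 * atom_idx - 1, 3 * atom_idx))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop("`", name, "` must be a single finite number")
  if (positive && x <= 0) stop("`", name, "` must be > 0")
  invisible(x)
}
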