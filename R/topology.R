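#' Topology of a bead- or atom-resolution protein model
#'
#' A `topology` records atoms (name, element, mass, parent residue) and
#' residues (author 1-based numbering, name, chain). Hydrogens may carry
#' an explicit covalent parent (`hpar`, the row index of their bonded
#' heavy atom), which hydrogen-bond detection requires.
#'
#' @param atoms data.frame with columns `eleno` (unique atom serial),
#'   `elety` (atom name, e.g. "CA"), `element`, `resno` (residue
#'   number), `resname`, `chain`, and optional `hpar` (integer row index
#'   of the bonded heavy atom, `NA` for non-hydrogens). A `mass` column
#'   is filled from `element` when absent.
#' @return Object of class `topology`.
#' @export
topology <- function(atoms) {
  req <- c("eleno", "elety", "element", "resno", "resname", "chain")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atoms table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$eleno))
    stop("topology format error: duplicate atom serial numbers (eleno)")
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (is.null(atoms$hpar)) atoms$hpar <- NA_integer_
  # residue indices must be strictly increasing within each chain
  for (ch in unique(atoms$chain)) {
    r <- atoms$resno[atoms$chain == ch]
    if (any(diff(rle(r)$values) <= 0))
      stop("residue indices not strictly increasing within chain ", ch)
  }
  res <- unique(atoms[, c("resno", "resname", "chain")])
  top <- structure(
    list(atoms = atoms, residues = res,
         n_atoms = nrow(atoms), n_residues = nrow(res)),
    class = "topology")
  top
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", x$n_atoms, "atoms,", x$n_residues, "residues\n")
  invisible(x)
}

#' Read a topology from a PDB file
#'
#' Masses are assigned from the element column (falling back to the
#' atom-name convention when the element field is blank); CA atoms are
#' identified per residue. Hydrogen covalent parents are inferred from
#' the PDB coordinates (nearest heavy atom within 1.25 A).
#'
#' @param pdb_path path to a PDB file.
#' @return A [topology()].
#' @export
load_topology <- function(pdb_path) {
  pdb <- bio3d::read.pdb(pdb_path, verbose = FALSE)
  at <- pdb$atom
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(!nzchar(trimws(el))))
    el <- bio3d::atom2ele(at$elety)
  el <- ifelse(is.na(el) | !nzchar(trimws(el)),
               bio3d::atom2ele(at$elety), trimws(el))
  atoms <- data.frame(
    eleno = at$eleno, elety = trimws(at$elety), element = toupper(el),
    resno = at$resno, resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain),
    stringsAsFactors = FALSE)
  atoms$mass <- element_mass(atoms$element)
  # infer hydrogen parents from geometry of the deposited coordinates
  atoms$hpar <- NA_integer_
  hyd <- which(atoms$element == "H")
  if (length(hyd)) {
    heavy <- which(atoms$element != "H")
    xyz <- cbind(at$x, at$y, at$z)
    for (h in hyd) {
      d2 <- rowSums((xyz[heavy, , drop = FALSE] -
                       matrix(xyz[h, ], length(heavy), 3, byrow = TRUE))^2)
      j <- which.min(d2)
      if (d2[j] <= 1.25^2) atoms$hpar[h] <- heavy[j]
    }
  }
  top <- topology(atoms)
  attr(top, "pdb_xyz") <- as.numeric(pdb$xyz[1, ])
  top
}

#' Indices of CA atoms for a residue set
#'
#' @param top a [topology()].
#' @param residues residue numbers (default: all residues).
#' @return Integer vector of atom indices, one per residue.
#' @export
ca_indices <- function(top, residues = NULL) {
  residues <- residues %||% top$residues$resno
  missing_res <- setdiff(residues, top$residues$resno)
  if (length(missing_res))
    stop("unknown residue(s): ", paste(missing_res, collapse = ", "))
  idx <- vapply(residues, function(r) {
    i <- which(top$atoms$resno == r & top$atoms$elety == "CA")
    if (length(i) == 0)
      stop("residue ", r, " has no CA atom")
    if (length(i) > 1)
      stop("residue ", r, " has more than one CA atom")
    i
  }, integer(1))
  idx
}

atom_index <- function(top, resno, elety) {
  i <- which(top$atoms$resno == resno & top$atoms$elety == elety)
  if (length(i) != 1)
    stop("atom ", elety, " of residue ", resno,
         if (length(i) == 0) " not found" else " is not unique")
  i
}

#' Named residue ranges for domains and secondary-structure elements
#'
#' @param domains named list of integer residue vectors (e.g. NTD, CCD,
#'   DBD, LD, SH2, TAD). Ranges must not overlap.
#' @param elements named list of secondary-structure elements (helices,
#'   sheets) as residue vectors; each must cover >= 3 residues. Elements
#'   must not overlap each other (they may lie inside domains).
#' @return Object of class `domain_map`.
#' @export
domain_map <- function(domains, elements = list()) {
  check_cat <- function(lst, what, min_len = 1) {
    if (length(lst) && is.null(names(lst)))
      stop(what, " must be a named list")
    all_res <- unlist(lst, use.names = FALSE)
    if (anyDuplicated(all_res))
      stop("overlapping residue ranges within ", what)
    for (nm in names(lst)) {
      if (length(lst[[nm]]) < min_len)
        stop(what, " '", nm, "' resolves to fewer than ", min_len,
             " residues")
    }
  }
  check_cat(domains, "domains", 1)
  check_cat(elements, "elements", 3)
  structure(list(domains = lapply(domains, as.integer),
                 elements = lapply(elements, as.integer)),
            class = "domain_map")
}

#' @export
print.domain_map <- function(x, ...) {
  cat("domain_map:", length(x$domains), "domains,",
      length(x$elements), "elements\n")
  invisible(x)
}

domain_residues <- function(dmap, name) {
  r <- dmap$domains[[name]] %||% dmap$elements[[name]]
  if (is.null(r)) stop("unknown domain or element: ", name)
  r
}
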