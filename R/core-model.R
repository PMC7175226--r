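# ---------------------------------------------------------------------------
# Monomer dictionary: the 20 standard amino acids, their one-letter codes,
# aromaticity, and the ring atoms used for local reference frames.
# TRP uses its 6-membered benzene ring; HIS its 5-membered imidazole.
# Ring atom names are listed in order around the ring.
# ---------------------------------------------------------------------------

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
          "I", "L", "K", "M", "F", "P", "S", "T", "W",
          "Y", "V")

.ring_atoms <- list(
  PHE = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
  TYR = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
  TRP = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"),
  HIS = c("CG", "ND1", "CE1", "NE2", "CD2")
)

#' Look up monomer information for a 3-letter residue code
#'
#' Returns the standard amino-acid dictionary entry: one-letter code,
#' aromaticity flag and, for aromatic residues (PHE, TYR, TRP, HIS), the
#' ordered names of the side-chain ring atoms used to build local reference
#' frames. Unknown codes map to one-letter `"X"` with no ring.
#'
#' @param code3 A 3-letter residue code (e.g. `"ALA"`).
#' @return A list with elements `code3`, `code1`, `is_aromatic`,
#'   `ring_atom_names`.
#' @examples
#' monomer_info("TRP")$is_aromatic
#' monomer_info("XYZ")$code1
#' @export
monomer_info <- function(code3) {
  code3 <- toupper(trimws(code3))
  i <- match(code3, .aa3)
  list(
    code3 = code3,
    code1 = if (is.na(i)) "X" else .aa1[i],
    is_aromatic = code3 %in% names(.ring_atoms),
    ring_atom_names = if (code3 %in% names(.ring_atoms))
      .ring_atoms[[code3]] else character(0)
  )
}

#' Convert a 3-letter residue code to its 1-letter code
#'
#' Standard IUPAC mapping for the 20 amino acids; anything unknown becomes
#' `"X"`. Vectorized.
#'
#' @param code3 Character vector of 3-letter codes.
#' @return Character vector of 1-letter codes.
#' @examples
#' three_to_one(c("ALA", "TRP", "XYZ"))
#' @export
three_to_one <- function(code3) {
  i <- match(toupper(trimws(code3)), .aa3)
  out <- .aa1[i]
  out[is.na(i)] <- "X"
  out
}

# ---------------------------------------------------------------------------
# Structure: a flat, ordered atom table plus identity. The Chain/Residue
# hierarchy is materialized on demand from the table; the table itself
# preserves file order, which makes round-tripping and filtering exact.
# ---------------------------------------------------------------------------

.atom_cols <- c("serial", "name", "alt_loc", "res_name", "chain_id",
                "res_seq", "i_code", "x", "y", "z", "occupancy",
                "b_factor", "element", "is_hetero")

#' Create a Structure from an atom table
#'
#' The atom table is the package's flat representation of one model: one row
#' per atom, in file order. `name` holds the 4-character PDB-aligned atom
#' name (e.g. `" CA "`); `element` is the stripped element symbol.
#'
#' @param atoms data.frame with columns `serial`, `name`, `alt_loc`,
#'   `res_name`, `chain_id`, `res_seq`, `i_code`, `x`, `y`, `z`,
#'   `occupancy`, `b_factor`, `element`, `is_hetero`.
#' @param id Label for the structure (file stem or code).
#' @param model_no Model number (>= 1).
#' @return An object of class `Structure`.
#' @export
new_structure <- function(atoms, id = "structure", model_no = 1L) {
  missing_cols <- setdiff(.atom_cols, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms <- atoms[, .atom_cols]
  rownames(atoms) <- NULL
  if (nrow(atoms) && !all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("atom coordinates must be finite")
  structure(
    list(id = id, model_no = as.integer(model_no), atoms = atoms),
    class = "Structure"
  )
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("<Structure %s> model %d: %d chain(s), %d residue(s), %d atom(s)\n",
              x$id, x$model_no, n_chains(x), n_residues(x), n_atoms(x)))
  invisible(x)
}

#' Number of atoms / residues / chains in a Structure
#' @param structure A `Structure`.
#' @return Integer count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' @rdname n_atoms
#' @export
n_residues <- function(structure) {
  length(unique(residue_keys(structure$atoms)))
}

#' @rdname n_atoms
#' @export
n_chains <- function(structure) length(unique(structure$atoms$chain_id))

# Residue identity key: (chain_id, res_seq, i_code) -- file numbering is
# authoritative. residue_index() provides the zero-free internal index used
# for array alignment (1-based, order of first appearance).
residue_keys <- function(atoms) {
  paste(atoms$chain_id, atoms$res_seq, atoms$i_code, sep = "\r")
}

#' Internal residue index for each atom
#'
#' Residues are numbered 1..n in order of first appearance in the file;
#' this is the index used by contact maps and trace arrays, independent of
#' the (possibly negative, gapped) author numbering.
#'
#' @param structure A `Structure`.
#' @return Integer vector, one entry per atom row.
#' @export
residue_index <- function(structure) {
  k <- residue_keys(structure$atoms)
  match(k, unique(k))
}

#' Materialize the Chain/Residue hierarchy of a Structure
#'
#' Returns the ordered list of chains; each chain is a list with `chain_id`
#' and `residues`, each residue a list with `res_name`, `res_seq`, `i_code`
#' and its atom-table rows (input order preserved).
#'
#' @param structure A `Structure`.
#' @return List of `Chain` objects.
#' @export
chains <- function(structure) {
  at <- structure$atoms
  ids <- unique(at$chain_id)
  lapply(ids, function(cid) {
    sub <- at[at$chain_id == cid, , drop = FALSE]
    keys <- residue_keys(sub)
    ukeys <- unique(keys)
    res <- lapply(ukeys, function(k) {
      r <- sub[keys == k, , drop = FALSE]
      rownames(r) <- NULL
      structure(list(res_name = r$res_name[1L], res_seq = r$res_seq[1L],
                     i_code = r$i_code[1L], atoms = r), class = "Residue")
    })
    structure(list(chain_id = cid, residues = res), class = "Chain")
  })
}

#' Iterate over all atoms of a Structure in file order
#'
#' @param structure A `Structure`.
#' @return The atom table (one row per atom, file order), carrying every
#'   chain/residue/atom field.
#' @export
iter_atoms <- function(structure) structure$atoms

# A row is a C-alpha iff the stripped name is "CA" and the element is carbon
# or blank -- this excludes calcium ions (element "CA").
is_ca_row <- function(atoms) {
  trimws(atoms$name) == "CA" & atoms$element %in% c("C", "")
}

#' Extract the C-alpha trace of a Structure
#'
#' One point per residue possessing a C-alpha atom, residue order preserved;
#' residues lacking a CA are skipped. An atom counts as C-alpha only if its
#' name strips to `"CA"` and its element is carbon (or blank), so calcium
#' ions never enter the trace.
#'
#' @param structure A `Structure`.
#' @return Numeric matrix with one row per CA (columns x, y, z).
#' @export
ca_trace <- function(structure) {
  at <- structure$atoms
  sel <- is_ca_row(at)
  if (!any(sel)) return(matrix(numeric(0), ncol = 3,
                               dimnames = list(NULL, c("x", "y", "z"))))
  sub <- at[sel, , drop = FALSE]
  # one CA per residue: keep first occurrence
  keys <- residue_keys(sub)
  sub <- sub[!duplicated(keys), , drop = FALSE]
  m <- as.matrix(sub[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
}

#' Apply a rigid-body transform to a Structure
#'
#' @param structure A `Structure`.
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric(3) translation, Angstrom.
#' @return The transformed `Structure`.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  new <- xyz %*% t(rotation) + rep(translation, each = nrow(xyz))
  structure$atoms$x <- new[, 1L]
  structure$atoms$y <- new[, 2L]
  structure$atoms$z <- new[, 3L]
  structure
}

# Pad a stripped atom name into the 4-character PDB field: single-letter
# elements start in column 14, two-letter elements in column 13.
pad_atom_name <- function(name, element) {
  name <- trimws(name)
  element <- trimws(element)
  mapply(function(nm, el) {
    if (nchar(nm) >= 4L) return(substr(nm, 1L, 4L))
    if (nchar(el) == 2L || nchar(nm) == 4L) sprintf("%-4s", nm)
    else sprintf(" %-3s", nm)
  }, name, element, USE.NAMES = FALSE)
}
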