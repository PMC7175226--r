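# Backbone torsions and Ramachandran classification.

#' Signed torsion angle of four points
#'
#' IUPAC sign convention via atan2 of the cross products of the bond-plane
#' normals; the cis arrangement is 0 degrees, trans is 180. The result lies
#' in (-180, 180].
#'
#' @param a,b,c,d Numeric(3) coordinates of four consecutive points.
#' @return Angle in degrees in (-180, 180].
#' @examples
#' dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))  # cis: 0
#' dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)) # trans: 180
#' @export
dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  if (v_norm(b2) == 0) stop("zero-length central bond in dihedral")
  n1 <- v_cross(b1, b2)
  n2 <- v_cross(b2, b3)
  if (v_norm(n1) == 0 || v_norm(n2) == 0)
    stop("collinear points: dihedral undefined")
  ang <- atan2(v_dot(v_cross(n1, n2), v_unit(b2)), v_dot(n1, n2)) * 180 / pi
  # map to (-180, 180]
  if (ang <= -180) ang <- ang + 360
  ang
}

ram_class <- function(res_name, next_res_name) {
  if (res_name == "GLY") "Glycine"
  else if (res_name == "PRO") "Proline"
  else if (!is.na(next_res_name) && next_res_name == "PRO") "Pre-Proline"
  else "General"
}

#' Backbone phi/psi angles and Ramachandran class per residue
#'
#' For each polymer residue i of each chain:
#' `phi_i = dihedral(C_{i-1}, N_i, CA_i, C_i)` and
#' `psi_i = dihedral(N_i, CA_i, C_i, N_{i+1})`. Phi is undefined (NA) for
#' chain-initial residues and psi for chain-final ones. Classes: GLY is
#' `Glycine`, PRO is `Proline`; otherwise a residue immediately preceding a
#' PRO is `Pre-Proline`, else `General` (identity outranks context). A
#' residue missing a backbone atom yields NA angles with a warning, not an
#' error.
#'
#' @param structure A `Structure` (all chains are processed).
#' @return data.frame with columns `chain_id`, `res_seq`, `i_code`,
#'   `res_name`, `phi`, `psi`, `klass`.
#' @export
phi_psi <- function(structure) {
  at <- structure$atoms
  recs <- list()
  backbone_xyz <- function(res_atoms, nm) {
    sel <- trimws(res_atoms$name) == nm &
      res_atoms$element %in% c(substr(nm, 1L, 1L), "")
    if (!any(sel)) return(NULL)
    as.numeric(res_atoms[which(sel)[1L], c("x", "y", "z")])
  }
  for (cid in unique(at$chain_id)) {
    sub <- at[at$chain_id == cid, , drop = FALSE]
    keys <- residue_keys(sub)
    ukeys <- unique(keys)
    res_name <- sub$res_name[match(ukeys, keys)]
    res_seq <- sub$res_seq[match(ukeys, keys)]
    i_code <- sub$i_code[match(ukeys, keys)]
    has_ca <- vapply(ukeys, function(k)
      any(is_ca_row(sub[keys == k, , drop = FALSE])), logical(1))
    poly <- which(is_polymer_residue(res_name, has_ca))
    if (!length(poly)) next
    bb <- lapply(poly, function(i) {
      ra <- sub[keys == ukeys[i], , drop = FALSE]
      list(N = backbone_xyz(ra, "N"), CA = backbone_xyz(ra, "CA"),
           C = backbone_xyz(ra, "C"))
    })
    n <- length(poly)
    phi <- psi <- rep(NA_real_, n)
    for (j in seq_len(n)) {
      ok <- !is.null(bb[[j]]$N) && !is.null(bb[[j]]$CA) && !is.null(bb[[j]]$C)
      if (!ok) {
        warning("residue ", res_name[poly[j]], " ", res_seq[poly[j]],
                " in chain '", cid, "' lacks backbone atoms; ",
                "angles undefined")
        next
      }
      if (j > 1L && !is.null(bb[[j - 1L]]$C))
        phi[j] <- dihedral(bb[[j - 1L]]$C, bb[[j]]$N, bb[[j]]$CA, bb[[j]]$C)
      if (j < n && !is.null(bb[[j + 1L]]$N))
        psi[j] <- dihedral(bb[[j]]$N, bb[[j]]$CA, bb[[j]]$C, bb[[j + 1L]]$N)
    }
    klass <- vapply(seq_len(n), function(j)
      ram_class(res_name[poly[j]],
                if (j < n) res_name[poly[j + 1L]] else NA_character_), "")
    recs[[length(recs) + 1L]] <- data.frame(
      chain_id = cid, res_seq = res_seq[poly], i_code = i_code[poly],
      res_name = res_name[poly], phi = phi, psi = psi, klass = klass,
      stringsAsFactors = FALSE)
  }
  if (!length(recs))
    return(data.frame(chain_id = character(0), res_seq = integer(0),
                      i_code = character(0), res_name = character(0),
                      phi = numeric(0), psi = numeric(0),
                      klass = character(0)))
  do.call(rbind, recs)
}

#' Write Ramachandran records as TSV
#'
#' @param records data.frame from [phi_psi()].
#' @param path Output path, or `""` for stdout; `NULL` returns the lines
#'   without writing.
#' @return The formatted lines, invisibly.
#' @export
write_ramachandran_tsv <- function(records, path = "") {
  header <- "#chain\tres_seq\tres_name\tphi\tpsi\tclass"
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t%s", records$chain_id,
                  records$res_seq, records$res_name,
                  ifelse(is.na(records$phi), "NA",
                         sprintf("%.3f", records$phi)),
                  ifelse(is.na(records$psi), "NA",
                         sprintf("%.3f", records$psi)),
                  records$klass)
  lines <- c(header, body)
  if (is.null(path)) return(lines)
  if (nzchar(path)) writeLines(lines, path) else writeLines(lines)
  invisible(lines)
}
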