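# Aromatic ring local reference frames and stacking descriptors.

ring_atom_coords <- function(res_atoms, res_name) {
  info <- monomer_info(res_name)
  if (!info$is_aromatic)
    stop("residue ", res_name, " is not aromatic (PHE, TYR, TRP, HIS)")
  nm <- trimws(res_atoms$name)
  idx <- match(info$ring_atom_names, nm)
  if (anyNA(idx))
    stop("residue ", res_name, " is missing ring atom(s): ",
         paste(info$ring_atom_names[is.na(idx)], collapse = ", "))
  as.matrix(res_atoms[idx, c("x", "y", "z")])
}

ring_frame_from_coords <- function(ring) {
  dimnames(ring) <- NULL
  centroid <- colMeans(ring)
  centered <- sweep(ring, 2L, centroid)
  # least-squares plane normal: singular vector of the smallest singular value
  sv <- svd(centered)
  z <- sv$v[, 3L]
  # deterministic sign: right-handed w.r.t. the ring atom ordering
  ref <- v_cross(centered[1L, ], centered[2L, ])
  if (v_dot(z, ref) < 0) z <- -z
  x <- centered[1L, ] - v_dot(centered[1L, ], z) * z
  x <- v_unit(x)
  y <- v_cross(z, x)
  list(origin = as.numeric(centroid), x_axis = x, y_axis = y, z_axis = z)
}

#' Local reference frame of an aromatic side-chain ring
#'
#' Builds a right-handed orthonormal frame from the ring atoms of an
#' aromatic residue (PHE/TYR use the benzene ring; TRP its 6-membered
#' ring; HIS the imidazole). The origin is the ring-atom centroid; the z
#' axis is the unit normal of the least-squares plane with its sign fixed
#' right-handed with respect to the ring atom ordering; x is the in-plane
#' unit projection of (first ring atom - centroid); y completes the frame.
#'
#' @param residue A `Residue` (from [chains()]) of an aromatic amino acid
#'   with all ring atoms present.
#' @return A `RingFrame`: list with `origin`, `x_axis`, `y_axis`, `z_axis`,
#'   `res_name`, `res_seq`, `chain_id`.
#' @export
ring_frame <- function(residue) {
  ring <- ring_atom_coords(residue$atoms, residue$res_name)
  fr <- ring_frame_from_coords(ring)
  fr$res_name <- residue$res_name
  fr$res_seq <- residue$res_seq
  fr$chain_id <- residue$atoms$chain_id[1L]
  structure(fr, class = "RingFrame")
}

aromatic_frames <- function(structure) {
  frames <- list()
  for (ch in chains(structure)) {
    for (res in ch$residues) {
      if (!monomer_info(res$res_name)$is_aromatic) next
      fr <- tryCatch(ring_frame(res), error = function(e) NULL)
      if (!is.null(fr)) frames[[length(frames) + 1L]] <- fr
    }
  }
  frames
}

#' Aromatic stacking descriptors of a structure
#'
#' For every unordered pair of aromatic residues whose ring centroids are
#' closer than `cutoff`: `centroid_distance` (Angstrom); `plane_angle`
#' `= acos(|z_a . z_b|)` in degrees, in [0, 90] and invariant to flipping
#' either normal; `lateral_offset`, the norm of the component of the
#' centroid displacement perpendicular to the first ring's normal.
#' Aromatic residues with incomplete rings are skipped.
#'
#' @param structure A `Structure`.
#' @param cutoff Centroid distance cutoff, Angstrom (> 0); default 6.5.
#' @return data.frame with one row per stacked pair: `chain_a`, `res_a`,
#'   `name_a`, `chain_b`, `res_b`, `name_b`, `centroid_distance`,
#'   `plane_angle`, `lateral_offset`.
#' @export
stacking_pairs <- function(structure, cutoff = 6.5) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  frames <- aromatic_frames(structure)
  rows <- list()
  if (length(frames) >= 2L) {
    for (i in seq_len(length(frames) - 1L)) {
      for (j in seq.int(i + 1L, length(frames))) {
        a <- frames[[i]]
        b <- frames[[j]]
        dvec <- b$origin - a$origin
        d <- v_norm(dvec)
        if (d >= cutoff) next
        cosang <- min(1, abs(v_dot(a$z_axis, b$z_axis)))
        perp <- dvec - v_dot(dvec, a$z_axis) * a$z_axis
        rows[[length(rows) + 1L]] <- data.frame(
          chain_a = a$chain_id, res_a = a$res_seq, name_a = a$res_name,
          chain_b = b$chain_id, res_b = b$res_seq, name_b = b$res_name,
          centroid_distance = d,
          plane_angle = acos(cosang) * 180 / pi,
          lateral_offset = v_norm(perp),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(chain_a = character(0), res_a = integer(0),
                      name_a = character(0), chain_b = character(0),
                      res_b = integer(0), name_b = character(0),
                      centroid_distance = numeric(0),
                      plane_angle = numeric(0),
                      lateral_offset = numeric(0)))
  do.call(rbind, rows)
}

#' Write stacking descriptors as TSV
#'
#' @param pairs data.frame from [stacking_pairs()].
#' @param path Output path, or `""` for stdout; `NULL` returns the lines
#'   without writing.
#' @return Formatted lines, invisibly.
#' @export
write_stacking_tsv <- function(pairs, path = "") {
  header <- "#chain_a\tres_a\tname_a\tchain_b\tres_b\tname_b\tdistance\tplane_angle\toffset"
  body <- sprintf("%s\t%d\t%s\t%s\t%d\t%s\t%.4f\t%.4f\t%.4f",
                  pairs$chain_a, pairs$res_a, pairs$name_a,
                  pairs$chain_b, pairs$res_b, pairs$name_b,
                  pairs$centroid_distance, pairs$plane_angle,
                  pairs$lateral_offset)
  lines <- c(header, body)
  if (is.null(path)) return(lines)
  if (nzchar(path)) writeLines(lines, path) else writeLines(lines)
  invisible(lines)
}
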