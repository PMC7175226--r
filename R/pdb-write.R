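# Fixed-column PDB writing. Coordinates are formatted %8.3f, so re-reading
# reproduces any value representable at three decimals exactly.

format_atom_lines <- function(atoms) {
  if (any(abs(c(atoms$x, atoms$y, atoms$z)) >= 10000))
    stop("coordinate magnitude >= 10000 Angstrom cannot be formatted ",
         "in the fixed 8.3 field")
  rec <- ifelse(atoms$is_hetero, "HETATM", "ATOM  ")
  sprintf("%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec,
          atoms$serial %% 100000L,  # serial overflow wraps
          substr(sprintf("%-4s", atoms$name), 1L, 4L),
          substr(paste0(atoms$alt_loc, " "), 1L, 1L),
          substr(sprintf("%-3s", atoms$res_name), 1L, 3L),
          substr(paste0(atoms$chain_id, " "), 1L, 1L),
          atoms$res_seq,
          substr(paste0(atoms$i_code, " "), 1L, 1L),
          atoms$x, atoms$y, atoms$z, atoms$occupancy, atoms$b_factor,
          sprintf("%2s", atoms$element))
}

structure_lines <- function(s) {
  at <- s$atoms
  out <- character(0)
  for (cid in unique(at$chain_id)) {
    sub <- at[at$chain_id == cid, , drop = FALSE]
    out <- c(out, format_atom_lines(sub))
    # TER after the polymer part of each chain
    last <- sub[nrow(sub), , drop = FALSE]
    out <- c(out, sprintf("TER   %5d      %-3s %1s%4d%1s",
                          (last$serial + 1L) %% 100000L,
                          substr(sprintf("%-3s", last$res_name), 1L, 3L),
                          substr(paste0(last$chain_id, " "), 1L, 1L),
                          last$res_seq,
                          substr(paste0(last$i_code, " "), 1L, 1L)))
  }
  out
}

#' Write one or more Structures to a PDB file
#'
#' A single structure is written as a plain coordinate file; several are
#' wrapped in MODEL/ENDMDL blocks. Coordinates are formatted `%8.3f`;
#' magnitudes of 10000 Angstrom or more are a formatting error.
#'
#' @param structures A `Structure` or a non-empty list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structures, path) {
  if (inherits(structures, "Structure")) structures <- list(structures)
  if (!length(structures)) stop("empty structure list")
  lines <- character(0)
  if (length(structures) == 1L) {
    lines <- structure_lines(structures[[1L]])
  } else {
    for (i in seq_along(structures)) {
      lines <- c(lines, sprintf("MODEL     %4d", i),
                 structure_lines(structures[[i]]), "ENDMDL")
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
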