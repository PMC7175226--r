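# Fixed-column PDB reading (wwPDB v3.3). Lines shorter than 80 columns are
# right-padded before extraction. The reader applies LineFilters to raw
# ATOM/HETATM text so rejected records are never materialized, and uses a
# coordinate-swap fast path for multi-model files with chemically identical
# models.

# --------------------------------------------------------------------------
# Line filters: pure predicates over raw 80-column lines, vectorized over a
# character vector. Composable with AND / OR / NOT.
# --------------------------------------------------------------------------

#' Line filters for the PDB reader
#'
#' A line filter is a pure, vectorized predicate `character -> logical`
#' applied to raw ATOM/HETATM lines before parsing, so excluded records are
#' never materialized. Filters compose with [filter_and()], [filter_or()]
#' and [filter_not()].
#'
#' `is_ca_filter()` accepts only `ATOM` lines whose atom-name field (columns
#' 13-16) strips to `"CA"` and whose element field (columns 77-78) is not
#' calcium — so `HETATM` calcium ions are rejected even though their name
#' also strips to `"CA"`.
#'
#' @return A function of class `LineFilter`.
#' @examples
#' f <- is_ca_filter()
#' f("ATOM      2  CA  ALA A   1      12.000   6.000  -6.000  1.00  0.00           C")
#' @export
is_ca_filter <- function() {
  new_line_filter(function(lines) {
    startsWith(lines, "ATOM  ") &
      trimws(substr(lines, 13L, 16L)) == "CA" &
      toupper(trimws(substr(lines, 77L, 78L))) != "CA"
  })
}

#' @rdname is_ca_filter
#' @param predicate Vectorized function from raw lines to logical.
#' @export
new_line_filter <- function(predicate) {
  stopifnot(is.function(predicate))
  structure(predicate, class = c("LineFilter", "function"))
}

#' @rdname is_ca_filter
#' @param f,g Line filters.
#' @export
filter_and <- function(f, g) {
  force(f); force(g)  # rebinding f <- filter_and(f, g) must not self-capture
  new_line_filter(function(lines) f(lines) & g(lines))
}

#' @rdname is_ca_filter
#' @export
filter_or <- function(f, g) {
  force(f); force(g)
  new_line_filter(function(lines) f(lines) | g(lines))
}

#' @rdname is_ca_filter
#' @export
filter_not <- function(f) {
  force(f)
  new_line_filter(function(lines) !f(lines))
}

# Combine a list of filters conjunctively; NULL/empty -> accept everything.
combine_filters <- function(filters) {
  if (is.null(filters)) return(NULL)
  if (inherits(filters, "LineFilter")) return(filters)
  if (!length(filters)) return(NULL)
  Reduce(filter_and, filters)
}

# --------------------------------------------------------------------------
# Fixed-column parsing
# --------------------------------------------------------------------------

pad80 <- function(lines) {
  n <- nchar(lines)
  short <- n < 80L
  if (any(short))
    lines[short] <- sprintf("%-80s", lines[short])
  lines
}

# Strict fixed-width numeric parse: blank allowed only where a default is
# given; anything else non-numeric is an error naming the column span and
# line number.
parse_fixed_num <- function(txt, from, to, line_no, default = NA_real_) {
  s <- trimws(txt)
  out <- suppressWarnings(as.numeric(s))
  blank <- s == ""
  out[blank] <- default
  bad <- is.na(out) & !blank | (blank & is.na(default))
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("malformed numeric field in columns %d-%d on line %d: '%s'",
                 from, to, line_no[i], txt[i]), call. = FALSE)
  }
  out
}

parse_fixed_int <- function(txt, from, to, line_no) {
  as.integer(parse_fixed_num(txt, from, to, line_no))
}

#' Parse ATOM/HETATM lines into an atom table
#'
#' Extracts the wwPDB v3.3 fixed columns: serial 7-11, name 13-16, altLoc
#' 17, resName 18-20, chainID 22, resSeq 23-26, iCode 27, x/y/z 31-54,
#' occupancy 55-60, B-factor 61-66, element 77-78 (1-based inclusive).
#' Blank occupancy parses as 1.00, blank B-factor as 0.00. Malformed
#' numeric fields raise an error naming the column span and line number.
#'
#' @param lines Character vector of raw ATOM/HETATM lines.
#' @param line_no Optional original line numbers (for error messages).
#' @return data.frame in the atom-table layout of [new_structure()].
#' @export
parse_atom_lines <- function(lines, line_no = seq_along(lines)) {
  lines <- pad80(lines)
  rec <- substr(lines, 1L, 6L)
  ok <- rec %in% c("ATOM  ", "HETATM")
  if (!all(ok))
    stop("line ", line_no[which(!ok)[1L]], " is not an ATOM/HETATM record")
  data.frame(
    serial = parse_fixed_int(substr(lines, 7L, 11L), 7L, 11L, line_no),
    name = substr(lines, 13L, 16L),
    alt_loc = substr(lines, 17L, 17L),
    res_name = trimws(substr(lines, 18L, 20L)),
    chain_id = substr(lines, 22L, 22L),
    res_seq = parse_fixed_int(substr(lines, 23L, 26L), 23L, 26L, line_no),
    i_code = substr(lines, 27L, 27L),
    x = parse_fixed_num(substr(lines, 31L, 38L), 31L, 38L, line_no),
    y = parse_fixed_num(substr(lines, 39L, 46L), 39L, 46L, line_no),
    z = parse_fixed_num(substr(lines, 47L, 54L), 47L, 54L, line_no),
    occupancy = parse_fixed_num(substr(lines, 55L, 60L), 55L, 60L, line_no,
                                default = 1),
    b_factor = parse_fixed_num(substr(lines, 61L, 66L), 61L, 66L, line_no,
                               default = 0),
    element = toupper(trimws(substr(lines, 77L, 78L))),
    is_hetero = rec == "HETATM",
    stringsAsFactors = FALSE
  )
}

# Drop all but the first-encountered alt-loc per (residue, atom name).
drop_alt_locs <- function(atoms) {
  key <- paste(atoms$chain_id, atoms$res_seq, atoms$i_code,
               trimws(atoms$name), sep = "\r")
  atoms[!duplicated(key), , drop = FALSE]
}

read_pdb_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Read a PDB file into one Structure per model
#'
#' One `Structure` is returned per MODEL block (exactly one when the file
#' has no MODEL records). When all models are chemically identical —
#' same atom count and the same sequence of (name, resName, chainID)
#' tuples as model 1 — models after the first reuse model 1's topology and
#' differ only in coordinates, occupancy and B-factor (the fast path). A
#' model violating identity triggers a full per-model parse with a warning.
#'
#' @param path PDB file; `.gz` input is accepted by extension.
#' @param filters A `LineFilter`, a list of them (combined with AND), or
#'   `NULL` for no filtering.
#' @param keep_hetero Keep HETATM records (default `TRUE`).
#' @param keep_alt_locs Keep all alternate locations; default `FALSE` keeps
#'   only the first-encountered alt-loc per (residue, atom name).
#' @param id Structure label; defaults to the file stem.
#' @return List of `Structure` objects, one per model.
#' @export
read_structures <- function(path, filters = NULL, keep_hetero = TRUE,
                            keep_alt_locs = FALSE, id = NULL) {
  if (is.null(id))
    id <- sub("\\.gz$", "", basename(path))
  id <- sub("\\.(pdb|ent)$", "", id)
  lines <- read_pdb_lines(path)
  filt <- combine_filters(filters)

  rec <- substr(pad80(lines), 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!keep_hetero) is_atom <- is_atom & rec != "HETATM"
  if (!is.null(filt)) {
    keep <- is_atom
    keep[is_atom] <- filt(pad80(lines[is_atom]))
    is_atom <- keep
  }
  if (!any(is_atom))
    stop("no atoms selected from '", path,
         "' (empty selection after filtering)")

  # model bounds: atoms between MODEL/ENDMDL; no MODEL records -> one model
  model_starts <- which(startsWith(lines, "MODEL"))
  atom_idx <- which(is_atom)
  if (length(model_starts) == 0L) {
    groups <- list(atom_idx)
    model_nos <- 1L
  } else {
    model_nos <- suppressWarnings(
      as.integer(trimws(substr(lines[model_starts], 7L, 80L))))
    if (anyNA(model_nos)) model_nos <- seq_along(model_starts)
    bins <- findInterval(atom_idx, model_starts)
    if (any(bins == 0L)) bins[bins == 0L] <- 1L  # atoms before first MODEL
    groups <- split(atom_idx, factor(bins, levels = seq_along(model_starts)))
    nonempty <- lengths(groups) > 0L
    groups <- groups[nonempty]
    model_nos <- model_nos[nonempty]
    if (!length(groups))
      stop("no atoms selected from '", path, "'")
  }

  first <- parse_atom_lines(lines[groups[[1L]]], groups[[1L]])
  if (!keep_alt_locs) first <- drop_alt_locs(first)
  out <- vector("list", length(groups))
  out[[1L]] <- new_structure(first, id = id, model_no = model_nos[1L])

  if (length(groups) > 1L) {
    sig1 <- topology_signature(lines[groups[[1L]]])
    for (m in seq_along(groups)[-1L]) {
      gl <- lines[groups[[m]]]
      if (identical(topology_signature(gl), sig1)) {
        # fast path: swap coordinates/occupancy/B into model 1's topology
        out[[m]] <- swap_coordinates(out[[1L]], gl, groups[[m]],
                                     keep_alt_locs, model_nos[m])
      } else {
        warning("model ", model_nos[m], " in '", path,
                "' is not chemically identical to model 1; ",
                "falling back to full parse")
        at <- parse_atom_lines(gl, groups[[m]])
        if (!keep_alt_locs) at <- drop_alt_locs(at)
        out[[m]] <- new_structure(at, id = id, model_no = model_nos[m])
      }
    }
  }
  out
}

# identity tuple for the fast path: (name, resName, chainID) per line
topology_signature <- function(lines) {
  lines <- pad80(lines)
  paste0(substr(lines, 13L, 16L), substr(lines, 18L, 20L),
         substr(lines, 22L, 22L))
}

swap_coordinates <- function(template, lines, line_no, keep_alt_locs,
                             model_no) {
  lines <- pad80(lines)
  x <- parse_fixed_num(substr(lines, 31L, 38L), 31L, 38L, line_no)
  y <- parse_fixed_num(substr(lines, 39L, 46L), 39L, 46L, line_no)
  z <- parse_fixed_num(substr(lines, 47L, 54L), 47L, 54L, line_no)
  occ <- parse_fixed_num(substr(lines, 55L, 60L), 55L, 60L, line_no, 1)
  b <- parse_fixed_num(substr(lines, 61L, 66L), 61L, 66L, line_no, 0)
  keep <- seq_along(lines)
  if (!keep_alt_locs) {
    # mirror the alt-loc policy applied to model 1
    at <- parse_atom_lines(lines, line_no)
    key <- paste(at$chain_id, at$res_seq, at$i_code, trimws(at$name),
                 sep = "\r")
    keep <- which(!duplicated(key))
  }
  s <- template
  s$atoms$x <- x[keep]
  s$atoms$y <- y[keep]
  s$atoms$z <- z[keep]
  s$atoms$occupancy <- occ[keep]
  s$atoms$b_factor <- b[keep]
  s$model_no <- as.integer(model_no)
  s
}

#' Read a single-model PDB file
#'
#' Convenience wrapper around [read_structures()] returning the first model.
#'
#' @inheritParams read_structures
#' @return A `Structure`.
#' @export
read_pdb <- function(path, filters = NULL, keep_hetero = TRUE,
                     keep_alt_locs = FALSE, id = NULL) {
  read_structures(path, filters, keep_hetero, keep_alt_locs, id)[[1L]]
}
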