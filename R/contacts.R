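# Residue contact maps over single- and multi-model inputs.

# Representative coordinates per residue for one model:
#  - "CA": the C-alpha position (residues without CA are skipped in CA mode)
#  - "any": all atoms (minimum inter-atomic distance defines the contact)
residue_coord_sets <- function(structure) {
  at <- structure$atoms
  idx <- residue_index(structure)
  n <- max(idx, 0L)
  keys <- residue_keys(at)
  first <- match(unique(keys), keys)
  list(
    n = n,
    chain_id = at$chain_id[first],
    res_seq = at$res_seq[first],
    i_code = at$i_code[first],
    xyz = as.matrix(at[, c("x", "y", "z")]),
    idx = idx
  )
}

#' Residue contact map of a structure ensemble
#'
#' A residue pair is in contact in one model iff its representative
#' distance is strictly below `cutoff`; counts are aggregated across
#' models. In `"CA"` mode the representative distance is between C-alpha
#' atoms (residues lacking CA never contact); in `"any"` mode it is the
#' minimum over all atom pairs. By default, intra-chain pairs closer than
#' `min_seq_sep` residues along the chain (internal index difference
#' `|i - j| < 2`) are excluded — sequence neighbours are trivially in
#' contact; set `min_seq_sep = 0` to disable.
#'
#' @param structures A `Structure` or list of them (models must share
#'   residue indexing).
#' @param cutoff Contact cutoff, Angstrom (> 0).
#' @param mode `"CA"` or `"any"`.
#' @param min_seq_sep Minimum intra-chain index separation (default 2).
#' @return A `ContactMap`: list with `pairs` (data.frame `i`, `j`,
#'   `chain_i`, `res_i`, `chain_j`, `res_j`, `count`, i < j by internal
#'   index, only pairs with count > 0), `cutoff`, `mode`, `n_models`.
#' @export
contact_map <- function(structures, cutoff, mode = c("CA", "any"),
                        min_seq_sep = 2L) {
  mode <- match.arg(mode)
  if (inherits(structures, "Structure")) structures <- list(structures)
  if (!length(structures)) stop("empty structure list")
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")

  ref <- residue_coord_sets(structures[[1L]])
  n <- ref$n
  counts <- matrix(0L, n, n)
  for (s in structures) {
    cs <- residue_coord_sets(s)
    if (cs$n != n)
      stop("models do not share residue indexing (", cs$n, " vs ", n, ")")
    if (mode == "CA") {
      sel <- is_ca_row(s$atoms)
      idx <- cs$idx[sel]
      xyz <- cs$xyz[sel, , drop = FALSE]
      keep <- !duplicated(idx)
      idx <- idx[keep]
      xyz <- xyz[keep, , drop = FALSE]
      if (length(idx) < 2L) next
      dm <- as.matrix(stats::dist(xyz))
      hit <- which(dm < cutoff & upper.tri(dm), arr.ind = TRUE)
      if (nrow(hit)) {
        ii <- idx[hit[, 1L]]
        jj <- idx[hit[, 2L]]
        counts[cbind(pmin(ii, jj), pmax(ii, jj))] <-
          counts[cbind(pmin(ii, jj), pmax(ii, jj))] + 1L
      }
    } else {
      dm <- as.matrix(stats::dist(cs$xyz))
      inc <- matrix(FALSE, n, n)
      hit <- which(dm < cutoff & upper.tri(dm), arr.ind = TRUE)
      if (nrow(hit)) {
        ii <- cs$idx[hit[, 1L]]
        jj <- cs$idx[hit[, 2L]]
        off <- ii != jj
        inc[cbind(pmin(ii[off], jj[off]), pmax(ii[off], jj[off]))] <- TRUE
      }
      counts <- counts + inc
    }
  }

  same_chain <- outer(ref$chain_id, ref$chain_id, "==")
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  excluded <- same_chain & sep < min_seq_sep
  counts[excluded] <- 0L

  hit <- which(counts > 0L & upper.tri(counts), arr.ind = TRUE)
  ord <- order(hit[, 1L], hit[, 2L])
  hit <- hit[ord, , drop = FALSE]
  pairs <- data.frame(
    i = hit[, 1L], j = hit[, 2L],
    chain_i = ref$chain_id[hit[, 1L]], res_i = ref$res_seq[hit[, 1L]],
    chain_j = ref$chain_id[hit[, 2L]], res_j = ref$res_seq[hit[, 2L]],
    count = counts[hit], stringsAsFactors = FALSE
  )
  structure(list(pairs = pairs, cutoff = cutoff, mode = mode,
                 n_models = length(structures)),
            class = "ContactMap")
}

#' @export
print.ContactMap <- function(x, ...) {
  cat(sprintf("<ContactMap> %d pair(s), cutoff %.2f A, %s mode, %d model(s)\n",
              nrow(x$pairs), x$cutoff, x$mode, x$n_models))
  invisible(x)
}

#' Write a contact map as TSV
#'
#' Columns: chain_i, res_i, chain_j, res_j, count; one '#'-prefixed header.
#'
#' @param cm A `ContactMap`.
#' @param path Output path, or `""` for stdout; `NULL` returns the lines
#'   without writing.
#' @return Formatted lines, invisibly.
#' @export
write_contact_map_tsv <- function(cm, path = "") {
  header <- "#chain_i\tres_i\tchain_j\tres_j\tcount"
  body <- sprintf("%s\t%d\t%s\t%d\t%d", cm$pairs$chain_i, cm$pairs$res_i,
                  cm$pairs$chain_j, cm$pairs$res_j, cm$pairs$count)
  lines <- c(header, body)
  if (is.null(path)) return(lines)
  if (nzchar(path)) writeLines(lines, path) else writeLines(lines)
  invisible(lines)
}
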