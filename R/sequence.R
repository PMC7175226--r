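# Sequences, FASTA I/O (backed by Biostrings) and sequence profiles.

#' Create a Sequence
#'
#' A minimal sequence record: free-text header plus a letter string over the
#' amino-acid alphabet extended with `X` (unknown) and `-` (gap).
#'
#' @param header Free-text identifier.
#' @param letters Sequence string.
#' @return Object of class `Sequence`.
#' @export
new_sequence <- function(header, letters) {
  structure(list(header = as.character(header),
                 letters = as.character(letters)),
            class = "Sequence")
}

#' @export
print.Sequence <- function(x, ...) {
  cat(sprintf(">%s (%d letters)\n", x$header, nchar(x$letters)))
  invisible(x)
}

# Polymer-residue test: standard amino acid OR has a C-alpha atom
# (tolerates modified residues); hetero-only ligands are excluded.
is_polymer_residue <- function(res_name, has_ca) {
  (toupper(res_name) %in% .aa3) | has_ca
}

#' Extract one sequence per chain from a Structure
#'
#' Concatenates the 1-letter codes of the polymer residues of each chain in
#' order. A residue counts as polymer if it is a standard amino acid or
#' carries a C-alpha atom (so modified residues survive as `X`); chains with
#' no polymer residue (e.g. ligand-only chains) are omitted. Headers are
#' `"<structure id>|<chain id>"`.
#'
#' @param structure A `Structure`.
#' @return List of `Sequence` objects, one per polymer chain.
#' @export
structure_to_sequences <- function(structure) {
  at <- structure$atoms
  out <- list()
  for (cid in unique(at$chain_id)) {
    sub <- at[at$chain_id == cid, , drop = FALSE]
    keys <- residue_keys(sub)
    ukeys <- unique(keys)
    res_name <- sub$res_name[match(ukeys, keys)]
    has_ca <- vapply(ukeys, function(k) any(is_ca_row(sub[keys == k, ,
                                                          drop = FALSE])),
                     logical(1))
    poly <- is_polymer_residue(res_name, has_ca)
    if (!any(poly)) next
    out[[length(out) + 1L]] <- new_sequence(
      paste0(structure$id, "|", cid),
      paste(three_to_one(res_name[poly]), collapse = "")
    )
  }
  out
}

#' Read and write FASTA files
#'
#' Standard FASTA, wrapped at 80 columns on write; reading concatenates
#' wrapped lines. A record with an empty body is an error naming its
#' header.
#'
#' @param path File path.
#' @param sequences List of `Sequence` objects (or a single one).
#' @return `read_fasta`: list of `Sequence`; `write_fasta`: `path`,
#'   invisibly.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  w <- Biostrings::width(set)
  if (any(w == 0L))
    stop("FASTA record '", names(set)[which(w == 0L)[1L]],
         "' has an empty sequence body")
  mapply(new_sequence, names(set), as.character(set),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  if (inherits(sequences, "Sequence")) sequences <- list(sequences)
  set <- Biostrings::BStringSet(vapply(sequences, `[[`, "", "letters"))
  names(set) <- vapply(sequences, `[[`, "", "header")
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Build a sequence profile from a multiple sequence alignment
#'
#' Column frequencies with optional additive pseudocount:
#' `freq(a) = (count_a + pc) / (n_nongap + A * pc)` where `A` is the
#' alphabet size. Gaps reduce the effective count rather than being an
#' alphabet symbol. An all-gap column with zero pseudocount is defined as
#' uniform so columns always sum to 1.
#'
#' @param sequences Equal-length list of `Sequence` (or character vector).
#' @param pseudocount Non-negative additive pseudocount (default 0).
#' @param alphabet Ordered symbol set; defaults to the 20 amino acids plus
#'   any additional non-gap symbols observed.
#' @return Object of class `SequenceProfile`: list with `columns` (L x A
#'   frequency matrix) and `alphabet`.
#' @export
profile_from_msa <- function(sequences, pseudocount = 0, alphabet = NULL) {
  if (inherits(sequences, "Sequence")) sequences <- list(sequences)
  lets <- vapply(sequences, function(s)
    if (inherits(s, "Sequence")) s$letters else as.character(s), "")
  if (!length(lets)) stop("at least one sequence required")
  if (length(unique(nchar(lets))) != 1L)
    stop("sequences must have equal length to form a profile")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  L <- nchar(lets[1L])
  mat <- do.call(rbind, strsplit(toupper(lets), ""))
  if (is.null(alphabet)) {
    seen <- setdiff(sort(unique(as.vector(mat))), c("-", "."))
    alphabet <- c(.aa1[order(.aa1)], setdiff(seen, .aa1))
  }
  A <- length(alphabet)
  cols <- matrix(0, nrow = L, ncol = A, dimnames = list(NULL, alphabet))
  for (j in seq_len(L)) {
    col <- mat[, j]
    col <- col[!(col %in% c("-", "."))]
    n <- length(col)
    counts <- tabulate(match(col, alphabet), nbins = A)
    if (length(col) && anyNA(match(col, alphabet)))
      stop("symbol(s) outside the alphabet in column ", j)
    denom <- n + A * pseudocount
    cols[j, ] <- if (denom > 0) (counts + pseudocount) / denom else rep(1 / A, A)
  }
  structure(list(columns = cols, alphabet = alphabet),
            class = "SequenceProfile")
}

#' Export a sequence profile as TSV
#'
#' One row per alignment column, one column per alphabet symbol, with a
#' header row of symbols.
#'
#' @param profile A `SequenceProfile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(profile$columns, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
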