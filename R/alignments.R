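# Pairwise global alignment (Needleman-Wunsch, linear gap penalty) and
# alignment assessment.

seq_letters <- function(s) {
  if (inherits(s, "Sequence")) s$letters else as.character(s)
}

#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Optimal global alignment under match/mismatch scoring or an arbitrary
#' substitution matrix, with a linear gap penalty. Traceback ties resolve
#' deterministically: diagonal over up (gap in `b`) over left (gap in
#' `a`).
#'
#' @param a,b `Sequence` objects or plain strings; non-empty.
#' @param match,mismatch Scores used when `submat` is NULL.
#' @param gap Gap penalty per gapped column (<= 0).
#' @param submat Optional substitution matrix with letter dimnames (e.g.
#'   from [read_substitution_matrix()]); overrides match/mismatch.
#' @return An `Alignment`: list with `aligned_a`, `aligned_b` (equal-length
#'   gapped strings), `score`, and `path` (data.frame of per-column moves
#'   `i`, `j`; 0 marks a gap).
#' @export
align_global <- function(a, b, match = 1, mismatch = -1, gap = -1,
                         submat = NULL) {
  sa <- strsplit(seq_letters(a), "")[[1L]]
  sb <- strsplit(seq_letters(b), "")[[1L]]
  if (!length(sa) || !length(sb)) stop("sequences must be non-empty")
  if (gap > 0) stop("gap penalty must be <= 0")
  score_of <- if (is.null(submat)) {
    function(x, y) if (x == y) match else mismatch
  } else {
    function(x, y) {
      if (is.na(match(x, rownames(submat))) ||
          is.na(match(y, colnames(submat))))
        stop("letter pair (", x, ", ", y, ") not in substitution matrix")
      submat[x, y]
    }
  }
  n <- length(sa)
  m <- length(sb)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- gap * (0:n)
  S[1L, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + score_of(sa[i], sb[j]),
                               S[i, j + 1L] + gap,
                               S[i + 1L, j] + gap)
    }
  }
  # traceback, tie preference: diagonal > up > left
  i <- n; j <- m
  ra <- rb <- character(0)
  pi_ <- pj_ <- integer(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] == S[i, j] + score_of(sa[i], sb[j])) {
      ra <- c(sa[i], ra); rb <- c(sb[j], rb)
      pi_ <- c(i, pi_); pj_ <- c(j, pj_)
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      ra <- c(sa[i], ra); rb <- c("-", rb)
      pi_ <- c(i, pi_); pj_ <- c(0L, pj_)
      i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(sb[j], rb)
      pi_ <- c(0L, pi_); pj_ <- c(j, pj_)
      j <- j - 1L
    }
  }
  structure(list(aligned_a = paste(ra, collapse = ""),
                 aligned_b = paste(rb, collapse = ""),
                 score = S[n + 1L, m + 1L],
                 path = data.frame(i = pi_, j = pj_)),
            class = "Alignment")
}

#' @export
print.Alignment <- function(x, ...) {
  cat(x$aligned_a, "\n", x$aligned_b, "\nscore: ", x$score, "\n", sep = "")
  invisible(x)
}

#' Percent identity of an alignment
#'
#' `100 * matches / columns`, counting only columns that are not
#' double-gaps.
#'
#' @param al An `Alignment`.
#' @return Percentage in [0, 100].
#' @export
percent_identity <- function(al) {
  ca <- strsplit(al$aligned_a, "")[[1L]]
  cb <- strsplit(al$aligned_b, "")[[1L]]
  keep <- !(ca == "-" & cb == "-")
  if (!any(keep)) stop("alignment has no non-empty columns")
  100 * sum(ca[keep] == cb[keep] & ca[keep] != "-") / sum(keep)
}

#' Read a substitution matrix from a whitespace table
#'
#' Expected layout: a header row of residue letters, then one row per
#' letter starting with its label — the usual plain-text layout of
#' tabulated 20 x 20 scoring matrices.
#'
#' @param path File path.
#' @return Numeric matrix with letter dimnames.
#' @export
read_substitution_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1L,
                                   check.names = FALSE))
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("substitution matrix must be square with matching row/col letters")
  m
}

#' Write a pairwise alignment as gapped FASTA plus a score line
#'
#' @param al An `Alignment`.
#' @param header_a,header_b Record headers.
#' @param path Output path, or `""` for stdout; `NULL` returns the lines
#'   without writing.
#' @return Formatted lines, invisibly.
#' @export
write_alignment_fasta <- function(al, header_a = "a", header_b = "b",
                                  path = "") {
  lines <- c(paste0(">", header_a), al$aligned_a,
             paste0(">", header_b), al$aligned_b,
             sprintf("# score: %g", al$score))
  if (is.null(path)) return(lines)
  if (nzchar(path)) writeLines(lines, path) else writeLines(lines)
  invisible(lines)
}
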