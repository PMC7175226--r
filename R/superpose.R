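# Optimal rigid-body superposition (Kabsch, SVD with reflection correction)
# and crmsd over C-alpha traces and ensembles.

#' Optimal superposition of two point sets (Kabsch algorithm)
#'
#' Finds the rotation (det = +1, reflections excluded) and translation
#' minimizing the RMSD between `mobile` and `reference`, via SVD of the
#' cross-covariance of the centered sets. Degenerate (planar or symmetric)
#' configurations resolve by SVD convention: implementation-defined but
#' deterministic.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3, equal n.
#' @return A `SuperpositionResult`: list with `rotation` (3x3), a
#'   `translation` (length 3) such that `mobile %*% t(rotation) +
#'   translation` best fits `reference`, and the minimized `crmsd`
#'   (Angstrom).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    stop("point sets differ in length: ", nrow(mobile), " vs ",
         nrow(reference))
  if (nrow(mobile) < 3L)
    stop("at least 3 points are required for superposition")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  A <- sweep(mobile, 2L, cm)
  B <- sweep(reference, 2L, cr)
  if (all(svd(A, nu = 0, nv = 0)$d[-1] < 1e-12) ||
      all(svd(B, nu = 0, nv = 0)$d[-1] < 1e-12))
    stop("all points are collinear; superposition is degenerate")
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- A %*% t(R)
  crmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cr - R %*% cm),
                 crmsd = crmsd),
            class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("<SuperpositionResult> crmsd = %.4f A\n", x$crmsd))
  invisible(x)
}

#' crmsd between the C-alpha traces of two structures
#'
#' Extracts both C-alpha traces and returns the Kabsch-minimized RMSD.
#'
#' @param structure_a,structure_b `Structure` objects with equal CA counts.
#' @return crmsd in Angstrom.
#' @export
crmsd_ca <- function(structure_a, structure_b) {
  ta <- ca_trace(structure_a)
  tb <- ca_trace(structure_b)
  if (nrow(ta) != nrow(tb))
    stop("CA trace lengths differ: ", nrow(ta), " (", structure_a$id,
         ") vs ", nrow(tb), " (", structure_b$id, ")")
  kabsch_superpose(ta, tb)$crmsd
}

#' All-pairs crmsd matrix over a structure ensemble
#'
#' Symmetric with a zero diagonal; entry (i, j) equals
#' `crmsd_ca(structures[[i]], structures[[j]])`. The result is independent
#' of evaluation order (each pair is computed directly), so the contract is
#' safe under any parallel partitioning.
#'
#' @param structures List of `Structure` with homogeneous CA-trace lengths.
#' @return A `DistanceMatrix` (see [distance_matrix()]), labelled by
#'   structure id and model number.
#' @export
pairwise_crmsd_matrix <- function(structures) {
  n <- length(structures)
  traces <- lapply(structures, ca_trace)
  lens <- vapply(traces, nrow, 0L)
  if (length(unique(lens)) > 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop("model ", bad, " (", structures[[bad]]$id, ") has CA trace length ",
         lens[bad], ", expected ", lens[1L])
  }
  m <- matrix(0, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        v <- kabsch_superpose(traces[[i]], traces[[j]])$crmsd
        m[i, j] <- v
        m[j, i] <- v
      }
    }
  }
  labels <- vapply(structures, function(s)
    paste0(s$id, "#", s$model_no), "")
  if (anyDuplicated(labels)) labels <- paste0(labels, ".", seq_len(n))
  distance_matrix(m, labels)
}
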