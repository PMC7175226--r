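# Agglomerative hierarchical clustering of structure ensembles (by crmsd)
# and of generic distance matrices, with medoid extraction. The
# agglomerator is a deterministic Lance-Williams implementation with
# lowest-index tie-breaking.

#' Create a validated DistanceMatrix
#'
#' @param values Symmetric n x n matrix, non-negative entries, zero
#'   diagonal (symmetry tolerance 1e-9; the stored matrix is exactly
#'   symmetrized).
#' @param labels n identifiers (default `"1"..."n"`).
#' @return Object of class `DistanceMatrix`: list with `values`, `labels`,
#'   `n`.
#' @export
distance_matrix <- function(values, labels = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("distance matrix must be square")
  if (any(values < 0)) stop("distance matrix has negative entries")
  if (max(abs(values - t(values))) > 1e-9)
    stop("distance matrix is not symmetric (tolerance 1e-9)")
  if (any(diag(values) != 0)) stop("distance matrix diagonal must be zero")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (length(labels) != n) stop("need one label per row")
  values <- (values + t(values)) / 2
  structure(list(values = values, labels = as.character(labels), n = n),
            class = "DistanceMatrix")
}

#' Read/write a distance matrix as whitespace-delimited square text
#'
#' The body is a plain n x n block of numbers. Labels travel in a
#' `# labels:` comment line (written first); files without one get default
#' labels. A non-numeric first body line (a bare label header, a common
#' dialect) is also accepted as labels on read.
#'
#' @param d A `DistanceMatrix`.
#' @param path File path.
#' @return `read_distance_matrix`: a `DistanceMatrix`;
#'   `write_distance_matrix`: `path`, invisibly.
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  labels <- NULL
  lab_line <- grep("^#\\s*labels:", lines, value = TRUE)
  if (length(lab_line))
    labels <- strsplit(trimws(sub("^#\\s*labels:", "", lab_line[1L])),
                       "\\s+")[[1L]]
  lines <- lines[!startsWith(lines, "#")]
  first <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (is.null(labels) && anyNA(suppressWarnings(as.numeric(first)))) {
    labels <- first
    lines <- lines[-1L]
  }
  rows <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  if (length(unique(lengths(rows))) != 1L)
    stop("ragged rows in distance matrix file '", path, "'")
  distance_matrix(do.call(rbind, rows), labels)
}

#' @rdname read_distance_matrix
#' @export
write_distance_matrix <- function(d, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste("# labels:", paste(d$labels, collapse = " ")), con)
  utils::write.table(format(d$values, digits = 12, trim = TRUE), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Standard Lance-Williams agglomeration under `single`, `complete` or
#' `average` (UPGMA) linkage. Deterministic: among equal-distance merge
#' candidates the lexicographically smallest active index pair wins. Merge
#' heights are non-decreasing for all three linkages.
#'
#' @param d A `DistanceMatrix` (or plain symmetric matrix), n >= 2.
#' @param linkage `"single"`, `"complete"` or `"average"` (default
#'   `"average"`, the usual choice for model-ensemble clustering).
#' @return A `Dendrogram`: list with `merge` (hclust-style (n-1) x 2,
#'   negatives are leaves), `height`, `labels`, `n`, `linkage`.
#' @export
agglomerate <- function(d, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (!inherits(d, "DistanceMatrix")) d <- distance_matrix(d)
  n <- d$n
  if (n < 2L) stop("need at least 2 items to cluster")
  D <- d$values
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  # cluster id per slot: negative leaf index, then positive merge index
  id <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    act <- which(active)
    for (ii in seq_along(act)[-length(act)]) {
      i <- act[ii]
      js <- act[act > i]
      dj <- D[i, js]
      m <- min(dj)
      if (m < best_d) {  # strict: keeps the lowest-index pair on ties
        best_d <- m
        best <- c(i, js[which(dj == m)[1L]])
      }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- best_d
    # Lance-Williams update into slot i
    others <- act[act != i & act != j]
    if (length(others)) {
      dnew <- switch(linkage,
        single = pmin(D[i, others], D[j, others]),
        complete = pmax(D[i, others], D[j, others]),
        average = (size[i] * D[i, others] + size[j] * D[j, others]) /
          (size[i] + size[j]))
      D[i, others] <- dnew
      D[others, i] <- dnew
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    D[j, ] <- Inf
    D[, j] <- Inf
    id[i] <- step
  }
  structure(list(merge = merge, height = height, labels = d$labels,
                 n = n, linkage = linkage),
            class = "Dendrogram")
}

#' @export
print.Dendrogram <- function(x, ...) {
  cat(sprintf("<Dendrogram> %d leaves, %s linkage, %d merges\n",
              x$n, x$linkage, nrow(x$merge)))
  invisible(x)
}

# leaves under each merge node
merge_members <- function(dend) {
  n <- dend$n
  members <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    get1 <- function(v) if (v < 0) -v else members[[v]]
    members[[s]] <- c(get1(dend$merge[s, 1L]), get1(dend$merge[s, 2L]))
  }
  members
}

#' Cut a dendrogram into a partition with medoids
#'
#' Cutting at `k` clusters undoes the last `k - 1` merges; cutting at
#' `height` undoes every merge above that height (merges at exactly the
#' cut height are kept). The medoid of each cluster minimizes the summed
#' intra-cluster distance (ties to the lowest leaf index). Cluster ids are
#' assigned 1..k in order of each cluster's first leaf.
#'
#' @param dend A `Dendrogram`.
#' @param d The `DistanceMatrix` the dendrogram was built from (needed for
#'   medoids).
#' @param k Number of clusters (1..n). Give exactly one of `k`, `height`.
#' @param height Cut height (>= 0).
#' @return A `ClusterReport`: list with `assignments` (integer per leaf),
#'   `medoids` (leaf index per cluster), `sizes`, `labels`, `k`.
#' @export
cut_dendrogram <- function(dend, d, k = NULL, height = NULL) {
  if (!is.null(k) && !is.null(height))
    stop("give either k or height, not both")
  if (is.null(k) && is.null(height))
    stop("one of k or height is required")
  n <- dend$n
  if (!is.null(k)) {
    if (k < 1L || k > n) stop("k must be in 1..", n)
    n_apply <- n - k
  } else {
    if (height < 0) stop("height must be >= 0")
    n_apply <- sum(dend$height <= height)
  }
  assign <- seq_len(n)
  if (n_apply > 0L) {
    members <- merge_members(dend)
    for (s in seq_len(n_apply)) {
      mem <- members[[s]]
      assign[mem] <- min(assign[mem])
    }
  }
  # relabel 1..k by first occurrence
  assign <- match(assign, unique(assign))
  kk <- max(assign)
  if (!inherits(d, "DistanceMatrix")) d <- distance_matrix(d)
  if (d$n != n) stop("distance matrix does not match dendrogram size")
  medoids <- integer(kk)
  for (c_id in seq_len(kk)) {
    mem <- which(assign == c_id)
    sums <- colSums(d$values[mem, mem, drop = FALSE])
    medoids[c_id] <- mem[which.min(sums)]
  }
  structure(list(assignments = assign, medoids = medoids,
                 sizes = tabulate(assign, kk), labels = dend$labels,
                 k = kk),
            class = "ClusterReport")
}

#' @export
print.ClusterReport <- function(x, ...) {
  cat(sprintf("<ClusterReport> %d cluster(s); sizes: %s\n", x$k,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Cluster a structure ensemble by pairwise crmsd
#'
#' Composition of [pairwise_crmsd_matrix()], [agglomerate()] and
#' [cut_dendrogram()] — the usual workflow for grouping models from a
#' simulation or decoy set and extracting representative (medoid)
#' structures.
#'
#' @param structures List of `Structure` with homogeneous CA traces.
#' @param linkage Linkage passed to [agglomerate()].
#' @param k Number of clusters.
#' @return The `ClusterReport`, with the crmsd `DistanceMatrix` attached as
#'   `$distances` and medoid structures as `$medoid_structures`.
#' @export
cluster_ensemble <- function(structures, linkage = "average", k = 2L) {
  d <- pairwise_crmsd_matrix(structures)
  report <- cut_dendrogram(agglomerate(d, linkage), d, k = k)
  report$distances <- d
  report$medoid_structures <- structures[report$medoids]
  report
}

#' Export a dendrogram in Newick format
#'
#' @param dend A `Dendrogram`.
#' @param path Optional output path; omitted returns the Newick string.
#' @return Newick string, invisibly if written to file.
#' @export
dendrogram_to_newick <- function(dend, path = NULL) {
  hc <- list(merge = dend$merge, height = dend$height,
             order = dendrogram_leaf_order(dend), labels = dend$labels,
             method = dend$linkage)
  class(hc) <- "hclust"
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

dendrogram_leaf_order <- function(dend) {
  walk <- function(v) {
    if (v < 0) return(-v)
    c(walk(dend$merge[v, 1L]), walk(dend$merge[v, 2L]))
  }
  walk(nrow(dend$merge))
}

#' Write a cluster report as TSV
#'
#' One row per leaf: label, cluster id, and whether it is its cluster's
#' medoid.
#'
#' @param report A `ClusterReport`.
#' @param path Output path, or `""` for stdout; `NULL` returns the lines
#'   without writing.
#' @return Formatted lines, invisibly.
#' @export
write_cluster_report_tsv <- function(report, path = "") {
  header <- "#label\tcluster\tis_medoid"
  body <- sprintf("%s\t%d\t%d", report$labels, report$assignments,
                  as.integer(seq_along(report$assignments) %in%
                               report$medoids))
  lines <- c(header, body)
  if (is.null(path)) return(lines)
  if (nzchar(path)) writeLines(lines, path) else writeLines(lines)
  invisible(lines)
}
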