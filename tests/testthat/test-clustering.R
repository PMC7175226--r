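random_dmat <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n, 0.1, 10), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  distance_matrix(m)
}

# two tight blobs: intra <= 1, inter >= 10
blob_dmat <- function(n1 = 4L, n2 = 4L, seed = 1L) {
  set.seed(seed)
  n <- n1 + n2
  m <- matrix(runif(n * n, 10, 12), n)
  m[1:n1, 1:n1] <- runif(n1 * n1, 0.1, 1)
  idx2 <- (n1 + 1):n
  m[idx2, idx2] <- runif(n2 * n2, 0.1, 1)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  distance_matrix(m)
}

test_that("two items merge at their distance; the 3-point case by hand", {
  d <- distance_matrix(matrix(c(0, 2.5, 2.5, 0), 2))
  dend <- agglomerate(d, "single")
  expect_equal(dend$height, 2.5)
  # d(1,2)=1, d(1,3)=2, d(2,3)=3: single linkage merges {1,2} at 1, then
  # joins 3 at min(2,3)=2
  m3 <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
  dend3 <- agglomerate(distance_matrix(m3), "single")
  expect_equal(dend3$height, c(1, 2))
  expect_equal(dend3$merge[1, ], c(-2L, -1L))
  # complete linkage joins 3 at max(2,3)=3
  expect_equal(agglomerate(distance_matrix(m3), "complete")$height, c(1, 3))
  # average at (2+3)/2
  expect_equal(agglomerate(distance_matrix(m3), "average")$height,
               c(1, 2.5))
})

test_that("merge heights equal the independent hclust reference", {
  for (trial in 1:20) {
    n <- sample(4:10, 1)
    d <- random_dmat(n, seed = 100 + trial)
    for (link in c("single", "complete", "average")) {
      got <- agglomerate(d, link)$height
      ref <- stats::hclust(stats::as.dist(d$values), method = link)$height
      expect_equal(sort(got), sort(ref), tolerance = 1e-9,
                   info = sprintf("n=%d link=%s trial=%d", n, link, trial))
      expect_true(all(diff(got) >= -1e-12))  # monotone heights
    }
  }
})

test_that("asymmetric or negative input is rejected", {
  m <- matrix(c(0, 1, 2, 0), 2)
  expect_error(distance_matrix(m), "symmetric")
  expect_error(distance_matrix(matrix(c(0, -1, -1, 0), 2)), "negative")
  expect_error(agglomerate(distance_matrix(matrix(0, 1, 1))), "at least 2")
})

test_that("cut at k=n and k=1 gives singletons and one cluster", {
  d <- random_dmat(6, 200)
  dend <- agglomerate(d)
  singles <- cut_dendrogram(dend, d, k = 6)
  expect_equal(singles$assignments, 1:6)
  expect_equal(sort(singles$medoids), 1:6)
  one <- cut_dendrogram(dend, d, k = 1)
  expect_equal(one$assignments, rep(1L, 6))
  expect_equal(one$sizes, 6L)
  expect_error(cut_dendrogram(dend, d, k = 2, height = 1), "not both")
  expect_error(cut_dendrogram(dend, d), "required")
})

test_that("well-separated blobs are recovered by all linkages", {
  d <- blob_dmat(4, 4, seed = 201)
  truth <- rep(1:2, each = 4)
  for (link in c("single", "complete", "average")) {
    rep_ <- cut_dendrogram(agglomerate(d, link), d, k = 2)
    expect_equal(rep_$assignments, truth, info = link)
    # medoid belongs to its cluster and minimizes the summed distance
    for (c_id in 1:2) {
      mem <- which(truth == c_id)
      expect_true(rep_$medoids[c_id] %in% mem)
      sums <- colSums(d$values[mem, mem])
      expect_equal(sums[match(rep_$medoids[c_id], mem)], min(sums),
                   ignore_attr = TRUE)
    }
  }
})

test_that("height cuts undo merges above the threshold", {
  d <- blob_dmat(3, 3, seed = 202)
  dend <- agglomerate(d, "average")
  rep_ <- cut_dendrogram(dend, d, height = 5)
  expect_equal(rep_$k, 2L)
})

test_that("ensemble clustering recovers basins and is order-equivariant", {
  helix <- random_fixture_structure(210, n_res = 8L)
  extended <- build_backbone(rep(180, 8), rep(180, 8))
  extended <- round_to_pdb_precision(extended)
  traj <- make_trajectory(NULL, 8L, rigid = TRUE, sigma = 0.2,
                          basins = list(helix, extended), seed = 211L)
  rep_ <- cluster_ensemble(traj$structures, k = 2L)
  # same partition as the generator's labels, up to relabeling
  expect_equal(length(unique(paste(rep_$assignments, traj$labels))), 2L)
  expect_true(all(rep_$medoids %in% seq_along(traj$structures)))
  # permuted input gives the same partition up to relabeling
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  rep_p <- cluster_ensemble(traj$structures[perm], k = 2L)
  expect_equal(length(unique(paste(rep_p$assignments,
                                   rep_$assignments[perm]))), 2L)
  # duplicate model vs far decoy: zero-distance pair sticks together
  dup <- list(helix, helix, extended)
  rep_d <- cluster_ensemble(dup, k = 2L)
  expect_equal(rep_d$assignments[1], rep_d$assignments[2])
  expect_false(rep_d$assignments[1] == rep_d$assignments[3])
})

test_that("distance matrices round trip as square text and export Newick", {
  d <- random_dmat(5, 220)
  f <- withr::local_tempfile(fileext = ".txt")
  write_distance_matrix(d, f)
  back <- read_distance_matrix(f)
  expect_equal(back$values, d$values, tolerance = 1e-9)
  expect_equal(back$labels, d$labels)
  nwk <- dendrogram_to_newick(agglomerate(d))
  tree <- ape::read.tree(text = nwk)
  expect_equal(sort(tree$tip.label), sort(d$labels))
})
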