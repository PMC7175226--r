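# Independent oracles used across the suite. Each deliberately reimplements
# the quantity under test by a different route than the package code.

# Torsion via projection onto the plane perpendicular to the central bond,
# signed by the right-hand rule about b->c.
oracle_dihedral <- function(a, b, c, d) {
  axis <- (c - b) / sqrt(sum((c - b)^2))
  u <- (a - b) - sum((a - b) * axis) * axis
  v <- (d - c) - sum((d - c) * axis) * axis
  crs <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
  ang <- atan2(sum(crs * axis), sum(u * v)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Horn's closed-form quaternion-eigenvalue solution for minimal RMSD;
# independent of the SVD route in kabsch_superpose().
oracle_horn_crmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  S <- t(A) %*% B
  N <- matrix(c(
    S[1,1] + S[2,2] + S[3,3], S[2,3] - S[3,2], S[3,1] - S[1,3], S[1,2] - S[2,1],
    S[2,3] - S[3,2], S[1,1] - S[2,2] - S[3,3], S[1,2] + S[2,1], S[3,1] + S[1,3],
    S[3,1] - S[1,3], S[1,2] + S[2,1], -S[1,1] + S[2,2] - S[3,3], S[2,3] + S[3,2],
    S[1,2] - S[2,1], S[3,1] + S[1,3], S[2,3] + S[3,2], -S[1,1] - S[2,2] + S[3,3]),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lambda) / nrow(A)
  sqrt(max(0, msd))
}

# Brute-force minimizer over sampled rotations (optimal translation per
# rotation is the centroid match). Returns the grid minimum; always an
# upper bound on the true crmsd.
oracle_grid_crmsd <- function(mobile, reference, n_rot = 20000L) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  best <- Inf
  for (r in seq_len(n_rot)) {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z), 2*(x*z + w*y),
                  2*(x*y + w*z), 1 - 2*(x^2 + z^2), 2*(y*z - w*x),
                  2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2 + y^2)),
                3, 3, byrow = TRUE)
    v <- sqrt(mean(rowSums((A %*% t(R) - B)^2)))
    if (v < best) best <- v
  }
  best
}

# O(n^2) double-loop contact counting straight from the definition.
oracle_contact_counts <- function(structures, cutoff, mode = "CA",
                                  min_seq_sep = 2L) {
  if (inherits(structures, "Structure")) structures <- list(structures)
  at1 <- iter_atoms(structures[[1]])
  key1 <- paste(at1$chain_id, at1$res_seq, at1$i_code)
  ukeys <- unique(key1)
  n <- length(ukeys)
  chain_of <- at1$chain_id[match(ukeys, key1)]
  counts <- matrix(0L, n, n)
  for (s in structures) {
    at <- iter_atoms(s)
    key <- paste(at$chain_id, at$res_seq, at$i_code)
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        if (chain_of[i] == chain_of[j] && abs(i - j) < min_seq_sep) next
        ai <- at[key == ukeys[i], , drop = FALSE]
        aj <- at[key == ukeys[j], , drop = FALSE]
        if (mode == "CA") {
          ai <- ai[trimws(ai$name) == "CA" & ai$element %in% c("C", ""), ,
                   drop = FALSE]
          aj <- aj[trimws(aj$name) == "CA" & aj$element %in% c("C", ""), ,
                   drop = FALSE]
          if (!nrow(ai) || !nrow(aj)) next
          ai <- ai[1, , drop = FALSE]
          aj <- aj[1, , drop = FALSE]
        }
        dmin <- Inf
        for (p in seq_len(nrow(ai))) for (q in seq_len(nrow(aj))) {
          d <- sqrt((ai$x[p] - aj$x[q])^2 + (ai$y[p] - aj$y[q])^2 +
                    (ai$z[p] - aj$z[q])^2)
          if (d < dmin) dmin <- d
        }
        if (dmin < cutoff) counts[i, j] <- counts[i, j] + 1L
      }
    }
  }
  counts
}

# turn a ContactMap into the same full matrix layout for comparison
contact_map_as_matrix <- function(cm, n) {
  m <- matrix(0L, n, n)
  if (nrow(cm$pairs)) m[cbind(cm$pairs$i, cm$pairs$j)] <- cm$pairs$count
  m
}

# Exhaustive global-alignment scoring by explicit recursion over all
# monotone paths (no tabulation).
oracle_align_score <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1) +
                    (if (sa[i] == sb[j]) match else mismatch))
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(length(sa), length(sb))
}

# random small all-atom-ish structure for IO tests: a seeded backbone with
# optional extra chain and ligand, rounded to PDB precision
random_fixture_structure <- function(seed, n_res = 6L, two_chains = FALSE,
                                     ligand = FALSE) {
  set.seed(seed)
  phi <- stats::runif(n_res, -180, 180)
  psi <- stats::runif(n_res, -180, 180)
  names_pool <- c("ALA", "GLY", "SER", "LEU", "TRP", "PHE", "PRO", "LYS")
  s <- build_backbone(phi, psi, sample(names_pool, n_res, replace = TRUE))
  if (two_chains) {
    s2 <- build_backbone(stats::runif(4, -180, 180),
                         stats::runif(4, -180, 180),
                         sample(names_pool, 4, replace = TRUE),
                         chain_id = "B", first_serial = max(s$atoms$serial) + 1L)
    s2 <- transform_structure(s2, diag(3), c(12, 0, 0))
    s$atoms <- rbind(s$atoms, s2$atoms)
  }
  if (ligand) s <- add_ligand(s)
  round_to_pdb_precision(s)
}

expect_structures_equal <- function(a, b) {
  testthat::expect_equal(a$atoms, b$atoms)
}
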