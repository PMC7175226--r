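test_that("dihedral matches planar references and the projection oracle", {
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)), 180)
  set.seed(61)
  for (i in 1:50) {
    pts <- matrix(rnorm(12, sd = 3), 4)
    got <- dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    expect_equal(got, oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 tolerance = 1e-9)
    expect_gt(got, -180)
    expect_lte(got, 180)
  }
  expect_error(dihedral(c(0, 1, 0), c(0, 0, 0), c(0, 0, 0), c(1, 1, 0)),
               "central bond")
})

# Note: the signed torsion is *invariant* under full path reversal
# (reversal maps n1 -> -n2, n2 -> -n1 and flips the axis, leaving both
# atan2 arguments unchanged); the sign flips under mirror reflection.
test_that("dihedral is invariant under path reversal, negates under mirror", {
  set.seed(62)
  for (i in 1:100) {
    pts <- matrix(rnorm(12, sd = 2), 4)
    a <- dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    b <- dihedral(pts[4, ], pts[3, ], pts[2, ], pts[1, ])
    expect_equal((a - b) %% 360, 0, tolerance = 1e-9)
    mir <- pts %*% diag(c(1, 1, -1))
    m <- dihedral(mir[1, ], mir[2, ], mir[3, ], mir[4, ])
    expect_equal(min(abs(a + m), abs(a + m - 360), abs(a + m + 360)), 0,
                 tolerance = 1e-9)
  }
})

test_that("phi_psi recovers construction targets and classifies residues", {
  s <- build_backbone(rep(-57, 10), rep(-47, 10))
  r <- phi_psi(s)
  expect_true(all(is.na(r$phi[1]) && !anyNA(r$phi[-1])))
  expect_true(all(is.na(r$psi[10]) && !anyNA(r$psi[-10])))
  expect_true(all(abs(r$phi[-1] + 57) < 0.5))
  expect_true(all(abs(r$psi[-10] + 47) < 0.5))
  # classification: identity outranks pre-proline context
  s2 <- build_backbone(rep(-60, 4), rep(140, 4),
                       c("ALA", "PRO", "GLY", "PRO"))
  r2 <- phi_psi(s2)
  expect_equal(r2$klass, c("Pre-Proline", "Proline", "Glycine", "Proline"))
  s3 <- build_backbone(rep(-60, 2), rep(140, 2), c("LYS", "SER"))
  expect_equal(phi_psi(s3)$klass, c("General", "General"))
})

test_that("missing backbone atoms warn and yield NA angles", {
  s <- build_backbone(rep(-57, 3), rep(-47, 3))
  s$atoms <- s$atoms[trimws(s$atoms$name) != "N" |
                       s$atoms$res_seq != 2L, ]
  expect_warning(r <- phi_psi(s), "lacks backbone")
  expect_true(is.na(r$phi[2]) && is.na(r$psi[2]))
  expect_false(is.na(r$psi[1]) && is.na(r$phi[3]))
})

test_that("kabsch_superpose recovers exact rigid motions", {
  set.seed(63)
  A <- matrix(rnorm(30, sd = 3), 10)
  res <- kabsch_superpose(A, A)
  expect_equal(res$crmsd, 0, tolerance = 1e-12)
  expect_equal(res$rotation, diag(3), tolerance = 1e-8)
  th <- pi / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  B <- A %*% t(R) + rep(c(4, -2, 7), each = 10)
  res2 <- kabsch_superpose(A, B)
  expect_lt(res2$crmsd, 1e-9)
  expect_equal(crossprod(res2$rotation), diag(3), tolerance = 1e-8)
  expect_equal(det(res2$rotation), 1, tolerance = 1e-8)
  # the returned transform actually maps mobile onto reference
  mapped <- A %*% t(res2$rotation) + rep(res2$translation, each = 10)
  expect_equal(mapped, B, tolerance = 1e-8)
})

test_that("kabsch agrees with the independent Horn quaternion solution", {
  set.seed(64)
  for (i in 1:20) {
    A <- matrix(rnorm(30, sd = 2), 10)
    B <- matrix(rnorm(30, sd = 2), 10)
    expect_equal(kabsch_superpose(A, B)$crmsd, oracle_horn_crmsd(A, B),
                 tolerance = 1e-6)
  }
})

test_that("kabsch input validation", {
  A <- matrix(rnorm(30), 10)
  expect_error(kabsch_superpose(A, A[1:9, ]), "differ in length")
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("crmsd is rigid-invariant and a pseudo-metric on traces", {
  set.seed(65)
  base <- random_fixture_structure(66, n_res = 8L)
  traj <- make_trajectory(base, 3L, rigid = TRUE, sigma = 0.5, seed = 66L)
  s <- traj$structures
  # symmetry
  expect_equal(crmsd_ca(s[[1]], s[[2]]), crmsd_ca(s[[2]], s[[1]]),
               tolerance = 1e-9)
  # rigid invariance
  moved <- transform_structure(s[[1]], structkit:::random_rotation(),
                               c(3, -1, 2))
  expect_equal(crmsd_ca(s[[1]], s[[2]]), crmsd_ca(moved, s[[2]]),
               tolerance = 1e-9)
  # triangle inequality
  d12 <- crmsd_ca(s[[1]], s[[2]])
  d13 <- crmsd_ca(s[[1]], s[[3]])
  d23 <- crmsd_ca(s[[2]], s[[3]])
  expect_lte(d12, d13 + d23 + 1e-6)
})

test_that("crmsd_ca reports both counts on mismatch", {
  a <- random_fixture_structure(67, n_res = 5L)
  b <- random_fixture_structure(68, n_res = 7L)
  expect_error(crmsd_ca(a, b), "5.*7")
})

test_that("pairwise_crmsd_matrix matches per-pair calls and permutes", {
  base <- random_fixture_structure(69, n_res = 6L)
  traj <- make_trajectory(base, 4L, rigid = TRUE, sigma = 0.4, seed = 70L)
  s <- traj$structures
  d <- pairwise_crmsd_matrix(s)
  expect_equal(diag(d$values), rep(0, 4))
  expect_equal(d$values, t(d$values))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(d$values[i, j], crmsd_ca(s[[i]], s[[j]]), tolerance = 1e-9)
  perm <- c(3, 1, 4, 2)
  d2 <- pairwise_crmsd_matrix(s[perm])
  expect_equal(d2$values, d$values[perm, perm], tolerance = 1e-9)
  # identical models give the zero matrix
  dz <- pairwise_crmsd_matrix(make_trajectory(base, 3L, rigid = TRUE,
                                              sigma = 0,
                                              seed = 71L)$structures)
  expect_true(all(dz$values < 1e-9))
})
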