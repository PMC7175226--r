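# Deterministic synthetic-fixture generators: backbones built from target
# internal coordinates, multi-model trajectories with known transforms and
# labels, aromatic ring pairs with prescribed stacking geometry, and small
# protein+ligand structures. Everything is seeded and reproducible; no
# downloads. Side chains beyond the constructed aromatic rings are omitted
# -- fixtures are metrically, not chemically, realistic.

# NeRF atom placement: returns D with |C-D| = r, angle(B,C,D) = theta and
# torsion(A,B,C,D) = chi (degrees).
place_atom <- function(A, B, C, r, theta, chi) {
  th <- theta * pi / 180
  ch <- chi * pi / 180
  u2 <- v_unit(C - B)
  n <- v_unit(v_cross(B - A, C - B))
  m <- v_cross(n, u2)
  C + r * (-u2 * cos(th) + m * sin(th) * cos(ch) + n * sin(th) * sin(ch))
}

# idealized backbone geometry (Angstrom / degrees)
.bb <- list(b_NCa = 1.458, b_CaC = 1.525, b_CN = 1.329,
            a_NCaC = 111.2, a_CaCN = 116.2, a_CNCa = 121.7, omega = 180)

#' Build a backbone structure from target phi/psi angles
#'
#' Chains a poly-alanine (or caller-named) backbone by internal-coordinate
#' placement with idealized geometry (N-CA 1.458, CA-C 1.525, C-N 1.329
#' Angstrom; omega fixed at 180). Measuring dihedrals on the result
#' recovers the targets to well within 0.5 degrees, which makes these
#' structures exact oracles for the Ramachandran machinery.
#'
#' @param phi Phi targets, degrees; `phi[1]` is unused (chain start).
#' @param psi Psi targets, degrees; the last entry is unused (chain end).
#'   `phi` and `psi` must have equal length n >= 1.
#' @param res_names Residue names, recycled to n (default `"ALA"`).
#' @param chain_id Chain identifier.
#' @param id Structure label.
#' @param first_serial Serial number of the first atom.
#' @param first_res_seq Residue number of the first residue.
#' @return A `Structure` with N, CA, C atoms per residue.
#' @export
build_backbone <- function(phi, psi, res_names = "ALA", chain_id = "A",
                           id = "backbone", first_serial = 1L,
                           first_res_seq = 1L) {
  n <- length(phi)
  if (length(psi) != n) stop("phi and psi must have equal length")
  if (n < 1L) stop("need at least one residue")
  res_names <- rep_len(toupper(res_names), n)
  N <- CA <- C <- matrix(NA_real_, n, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(.bb$b_NCa, 0, 0)
  ang <- .bb$a_NCaC * pi / 180
  C[1L, ] <- CA[1L, ] + .bb$b_CaC * c(cos(pi - ang), sin(pi - ang), 0)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      N[i + 1L, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                                .bb$b_CN, .bb$a_CaCN, psi[i])
      CA[i + 1L, ] <- place_atom(CA[i, ], C[i, ], N[i + 1L, ],
                                 .bb$b_NCa, .bb$a_CNCa, .bb$omega)
      C[i + 1L, ] <- place_atom(C[i, ], N[i + 1L, ], CA[i + 1L, ],
                                .bb$b_CaC, .bb$a_NCaC, phi[i + 1L])
    }
  }
  xyz <- matrix(NA_real_, 3L * n, 3L)
  xyz[seq(1L, 3L * n, 3L), ] <- N
  xyz[seq(2L, 3L * n, 3L), ] <- CA
  xyz[seq(3L, 3L * n, 3L), ] <- C
  atoms <- data.frame(
    serial = seq.int(first_serial, length.out = 3L * n),
    name = rep(c(" N  ", " CA ", " C  "), n),
    alt_loc = " ",
    res_name = rep(res_names, each = 3L),
    chain_id = chain_id,
    res_seq = rep(seq.int(first_res_seq, length.out = n), each = 3L),
    i_code = " ",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    occupancy = 1, b_factor = 0,
    element = rep(c("N", "C", "C"), n),
    is_hetero = FALSE,
    stringsAsFactors = FALSE
  )
  new_structure(atoms, id = id)
}

#' Append a hetero ligand (and optionally a calcium ion) to a structure
#'
#' Adds a two-atom `LIG` hetero residue and, optionally, a calcium ion
#' whose atom name also strips to `"CA"` — the classic trap for naive
#' C-alpha selection (calcium carries element `CA` and a HETATM record).
#'
#' @param structure A `Structure`.
#' @param chain_id Chain for the ligand (default `"L"`).
#' @param calcium Also add a CA (calcium) ion.
#' @return The extended `Structure`.
#' @export
add_ligand <- function(structure, chain_id = "L", calcium = TRUE) {
  base <- max(structure$atoms$serial)
  lig <- data.frame(
    serial = base + 1:2, name = c(" C1 ", " O1 "), alt_loc = " ",
    res_name = "LIG", chain_id = chain_id, res_seq = 901L, i_code = " ",
    x = c(30, 31.2), y = c(30, 30), z = c(30, 30.5),
    occupancy = 1, b_factor = 0, element = c("C", "O"), is_hetero = TRUE,
    stringsAsFactors = FALSE)
  if (calcium)
    lig <- rbind(lig, data.frame(
      serial = base + 3L, name = "CA  ", alt_loc = " ", res_name = "CA",
      chain_id = chain_id, res_seq = 902L, i_code = " ",
      x = 35, y = 35, z = 35, occupancy = 1, b_factor = 0,
      element = "CA", is_hetero = TRUE, stringsAsFactors = FALSE))
  structure$atoms <- rbind(structure$atoms, lig)
  structure
}

# uniform random rotation matrix from a random unit quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  quaternion_to_rotation(q)
}

quaternion_to_rotation <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

#' Generate a multi-model trajectory with known ground truth
#'
#' Model 1 is the base structure; each subsequent model applies a recorded
#' rigid motion and/or adds Gaussian coordinate noise. With `basins`
#' supplied, each model is instead drawn from one of the given reference
#' conformations (plus noise), and the basin labels are returned — the
#' ground-truth partition for clustering tests.
#'
#' @param base A `Structure` (ignored when `basins` is given).
#' @param n_models Number of models (>= 1).
#' @param rigid Apply a random rigid motion to models 2..n.
#' @param sigma Std-dev of isotropic Gaussian coordinate noise, Angstrom.
#' @param basins Optional list of reference `Structure`s; models cycle
#'   through them.
#' @param seed Integer seed; same spec + seed reproduces the trajectory
#'   exactly.
#' @return List with `structures` (model_no set 1..n), `labels` (basin of
#'   each model, 1 when no basins), and `transforms` (recorded rigid
#'   motions, NULL entries when none).
#' @export
make_trajectory <- function(base, n_models, rigid = TRUE, sigma = 0,
                            basins = NULL, seed = 1L) {
  if (n_models < 1L) stop("n_models must be >= 1")
  set.seed(seed)
  out <- vector("list", n_models)
  labels <- integer(n_models)
  transforms <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    if (is.null(basins)) {
      s <- base
      labels[m] <- 1L
    } else {
      labels[m] <- ((m - 1L) %% length(basins)) + 1L
      s <- basins[[labels[m]]]
    }
    if (m > 1L || !is.null(basins)) {
      if (rigid) {
        R <- random_rotation()
        tr <- stats::runif(3, -5, 5)
        s <- transform_structure(s, R, tr)
        transforms[[m]] <- list(rotation = R, translation = tr)
      }
      if (sigma > 0) {
        k <- nrow(s$atoms)
        s$atoms$x <- s$atoms$x + stats::rnorm(k, sd = sigma)
        s$atoms$y <- s$atoms$y + stats::rnorm(k, sd = sigma)
        s$atoms$z <- s$atoms$z + stats::rnorm(k, sd = sigma)
      }
    }
    s$model_no <- m
    out[[m]] <- s
  }
  list(structures = out, labels = labels, transforms = transforms)
}

# regular ring of given radius in the xy-plane, first atom on +x
ring_coords <- function(k = 6L, radius = 1.39) {
  ang <- 2 * pi * (seq_len(k) - 1L) / k
  cbind(radius * cos(ang), radius * sin(ang), 0)
}

phe_residue_atoms <- function(ring, serial0, res_seq, chain_id) {
  # stub N/CA/CB placed off-ring; geometry of the stub is irrelevant to
  # the frame, it only makes the residue a legal polymer residue
  cg <- ring[1L, ]
  out_dir <- v_unit(cg - colMeans(ring))
  cb <- cg + 1.5 * out_dir
  ca <- cb + 1.52 * v_unit(out_dir + c(0, 0, 0.8))
  nn <- ca + 1.46 * v_unit(out_dir + c(0, 0.7, -0.4))
  xyz <- rbind(nn, ca, cb, ring)
  data.frame(
    serial = seq.int(serial0, length.out = nrow(xyz)),
    name = pad_atom_name(c("N", "CA", "CB",
                           c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
                         "C"),
    alt_loc = " ", res_name = "PHE", chain_id = chain_id,
    res_seq = res_seq, i_code = " ",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    occupancy = 1, b_factor = 0,
    element = c("N", rep("C", nrow(xyz) - 1L)), is_hetero = FALSE,
    stringsAsFactors = FALSE)
}

#' Construct two PHE rings with prescribed stacking geometry
#'
#' Ring A sits in the xy-plane centered at the origin; ring B's centroid is
#' placed at lateral offset `offset` along x and height
#' `sqrt(distance^2 - offset^2)` along z, with its plane tilted by `angle`
#' degrees about the x axis. [stacking_pairs()] on the result recovers
#' `(distance, angle, offset)` exactly (well within 1e-6).
#'
#' @param distance Centroid-centroid distance, Angstrom (> 0).
#' @param angle Inter-plane angle, degrees in [0, 90].
#' @param offset Lateral offset, Angstrom; must satisfy `offset <=
#'   distance`.
#' @return A `Structure` with two PHE residues.
#' @export
make_aromatic_pair <- function(distance = 3.5, angle = 0, offset = 0) {
  if (distance <= 0) stop("distance must be > 0")
  if (angle < 0 || angle > 90) stop("angle must be in [0, 90] degrees")
  if (offset < 0 || offset > distance)
    stop("offset must satisfy 0 <= offset <= distance")
  ringA <- ring_coords()
  h <- sqrt(distance^2 - offset^2)
  a <- angle * pi / 180
  Rx <- matrix(c(1, 0, 0,
                 0, cos(a), -sin(a),
                 0, sin(a), cos(a)), 3L, 3L, byrow = TRUE)
  ringB <- ring_coords() %*% t(Rx)
  ringB <- sweep(ringB, 2L, c(offset, 0, h), "+")
  atoms <- rbind(phe_residue_atoms(ringA, 1L, 1L, "A"),
                 phe_residue_atoms(ringB, 10L, 2L, "A"))
  new_structure(atoms, id = "aromatic_pair")
}

#' Write the ground-truth sidecar of a fixture trajectory
#'
#' Machine-readable TSV with one row per (model, atom): model number, atom
#' serial and exact generated coordinates, plus the model's basin label.
#' Tests compare parsed files against this record.
#'
#' @param trajectory Result of [make_trajectory()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_truth <- function(trajectory, path) {
  rows <- do.call(rbind, lapply(seq_along(trajectory$structures),
    function(m) {
      s <- trajectory$structures[[m]]
      data.frame(model = m, label = trajectory$labels[m],
                 serial = s$atoms$serial, x = s$atoms$x, y = s$atoms$y,
                 z = s$atoms$z)
    }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Round a structure's writable fields to PDB precision
#'
#' Coordinates to 3 decimals, occupancy/B-factor to 2 — the precision of
#' the fixed-column format. A structure rounded this way survives a
#' write/read cycle bit-exactly, which the round-trip tests rely on.
#'
#' @param structure A `Structure`.
#' @return The rounded `Structure`.
#' @export
round_to_pdb_precision <- function(structure) {
  structure$atoms$x <- round(structure$atoms$x, 3)
  structure$atoms$y <- round(structure$atoms$y, 3)
  structure$atoms$z <- round(structure$atoms$z, 3)
  structure$atoms$occupancy <- round(structure$atoms$occupancy, 2)
  structure$atoms$b_factor <- round(structure$atoms$b_factor, 2)
  structure
}
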