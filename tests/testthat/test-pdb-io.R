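ref_line <- "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N"

test_that("parse_atom_lines extracts the fixed columns", {
  at <- parse_atom_lines(ref_line)
  expect_equal(at$serial, 1L)
  expect_equal(at$name, " N  ")
  expect_equal(at$res_name, "ALA")
  expect_equal(at$chain_id, "A")
  expect_equal(at$res_seq, 1L)
  expect_equal(c(at$x, at$y, at$z), c(11.104, 6.134, -6.504))
  expect_false(at$is_hetero)
  het <- sub("^ATOM  ", "HETATM", ref_line)
  expect_true(parse_atom_lines(het)$is_hetero)
})

test_that("blank occupancy/B parse as 1.00/0.00 and short lines are padded", {
  short <- substr(ref_line, 1, 54)  # no occupancy, B, or element
  at <- parse_atom_lines(short)
  expect_equal(at$occupancy, 1)
  expect_equal(at$b_factor, 0)
  expect_equal(at$element, "")
})

test_that("malformed numeric fields name the column span and line", {
  bad <- ref_line
  substr(bad, 31, 38) <- "  xx.xxx"
  expect_error(parse_atom_lines(bad, line_no = 42L), "columns 31-38.*line 42")
})

test_that("is_ca_filter accepts C-alpha, rejects CB and calcium", {
  f <- is_ca_filter()
  ca <- "ATOM      2  CA  ALA A   1      12.000   6.000  -6.000  1.00  0.00           C"
  cb <- "ATOM      5  CB  ALA A   1      12.000   7.000  -6.000  1.00  0.00           C"
  calcium <- "HETATM  900 CA    CA L 902      35.000  35.000  35.000  1.00  0.00          CA"
  expect_true(f(ca))
  expect_false(f(cb))
  expect_false(f(calcium))
})

test_that("filters compose with AND/OR/NOT and bind atoms to their lines", {
  s <- random_fixture_structure(21, n_res = 8L, two_chains = TRUE,
                                ligand = TRUE)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  name_is <- function(nm) new_line_filter(function(l)
    trimws(substr(l, 13, 16)) == nm)
  flt <- filter_or(is_ca_filter(), name_is("N"))
  got <- read_pdb(f, filters = flt)
  # oracle: full parse restricted to the filter applied to raw atom lines
  lines <- readLines(f)
  atom_lines <- lines[grepl("^(ATOM  |HETATM)", lines)]
  full <- read_pdb(f)
  expect_equal(got$atoms, full$atoms[flt(sprintf("%-80s", atom_lines)), ],
               ignore_attr = TRUE)
  # NOT filter complements within the same universe
  got_not <- read_pdb(f, filters = filter_not(flt))
  expect_equal(nrow(got$atoms) + nrow(got_not$atoms), nrow(full$atoms))
})

test_that("empty selection after filtering raises a 'no atoms' error", {
  s <- random_fixture_structure(5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  never <- new_line_filter(function(l) rep(FALSE, length(l)))
  expect_error(read_structures(f, filters = never), "no atoms")
})

test_that("multi-model reading: fast path equals naive per-model parsing", {
  base <- random_fixture_structure(31, n_res = 7L)
  traj <- make_trajectory(base, 6L, rigid = TRUE, sigma = 0.2, seed = 5L)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(lapply(traj$structures, round_to_pdb_precision), f)
  models <- read_structures(f)
  expect_length(models, 6L)
  expect_equal(vapply(models, function(m) m$model_no, 0L), 1:6)
  # naive: re-parse each MODEL block independently
  lines <- readLines(f)
  starts <- which(startsWith(lines, "MODEL"))
  ends <- which(startsWith(lines, "ENDMDL"))
  for (m in seq_along(starts)) {
    blk <- lines[(starts[m] + 1):(ends[m] - 1)]
    naive <- parse_atom_lines(blk[grepl("^(ATOM  |HETATM)", blk)])
    expect_equal(models[[m]]$atoms, naive, ignore_attr = TRUE)
  }
})

test_that("a chemically different model falls back to full parse with warning", {
  base <- random_fixture_structure(32, n_res = 4L)
  m2 <- base
  m2$atoms <- m2$atoms[-2L, ]  # drop one atom
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(list(base, m2), f)
  expect_warning(models <- read_structures(f), "not chemically identical")
  expect_equal(n_atoms(models[[1]]), n_atoms(base))
  expect_equal(n_atoms(models[[2]]), n_atoms(base) - 1L)
})

test_that("alt-loc policy keeps the first conformer unless asked otherwise", {
  l1 <- "ATOM      2  CA AALA A   1      12.000   6.000  -6.000  0.60  0.00           C"
  l2 <- "ATOM      3  CA BALA A   1      12.500   6.000  -6.000  0.40  0.00           C"
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(l1, l2, "END"), f)
  one <- read_pdb(f)
  expect_equal(n_atoms(one), 1L)
  expect_equal(one$atoms$alt_loc, "A")
  both <- read_pdb(f, keep_alt_locs = TRUE)
  expect_equal(n_atoms(both), 2L)
})

test_that("write_pdb round trips and wraps multiple models", {
  structs <- lapply(c(41, 42, 43), random_fixture_structure, n_res = 4L)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(structs, f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "MODEL")), 3L)
  expect_equal(sum(startsWith(lines, "ENDMDL")), 3L)
  # the three "models" are distinct structures, so the reader rightly
  # warns that the fast path does not apply
  back <- suppressWarnings(read_structures(f))
  for (i in 1:3) expect_equal(back[[i]]$atoms, structs[[i]]$atoms)
  # read -> write -> read is a fixed point
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(back, f2)
  expect_equal(readLines(f2), lines)
})

test_that("coordinates of 10000 A or more refuse to format", {
  s <- random_fixture_structure(44)
  s$atoms$x[1] <- 10000
  expect_error(write_pdb(s, withr::local_tempfile(fileext = ".pdb")),
               "10000")
})

test_that("gzip-compressed input is accepted by extension", {
  s <- random_fixture_structure(45)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  gz <- paste0(f, ".gz")
  con <- gzfile(gz, "wt")
  writeLines(readLines(f), con)
  close(con)
  expect_equal(read_pdb(gz)$atoms, s$atoms)
})
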