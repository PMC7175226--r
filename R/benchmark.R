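# Local micro-benchmark harness over the six scripted everyday tasks.
# There is no numeric target: wall-clock numbers are hardware-dependent.
# The harness exists so the whole task surface can be exercised and timed
# in one call; completion, not speed, is what the test suite checks.

#' Run the six-task micro-benchmark on generated fixtures
#'
#' Generates a small fixture set (a multi-model trajectory and two
#' single-model files) and times the six everyday tasks: reading a PDB
#' file, merging CA-only models, computing a contact map, extracting FASTA
#' sequences, tabulating phi/psi angles, and a pairwise crmsd. Timings are
#' reported for information only.
#'
#' @param n_residues Backbone length of the fixture (default 30).
#' @param n_models Trajectory length (default 10).
#' @param seed Seed for the fixture generator.
#' @return data.frame with columns `task` and `seconds`.
#' @export
run_benchmarks <- function(n_residues = 30L, n_models = 10L, seed = 7L) {
  dir <- tempfile("bench")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  base <- build_backbone(rep(-57, n_residues), rep(-47, n_residues))
  traj <- make_trajectory(base, n_models, rigid = TRUE, sigma = 0.3,
                          seed = seed)
  multi <- file.path(dir, "traj.pdb")
  write_pdb(traj$structures, multi)
  single_a <- file.path(dir, "a.pdb")
  single_b <- file.path(dir, "b.pdb")
  write_pdb(traj$structures[[1L]], single_a)
  write_pdb(traj$structures[[2L]], single_b)

  tasks <- list(
    read_pdb = function() read_structures(multi),
    ca_only_multimodel = function() {
      out <- file.path(dir, "ca.pdb")
      write_pdb(lapply(c(single_a, single_b), read_pdb,
                       filters = is_ca_filter()), out)
    },
    contact_map = function() contact_map(read_structures(multi), 8),
    pdb_to_fasta = function() structure_to_sequences(read_pdb(single_a)),
    ramachandran = function() phi_psi(read_pdb(single_a)),
    rmsd = function() crmsd_ca(read_pdb(single_a), read_pdb(single_b))
  )
  seconds <- vapply(tasks, function(f) {
    as.numeric(system.time(f())[["elapsed"]])
  }, 0)
  data.frame(task = names(tasks), seconds = unname(seconds),
             stringsAsFactors = FALSE)
}
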