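# structkit

`structkit` is an R toolkit for everyday structural bioinformatics: reading
and writing PDB coordinate files (including large multi-model trajectories),
extracting sequences, measuring geometry (optimal superposition and crmsd,
backbone φ/ψ dihedrals, residue contact maps, aromatic stacking), clustering
structure ensembles by crmsd with medoid extraction, pairwise global sequence
alignment, and a "one task – one app" command-line suite. It is aimed at
people who process protein models in bulk — simulation trajectories, decoy
sets, web-service backends — and want a single dependency-light library
instead of a collection of one-off scripts.

## What is inside

- **Data model** — a `Structure` holds an ordered, flat atom table (one row
  per atom, file order preserved); the `Chain` → `Residue` hierarchy is
  materialized on demand with `chains()`. Residue identity is
  `(chain_id, res_seq, i_code)`, exactly as numbered in the file; a separate
  internal 1..n index (`residue_index()`) aligns residues with arrays.
- **PDB I/O with line filters** — `read_structures()` applies *line filters*
  (pure predicates over the raw 80-column text, composable with
  `filter_and/or/not`) before parsing, so excluded records are never
  materialized; `is_ca_filter()` selects C-alpha records and rejects calcium
  ions by element. Multi-model files with chemically identical models take a
  fast path: model 1 is parsed fully, later models only swap coordinates,
  occupancy and B-factor into the same topology.
- **Geometry** — `kabsch_superpose()` solves the optimal rigid-body
  superposition in closed form (SVD of the cross-covariance, determinant
  correction so reflections are excluded); the minimized RMSD is the *crmsd*

      crmsd(X, Y) = min over rotations R, translations t of
                    sqrt( (1/n) * sum_i || R x_i + t - y_i ||^2 )

  `phi_psi()` reports the IUPAC backbone torsions
  φ_i = torsion(C_{i−1}, N_i, CA_i, C_i), ψ_i = torsion(N_i, CA_i, C_i,
  N_{i+1}) with the standard Ramachandran classes (Glycine, Proline,
  Pre-Proline, General). `contact_map()` counts, across models, residue
  pairs whose representative distance (CA–CA or minimum inter-atomic) is
  strictly below a cutoff. `ring_frame()` and `stacking_pairs()` describe
  aromatic ring pairs by centroid distance, inter-plane angle
  `acos(|z_a · z_b|)` and lateral offset.
- **Clustering** — `agglomerate()` is a deterministic Lance–Williams
  agglomerator (single/complete/average linkage, lowest-index tie-break);
  `cut_dendrogram()` yields partitions with per-cluster medoids;
  `cluster_ensemble()` chains crmsd matrix → dendrogram → partition, the
  usual workflow for grouping models and picking representatives.
- **Sequences and alignments** — FASTA I/O, per-chain sequence extraction,
  sequence profiles from MSAs, and Needleman–Wunsch global alignment with
  match/mismatch or substitution-matrix scoring.
- **Fixture generators** — `build_backbone()` chains an idealized backbone
  from target φ/ψ by internal-coordinate (NeRF) placement;
  `make_trajectory()` and `make_aromatic_pair()` produce inputs whose ground
  truth is known by construction. The test suite is built entirely on them —
  no downloads.

## Worked example

```r
library(structkit)
helix <- build_backbone(rep(-57, 12), rep(-47, 12))       # ideal alpha-helix
traj  <- make_trajectory(helix, 6, rigid = TRUE, sigma = 0.4, seed = 42)
write_pdb(lapply(traj$structures, round_to_pdb_precision), "traj.pdb")

models <- read_structures("traj.pdb")
length(models)
#> [1] 6
crmsd_ca(models[[1]], models[[2]])
#> [1] 0.8545...   # Angstrom, after optimal superposition

cluster_ensemble(models, k = 2)
#> <ClusterReport> 2 cluster(s); sizes: 5, 1

head(phi_psi(models[[1]]), 3)
#>   chain_id res_seq i_code res_name       phi       psi   klass
#> 1        A       1             ALA        NA -47.00626 General
#> 2        A       2             ALA -57.00776 -46.96666 General
#> 3        A       3             ALA -57.03886 -46.98720 General

contact_map(models, cutoff = 8)
#> <ContactMap> 28 pair(s), cutoff 8.00 A, CA mode, 6 model(s)

stacking_pairs(make_aromatic_pair(3.8, 20, 1.2))[, 7:9]
#>   centroid_distance plane_angle lateral_offset
#> 1               3.8          20            1.2
```

The φ/ψ values recover the construction targets (−57, −47) to much better
than 0.5°; the first φ and last ψ are undefined at chain ends. Contact
counts run from 1 to the number of models; the stacking row returns exactly
the distance/angle/offset used to build the fixture.

## Command line

Every subcommand wraps exactly one library call and writes TSV (one
`#`-prefixed header) or plain text to stdout (`-o FILE` to redirect);
malformed input gives a one-line diagnostic and a non-zero exit.

```sh
CLI=$(Rscript -e 'cat(system.file("scripts", "structkit", package = "structkit"))')
Rscript "$CLI" read_pdb traj.pdb
# traj.pdb: 6 model(s), 1 chain(s), 12 residue(s), 36 atom(s)
Rscript "$CLI" rmsd model_a.pdb model_b.pdb
Rscript "$CLI" contact_map traj.pdb --cutoff 8
Rscript "$CLI" ramachandran traj.pdb
Rscript "$CLI" pdb_to_fasta traj.pdb
Rscript "$CLI" ca_only_multimodel a.pdb b.pdb c.pdb -o merged.pdb
Rscript "$CLI" clust traj.pdb --linkage average --k 2
Rscript "$CLI" stacking complex.pdb --cutoff 6.5
Rscript "$CLI" seqc input.fasta        # or a PDB file
Rscript "$CLI" strc traj.pdb --ca-only -o ca.pdb
```

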