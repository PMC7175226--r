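---
title: "structkit: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{structkit: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structkit)
```

This vignette is the package's own account of what it computes and why the
conventions are what they are. It states no empirical result that the test
suite does not itself compute.

## The data model

A `Structure` is one model of a macromolecule: an ordered, flat atom table
(one row per atom, file order preserved) plus an identity label and model
number. The `Chain → Residue → atom` hierarchy familiar from other
structural toolkits is materialized on demand by `chains()` rather than
stored — for the bulk operations this package targets (filtering, traces,
distance matrices over many models) a flat table is both faster and easier
to keep faithful to the file.

Residue identity is the triple `(chain_id, res_seq, i_code)`: author
numbering is authoritative, may be negative and may repeat across insertion
codes. A parallel internal index (`residue_index()`, 1..n in order of first
appearance) aligns residues with arrays such as contact-map rows, so
downstream code never arithmetics on author numbering.

Two policies the PDB format leaves open:

* **Alternate locations.** By default the reader keeps the
  first-encountered alt-loc per (residue, atom name) — a deterministic
  single-conformer geometry. `keep_alt_locs = TRUE` retains everything.
* **TER and chain identity.** TER records are tolerated and do not split
  chain objects: atoms are grouped by chain identifier in order of first
  appearance. This preserves the invariant that chain ids are unique within
  a model even when HETATM records follow the polymer's TER under the same
  id (the common case for bound ligands).

A C-alpha is an atom whose name strips to `CA` *and* whose element is
carbon or blank. The element test matters: calcium ions also carry the
stripped name `CA`, and a name-only test silently pollutes traces, rmsd and
contact maps. The same rule is applied at the raw-text level by
`is_ca_filter()`.

## Reading PDB text: filters and the fast path

Line filters are pure, vectorized predicates over the raw 80-column text,
composed with `filter_and/or/not`. Filtering happens *before* parsing, so a
rejected record is never materialized — for CA-only workflows that skips
~90% of the numeric parsing. The soundness contract (tested): for any
filter, the filtered parse equals the full parse restricted to the accepted
lines.

Multi-model files from simulations usually contain chemically identical
models. The reader parses model 1 fully; for each later model it compares
the cheap per-line signature `(atom name, residue name, chain id)` plus the
atom count against model 1. On a match it reuses model 1's topology and
swaps in only coordinates, occupancy and B-factor; on a mismatch it falls
back to a full parse of that model with a warning. Verification is cheap
(one string compare per line), so this artifact verifies rather than
trusts — the equivalence of the two paths is asserted by the acceptance
suite on 20-model trajectories.

Lines shorter than 80 columns are right-padded before column extraction;
blank occupancy and B-factor parse as 1.00 and 0.00; `.gz` input is
accepted by extension. Writing formats coordinates `%8.3f`, so any value
representable at three decimals round-trips exactly; magnitudes ≥ 10⁴ Å are
a formatting error rather than silent field overflow.

## Geometry

**Torsions.** `dihedral()` returns the signed torsion in (−180°, 180°] via
`atan2((n1 × n2)·b̂2, n1·n2)`, the IUPAC convention in which a right-handed
α-helix measures φ ≈ −57°. One identity worth recording, because it is easy
to get backwards: the signed torsion is *invariant* under full path
reversal — reversal maps n1 → −n2, n2 → −n1 and flips the axis, leaving
both `atan2` arguments unchanged — while the sign flips under mirror
reflection of the coordinates. The test suite asserts both identities on
1000 random quadruples, which pins the sign convention more tightly than
either alone; during development this caught an implementation whose sign
was consistently mirrored.

**Ramachandran records.** φ is undefined for chain-initial residues and ψ
for chain-final ones (NA, never fabricated). Classes: GLY → Glycine, PRO →
Proline, a residue immediately before a PRO → Pre-Proline, else General.
Identity outranks context: a glycine before a proline is Glycine. Missing
backbone atoms produce a warning and NA angles, not an error — partially
resolved residues are routine in real files.

**Superposition.** `kabsch_superpose()` is the SVD closed form with the
determinant correction that excludes reflections; degenerate (planar or
symmetric) configurations resolve by the SVD's own deterministic
convention. The independent checks are deliberately different mathematics:
the quaternion eigenvalue method (Horn) agrees to 1e−6, and a seeded
quaternion-grid brute force bounds the optimum from above within the grid's
resolution (the test derives the bound `2·sin(θ/2)·r_max` from the sampling
density rather than tuning it).

**Contact maps.** "Within a cutoff" is a *strict* inequality on the
representative distance — CA–CA by default, minimum inter-atomic in
`"any"` mode; both are exposed because conventions differ across the
literature. Intra-chain pairs with internal-index separation < 2 are
excluded by default (sequence neighbours are trivially in contact);
`min_seq_sep = 0` disables the exclusion. Counts aggregate across models
and are bounded by the model count.

**Aromatic frames and stacking.** PHE/TYR use the benzene ring, TRP its
6-membered ring, HIS the imidazole — one well-defined plane per residue.
The frame's z axis is the least-squares plane normal; its sign is fixed
right-handed with respect to the ring-atom ordering, i.e. so that
`z · ((p1 − c) × (p2 − c)) > 0` for the first two ring atoms. (A convention
based on a CG-to-centroid vector crossed with the first-ring-atom vector is
degenerate when CG *is* the first ring atom, which it is for PHE/TYR/HIS.)
Stacking descriptors are `centroid_distance`, `plane_angle =
acos(|z_a·z_b|)` ∈ [0°, 90°] (invariant to flipping either normal), and
`lateral_offset`, the component of the centroid displacement perpendicular
to the *first* ring's normal — the triple that separates parallel stacks
from T-shaped contacts. The default centroid cutoff is 6.5 Å, the upper end
of distances usually accepted as an aromatic interaction; always
overridable.

## Clustering

`agglomerate()` is a plain Lance–Williams agglomerator (single, complete,
average/UPGMA). Determinism is part of the contract: among equal-distance
candidates the lexicographically smallest active index pair merges first.
Average linkage is the default — the customary choice for model-ensemble
clustering. Merge heights are non-decreasing for all three linkages (no
inversions are possible under these updates), and the suite checks the
heights against an independent reference agglomerator on random matrices.

`cut_dendrogram()` needs the distance matrix because cluster
representatives are *medoids* — the member minimizing summed intra-cluster
distance — which is what one actually wants from an ensemble: a real model,
not an average of models. Cutting at `k` undoes the last `k − 1` merges;
cutting at a height keeps merges at exactly that height.

## Sequences, profiles, alignments

A residue is a polymer residue if its three-letter code is a standard amino
acid *or* it carries a C-alpha — so chemically modified residues stay in
the sequence (as `X`) instead of silently truncating chains, and extraction
gives identical sequences on all-atom and CA-only reads of the same file.
Ligand-only chains are omitted.

Profile columns use the additive-pseudocount estimate
`(count + pc) / (n_nongap + A·pc)`; gaps reduce the effective count rather
than being an alphabet symbol (the standard profile convention). An all-gap
column with `pc = 0` is defined as uniform so columns always sum to 1 —
the only self-consistent completion of the formula's 0/0 case.

Alignment is classic Needleman–Wunsch with a linear gap penalty; affine
gaps are deliberately out of scope. The traceback resolves ties
deterministically (diagonal, then gap-in-second, then gap-in-first), and a
tabulated substitution matrix can replace match/mismatch scoring.

## The synthetic-data generators, and what a green test proves

`build_backbone()` chains N–CA–C backbones from target φ/ψ by
internal-coordinate placement with idealized geometry (N–CA 1.458 Å, CA–C
1.525 Å, C–N 1.329 Å; angles 111.2°/116.2°/121.7°; ω fixed at 180°).
Because each target torsion is the very torsion the placement consumes,
measuring the result recovers the targets to ~1e−6° — these structures are
exact oracles for the Ramachandran machinery. `make_trajectory()` applies
recorded rigid motions and/or Gaussian coordinate noise (or draws models
from labelled reference "basins"), so crmsd, fast-path and clustering tests
know their ground truth by construction. `make_aromatic_pair()` places two
phenylalanine rings at an exact (distance, plane angle, offset) triple.
Default noise levels in the tests (σ ≈ 0.2–0.8 Å) sit in the range of
tight decoy-set variation; basin pairs (helix vs. fully extended) are
separated by far more than the noise, which is what makes "exact partition
recovery" a fair requirement.

What the generators do *not* emulate: side chains beyond the constructed
rings, hydrogens, chemically plausible packing, B-factor structure,
disorder, or the many dialect violations of real-world PDB files. A green
suite therefore establishes metric and format correctness on well-formed
input, not robustness to every archival curiosity.

## Numerical choices

* Distance-matrix symmetry tolerance 1e−9 (then exactly symmetrized);
  diagonal must be exactly zero.
* Superposition requires ≥ 3 non-collinear points; collinearity is detected
  from the singular values.
* Torsions require a non-zero central bond; collinear consecutive points
  are an error, not NaN.
* Profile columns sum to 1 within 1e−9 by construction.
* Serial numbers wrap modulo 10⁵ on write (fixed five-column field).
* All tie-breaks (agglomeration candidates, alignment traceback, medoid
  ties, SVD degeneracies) are deterministic; repeated runs of any CLI
  subcommand are byte-identical.

## Known limitations

No mmCIF, no header metadata (SEQRES, HELIX/SHEET, CONECT, ANISOU are
skipped), no bond topology or hydrogen inference, no secondary-structure
assignment, no structure alignment, no affine-gap or local alignment
beyond the documented scope, and clustering implements the generic
linkages rather than any bespoke merge heuristic. The micro-benchmark
harness (`run_benchmarks()`) reports wall-clock timings for the six
everyday tasks but carries no numeric target — timings are
hardware-dependent by nature.
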