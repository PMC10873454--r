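---
title: "Methods: interaction detection, surface profiling, and differential-residue analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interaction detection, surface profiling, and differential-residue analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protrin)
```

# Scope and model

`protrin` implements the computational half of a comparative study design
that asks which sequence and structure features separate one cluster of
homologous enzymes from another — the motivating case being acid-stable
GH10 xylanases versus their acid-sensitive relatives. Four analyses are
chained: a residue interaction network (RIN) census per structure, an
acidic/basic charge profile over the whole protein and its surface, a
conservation-based classification of differential alignment columns with
substitution-set mutant design, and two-sample statistics across clusters
plus clade branch-length summaries on a phylogeny.

All structure-based stages are purely geometric: contacts are defined by
distances between heavy atoms or derived pseudo-atoms (ring centroids,
cation points). No energies, angles, or hydrogens enter the default
criteria. This is a deliberate modelling assumption — the distance-only
rules are reproducible from coordinates alone and robust to structures
(e.g. homology models) that carry no hydrogens; the cost is that some
contacts counted here would fail an angular or energetic filter.

# Interaction detection

Each detector emits at most one edge per residue pair per type, keeping the
minimal qualifying distance (for Van der Waals, the minimal surface gap).
A pair may carry several types. Within a chain, residues closer than
`sequence_separation_min = 2` in author numbering are skipped so covalent
neighbours are never counted as contacts; the limit is configurable.

The per-type rules and default cutoffs are:

* **Hydrogen bonds, 3.5 Å.** Donor-capable N/O heavy atoms against
  acceptor-capable N/O heavy atoms, from a fixed per-residue table:
  backbone N donates (except proline), backbone O and OXT accept,
  side-chain N/O follow standard chemistry, hydroxyls and histidine ring
  nitrogens are both.
* **Van der Waals, gap ≤ 0.5 Å.** Side-chain heavy atoms plus Cβ only, so
  the detector measures packing rather than mirroring the covalent
  backbone. Radii: C 1.70, N 1.55, O 1.52, S 1.80 Å, fixed in the
  configuration and echoed in pipeline reports. Atom pairs covalently
  joined through a detected disulfide (SG–SG and the 1–3 pairs CB–SG′) are
  excluded, mirroring force-field nonbonded exclusion lists; without this a
  disulfide would always double-count as a Van der Waals contact, since any
  S–S bond length sits far inside the 4.1 Å S–S contact reach.
* **Disulfides, 2.5 Å.** Cysteine SG–SG.
* **Ionic, 4.0 Å.** Asp OD1/OD2 and Glu OE1/OE2 (plus C-terminal OXT)
  against Lys NZ, Arg NE/NH1/NH2, His ND1/NE2, and the N-terminal backbone
  N of each chain; opposite signs only. Histidine is counted positively
  charged here, consistent with counting H among the basic residues.
* **π–π stacking, 6.5 Å.** Ring-centroid distance between aromatic
  residues; Phe/Tyr contribute one six-ring centroid, His its imidazole
  (toggleable via `include_his_aromatic`), Trp both its five- and six-ring
  centroids. A Trp can therefore reach a partner through either ring, but
  the pair is still counted once. Pair types are tagged by sorted 1-letter
  codes ("F-F", "F-Y", ...).
* **π–cation, 5.0 Å.** Lys NZ or the Arg guanidinium centroid (CZ, NE,
  NH1, NH2) against a ring centroid. Histidine does not act as a cation by
  default (`his_as_cation`), because its protonation state is unknowable
  from coordinates; it still participates on the aromatic side.

Open choices resolved here: whether the "corresponding atoms" of each
cutoff are atoms, centroids, or group points is fixed as above (donor and
acceptor heavy atoms; SG; charged-group atoms; centroids); angle criteria
exist in the literature for hydrogen bonds and stacking but are omitted so
the rules stay distance-only, which means absolute counts can differ from
tools that apply angular filters. Both His toggles and every cutoff are
arguments of `interaction_config()`.

# Solvent accessibility and charge profiles

`compute_sasa()` is a Shrake–Rupley implementation: each heavy atom's
sphere of radius `r_atom + probe` (probe 1.4 Å, water) is sampled on a
deterministic golden-spiral lattice of `n_sphere_points = 960` points, and
a point is accessible when it lies outside every neighbour's expanded
sphere. There is no random number use, so results are bit-stable.

Because a fixed world-frame lattice is not rotation invariant, coordinates
are first rotated into a canonical principal-axes frame (eigenvectors of
the coordinate second-moment matrix, signs fixed by third moments). For a
generic protein-sized atom cloud this makes SASA invariant under rigid
motion of the input to within floating-point error; for highly symmetric
or degenerate clouds (fewer than three atoms, near-equal eigenvalues) the
canonical frame is ill-defined and invariance is only approximate. An
isolated atom is exact regardless: with no occluders its SASA equals
4π(r + probe)² for any lattice.

Surface classification divides per-residue SASA by the residue-type
theoretical maximum (Tien et al. 2013) and flags residues at relative SASA
≥ `rsasa_threshold = 0.25`. The threshold is a convention, not a measured
quantity; sensitivity can be probed by rerunning at 0.20/0.30, and the
value used is recorded in pipeline reports. Charge profiles count D and E
as acidic, and R, K, H as basic, over all residues and again over the
surface subset; the acidic/basic ratio is reported as missing when no
basic residues exist rather than as infinity.

# Differential residues and mutant design

`classify_columns()` compares a query against a reference across an
aligned homolog cluster that includes the query. For each column where the
query differs from the reference, the column is **group A** when every
cluster member differs from the reference there, **group B** when only a
proper subset does. Gap policy: a gap differs from any residue (and from a
non-gap reference), so insertions and deletions count as differences; a
column gapped in the query yields a record but no mutable query position.
Positions are 1-based throughout, matching the "A113H" style of mutant
nomenclature.

`design_mutants()` writes the reference residue over the query at each
selected position. The operation is idempotent and composes: replacing the
group-A positions and then the group-B positions equals replacing all
differential positions, a property exercised on every synthetic alignment
in the test suite. `split_termini()` supports the half-set designs either
by count (first ⌈k/2⌉ sorted positions to the N half — the tie goes to the
N terminus) or at the sequence midpoint.

Spatially enriched regions are single-linkage connected components of the
selected residues under Cβ distance (Cα for glycine) at
`linkage_cutoff = 10` Å, discarding components smaller than
`min_size = 3`. Published analyses often circle such regions by eye; the
explicit cutoff and minimum size make the surrogate reproducible, and both
are configurable and recorded in reports.

# Cluster statistics

`compare_groups()` follows the F-test-then-t-test recipe: the variance
ratio (larger over smaller) is tested two-sided against the F
distribution; when equal variances are not rejected at α the pooled
two-sample t test is used, otherwise Welch. Both t tests are two-sided.
Degenerate inputs are defined rather than errors: two constant groups with
equal means give t = 0, p = 1; constant groups with different means give
infinite t and p = 0. The compact letter display assigns letters as the
maximal cliques of the pairwise non-significance graph, ordered by the
highest-mean member, so two clusters share a letter exactly when their
pairwise test is not significant. No multiple-testing correction is
applied by default, matching the plain per-pair convention; a Holm mode is
available.

"Average branch length" of a clade has no single convention, so
`clade_branch_stats()` reports both defensible readings: the primary value
is the mean over all edges strictly inside the clade's MRCA subtree
(excluding the MRCA's parent edge), and the mean tip-to-MRCA depth is
always co-reported. Clades must be monophyletic; violations are errors
naming the offending leaves.

# Synthetic data: what it emulates and what it does not

The generators exist so every stage can be verified against planted truth
without downloading anything.

* `make_structure_fixture()` places isolated residue pairs on a 40 Å grid,
  each realizing one interaction at `cutoff − margin` using idealized
  side-chain templates, with decoys at `cutoff + margin` (disulfide decoys
  are pushed outside the S–S Van der Waals reach as well, since a cysteine
  pair just past 2.5 Å is still a packing contact). Margins are capped at
  0.4 Å because a salt bridge planted much closer than 3.6 Å would also
  qualify as a Van der Waals contact. Each unit receives a seeded random
  rotation; output is a legal PDB file, byte-identical for a given seed.
* `make_msa_fixture()` plants group-A columns (all cluster rows differ
  from the reference) and group-B columns (the query plus a uniform-random
  0..n−2 other members differ, keeping the differing set a proper subset);
  all other columns are identical.
* `make_charge_fixture()` shuffles a sequence with an exact D/E, R/K/H,
  and neutral composition.
* `make_tree_fixture()` joins random per-clade topologies on a ladder
  backbone with exponential edge lengths; the fast clade's mean is
  multiplied. The defaults — four clades, base mean edge length 0.13, and
  a 4.5-fold multiplier giving the fast clade a mean near 0.57 — mirror
  the kind of rate contrast seen in a four-cluster enzyme phylogeny where
  one clade evolves several-fold faster.

These fixtures are deliberately unlike real proteins: residues are
isolated, packing is absent, side chains are idealized, alignments have no
phylogenetic correlation between columns, and trees have independent
exponential branch lengths. Passing tests therefore demonstrate that the
detectors, classifiers and statistics implement their stated rules exactly
— not that the rules themselves capture everything about real structures.
In particular, real-structure contact counts depend on model quality and
on conventions (angle filters, surface definitions) that published tools
vary in.

# Numerical choices and test scale

Distance comparisons are exact inequalities on double precision values;
planted fixtures keep geometry at least the margin away from every
boundary, so floating-point noise cannot flip an edge. Edges are
canonically oriented (lower file-order residue first) and sorted by
residue then type, making outputs deterministic and diffable. The
brute-force oracle used in the tests is an independent all-pairs double
loop with its own chemistry tables.

The test suite runs at sizes chosen to exercise every property while
staying quick: 100 random 50-residue structures for detector–oracle
agreement, 100 planted fixture specifications at 0.2 Å margins, 20 rigid
motions for invariance, 10,000 null simulations (n = 10 per group) for the
type-I error of the testing scheme, 50 alignment fixtures for the A/B
recovery and composition properties, and a 2 × 5-structure pipeline run
with a planted three-pair F-F stacking excess. `scripts/acceptance.R`
recomputes the same quantities from scratch under a caller-supplied seed.

# Known limitations

* Distance-only criteria over-count relative to angle-aware detectors;
  absolute edge counts are comparable only within a fixed configuration.
* SASA rotation invariance relies on a well-conditioned principal-axes
  frame; pathological symmetric inputs fall back to the file frame.
* Histidine charge and aromaticity are binary toggles, not pKa models.
* The accession-based worked example (aligning a specific query and
  reference enzyme and counting their differential columns) requires the
  public sequences; the repository ships only the machinery, not the data.
* Mutant design reproduces the selection grammar (all/A/B/halves/regions);
  choosing *which* designs to build remains a scientific decision outside
  the package.
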