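---
title: "Methods: hierarchical maximum-likelihood superposition of polymerase structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical maximum-likelihood superposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polsuper)
```

## The model

`polsuper` superposes families of polymerase structures by maximum
likelihood.  For a superposition set with members $i = 1..m$ and alignment
columns $j = 1..c$, the observed C$\alpha$ coordinates $x_{ij}$ (after the
member's rigid transform $R_i, t_i$) are modelled as draws from a
column-specific isotropic Gaussian:

$$ R_i x_{ij} + t_i \sim \mathcal{N}(\mu_j,\; \sigma_j^2 I_3). $$

Up to constants, the negative log-likelihood is

$$ \mathcal{L} = \sum_j \Big[\, 3\, n_j \log \sigma_j^2 +
   \frac{1}{\sigma_j^2} \sum_{i \in P_j} \lVert R_i x_{ij} + t_i - \mu_j \rVert^2 \Big], $$

where $P_j$ is the set of members present at column $j$ and $n_j = |P_j|$.
`ml_superpose()` minimizes $\mathcal{L}$ by coordinate descent:

1. **Initialization** — every member is fitted to the first member (the
   set's seed, guaranteeing a deterministic frame) by unweighted Kabsch over
   their shared columns.
2. **Mean** — $\mu_j$ is the mean over present members.
3. **Variance** — $\hat\sigma_j^2 = \sum_{i \in P_j} \lVert x_{ij} - \mu_j
   \rVert^2 / (3 n_j)$, floored at $10^{-4}\,\mathrm{\AA}^2$.
4. **Refit** — each member is refitted to $\mu$ by weighted Kabsch with
   per-column weights $1/\hat\sigma_j^2$, over its present columns only.

Each sub-step is the exact minimizer of $\mathcal{L}$ in its block, so the
objective is non-increasing; the iteration stops when the relative change
falls below `tol` (default $10^{-8}$) or after `max_iter` (200) rounds.
Non-convergence is reported through the `converged` flag, never as an error.
Columns present in fewer than two members carry no information and are
dropped before iteration (recorded in `columns_used`); MISSING entries
(alignment gaps, unmodelled residues) are excluded from means, variances and
fits via per-member column masks.

The practical consequence of the variance weighting is that structurally
divergent columns are down-weighted automatically: a flexible loop inflates
its own $\sigma_j^2$ and loses its grip on the rotation, so the fit converges
about the conserved core.  Pinning the weights uniform
(`options = list(uniform_variance = TRUE)`) recovers iterated unweighted
least squares (generalized Procrustes), which the test suite verifies against
an independently coded oracle to $10^{-8}$.

This estimator is a deliberate simplification of the full hierarchical
Bayesian treatment used by dedicated superposition programs: we estimate one
scalar variance per column with a floor rather than anisotropic tensors with
inverse-gamma priors.  The observables this package reports — orientations,
per-column variances, pseudo-B values — are reproduced by the simpler model;
we do not claim bit-compatibility with any external program's output.

### Pseudo B-factors

Positional heterogeneity is exported as $B_j = 8\pi^2 \sigma_j^2$, the
crystallographic temperature factor a position would have if the coordinate
spread across the family were thermal motion ($8\pi^2 \approx 78.9568$).
`mean_structure()` writes one C$\alpha$ pseudo-residue per column with $B_j$
in the B column (capped at 999.99, the fixed-column format's ceiling);
`write_variances()` emits the full listing
(`super/theseus_variances.txt`).

## Residue equivalence

Structures are aligned in three dimensions only after their residues are
matched one-to-one.  Two routes exist:

* **Automatic** (`alignment: AUTO`): the built-in progressive aligner —
  3-mer distances, a UPGMA guide tree (`stats::hclust`, average linkage),
  and profile–profile Needleman–Wunsch with affine gaps (BLOSUM62, gap open
  10, extend 0.5; a gap of length $L$ costs $10 + 0.5L$).  The pairwise
  engine is verified against an independent dynamic-programming
  implementation on random sequences.  Minor misassignments are tolerable by
  design: they surface as high-variance columns and are down-weighted.
* **Curated** (`alignment: <file>`): a CLUSTAL-format alignment, used for
  families whose equivalences need structural judgement (the picornaviral
  branch in the bundled catalog).  Divergent segments may be placed in
  *non-overlapping sections* — columns gapped in every other row — which
  parse as ordinary columns and simply go un-superposed.

`build_correspondence()` requires each alignment row to reproduce its
trace's sequence exactly (an `X` matches anything) and maps each column to a
residue index or MISSING; per-member indices are strictly increasing
(colinearity) and no residue is used twice.

## The alignment tree

A tree configuration (YAML; see `inst/extdata/polymerase_tree.yaml`) names
for every set its parent, seed member, members (`pdb`, `chain`, `file`),
alignment source and region.  Executing a set (Fig.-7-style pipeline in
`run_set()`): read members, extract C$\alpha$ traces, align, build the
correspondence, restrict to the region, `ml_superpose()`, re-anchor, write.

**Anchoring.**  The ML frame is arbitrary, so the family is re-anchored by
the rigid transform $G$ mapping the seed's fitted region coordinates onto
its parent-frame coordinates — *unweighted* Kabsch, because the inherited
frame must be matched exactly rather than statistically.  All member
transforms are premultiplied by $G$; relative geometry is untouched.  Within
`run_tree()` the parent-frame coordinates are taken from the parent's
in-memory result at full double precision, so the seed retains its inherited
frame to $\sim 10^{-14}\,\mathrm{\AA}$ RMSD; reading them from the written
files instead (the standalone fallback) would bottleneck at the 3-decimal
PDB format ($\sim 5\times10^{-4}\,\mathrm{\AA}$).

**Open/closed pivots.**  No special machinery: a pivot is an ordinary
FULL-region set whose children name a *different* member as their seed (the
open-form structure), handing the conformational switch down the tree while
full-structure alignment keeps the subtle active-site change from biasing
the fit.

**Outputs.**  Each member yields the complete original entry — all chains
and heteroatoms — reoriented by its polymerase chain's transform (an entry
with two polymerase chains yields two outputs) under
`<set>/pdb/pdbid_Chain-set.pdb`; representatives are written as upper-case
`NAME.pdb`.  TITLE is the only header retained; symmetry records are never
emitted because reorientation invalidates them.  No check is made for strict
non-crystallographic symmetry: such chains simply produce duplicate
coordinates.  `_readme.txt` lists each member's TITLE, residue ranges and
atom count; `_All_PDBs/` mirrors every `pdb/` output.  All writers are
deterministic, so reruns are byte-identical; the only timestamp lives in the
CLI's `run_manifest.json`, which is excluded from determinism comparisons.

## Spatial analyses

Because all outputs share one frame, fixed anchor coordinates select
equivalent regions in every structure ("expand" semantics, closed boundary
$\le r$):

* motif A aspartate C$\alpha$: $(3.5, -17.0, -11.5)$, radius 2.5 Å — wider
  than motif C's because this aspartate moves between the open and closed
  conformations;
* motif C (GDD) aspartate C$\alpha$: $(10.0, -16.3, -13.8)$, radius 2.0 Å;
* nascent base-pair centre: $(14.5, -4.5, -15.5)$, radius 22 Å for monomer
  trimming (reduce when a neighbouring polymerase chain is caught).

`dd_distance()` is the C$\alpha$–C$\alpha$ separation of the two catalytic
aspartates (nearest Asp to each anchor wins; absence raises a
`no_active_site` condition).  `survey_dd()` emits one record per file,
skipping — never failing on — files without a locatable active site, and
bins distances with 0.1 Å bins spanning at least 5–9 Å; values sitting
exactly on a bin edge are placed in the right-hand bin via an epsilon guard.
Distances are computed in double precision and reported to 2 decimals.

`pool_ions()` collects every metal HETATM (default element set: MG, MN, CA,
ZN, NA, K, SR, CS, CD, CO, NI, PB, LU) into `IONS-<set>.pdb`, each line
tagged after column 80 with its source file; duplicates are kept,
consistent with the no-NCS-check policy.  `assign_ion_sites()` labels ions
by nearest centroid within a 3.0 Å cutoff (else OTHER).  The default
meA/meB/meB$'$ centroids are the package authors' estimates placed around
the catalytic-aspartate anchors — a working default, deliberately exposed
through `ion_site_model()` for override, since no published coordinates
exist for these site centres.

## Synthetic fixtures and what they show

All tests run on generated data with known ground truth; every generator is
a pure function of its spec and seed.

* **Template**: a three-helix bundle (`helical_bundle()`) built from ideal
  helices (rise 1.5 Å, 100°/residue, radius 2.3 Å, the canonical 3.8 Å
  C$\alpha$ spacing).  A single helix would be rod-like and leave rotation
  about its long axis weakly determined — no globular domain behaves that
  way, so the bundle is the more faithful minimal model.
* **Families** (`synth_family()`): members are planted rigid transforms of
  the template plus position-dependent Gaussian noise, with optional
  deletions.  The standard study condition is 20 members with
  $\sigma = 0.1$ Å over a 40-column core and 1.5 Å over 20 loop columns:
  large enough to exercise the down-weighting, small enough that planted
  orientations are recoverable within 1° and 0.1 Å.
* **Trees** (`synth_tree()`): a chain of sets whose regions grow
  13 → 40 → 65 → FULL columns, with region segments spread over different
  helices (as motifs A and C are: distant in sequence, adjacent in space).
  Noise is 0.04 Å through column 65 and 0.3 Å beyond — a conserved fold
  with a divergent tail.  The root seed is planted with the identity
  transform so the common frame equals the template frame and every
  member's true coordinates are known.  Tests assert recovery within three
  times the planted noise over the clean columns.
* **Entries** (`synth_pdb_entry()`): multi-chain PDB files with aspartates
  at (or offset from) the frame anchors, optional RNA, decoy chains, metal
  ions at the site centroids, waters, altlocs and extra MODELs; layouts with
  atom clashes (< 0.5 Å) are rejected.

What passing these tests does *not* show: performance on real polymerase
structures, whose deviations from rigidity are neither Gaussian nor
independent across positions, whose sequences can be hard to align
automatically, and whose crystallographic artifacts (alternate conformers,
unmodelled loops, NCS copies) appear here only in stylized form.  The
curated-alignment path and the skip-and-log policies exist precisely for
those cases, but desk-scale fixtures cannot certify them.

## Numerical and design choices

* Alternate locations: highest occupancy wins, ties broken by altloc
  character order — traces are deterministic single-conformer objects.
  Zero-occupancy atoms and deuterium are ordinary atoms.
* Multi-MODEL files: the first model by default; the inputs of interest are
  crystal structures.
* Residue order is file order (never numeric sort), with insertion codes
  part of the residue identity — non-monotonic author numbering survives.
* Elements are taken from columns 77–78 when present, else inferred from
  the atom-name field per the fixed-column convention; the record kind
  (ATOM/HETATM) distinguishes a calcium ion named `CA` from a C$\alpha$.
* `kabsch_fit()` corrects reflections via the sign of the smallest singular
  value and rejects degenerate (collinear/coincident) point sets detected by
  the ratio of singular values.
* The variance floor ($10^{-4}\,\mathrm{\AA}^2$) keeps weights finite for
  exactly-conserved columns; in the zero-noise limit all variances sit at
  the floor and the fit reduces to least squares.
* Problem sizes in the shipped tests — families of 3–20 members × 20–80
  residues, trees of 2–3 levels × 3–4 members, 10$^5$-trial brute-force
  rotation searches — were chosen as the smallest sizes at which the
  statistical properties under test are unambiguous.
* The configuration format is YAML: one document per tree, explicit member
  lists, human-diffable, and round-trippable by the fixture generators.
* `ml_superpose()` returns a classed S3 object with `print`, `summary`,
  `coef`, `fitted`, `residuals`, `simulate` and `plot` methods, following
  the classic R modelling idiom; `simulate()` draws synthetic members from
  the fitted Gaussian, closing the loop with the fixture generators.

## Known limitations

* No mmCIF input, no assembly/symmetry expansion, no hydrogen handling.
* No structure-based alignment generation: curated alignments must be built
  elsewhere when sequence alignment is insufficient.
* Isotropic per-column variances cannot represent anisotropic flexibility.
* The bundled polymerase catalog fixes the published topology and region
  sizes, but entries the publication does not name are placeholders that a
  curator must fill in before the real tree can be rebuilt, and rebuilding
  the full 646-structure collection additionally requires bulk PDB
  downloads, which this package deliberately does not perform.
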