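---
title: "Template-based prediction of DNA-binding proteins: model and methods"
author: "dnathread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based prediction of DNA-binding proteins: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnathread)
```

## The problem and the approach

Most proteins discovered by sequencing have no experimentally determined
function. One high-value call is whether a protein binds DNA, and — if it
does — where. `dnathread` makes that call at the level of a modeled
protein–DNA complex rather than as a bare two-state label. The idea is
classical template-based function prediction:

1. **Match.** A query sequence is compared against a library of solved
   protein–DNA complex structures. The match confidence is a probability
   (from an external profile–profile fold-recognition tool via its HHR
   report, or from the package's internal fallback aligner).
2. **Thread.** For a confident match, the query sequence is copied onto
   the template's protein coordinates according to the alignment, residue
   for residue, while the template DNA is kept intact. No loops are
   rebuilt and no side chains are packed: the model carries main-chain
   atoms (plus CB) only, which is exactly what the energy function needs.
3. **Score.** The threaded complex is scored with a knowledge-based
   statistical potential between protein main-chain atoms and DNA atoms
   (below). Lower (more negative) totals mean stronger predicted binding.
4. **Decide.** The query is called DNA-binding iff the match probability
   reaches `p_min` *and* the energy is at most `e_max`. Two gates, two
   tunable parameters, nothing else.
5. **Annotate.** For accepted queries, every residue with a heavy atom
   strictly closer than 4.5 Å to a heavy atom of a DNA *base* in the model
   is reported as a predicted DNA-binding residue, and the model itself is
   written as PDB.

The combination matters: fold recognition alone over-predicts (a fold can
be shared by binders and non-binders), and the energy gate removes most of
those false positives at a small cost in sensitivity.

## The statistical potential

The energy is a distance-scaled finite ideal-gas reference-state (DFIRE
family) potential. For protein atom type $i$, DNA atom type $j$ and
distance bin with midpoint $r$:

$$
u(i,j,r) \;=\; -\eta\,\ln
\frac{N_{\mathrm{obs}}(i,j,r) + p}
     {\left(r/r_{\mathrm{ref}}\right)^{\alpha}
      \left(N_{\mathrm{obs}}(i,j,r_{\mathrm{ref}}) + p\right)},
\qquad u \equiv 0 \text{ for } r \ge r_{\mathrm{cut}} .
$$

$N_{\mathrm{obs}}$ are pair counts accumulated over the training
complexes (cross protein–DNA pairs within one complex only). The
denominator is the finite ideal-gas expectation: in a non-interacting
system pair counts grow like $r^{\alpha}\,\Delta r$, with $\alpha = 2$ for
an unbounded gas and $\alpha < 2$ for finite biomolecules. Distances at
which contacts are observed *more* often than the reference predicts get
negative (attractive) energies; depleted distances (e.g. clash-range
bins) get positive ones.

Choices a user can change, with defaults and reasons:

* `alpha = 1.61` — the published DFIRE exponent for finite biomolecular
  systems; `alpha = 2` recovers the pure ideal gas and is used by the
  self-test that the trained energies then vanish on $r^2\Delta r$ counts.
* `r_cut = 15` Å, `width = 0.5` Å — conventional DFIRE-style binning; the
  reference distance $r_{\mathrm{ref}}$ is the midpoint of the last bin
  below the cutoff, which makes the ideal-gas limit exact rather than
  approximate.
* `pseudo_count = 0.5` and `min_pair_total = 20` — regularization for
  sparse bins; type pairs with fewer than 20 total observations are not
  scored at all (their energies are zero).
* **Atom typing.** Protein: `N`, `CA`, `C`, `O`, `CB`, with a virtual CB
  built for glycine at the ideal tetrahedral position (1.53 Å bond). The
  main-chain restriction is what makes threaded models scoreable — those
  are the only coordinates a threading step can copy with confidence.
  CB is included to retain the side-chain direction signal and can be
  switched off (`atom_type_scheme(include_cb = FALSE)`). DNA: one class
  per (base, atom name) for nucleobase atoms, base-independent classes
  for the sugar–phosphate backbone (`OP1`/`OP2` collapse to `OP`).

The published operating threshold `e_max = -8.6` belongs to the
originally distributed potential table. A potential retrained on other
data (including the synthetic fixtures here) lives on its own energy
scale, so thresholds must be recalibrated with
`optimize_thresholds()` — the package treats −8.6 purely as a default
for use with a compatible artifact.

## Decision rule and conventions

* Statistical potentials are negative for attraction, so "affinity above
  threshold" is implemented as $E \le e_{\max}$; both gates accept at
  equality.
* Among the top `K = 10` candidates above `p_min`, all are threaded and
  scored and the lowest energy wins; ties break by higher probability,
  then lexicographic template id, so runs are fully deterministic.
* Energies are totals, not per-residue averages: a single global energy
  threshold implies unnormalized sums. (`score_complex` exposes a
  per-residue decomposition for inspection, and it sums exactly to the
  total.)
* Binding residues are reported in 1-based query numbering; author
  numbering with insertion codes is preserved internally as composite
  keys.
* The interface rule counts DNA *base* heavy atoms only — the backbone is
  excluded — matching the curation rule the template filters use. A
  `contact_atoms = "all_dna"` switch exists because the boundary between
  the two conventions is not always stated in legacy datasets.

## Template library curation

`build_library()` applies the standard curation filters for protein–DNA
template sets: resolution ≤ 3 Å, protein length ≥ 40 residues, ≥ 6
Watson–Crick base pairs, ≥ 5 residues contacting DNA, then removes
redundancy at 35 % pairwise sequence identity. Details we had to pin
down:

* **Sequence identity** is computed from a Needleman–Wunsch global
  alignment (BLOSUM62, gap open 11 / extend 1 — the BLAST defaults) as
  identical positions over the *shorter* sequence length. The shorter-
  sequence denominator keeps domain-versus-chain comparisons honest and
  makes the measure symmetric.
* **Redundancy removal** is greedy: entries are visited longest-first
  (id-lexicographic within ties) and kept iff they are ≤ 35 % identical
  to everything already kept. The survivors are guaranteed mutually
  non-redundant; the procedure is deterministic.
* **Base pairs** are counted by a Watson–Crick criterion of our own
  construction (the curation rule only thresholds the count): nucleotides
  on distinct chains with complementary bases whose glycosidic-face atoms
  (purine N1, pyrimidine N3) lie within 3.5 Å, matched greedily by
  ascending distance, one partner per nucleotide.
* Missing resolution is a violation (`resolution-unknown`), not a pass.

## Leave-one-out with identity exclusion

`leave_one_out()` evaluates each labeled query after removing every
template with sequence identity strictly above the cutoff (0.30 by
default) — including the query itself when it doubles as a template. The
identity of every (target, template) pair that is actually scored is
recorded in the result, and the run asserts internally that none exceeds
the cutoff. Thresholds are either supplied or chosen by exhaustive MCC
maximization over the grid of observed probability × energy values
(ties: higher `p_min`, then lower `e_max`). By default the potential is
trained once on all positive structures, matching the common practice of
a fixed published table; `retrain_per_fold = TRUE` retrains without the
excluded structures for a stricter protocol.

## What the synthetic generator emulates — and what it does not

All tests and the acceptance script run on synthetic fixtures, because
real benchmark sets require external PDB data and profile databases. The
generator (`make_bdna`, `make_complex`, `make_decoy`, `make_benchmark`)
produces:

* an idealized B-form duplex (3.38 Å rise, 36° twist, Watson–Crick face
  atoms 2.9 Å apart, consecutive C1′ atoms ≈ 6.8 Å apart) with a reduced
  but validly named heavy-atom set;
* an idealized α-helical protein (1.5 Å rise, 100°/residue) laid parallel
  to the DNA at a configurable axis offset. The offset controls interface
  size: ≤ 9 Å yields a filter-passing interface (≥ 5 contact residues for
  ≥ 40-residue proteins), 30 Å yields none. These calibration claims are
  themselves asserted in the test suite;
* labeled benchmarks: positive clusters whose within-cluster identity is
  planted by point mutation (hit to within a few percentage points), plus
  shuffled-sequence, protein-only negatives.

Benchmark defaults are chosen once as study conditions: 6 clusters × 2
positives with a 25 % within-cluster homolog (so each target retains
exactly one usable template under the 30 % exclusion), 30 negatives, 10
base pairs, 8 Å interface offset, and 200-residue proteins — domain-scale
sequences long enough that composition-matched shuffles stay clearly
below the 25 % planted homolog identity under global alignment, which is
what makes the planted identity structure of the benchmark meaningful at
all.

What passing on fixtures does **not** show: real proteins are not ideal
helices, real interfaces are not groove-parallel, fixture energies are
not on the published −8.6 scale, and the fallback aligner is not a
profile HMM. Fixture results validate the *machinery* — geometry rules,
reference-state algebra, exclusion logic, decision monotonicity — not
biological accuracy on real data. Benchmark-grade runs need real PDB
templates and real HHR reports.

## Numerical and degenerate-input choices

* Distances bin as `floor(d / width)`, half-open bins; contacts compare
  with strict `<`, thresholds gates with `<=`/`>=` at their stated
  boundaries.
* All-zero count tables, empty alignments, DNA-free models, empty
  residue universes and single-class threshold optimization raise errors
  rather than returning silent zeros; undefined metric denominators are
  flagged (`defined`), with the MCC-is-0 convention when a marginal is
  empty.
* RNA chains (O2′-bearing sugars) are dropped with a warning at parse
  time; waters, ions, hydrogens, alternate locations beyond the first and
  MODEL blocks beyond the first are dropped silently.
* The fallback aligner's pseudo-probability is a logistic map of global
  sequence identity anchored at (identity 0.30 → 0.84) and (1.0 →
  0.999), so the default probability gate has the same meaning in
  fallback mode as with real fold-recognition reports. Records carry
  `source = "fallback"` so downstream consumers can tell.

## Problem sizes used by the self-tests

The test suite and `scripts/acceptance.R` use deliberately small
instances — toy complexes of a few residues for oracle comparisons,
30-to-60-residue helices for potential training, a 42-query benchmark
(12 positives / 30 negatives) for leave-one-out, and 50 repetitions of
the 30-complex native-versus-decoy experiment — sizes at which the
brute-force reference implementations are still exact and fast.

## Known limitations

* No loop modeling, side-chain packing or energy minimization: query
  insertions are simply unmodeled, so coverage (not accuracy) absorbs
  alignment gaps.
* One template per decision; evidence across multiple accepted templates
  is not combined into a consensus interface.
* No mmCIF input, no modified residues or nucleotides, no RNA.
* The fallback aligner is a convenience for running without external
  tools; its probabilities are calibrated but not comparable to
  profile–profile statistics on hard (remote-homology) targets.
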