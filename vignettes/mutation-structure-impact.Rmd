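---
title: "Quantifying mutation-induced RNA structure changes with snvfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mutation-induced RNA structure changes with snvfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvfold)
```

## The problem

A single-nucleotide variant (SNV) in an RNA can reshape the molecule's
whole repertoire of secondary structures. Because RNAs fold into an
ensemble of structures rather than a single one, the right object to
compare between a wildtype and its mutant is the Boltzmann ensemble: the
probability of every base pair `(i, j)` and the probability that each
position is unpaired (its *accessibility*). Variants that substantially
redistribute this ensemble — sometimes called riboSNitches — can disrupt
regulatory elements such as the iron-responsive hairpin of ferritin
mRNAs, or change accessibility around a start codon.

snvfold folds a wildtype sequence and a mutated variant, compares the
two ensembles position by position and pair by pair, scores the overall
aberration, and renders the comparisons.

## The ensemble model

A secondary structure is a set of pairs with the usual restrictions:
each position in at most one pair, no crossing pairs (pseudoknot-free),
only canonical pairs (AU, GC and the GU wobble), and hairpin loops of at
least `h = 3` unpaired nucleotides. Lonely pairs are allowed. A
structure `s` has energy `E(s)` and Boltzmann probability
`exp(-E(s)/RT) / Z`, with `Z` the partition function over all legal
structures.

Pair probabilities are computed exactly by inside/outside dynamic
programming (the McCaskill scheme): the inside pass fills `Q(i, j)` (the
partition function of the subsequence) and `Qb(i, j)` (restricted to
structures in which `(i, j)` pair); the outside pass accumulates, for
every pair, the Boltzmann weight of everything outside it, using the
fact that an enclosed pair has a unique *immediate* enclosing pair, so
the two gap intervals between them fold independently. The result equals
exhaustive enumeration to machine precision, which is exactly how it is
tested: `bruteforce_ensemble()` enumerates every structure of short
sequences and the suite requires agreement below `1e-9` on hundreds of
random sequences under every energy model.

### Energy models

Three models ship, chosen so that every number the package produces can
be verified independently:

* **toy-uniform** — every pair contributes −1.0 kcal/mol, `RT = 1`.
  Small hairpins then have closed-form probabilities, e.g. `GAAAC` has
  exactly two structures and `P(1,5) = e/(1+e) ≈ 0.7310586`.
* **toy-pairtype** — per-pair-type energies (GC/CG −3, AU/UA −2, GU/UG
  −1 kcal/mol, `RT = 1`), so substitutions that exchange pair types
  (GC→GU) reweight rather than delete structures.
* **stacking** — a nearest-neighbor model: a per-pair baseline (0 for
  GC/CG, +0.45 kcal/mol for AU/UA/GU/UG, a terminal-penalty-like term)
  plus a stack term for every pair of adjacent nested pairs, with
  `RT = 0.6163` kcal/mol (37 °C). The stack table
  (`inst/extdata/stacking.params`) adapts Watson–Crick and wobble
  nearest-neighbor free energies from the Turner-lab tables and is
  completed under helix-flip symmetry. Dangling ends, coaxial stacking
  and special hairpin bonuses are deliberately excluded.

The model is a deliberate simplification: it exists to make the
*differential* machinery exact and auditable, not to reproduce any
particular external folding engine's numbers. Absolute probabilities
from the toy models should not be read as predictions for real RNAs;
the differential quantities behave qualitatively like those of full
nearest-neighbor engines because they share the ensemble formalism.

### Folding parameters

* `window` (W, nt) — local folding window. `W >= n` (the default) is
  global folding. With `W < n` every length-W window is folded
  separately and each pair's probability is the unweighted mean over all
  windows fully containing it; pairs near the ends are covered by fewer
  windows, and the divisor is the number of covering windows, not a
  constant.
* `max_span` (L, nt) — maximum pair span `j - i + 1`. With `W = L = n`
  the local machinery reproduces the global fold to `1e-12`, which the
  tests assert.
* `u_lengths` — stretch lengths for accessibility: the probability that
  `u` consecutive positions are simultaneously unpaired, computed as a
  constrained-over-unconstrained partition-function ratio
  `Z_constrained/Z`, where the constrained fold bars the stretch from
  pairing. This naive recomputation is `O(u · n^3)` per profile and was
  chosen over the optimized exterior-loop recursion because it is
  trivially oracle-verifiable; it is exact, not approximate.
* Presets: `preset = "global"` (W = L = n) and `preset = "local"`
  (W = 200, L = 150, typical local-folding practice for long RNAs).

Since Boltzmann weights are represented directly (not in log space),
partition functions overflow for very long, very stable sequences under
the stacking model; the fold then stops with an explicit overflow error.
The default CLI length cap is 2000 nt; the package is designed for
desk-scale analyses of single elements, not transcriptome scans.

## Differential representations

With wildtype matrix `P_wt` and mutant matrix `P_mut` (same folding
parameters — mixing global and local results is an error):

* `delta = P_mut − P_wt`: positive entries are pairs strengthened by
  the mutation, negative entries weakened.
* `weakened = max(0, −delta)`, `strengthened = max(0, delta)`: a
  disjoint, exact decomposition (`strengthened − weakened = delta`).
* the combined triangle matrix: wildtype above the diagonal, mutant
  below — the two ensembles in one dot-plot-style panel.
* `acc_delta = pu_wt − pu_mut`: note the **opposite sign convention** to
  `delta`. Negative values mark positions *more accessible in the
  mutant*. Both conventions are standard in differential structure
  tracks and both are kept deliberately, with axis labels and TSV
  headers naming them explicitly.

Identity edits (e.g. `A4A`) are accepted and produce exactly-zero
differentials — a useful null control exercised by the tests.

## Impact scores

### Ensemble relative entropy

The Kullback–Leibler divergence between the two Boltzmann distributions
is infinite whenever the wildtype supports any structure the mutant
cannot form (a GC→GA edit deletes every structure using that pair). The
package therefore conditions on the **common structure space**
`S_common` — structures legal for both sequences — and reports

* `d_common = Σ_{s∈S_common} q_wt(s) ln(q_wt(s)/q_mut(s))` in nats
  (`d_bits` in bits), where `q_x` is sequence x's Boltzmann
  distribution renormalized over `S_common`;
* `coverage_wt`, `coverage_mut` — the probability mass each full
  ensemble places on `S_common`;
* `infinite_flag` — raised when `coverage_wt < 1`, i.e. when the strict
  unconditional divergence diverges.

This is computed without enumeration:
`d_common = ⟨E_mut − E_wt⟩_{q_wt} / RT + ln(Z'_mut/Z'_wt)`, where the
primed partition functions restrict pairing to jointly-canonical pairs
and the energy expectation decomposes over pair (and stack) features
using restricted-ensemble feature probabilities — for the stacking model
this needs the probability that two adjacent pairs co-occur, which the
outside pass provides directly. The DP agrees with brute-force
enumeration of both ensembles below `1e-9` across random sequences and
all models.

### Region scan and empirical p-values

To localize the change, windows of configurable lengths (default 50 nt,
clipped to `n`) slide over the sequence with stride `step` (default 5).
For each interval the upper-triangle pair probabilities of wildtype and
mutant are compared by Euclidean distance `d` and Pearson correlation
`r`; the scan reports the interval maximizing `d` and the one
minimizing `r`. Ties break toward the smallest start, then the smallest
length. Degenerate intervals are defined explicitly: if either vector
has zero variance, `r = 1` when the vectors are equal and `0`
otherwise.

Significance uses an **exhaustive on-the-fly background**: the scores of
all `3n` single-nucleotide substitutions of the wildtype, each refolded
and rescanned identically, with
`p = (1 + #{background ≥ observed}) / (1 + 3n)` for `d` (`≤` for `r`).
The `+1` correction keeps `p > 0`. This replaces precomputed background
tables binned by GC content and length: it costs `3n` refolds but is
fully reproducible and makes no reference to shipped data. For
calibration studies, `pvalue_calibration()` scores each substitution
against the *other* `3n − 1` (leave-one-out), under which the p-values
are uniform up to ties and the most disruptive variant attains
`1/(3n+1)`; including the scored variant in its own background (as
`empirical_pvalue()` does, per its definition) would floor the minimum
at `2/(3n+1)` instead.

## Visualization

All five figure types (probability and differential heatmaps, circular
chord plots, wildtype-above/mutant-below arc diagrams, accessibility
tracks) are assembled from drawing primitives and written both as
hand-generated SVG and as PNG. The SVG path is byte-deterministic for
fixed input and carries structural metadata (`class` and `data-*`
attributes on cells, chords, ticks and mutation guides), so the test
suite inspects figures structurally instead of comparing pixels.
Conventions: 1-based coordinates everywhere, ticks every 10 nt by
default, red full-length guide lines at mutation positions, grayscale
(white→black) for probabilities and a blue/white/red diverging map for
differences, symmetric about zero with the color limit floored at
±0.1 so near-null results are not amplified. Chords and arcs below
|value| = 1e-3 are dropped for legibility (configurable); the circular
layout starts 5′ at the bottom slightly left and runs clockwise.

## Interoperability and the results bundle

Dot plots are read and written in the ViennaRNA PostScript dialect
(`i j v ubox` lines with `v = sqrt(P)`; `lbox` single-structure entries
are ignored with a warning), so externally produced matrices can be
compared with `--backend dotplot-files` in place of internal folding —
for that backend the relative entropy and p-values (which need the
energy model) are skipped and the log says so. The parser is tested
against a genuine ViennaRNA-written file. TSV exports truncate values
below `1e-7` to zero to bound file size; in-memory values are never
truncated. Each CLI run writes figures, TSVs, the impact JSON, a log, a
config echo, a manifest and a ZIP of the bundle (store-method, written
by the package itself, readable by any unzip).

## Synthetic fixtures

`make_fixture_sequences()` draws random sequences and plants one perfect
complementary stem (4 bp up to the longest that fits, with a ≥3 nt
loop) so every fixture has non-trivial ensemble structure. This is what
the test fixtures emulate: short structured elements with a dominant
helix. They do not emulate long-range tertiary context, modified bases,
kinetic effects, or the length scales of full-length mRNAs — passing
tests demonstrate the correctness of the ensemble mathematics, not
predictive accuracy on real transcripts.

## Problem sizes used by the tests

The suite validates the DP against enumeration on 200 random sequences
of 8–15 nt under all three models, runs the p-value calibration on all
90 substitutions of a seeded 30-mer, and exercises the full CLI on
hairpins of 5–24 nt. These sizes keep the whole suite in well under a
minute while covering every code path; all guarantees checked are
size-independent properties of the algorithms.

## Known limitations

* The energy models are intentionally minimal; no claim of numerical
  agreement with Turner-2004-parameterized engines is made.
* Direct (non-log-space) Boltzmann weighting limits sequence length
  under the stacking model before the partition function overflows.
* Substitutions only — indels would change coordinates and are out of
  scope, as are pseudoknots, genome coordinates and VCF input.
* The windowed-averaging semantics for local folding are a contract of
  this package (unweighted mean over covering windows); other local
  folding tools may weight windows differently.
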