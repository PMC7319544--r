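# snvfold

Differential RNA secondary-structure analysis of point mutations.

Single-nucleotide variants can redistribute an RNA's entire Boltzmann
ensemble of secondary structures — weakening a regulatory hairpin,
opening a protein binding site, or burying a previously accessible
region. Because no single structure represents an RNA, snvfold compares
*ensembles*: it computes base-pair probability matrices and positional
unpaired probabilities (accessibilities) for a wildtype sequence and a
mutated variant by exact partition-function (inside/outside) folding,
derives differential representations, quantifies the aberration, and
renders the comparison. It is aimed at anyone triaging candidate
structure-disrupting variants (riboSNitches) in regulatory RNA
elements.

## What it computes

For a wildtype `x` and a mutant `x'` (mutation codes like `G10A` or
`G10A-C12G`):

* **Ensemble probabilities** — `P(i,j)`, the Boltzmann probability that
  positions i and j pair, via McCaskill inside/outside dynamic
  programming over a pseudoknot-free, canonical-pair structure space
  (hairpin loops ≥ 3 nt); and `pu(i)` (and stretch variants `pu_u`),
  the probability that positions are unpaired, via constrained
  partition functions `Z_constrained/Z`. Global or windowed local
  folding (window W, pair span ≤ L).
* **Differentials** — `Δ(i,j) = P_mut − P_wt`, its exact decomposition
  into weakened/strengthened maps, a combined triangle matrix (WT upper,
  mutant lower), and the accessibility change `pu_wt − pu_mut`.
* **Impact scores** — (1) the ensemble relative entropy
  `d = Σ q_wt ln(q_wt/q_mut)` conditioned on the common structure
  space, with coverages and an infinity flag for the strict divergence;
  (2) a region scan reporting the interval with the largest Euclidean
  distance / smallest correlation between local pair probabilities,
  with empirical p-values `p = (1 + #{bg ≥ obs})/(1 + 3n)` from the
  exhaustive background of all 3n point mutations.
* **Figures** — heatmaps, differential heatmaps, circular chord plots,
  arc diagrams and accessibility tracks, as deterministic SVG plus
  high-resolution PNG.

Three self-contained energy models ship (`toy-uniform`, `toy-pairtype`,
and a nearest-neighbor `stacking` model); every probability the package
produces is validated against exhaustive structure enumeration. See the
vignette (`vignettes/mutation-structure-impact.Rmd`) for the model and
the design decisions.

## Worked example

The 5-nt hairpin `GAAAC` closes a single GC pair. Under the
`toy-pairtype` model (GC = −3 kcal/mol, RT = 1) the ensemble has two
structures, so the pair probability is `e^3/(1+e^3)`:

```r
library(snvfold)
wt <- validate_sequence("GAAAC", "toy-hairpin")
model <- energy_model("toy-pairtype")

pair_probabilities_global(wt, model)$P[1, 5]
#> [1] 0.952574

report <- build_impact_report(wt, "C5U", model,
                              window_lengths = 5, step = 1)
report
#> <impact_report> C5U (model toy-pairtype)
#>   d_common = 0.169823 nats
#>   d_max = 0.221516 in [1, 5], p_d = 0.4375
#>   r_min = 1, p_r = 1
```

Reading: the C5U edit turns the GC pair into a wobble GU, which keeps
the hairpin but weakens it (pair probability drops from 0.9526 to
0.7311, hence the Euclidean distance 0.2215 in the interval [1, 5]).
Both hairpin structures remain legal for both sequences, so the
relative entropy over the (fully covered) common structure space is
finite: 0.1698 nats. Of the 15 possible point mutations of this 5-mer
(the empirical background), 6 score a distance at least as large, so
p = (1+6)/16 ≈ 0.44; the correlation is unchanged (r = 1) because the
single pair only rescales.

## Command line

```sh
Rscript inst/cli/snvfold.R --fasta wt.fa --mutation G10A \
    --model stacking --preset local --out-dir results_G10A
```

writes a results bundle: `pairs.tsv` and `accessibility.tsv` (long
format, sign conventions documented in their headers), `impact.json`,
ViennaRNA-dialect dot plots (`wt_dp.ps`, `mut_dp.ps`), nine figures in
SVG and PNG, a run log, a config echo, a manifest, and `bundle.zip`.
`--backend dotplot-files --wt-dotplot A.ps --mut-dotplot B.ps` runs the
differential analysis on externally produced dot plots instead of
folding internally. Exit codes: 0 success, 1 data error (e.g. the
stated wildtype base does not match the sequence), 2 usage error.

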