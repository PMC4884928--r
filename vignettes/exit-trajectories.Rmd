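---
title: "Methods: multi-trajectory analysis of drug-induced cell-state exit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-trajectory analysis of drug-induced cell-state exit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exitpaths)
```

# The problem and the model

A cell state — proliferative, differentiated, apoptotic — corresponds to a
stable configuration of a gene regulatory network, and a transcriptome is
the measurable proxy for that configuration. When a panel of chemically
unrelated drugs all push a cancer cell population toward the same
differentiated phenotype, the natural question is whether they drive the
cells along one common route in expression state space or along many.
`exitpaths` implements the quantitative side of that question for a study
design with: a drug library screened for differentiation at several doses;
a panel of effective drugs profiled by expression arrays at days 1, 3 and 5;
a pool of untreated replicate arrays standing for day 0; drug–target and
protein–interaction annotation; and binary chemical fingerprints.

The package treats the analysis as five cooperating modules — screening,
trajectory classification, dispersion statistics, drug similarity, and the
CAP-Net network intersection — plus a synthetic-data module that generates
every input with planted structure so that each stage has a ground-truth
validation surface. `run_pipeline()` chains them.

## Screen hit calling

At a reference dose (the top dose by default), each drug's percentage of
differentiated cells and live-cell count are standardized against the
whole library: `z = (x − mean)/sd`, with the sample (n−1) SD — the
convention is fixed here and in the tests. A drug is a hit when
`z_diff > 1.8` **and** `z_tox > −1`; the second criterion removes
compounds that "differentiate" by killing. Both thresholds are exposed
(`select_effective()`); 1.8 is the default because it is the stricter of
the two figure-level criteria in this analysis style and the one under
which the planted screens are constructed.

## Error model and differential calls

`fit_control_model()` estimates, per gene, the mean `x̄_i⁰` and sample SD
`σ_i⁰` over the untreated replicates (14 by default). The model assumes
replicate noise on log2 scale is adequately summarized by a per-gene SD;
no distributional assumption beyond that is used downstream. A value is
differential when `|x_i − x̄_i⁰| > 3σ_i⁰`, with a **strict** inequality at
the boundary. Genes with `σ_i⁰ = 0` make the test undefined:
`is_differential()` raises an error naming them, and the category
assignment excludes them with a warning and a count (`n_excluded`), rather
than silently treating them as significant or not.

With an SD estimated from 14 replicates, the 3σ̂ rule has a realized
false-positive rate of about 0.6–1% per (gene, drug, day) test rather than
the Gaussian 0.27% — the χ²-distributed σ̂ occasionally undershoots. This
matters for interpreting the C5 catch-all category (below), not for the
planted classes, whose effects sit at 6σ.

## Detection filtering

Array expression below the platform's background control is unreliable,
so a gene is kept only if its detection p-value is ≤ 0.05 in at least one
sample anywhere in the time series. Filtering is applied jointly across
all series (a gene detected in any drug's course, or in the controls, is
kept globally); the alternative — filtering each drug's series
independently — would give different gene universes per drug and break
the pairwise machinery.

## Divergent–convergent classification and categories C1–C5

For day *t* and every unordered pair *m* of drugs, `pairwise_diffs()`
computes `d_i^m(t) = |x_i^a(t) − x_i^b(t)|` (M = D(D−1)/2 pairs; 120 for
16 drugs). The differences are **absolute**: the classification compares
their mean to a positive threshold, and signed means could cancel drug
disagreements that are precisely the divergence being measured. A gene is
divergent–convergent (flag D) when `(1/M) Σ_m d_i^m` exceeds `3σ_i⁰` at
day 1 **or** day 3 and falls below `3σ_i⁰` at day 5.

Two more flags are computed from the differential rule: net change N
(differential at day 5 in more than `majority_fraction` of drugs) and
transience T (differential at day 1 or 3 in more than `majority_fraction`
of drugs, but not N). The quorum defaults to 0.5; the aggregation "across
all drug treatments" admits several readings and a majority is the least
committal. The decision table is this package's contract:

| label | rule |
|---|---|
| C1 | D and not N (transient drug-specific excursions, full return) |
| C3 | D and N (drug-specific excursions converging to a new level) |
| C4 | N without D (concordant net change) |
| C2 | T without D (concordant transient) |
| C5 | any remaining gene differential in ≥ 1 drug at ≥ 1 day |
| background | everything else |

C2 and C5 are interpretations: the category scheme distinguishes
divergence, transience and net change, but the literature this follows
does not pin down the residual classes, so C5 deliberately absorbs
everything with *some* differential signal that reaches no quorum. Its
size therefore scales with the 3σ̂ false-positive rate times the number of
tests — on synthetic data roughly 10–20% of background genes land in C5,
and essentially none in C1/C3/C4. Tests assert the planted classes, not
the catch-all.

## Dispersion: modified Pearson correlation

To quantify how dispersed the same-day transcriptomes of different drugs
are, the package uses a Pearson-form correlation in which each gene's
deviation is taken from its own *temporal mean* over that drug's course
(day 0 = control mean, then days 1/3/5) rather than from the sample-wide
mean:

r(a, b) = Σᵢ (aᵢ − m̄ᵢᵃ)(bᵢ − m̄ᵢᵇ) / (‖a − m̄ᵃ‖ ‖b − m̄ᵇ‖)

Each sample is paired with its **own drug's** temporal means. When the
supplied means equal each sample's cross-gene mean, the statistic reduces
exactly to standard Pearson correlation — this identity is a test oracle.
Low mean r at a day means the drugs' transcriptomes point in unrelated
directions relative to their own courses, i.e. divergence.
`subsample_dispersion()` repeats the computation over random gene subsets
(500 genes × 100 repetitions by default) to show the pattern is not an
artifact of particular genes; it is deterministic under its seed.
Degenerate samples (zero deviation norm) raise errors rather than
returning NaN.

## Drug similarity and the shared-target null

Tanimoto (`TS = XY/(X+Y−XY)`), efficiency similarity
(`100 − |E(a)−E(b)|`) and Jaccard index are closed forms with exact
tests. Target sets are filtered at confidence ≥ 0.8, **inclusive** at the
boundary. The shared-target permutation test draws `n_perm` (default
10,000) uniformly random pairs of distinct library drugs and counts how
often a random pair shares at least as many filtered targets as the
tested pair (`k_obs`); exceedance (≥ `k_obs`) rather than exact set
identity is used, the standard permutation statistic. Two numerical
choices:

- the empirical p-value uses the add-one correction
  `p = (1 + exceedances)/(n_perm + 1)`, avoiding p = 0 from a finite
  null;
- the tested pair itself is excluded from the draws (resampled). The pair
  must belong to the library, so without exclusion the null would contain
  the observation and a pair that is the *only* sharer could never reach
  the floor `1/(n_perm+1)`.

The test is only as calibrated as the null distribution is fine-grained:
when drugs carry very few targets the shared count takes a handful of
values and no implementation can reject at close to a nominal α. The
calibration check in the test suite therefore uses libraries whose
per-drug target counts vary widely (uniform on 40..120 over a 400-target
universe), making the achievable p-values nearly uniform; this is a
property of the experimental design, not of the algorithm.

## CAP-Net

For each drug, `build_spnet()` computes the union of the edges on *all*
shortest paths (unweighted hop count, all equal-length ties included)
between the drug's filtered targets and its DEGs — genes at least
1.5-fold changed versus the control mean (`|Δlog2| ≥ log2 1.5`,
inclusive). Edge membership is decided by the distance criterion: edge
(u, v) lies on a shortest s–t path iff `d(s,u) + 1 + d(v,t) = d(s,t)` in
either orientation. This is the edge set of the BFS predecessor DAG —
exactly equivalent to enumerating every tied path, but immune to their
combinatorially explosive number. The equivalence is verified against
brute-force path enumeration on random graphs in the tests. Confidence
scores gate edge inclusion (≥ 0.8 by default, mirroring the target
filter) but never weight the paths: no weighting scheme is part of the
method's definition, so hop count is the contract.

`intersect_spnets()` keeps edges supported by at least `min_support`
drugs (default 2; set it to the number of drugs for the strict all-drug
intersection). Targets and DEGs missing from the network are reported and
skipped — identifier gaps are routine in real annotation databases —
while an empty target or DEG set is an error, since it means the drug
cannot be analysed at all.

`capnet_pvalues()` asks how unusual it is for an edge to lie on the
shortest paths of a *random* connected node pair: `n_null` pairs are
drawn uniformly (disconnected pairs resampled, since they have no path to
compare), and `p = (1 + hits)/(n_null + 1)`. Pair sampling is uniform
over nodes, not degree-matched — the simplest null consistent with
"randomly selected shortest path". One consequence deserves emphasis:
because the null conditions on connectivity, edge significance is only
meaningful when the filtered network has a large connected pair
population. On a very sparse, fragmented background the few connected
pairs concentrate inside small components (including the planted one) and
even genuinely planted edges receive mediocre p-values; on a connected
background, planted backbone edges reach p ≤ 0.015 while typical edges do
not. The test suite therefore evaluates *recovery* (precision/recall
against the planted backbone) in the sparse regime and *significance* in
the connected regime.

# The synthetic-data generators

The generators define the study conditions; their defaults are fixed once
and the tests are run under them.

- **Expression.** 1000 genes × (14 controls + 16 drugs × days 1/3/5) by
  default. Per-gene baseline ~ N(8, 1.5²) log2 units, replicate noise
  Gaussian with `noise_sd = 0.2` (a minimal stand-in for an empirical
  replicate error model). Planted effects are `effect_sd_multiplier = 6`
  noise SDs — the magnitude distribution of real drug effects is unknown,
  so this is a free parameter chosen to make the planted structure
  unambiguous, not an estimate. C1/C3 genes get per-drug random-signed
  excursions ramping to a maximum at day 3 (so divergence peaks there, as
  a mid-course maximum is what makes convergence observable by day 5);
  C3/C4 converge to a common shifted level; C2 is a concordant transient;
  C5 shifts in exactly one drug. A 6σ shift at `noise_sd` 0.2 is 1.2 log2
  units ≈ 2.3-fold, comfortably beyond the 1.5-fold DEG rule.
- **Detection p-values** are near zero for expressed genes and uniform on
  [0.05, 1] for a planted "undetected" fraction (default 5%, drawn from
  background genes so detection filtering is orthogonal to category
  recovery).
- **Screen.** Four doses (0.08/0.4/2/10), ~25% basal spontaneous
  differentiation. Basal fluctuation is uniform on ±7 percentage points —
  bounded by design, so that an unplanted drug can never cross the
  Z > 1.8 criterion and hit recovery is a construction guarantee, while
  planted effective drugs reach 70–90% at top dose with preserved
  viability. Toxic decoys differentiate but lose ~70% of cells at top
  dose.
- **Interaction network.** Erdős–Rényi background (Barabási–Albert
  available via `ppi_model`; recovery must not depend on the degree
  distribution) with confidence weights uniform on [0, 1], plus a planted
  backbone chain at confidence 1.0 from a shared target entry node to a
  planted DEG node. At the default density (200 nodes, p = 0.02) the
  post-filter background is sparse enough that the backbone is the unique
  shortest route in ≈ 99% of seeds.
- **Targets and fingerprints.** Effective drugs share the backbone entry
  node as a high-confidence target; other targets are random with a
  configurable low-confidence fraction to exercise the ≥ 0.8 filter.
  Fingerprints are random bit vectors (1024 bits, density 0.1); drugs in
  a similarity group share a core of set bits sized as s = 2t/(1+t) of
  their bits to realize a target Tanimoto score t.

Determinism is a contract: the same `sim_config(seed)` produces
bit-identical outputs, and every generator restores the caller's RNG
state. The pipeline derives independent per-stage seeds from one global
seed, so adding a stage never changes an earlier stage's draws.

What the generator does **not** emulate: probe-level microarray
artifacts, batch effects, heteroscedastic or heavy-tailed replicate
noise, dose–response pharmacology, correlated gene modules, and the
identifier mismatches of real target/interaction databases. Passing the
planted-recovery tests therefore demonstrates that the algorithms
correctly extract the structure they are defined to extract — not that
real data satisfies these idealizations.

# Problem sizes in the test suite

The suite validates at sizes chosen to keep the statistical assertions
sharp while remaining quick: category recovery pools 10 seeds × 1000
genes × 16 drugs; the SPNet oracle compares against brute-force
enumeration on 100 random graphs of ≤ 12 nodes; backbone recovery uses
10 seeds of the 6-drug, 200-node scenario; dispersion uses 100 × 500-gene
subsamples; the permutation calibration uses 1000 simulated pairs at
2000 draws each. `scripts/acceptance.R` recomputes the same quantities
from scratch under a caller-supplied seed.

# Known limitations

- The C2/C5 semantics are this package's interpretation of an
  under-specified residual classification; results for those two labels
  should be read accordingly.
- The 3σ rule inherits the σ̂ estimation noise of 14 replicates; with few
  replicates the effective per-test false-positive rate is several times
  the nominal Gaussian tail.
- CAP-Net edge p-values are interpretable only on networks with a
  substantial connected pair population (see above), and the uniform pair
  null does not control for target/DEG degree bias.
- The efficiency-similarity transform `100 − |ΔE|` is scale-bound to
  percentages; it is not a calibrated statistical similarity.
- Real fingerprint computation from structures is out of scope; the
  package consumes externally computed fingerprints (or simulates them).
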