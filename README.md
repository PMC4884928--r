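# exitpaths

Multi-trajectory analysis of how non-cytotoxic drugs move cancer cells out
of the proliferative state.

When many different drugs all push a cell population toward the same
phenotype (for example MCF7 breast-cancer cells toward a differentiated,
lipid-vesicle-positive state), the transcriptome time courses they trigger
form a *bundle of trajectories* in gene-expression state space. This
package implements the quantitative machinery for analysing such
multi-perturbation experiments end to end:

- **Screen hit calling.** Per-drug Z-scores of differentiation efficiency
  and viability at a reference dose, with the dual criterion
  `Z_diff > 1.8` and `Z_tox > -1` for selecting effective, non-toxic
  compounds.
- **Error model and differential calls.** Per-gene mean `x̄_i⁰` and sample
  SD `σ_i⁰` from untreated replicate arrays; a gene is up/down-regulated in
  a sample when `|x_i − x̄_i⁰| > 3 σ_i⁰`.
- **Divergent–convergent trajectory classification.** For each gene and
  day, the mean absolute between-drug difference over all `M = D(D−1)/2`
  drug pairs, `(1/M) Σ_m d_i^m`; a gene is divergent–convergent when this
  mean exceeds `3 σ_i⁰` at day 1 or day 3 but falls below `3 σ_i⁰` at
  day 5. Combining this flag with net change and transience yields the
  trajectory categories C1–C5.
- **Dispersion statistics.** A modified Pearson correlation in which each
  gene's deviation is taken from its own temporal mean over a drug's time
  course, computed between all same-day sample pairs and over random
  500-gene subsamples.
- **Drug similarity.** Tanimoto fingerprint similarity
  `TS = XY/(X+Y−XY)`, efficiency similarity
  `Eff-Sim(a,b) = 100 − |E(a)−E(b)|`, Jaccard index `|A∩B|/|A∪B|` of
  high-confidence (≥ 0.8) target sets, and a permutation null for shared
  drug targets.
- **CAP-Net.** Per-drug shortest-path networks (SPNets) between drug
  targets and ≥ 1.5-fold differentially expressed genes on a
  confidence-filtered protein-interaction network (all tied shortest paths
  included); the Commonly Affected Paths Network is the set of edges
  supported by at least two drugs, with empirical edge p-values from
  random shortest-path draws.
- **Synthetic data with planted ground truth.** Generators for every input
  (expression + detection p-values, screen table, PPI network with a
  planted backbone pathway, drug-target table, fingerprints) so that each
  stage can be validated against known structure.

## Worked example

Run the whole pipeline on a simulated study (8 drugs profiled at days
1/3/5 against 14 untreated replicates, screened out of a 60-drug library,
with a planted 3-edge pathway in a 150-node interaction network):

```r
library(exitpaths)
cfg <- run_config(sim = sim_config(n_genes = 500, n_drugs = 8,
                                   ppi_nodes = 150, seed = 11),
                  n_library = 60, n_perm = 2000, n_null = 2000,
                  subsample_genes = 300, subsample_reps = 50, seed = 11)
res <- run_pipeline(cfg, "demo_out")
cat(readLines(res$artifacts["summary"]), sep = "\n")
```

```
# Pipeline summary

- screen hits (Z_diff > 1.8, Z_tox > -1): 8 [drug01, drug04, drug06, drug05, drug07, drug08, drug02, drug03]
- genes after detection filter: 475
- category counts: C1=59, C2=19, C3=58, C4=46, C5=84, background=209
- mean pairwise modified-Pearson r by day: day 1: 0.515; day 3: 0.116; day 5: 0.665
- similarity correlations vs Eff-Sim: TS -0.227, shared-DEG JI 0.477
- CAP-Net: 3 edges, backbone recall 1.00, precision 1.00
```

Reading the output: all 8 planted effective drugs pass both screen
thresholds; the mean between-drug correlation is lowest at day 3 — the
transcriptomes diverge before they converge; the drugs' chemical
similarity carries no information about efficacy similarity while shared
downstream expression does; and the CAP-Net recovers exactly the planted
common pathway, whose edges carry the smallest empirical p-values. All
artifacts (`hits.tsv`, `categories.tsv`, `dispersion.tsv`, `pca.tsv`,
`similarity_pairs.tsv`, `capnet_edges.tsv`, GraphML/SIF exports, a JSON
manifest) land in `demo_out/`; re-running with the same configuration
reproduces them byte for byte.

## Methods

See the vignette source in `vignettes/exit-trajectories.Rmd` for the
model assumptions, parameter choices, what the synthetic generator does
and does not emulate, and known limitations.
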