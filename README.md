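# biogasnet

Downstream analysis of biogas-plant (anaerobic digester) metaproteomes
in R: which methanogenic pathway dominates each digester, and which
microbial co-occurrence structure goes with it.

Agricultural biogas plants run on a microbial food web whose last step,
methanogenesis, proceeds mainly through two routes: **acetoclastic**
(acetate-splitting, e.g. *Methanosarcina*) and **hydrogenotrophic**
(H₂ + CO₂, e.g. *Methanoculleus*). Given a protein-group
relative-abundance table (features × plant:replicate samples) with
KO/species annotation, plus per-plant process metadata, `biogasnet`
provides:

* **Pathway classification (factor F).** Protein abundances of KOs
  unique to each route are summed per sample or plant and
  F = Σ aceto-unique / Σ hydro-unique computed; F ≥ 2.5 ⇒
  acetoclastic, F ≤ 0.4 ⇒ hydrogenotrophic, otherwise both routes
  contribute. KO sets for the three methanogenesis modules
  (acetoclastic / hydrogenotrophic / methylotrophic) are packaged, and a
  16-plant reference KO abundance table ships with the package.
* **Ensemble co-occurrence networks** per pathway class: Pearson,
  Spearman and Kendall correlations plus Bray–Curtis and symmetrized
  Kullback–Leibler dissimilarities; 60% prevalence filter; per-method
  top/bottom candidate edges; consensus support filter (≥ 3 of 5
  methods, majority direction); bootstrap-normal p-values (100
  iterations, per-edge derived seeds); Brown's method for combining the
  dependent per-method p-values; Benjamini–Hochberg control at 0.05.
* **Topological roles**: greedy-modularity module detection, the
  Guimerà–Amaral within-module degree z and participation coefficient
  P_i, role assignment (peripheral / connector / module hub / network
  hub at z = 2.5, P = 0.62), and per-network summary tables.
* **Environmental screens**: Spearman correlation of taxa/functions
  (≥ 0.1% mean abundance) against process parameters at p ≤ 0.01, and an
  iterative VIF < 10 collinearity screen of the metadata.
* **A synthetic-data generator** with known ground truth (planted
  factor-F design, planted co-presence/exclusion pairs, planted
  metadata links) and recovery metrics, so the whole pipeline is
  testable offline.

## Worked example

Classify the 16 packaged reference plants and inspect the result:

```r
library(biogasnet)

ref <- load_reference_ko_table()
kt  <- ref$ko_table
m   <- abundance_matrix(as.matrix(kt[, -(1:3)]) |>
                          `rownames<-`(kt$ko),
                        plant = colnames(kt)[-(1:3)],
                        replicate = rep(1L, 16))
calls <- classify_units(m, mode = "per_replicate")
head(calls[order(calls$F), c("unit_id", "aceto_sum", "hydro_sum", "F", "label")])
#>    unit_id aceto_sum hydro_sum          F            label
#> 9     BP16     0.622    13.227 0.04702502 hydrogenotrophic
#> 13    BP04     1.325    13.295 0.09966153 hydrogenotrophic
#> 6     BP10     1.297     9.012 0.14391922 hydrogenotrophic
#> 3     BP08     1.844    10.899 0.16918983 hydrogenotrophic
#> 2     BP07     2.033    10.548 0.19273796 hydrogenotrophic
#> 4     BP12     2.394    11.349 0.21094370 hydrogenotrophic
table(calls$label)
#>     acetoclastic             both hydrogenotrophic
#>                5                3                8
```

BP16's factor F of 0.047 means its acetoclastic-unique protein mass is
about 5% of the hydrogenotrophic-unique mass — a clearly
hydrogenotrophic digester; the 8/5/3 split reproduces the published
labels for all 16 plants.

End-to-end on synthetic data with known truth:

```r
sim <- simulate_dataset(simulation_config(seed = 1))
res <- run_pipeline(pipeline_config(outdir = "run1", seed = 1), data = sim)
res$summaries           # Table-3-style per-network counts
recovery_report(sim$truth, calls = classify_units(
  aggregate_features(sim$matrix, sim$annotation, "ko"), mode = "per_plant"))
#> $label_accuracy
#> [1] 1
```

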