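# beconcord

Cross-system concordance of Barrett's esophagus expression profiles.

Barrett's esophagus (BE) is a premalignant condition in which the squamous
epithelium of the distal esophagus is replaced by intestinal-type columnar
epithelium under chronic reflux. Its pathogenesis is studied in surrogate
systems — esophageal squamous cell lines (Het-1A, EPC2) treated with
acidified bile salts, and the surgical rat reflux model — whose translational
relevance is routinely questioned. `beconcord` makes that question
quantitative: it defines the human BE molecular profile from multi-dataset
differential expression, converts model-system qPCR measurements into
direction-of-change calls, and scores each system's agreement with the human
panel.

For transcriptomics-minded users: the package is tidyverse-native (tibbles
in and out, pipeable verbs, `tidy()`/`glance()`/`autoplot()` methods) and
ships a seeded synthetic-data generator so the entire pipeline runs and is
tested without any downloads.

## What it computes

* **Differential expression** (`moderated_t()`): per-probe log2 fold change
  between BE and normal groups, with an empirical-Bayes moderated
  t-statistic — the per-gene variance s²_g is shrunk toward a scaled
  inverse-chi-square prior, t = logFC / (s̃_g √(1/n₁ + 1/n₂)) on d_g + d₀
  degrees of freedom, with (d₀, s₀²) estimated by moment matching of
  log s²_g. Benjamini–Hochberg FDR adjustment via `bh_adjust()`.
* **Panel selection** (`select_genes()`): a gene enters the human panel when
  present in every dataset and significant (adjusted p < 0.05) with
  |logFC| > 2 in at least one, all qualifying datasets agreeing in sign.
* **qPCR relative quantification** (`delta_delta_ct()`): RQ = 2^−ΔΔCt with
  dual reference genes (ACTB/GAPDH), majority-rule replicate aggregation,
  and group testing on ΔCt — Student's t for two groups, ANOVA + Dunnett
  many-to-one (exact equicorrelated multivariate t) for more.
* **Direction calls** (`call_direction()`): up/down require both an at
  least two-fold change and p < 0.05; never-amplified targets are `na`.
* **Concordance** (`concordance_fraction()`, `combined_concordance()`,
  `venn_partition()`): fraction of panel genes whose model call matches the
  human direction, with the published denominator convention (`nd` genes
  excluded, `na` counted as non-matches), plus union concordance over
  several systems and exclusive Venn region counts.
* **Simulation** (`simulate_expression()`, `simulate_ct()`): seeded
  generators with known ground truth for both data types.

## Worked example

The package bundles the published evidence table (per-dataset logFC and
adjusted p for 33 candidate genes across three human biopsy microarray
series) and the published cross-system direction profile.

```r
library(beconcord)
library(dplyr)

panel <- select_genes(table1_evidence())
count(panel, decision)
#> # A tibble: 3 × 2
#>   decision          n
#>   <chr>         <int>
#> 1 excluded         10
#> 2 selected_down    10
#> 3 selected_up      13
```

Of the 33 candidates, 23 form the human BE panel: 10 squamous-epithelium
keratins significantly down in BE biopsies and 13 columnar/intestinal genes
(keratins, trefoil factors, mucins, villin) significantly up; 10 candidates
fail the thresholds.

```r
prof <- table5_profile()
bind_rows(
  concordance_fraction(prof, "het1a"),
  concordance_fraction(prof, "epc2"),
  concordance_fraction(prof, "rat"),
  combined_concordance(prof, c("het1a", "epc2"))
) |> select(-matched_genes)
#> # A tibble: 4 × 7
#>   system     matches denominator fraction pct_nearest pct_floor pct_printed
#>   <chr>        <int>       <int>    <dbl>       <dbl>     <dbl>       <dbl>
#> 1 het1a            6          23    0.261          26        26          26
#> 2 epc2            13          23    0.565          57        56          57
#> 3 rat             10          22    0.455          45        45          45
#> 4 het1a+epc2      17          23    0.739          74        73          73
```

Reading: the EPC2 cell line reproduces the human direction for 13 of the 23
panel genes (57%), Het-1A for 6 (26%), the rat model for 10 of the 22 genes
it was assayed on (45%, KRT6 was not determined in the rat), and the two
cell lines together cover 17 of 23 (73.9%, printed 73 under floor
rounding). `plot_concordance()` and `plot_venn()` visualise the reports;
`autoplot()` on a `moderated_t()` fit draws a volcano plot.

The same numbers fall out of the end-to-end route: simulate per-system Ct
tables, quantify with `delta_delta_ct()`, call directions, assemble the
profile with `build_profile_table()`, and score — `run_pipeline()` wires
the stages together from a flat config file, and
`inst/cli/beconcord.R` exposes them as shell subcommands.

## Bundled data

* `table1_evidence()` — per-gene, per-dataset logFC / adjusted p for the
  three biopsy series (GSE13083, GSE34619, GSE1420), transcribed as
  published, with presence flags for genes missing from a platform.
* `table5_profile()` — the 23-gene direction profile across human, Het-1A,
  EPC2 and rat systems (arrow symbols accepted on input and mapped to
  ASCII tokens).

See the vignette (`vignettes/concordance-methods.Rmd`) for the model
details, denominator and rounding conventions, simulation design, and known
limitations.
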