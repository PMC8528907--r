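# specdis

Diversity responses to disturbance in microbial communities.

`specdis` is an R package for microbial ecologists testing the
**specialization-disturbance hypothesis**: disturbance selects against
specialist taxa and favors generalists, so a disturbed community should show
*lower taxonomic diversity* together with *higher functional diversity*.
The package takes ordinary feature count tables — an OTU table
(taxonomy) and a Gene Ontology molecular-function term table (function),
features × samples, TSV — plus a sample metadata table
(`disturbed`/`control`), and produces a summary-table-style comparison of
the two diversity responses.

## What it computes

All diversity is expressed as Hill numbers `^qD` (effective numbers of
equally abundant features), `^qD = (Σ pᵢ^q)^(1/(1−q))`.

* **Taxonomic diversity** — coverage-based rarefaction at order q = 2.
  Every sample is interpolated down to one global target coverage (that of
  the lowest-coverage sample, Good-Turing `Ĉ = 1 − f₁/n`), and the inverse
  Simpson index is computed analytically at the matching subsample size:
  `^2D(m) = [1/m + (1 − 1/m)·ΣXᵢ(Xᵢ−1)/(n(n−1))]⁻¹`.
* **Functional diversity** — the Chao-Shen coverage-adjusted,
  Horvitz-Thompson-corrected Shannon entropy of the GO-term counts,
  exponentiated to `^1D`, an effective number of GO terms.
* **Group comparison** — per-group mean, sample SD and n, an
  Anderson-Darling normality screen (not computed when n < 8), and a
  two-tailed Welch t-test at alpha 0.05. The Welch test operates on
  `(mean, sd, n)` summaries, so published summary rows are directly
  testable (`dwh_diversity_summaries()` ships a set from a published
  oil-spill mesocosm/field comparison).
* **Synthetic experiments** — a generator for specialist/generalist
  communities (many small-repertoire specialists sharing a core function
  pool, few large-repertoire generalists, disturbance as selection on
  repertoire size, multinomial read sampling) producing paired OTU and
  GO-term tables, so the entire pipeline runs with no sequencing data.

## Worked example

```r
library(specdis)

experiment <- generate_experiment(simulation_config())  # reference scenario
report <- run_disturbance_analysis(experiment$taxonomic,
                                   experiment$functional,
                                   experiment$metadata)
report
#> <analysis_report>
#>          index disturbed_mean disturbed_sd disturbed_n disturbed_ad_p
#>   taxonomic_2D          2.177        0.809           5             NA
#>  functional_1D       1598.727      395.965           5             NA
#>  control_mean control_sd control_n control_ad_p welch_t welch_df   welch_p
#>         71.48      9.005         5           NA -17.140    4.065 6.065e-05
#>        500.37     29.887         5           NA   6.185    4.046 3.345e-03
#>  significant
#>         TRUE
#>         TRUE
```

Reading the rows: in the disturbed group the effective number of dominant
OTUs (`taxonomic_2D`, coverage-rarefied inverse Simpson) collapses from
~71 to ~2.2 — abundance has concentrated on the few generalists — while
the effective number of GO molecular functions (`functional_1D`,
Chao-Shen) rises from ~500 to ~1600, because those generalists carry large,
diverse functional repertoires. Both Welch p-values are below 0.05, so
this synthetic disturbance shows exactly the signature the
specialization-disturbance hypothesis predicts. AD p-values are `NA`
because n = 5 < 8 per group. `write_report()` writes the same table as
TSV/JSON with the rarefaction decisions (target coverage, per-sample m).

Single estimators are available directly:

```r
v <- abundance_vector(c(40, 25, 12, 8, 5, 3, 2, 1))
good_turing_coverage(v)$value                              # 0.9895833
rarefied_inverse_simpson(v, size_at_coverage(v, 0.95))$value
chao_shen_effective_functions(v)$value
welch_t_test(group_summary(199, 16.5, 6), group_summary(116, 33.4, 8))
#> <welch_result> t=6.1053  df=10.709  p=8.605e-05  significant at alpha=0.05
```

A thin CLI wraps the same functions
(`exec/specdis simulate|diversity|compare`, see `Rscript exec/specdis`).

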