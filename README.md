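# pepfreq

Spectral-counting differential analysis of endogenous plasma peptidomes.

## What this package is for

When individual plasma samples are fractionated and sampled randomly and
independently by LC–ESI–MS/MS, every peptide-spectrum match (PSM) is one
observation of its parent protein. Counting those observations per gene
symbol turns protein quantification into a counting problem that can be
compared between a disease arm and its matched control with classical
statistics. `pepfreq` is for analysts working with such PSM tables (the
output of search engines like X!TANDEM and SEQUEST, exported to
TSV/CSV): it implements the full downstream workflow from engine output
to differential candidates, with a ground-truth synthetic generator so
the whole pipeline is testable without clinical data.

The core statistic compares the observation frequency of gene symbol
*g* between arms after correcting the control for sampling depth:

    corrected_ctrl(g) = n_ctrl(g) · T_case / T_ctrl
    χ²(g) = (n_case(g) − corrected_ctrl(g))² / (corrected_ctrl(g) + 1)

where `T_case`, `T_ctrl` are the per-stream totals of retained PSMs.
The +1 pseudocount makes the one-cell statistic conservative for rarely
observed symbols. Nominal p-values at 1 df get Benjamini–Hochberg FDR
control within each stream; candidates must satisfy a corrected
difference Δ ≥ 9 counts *and* χ² ≥ 25 (nominal p ≤ 0.001).

Around that core the package provides:

* validated PSM ingestion (modification vocabulary, charge, intensity,
  phospho-site checks), with exact round-tripping result tables;
* the retention rules — inclusive ≥10,000-count precursor filter,
  best-fit deduplication of redundant charge-state correlations, and
  independent TRYP (tryptic) / STYP (S/T/Y-phosphopeptide) streams;
* log10-intensity treatment means/SE/N, one-way ANOVA and additive
  two-way ANOVA (Type II SS) across a 26-panel treatment design, plus
  quantile/box-plot exports;
* sequence utilities: in-silico tryptic digestion (`[RK]|{P}` rule),
  full-trypticity checks, peptide localization, Kyte–Doolittle
  hydropathy profiles;
* network descriptors of protein-interaction edge lists (nodes, edges,
  average degree, average local clustering);
* a synthetic PSM generator emulating the study design (12+12 patients,
  10 fractions, log-normal intensities straddling the filter threshold,
  planted enrichments) with recovery scoring against its truth manifest.

## Worked example

```r
library(pepfreq)

sim <- simulate_experiment(sim_config(n_symbols = 50, enriched_symbols = 5,
                                      seed = 42))
cmp <- run_frequency_comparison(sim$case, sim$control)
cmp$TRYP$records[selected == TRUE,
                 .(gene_symbol, count_case, corrected_control, delta, chi2)]
#>    gene_symbol count_case corrected_control     delta     chi2
#>         <char>      <int>             <num>     <num>    <num>
#> 1:     SYM0005       1640          475.5269 1164.4731 2845.584
#> 2:     SYM0004        818          191.2307  626.7693 2043.585
#> 3:     SYM0003        863          228.2019  634.7981 1758.138
#> 4:     SYM0002        839          232.0265  606.9735 1581.008
#> 5:     SYM0001        824          230.7517  593.2483 1518.624

score_recovery(cmp$TRYP$records, sim$truth)[
  c("sensitivity", "false_positive_fraction")]
#> $sensitivity
#> [1] 1
#>
#> $false_positive_fraction
#> [1] 0
```

All five planted 5-fold enrichments are recovered (`sensitivity` 1) with
no null symbol selected: each selected row shows the raw case count, the
depth-corrected control count, their difference Δ and the pseudocounted
χ² that cleared the Δ ≥ 9, χ² ≥ 25 gate.

The `analysis/` directory holds the same workflow as numbered driver
scripts (`01_simulate.R` … `05_disc1_sequence.R`), each writing its
tables under `results/`.

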