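---
title: "Spectral-counting differential analysis of endogenous plasma peptidomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-counting differential analysis of endogenous plasma peptidomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepfreq)
library(data.table)
```

## The problem

Endogenous tryptic peptides circulate in blood plasma without in-vitro
digestion: they are the footprints of proteolytic processing of plasma
and tissue proteins. When individual patient samples are fractionated
(here, a 10-step organic/water step gradient per sample) and each
fraction is sampled randomly and independently by LC--ESI--MS/MS, every
MS/MS spectrum correlated to a peptide sequence (a peptide-spectrum
match, PSM) becomes one Bernoulli-style observation of its parent
protein. Counting these observations per protein gene symbol --
*spectral counting* -- yields a discrete abundance measure that can be
compared between a disease arm and its matched control with classical
counting statistics, independently of the (noisier) precursor-intensity
scale.

`pepfreq` implements that workflow end to end: PSM ingestion and
validation, retention filtering, redundancy removal, independent
analysis streams for unmodified tryptic peptides (TRYP) and
S/T/Y-phosphorylated tryptic peptides (STYP), observation-frequency
counting with sampling-depth correction, a pseudocounted one-cell
chi-square statistic with FDR control, log10-intensity ANOVA across a
26-panel treatment design, sequence utilities (tryptic digestion,
peptide localization, hydropathy), network descriptors, and a
ground-truth synthetic generator that makes every stage testable without
clinical data.

## The retention and redundancy rules

Three rules decide which PSMs enter the statistics:

* **Intensity threshold.** Only PSMs whose precursor exceeds
  10,000 arbitrary counts (the "E4" rule) are retained. The boundary is
  treated as *inclusive* (`>= 10000`): the sampling-depth totals that
  drive the correction are defined over "`>=` E4" spectra, so the filter
  uses the same convention. The threshold is a `filter_config()`
  parameter.
* **Best-fit deduplication.** A single MS/MS spectrum can be correlated
  to peptides at both +2 and +3 charge, or to different sequences;
  counting a spectrum twice inflates the frequency statistic. Within
  each spectrum id (per engine table) only the highest-scoring record is
  kept. The tie-break -- lower charge, then lexicographically smaller
  peptide, then smaller accession -- is a deterministic convention; any
  fixed rule serves, and this one is recorded so runs are reproducible
  bit for bit.
* **Engine attribution.** When PSM tables carry both X!TANDEM and
  SEQUEST rows, counting restricts to the SEQUEST-attributed table;
  X!TANDEM identifications are carried as annotation. Deduplication is
  applied within each engine's table, never across engines.

The pipeline order is fixed: filter, then dedup, then stream split.
Both filtering and deduplication are idempotent, and the stream split is
an exact partition -- these are tested as properties, not examples.

## The frequency statistic

Let `n_case(g)` and `n_ctrl(g)` be the retained PSM counts for gene
symbol `g` in the two arms, and `T_case`, `T_ctrl` the per-stream totals
of retained PSMs. The arms differ in sampling depth, so the control
count is first rescaled to the case depth:

```
corrected_ctrl(g) = n_ctrl(g) * T_case / T_ctrl
```

The direction of the correction (control rescaled toward case, rather
than the reverse or a midpoint) is the package's reading of the
statistic's asymmetric form below, where the corrected control plays the
role of the expected value; it is applied uniformly and logged in every
run manifest. The per-symbol statistic is then

```
chi2(g) = (n_case(g) - corrected_ctrl(g))^2 / (corrected_ctrl(g) + 1)
```

a one-cell chi-square analogue with a +1 pseudocount in the denominator.
Relative to the textbook `(obs - exp)^2 / exp` the pseudocount shrinks
the statistic, most strongly for rarely observed symbols; the two agree
in the limit of large corrected counts (a tested property). Because the
statistic is not an exact Pearson chi-square, p-values referred to the
1-df chi-square distribution are *nominal*; they are labeled as such and
adjusted by the Benjamini--Hochberg step-up within each stream
separately (the TRYP and STYP streams are analyzed independently
throughout). Tail probabilities of very large statistics underflow to
zero in double precision; they are floored at the smallest positive
double so p- and q-values stay in (0, 1].

Two per-symbol aggregations are emitted when several accessions map to
one symbol: counts are summed and the statistic recomputed
(`chi2_pooled`), and the accession-level statistics are averaged
(`chi2_avg`). The selection gate uses the averaged value, mirroring the
per-symbol averaging convention of the frequency analysis; both columns
are always present so either convention can be inspected.

Candidates are selected when the corrected difference
`delta = n_case - corrected_ctrl` is at least 9 counts *and*
`chi2 >= 25` (nominal p <= 0.001), both inclusive. The difference gate
matters: under strong global enrichment the depth correction deflates
every null symbol's corrected difference below zero, so null symbols
with large chi-square values (driven by negative deltas) are excluded.
A `delta_min` of 10 reproduces the network-illustration variant of the
rule.

## The intensity statistics

Log10-transformed precursor intensity is approximately normal, so
treatment comparisons use means, standard errors (`sd/sqrt(n)`, missing
at n = 1) and fixed-effects ANOVA on the log10 scale. Every retained
PSM counts as one record -- replicate observations of one peptide in one
patient are not pooled, and the record counts are reported so the
convention is visible. One-way ANOVA is the standard decomposition
across treatments. The two-way model over treatment and peptide is
*additive* (no interaction): treatment-by-peptide layouts from sparse
sampling leave many empty cells, making the interaction inestimable.
Type II sums of squares are used for unbalanced data; with zero residual
variance the Type II machinery is bypassed and the factor sums of
squares are computed directly from marginal-model residuals, with the
degenerate fit flagged rather than silently reported. Quantile and
box-plot exports use linear interpolation between order statistics
(quantile type 7), recorded in the output because small-n summaries are
convention-sensitive. Records with missing intensity are rejected at
ingestion, never imputed.

## Sequence utilities

In-silico tryptic digestion cleaves after K or R except before P (the
`[RK]|{P}` rule matching the search engines' trypsin definition; the
no-proline-rule variant is a flag). With no missed cleavages the
products tile the parent exactly, and every product is fully tryptic at
its own location -- both tested as properties. Peptide localization uses
1-based inclusive coordinates. Hydropathy profiles are centered
sliding-window means of the Kyte--Doolittle scale (window 9 by default),
defined where the full window fits.

The bundled DISC1 fixture (`inst/extdata/disc1_nterm_synthetic.fasta`)
is a **synthetic stand-in**, not the database record: it is constructed
so that the two reference peptides of the DISC1 analysis occur at their
reference coordinates (the 35-residue N-terminal peptide at position 1;
ARQCGLDSR at 83--91, tryptically flanked). Tests assert only those
locations. The reported subscript range 1--45 for the 35-residue
N-terminal peptide is internally inconsistent (35 residues cannot span
45 positions), so only the 83--91 location is asserted.

## Network descriptors

Protein-interaction edge lists are summarized by node count, edge count,
average degree (`2E/N`, exact before rounding) and average local
clustering coefficient. Nodes of degree < 2 contribute a local
clustering of 0 to the average (the inclusive convention); excluding
them would change the average, so the convention travels with the
output. Self-loops are rejected, duplicate edges collapse, and summaries
are invariant to edge order. Enrichment testing against annotation
databases is out of scope: edge lists are user-supplied files, and
quantities internal to interaction databases (expected edge counts,
enrichment p-values) are not recomputed.

## The synthetic generator

`simulate_experiment()` emulates the study design rather than any
particular dataset. Defaults are fixed once, as the design conditions:

| parameter | default | rationale |
|---|---|---|
| patients | 12 + 12 | the case/control arm sizes of the design |
| fractions | 10 | the step-gradient depth per patient |
| symbols | 200 | desk-scale namespace, large enough for stable tail estimates |
| enriched symbols | 20 | 10% planted positives |
| enrichment ratio | 5 | a clearly detectable effect; the real effect sizes are unpublished, so this is a test-design choice, not an estimate |
| baseline rate | 2 per peptide/patient/fraction | gives ~240 expected control PSMs per single-peptide symbol, comfortably above the selection gates |
| log10 intensity | Normal(4.5, 0.5), truncated at 10^3.5 | straddles the 10,000-count threshold so the filter removes a known ~14% |
| phospho fraction | 0.2 | a minority STYP stream with enough mass for stream-level tests |
| redundancy rate | 0.1 | exercises deduplication without dominating the tables |

Counts are Poisson per (peptide, patient, fraction) cell -- the design
asserts only log10-normal intensity of the observed data, so the Poisson choice is a
modeling decision, exposed in the configuration. Candidate peptides are
digest products of length 6--30 containing at least one S/T/Y, so a PSM
designated phospho always has a valid site and the realized STYP
fraction converges to the parameter. Patients and fractions are
generated as metadata but pooled for frequency analysis, mirroring the
pooling of sample-fractions per treatment arm. What the generator does
*not* emulate: chromatographic suppression, retention times, engine
score distributions (scores are ordinal draws), shared peptides across
symbols, and inter-patient biological variance beyond Poisson sampling.
Passing recovery tests therefore demonstrate the pipeline's correctness
under its own assumptions, not clinical performance.

Under the default conditions the planted 5-fold enrichments yield
expected case counts several-fold above the corrected control with
chi-square values in the thousands, so sensitivity at the
delta >= 9 / chi2 >= 25 gate is expected near 1, and the +1 pseudocount
keeps the null exceedance of chi2 >= 25 well under 1% -- both are
asserted end to end in the test suite, with the null calibration run at
one peptide per symbol across 20 seeds to keep the suite fast at a
problem size (about 96,000 PSMs per arm per seed) that still gives
stable tail fractions.

## A worked example

```{r example}
sim <- simulate_experiment(sim_config(n_symbols = 50, enriched_symbols = 5,
                                      seed = 42))
cmp <- run_frequency_comparison(sim$case, sim$control)
head(cmp$TRYP$records[, .(gene_symbol, count_case, corrected_control,
                          delta, chi2, qvalue, selected)])
score_recovery(cmp$TRYP$records, sim$truth)[
  c("sensitivity", "false_positive_fraction")]
```

## Numerical choices and limitations

* Integer counts are exact; result tables serialize reals with 15
  significant digits and round-trip to at least 12.
* The chi-square tail at 1 df equals `erfc(sqrt(x/2))`; the
  implementation is checked against that closed form to 1e-12.
* All randomness flows through a single integer seed per generator call;
  `(config, seed)` determines every output byte.
* Shared-peptide apportionment is intentionally out of scope: each PSM
  carries one pre-resolved gene symbol, and how symbols were assigned to
  multi-mapping peptides upstream is the caller's responsibility.
* The statistic's p-values are nominal; rankings and the delta/chi2
  gates, not the absolute p-values, carry the inferential weight.
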