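#' Count observation frequency per gene symbol
#'
#' The observation frequency of a gene symbol is the number of retained
#' spectrum-to-peptide correlations carrying that symbol. Each PSM
#' contributes to exactly one symbol, so the counts sum to the number of
#' input PSMs.
#'
#' @param psms Filtered, deduplicated PSM table.
#' @param by Grouping columns (default `"gene_symbol"`; use
#'   `c("gene_symbol", "protein_accession")` for accession-level counts).
#' @return A `data.table` with the grouping columns and `count`.
#' @export
count_frequency <- function(psms, by = "gene_symbol") {
  dt <- as.data.table(psms)
  if (nrow(dt) == 0)
    return(setnames(data.table(matrix(character(0), 0, length(by))), by)[
      , count := integer(0)][])
  if (any(!nzchar(dt$gene_symbol) | is.na(dt$gene_symbol)))
    stop("empty gene_symbol encountered while counting")
  dt[, .(count = .N), by = by]
}

#' Total retained correlations per arm
#'
#' The per-arm totals of retained MS/MS correlations are the
#' normalization denominators used to correct observation frequency for
#' unequal sampling depth.
#'
#' @param case_psms,control_psms Filtered, deduplicated PSM tables.
#' @return A list with `total_case` and `total_control` (integers).
#' @export
stream_totals <- function(case_psms, control_psms) {
  tot <- list(total_case = nrow(as.data.table(case_psms)),
              total_control = nrow(as.data.table(control_psms)))
  if (tot$total_control == 0)
    warning("control total is 0: the depth correction is undefined")
  tot
}

#' Correct control counts to the case sampling depth
#'
#' Control observation frequencies are rescaled by the ratio of total
#' retained correlations, `count * total_case / total_control`, so that
#' both arms are compared at equal sampling depth.
#'
#' @param count_control Raw control count(s), non-negative.
#' @param totals A list with `total_case` and `total_control`
#'   (see [stream_totals()]).
#' @return Corrected control count(s), real-valued.
#' @export
correct_control <- function(count_control, totals) {
  if (totals$total_control <= 0)
    stop("control total must be positive for depth correction")
  if (any(count_control < 0)) stop("counts must be non-negative")
  count_control * totals$total_case / totals$total_control
}

#' Pseudocounted one-cell chi-square statistic
#'
#' The frequency-comparison statistic
#' `(count_case - corrected_control)^2 / (corrected_control + 1)`.
#' The +1 pseudocount stabilizes symbols with few or no control
#' observations and makes the statistic conservative relative to the
#' textbook one-cell `(obs - exp)^2 / exp`, with which it agrees in the
#' limit of large corrected control counts.
#'
#' @param count_case Case observation frequency, non-negative.
#' @param corrected_control Depth-corrected control frequency,
#'   non-negative.
#' @return The chi-square value(s), >= 0.
#' @export
chi_square_pseudo <- function(count_case, corrected_control) {
  if (any(count_case < 0) || any(corrected_control < 0))
    stop("counts must be non-negative")
  (count_case - corrected_control)^2 / (corrected_control + 1)
}

#' Upper-tail chi-square probability
#'
#' Nominal p-value for a chi-square value at `df` degrees of freedom
#' (default 1, the convention used for the frequency comparison).
#'
#' @param chi2 Chi-square value(s), >= 0.
#' @param df Degrees of freedom (default 1).
#' @return Upper-tail probabilities in (0, 1].
#' @export
chi2_pvalue <- function(chi2, df = 1) {
  if (any(chi2 < 0)) stop("chi2 must be non-negative")
  stats::pchisq(chi2, df = df, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment of p-values to q-values:
#' `q_(i) = min_(j >= i) p_(j) * m / j` over the sorted p-values, mapped
#' back to input order.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return q-values in (0, 1], same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Aggregate accession-level records per gene symbol
#'
#' Multiple accessions may map to one gene symbol. Per (symbol, stream),
#' counts are summed across accessions while the chi-square value is
#' reported as the arithmetic mean of the accession-level values
#' (`chi2_avg`). The statistic recomputed from the summed counts
#' (`chi2_pooled`) is emitted alongside.
#'
#' @param records Accession-level `data.table` with columns
#'   `gene_symbol`, `stream`, `protein_accession`, `count_case`,
#'   `count_control`, `chi2`.
#' @param totals Totals used to re-derive the corrected control for the
#'   pooled statistic (see [stream_totals()]).
#' @return Per-(symbol, stream) `data.table` with summed counts,
#'   `corrected_control`, `delta`, `chi2_avg`, `chi2_pooled` and the
#'   number of contributing accessions `n_acc`.
#' @export
average_chi_per_symbol <- function(records, totals) {
  dt <- as.data.table(records)
  if (nrow(dt) == 0)
    return(data.table(gene_symbol = character(), stream = character(),
                      count_case = integer(), count_control = integer(),
                      corrected_control = numeric(), delta = numeric(),
                      chi2_avg = numeric(), chi2_pooled = numeric(),
                      n_acc = integer()))
  out <- dt[, .(count_case = sum(count_case),
                count_control = sum(count_control),
                chi2_avg = mean(chi2),
                n_acc = .N),
            by = .(gene_symbol, stream)]
  out[, corrected_control := correct_control(count_control, totals)]
  out[, delta := count_case - corrected_control]
  out[, chi2_pooled := chi_square_pseudo(count_case, corrected_control)]
  setcolorder(out, c("gene_symbol", "stream", "count_case", "count_control",
                     "corrected_control", "delta", "chi2_avg", "chi2_pooled",
                     "n_acc"))
  out[]
}

#' Select differential candidates
#'
#' A symbol is selected when its corrected frequency difference and its
#' chi-square value both meet the configured minima (inclusive).
#'
#' @param records Frequency records carrying `delta` and `chi2`.
#' @param config A [selection_config()].
#' @return The selected rows, ordered by descending `chi2` with ties
#'   broken by symbol.
#' @export
select_candidates <- function(records, config = selection_config()) {
  dt <- as.data.table(records)
  if (nrow(dt) == 0) return(copy(dt))
  sel <- dt[delta >= config$delta_min & chi2 >= config$chi2_min]
  setorderv(sel, c("chi2", "gene_symbol"), order = c(-1L, 1L))
  sel[]
}

#' Run the full frequency comparison between two arms
#'
#' The complete spectral-counting pipeline for a case arm against its
#' matched control: intensity filter, engine restriction (SEQUEST counts
#' when both engines are present), best-fit deduplication, independent
#' TRYP/STYP streams, per-stream totals and depth correction,
#' accession-level chi-square, per-symbol aggregation, nominal df=1
#' p-values, Benjamini-Hochberg q-values within each stream, and
#' candidate selection flags.
#'
#' @param case_psms,control_psms Raw PSM tables for the two arms.
#' @param filter_cfg A [filter_config()].
#' @param selection_cfg A [selection_config()].
#' @return A list with per-stream elements (each a list holding `records`
#'   -- the per-symbol table with `selected` flags -- `totals` and
#'   `correction_factor`), plus `streams`, the processed stream names.
#' @export
run_frequency_comparison <- function(case_psms, control_psms,
                                     filter_cfg = filter_config(),
                                     selection_cfg = selection_config()) {
  case_dt <- validate_psm_table(case_psms)
  control_dt <- validate_psm_table(control_psms)

  prep <- function(dt) {
    dt <- filter_min_intensity(dt, filter_cfg)
    # Counting follows the SEQUEST-attributed table when both engines
    # contributed; X!TANDEM identifications ride along as annotation.
    if (nrow(dt) && length(unique(dt$engine)) > 1)
      dt <- dt[engine == "SEQUEST"]
    dedup_best_fit(dt)
  }
  case_streams <- split_streams(prep(case_dt))
  control_streams <- split_streams(prep(control_dt))

  wanted <- if (filter_cfg$stream_mode == "both") c("TRYP", "STYP")
            else filter_cfg$stream_mode
  out <- list()
  for (s in wanted) {
    ca <- case_streams[[s]]
    co <- control_streams[[s]]
    totals <- suppressWarnings(stream_totals(ca, co))
    acc <- merge(
      count_frequency(ca, by = c("gene_symbol", "protein_accession")),
      count_frequency(co, by = c("gene_symbol", "protein_accession")),
      by = c("gene_symbol", "protein_accession"), all = TRUE,
      suffixes = c("_case", "_control"))
    if (nrow(acc) == 0) {
      out[[s]] <- list(records = empty_frequency_records(),
                       totals = totals, correction_factor = NA_real_)
      next
    }
    if (totals$total_control == 0)
      stop("stream ", s, ": control arm has no retained PSMs; ",
           "depth correction undefined")
    setnafill(acc, fill = 0L, cols = c("count_case", "count_control"))
    acc[, stream := s]
    acc[, corrected_control := correct_control(count_control, totals)]
    acc[, chi2 := chi_square_pseudo(count_case, corrected_control)]
    sym <- average_chi_per_symbol(acc, totals)
    # Table-1 convention: the per-symbol chi-square is the accession
    # average; the pooled recomputation is kept as a companion column.
    sym[, chi2 := chi2_avg]
    # very large chi2 underflows the upper tail to 0; floor at the
    # smallest positive double so p and q stay in (0, 1]
    sym[, pvalue := pmax(chi2_pvalue(chi2), .Machine$double.xmin)]
    sym[, qvalue := bh_fdr(pvalue)]
    sym[, selected := delta >= selection_cfg$delta_min &
            chi2 >= selection_cfg$chi2_min]
    setorderv(sym, c("chi2", "gene_symbol"), order = c(-1L, 1L))
    out[[s]] <- list(records = sym[], totals = totals,
                     correction_factor =
                       totals$total_case / totals$total_control)
  }
  out$streams <- wanted
  out
}

empty_frequency_records <- function() {
  data.table(gene_symbol = character(), stream = character(),
             count_case = integer(), count_control = integer(),
             corrected_control = numeric(), delta = numeric(),
             chi2_avg = numeric(), chi2_pooled = numeric(),
             n_acc = integer(), chi2 = numeric(), pvalue = numeric(),
             qvalue = numeric(), selected = logical())
}
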