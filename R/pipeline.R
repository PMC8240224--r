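#' Run the end-to-end case/control comparison and write a results bundle
#'
#' Orchestrates the full analysis for one case arm against its matched
#' control: frequency comparison per stream (filter, dedup, depth
#' correction, chi-square, FDR, selection), optional intensity
#' means/ANOVA for requested symbols, optional network summary of a
#' supplied edge list, and a JSON run manifest capturing every threshold
#' and total so the run can be re-executed from the manifest alone.
#'
#' @param case Path to the case PSM TSV, or a PSM table.
#' @param control Path to the control PSM TSV, or a PSM table.
#' @param out_dir Output directory (created if absent).
#' @param filter_cfg A [filter_config()].
#' @param selection_cfg A [selection_config()].
#' @param design A [treatment_design()].
#' @param anova_symbols Optional character vector of gene symbols for
#'   which per-treatment intensity means and ANOVA tables are written.
#' @param edge_list Optional path to a two-column TSV edge list; its
#'   summary and the summary induced by the selected TRYP candidates are
#'   added to the manifest.
#' @return Invisibly, a list with the per-stream frequency results, the
#'   manifest, and the paths written.
#' @export
run_full_comparison <- function(case, control, out_dir,
                                filter_cfg = filter_config(),
                                selection_cfg = selection_config(),
                                design = treatment_design(),
                                anova_symbols = NULL,
                                edge_list = NULL) {
  load_arm <- function(x, what) {
    if (is.character(x) && length(x) == 1) {
      if (!file.exists(x)) stop("missing ", what, " file: ", x)
      read_psm_table(x)
    } else validate_psm_table(x)
  }
  case_dt <- load_arm(case, "case")
  control_dt <- load_arm(control, "control")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cmp <- run_frequency_comparison(case_dt, control_dt, filter_cfg,
                                  selection_cfg)
  paths <- character(0)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pepfreq")),
    min_intensity = filter_cfg$min_intensity,
    stream_mode = filter_cfg$stream_mode,
    chi2_min = selection_cfg$chi2_min,
    delta_min = selection_cfg$delta_min,
    case_treatment = design$case_id,
    control_treatment = design$control_id,
    streams = list())
  for (s in cmp$streams) {
    res <- cmp[[s]]
    freq_path <- file.path(out_dir, sprintf("frequency_%s.tsv", s))
    write_frequency_table(res$records, freq_path)
    sel_path <- file.path(out_dir, sprintf("candidates_%s.tsv", s))
    fwrite(res$records[selected == TRUE,
                       .(gene_symbol, count_case, corrected_control,
                         delta, chi2, pvalue, qvalue)],
           sel_path, sep = "\t", quote = FALSE)
    paths <- c(paths, freq_path, sel_path)
    manifest$streams[[s]] <- list(
      total_case = res$totals$total_case,
      total_control = res$totals$total_control,
      correction_factor = res$correction_factor,
      n_symbols = nrow(res$records),
      n_selected = sum(res$records$selected))
  }

  if (!is.null(anova_symbols)) {
    rec <- to_intensity_records(
      rbind(filter_min_intensity(case_dt, filter_cfg),
            filter_min_intensity(control_dt, filter_cfg)),
      design)
    for (sym in anova_symbols) {
      tm <- treatment_means(rec, symbol = sym)
      tm_path <- file.path(out_dir, sprintf("means_%s.tsv", sym))
      fwrite(format_real_cols(tm, c("mean", "se")), tm_path, sep = "\t",
             quote = FALSE)
      paths <- c(paths, tm_path)
      sub <- rec[gene_symbol == sym]
      if (length(unique(sub$treatment_id)) >= 2 &&
          any(table(sub$treatment_id) >= 2)) {
        aov1 <- anova_oneway(sub$log10_intensity, sub$treatment_id)
        an_path <- file.path(out_dir, sprintf("anova_oneway_%s.tsv", sym))
        fwrite(as.data.table(aov1$table), an_path, sep = "\t", quote = FALSE)
        paths <- c(paths, an_path)
      }
    }
  }

  if (!is.null(edge_list)) {
    el <- read_edge_list(edge_list)
    manifest$network <- graph_summary(el)[
      c("nodes", "edges", "average_degree", "average_local_clustering")]
    sel_tryp <- cmp$TRYP$records[selected == TRUE, gene_symbol]
    manifest$network_selected <- subnetwork_by_selection(el, sel_tryp)$summary[
      c("nodes", "edges", "average_degree", "average_local_clustering")]
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, manifest_path)
  invisible(list(comparison = cmp, manifest = manifest, paths = paths))
}
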