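#' Configuration for the synthetic PSM generator
#'
#' Defaults emulate the study design of the plasma comparison: 12 case
#' and 12 control patients, 10 step-gradient fractions per patient,
#' log-normal precursor intensities straddling the 10,000-count
#' retention threshold, redundant charge-state correlations, and a
#' phospho-tryptic (STYP) sub-stream. Counts per peptide, patient and
#' fraction are Poisson; enriched symbols have their case rate multiplied
#' by `enrichment_ratio`.
#'
#' @param n_symbols Number of gene symbols (default 200).
#' @param n_peptides_per_symbol Integer range (length-2 vector) of
#'   peptides drawn per symbol from its tryptic digest (default `c(1, 3)`).
#' @param n_patients_case,n_patients_control Patients per arm
#'   (defaults 12 and 12).
#' @param n_fractions Step-gradient fractions per patient (default 10).
#' @param baseline_rate Mean PSM count per peptide per patient per
#'   fraction (Poisson; default 2).
#' @param enriched_symbols Number of symbols with a planted case
#'   enrichment (default 20).
#' @param enrichment_ratio Case/control rate ratio for enriched symbols
#'   (default 5; 1 means a null configuration).
#' @param phospho_fraction Probability that a generated PSM carries one
#'   S/T/Y phosphorylation and thus enters the STYP stream (default 0.2).
#' @param log10_intensity_mean,log10_intensity_sd Parameters of the
#'   log10-normal precursor-intensity model (defaults 4.5 and 0.5).
#' @param intensity_floor Retention threshold the generated intensities
#'   straddle (default 10000); intensities are truncated below at
#'   `intensity_floor * 10^-0.5` so a known fraction falls under the
#'   filter.
#' @param redundancy_rate Probability that a spectrum receives a second,
#'   strictly lower-scoring correlation at the other charge state
#'   (default 0.1).
#' @param seed Integer seed; together with the configuration it
#'   determines every output byte.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_symbols = 200L,
                       n_peptides_per_symbol = c(1L, 3L),
                       n_patients_case = 12L,
                       n_patients_control = 12L,
                       n_fractions = 10L,
                       baseline_rate = 2,
                       enriched_symbols = 20L,
                       enrichment_ratio = 5,
                       phospho_fraction = 0.2,
                       log10_intensity_mean = 4.5,
                       log10_intensity_sd = 0.5,
                       intensity_floor = 10000,
                       redundancy_rate = 0.1,
                       seed = 1L) {
  cfg <- list(n_symbols = as.integer(n_symbols),
              n_peptides_per_symbol = as.integer(n_peptides_per_symbol),
              n_patients_case = as.integer(n_patients_case),
              n_patients_control = as.integer(n_patients_control),
              n_fractions = as.integer(n_fractions),
              baseline_rate = baseline_rate,
              enriched_symbols = as.integer(enriched_symbols),
              enrichment_ratio = enrichment_ratio,
              phospho_fraction = phospho_fraction,
              log10_intensity_mean = log10_intensity_mean,
              log10_intensity_sd = log10_intensity_sd,
              intensity_floor = intensity_floor,
              redundancy_rate = redundancy_rate,
              seed = as.integer(seed))
  if (cfg$n_symbols < 1) stop("n_symbols must be >= 1")
  if (length(cfg$n_peptides_per_symbol) != 2 ||
      cfg$n_peptides_per_symbol[1] < 1 ||
      diff(cfg$n_peptides_per_symbol) < 0)
    stop("n_peptides_per_symbol must be an increasing range of positive ints")
  if (cfg$n_patients_case < 1 || cfg$n_patients_control < 1)
    stop("patient counts must be >= 1")
  if (cfg$n_fractions < 1) stop("n_fractions must be >= 1")
  if (cfg$baseline_rate <= 0 || cfg$enrichment_ratio <= 0)
    stop("rates must be positive")
  if (cfg$enriched_symbols < 0 || cfg$enriched_symbols > cfg$n_symbols)
    stop("enriched_symbols must lie in [0, n_symbols]")
  for (p in c("phospho_fraction", "redundancy_rate"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  if (cfg$intensity_floor <= 0) stop("intensity_floor must be positive")
  if (cfg$log10_intensity_sd <= 0) stop("log10_intensity_sd must be positive")
  structure(cfg, class = "sim_config")
}

# Random parent sequence whose tryptic digest offers at least `need`
# peptides of length 6-30 containing S/T/Y (phospho-capable by
# construction). Retries with longer sequences until satisfied.
random_parent <- function(need) {
  len <- 240L
  repeat {
    seqc <- paste(sample(AA_20, len, replace = TRUE), collapse = "")
    dig <- tryptic_digest(seqc)
    cand <- dig[nchar(peptide) >= 6 & nchar(peptide) <= 30 &
                  grepl("[STY]", peptide)]
    if (nrow(cand) >= need) return(list(sequence = seqc, candidates = cand))
    len <- len + 120L
  }
}

#' Simulate a case/control PSM experiment with known truth
#'
#' Generates paired case and control PSM tables with the statistical
#' structure the analysis pipeline assumes, plus a ground-truth manifest
#' of the planted per-symbol enrichments. Symbols receive random parent
#' protein sequences; their peptides are drawn from the tryptic digest
#' and are therefore fully tryptic by construction. Spectrum ids encode
#' (arm, patient, fraction, serial) so deduplication is auditable, and
#' every output is reproducible from `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @return A list: `case` and `control` (validated PSM tables), `truth`
#'   (a `data.table` with `gene_symbol`, `stream`, `case_rate`,
#'   `control_rate`, `enriched`) and `proteins` (named character vector
#'   of the generated parent sequences).
#' @export
simulate_experiment <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  withr::with_seed(config$seed, simulate_experiment_impl(config))
}

simulate_experiment_impl <- function(cfg) {
  symbols <- sprintf("SYM%04d", seq_len(cfg$n_symbols))
  accessions <- sprintf("ACC%04d.1", seq_len(cfg$n_symbols))
  npep <- if (diff(cfg$n_peptides_per_symbol) == 0)
    rep(cfg$n_peptides_per_symbol[1], cfg$n_symbols)
  else
    sample(cfg$n_peptides_per_symbol[1]:cfg$n_peptides_per_symbol[2],
           cfg$n_symbols, replace = TRUE)

  proteins <- character(cfg$n_symbols)
  pep_tab <- vector("list", cfg$n_symbols)
  for (i in seq_len(cfg$n_symbols)) {
    par <- random_parent(npep[i])
    proteins[i] <- par$sequence
    pick <- par$candidates[sample(nrow(par$candidates), npep[i])]
    pep_tab[[i]] <- data.table(gene_symbol = symbols[i],
                               protein_accession = accessions[i],
                               peptide = pick$peptide)
  }
  names(proteins) <- accessions
  pep_tab <- rbindlist(pep_tab)

  enriched <- c(rep(TRUE, cfg$enriched_symbols),
                rep(FALSE, cfg$n_symbols - cfg$enriched_symbols))
  ratio <- ifelse(enriched & cfg$enrichment_ratio != 1,
                  cfg$enrichment_ratio, 1)
  truth <- data.table(gene_symbol = symbols, stream = "TRYP",
                      case_rate = cfg$baseline_rate * ratio,
                      control_rate = cfg$baseline_rate,
                      enriched = enriched & cfg$enrichment_ratio != 1)

  sym_rate <- setNames(truth$case_rate, symbols)
  gen_arm <- function(arm, n_patients, treatment_id, rate_by_symbol) {
    cells <- CJ(patient = seq_len(n_patients),
                fraction = seq_len(cfg$n_fractions),
                pep_row = seq_len(nrow(pep_tab)))
    cells[, gene_symbol := pep_tab$gene_symbol[pep_row]]
    cells[, lambda := rate_by_symbol[gene_symbol]]
    cells[, n_psm := rpois(.N, lambda)]
    cells <- cells[n_psm > 0]
    idx <- rep(seq_len(nrow(cells)), cells$n_psm)
    psm <- cells[idx, .(patient, fraction, pep_row)]
    n <- nrow(psm)
    if (n == 0) return(empty_psm_table())
    psm[, peptide := pep_tab$peptide[pep_row]]
    psm[, protein_accession := pep_tab$protein_accession[pep_row]]
    psm[, gene_symbol := pep_tab$gene_symbol[pep_row]]
    psm[, pep_row := NULL]

    # log10-normal intensity, truncated below at floor * 10^-0.5
    lo <- log10(cfg$intensity_floor) - 0.5
    u <- runif(n, pnorm(lo, cfg$log10_intensity_mean, cfg$log10_intensity_sd),
               1)
    psm[, precursor_intensity :=
          10^qnorm(u, cfg$log10_intensity_mean, cfg$log10_intensity_sd)]

    styp <- runif(n) < cfg$phospho_fraction
    mods <- character(n)
    if (any(styp)) {
      # S/T/Y sites computed once per distinct peptide, then one site
      # drawn uniformly per STYP record
      upep <- unique(psm$peptide[styp])
      site_map <- lapply(gregexpr("[STY]", upep), as.integer)
      names(site_map) <- upep
      site_list <- site_map[psm$peptide[styp]]
      lens <- lengths(site_list)
      pick <- floor(runif(length(lens)) * lens) + 1L
      flat <- unlist(site_list, use.names = FALSE)
      pos <- flat[cumsum(lens) - lens + pick]
      res <- substring(psm$peptide[styp], pos, pos)
      mods[styp] <- sprintf("%d:phospho_%s", pos, res)
    }
    psm[, modifications := mods]
    psm[, charge := sample(c(2L, 3L), n, replace = TRUE)]
    psm[, score := round(runif(n, 1, 10), 4)]
    psm[, spectrum_id := sprintf("%s-P%02d-F%02d-%06d", arm, patient,
                                 fraction, seq_len(n))]
    psm[, sample_id := sprintf("%s-P%02d", arm, patient)]
    psm[, fraction := sprintf("F%02d", fraction)]
    psm[, treatment_id := treatment_id]
    psm[, engine := "SEQUEST"]

    # redundant second correlation at the other charge, strictly lower score
    dup <- psm[runif(n) < cfg$redundancy_rate]
    if (nrow(dup)) {
      dup[, charge := ifelse(charge == 2L, 3L, 2L)]
      dup[, score := round(score - runif(.N, 0.01, 0.5), 4)]
      psm <- rbind(psm, dup)
    }
    setcolorder(psm, PSM_COLUMNS)
    setorderv(psm, c("spectrum_id", "charge"))
    validate_psm_table(psm)
  }

  case <- gen_arm("AD", cfg$n_patients_case, 3L, sym_rate)
  control <- gen_arm("CT", cfg$n_patients_control, 1L,
                     setNames(truth$control_rate, symbols))
  list(case = case, control = control, truth = truth, proteins = proteins)
}

empty_psm_table <- function() {
  validate_psm_table(data.table(
    spectrum_id = character(), sample_id = character(),
    fraction = character(), treatment_id = integer(),
    peptide = character(), modifications = character(),
    charge = integer(), engine = character(), score = numeric(),
    precursor_intensity = numeric(), protein_accession = character(),
    gene_symbol = character()))
}

#' Score recovery of planted enrichments
#'
#' Compares the candidates selected by the frequency comparison with the
#' generator's truth manifest. Sensitivity is the fraction of enriched
#' symbols selected; the false-positive fraction is the fraction of null
#' symbols selected. Symbols absent from the records (never observed)
#' count as unselected.
#'
#' @param frequency_records Per-symbol records with `gene_symbol`,
#'   `delta` and `chi2` (one stream).
#' @param truth Truth manifest from [simulate_experiment()].
#' @param selection_cfg A [selection_config()].
#' @return A list with `sensitivity`, `false_positive_fraction`,
#'   `n_enriched`, `n_null` and `selected_symbols`.
#' @export
score_recovery <- function(frequency_records, truth,
                           selection_cfg = selection_config()) {
  rec <- as.data.table(frequency_records)
  tru <- as.data.table(truth)
  stray <- setdiff(rec$gene_symbol, tru$gene_symbol)
  if (length(stray))
    stop("records contain symbol(s) outside the truth namespace: ",
         paste(head(stray, 5), collapse = ", "))
  sel <- select_candidates(rec, selection_cfg)$gene_symbol
  enriched <- tru$gene_symbol[tru$enriched]
  null_sym <- tru$gene_symbol[!tru$enriched]
  list(
    sensitivity = if (length(enriched))
      length(intersect(sel, enriched)) / length(enriched) else NA_real_,
    false_positive_fraction = if (length(null_sym))
      length(intersect(sel, null_sym)) / length(null_sym) else NA_real_,
    n_enriched = length(enriched),
    n_null = length(null_sym),
    selected_symbols = sel)
}
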