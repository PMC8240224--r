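#' Treatment design: the 26-panel disease/control map
#'
#' Builds the panel of treatment identifiers used throughout the study
#' design: 13 disease/control conditions, each contributed by a tryptic
#' (TRYP) and a phospho-tryptic (STYP) panel, numbered 1--26. Odd ids are
#' TRYP panels, even ids the matching STYP panels. The default comparison
#' is Alzheimer dementia (id 3) against the Alzheimer normal control
#' (id 1).
#'
#' @param case_id Treatment id used as the case arm (default 3).
#' @param control_id Treatment id used as the matched control arm
#'   (default 1).
#' @return An object of class `treatment_design`: a list with `panel`
#'   (a `data.table` with columns `treatment_id`, `label`, `stream`),
#'   `case_id` and `control_id`.
#' @examples
#' d <- treatment_design()
#' d$panel[treatment_id %in% c(1, 3)]
#' @export
treatment_design <- function(case_id = 3L, control_id = 1L) {
  case_id <- as.integer(case_id)
  control_id <- as.integer(control_id)
  panel <- data.table(
    treatment_id = 1:26,
    label = TREATMENT_LABELS,
    stream = ifelse(seq_len(26) %% 2L == 0L, "STYP", "TRYP"))
  if (anyDuplicated(panel$treatment_id) > 0)
    stop("treatment ids must be unique")
  for (id in c(case_id, control_id)) {
    if (!id %in% panel$treatment_id)
      stop("treatment id ", id, " is not in the 1-26 panel")
  }
  structure(list(panel = panel, case_id = case_id, control_id = control_id),
            class = "treatment_design")
}

#' @export
print.treatment_design <- function(x, ...) {
  cat("Treatment design: ", nrow(x$panel), " panels; case = ", x$case_id,
      " (", x$panel$label[x$panel$treatment_id == x$case_id], "), control = ",
      x$control_id,
      " (", x$panel$label[x$panel$treatment_id == x$control_id], ")\n",
      sep = "")
  invisible(x)
}

#' Retention-filter configuration
#'
#' @param min_intensity Minimum precursor intensity in arbitrary counts;
#'   a PSM is retained when its intensity is greater than or equal to
#'   this value (inclusive E4 rule, default 10000).
#' @param stream_mode Which analysis streams to process: `"both"`,
#'   `"TRYP"` or `"STYP"`.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_intensity = 10000,
                          stream_mode = c("both", "TRYP", "STYP")) {
  stream_mode <- match.arg(stream_mode)
  if (!is.numeric(min_intensity) || length(min_intensity) != 1 ||
      !is.finite(min_intensity) || min_intensity <= 0)
    stop("min_intensity must be a single positive number")
  structure(list(
    min_intensity = min_intensity,
    stream_mode = stream_mode,
    dedup_keys = "max score, then lower charge, then peptide, then accession"),
    class = "filter_config")
}

#' Candidate-selection configuration
#'
#' Defaults reproduce the primary selection rule: a corrected frequency
#' difference of at least 9 counts together with a chi-square value of at
#' least 25 (nominal p <= 0.001 at 1 df). The frequency-difference gate is
#' exposed because network illustrations use a difference greater than 10.
#'
#' @param chi2_min Minimum chi-square value (inclusive, default 25).
#' @param delta_min Minimum corrected frequency difference
#'   (inclusive, default 9).
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(chi2_min = 25, delta_min = 9) {
  if (!is.numeric(chi2_min) || chi2_min < 0)
    stop("chi2_min must be non-negative")
  if (!is.numeric(delta_min)) stop("delta_min must be numeric")
  structure(list(chi2_min = chi2_min, delta_min = delta_min),
            class = "selection_config")
}

# ---- modification serialization -------------------------------------------

#' Parse serialized modification strings
#'
#' Modifications are serialized as semicolon-joined `"pos:type"` tokens,
#' e.g. `"3:phospho_S;7:oxidation_M"`; the empty string means no
#' modifications.
#'
#' @param x Character vector of serialized modification strings.
#' @return A list (one element per input) of data.frames with columns
#'   `position` (integer) and `type` (character).
#' @export
parse_modifications <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s))
      return(data.frame(position = integer(), type = character()))
    toks <- strsplit(s, ";", fixed = TRUE)[[1]]
    ok <- grepl("^[0-9]+:[A-Za-z_]+$", toks)
    if (!all(ok))
      stop("unparsable modification token(s): ",
           paste(toks[!ok], collapse = ", "))
    pos <- as.integer(sub(":.*$", "", toks))
    type <- sub("^[0-9]+:", "", toks)
    bad <- !type %in% MOD_TYPES
    if (any(bad))
      stop("unknown modification type(s): ",
           paste(unique(type[bad]), collapse = ", "))
    data.frame(position = pos, type = type)
  })
}

# Canonical serialization: tokens sorted by position then type.
serialize_modifications <- function(mods) {
  vapply(mods, function(m) {
    if (nrow(m) == 0) return("")
    o <- order(m$position, m$type)
    paste(sprintf("%d:%s", m$position[o], m$type[o]), collapse = ";")
  }, character(1))
}

# ---- PSM table validation --------------------------------------------------

#' Validate a PSM table
#'
#' Checks the schema and the row-level invariants of a table of
#' peptide-spectrum matches: non-empty peptides over the 20-letter amino
#' acid alphabet, charge in \{2, 3\}, engine in \{XTANDEM, SEQUEST\},
#' positive precursor intensity, modification positions within the
#' peptide, and phosphorylation restricted to S/T/Y residues.
#'
#' @param psms A `data.frame`/`data.table` with the PSM schema.
#' @return The validated table as a `data.table` (invisibly the same
#'   content; a copy is made).
#' @export
validate_psm_table <- function(psms) {
  dt <- as.data.table(psms)
  missing_cols <- setdiff(PSM_COLUMNS, names(dt))
  if (length(missing_cols))
    stop("PSM table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  dt <- dt[, PSM_COLUMNS, with = FALSE]
  if (nrow(dt) == 0) return(dt)
  dt[, treatment_id := as.integer(treatment_id)]
  dt[, charge := as.integer(charge)]
  dt[, score := as.numeric(score)]
  dt[, precursor_intensity := as.numeric(precursor_intensity)]
  dt[, modifications := fifelse(is.na(modifications), "",
                                as.character(modifications))]

  fail <- function(rows, what) {
    stop("PSM validation error (", what, ") at row(s): ",
         paste(head(rows, 10), collapse = ", "),
         if (length(rows) > 10) " ..." else "")
  }
  bad <- which(!nzchar(dt$peptide) |
                 grepl(paste0("[^", paste(AA_20, collapse = ""), "]"),
                       dt$peptide))
  if (length(bad)) fail(bad, "peptide must be non-empty over the 20 amino acids")
  bad <- which(!dt$charge %in% c(2L, 3L))
  if (length(bad)) fail(bad, "charge must be 2 or 3")
  bad <- which(!dt$engine %in% c("XTANDEM", "SEQUEST"))
  if (length(bad)) fail(bad, "engine must be XTANDEM or SEQUEST")
  bad <- which(!is.finite(dt$precursor_intensity) |
                 dt$precursor_intensity <= 0)
  if (length(bad)) fail(bad, "precursor_intensity must be positive")
  bad <- which(!nzchar(dt$gene_symbol))
  if (length(bad)) fail(bad, "gene_symbol must be non-empty")

  # modification tokens, validated in bulk (one long token vector rather
  # than per-row parses)
  nz <- which(nzchar(dt$modifications))
  if (length(nz)) {
    toks <- strsplit(dt$modifications[nz], ";", fixed = TRUE)
    row_idx <- rep(nz, lengths(toks))
    tok <- unlist(toks, use.names = FALSE)
    ok <- grepl("^[0-9]+:[A-Za-z_]+$", tok)
    if (!all(ok)) fail(unique(row_idx[!ok]), "unparsable modification token")
    pos <- as.integer(sub(":.*$", "", tok))
    type <- sub("^[0-9]+:", "", tok)
    unknown <- !type %in% MOD_TYPES
    if (any(unknown))
      fail(unique(row_idx[unknown]),
           paste("unknown modification type:",
                 paste(unique(type[unknown]), collapse = ", ")))
    plen <- nchar(dt$peptide)[row_idx]
    oob <- pos < 1 | pos > plen
    if (any(oob)) fail(unique(row_idx[oob]),
                       "modification position outside peptide")
    ph <- type %in% PHOSPHO_TYPES
    if (any(ph)) {
      res <- substring(dt$peptide[row_idx[ph]], pos[ph], pos[ph])
      mism <- res != sub("^phospho_", "", type[ph])
      if (any(mism))
        fail(unique(row_idx[ph][mism]),
             "phospho modification must fall on the matching S/T/Y residue")
    }
    # canonical serialization: tokens ordered by position, then type
    m <- data.table(row = row_idx, pos = pos, type = type)
    setorder(m, row, pos, type)
    canon <- m[, .(mods = paste(sprintf("%d:%s", pos, type),
                                collapse = ";")), by = row]
    set(dt, i = canon$row, j = "modifications", value = canon$mods)
  }
  dt[]
}
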