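#' Apply the precursor-intensity retention threshold
#'
#' Retains PSMs whose precursor intensity is greater than or equal to the
#' configured minimum (the inclusive E4 rule: 10,000 arbitrary counts by
#' default). Row order is preserved and the input is not modified.
#'
#' @param psms Validated PSM table.
#' @param config A [filter_config()].
#' @return The retained rows as a `data.table`.
#' @export
filter_min_intensity <- function(psms, config = filter_config()) {
  dt <- as.data.table(psms)
  if (nrow(dt) == 0) return(copy(dt))
  if (any(!is.finite(dt$precursor_intensity) | dt$precursor_intensity <= 0))
    stop("non-positive precursor intensity encountered")
  dt[precursor_intensity >= config$min_intensity]
}

#' Deduplicate redundant spectrum-to-peptide correlations
#'
#' A single MS/MS spectrum may be correlated to peptides at both charge
#' states or to different sequences; such redundant correlations are a
#' source of type I error. Within each `spectrum_id` group (per engine
#' table) only the best fit is retained: maximal engine score, ties
#' broken by lower charge, then lexicographically smaller peptide, then
#' smaller accession. Idempotent.
#'
#' @param psms Validated PSM table.
#' @param by_engine Deduplicate within each engine's table separately
#'   (default TRUE); with FALSE a spectrum keeps one row overall.
#' @return A `data.table` with exactly one row per `spectrum_id` (and
#'   engine, when `by_engine` is TRUE).
#' @export
dedup_best_fit <- function(psms, by_engine = TRUE) {
  dt <- as.data.table(psms)
  if (nrow(dt) == 0) return(copy(dt))
  keys <- if (by_engine) c("engine", "spectrum_id") else "spectrum_id"
  ord <- copy(dt)
  ord[, `.row_order` := .I]
  setorderv(ord, c(keys, "score", "charge", "peptide", "protein_accession"),
            order = c(rep(1L, length(keys)), -1L, 1L, 1L, 1L))
  out <- unique(ord, by = keys)   # first row per group is the best fit
  setorderv(out, ".row_order")
  out[, `.row_order` := NULL]
  setcolorder(out, names(dt))
  out[]
}

#' Classify PSMs into the TRYP or STYP stream
#'
#' A PSM belongs to the phospho-tryptic (STYP) stream iff it carries at
#' least one phosphorylation on serine, threonine or tyrosine; otherwise
#' it is tryptic (TRYP). Acetylation, methionine oxidation and neutral
#' losses do not change the stream.
#'
#' @param psms Validated PSM table (or any table with a serialized
#'   `modifications` column).
#' @return Character vector of `"TRYP"`/`"STYP"`, one per row.
#' @export
classify_stream <- function(psms) {
  mods <- as.data.table(psms)$modifications
  mods[is.na(mods)] <- ""
  ifelse(grepl("phospho_[STY]", mods), "STYP", "TRYP")
}

#' Partition PSMs into the two analysis streams
#'
#' @param psms Validated PSM table.
#' @return A list with elements `TRYP` and `STYP`; together they
#'   partition the input (no row lost or duplicated).
#' @export
split_streams <- function(psms) {
  dt <- as.data.table(psms)
  s <- classify_stream(dt)
  list(TRYP = dt[s == "TRYP"], STYP = dt[s == "STYP"])
}
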