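#' Read a PSM table
#'
#' Reads a TSV or CSV table of peptide-spectrum matches (one row per
#' MS/MS-spectrum-to-peptide correlation) and validates every row.
#' Modifications are expected as semicolon-joined `"pos:type"` tokens
#' (see [parse_modifications()]).
#'
#' @param path File path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A validated `data.table` with the PSM schema; row order
#'   preserved. A file with a header and zero data rows yields an empty
#'   table.
#' @export
read_psm_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("PSM file not found: ", path)
  dt <- fread(path, sep = if (dialect == "tsv") "\t" else ",",
              header = TRUE, colClasses = list(
                character = c("spectrum_id", "sample_id", "fraction",
                              "peptide", "modifications", "engine",
                              "protein_accession", "gene_symbol")),
              fill = FALSE, na.strings = NULL)
  validate_psm_table(dt)
}

#' Write a PSM table
#'
#' @param psms Validated PSM table.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  dt <- validate_psm_table(psms)
  fwrite(format_real_cols(dt, c("score", "precursor_intensity")),
         path, sep = "\t", quote = FALSE)
  invisible(path)
}

# Reals are written with 15 significant digits so that write -> read
# round-trips beyond the documented 12-significant-digit contract.
format_real_cols <- function(dt, cols) {
  out <- copy(as.data.table(dt))
  for (cl in intersect(cols, names(out))) {
    v <- out[[cl]]
    if (is.numeric(v))
      set(out, j = cl, value = ifelse(is.na(v), NA_character_,
                                      sprintf("%.15g", v)))
  }
  out
}

#' Write a frequency-comparison result table
#'
#' Writes per-symbol frequency records as TSV with the fixed column order
#' `gene_symbol, stream, count_case, count_control, corrected_control,
#' delta, chi2, pvalue, qvalue`. `(gene_symbol, stream)` is the primary
#' key; duplicates are rejected.
#'
#' @param records `data.table`/`data.frame` of frequency records.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_frequency_table <- function(records, path) {
  dt <- as.data.table(records)
  missing_cols <- setdiff(FREQ_COLUMNS, names(dt))
  if (length(missing_cols))
    stop("frequency table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(dt) && anyDuplicated(dt[, .(gene_symbol, stream)]) > 0)
    stop("duplicate (gene_symbol, stream) rows violate the primary key")
  dt <- dt[, FREQ_COLUMNS, with = FALSE]
  fwrite(format_real_cols(dt, c("corrected_control", "delta", "chi2",
                                "pvalue", "qvalue")),
         path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a frequency-comparison result table
#'
#' @param path TSV path written by [write_frequency_table()].
#' @return A `data.table` of frequency records.
#' @export
read_frequency_table <- function(path) {
  if (!file.exists(path)) stop("frequency table not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = c("gene_symbol", "stream")))
  missing_cols <- setdiff(FREQ_COLUMNS, names(dt))
  if (length(missing_cols))
    stop("frequency table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  dt[, count_case := as.integer(count_case)]
  dt[, count_control := as.integer(count_control)]
  dt[]
}

#' Read protein sequences from FASTA
#'
#' The accession is the first whitespace-delimited token of the header
#' line. Sequences are uppercased; gap (`-`) or stop (`*`) characters and
#' anything outside the 20-residue alphabet are rejected, as are
#' duplicate accessions and empty sequences.
#'
#' @param path FASTA file path.
#' @return A named character vector mapping accession to sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  acc <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(acc) > 0)
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  seqs <- toupper(as.character(aa))
  if (any(!nzchar(seqs)))
    stop("empty sequence(s) in FASTA: ",
         paste(acc[!nzchar(seqs)], collapse = ", "))
  bad <- grepl(paste0("[^", paste(AA_20, collapse = ""), "]"), seqs)
  if (any(bad))
    stop("illegal characters in sequence(s): ",
         paste(acc[bad], collapse = ", "))
  setNames(seqs, acc)
}

#' Write protein sequences to FASTA
#'
#' @param seqs Named character vector (accession -> sequence).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read an undirected edge list
#'
#' Two-column TSV, one undirected edge per row. Lines beginning with `#`
#' are skipped.
#'
#' @param path TSV path.
#' @return A `data.table` with columns `from` and `to`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  dt <- fread(path, sep = "\t", header = FALSE, colClasses = "character",
              select = 1:2)
  setnames(dt, c("from", "to"))
  dt[]
}
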