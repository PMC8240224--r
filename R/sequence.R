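check_sequence <- function(sequence) {
  if (length(sequence) != 1 || is.na(sequence))
    stop("sequence must be a single string")
  sequence <- toupper(sequence)
  if (nzchar(sequence) &&
      grepl(paste0("[^", paste(AA_20, collapse = ""), "]"), sequence))
    stop("illegal residue(s) in sequence")
  sequence
}

# 0-based cleavage points after K/R (optionally not before P); the
# returned vector includes 0 and nchar(sequence) so consecutive pairs
# delimit the fully tryptic fragments.
cleavage_points <- function(sequence, proline_rule = TRUE) {
  n <- nchar(sequence)
  if (n == 0) return(integer(0))
  res <- strsplit(sequence, "")[[1]]
  cut <- which(res %in% c("K", "R"))
  cut <- cut[cut < n]
  if (proline_rule) cut <- cut[res[cut + 1] != "P"]
  c(0L, cut, n)
}

#' In-silico tryptic digestion
#'
#' Cleaves after lysine or arginine, by default not when the next residue
#' is proline (the `[RK]|{P}` rule used by the search engines' trypsin
#' definition). With `missed_cleavages = 0` the peptides tile the
#' sequence exactly; with `m` missed cleavages every concatenation of up
#' to `m + 1` adjacent fragments is emitted, ordered by start position
#' then span.
#'
#' @param sequence Amino-acid sequence.
#' @param missed_cleavages Maximum number of internal missed cleavage
#'   sites (default 0).
#' @param proline_rule Suppress cleavage before proline (default TRUE).
#' @return A `data.table` with `peptide`, `start`, `end` (1-based
#'   inclusive) and `missed` (number of internal sites retained).
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 0,
                           proline_rule = TRUE) {
  sequence <- check_sequence(sequence)
  pts <- cleavage_points(sequence, proline_rule)
  if (length(pts) == 0)
    return(data.table(peptide = character(), start = integer(),
                      end = integer(), missed = integer()))
  nfrag <- length(pts) - 1L
  rows <- list()
  for (i in seq_len(nfrag)) {
    for (m in 0:missed_cleavages) {
      j <- i + m
      if (j > nfrag) break
      rows[[length(rows) + 1L]] <- data.table(
        peptide = substring(sequence, pts[i] + 1L, pts[j + 1L]),
        start = pts[i] + 1L, end = pts[j + 1L], missed = m)
    }
  }
  out <- rbindlist(rows)
  setorderv(out, c("start", "end"))
  out[]
}

#' Test whether a peptide occurrence is fully tryptic
#'
#' A peptide is fully tryptic at a position when both termini are
#' consistent with trypsin cleavage: the N side is the protein terminus
#' or preceded by K/R (with the peptide not starting in P under the
#' proline rule), and the C side ends the protein or ends in K/R with the
#' following residue not P.
#'
#' @param sequence Parent protein sequence.
#' @param peptide Peptide expected to occur at `start`.
#' @param start 1-based start position of the occurrence.
#' @param proline_rule Apply the no-cleavage-before-proline clause
#'   (default TRUE).
#' @return Logical scalar.
#' @export
is_fully_tryptic <- function(sequence, peptide, start, proline_rule = TRUE) {
  sequence <- check_sequence(sequence)
  peptide <- check_sequence(peptide)
  if (!nzchar(peptide)) stop("peptide must be non-empty")
  end <- start + nchar(peptide) - 1L
  if (start < 1 || end > nchar(sequence) ||
      substring(sequence, start, end) != peptide)
    stop("peptide does not occur at position ", start, " in the sequence")
  first <- substring(peptide, 1, 1)
  last <- substring(peptide, nchar(peptide), nchar(peptide))
  prev <- if (start == 1) "" else substring(sequence, start - 1, start - 1)
  nxt <- if (end == nchar(sequence)) "" else substring(sequence, end + 1,
                                                       end + 1)
  n_ok <- start == 1 ||
    (prev %in% c("K", "R") && (!proline_rule || first != "P"))
  c_ok <- end == nchar(sequence) ||
    (last %in% c("K", "R") && (!proline_rule || nxt != "P"))
  n_ok && c_ok
}

#' Locate a peptide within a parent sequence
#'
#' All (possibly overlapping) occurrences, with 1-based inclusive
#' coordinates and the flanking residues (empty string at the protein
#' termini). No occurrence yields an empty result, not an error.
#'
#' @param sequence Parent protein sequence.
#' @param peptide Non-empty peptide.
#' @return A `data.table` with `start`, `end`, `preceding`, `following`.
#' @export
locate_peptide <- function(sequence, peptide) {
  sequence <- check_sequence(sequence)
  peptide <- check_sequence(peptide)
  if (!nzchar(peptide)) stop("peptide must be non-empty")
  starts <- integer(0)
  from <- 1L
  repeat {
    hit <- regexpr(peptide, substring(sequence, from), fixed = TRUE)
    if (hit == -1L) break
    starts <- c(starts, from + as.integer(hit) - 1L)
    from <- from + as.integer(hit)    # allow overlapping occurrences
  }
  if (length(starts) == 0)
    return(data.table(start = integer(), end = integer(),
                      preceding = character(), following = character()))
  ends <- starts + nchar(peptide) - 1L
  data.table(
    start = starts, end = ends,
    preceding = ifelse(starts == 1L, "",
                       substring(sequence, starts - 1L, starts - 1L)),
    following = ifelse(ends == nchar(sequence), "",
                       substring(sequence, ends + 1L, ends + 1L)))
}

#' Sliding-window hydropathy profile
#'
#' Centered sliding-window mean of the Kyte-Doolittle hydropathy scale.
#' Values are defined only where the full window fits, i.e. for centers
#' `(w+1)/2 .. n-(w-1)/2`.
#'
#' @param sequence Amino-acid sequence.
#' @param window Odd window width, at most the sequence length
#'   (default 9).
#' @param scale Named per-residue scale (defaults to Kyte-Doolittle).
#' @return A `data.table` with `position` (window center, 1-based) and
#'   `hydropathy` (window mean).
#' @export
hydropathy_profile <- function(sequence, window = 9, scale = KD_SCALE) {
  sequence <- check_sequence(sequence)
  if (window %% 2 != 1) stop("window must be odd")
  n <- nchar(sequence)
  if (window > n) stop("window exceeds sequence length")
  vals <- unname(scale[strsplit(sequence, "")[[1]]])
  if (anyNA(vals)) stop("residue missing from the hydropathy scale")
  half <- (window - 1L) / 2L
  cs <- c(0, cumsum(vals))
  centers <- (half + 1L):(n - half)
  data.table(
    position = centers,
    hydropathy = (cs[centers + half + 1L] - cs[centers - half]) / window)
}
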