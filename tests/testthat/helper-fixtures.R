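# Small PSM table builder with sensible defaults; every argument is
# recycled against the longest one.
psm_fixture <- function(spectrum_id = "s1",
                        peptide = "ARQCGLDSR",
                        modifications = "",
                        charge = 2L,
                        engine = "SEQUEST",
                        score = 5,
                        precursor_intensity = 20000,
                        sample_id = "AD-P01",
                        fraction = "F01",
                        treatment_id = 3L,
                        protein_accession = "ACC1",
                        gene_symbol = "SYM1") {
  data.table::data.table(
    spectrum_id = spectrum_id, sample_id = sample_id, fraction = fraction,
    treatment_id = treatment_id, peptide = peptide,
    modifications = modifications, charge = charge, engine = engine,
    score = score, precursor_intensity = precursor_intensity,
    protein_accession = protein_accession, gene_symbol = gene_symbol)
}

# A PSM table with n rows, unique spectrum ids, one symbol per row drawn
# from `symbols`.
psm_block <- function(n, symbols = "SYM1", prefix = "s", ...) {
  psm_fixture(spectrum_id = sprintf("%s%04d", prefix, seq_len(n)),
              gene_symbol = rep_len(symbols, n), ...)
}

# Independent brute-force Benjamini-Hochberg step-up: for each p, the
# minimum over all ranks j >= rank(p) of p_(j) * m / j, capped at 1.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Deterministic simple graph with exactly `n` nodes and `e` edges built
# from a ring plus short chords (no RNG; requires e <= 4n and chords
# shorter than n/2).
ring_chord_graph <- function(n, e) {
  stopifnot(e >= n, n > 12, e <= n * (n %/% 2 - 1))
  from <- integer(0); to <- integer(0)
  k <- 1L
  while (length(from) < e) {
    take <- min(n, e - length(from))
    i <- seq_len(take)
    from <- c(from, i)
    to <- c(to, ((i + k - 1L) %% n) + 1L)
    k <- k + 1L
  }
  data.table::data.table(from = sprintf("n%04d", from),
                         to = sprintf("n%04d", to))
}
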