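test_that("PSM tables round-trip through write and read", {
  psms <- psm_fixture(
    spectrum_id = c("s1", "s2", "s3"),
    peptide = c("ARQCGLDSR", "MKPTIDES", "AAASTYK"),
    modifications = c("", "4:phospho_T;1:oxidation_M", "5:phospho_T"),
    charge = c(2L, 3L, 2L),
    score = c(2.1, 3.14159265358979, 7.5),
    precursor_intensity = c(15000, 12345.6789012345, 99999.5),
    gene_symbol = c("DISC1", "KIF12", "NGF"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(psms, path)
  back <- read_psm_table(path)
  expect_equal(back$spectrum_id, psms$spectrum_id)
  expect_identical(back$charge, psms$charge)
  expect_identical(back$treatment_id, psms$treatment_id)
  expect_equal(back$score, psms$score, tolerance = 1e-12)
  expect_equal(back$precursor_intensity, psms$precursor_intensity,
               tolerance = 1e-12)
  # modification strings come back in canonical position-sorted order
  expect_equal(parse_modifications(back$modifications),
               lapply(parse_modifications(psms$modifications), function(m) {
                 m[order(m$position, m$type), , drop = FALSE]
               }),
               ignore_attr = TRUE)
})

test_that("a header-only PSM file yields an empty table", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(psm_fixture()[0], path)
  back <- read_psm_table(path)
  expect_equal(nrow(back), 0)
  expect_true(all(c("spectrum_id", "gene_symbol") %in% names(back)))
})

test_that("PSM validation rejects malformed rows with diagnostics", {
  # missing column named in the error
  bad <- psm_fixture()
  bad$charge <- NULL
  expect_error(validate_psm_table(bad), "charge")
  # unknown modification type (phospho on a residue letter outside STY)
  expect_error(validate_psm_table(psm_fixture(modifications = "2:phospho_A")),
               "unknown modification")
  # phospho annotated on a residue that is not the matching S/T/Y
  expect_error(
    validate_psm_table(psm_fixture(peptide = "ARQCGLDSR",
                                   modifications = "1:phospho_S")),
    "S/T/Y")
  # unparsable token
  expect_error(validate_psm_table(psm_fixture(modifications = "phospho_S@3")),
               "unparsable")
  # modification position beyond the peptide
  expect_error(validate_psm_table(psm_fixture(peptide = "AASK",
                                              modifications = "9:phospho_S")),
               "outside")
  # charge outside {2,3} and non-positive intensity
  expect_error(validate_psm_table(psm_fixture(charge = 4L)), "charge")
  expect_error(validate_psm_table(psm_fixture(precursor_intensity = 0)),
               "positive")
})

test_that("frequency tables round-trip and enforce their primary key", {
  rec <- data.table::data.table(
    gene_symbol = c("DISC1", "KIF12"), stream = c("TRYP", "TRYP"),
    count_case = c(30L, 17L), count_control = c(10L, 2L),
    corrected_control = c(11.4549505762793, 2.29099011525586),
    delta = c(18.5450494237207, 14.7090098847441),
    chi2 = c(27.6175559862745, 65.7246917050059),
    pvalue = c(1.47e-07, 5.2e-16), qvalue = c(1.47e-07, 1.04e-15))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_frequency_table(rec, path)
  back <- read_frequency_table(path)
  expect_identical(back$count_case, rec$count_case)
  expect_identical(back$count_control, rec$count_control)
  for (cl in c("corrected_control", "delta", "chi2", "pvalue", "qvalue"))
    expect_equal(back[[cl]], rec[[cl]], tolerance = 1e-11)

  write_frequency_table(rec[0], path)
  expect_equal(nrow(read_frequency_table(path)), 0)

  expect_error(write_frequency_table(rbind(rec, rec[1]), path),
               "primary key")
})

test_that("FASTA reading validates accessions and sequences", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "MKR", ">p2", "aastyk"), path)
  seqs <- read_fasta(path)
  expect_equal(seqs, c(p1 = "MKR", p2 = "AASTYK"))

  writeLines(c(">p1", "MKR", ">p1", "AAA"), path)
  expect_error(read_fasta(path), "duplicate")
  writeLines(c(">p1", "MK*R"), path)
  expect_error(read_fasta(path), "illegal")
  writeLines(c(">p1", "", ">p2", "AAA"), path)
  expect_error(read_fasta(path), "empty")
})

test_that("the treatment design covers the full 26-panel map", {
  d <- treatment_design()
  expect_equal(nrow(d$panel), 26)
  expect_equal(d$panel$treatment_id, 1:26)
  expect_equal(d$case_id, 3L)
  expect_equal(d$control_id, 1L)
  expect_equal(d$panel$stream, rep(c("TRYP", "STYP"), 13))
  expect_error(treatment_design(case_id = 27), "panel")
})
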