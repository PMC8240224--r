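test_that("observation frequency tallies PSMs per symbol", {
  psms <- psm_block(5, symbols = c("DISC1", "DISC1", "DISC1",
                                   "KIF12", "KIF12"))
  cnt <- count_frequency(psms)
  expect_equal(cnt[order(gene_symbol)],
               data.table::data.table(gene_symbol = c("DISC1", "KIF12"),
                                      count = c(3L, 2L)))
  expect_equal(sum(cnt$count), nrow(psms))
  expect_equal(nrow(count_frequency(psms[0])), 0)
  expect_equal(count_frequency(psm_fixture())$count, 1L)
  bad <- data.table::copy(psms)[1, gene_symbol := ""]
  expect_error(count_frequency(bad), "gene_symbol")
})

test_that("depth correction rescales control counts by the totals ratio", {
  expect_equal(correct_control(7, list(total_case = 100, total_control = 100)),
               7)
  # the study's printed per-arm totals as the correction input
  expect_equal(
    correct_control(100, list(total_case = 486367, total_control = 424591)),
    100 * 486367 / 424591, tolerance = 1e-12)
  expect_equal(round(
    correct_control(100, list(total_case = 486367, total_control = 424591)),
    1), 114.5)
  expect_equal(correct_control(0, list(total_case = 5, total_control = 9)), 0)
  expect_error(correct_control(1, list(total_case = 5, total_control = 0)),
               "positive")
  tot <- stream_totals(psm_block(100), psm_block(80))
  expect_equal(tot, list(total_case = 100L, total_control = 80L))
  expect_warning(stream_totals(psm_block(3), psm_block(1)[0]), "undefined")
})

test_that("the pseudocounted chi-square matches direct evaluation", {
  expect_equal(chi_square_pseudo(0, 0), 0)
  expect_equal(chi_square_pseudo(10, 0), 100)
  expect_equal(chi_square_pseudo(4, 4), 0)
  expect_equal(chi_square_pseudo(30, 10), (30 - 10)^2 / 11)
  expect_error(chi_square_pseudo(-1, 0), "non-negative")

  # agreement with the textbook one-cell (obs-exp)^2/exp as the corrected
  # control grows
  for (cc in c(1e2, 1e4, 1e6)) {
    obs <- cc * 1.1
    rel <- abs(chi_square_pseudo(obs, cc) - (obs - cc)^2 / cc) /
      ((obs - cc)^2 / cc)
    expect_lt(rel, 2 / cc)
  }

  # monotone in |case - corrected control| at fixed corrected control
  cc <- 12.5
  diffs <- seq(0, 40, by = 0.5)
  vals <- chi_square_pseudo(cc + diffs, cc)
  expect_true(all(diff(vals) >= 0))
})

test_that("df=1 tail probabilities map the selection thresholds to their significance levels", {
  expect_lte(chi2_pvalue(25), 0.001)
  expect_lte(chi2_pvalue(9), 0.01)
  expect_equal(chi2_pvalue(0), 1)
  expect_error(chi2_pvalue(-2), "non-negative")
  # closed form for df = 1: erfc(sqrt(x/2))
  x <- c(0.01, 0.5, 1, 3.84, 9, 25, 50)
  expect_equal(chi2_pvalue(x), pracma::erfc(sqrt(x / 2)), tolerance = 1e-13)
})

test_that("BH adjustment equals the brute-force step-up", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")

  withr::with_seed(42, {
    for (i in 1:50) {
      p <- runif(sample(1:12, 1))
      q <- bh_fdr(p)
      expect_equal(q, bh_bruteforce(p), tolerance = 1e-12)
      expect_true(all(q[order(p)] == cummax(q[order(p)])))  # monotone in p
    }
  })
})

test_that("per-symbol aggregation averages accession chi-squares", {
  totals <- list(total_case = 1000, total_control = 1000)
  acc <- data.table::data.table(
    gene_symbol = c("DISC1", "DISC1", "KIF12"),
    stream = "TRYP",
    protein_accession = c("A1", "A2", "B1"),
    count_case = c(20L, 10L, 8L),
    count_control = c(5L, 2L, 8L))
  acc[, chi2 := chi_square_pseudo(count_case,
                               correct_control(count_control, totals))]
  sym <- average_chi_per_symbol(acc, totals)
  d <- sym[gene_symbol == "DISC1"]
  expect_equal(d$chi2_avg, mean(c((20 - 5)^2 / 6, (10 - 2)^2 / 3)))
  expect_equal(d$count_case, 30L)
  expect_equal(d$chi2_pooled, (30 - 7)^2 / 8)
  expect_equal(d$n_acc, 2L)
  # single accession: average equals the accession value
  k <- sym[gene_symbol == "KIF12"]
  expect_equal(k$chi2_avg, 0)
  expect_equal(k$n_acc, 1L)
  expect_equal(nrow(average_chi_per_symbol(acc[0], totals)), 0)
})

test_that("candidate selection is inclusive at both gates", {
  rec <- data.table::data.table(
    gene_symbol = c("A", "B", "C", "D"),
    delta = c(10, 5, 9, 8.999),
    chi2 = c(30, 100, 25, 1000))
  sel <- select_candidates(rec, selection_config())
  expect_setequal(sel$gene_symbol, c("A", "C"))   # delta gate rejects B, D
  expect_equal(sel$gene_symbol, c("A", "C"))      # descending chi2 order
})

test_that("the full frequency comparison reproduces hand-computed cases", {
  # null self-comparison: all chi2 zero, nothing selected
  psms <- psm_block(40, symbols = c("A", "A", "B", "C"))
  cmp <- run_frequency_comparison(psms, psms)
  expect_true(all(cmp$TRYP$records$chi2 == 0))
  expect_false(any(cmp$TRYP$records$selected))
  expect_equal(cmp$TRYP$correction_factor, 1)

  # case 30 vs control 10 for one symbol, with a balancing symbol making
  # the totals equal: chi2 = (30-10)^2/11
  case <- psm_block(40, prefix = "c", symbols = c(rep("TARGET", 3),
                                                  rep("BAL", 1)))
  ctrl <- psm_block(40, prefix = "k", symbols = c(rep("TARGET", 1),
                                                  rep("BAL", 3)))
  cmp2 <- run_frequency_comparison(case, ctrl)
  tgt <- cmp2$TRYP$records[gene_symbol == "TARGET"]
  expect_equal(tgt$count_case, 30L)
  expect_equal(tgt$corrected_control, 10)
  expect_equal(tgt$chi2, (30 - 10)^2 / 11)
  expect_true(tgt$selected)
  expect_equal(tgt$pvalue, chi2_pvalue((30 - 10)^2 / 11))

  # conservation: per-stream symbol counts sum to retained PSMs
  sim <- simulate_experiment(sim_config(n_symbols = 20, seed = 3))
  cmp3 <- run_frequency_comparison(sim$case, sim$control)
  retained <- split_streams(dedup_best_fit(filter_min_intensity(sim$case)))
  expect_equal(sum(cmp3$TRYP$records$count_case), nrow(retained$TRYP))
  expect_equal(sum(cmp3$STYP$records$count_case), nrow(retained$STYP))
})

test_that("counting uses the SEQUEST table when both engines are present", {
  both <- rbind(
    psm_block(6, prefix = "s", symbols = "A"),
    psm_block(4, prefix = "x", symbols = "A", engine = "XTANDEM"))
  ctrl <- rbind(
    psm_block(3, prefix = "t", symbols = "A"),
    psm_block(9, prefix = "y", symbols = "A", engine = "XTANDEM"))
  cmp <- run_frequency_comparison(both, ctrl)
  rec <- cmp$TRYP$records
  expect_equal(rec$count_case, 6L)
  expect_equal(rec$count_control, 3L)
})
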