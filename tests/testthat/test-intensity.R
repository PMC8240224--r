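test_that("intensity records carry exact log10 transforms and panel labels", {
  psms <- psm_fixture(spectrum_id = c("s1", "s2"),
                      precursor_intensity = c(10000, 1e6),
                      treatment_id = c(3L, 1L))
  rec <- to_intensity_records(psms)
  expect_equal(rec$log10_intensity, c(4, 6))
  expect_equal(rec$label[rec$treatment_id == 3], "Alzheimer dementia")
  expect_error(to_intensity_records(psm_fixture(treatment_id = 99L)),
               "unknown treatment")
})

test_that("treatment means report mean, se and n on the log10 scale", {
  rec <- data.table::data.table(
    treatment_id = c(1L, 3L, 3L, 5L),
    label = "x", gene_symbol = "DISC1",
    peptide = c("ARQCGLDSR", "ARQCGLDSR", "MPGGGPQK", "ARQCGLDSR"),
    log10_intensity = c(4.5, 4.0, 5.0, 6.0))
  tm <- treatment_means(rec, symbol = "DISC1")
  expect_equal(tm$treatment_id, c(1L, 3L, 5L))
  expect_equal(tm[treatment_id == 1L, .(mean, n)],
               data.table::data.table(mean = 4.5, n = 1L))
  expect_true(is.na(tm[treatment_id == 1L, se]))
  expect_equal(tm[treatment_id == 3L, mean], 4.5)
  expect_equal(tm[treatment_id == 3L, se], sd(c(4, 5)) / sqrt(2))
  expect_equal(tm[treatment_id == 3L, se], 0.5)
  # n column conserves the record count of the restriction
  expect_equal(sum(tm$n), nrow(rec))
  # peptide whitelist restriction
  tm2 <- treatment_means(rec, symbol = "DISC1", peptides = "MPGGGPQK")
  expect_equal(tm2$n, 1L)
  # empty restriction is an empty table, not an error
  expect_equal(nrow(treatment_means(rec, symbol = "NONE")), 0)
})

test_that("one-way ANOVA matches the explicit sum-of-squares oracle", {
  vals <- c(4.0, 4.2, 5.0, 5.2)
  grp <- c("a", "a", "b", "b")
  res <- anova_oneway(vals, grp)
  # independent oracle: textbook decomposition evaluated directly
  grand <- mean(vals)
  ssb <- 2 * (mean(c(4.0, 4.2)) - grand)^2 + 2 * (mean(c(5.0, 5.2)) - grand)^2
  ssw <- sum((c(4.0, 4.2) - 4.1)^2) + sum((c(5.0, 5.2) - 5.1)^2)
  f_oracle <- (ssb / 1) / (ssw / 2)
  expect_equal(res$table$sum_sq, c(ssb, ssw))
  expect_equal(res$table$F[1], f_oracle)
  expect_equal(res$table$pvalue[1], pf(f_oracle, 1, 2, lower.tail = FALSE))
  expect_false(res$degenerate)
})

test_that("one-way ANOVA reports degenerate regimes explicitly", {
  res0 <- anova_oneway(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res0$table$F[1], 0)
  expect_equal(res0$table$pvalue[1], 1)
  resd <- anova_oneway(c(0, 0, 1, 1), c("a", "a", "b", "b"))
  expect_true(resd$degenerate)
  expect_equal(resd$table$F[1], Inf)
  expect_equal(resd$table$pvalue[1], 0)
  expect_error(anova_oneway(1:3, rep("a", 3)), "levels")
})

test_that("one-way SS are additive and F equals t^2 on random data", {
  withr::with_seed(99, {
    for (i in 1:20) {
      g <- sample(letters[1:4], 40, replace = TRUE)
      y <- rnorm(40) + as.integer(factor(g)) * 0.3
      res <- anova_oneway(y, g)
      ss_total <- sum((y - mean(y))^2)
      expect_equal(sum(res$table$sum_sq), ss_total, tolerance = 1e-9)
    }
    for (i in 1:20) {
      g <- rep(c("a", "b"), c(7, 9))
      y <- rnorm(16) + (g == "b") * 0.5
      res <- anova_oneway(y, g)
      tt <- t.test(y[g == "a"], y[g == "b"], var.equal = TRUE)
      expect_equal(res$table$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
      expect_equal(res$table$pvalue[1], tt$p.value, tolerance = 1e-10)
    }
  })
})

test_that("two-way additive ANOVA handles balanced and degenerate designs", {
  # balanced 2x2 with a pure treatment effect: the peptide factor carries
  # nothing and the treatment F matches the one-way value
  y <- c(4.0, 4.1, 5.0, 5.1, 4.0, 4.1, 5.0, 5.1)
  tr <- rep(rep(c("t1", "t2"), each = 2), 2)
  pep <- rep(c("p1", "p2"), each = 4)
  res <- anova_twoway(y, tr, pep, names = c("treatment", "peptide"))
  one <- anova_oneway(y, tr)
  # in the balanced design the treatment SS equals the one-way between-SS
  # and the peptide factor absorbs nothing
  expect_equal(res$table$sum_sq[1], one$table$sum_sq[1], tolerance = 1e-10)
  expect_equal(res$table$sum_sq[2], 0, tolerance = 1e-10)
  expect_equal(res$table$F[2], 0, tolerance = 1e-10)
  # the treatment F is the one-way F re-referenced to the additive
  # model's residual mean square
  expect_equal(res$table$F[1],
               one$table$sum_sq[1] / (res$table$sum_sq[3] / res$table$df[3]),
               tolerance = 1e-9)

  # all responses equal: both factor F = 0
  res0 <- anova_twoway(rep(2, 8), tr, pep)
  expect_equal(res0$table$F[1:2], c(0, 0))
  expect_equal(res0$table$pvalue[1:2], c(1, 1))

  expect_error(anova_twoway(y, rep("t1", 8), pep,
                            names = c("treatment", "peptide")),
               "treatment")
})

test_that("two-way Type II SS agree with a normal-equations oracle", {
  withr::with_seed(7, {
    for (i in 1:10) {
      n <- 30
      f1 <- sample(c("a", "b", "c"), n, replace = TRUE)
      f2 <- sample(c("u", "v"), n, replace = TRUE)
      y <- rnorm(n) + (f1 == "b") * 0.8 + (f2 == "v") * 0.4
      res <- anova_twoway(y, f1, f2)
      # oracle: Type II SS via residual sums of squares of explicitly
      # solved least-squares fits (normal equations on design matrices)
      rss <- function(X) {
        b <- solve(crossprod(X), crossprod(X, y))
        sum((y - X %*% b)^2)
      }
      X_full <- model.matrix(~ factor(f1) + factor(f2))
      X_f1 <- model.matrix(~ factor(f1))
      X_f2 <- model.matrix(~ factor(f2))
      ss1 <- rss(X_f2) - rss(X_full)
      ss2 <- rss(X_f1) - rss(X_full)
      expect_equal(res$table$sum_sq[1], ss1, tolerance = 1e-9)
      expect_equal(res$table$sum_sq[2], ss2, tolerance = 1e-9)
      expect_equal(res$table$sum_sq[3], rss(X_full), tolerance = 1e-9)
      # residuals orthogonal to both factors' indicator columns
      r <- residuals(res$model)
      expect_lt(max(abs(crossprod(X_full, r))), 1e-9)
    }
  })
})

test_that("distribution export uses the linear-interpolation quantiles", {
  ex <- export_distribution(c(5, 3, 1, 4, 2), rep("g", 5))
  expect_equal(ex$sorted$g, 1:5)
  expect_equal(ex$summary[, .(min, q1, median, q3, max)],
               data.table::data.table(min = 1, q1 = 2, median = 3, q3 = 4,
                                      max = 5))
  sing <- export_distribution(4.2, "g")
  expect_true(all(unlist(sing$summary[, .(min, q1, median, q3, max)]) == 4.2))
  # empty groups are omitted
  ex2 <- export_distribution(c(1, 2), c("a", "a"))
  expect_equal(names(ex2$sorted), "a")
  expect_match(ex2$quantile_convention, "linear interpolation")
})
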