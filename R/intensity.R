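#' Convert PSMs to log10 intensity records
#'
#' The log10 transform of precursor intensity yields an approximately
#' normal distribution, so downstream comparisons (means, SE, ANOVA) are
#' performed on the log10 scale.
#'
#' @param psms Validated PSM table.
#' @param design A [treatment_design()]; every `treatment_id` in the
#'   input must be present in the panel.
#' @return A `data.table` with `treatment_id`, `label`, `gene_symbol`,
#'   `peptide`, `log10_intensity`.
#' @export
to_intensity_records <- function(psms, design = treatment_design()) {
  dt <- as.data.table(psms)
  if (nrow(dt) == 0)
    return(data.table(treatment_id = integer(), label = character(),
                      gene_symbol = character(), peptide = character(),
                      log10_intensity = numeric()))
  unknown <- setdiff(unique(dt$treatment_id), design$panel$treatment_id)
  if (length(unknown))
    stop("unknown treatment id(s): ", paste(unknown, collapse = ", "))
  if (any(!is.finite(dt$precursor_intensity) | dt$precursor_intensity <= 0))
    stop("non-positive precursor intensity encountered")
  out <- dt[, .(treatment_id, gene_symbol, peptide,
                log10_intensity = log10(precursor_intensity))]
  out <- merge(out, design$panel[, .(treatment_id, label)],
               by = "treatment_id", sort = FALSE)
  setcolorder(out, c("treatment_id", "label", "gene_symbol", "peptide",
                     "log10_intensity"))
  out[]
}

#' Per-treatment means of log10 intensity
#'
#' Mean, standard error and record count of log10 precursor intensity per
#' treatment, optionally restricted to one gene symbol and/or a peptide
#' whitelist (e.g. peptides within a stated parent-sequence window).
#' Every retained PSM counts as one record. SE is `sd/sqrt(n)` and is
#' reported as missing when `n = 1`; treatments with no records are
#' omitted.
#'
#' @param records Intensity records from [to_intensity_records()].
#' @param symbol Optional gene symbol to restrict to.
#' @param peptides Optional character vector of peptides to restrict to.
#' @return A `data.table` with `treatment_id`, `mean`, `se`, `n`.
#' @export
treatment_means <- function(records, symbol = NULL, peptides = NULL) {
  dt <- as.data.table(records)
  if (!is.null(symbol)) dt <- dt[gene_symbol == symbol]
  if (!is.null(peptides)) dt <- dt[peptide %in% peptides]
  if (nrow(dt) == 0)
    return(data.table(treatment_id = integer(), mean = numeric(),
                      se = numeric(), n = integer()))
  out <- dt[, .(mean = mean(log10_intensity),
                se = if (.N > 1) sd(log10_intensity) / sqrt(.N) else NA_real_,
                n = .N),
            by = treatment_id]
  setorderv(out, "treatment_id")
  out[]
}

#' One-way fixed-effects ANOVA
#'
#' Standard decomposition of a response over one categorical factor:
#' `F = MS_between / MS_within` with the p-value from the F
#' distribution. Two degenerate regimes are reported explicitly rather
#' than erroring: when every observation is identical the F statistic is
#' 0 with p = 1; when the within-group variance is zero but group means
#' differ, F is infinite with p = 0 and the result is flagged degenerate.
#'
#' @param values Numeric response vector.
#' @param groups Factor (or coercible) of the same length; at least two
#'   groups, at least one with two or more observations.
#' @return A list of class `anova_result`: `table` (a `data.frame` with
#'   rows for the factor and residuals: `term`, `df`, `sum_sq`,
#'   `mean_sq`, `F`, `pvalue`) and `degenerate` (logical).
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (length(values) != length(groups))
    stop("values and groups must have equal length")
  if (any(!is.finite(values))) stop("missing or non-finite response values")
  if (nlevels(droplevels(groups)) < 2)
    stop("factor 'groups' must have at least 2 levels")
  if (!any(table(groups) >= 2))
    stop("at least one group needs 2 or more observations")
  groups <- droplevels(groups)

  grand <- mean(values)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  ss_between <- sum(gn * (gm[levels(groups)] - grand)^2)
  ss_within <- sum((values - gm[as.character(groups)])^2)
  df_between <- nlevels(groups) - 1L
  df_within <- length(values) - nlevels(groups)

  ms_between <- ss_between / df_between
  ms_within <- if (df_within > 0) ss_within / df_within else NA_real_
  eps <- 1e-12 * max(1, sum(values^2))
  degenerate <- FALSE
  if (ss_within <= eps && ss_between <= eps) {
    f <- 0; p <- 1
  } else if (ss_within <= eps) {
    f <- Inf; p <- 0; degenerate <- TRUE
  } else {
    f <- ms_between / ms_within
    p <- stats::pf(f, df_between, df_within, lower.tail = FALSE)
  }
  tab <- data.frame(
    term = c("groups", "residuals"),
    df = c(df_between, df_within),
    sum_sq = c(ss_between, ss_within),
    mean_sq = c(ms_between, ms_within),
    F = c(f, NA_real_),
    pvalue = c(p, NA_real_))
  structure(list(table = tab, degenerate = degenerate),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  print(x$table, row.names = FALSE)
  if (isTRUE(x$degenerate))
    cat("note: degenerate fit (zero within-cell variance)\n")
  invisible(x)
}

#' Two-way additive ANOVA (Type II sums of squares)
#'
#' Additive fixed-effects model `response ~ factor1 + factor2` fit by
#' least squares, with Type II sums of squares per factor. No interaction
#' term is fit: in sparse treatment-by-peptide layouts many cells are
#' empty and the interaction is inestimable. Unbalanced and incomplete
#' designs are allowed.
#'
#' @param values Numeric response vector.
#' @param factor1,factor2 The two crossed categorical factors.
#' @param names Character vector of length 2 naming the factors in the
#'   output.
#' @return An `anova_result` with one row per factor plus residuals.
#' @export
anova_twoway <- function(values, factor1, factor2,
                         names = c("factor1", "factor2")) {
  f1 <- droplevels(factor(factor1))
  f2 <- droplevels(factor(factor2))
  if (length(values) != length(f1) || length(values) != length(f2))
    stop("values and factors must have equal length")
  if (any(!is.finite(values))) stop("missing or non-finite response values")
  if (nlevels(f1) < 2)
    stop("factor '", names[1], "' has a single level")
  if (nlevels(f2) < 2)
    stop("factor '", names[2], "' has a single level")

  dat <- data.frame(y = values, f1 = f1, f2 = f2)
  fit <- stats::lm(y ~ f1 + f2, data = dat)
  ss_res <- sum(stats::residuals(fit)^2)
  df_res <- stats::df.residual(fit)
  eps <- 1e-12 * max(1, sum(values^2))
  if (ss_res > eps) {
    a2 <- car::Anova(fit, type = 2)
    rows <- match(c("f1", "f2"), rownames(a2))
    ss_fac <- a2$`Sum Sq`[rows]
    df_fac <- a2$Df[rows]
    f_fac <- a2$`F value`[rows]
    p_fac <- a2$`Pr(>F)`[rows]
  } else {
    # zero residual variance breaks the standard Type II machinery;
    # compute each factor's SS directly as the drop from the marginal fit
    ss_fac <- c(sum(stats::residuals(stats::lm(y ~ f2, dat))^2) - ss_res,
                sum(stats::residuals(stats::lm(y ~ f1, dat))^2) - ss_res)
    df_fac <- c(nlevels(f1) - 1L, nlevels(f2) - 1L)
    f_fac <- p_fac <- c(NA_real_, NA_real_)
  }
  tab <- data.frame(
    term = c(names, "residuals"),
    df = c(df_fac, df_res),
    sum_sq = c(ss_fac, ss_res),
    mean_sq = c(ss_fac / df_fac,
                if (df_res > 0) ss_res / df_res else NA_real_),
    F = c(f_fac, NA_real_),
    pvalue = c(p_fac, NA_real_))
  degenerate <- FALSE
  if (ss_res <= eps) {
    # zero residual variance: factors with zero SS get F = 0, p = 1;
    # factors still explaining variance are flagged degenerate (F = Inf)
    zero <- tab$sum_sq[1:2] <= eps
    tab$F[1:2] <- ifelse(zero, 0, Inf)
    tab$pvalue[1:2] <- ifelse(zero, 1, 0)
    degenerate <- any(!zero)
  }
  structure(list(table = tab, degenerate = degenerate, model = fit),
            class = "anova_result")
}

#' Sorted samples and five-number summaries per group
#'
#' Exports, per group, the sorted sample (quantile-plot ready) and the
#' box-plot five-number summary min/Q1/median/Q3/max. Quartiles use the
#' linear-interpolation convention between order statistics
#' (`stats::quantile` type 7), recorded in the output metadata because
#' the convention affects small-n summaries. Empty groups are omitted.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length.
#' @return A list: `sorted` (named list of sorted numeric vectors),
#'   `summary` (a `data.table` with `group`, `min`, `q1`, `median`, `q3`,
#'   `max`, `n`) and `quantile_convention`.
#' @export
export_distribution <- function(values, groups) {
  if (length(values) != length(groups))
    stop("values and groups must have equal length")
  keep <- is.finite(values)
  values <- values[keep]
  groups <- as.character(groups)[keep]
  sorted <- lapply(split(values, groups), sort)
  summ <- rbindlist(lapply(names(sorted), function(g) {
    v <- sorted[[g]]
    q <- stats::quantile(v, probs = c(0, .25, .5, .75, 1), type = 7,
                         names = FALSE)
    data.table(group = g, min = q[1], q1 = q[2], median = q[3],
               q3 = q[4], max = q[5], n = length(v))
  }))
  list(sorted = sorted, summary = summ,
       quantile_convention = "linear interpolation (type 7)")
}
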