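# ROC/AUC estimation and the paired comparisons used to validate a two-stage
# screen against its one-stage parent: DeLong placement-value CIs and tests, a
# stratified bootstrap paired ROC test, McNemar paired accuracy tests, and
# Welch heteroscedastic one-way ANOVA for risk-tier group validation.

# Placement values (Sun & Xu midrank algorithm).  For diseased i,
# V10_i = P-hat(score_healthy < score_i) with ties counting 1/2; likewise V01
# for healthy.  mean(V10) = mean(V01) = AUC (Mann-Whitney with tie correction).
delong_placements <- function(scores, labels) {
  y <- as.logical(labels)
  if (!any(y) || all(y)) stop("both outcome classes must be present",
                              call. = FALSE)
  x <- scores[y]; z <- scores[!y]
  m <- length(x); n <- length(z)
  r_all <- rank(c(x, z))
  v10 <- (r_all[seq_len(m)] - rank(x)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(z)) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' AUC with a DeLong confidence interval
#'
#' Area under the ROC curve by the Mann-Whitney pair-counting estimator (ties
#' count one half), with variance from DeLong's placement-value method and a
#' normal-theory interval clipped to `[0, 1]`. Higher scores are taken to
#' indicate disease.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcome (1/TRUE = diseased).
#' @param ci_level Confidence level, default 0.95.
#' @return A list with `auc`, `ci_low`, `ci_high`, `se`, `n_diseased`,
#'   `n_healthy`.
#' @export
auc_delong <- function(scores, labels, ci_level = 0.95) {
  pl <- delong_placements(scores, labels)
  v <- stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  list(auc = pl$auc,
       ci_low = max(0, pl$auc - z * sqrt(v)),
       ci_high = min(1, pl$auc + z * sqrt(v)),
       se = sqrt(v), n_diseased = pl$m, n_healthy = pl$n)
}

#' DeLong test for two paired ROC curves
#'
#' Tests `AUC_a = AUC_b` for two scores measured on the same children using
#' the DeLong covariance of paired placement values;
#' `z = dAUC / sqrt(var(dAUC))` with a two-sided normal p-value.
#'
#' @param scores_a,scores_b Two risk scores for the same children.
#' @param labels Binary outcome.
#' @param ci_level Confidence level for the per-curve DeLong intervals.
#' @return An object of class `roc_comparison` with `auc1`, `auc2`,
#'   `delta_auc`, `ci1`, `ci2`, `statistic` (z), `p_value`,
#'   `method = "delong"`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels, ci_level = 0.95) {
  stopifnot(length(scores_a) == length(scores_b))
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  v <- stats::var(pa$v10 - pb$v10) / pa$m + stats::var(pa$v01 - pb$v01) / pa$n
  delta <- pa$auc - pb$auc
  z <- if (v > 0) delta / sqrt(v) else 0
  structure(list(auc1 = pa$auc, auc2 = pb$auc, delta_auc = delta,
                 ci1 = auc_delong(scores_a, labels, ci_level)[c("ci_low", "ci_high")],
                 ci2 = auc_delong(scores_b, labels, ci_level)[c("ci_low", "ci_high")],
                 statistic = z,
                 p_value = if (v > 0) 2 * stats::pnorm(-abs(z)) else 1,
                 method = "delong", n_boot = NA_integer_, seed = NA_integer_),
            class = "roc_comparison")
}

#' Stratified bootstrap test for two paired ROC curves
#'
#' Children are resampled with replacement separately within the diseased and
#' non-diseased strata (so every replicate contains both classes), keeping the
#' two scores of a child paired. The statistic is
#' `D = dAUC / sd(bootstrap dAUC)` with a two-sided normal p-value.
#'
#' @inheritParams delong_paired_test
#' @param n_boot Number of bootstrap replicates (>= 100), default 2000.
#' @param seed Integer seed; `NULL` continues the caller's RNG stream (used by
#'   the pipeline so all randomness flows from one configured seed).
#' @return An object of class `roc_comparison` with `statistic` (D) and
#'   `method = "bootstrap"`.
#' @export
bootstrap_paired_test <- function(scores_a, scores_b, labels, n_boot = 2000L,
                                  seed = NULL, ci_level = 0.95) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  if (n_boot < 100L) stop("'n_boot' must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  y <- as.logical(labels)
  if (!any(y) || all(y)) stop("both outcome classes must be present",
                              call. = FALSE)
  idx_d <- which(y); idx_h <- which(!y)
  m <- length(idx_d); n <- length(idx_h)

  fast_auc <- function(x, z) {
    r <- rank(c(x, z))
    (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
      (length(x) * length(z))
  }
  delta_obs <- fast_auc(scores_a[idx_d], scores_a[idx_h]) -
    fast_auc(scores_b[idx_d], scores_b[idx_h])
  deltas <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    di <- idx_d[sample.int(m, m, replace = TRUE)]
    hi <- idx_h[sample.int(n, n, replace = TRUE)]
    deltas[b] <- fast_auc(scores_a[di], scores_a[hi]) -
      fast_auc(scores_b[di], scores_b[hi])
  }
  sd_b <- stats::sd(deltas)
  D <- if (sd_b > 0) delta_obs / sd_b else 0
  structure(list(auc1 = fast_auc(scores_a[idx_d], scores_a[idx_h]),
                 auc2 = fast_auc(scores_b[idx_d], scores_b[idx_h]),
                 delta_auc = delta_obs,
                 ci1 = auc_delong(scores_a, labels, ci_level)[c("ci_low", "ci_high")],
                 ci2 = auc_delong(scores_b, labels, ci_level)[c("ci_low", "ci_high")],
                 statistic = D,
                 p_value = if (sd_b > 0) 2 * stats::pnorm(-abs(D)) else 1,
                 method = "bootstrap", n_boot = as.integer(n_boot),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("Paired ROC comparison (%s)\n", x$method))
  cat(sprintf("  AUC 1 = %.4f, AUC 2 = %.4f, dAUC = %.4f\n",
              x$auc1, x$auc2, x$delta_auc))
  cat(sprintf("  statistic = %.3f, p = %.4f\n", x$statistic, x$p_value))
  invisible(x)
}

#' McNemar test for paired binary accuracy
#'
#' Compares two screens on the same children via the discordant pairs:
#' `b` = correct under A only, `c` = correct under B only;
#' `chi2 = (b - c)^2 / (b + c)` without continuity correction, referred to
#' chi-square with 1 df (two-sided). When `b + c < 25` an exact two-sided
#' binomial p-value (`2 * P(Bin(b+c, 1/2) <= min(b, c))`, capped at 1) is also
#' reported.
#'
#' @param correct_a,correct_b Logical vectors: was each child classified
#'   correctly (e.g., among diseased children, "screen positive") by screen A
#'   and B respectively.
#' @return A `paired_binary_test` list with `discordant_b`, `discordant_c`,
#'   `chi_square`, `df`, `p_value`, and `p_exact` (`NA` unless `b + c < 25`).
#' @export
mcnemar_paired <- function(correct_a, correct_b) {
  stopifnot(length(correct_a) == length(correct_b))
  a <- as.logical(correct_a); bb <- as.logical(correct_b)
  b <- sum(a & !bb)
  cc <- sum(!a & bb)
  if (b + cc == 0L) {
    stop("no discordant pairs: the McNemar test is undefined", call. = FALSE)
  }
  chi <- (b - cc)^2 / (b + cc)
  p_exact <- if (b + cc < 25L) {
    min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
  } else {
    NA_real_
  }
  structure(list(discordant_b = b, discordant_c = cc, chi_square = chi,
                 df = 1L, p_value = stats::pchisq(chi, 1, lower.tail = FALSE),
                 p_exact = p_exact),
            class = "paired_binary_test")
}

#' Welch heteroscedastic one-way ANOVA with eta-squared
#'
#' Welch's F with Welch-Satterthwaite fractional denominator degrees of
#' freedom, plus per-group means/SDs and eta-squared computed from the
#' between-group and total sums of squares of the pooled sample.
#'
#' @param groups A named (or unnamed) list of numeric vectors, one per group;
#'   at least two groups, each with at least two values and positive variance.
#' @return A `group_comparison` list with `means`, `sds`, `ns`, `welch_F`,
#'   `df1`, `df2`, `p_value`, `eta_squared`.
#' @export
welch_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group needs at least 2 values", call. = FALSE)
  vars <- vapply(groups, stats::var, numeric(1))
  if (any(vars <= 0)) stop("every group needs positive variance", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))

  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), sizes), levels = names(groups))
  wt <- stats::oneway.test(values ~ g, var.equal = FALSE)

  means <- vapply(groups, mean, numeric(1))
  grand <- mean(values)
  ss_between <- sum(sizes * (means - grand)^2)
  ss_total <- sum((values - grand)^2)

  structure(list(means = means, sds = sqrt(vars), ns = sizes,
                 welch_F = unname(wt$statistic),
                 df1 = unname(wt$parameter[1]),
                 df2 = unname(wt$parameter[2]),
                 p_value = unname(wt$p.value),
                 eta_squared = ss_between / ss_total),
            class = "group_comparison")
}
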