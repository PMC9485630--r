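# Two-stage score composition, constrained cutoffs, risk tiers, and all
# confusion-matrix accuracy statistics.
#
# Orientation convention used everywhere: higher score = higher risk, and a
# child screens POSITIVE iff score >= cutoff.  Candidate cutoffs are the
# midpoints between adjacent distinct observed scores plus -Inf and +Inf, so
# selected cutoffs do not sit on arbitrary observed values.

#' Confusion counts at a cutoff
#'
#' @param scores Numeric risk scores (higher = higher risk).
#' @param labels Binary outcome (1/TRUE = diseased).
#' @param cutoff Positive screen iff `score >= cutoff`.
#' @return A `confusion_counts` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at <- function(scores, labels, cutoff) {
  if (length(scores) == 0L) stop("empty input", call. = FALSE)
  stopifnot(length(scores) == length(labels))
  y <- as.logical(labels)
  pos <- scores >= cutoff
  confusion_counts(tp = sum(pos & y), fp = sum(pos & !y),
                   tn = sum(!pos & !y), fn = sum(!pos & y))
}

#' Construct confusion counts directly
#'
#' @param tp,fp,tn,fn Non-negative integer cell counts.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(counts), class = "confusion_counts")
}

# Clopper-Pearson exact interval for x successes out of n
clopper_pearson <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

#' Diagnostic accuracy statistics with confidence intervals
#'
#' Sensitivity, specificity, predictive values and the screening failure rate
#' with Clopper-Pearson exact intervals; positive and negative diagnostic
#' likelihood ratios (`DLR+ = Se/(1-Sp)`, `DLR- = (1-Se)/Sp`) with log-method
#' (Simel) intervals. A statistic whose denominator is zero (or a likelihood
#' ratio with a zero cell) is reported as `NA` with the reason recorded in the
#' `undefined` element rather than propagating `NaN`.
#'
#' @param counts A `confusion_counts` object.
#' @param ci_level Confidence level, default 0.95.
#' @return An object of class `diagnostic_stats`: a list of
#'   `(estimate, ci_low, ci_high)` triplets for `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `dlr_pos`, `dlr_neg`, `fail_rate`, plus `counts` and
#'   `undefined` (named character vector of reasons).
#' @export
diagnostic_stats <- function(counts, ci_level = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0L) stop("all counts are zero", call. = FALSE)
  undefined <- character()
  prop <- function(x, n, what) {
    if (n == 0L) {
      undefined[[what]] <<- paste0(what, " undefined: denominator is zero")
      return(list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
    }
    ci <- clopper_pearson(x, n, ci_level)
    list(estimate = x / n, ci_low = ci[1], ci_high = ci[2])
  }
  se <- prop(tp, tp + fn, "sensitivity")
  sp <- prop(tn, tn + fp, "specificity")
  ppv <- prop(tp, tp + fp, "ppv")
  npv <- prop(tn, tn + fn, "npv")
  fail <- prop(tp + fp, total, "fail_rate")

  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  dlr <- function(num, den, var_terms, what) {
    if (is.na(num) || is.na(den) || den == 0 || num == 0 ||
        any(!is.finite(var_terms))) {
      undefined[[what]] <<- paste0(what,
        " undefined: requires non-zero sensitivity/specificity cells")
      return(list(estimate = if (!is.na(num) && !is.na(den) && den > 0)
        num / den else NA_real_, ci_low = NA_real_, ci_high = NA_real_))
    }
    est <- num / den
    se_log <- sqrt(sum(var_terms))
    list(estimate = est, ci_low = exp(log(est) - z * se_log),
         ci_high = exp(log(est) + z * se_log))
  }
  # Simel et al. log-method variances
  dlr_pos <- dlr(se$estimate, 1 - sp$estimate,
                 c(if (tp > 0) (1 - se$estimate) / tp else Inf,
                   if (fp > 0) sp$estimate / fp else Inf),
                 "dlr_pos")
  dlr_neg <- dlr(1 - se$estimate, sp$estimate,
                 c(if (fn > 0) se$estimate / fn else Inf,
                   if (tn > 0) (1 - sp$estimate) / tn else Inf),
                 "dlr_neg")

  structure(list(sensitivity = se, specificity = sp, ppv = ppv, npv = npv,
                 dlr_pos = dlr_pos, dlr_neg = dlr_neg, fail_rate = fail,
                 counts = counts, ci_level = ci_level,
                 undefined = undefined),
            class = "diagnostic_stats")
}

#' @export
print.diagnostic_stats <- function(x, ...) {
  nm <- c("sensitivity", "specificity", "ppv", "npv", "dlr_pos", "dlr_neg",
          "fail_rate")
  tab <- do.call(rbind, lapply(x[nm], function(s)
    data.frame(estimate = s$estimate, ci_low = s$ci_low, ci_high = s$ci_high)))
  rownames(tab) <- nm
  print(format(tab, digits = 3))
  if (length(x$undefined) > 0L) cat(paste(x$undefined, collapse = "\n"), "\n")
  invisible(x)
}

#' Stratum-specific (category) positive likelihood ratios
#'
#' For a multi-level screening result (risk tiers), the likelihood ratio of
#' tier *t* is `(diseased_t / diseased_total) / (nondiseased_t /
#' nondiseased_total)`: the factor by which membership in the tier multiplies
#' the pre-screening odds of disease.
#'
#' @param tiers A `data.frame` with columns `tier`, `diseased`,
#'   `non_diseased` (counts per tier).
#' @return The input with an added `dlr` column (`NA` with a `reason` for an
#'   empty tier or a zero non-diseased total share).
#' @export
category_dlr <- function(tiers) {
  stopifnot(is.data.frame(tiers),
            all(c("tier", "diseased", "non_diseased") %in% names(tiers)))
  D <- sum(tiers$diseased)
  H <- sum(tiers$non_diseased)
  if (D == 0L || H == 0L) {
    stop("overall diseased and non-diseased totals must be positive",
         call. = FALSE)
  }
  empty <- (tiers$diseased + tiers$non_diseased) == 0L
  dlr <- ifelse(empty, NA_real_,
                (tiers$diseased / D) / (tiers$non_diseased / H))
  tiers$dlr <- dlr
  tiers$reason <- ifelse(empty, "empty tier: likelihood ratio undefined", "")
  tiers
}

candidate_cutoffs <- function(scores) {
  s <- sort(unique(scores))
  if (length(s) < 2L) {
    stop("degenerate score vector: all scores are equal", call. = FALSE)
  }
  c(-Inf, (s[-1L] + s[-length(s)]) / 2, Inf)
}

cutpoint_table <- function(scores, labels) {
  y <- as.logical(labels)
  if (!any(y) || all(y)) stop("both outcome classes must be present",
                              call. = FALSE)
  cand <- candidate_cutoffs(scores)
  n_d <- sum(y); n_h <- sum(!y)
  tp <- vapply(cand, function(ct) sum(scores >= ct & y), numeric(1))
  fp <- vapply(cand, function(ct) sum(scores >= ct & !y), numeric(1))
  data.frame(cutoff = cand, tp = tp, fp = fp,
             se = tp / n_d, sp = (n_h - fp) / n_h,
             ppv = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_))
}

#' Cutoff achieving a target sensitivity
#'
#' Searches all candidate cutoffs (midpoints of adjacent distinct scores plus
#' the infinities) and selects the one whose sensitivity is closest to
#' `target_se`; ties are broken by higher specificity, then by the higher
#' cutoff.
#'
#' @inheritParams confusion_at
#' @param target_se Target sensitivity in (0, 1].
#' @param ci_level Confidence level for the accompanying statistics.
#' @return A list with `cutoff`, `counts` (a `confusion_counts`), and `stats`
#'   (a [diagnostic_stats()] object).
#' @export
cutoff_for_sensitivity <- function(scores, labels, target_se,
                                   ci_level = 0.95) {
  tab <- cutpoint_table(scores, labels)
  best <- order(abs(tab$se - target_se), -tab$sp, -tab$cutoff)[1L]
  ct <- tab$cutoff[best]
  counts <- confusion_at(scores, labels, ct)
  list(cutoff = ct, counts = counts,
       stats = diagnostic_stats(counts, ci_level))
}

#' Cutoff achieving a target positive predictive value
#'
#' Among candidate cutoffs with `PPV >= target_ppv`, selects the one
#' maximizing sensitivity (ties broken by the lower cutoff). If no cutoff
#' reaches the target, the cutoff with the maximal attainable PPV is returned
#' and `target_met` is `FALSE`.
#'
#' @inheritParams cutoff_for_sensitivity
#' @param target_ppv Target PPV in `[0, 1]`.
#' @return A list with `cutoff`, `counts`, `stats`, and `target_met`.
#' @export
cutoff_for_ppv <- function(scores, labels, target_ppv, ci_level = 0.95) {
  tab <- cutpoint_table(scores, labels)
  ok <- which(!is.na(tab$ppv) & tab$ppv >= target_ppv)
  if (length(ok) > 0L) {
    best <- ok[order(-tab$se[ok], tab$cutoff[ok])[1L]]
    target_met <- TRUE
  } else {
    with_ppv <- which(!is.na(tab$ppv))
    best <- with_ppv[which.max(tab$ppv[with_ppv])]
    target_met <- FALSE
    warning("no cutoff reaches PPV >= ", target_ppv,
            "; returning the cutoff with maximal PPV", call. = FALSE)
  }
  ct <- tab$cutoff[best]
  counts <- confusion_at(scores, labels, ct)
  list(cutoff = ct, counts = counts,
       stats = diagnostic_stats(counts, ci_level), target_met = target_met)
}

#' Compose the total two-stage screening score
#'
#' The total score equals the stage-1 probability for children who passed
#' stage 1 and the stage-2 probability for children who failed it. A child
#' fails stage 1 iff `stage1_prob >= stage1_cutoff` (a score exactly at the
#' cutoff fails).
#'
#' @param stage1_prob Stage-1 SLD probabilities, one per child.
#' @param stage1_cutoff Stage-1 failure cutoff on the probability scale.
#' @param stage2_prob Stage-2 probabilities; must be non-missing for every
#'   stage-1 failure (values for passes, if any, are ignored).
#' @return A `data.frame` with `stage1_prob`, `stage1_fail`, `stage2_prob`
#'   (`NA` for passes), and `total_score`.
#' @export
compose_two_stage <- function(stage1_prob, stage1_cutoff, stage2_prob) {
  stopifnot(length(stage2_prob) == length(stage1_prob))
  fail <- stage1_prob >= stage1_cutoff
  bad <- which(fail & is.na(stage2_prob))
  if (length(bad) > 0L) {
    stop("missing stage-2 probability for ", length(bad),
         " stage-1 failure(s) (first at position ", bad[1L], ")",
         call. = FALSE)
  }
  s2 <- ifelse(fail, stage2_prob, NA_real_)
  data.frame(stage1_prob = stage1_prob, stage1_fail = fail,
             stage2_prob = s2,
             total_score = ifelse(fail, s2, stage1_prob))
}

#' Assign risk tiers and summarize the screening flow
#'
#' `high` iff `total_score >= cut_high`; `moderate` iff `cut_moderate <=
#' total_score < cut_high`; `low` otherwise.
#'
#' @param total_score Total two-stage screening scores.
#' @param cut_high,cut_moderate Tier cutoffs, `cut_high >= cut_moderate`.
#' @param labels Optional binary outcome; when present the summary carries
#'   per-tier diseased counts, tier prevalence and category likelihood ratios.
#' @return A list with `tier` (factor `low < moderate < high`) and `summary`
#'   (per-tier `data.frame`).
#' @export
stratify_risk <- function(total_score, cut_high, cut_moderate, labels = NULL) {
  if (cut_high < cut_moderate) {
    stop("'cut_high' must be >= 'cut_moderate'", call. = FALSE)
  }
  tier <- factor(ifelse(total_score >= cut_high, "high",
                        ifelse(total_score >= cut_moderate, "moderate", "low")),
                 levels = c("low", "moderate", "high"), ordered = TRUE)
  summary <- data.frame(tier = levels(tier),
                        n = as.integer(table(tier)),
                        proportion = as.numeric(table(tier)) / length(tier))
  if (!is.null(labels)) {
    y <- as.logical(labels)
    summary$diseased <- as.integer(tapply(y, tier, sum, default = 0L))
    summary$non_diseased <- summary$n - summary$diseased
    summary$tier_prevalence <- ifelse(summary$n > 0,
                                      summary$diseased / summary$n, NA_real_)
    summary <- category_dlr(summary)
  }
  list(tier = tier, summary = summary)
}
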