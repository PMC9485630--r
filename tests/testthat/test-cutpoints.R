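# Confusion counts, accuracy statistics, category DLRs, constrained cutoffs,
# two-stage composition, risk tiers.

test_that("confusion counts match per-record classification", {
  expect_equal(unclass(confusion_at(c(0.9, 0.1), c(1, 0), 0.5))[c("tp", "fp", "tn", "fn")],
               list(tp = 1L, fp = 0L, tn = 1L, fn = 0L))
  cm <- confusion_at(c(0.9, 0.1), c(1, 0), 0.95)
  expect_equal(cm$tp + cm$fp, 0L)

  fx <- make_score_fixture(20, seed = 5)
  for (ct in c(-1, 0, 0.4, 1.2)) {
    got <- confusion_at(fx$scores, fx$labels, ct)
    want <- bf_confusion(fx$scores, fx$labels, ct)
    expect_equal(unclass(got)[names(want)], want)
  }
  expect_error(confusion_at(numeric(0), logical(0), 0.5), "empty")
})

test_that("accuracy statistics reproduce the published worked examples", {
  # stage-1 operating point: 63/70 detected, 224 of 621 fail
  st1 <- diagnostic_stats(confusion_counts(tp = 63, fp = 161, tn = 390, fn = 7))
  expect_equal(st1$sensitivity$estimate, 0.900, tolerance = 1e-3)
  expect_equal(st1$specificity$estimate, 0.708, tolerance = 1e-3)
  expect_equal(st1$ppv$estimate, 0.281, tolerance = 1e-3)
  expect_equal(st1$npv$estimate, 0.982, tolerance = 1e-3)
  expect_equal(st1$dlr_pos$estimate, 3.080, tolerance = 1e-3)
  expect_equal(round(st1$dlr_neg$estimate, 3), 0.141)

  # high-risk tier: 20 of 25 screen-positives have the deficit
  high <- diagnostic_stats(confusion_counts(tp = 20, fp = 5, tn = 546, fn = 50))
  expect_equal(high$ppv$estimate, 0.80)
  expect_equal(high$sensitivity$estimate, 20 / 70)

  # moderate+high: 52 of 70 detected, 476 of 551 healthy cleared
  ms <- diagnostic_stats(confusion_counts(tp = 52, fp = 75, tn = 476, fn = 18))
  expect_equal(ms$sensitivity$estimate, 0.743, tolerance = 1e-3)
  expect_equal(ms$specificity$estimate, 0.864, tolerance = 1e-3)
})

test_that("zero denominators yield explained undefined statistics, not NaN", {
  st <- diagnostic_stats(confusion_counts(tp = 0, fp = 0, tn = 10, fn = 5))
  expect_true(is.na(st$ppv$estimate))
  expect_match(st$undefined[["ppv"]], "denominator")
  expect_false(any(vapply(st[c("sensitivity", "specificity", "npv")],
                          function(s) is.nan(s$estimate), logical(1))))
})

test_that("DLR identities hold to 1e-12 and intervals use the log method", {
  fx <- make_score_fixture(200, seed = 9)
  st <- diagnostic_stats(confusion_at(fx$scores, fx$labels, 0.3))
  se <- st$sensitivity$estimate; sp <- st$specificity$estimate
  expect_equal(st$dlr_pos$estimate, se / (1 - sp), tolerance = 1e-12)
  expect_equal(st$dlr_neg$estimate, (1 - se) / sp, tolerance = 1e-12)
  # log-method interval is symmetric on the log scale
  expect_equal(log(st$dlr_pos$ci_high) - log(st$dlr_pos$estimate),
               log(st$dlr_pos$estimate) - log(st$dlr_pos$ci_low),
               tolerance = 1e-10)
  # proportion CIs are exact Clopper-Pearson
  cm <- st$counts
  bt <- binom.test(cm$tp, cm$tp + cm$fn)$conf.int
  expect_equal(c(st$sensitivity$ci_low, st$sensitivity$ci_high),
               as.numeric(bt), tolerance = 1e-9)
})

test_that("category DLRs reproduce the published high-risk value", {
  tiers <- data.frame(tier = c("high", "moderate", "low"),
                      diseased = c(20, 32, 18),
                      non_diseased = c(5, 70, 476))
  got <- category_dlr(tiers)
  expect_equal(got$dlr[1], 31.486, tolerance = 1e-3)
  expect_equal(got$dlr, (tiers$diseased / 70) / (tiers$non_diseased / 551),
               tolerance = 1e-12)
  # tier shares over exhaustive tiers sum to one
  expect_equal(sum(tiers$diseased) / 70, 1)
  expect_equal(sum(tiers$non_diseased) / 551, 1)

  # a tier containing all children has LR exactly 1
  all_in <- category_dlr(data.frame(tier = "all", diseased = 70,
                                    non_diseased = 551))
  expect_equal(all_in$dlr, 1)
  empty <- category_dlr(data.frame(tier = c("a", "b"), diseased = c(70, 0),
                                   non_diseased = c(551, 0)))
  expect_true(is.na(empty$dlr[2]))
  expect_match(empty$reason[2], "empty tier")
})

test_that("sensitivity-targeted cutoff matches exhaustive enumeration", {
  scores <- c(0.9, 0.7, 0.3, 0.6, 0.2, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  res <- cutoff_for_sensitivity(scores, labels, 2 / 3)
  expect_equal(res$cutoff, 0.65)  # Se = 2/3 with Sp = 1 beats Sp = 2/3 tie
  expect_equal(res$stats$sensitivity$estimate, 2 / 3)
  expect_equal(res$stats$specificity$estimate, 1)

  res1 <- cutoff_for_sensitivity(scores, labels, 1.0)
  expect_equal(res1$stats$sensitivity$estimate, 1)
  expect_lt(res1$cutoff, 0.3)

  expect_error(cutoff_for_sensitivity(rep(0.4, 6), labels, 0.9), "degenerate")
})

test_that("PPV-targeted cutoff maximizes sensitivity among qualifying points", {
  scores <- c(0.9, 0.7, 0.3, 0.6, 0.2, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  res <- cutoff_for_ppv(scores, labels, 1.0)
  expect_equal(res$cutoff, 0.65)
  expect_equal(res$stats$ppv$estimate, 1)
  expect_equal(res$stats$sensitivity$estimate, 2 / 3)
  expect_true(res$target_met)

  res0 <- cutoff_for_ppv(scores, labels, 0)
  expect_equal(res0$cutoff, -Inf)
  expect_equal(res0$stats$sensitivity$estimate, 1)
})

test_that("constrained searches equal brute-force scans on random fixtures", {
  for (seed in 1:25) {
    fx <- make_score_fixture(60, seed = seed)
    for (target in c(0.5, 0.75, 0.9)) {
      expect_equal(cutoff_for_sensitivity(fx$scores, fx$labels, target)$cutoff,
                   bf_cutoff_for_sensitivity(fx$scores, fx$labels, target))
    }
    for (target in c(0.3, 0.6, 0.8)) {
      got <- suppressWarnings(cutoff_for_ppv(fx$scores, fx$labels, target))
      expect_equal(got$cutoff, bf_cutoff_for_ppv(fx$scores, fx$labels, target))
    }
  }
})

test_that("sensitivity and 1-specificity are non-increasing in the cutoff", {
  fx <- make_score_fixture(150, seed = 3)
  cand <- sort(unique(fx$scores))
  se <- sp1 <- numeric(length(cand))
  for (i in seq_along(cand)) {
    st <- diagnostic_stats(confusion_at(fx$scores, fx$labels, cand[i]))
    se[i] <- st$sensitivity$estimate
    sp1[i] <- 1 - st$specificity$estimate
  }
  expect_true(all(diff(se) <= 1e-12))
  expect_true(all(diff(sp1) <= 1e-12))
})

test_that("two-stage composition follows the pass/fail rule with >= boundary", {
  res <- compose_two_stage(c(0.03, 0.30, 0.05),
                           stage1_cutoff = 0.05,
                           stage2_prob = c(NA, 0.55, 0.40))
  expect_equal(res$stage1_fail, c(FALSE, TRUE, TRUE))  # exactly at cutoff fails
  expect_equal(res$total_score, c(0.03, 0.55, 0.40))
  expect_true(is.na(res$stage2_prob[1]))
  expect_error(compose_two_stage(c(0.2, 0.8), 0.1, c(0.3, NA)),
               "missing stage-2")
})

test_that("risk tiers match the published cutoffs and brute-force counts", {
  tiers <- stratify_risk(c(0.9, 0.3, 0.01), cut_high = 0.594,
                         cut_moderate = 0.169)
  expect_equal(as.character(tiers$tier), c("high", "moderate", "low"))

  eq <- stratify_risk(c(0.2, 0.5, 0.05), cut_high = 0.3, cut_moderate = 0.3)
  expect_equal(sum(eq$tier == "moderate"), 0L)
  expect_error(stratify_risk(0.5, cut_high = 0.1, cut_moderate = 0.2),
               "cut_high")

  fx <- make_score_fixture(500, seed = 13)
  s <- plogis(fx$scores)
  res <- stratify_risk(s, cut_high = 0.6, cut_moderate = 0.4,
                       labels = fx$labels)
  bf <- table(ifelse(s >= 0.6, "high", ifelse(s >= 0.4, "moderate", "low")))
  expect_equal(res$summary$n[res$summary$tier == "high"], unname(bf["high"]))
  expect_equal(res$summary$n[res$summary$tier == "low"], unname(bf["low"]))
  expect_equal(sum(res$summary$n), 500L)
  expect_equal(sum(res$summary$diseased), sum(fx$labels))
})
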