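# AUC, DeLong and bootstrap paired ROC tests, McNemar, Welch ANOVA.

test_that("AUC equals explicit pair counting, including ties", {
  expect_equal(auc_delong(c(0.8, 0.6, 0.7, 0.1), c(1, 1, 0, 0))$auc, 0.75)

  fx <- make_score_fixture(80, seed = 2)
  fx$scores <- round(fx$scores, 1)  # induce ties
  expect_equal(auc_delong(fx$scores, fx$labels)$auc,
               bf_auc(fx$scores, fx$labels), tolerance = 1e-12)

  perfect <- auc_delong(c(5, 6, 1, 2), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_error(auc_delong(1:5, rep(1, 5)), "both outcome classes")
})

test_that("uninformative scores give AUC compatible with one half", {
  set.seed(6)
  scores <- rnorm(10000)
  labels <- rbinom(10000, 1, 0.2)
  a <- auc_delong(scores, labels)
  expect_true(a$ci_low <= 0.5 && 0.5 <= a$ci_high)
})

test_that("DeLong AUC and CI agree with the pROC reference implementation", {
  fx <- make_score_fixture(300, seed = 4)
  ours <- auc_delong(fx$scores, fx$labels)
  ref <- pROC::roc(fx$labels, fx$scores, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(c(ours$ci_low, ours$ci_high),
               as.numeric(pROC::ci.auc(ref, method = "delong"))[c(1, 3)],
               tolerance = 1e-9)
})

test_that("the paired DeLong test matches pROC and degenerates sensibly", {
  fx <- make_score_fixture(200, seed = 8)
  set.seed(9)
  other <- fx$scores + rnorm(200, sd = 0.8)

  same <- delong_paired_test(fx$scores, fx$scores, fx$labels)
  expect_equal(same$delta_auc, 0)
  expect_equal(same$p_value, 1)

  ours <- delong_paired_test(fx$scores, other, fx$labels)
  expect_equal(ours$delta_auc, ours$auc1 - ours$auc2, tolerance = 1e-12)
  ra <- pROC::roc(fx$labels, fx$scores, quiet = TRUE, direction = "<")
  rb <- pROC::roc(fx$labels, other, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(unname(ours$statistic), unname(as.numeric(ref$statistic)),
               tolerance = 1e-9)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("DeLong variance approximates a jackknife estimate", {
  fx <- make_score_fixture(50, seed = 10)
  ours <- auc_delong(fx$scores, fx$labels)
  n <- 50
  loo <- vapply(seq_len(n), function(i) {
    bf_auc(fx$scores[-i], fx$labels[-i])
  }, numeric(1))
  jack_var <- (n - 1) / n * sum((loo - mean(loo))^2)
  expect_lt(abs(ours$se^2 - jack_var) / jack_var, 0.10)
})

test_that("the stratified bootstrap test is reproducible and consistent
           with DeLong on a clear AUC gap", {
  fx <- make_score_fixture(600, seed = 11, auc_gap = 1.5)
  set.seed(12)
  weaker <- fx$scores + rnorm(600, sd = 1.5)

  b1 <- bootstrap_paired_test(fx$scores, weaker, fx$labels, n_boot = 500,
                              seed = 99)
  b2 <- bootstrap_paired_test(fx$scores, weaker, fx$labels, n_boot = 500,
                              seed = 99)
  expect_identical(b1$statistic, b2$statistic)
  expect_identical(b1$p_value, b2$p_value)

  dl <- delong_paired_test(fx$scores, weaker, fx$labels)
  expect_equal(sign(b1$statistic), sign(dl$statistic))
  expect_lt(b1$p_value, 0.05)
  expect_lt(dl$p_value, 0.05)

  ident <- bootstrap_paired_test(fx$scores, fx$scores, fx$labels,
                                 n_boot = 200, seed = 1)
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_error(bootstrap_paired_test(fx$scores, weaker, fx$labels,
                                     n_boot = 50, seed = 1), "at least 100")
})

test_that("bootstrap D approaches the DeLong z as replicates grow", {
  fx <- make_score_fixture(400, seed = 13)
  set.seed(14)
  other <- 0.7 * fx$scores + rnorm(400, sd = 0.7)
  dl <- delong_paired_test(fx$scores, other, fx$labels)
  d_small <- bootstrap_paired_test(fx$scores, other, fx$labels,
                                   n_boot = 200, seed = 7)$statistic
  d_big <- bootstrap_paired_test(fx$scores, other, fx$labels,
                                 n_boot = 4000, seed = 7)$statistic
  expect_equal(sign(d_big), sign(dl$statistic))
  expect_lte(abs(d_big - dl$statistic), abs(d_small - dl$statistic) + 0.05)
  expect_lt(abs(d_big - dl$statistic) / abs(dl$statistic), 0.25)
})

test_that("McNemar chi-square, exact p and the stats oracle agree", {
  correct_a <- c(rep(TRUE, 15), rep(FALSE, 3), rep(TRUE, 40))
  correct_b <- c(rep(FALSE, 15), rep(TRUE, 3), rep(TRUE, 40))
  got <- mcnemar_paired(correct_a, correct_b)
  expect_equal(got$chi_square, 8)  # (15-3)^2 / 18
  ref <- mcnemar.test(table(correct_a, correct_b), correct = FALSE)
  expect_equal(got$chi_square, unname(ref$statistic))
  expect_equal(got$p_value, unname(ref$p.value))
  expect_equal(got$p_exact, min(1, 2 * pbinom(3, 18, 0.5)))

  tie <- mcnemar_paired(c(TRUE, FALSE, TRUE, TRUE), c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(tie$chi_square, 0)
  expect_equal(tie$p_value, 1)
  expect_error(mcnemar_paired(c(TRUE, TRUE), c(TRUE, TRUE)), "discordant")

  # exact two-sided binomial oracle at b + c = 10
  e <- mcnemar_paired(c(rep(TRUE, 8), rep(FALSE, 2)),
                      c(rep(FALSE, 8), rep(TRUE, 2)))
  expect_equal(e$p_exact, min(1, 2 * pbinom(2, 10, 0.5)))
})

test_that("Welch ANOVA matches oneway.test, t^2 identity and eta-squared", {
  set.seed(15)
  g <- list(a = rnorm(30), b = rnorm(25, 1), c = rnorm(40, 2, 2))
  got <- welch_anova(g)
  ref <- oneway.test(v ~ grp, data = data.frame(
    v = unlist(g), grp = rep(names(g), lengths(g))), var.equal = FALSE)
  expect_equal(got$welch_F, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(got$df2, unname(ref$parameter[2]), tolerance = 1e-9)

  # two groups: F equals the square of Welch's t
  g2 <- g[c("a", "c")]
  t2 <- t.test(g2$a, g2$c)$statistic^2
  expect_equal(welch_anova(g2)$welch_F, unname(t2), tolerance = 1e-9)

  # identical groups: F = 0
  same <- list(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4))
  expect_equal(welch_anova(same)$welch_F, 0)

  # eta-squared from sums of squares
  values <- unlist(g); grand <- mean(values)
  ssb <- sum(lengths(g) * (vapply(g, mean, numeric(1)) - grand)^2)
  sst <- sum((values - grand)^2)
  expect_equal(got$eta_squared, ssb / sst, tolerance = 1e-12)
  expect_error(welch_anova(list(a = 1, b = c(1, 2))), "at least 2")
})
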