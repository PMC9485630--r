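# Independent brute-force oracles used across the suite.  These deliberately
# use naive per-record loops so they share no code with the implementations
# they check.

# AUC by explicit pair counting (ties count one half)
bf_auc <- function(scores, labels) {
  x <- scores[as.logical(labels)]
  y <- scores[!as.logical(labels)]
  total <- 0
  for (xi in x) for (yj in y) {
    total <- total + (xi > yj) + 0.5 * (xi == yj)
  }
  total / (length(x) * length(y))
}

# confusion counts by per-record classification
bf_confusion <- function(scores, labels, cutoff) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(scores)) {
    pos <- scores[i] >= cutoff
    dis <- as.logical(labels[i])
    if (pos && dis) tp <- tp + 1L
    if (pos && !dis) fp <- fp + 1L
    if (!pos && !dis) tn <- tn + 1L
    if (!pos && dis) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

bf_candidates <- function(scores) {
  s <- sort(unique(scores))
  c(-Inf, (s[-1] + s[-length(s)]) / 2, Inf)
}

# exhaustive scan: sensitivity closest to target, ties -> higher specificity,
# then higher cutoff
bf_cutoff_for_sensitivity <- function(scores, labels, target) {
  best <- NULL
  for (ct in bf_candidates(scores)) {
    cm <- bf_confusion(scores, labels, ct)
    se <- cm$tp / (cm$tp + cm$fn)
    sp <- cm$tn / (cm$tn + cm$fp)
    cand <- list(cutoff = ct, dist = abs(se - target), sp = sp)
    if (is.null(best) ||
        cand$dist < best$dist - 1e-15 ||
        (abs(cand$dist - best$dist) <= 1e-15 && cand$sp > best$sp + 1e-15) ||
        (abs(cand$dist - best$dist) <= 1e-15 && abs(cand$sp - best$sp) <= 1e-15 &&
         cand$cutoff > best$cutoff)) {
      best <- cand
    }
  }
  best$cutoff
}

# exhaustive scan: among PPV >= target maximize sensitivity, ties -> lower
# cutoff; if none qualifies, maximal PPV
bf_cutoff_for_ppv <- function(scores, labels, target) {
  qualifying <- NULL
  fallback <- NULL
  for (ct in bf_candidates(scores)) {
    cm <- bf_confusion(scores, labels, ct)
    if (cm$tp + cm$fp == 0L) next
    ppv <- cm$tp / (cm$tp + cm$fp)
    se <- cm$tp / (cm$tp + cm$fn)
    if (ppv >= target) {
      if (is.null(qualifying) || se > qualifying$se + 1e-15 ||
          (abs(se - qualifying$se) <= 1e-15 && ct < qualifying$cutoff)) {
        qualifying <- list(cutoff = ct, se = se)
      }
    }
    if (is.null(fallback) || ppv > fallback$ppv + 1e-15) {
      fallback <- list(cutoff = ct, ppv = ppv)
    }
  }
  if (!is.null(qualifying)) qualifying$cutoff else fallback$cutoff
}

# a reusable small scored fixture
make_score_fixture <- function(n, seed, auc_gap = 1) {
  set.seed(seed)
  labels <- rbinom(n, 1, 0.3)
  scores <- rnorm(n, mean = auc_gap * labels)
  list(scores = scores, labels = labels)
}
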