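# End-to-end screening construction and validation:
# cohort -> stage-1 model (backward LR elimination) -> stage-1 cutoff at a
# fixed sensitivity -> stage-2 model on stage-1 failures (adding word
# comprehension) -> total two-stage score -> paired ROC comparison ->
# constrained tier cutoffs -> risk-tier flow report and group validation.

#' Pipeline configuration
#'
#' @param generator A [generator_config()] to simulate the cohort, or `NULL`.
#' @param cohort A cohort `data.frame`, or a path to a cohort CSV; ignored if
#'   `generator` is given.
#' @param stage1_candidates Candidate predictor columns for stage 1 (design
#'   columns; parental education enters as three dummies with `university` as
#'   the reference).
#' @param stage1_target_se Sensitivity fixed for the stage-1 failure cutoff,
#'   default 0.90.
#' @param high_risk_target_ppv PPV fixed for the high-risk cutoff, default
#'   0.80.
#' @param moderate_target_se Sensitivity target for the moderate-risk cutoff,
#'   one of 0.75 / 0.80 / 0.85, default 0.75.
#' @param removal_alpha Backward-elimination removal threshold, default 0.10.
#' @param ci_level Confidence level for all intervals, default 0.95.
#' @param n_boot Bootstrap replicates for the paired ROC test, default 2000.
#' @param seed Integer seed; the single source of randomness for the run
#'   (cohort generation consumes it first, the bootstrap continues the same
#'   stream).
#' @param fit_stage2_on_all Fit the stage-2 model on all children instead of
#'   only stage-1 failures (sensitivity analysis); default `FALSE`.
#' @param freeze_stage1_cutoff Use this fixed stage-1 cutoff instead of
#'   re-estimating it from the data; default `NULL` (re-estimate).
#' @param output_dir Directory for the report artifacts (JSON report, tier
#'   CSV); `NULL` writes nothing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(generator = NULL,
                            cohort = NULL,
                            stage1_candidates = c("edu_compulsory",
                                                  "edu_vocational",
                                                  "edu_university_entrance",
                                                  "sex_male", "age_months",
                                                  "parental_concerns",
                                                  "no_two_word", "vocab_count"),
                            stage1_target_se = 0.90,
                            high_risk_target_ppv = 0.80,
                            moderate_target_se = 0.75,
                            removal_alpha = 0.10,
                            ci_level = 0.95,
                            n_boot = 2000L,
                            seed = 1L,
                            fit_stage2_on_all = FALSE,
                            freeze_stage1_cutoff = NULL,
                            output_dir = NULL) {
  cfg <- list(generator = generator, cohort = cohort,
              stage1_candidates = stage1_candidates,
              stage1_target_se = stage1_target_se,
              high_risk_target_ppv = high_risk_target_ppv,
              moderate_target_se = moderate_target_se,
              removal_alpha = removal_alpha, ci_level = ci_level,
              n_boot = as.integer(n_boot), seed = as.integer(seed),
              fit_stage2_on_all = fit_stage2_on_all,
              freeze_stage1_cutoff = freeze_stage1_cutoff,
              output_dir = output_dir)
  targets <- c(stage1_target_se, high_risk_target_ppv, moderate_target_se,
               ci_level)
  if (any(targets <= 0 | targets >= 1)) {
    stop("targets must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(generator) && is.null(cohort)) {
    stop("either 'generator' or 'cohort' must be supplied", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

# Numeric design columns from cohort fields (reference level: university,
# female).
build_design <- function(cohort) {
  data.frame(
    edu_compulsory = as.numeric(cohort$parental_education == "compulsory"),
    edu_vocational = as.numeric(cohort$parental_education == "vocational"),
    edu_university_entrance =
      as.numeric(cohort$parental_education == "university_entrance"),
    sex_male = as.numeric(cohort$sex == "male"),
    age_months = as.numeric(cohort$age_months),
    parental_concerns = as.numeric(cohort$parental_concerns),
    no_two_word = as.numeric(cohort$no_two_word),
    vocab_count = as.numeric(cohort$vocab_count),
    word_comprehension = as.numeric(cohort$word_comprehension)
  )
}

#' Run the full screening construction and validation pipeline
#'
#' Executes, in order: cohort acquisition, removal of incomplete records
#' (logged), stage-1 logistic fit with likelihood-ratio backward elimination,
#' stage-1 cutoff at the configured sensitivity, stage-2 fit on stage-1
#' failures with word comprehension added, composition of the total two-stage
#' score, DeLong and stratified-bootstrap paired ROC comparison of the
#' two-stage against the one-stage score, constrained high-risk
#' (PPV-targeted) and moderate-risk (sensitivity-targeted) cutoffs for both
#' scores, risk-tier stratification with category likelihood ratios and a
#' flow table, McNemar paired sensitivity/specificity comparisons at the tier
#' cutoffs, Welch ANOVA of the two reference scales across tiers, and a
#' sample-characteristics table.
#'
#' Word comprehension is read only for stage-1 failures (and is masked in the
#' per-child score table for passes), so cohorts in which stage-1 passes were
#' never assessed at stage 2 run identically.
#'
#' @param config A [pipeline_config()].
#' @return A `validation_report` list; if `config$output_dir` is set, also
#'   writes `report.json` and `tier_table.csv` there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  decisions <- character()
  note <- function(...) {
    msg <- paste0(...)
    decisions <<- c(decisions, msg)
    message(msg)
  }

  cohort <- if (!is.null(config$generator)) {
    generate_cohort(config$generator)
  } else if (is.character(config$cohort)) {
    read_cohort_csv(config$cohort)
  } else {
    validate_cohort(config$cohort)
  }

  design_all <- build_design(cohort)
  needed <- config$stage1_candidates
  complete <- stats::complete.cases(design_all[needed]) & !is.na(cohort$sld_age3)
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    note("dropped ", n_dropped, " record(s) with incomplete stage-1 data")
  }
  cohort <- cohort[complete, , drop = FALSE]
  design <- design_all[complete, , drop = FALSE]
  y <- as.logical(cohort$sld_age3)
  n <- nrow(cohort)

  sds <- vapply(design[needed], stats::sd, numeric(1))
  if (any(sds == 0)) {
    note("dropped constant candidate predictor(s): ",
         paste(needed[sds == 0], collapse = ", "))
    needed <- needed[sds > 0]
  }

  # stage 1: model selection and score
  stage1_fit <- backward_eliminate_lr(design[needed], y,
                                      removal_alpha = config$removal_alpha)
  if (nrow(stage1_fit$elimination_log) > 0L) {
    note("stage 1 eliminated: ",
         paste(stage1_fit$elimination_log$term, collapse = ", "))
  }
  stage1_prob <- predict_probability(stage1_fit, design)

  if (is.null(config$freeze_stage1_cutoff)) {
    s1 <- cutoff_for_sensitivity(stage1_prob, y, config$stage1_target_se,
                                 config$ci_level)
    stage1_cutoff <- s1$cutoff
  } else {
    stage1_cutoff <- config$freeze_stage1_cutoff
    s1 <- list(cutoff = stage1_cutoff,
               counts = confusion_at(stage1_prob, y, stage1_cutoff))
    s1$stats <- diagnostic_stats(s1$counts, config$ci_level)
  }
  note("stage-1 cutoff = ", format(stage1_cutoff, digits = 6))

  fails <- stage1_prob >= stage1_cutoff
  if (sum(y[fails]) < 10L) {
    stop("stage-1 failure set has fewer than 10 deficit cases (",
         sum(y[fails]), "); the stage-2 model cannot be fit reliably",
         call. = FALSE)
  }

  # stage 2: add the pediatric word-comprehension score
  stage2_rows <- if (config$fit_stage2_on_all) rep(TRUE, n) else fails
  stage2_terms <- c(stage1_fit$predictor_names, "word_comprehension")
  wc_missing <- is.na(design$word_comprehension) & stage2_rows
  if (any(wc_missing)) {
    note("dropped ", sum(wc_missing),
         " stage-1 failure(s) with missing word comprehension")
    stage2_rows <- stage2_rows & !wc_missing
  }
  stage2_fit <- fit_logistic(design[stage2_rows, stage2_terms, drop = FALSE],
                             y[stage2_rows])

  stage2_prob <- rep(NA_real_, n)
  score_idx <- fails & !is.na(design$word_comprehension)
  stage2_prob[score_idx] <- predict_probability(
    stage2_fit, design[score_idx, stage2_terms, drop = FALSE])
  keep <- !fails | !is.na(stage2_prob)
  if (any(!keep)) {
    note("dropped ", sum(!keep),
         " stage-1 failure(s) unscoreable at stage 2")
  }

  cohort <- cohort[keep, , drop = FALSE]
  y <- y[keep]
  scores <- compose_two_stage(stage1_prob[keep], stage1_cutoff,
                              stage2_prob[keep])
  n <- nrow(cohort)

  # paired ROC comparison: two-stage (first) vs one-stage
  delong <- delong_paired_test(scores$total_score, scores$stage1_prob, y,
                               config$ci_level)
  boot <- bootstrap_paired_test(scores$total_score, scores$stage1_prob, y,
                                n_boot = config$n_boot, seed = NULL,
                                ci_level = config$ci_level)

  # constrained cutoffs for both scores
  high_1 <- cutoff_for_ppv(scores$stage1_prob, y, config$high_risk_target_ppv,
                           config$ci_level)
  high_2 <- cutoff_for_ppv(scores$total_score, y, config$high_risk_target_ppv,
                           config$ci_level)
  mod_1 <- cutoff_for_sensitivity(scores$stage1_prob, y,
                                  config$moderate_target_se, config$ci_level)
  mod_2 <- cutoff_for_sensitivity(scores$total_score, y,
                                  config$moderate_target_se, config$ci_level)
  if (!high_2$target_met) note("high-risk PPV target not attainable")
  note("tier cutoffs (two-stage): high = ", format(high_2$cutoff, digits = 6),
       ", moderate = ", format(mod_2$cutoff, digits = 6))

  tiers <- stratify_risk(scores$total_score, cut_high = high_2$cutoff,
                         cut_moderate = mod_2$cutoff, labels = y)

  # paired accuracy at matched operating points
  mcnemar_se <- mcnemar_or_null(
    scores$total_score[y] >= high_2$cutoff,
    scores$stage1_prob[y] >= high_1$cutoff)
  mcnemar_sp <- mcnemar_or_null(
    scores$total_score[!y] < mod_2$cutoff,
    scores$stage1_prob[!y] < mod_1$cutoff)

  group_val <- lapply(c(ref_vocab_z = "ref_vocab_z",
                        ref_grammar_z = "ref_grammar_z"), function(col) {
    g <- split(cohort[[col]], tiers$tier)
    if (any(lengths(g) < 2L)) NULL else welch_anova(g)
  })

  tier_table <- make_tier_table(high_1, high_2, mod_1, mod_2, n)
  scores$risk_tier <- as.character(tiers$tier)
  scores$child_id <- cohort$child_id
  scores$stage2_prob[!scores$stage1_fail] <- NA_real_

  report <- structure(list(
    n = n,
    n_dropped_incomplete = n_dropped,
    prevalence = mean(y),
    stage1_model = model_table(stage1_fit, config$ci_level),
    stage1_elimination = stage1_fit$elimination_log,
    stage1_cutoff = stage1_cutoff,
    stage1_stats = stats_row(s1$stats),
    stage2_model = model_table(stage2_fit, config$ci_level),
    stage2_n = sum(stage2_rows),
    nagelkerke = c(stage1 = nagelkerke_r2(stage1_fit),
                   stage2 = nagelkerke_r2(stage2_fit)),
    standardized_b = list(
      stage1 = as.numeric(standardized_coefficients(stage1_fit)),
      stage1_terms = stage1_fit$predictor_names,
      stage2 = as.numeric(standardized_coefficients(stage2_fit)),
      stage2_terms = stage2_fit$predictor_names),
    roc = list(delong = unclass(delong), bootstrap = unclass(boot)),
    tier_table = tier_table,
    tier_flow = tiers$summary,
    mcnemar_sensitivity = if (is.null(mcnemar_se)) NULL else unclass(mcnemar_se),
    mcnemar_specificity = if (is.null(mcnemar_sp)) NULL else unclass(mcnemar_sp),
    group_validation = lapply(group_val,
                              function(g) if (is.null(g)) NULL else unclass(g)),
    sample_characteristics = describe_cohort(cohort),
    scores = scores,
    decisions = decisions,
    seed = config$seed
  ), class = "validation_report")

  stopifnot(sum(tiers$summary$n) == n)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report[setdiff(names(report), "scores")],
                         file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, na = "null",
                         pretty = TRUE, force = TRUE)
    utils::write.csv(tier_table,
                     file.path(config$output_dir, "tier_table.csv"),
                     row.names = FALSE)
  }
  report
}

mcnemar_or_null <- function(a, b) {
  if (sum(a & !b) + sum(!a & b) == 0L) NULL else mcnemar_paired(a, b)
}

model_table <- function(fit, ci_level = 0.95) {
  terms <- c("(Intercept)", fit$predictor_names)
  rows <- lapply(terms, function(t) {
    orci <- wald_or_ci(fit$coefficients[[t]],
                       fit$standard_errors[[t]], ci_level)
    data.frame(term = t, b = fit$coefficients[[t]],
               se = fit$standard_errors[[t]],
               or = if (t == "(Intercept)") NA_real_ else orci$odds_ratio,
               or_low = if (t == "(Intercept)") NA_real_ else orci$ci_low,
               or_high = if (t == "(Intercept)") NA_real_ else orci$ci_high,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

stats_row <- function(st) {
  nm <- c("sensitivity", "specificity", "ppv", "npv", "dlr_pos", "dlr_neg",
          "fail_rate")
  out <- lapply(st[nm], function(s) s[c("estimate", "ci_low", "ci_high")])
  names(out) <- nm
  out
}

make_tier_table <- function(high_1, high_2, mod_1, mod_2, n) {
  row <- function(label, res) {
    st <- res$stats
    data.frame(screen = label,
               cutoff = res$cutoff,
               pct_fails = (res$counts$tp + res$counts$fp) / n,
               sens = st$sensitivity$estimate,
               sens_low = st$sensitivity$ci_low, sens_high = st$sensitivity$ci_high,
               spec = st$specificity$estimate,
               spec_low = st$specificity$ci_low, spec_high = st$specificity$ci_high,
               ppv = st$ppv$estimate, ppv_low = st$ppv$ci_low,
               ppv_high = st$ppv$ci_high,
               npv = st$npv$estimate, npv_low = st$npv$ci_low,
               npv_high = st$npv$ci_high,
               dlr_pos = st$dlr_pos$estimate, dlr_pos_low = st$dlr_pos$ci_low,
               dlr_pos_high = st$dlr_pos$ci_high,
               dlr_neg = st$dlr_neg$estimate, dlr_neg_low = st$dlr_neg$ci_low,
               dlr_neg_high = st$dlr_neg$ci_high,
               stringsAsFactors = FALSE)
  }
  rbind(row("high_risk_stage1", high_1),
        row("high_risk_two_stage", high_2),
        row("moderate_risk_stage1", mod_1),
        row("moderate_risk_two_stage", mod_2))
}

describe_cohort <- function(cohort) {
  list(n = nrow(cohort),
       age_mean = mean(cohort$age_months),
       age_sd = stats::sd(cohort$age_months),
       male_pct = mean(cohort$sex == "male"),
       education = as.list(table(cohort$parental_education) / nrow(cohort)),
       vocab_mean = mean(cohort$vocab_count),
       vocab_sd = stats::sd(cohort$vocab_count),
       no_two_word_pct = mean(cohort$no_two_word),
       concerns_pct = mean(cohort$parental_concerns),
       comprehension_mean = mean(cohort$word_comprehension, na.rm = TRUE),
       comprehension_sd = stats::sd(cohort$word_comprehension, na.rm = TRUE),
       sld_pct = mean(cohort$sld_age3))
}

#' Compare two cohorts field by field with effect sizes
#'
#' Continuous fields are compared with Welch t-tests and Cohen's d (pooled
#' SD); binary fields with chi-square tests (no continuity correction) and
#' phi = `sqrt(chi2 / n)`; multi-level categorical fields with chi-square and
#' Cramer's V.
#'
#' @param sample_a,sample_b Two cohort `data.frame`s sharing the cohort schema.
#' @return A `data.frame` with `field`, `type`, `effect_size_name`,
#'   `effect_size`, `p_value`.
#' @export
sample_comparison <- function(sample_a, sample_b) {
  if (nrow(sample_a) == 0L || nrow(sample_b) == 0L) {
    stop("empty cohort", call. = FALSE)
  }
  fields <- list(
    age_months = "continuous", vocab_count = "continuous",
    word_comprehension = "continuous",
    ref_vocab_z = "continuous", ref_grammar_z = "continuous",
    sex = "binary", no_two_word = "binary", parental_concerns = "binary",
    sld_age3 = "binary", parental_education = "categorical"
  )
  fields <- fields[names(fields) %in% intersect(names(sample_a), names(sample_b))]
  rows <- lapply(names(fields), function(f) {
    a <- sample_a[[f]]; b <- sample_b[[f]]
    type <- fields[[f]]
    if (type == "continuous") {
      a <- as.numeric(a); b <- as.numeric(b)
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      sp <- sqrt(((length(a) - 1) * stats::var(a) +
                    (length(b) - 1) * stats::var(b)) /
                   (length(a) + length(b) - 2))
      d <- if (sp > 0) (mean(a) - mean(b)) / sp else 0
      p <- if (sp > 0) stats::t.test(a, b)$p.value else 1
      data.frame(field = f, type = type, effect_size_name = "cohens_d",
                 effect_size = d, p_value = p, stringsAsFactors = FALSE)
    } else {
      lev <- sort(unique(c(as.character(a), as.character(b))))
      tab <- rbind(table(factor(as.character(a), levels = lev)),
                   table(factor(as.character(b), levels = lev)))
      if (any(colSums(tab) == 0) || ncol(tab) < 2L) {
        return(data.frame(field = f, type = type,
                          effect_size_name = if (type == "binary") "phi" else "cramers_v",
                          effect_size = 0, p_value = 1, stringsAsFactors = FALSE))
      }
      chs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      n_tot <- sum(tab)
      es <- if (type == "binary" && ncol(tab) == 2L) {
        sqrt(unname(chs$statistic) / n_tot)
      } else {
        sqrt(unname(chs$statistic) / (n_tot * (min(dim(tab)) - 1)))
      }
      data.frame(field = f, type = type,
                 effect_size_name = if (type == "binary" && ncol(tab) == 2L)
                   "phi" else "cramers_v",
                 effect_size = es, p_value = unname(chs$p.value),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Score a cohort with a published coefficient table
#'
#' Applies frozen stage-1 and stage-2 logistic coefficients (e.g., imported
#' with [import_fit_json()] or the bundled [published_stage1_fit()] /
#' [published_stage2_fit()]) to a new cohort: no refitting, fixed cutoffs.
#'
#' @param cohort A cohort `data.frame` (may be empty).
#' @param stage1_fit,stage2_fit `logistic_fit` objects.
#' @param stage1_cutoff Stage-1 failure cutoff; default 0.05, the published
#'   operating point of the validated instrument.
#' @param cut_high,cut_moderate Tier cutoffs on the total score; defaults
#'   0.594 and 0.169, the published two-stage tier cutoffs.
#' @return A list with `scores` (per-child table including `risk_tier`) and
#'   `tier_summary` (with category likelihood ratios when `sld_age3` is
#'   present and both classes occur).
#' @export
score_with_published_model <- function(cohort, stage1_fit, stage2_fit,
                                       stage1_cutoff = 0.05,
                                       cut_high = 0.594,
                                       cut_moderate = 0.169) {
  if (nrow(cohort) == 0L) {
    return(list(scores = data.frame(), tier_summary = data.frame()))
  }
  design <- build_design(cohort)
  missing_p <- setdiff(unique(c(stage1_fit$predictor_names,
                                stage2_fit$predictor_names)), names(design))
  if (length(missing_p) > 0L) {
    stop("cohort lacks predictor column(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  p1 <- predict_probability(stage1_fit, design)
  fails <- p1 >= stage1_cutoff
  p2 <- rep(NA_real_, nrow(cohort))
  if (any(fails)) {
    p2[fails] <- predict_probability(stage2_fit, design[fails, , drop = FALSE])
  }
  scores <- compose_two_stage(p1, stage1_cutoff, p2)
  labels <- if (!is.null(cohort$sld_age3) && !anyNA(cohort$sld_age3) &&
                length(unique(cohort$sld_age3)) == 2L) cohort$sld_age3 else NULL
  tiers <- stratify_risk(scores$total_score, cut_high = cut_high,
                         cut_moderate = cut_moderate, labels = labels)
  scores$risk_tier <- as.character(tiers$tier)
  scores <- cbind(child_id = cohort$child_id, scores)
  list(scores = scores, tier_summary = tiers$summary)
}

#' Published screening coefficient tables
#'
#' The stage-1 (parent report: concerns, no two-word combinations, 37-word
#' expressive vocabulary) and stage-2 (plus 9-item word comprehension)
#' logistic coefficient tables of the validated two-stage instrument, bundled
#' as importable fits for scoring new cohorts. Log-likelihoods are not part of
#' the published tables, so [nagelkerke_r2()] is unavailable for these fits.
#'
#' @return A `logistic_fit`.
#' @export
published_stage1_fit <- function() {
  import_fit_json(system.file("extdata", "published_stage1_fit.json",
                              package = "twostagescreen", mustWork = TRUE))
}

#' @rdname published_stage1_fit
#' @export
published_stage2_fit <- function() {
  import_fit_json(system.file("extdata", "published_stage2_fit.json",
                              package = "twostagescreen", mustWork = TRUE))
}
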