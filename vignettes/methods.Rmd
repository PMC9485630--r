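---
title: "Statistical methods behind the two-stage screening validator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind the two-stage screening validator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostagescreen)
```

## The screening problem

Specific language disorder (SLD) at age three affects roughly one child in
nine, but direct assessment of every toddler is too expensive for routine
well-child care. A two-stage design addresses this:

1. **Stage 1 (universal, parent-reported).** At about age two, parents answer
   whether they are concerned about the child's language, whether the child
   does not yet combine two words, and which of 37 common words the child
   says (an expressive vocabulary count, 0–37). A logistic model converts
   these to a risk probability; children at or above a sensitivity-targeted
   cutoff "fail" stage 1.
2. **Stage 2 (selective, direct assessment).** Only stage-1 failures receive
   a brief word-comprehension task (0–9 items correct). A second logistic
   model, fit on the failure subsample with comprehension added, refines
   their risk.
3. **Total score and tiers.** A child's total score is the stage-1
   probability if they passed stage 1 and the stage-2 probability if they
   failed. Two further cutoffs split children into *high*, *moderate*, and
   *low* risk tiers: the high cutoff targets a fixed positive predictive
   value (default 0.80), the moderate cutoff a fixed sensitivity (default
   0.75).

`run_pipeline()` executes this whole construction on a cohort and reports
model tables, tier accuracy with confidence intervals, paired ROC
comparisons between the one-stage and two-stage scores, McNemar tests at
matched operating points, and Welch heteroscedastic comparisons of external
language measures across tiers.

## The synthetic cohort model

`generate_cohort()` draws cohorts from a one-factor latent-ability model:

* Latent language ability at age 2, $L_2 \sim N(0, 1)$.
* Ability at age 3, $L_3 = \rho L_2 + \sqrt{1-\rho^2}\,\varepsilon$ with
  $\varepsilon \sim N(0,1)$ and stability $\rho = 0.6$ by default.
* SLD at age 3 is defined as $L_3 < \Phi^{-1}(\pi)$ with target prevalence
  $\pi = 0.113$, so prevalence is exact in expectation by construction.
* The expressive vocabulary count is Binomial$(37, \text{logit}^{-1}(a + b
  Z))$ and the comprehension score Binomial$(9, \cdot)$, where $Z$ is a
  predictor-specific blend of $L_2$ and $L_3$ (below). The intercept $a$ and
  loading $b$ are calibrated by one-dimensional root finding against
  numerically integrated moments so that the population mean *and* SD match
  the configured targets (defaults: vocabulary mean 24, SD 8; comprehension
  mean 6.86, SD 1.80).
* The binary flags (parental concerns, failure to combine two words) are
  Bernoulli with logistic dependence on the blend; their intercepts are
  calibrated the same way to hit the target marginal rates (12.4% and 5.6%).
* Sociodemographics (sex, age in months 23–25, parental education in four
  levels) are drawn independently of ability: they are distributional
  scenery for representativeness analyses, not risk factors.
* Two external criterion measures (`ref_vocab_z`, `ref_grammar_z`) are noisy
  linear functions of $L_3$, used for known-groups validation across tiers.

### Why predictors blend $L_2$ and $L_3$ (`l3_share`)

If every stage-1 predictor depended on $L_2$ alone, the vocabulary count —
the highest-information proxy — would render the two binary flags
conditionally redundant, and backward elimination would correctly remove
them; moreover no score could reach PPV 0.80, because all predictors would
see the outcome only through the noisy $L_2 \to L_3$ channel. Real parental
reports partly reflect enduring traits that persist to age 3. The
`l3_share` configuration therefore lets each predictor load on a normalized
blend $((1-w)L_2 + wL_3)$, with default $w = 0.5$ for the flags and the
comprehension task and $w = 0$ for the vocabulary count. Under these
defaults the fitted models reproduce the qualitative structure of published
late-talker instruments: both flags survive elimination alongside
vocabulary, comprehension carries the largest standardized coefficient in
stage 2, and a PPV of 0.80 is attainable.

### What the generator does and does not emulate

It emulates marginal rates, means, SDs, the latent correlation structure,
and the resulting predictor–outcome hierarchy. It does **not** emulate item
non-response, clinic-level clustering, attrition mechanisms (dropping
incomplete records is supported when reading external cohorts, but the
generator emits complete data), or measurement drift between ages. Age and
demographic variables carry no risk information by design, so analyses that
"discover" such effects in synthetic cohorts are seeing noise.

## Estimation and inference choices

* **Logistic fitting** uses maximum likelihood (`stats::glm`) with a strict
  convergence tolerance; fits are wrapped in a plain `logistic_fit` record
  (coefficients, SEs, log-likelihoods) that serializes to JSON so frozen
  published coefficients can be applied to new cohorts without refitting
  (`score_with_published_model()`). Complete or quasi-complete separation
  is detected (degenerate fitted probabilities together with an escaped
  standardized coefficient) and raised as an error rather than reported as
  a huge finite odds ratio.
* **Backward elimination** removes, one term per step, the predictor whose
  single-term likelihood-ratio test has the largest p-value above
  `removal_alpha` (default 0.10, the conventional Backward:LR removal
  threshold). The elimination log records each step's LR $\chi^2$ and
  p-value.
* **Model summaries**: Wald odds-ratio intervals ($e^{b \pm z\,SE}$),
  Nagelkerke pseudo-$R^2$ (Cox–Snell rescaled to a 0–1 range), and
  standardized coefficients $b_j \cdot SD(x_j)$ for ranking predictors on a
  common scale.
* **Cutoff search** considers midpoints between adjacent distinct observed
  scores plus $\pm\infty$, so every achievable confusion table is visited
  exactly once and results do not depend on whether an observed value is
  used as its own threshold. Classification uses the `>=` boundary: a score
  exactly at the cutoff fails. The sensitivity-targeted search picks the
  candidate closest to the target sensitivity, breaking ties by higher
  specificity and then by the higher cutoff; the PPV-targeted search
  maximizes sensitivity among candidates meeting the PPV target, breaking
  ties toward the lower cutoff, and falls back to the maximum attainable
  PPV (flagged `target_met = FALSE`) when the target is infeasible.
* **Interval estimation**: proportions (Se, Sp, PPV, NPV, fail rate) get
  exact Clopper–Pearson intervals; diagnostic likelihood ratios get the
  Simel log-method interval, which is symmetric on the log scale. Zero
  denominators yield `NA` with a recorded reason, never `NaN`.
* **Paired ROC comparison**: the primary test is DeLong's placement-value
  method (midranks, so ties count one half), with a two-sided normal
  p-value; a stratified paired bootstrap (resampling diseased and
  non-diseased children separately, recomputing the AUC difference) is
  reported alongside as a robustness check. McNemar tests (no continuity
  correction; exact binomial added when discordant pairs are fewer than 25)
  compare sensitivity and specificity at matched operating points. Group
  validation across risk tiers uses Welch's heteroscedastic ANOVA with
  $\eta^2$ effect sizes.
* **Determinism**: `run_pipeline()` seeds the R generator once and lets
  every stochastic step consume the same stream, so a configuration plus a
  seed reproduces a byte-identical `report.json`.

## Deliberate policy decisions

Some choices are genuinely ambiguous in practice; the package picks a
default and exposes a switch:

* **Recompute vs. freeze the stage-1 cutoff.** By default the pipeline
  recomputes the sensitivity-targeted stage-1 cutoff on the analysis
  cohort; `freeze_stage1_cutoff` pins it (e.g. to a previously published
  0.05) for external validation runs.
* **Stage-2 estimation sample.** The stage-2 model is fit on stage-1
  failures only, matching the selective design; `fit_stage2_on_all = TRUE`
  exists for sensitivity analysis.
* **Standardization basis.** Standardized coefficients use the observed
  predictor SDs in the estimation sample (`method = "x_sd"`); a
  latent-scale variant is available for comparison with conventions that
  also rescale by the latent outcome SD.
* **Analysis-sample prevalence.** All accuracy statistics condition on the
  analysed cohort's own case mix; no external prevalence reweighting is
  applied.

## A worked example

```{r example, eval = FALSE}
report <- run_pipeline(pipeline_config(
  generator = generator_config(n = 8000, seed = 1),
  n_boot = 500, seed = 1))

report$stage1_model      # Wald ORs for the retained stage-1 predictors
report$roc$delong        # paired AUC comparison, two-stage vs stage 1
report$tier_table        # tier accuracy with exact and log-method CIs
```
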