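# Synthetic screening cohorts
#
# A single latent language ability at age 2 (L2, standard normal) drives every
# parent-reported and pediatric predictor; ability at age 3 is an AR(1)-style
# blend L3 = rho * L2 + sqrt(1 - rho^2) * innovation, reflecting the known
# instability of early language trajectories.  The age-3 deficit label is the
# lower tail of L3, calibrated to a target prevalence rather than to a literal
# -1.5 SD rule, so that downstream accuracy statistics see the event rate the
# screening instrument was validated against.

#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions a simulated screening cohort should reproduce:
#' the sample size, the stability of language ability between ages 2 and 3,
#' the prevalence of a significant language deficit (SLD) at age 3, the
#' strength with which each observable loads on latent ability, and the
#' marginal distributions of the parent-reported and pediatric measures.
#'
#' Bounded count measures (the 37-word expressive-vocabulary list and the
#' 9-item word-comprehension subtest) are binomial with a logistic-normal
#' success probability; both the intercept and the latent loading are
#' calibrated numerically so that the simulated mean and standard deviation
#' match `marginal_targets`. Binary flags (no two-word combinations, parental
#' concerns) take their loading from `loadings` and have the intercept
#' calibrated to the target rate.
#'
#' @param n Number of children to simulate.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @param latent_stability_rho Correlation between age-2 and age-3 latent
#'   ability, in `[0, 1]`. The default 0.6 reflects that roughly half of
#'   2-year-old late talkers attain age-appropriate language by age 3-4.
#' @param target_prevalence Proportion of children with SLD at age 3, in
#'   `(0, 1)`. Default 0.113, the analysis-sample rate of the validation
#'   cohort the defaults are calibrated to.
#' @param loadings Named numeric vector of latent loadings for the binary and
#'   continuous observables. Negative loadings on `no_two_word` and
#'   `concerns` mean lower ability makes the flag more likely.
#'   Sociodemographics (sex, age, parental education) have zero loading: they
#'   are drawn independently of ability, matching their null effects in the
#'   validated instrument.
#' @param marginal_targets Named numeric vector of marginal calibration
#'   anchors: `no_two_word_rate`, `concerns_rate`, `comprehension_mean`,
#'   `comprehension_sd`, `vocab_mean`, `vocab_sd`.
#' @param l3_share Named vector in `[0, 1]`: the share of each language
#'   observable's latent loading that falls on age-3 rather than age-2
#'   ability. The expressive-vocabulary count is a pure age-2 measure
#'   (share 0); parental concerns, two-word-combination use and the directly
#'   assessed word comprehension carry persistence-related signal beyond the
#'   age-2 word list (default share 0.5), which is what makes them retain
#'   independent predictive value next to the vocabulary score and gives the
#'   stage-2 assessment its incremental worth.
#' @param overdispersion Standard deviation of extra per-child logit noise
#'   added to the count measures; 0 (default) disables it.
#'
#' @return An object of class `generator_config` (a list).
#' @seealso [generate_cohort()], [generate_item_matrix()]
#' @export
generator_config <- function(n,
                             seed = 1L,
                             latent_stability_rho = 0.6,
                             target_prevalence = 0.113,
                             loadings = c(no_two_word = -1.4,
                                          concerns = -1.2,
                                          ref_vocab = 0.85,
                                          ref_grammar = 0.85),
                             marginal_targets = c(no_two_word_rate = 0.056,
                                                  concerns_rate = 0.124,
                                                  comprehension_mean = 6.86,
                                                  comprehension_sd = 1.80,
                                                  vocab_mean = 24,
                                                  vocab_sd = 8),
                             l3_share = c(vocab = 0,
                                          comprehension = 0.5,
                                          no_two_word = 0.5,
                                          concerns = 0.5),
                             overdispersion = 0) {
  if (length(n) != 1L || is.na(n) || n < 1) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  if (latent_stability_rho < 0 || latent_stability_rho > 1) {
    stop("'latent_stability_rho' must lie in [0, 1]", call. = FALSE)
  }
  if (target_prevalence <= 0 || target_prevalence >= 1) {
    stop("'target_prevalence' must lie in (0, 1)", call. = FALSE)
  }
  defaults <- eval(formals(generator_config)$marginal_targets)
  missing_t <- setdiff(names(defaults), names(marginal_targets))
  marginal_targets <- c(marginal_targets, defaults[missing_t])
  default_l <- eval(formals(generator_config)$loadings)
  missing_l <- setdiff(names(default_l), names(loadings))
  loadings <- c(loadings, default_l[missing_l])
  default_w <- eval(formals(generator_config)$l3_share)
  missing_w <- setdiff(names(default_w), names(l3_share))
  l3_share <- c(l3_share, default_w[missing_w])
  if (any(l3_share < 0 | l3_share > 1)) {
    stop("'l3_share' entries must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         latent_stability_rho = latent_stability_rho,
         target_prevalence = target_prevalence,
         loadings = loadings,
         marginal_targets = marginal_targets,
         l3_share = l3_share,
         overdispersion = overdispersion),
    class = "generator_config"
  )
}

#' Read a generator configuration from YAML or JSON
#'
#' The file mirrors the [generator_config()] argument names.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `generator_config` object.
#' @export
read_generator_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configurations",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (nm in c("loadings", "marginal_targets")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(generator_config, raw)
}

# E[ f(plogis(a + b Z)) ], Z ~ N(0,1); f vectorised
logit_normal_moment <- function(a, b, f = identity) {
  stats::integrate(function(x) f(stats::plogis(a + b * x)) * stats::dnorm(x),
                   -Inf, Inf, rel.tol = 1e-10)$value
}

# Intercept giving E[plogis(a + b Z)] = p_target for fixed loading b.
calibrate_intercept <- function(b, p_target) {
  stats::uniroot(function(a) logit_normal_moment(a, b) - p_target,
                 lower = -25, upper = 25, tol = 1e-10)$root
}

# (intercept, loading) of a Binomial(N, plogis(a + b Z)) count matching a
# target mean and standard deviation.  The SD is monotone increasing in |b|,
# so a one-dimensional root search over b (with a profiled out) suffices.
calibrate_binomial <- function(N, mean_target, sd_target) {
  p_target <- mean_target / N
  sd_for <- function(b) {
    a <- calibrate_intercept(b, p_target)
    ep <- p_target
    ep2 <- logit_normal_moment(a, b, function(p) p^2)
    v <- N * ep - N * ep2 + N^2 * (ep2 - ep^2)
    sqrt(v)
  }
  if (sd_target <= sd_for(0)) {
    return(list(a = calibrate_intercept(0, p_target), b = 0))
  }
  b <- stats::uniroot(function(b) sd_for(b) - sd_target,
                      lower = 0, upper = 8, tol = 1e-8)$root
  list(a = calibrate_intercept(b, p_target), b = b)
}

#' Simulate a screening cohort
#'
#' Draws `config$n` children from the one-factor generative model described in
#' [generator_config()]. The output has the statistical structure the
#' two-stage screening analysis assumes: all language observables are noisy
#' proxies of a common age-2 ability, the age-3 deficit label is the lower
#' quantile of a correlated age-3 ability, and the two reference scales are
#' z-scaled functions of age-3 ability plus independent noise.
#'
#' @param config A [generator_config()] object.
#' @return A `data.frame` with one row per child and columns `child_id`,
#'   `age_months`, `sex`, `parental_education`, `vocab_count`, `no_two_word`,
#'   `parental_concerns`, `word_comprehension`, `sld_age3`, `ref_vocab_z`,
#'   `ref_grammar_z`. `word_comprehension` is generated for every child;
#'   masking it for stage-1 passes (the real protocol) is the pipeline's job.
#' @examples
#' cohort <- generate_cohort(generator_config(n = 500, seed = 7))
#' mean(cohort$sld_age3)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n
  rho <- config$latent_stability_rho
  mt <- config$marginal_targets
  ld <- config$loadings

  cal_vocab <- calibrate_binomial(37L, mt[["vocab_mean"]], mt[["vocab_sd"]])
  cal_comp <- calibrate_binomial(9L, mt[["comprehension_mean"]],
                                 mt[["comprehension_sd"]])
  a_ntw <- calibrate_intercept(abs(ld[["no_two_word"]]), mt[["no_two_word_rate"]])
  a_con <- calibrate_intercept(abs(ld[["concerns"]]), mt[["concerns_rate"]])

  set.seed(config$seed)
  L2 <- stats::rnorm(n)
  innov <- stats::rnorm(n)
  L3 <- rho * L2 + sqrt(1 - rho^2) * innov
  sld <- L3 < stats::qnorm(config$target_prevalence)

  # unit-variance blend of the age-2 and age-3 abilities behind observable x
  blend <- function(what) {
    w <- config$l3_share[[what]]
    ((1 - w) * L2 + w * L3) / sqrt((1 - w)^2 + w^2 + 2 * w * (1 - w) * rho)
  }
  od <- function() if (config$overdispersion > 0)
    stats::rnorm(n, sd = config$overdispersion) else 0
  vocab <- stats::rbinom(n, 37L, stats::plogis(
    cal_vocab$a + cal_vocab$b * blend("vocab") + od()))
  comp <- stats::rbinom(n, 9L, stats::plogis(
    cal_comp$a + cal_comp$b * blend("comprehension") + od()))
  ntw <- stats::rbinom(n, 1L, stats::plogis(
    a_ntw + ld[["no_two_word"]] * blend("no_two_word"))) == 1L
  con <- stats::rbinom(n, 1L, stats::plogis(
    a_con + ld[["concerns"]] * blend("concerns"))) == 1L

  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.518, 0.482))
  age <- sample(23:25, n, replace = TRUE, prob = c(0.40, 0.28, 0.32))
  edu <- sample(c("compulsory", "vocational", "university_entrance", "university"),
                n, replace = TRUE, prob = c(0.014, 0.470, 0.258, 0.258))

  lam_v <- min(ld[["ref_vocab"]], 1)
  lam_g <- min(ld[["ref_grammar"]], 1)
  ref_v <- lam_v * L3 + sqrt(1 - lam_v^2) * stats::rnorm(n)
  ref_g <- lam_g * L3 + sqrt(1 - lam_g^2) * stats::rnorm(n)

  data.frame(
    child_id = sprintf("C%06d", seq_len(n)),
    age_months = as.integer(age),
    sex = sex,
    parental_education = edu,
    vocab_count = as.integer(vocab),
    no_two_word = ntw,
    parental_concerns = con,
    word_comprehension = as.integer(comp),
    sld_age3 = sld,
    ref_vocab_z = ref_v,
    ref_grammar_z = ref_g,
    stringsAsFactors = FALSE
  )
}

#' Simulate a word-list item response matrix
#'
#' Generates per-word endorsement indicators ("child says this word") for the
#' same latent abilities as [generate_cohort()] under the same configuration:
#' the first `config$n` standard-normal draws under `config$seed` are the
#' shared age-2 abilities, so the item matrix aligns row-for-row with the
#' cohort and its outcome labels. Endorsement of item *j* by child *i* is
#' Bernoulli with probability `plogis(L2_i - difficulty_j)`.
#'
#' @param config A [generator_config()] object.
#' @param n_items Number of word-list items (default 260, a full
#'   parent-reported vocabulary checklist).
#' @param difficulties Optional numeric vector of item difficulties on the
#'   logit scale; defaults to an even grid on `[-3, 3]` so endorsement rates
#'   span roughly 5-95% and some items fall under any usage threshold.
#'   `+Inf` yields an item nobody endorses.
#' @return A list of class `item_matrix` with elements `child_id`,
#'   `age_months`, `items` (an `n x n_items` binary matrix with columns
#'   `item001`, ...), and `difficulties`.
#' @export
generate_item_matrix <- function(config, n_items = 260L, difficulties = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (length(n_items) != 1L || is.na(n_items) || n_items < 1) {
    stop("'n_items' must be a positive integer", call. = FALSE)
  }
  n_items <- as.integer(n_items)
  if (is.null(difficulties)) {
    difficulties <- if (n_items == 1L) 0 else seq(-3, 3, length.out = n_items)
  }
  stopifnot(length(difficulties) == n_items)

  set.seed(config$seed)
  n <- config$n
  L2 <- stats::rnorm(n)
  age <- sample(23:25, n, replace = TRUE, prob = c(0.40, 0.28, 0.32))

  p <- stats::plogis(outer(L2, difficulties, `-`))
  items <- matrix(stats::rbinom(n * n_items, 1L, p), nrow = n)
  colnames(items) <- sprintf("item%03d", seq_len(n_items))

  structure(list(child_id = sprintf("C%06d", seq_len(n)),
                 age_months = as.integer(age),
                 items = items,
                 difficulties = difficulties),
            class = "item_matrix")
}
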