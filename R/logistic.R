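# Logistic risk models for the two screening stages.
#
# Fitting is maximum likelihood via stats::glm (IRLS); this module adds the
# pieces screening construction needs on top of the fit: honest separation
# diagnostics, likelihood-ratio backward elimination, Wald odds-ratio
# intervals, Nagelkerke R^2, x-standardized coefficients, and a JSON
# round-trip so a published coefficient table can score new cohorts without
# refitting.

#' Fit a logistic risk model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, convergence tolerance 1e-8 on the deviance, at most 100
#' iterations) of a binary outcome on a set of numeric predictors, with
#' standard errors from the observed information.
#'
#' Complete or quasi-complete separation is reported as an error naming the
#' predictor that dominates the diverging linear predictor, with a hint that a
#' penalized (Firth-type) fit would be needed for such data.
#'
#' @param predictors A `data.frame` (or matrix) of numeric predictor columns;
#'   may have zero columns for an intercept-only model.
#' @param outcome Binary vector (logical or 0/1), one value per row.
#' @return An object of class `logistic_fit`: a list with
#'   `predictor_names`, `coefficients` (named, including `(Intercept)`),
#'   `standard_errors`, `log_likelihood`, `null_log_likelihood`, `n`,
#'   `converged`, and `predictor_sd`.
#' @examples
#' co <- generate_cohort(generator_config(n = 800, seed = 1))
#' fit <- fit_logistic(co[, c("vocab_count", "parental_concerns")], co$sld_age3)
#' coef(fit)
#' @export
fit_logistic <- function(predictors, outcome) {
  if (is.null(predictors)) predictors <- data.frame(row.names = seq_along(outcome))
  predictors <- as.data.frame(predictors)
  y <- as.integer(outcome)
  if (!all(y %in% c(0L, 1L))) stop("outcome must be binary", call. = FALSE)
  if (ncol(predictors) > 0L && nrow(predictors) != length(y)) {
    stop("predictors and outcome lengths differ", call. = FALSE)
  }
  n <- length(y)
  if (n <= ncol(predictors) + 1L) {
    stop("more parameters than observations", call. = FALSE)
  }
  for (nm in names(predictors)) {
    predictors[[nm]] <- as.numeric(predictors[[nm]])
    if (stats::sd(predictors[[nm]]) == 0) {
      stop("predictor '", nm, "' has zero variance", call. = FALSE)
    }
  }

  dat <- if (ncol(predictors) > 0L) cbind(.outcome = y, predictors) else
    data.frame(.outcome = y)
  fml <- if (ncol(predictors) > 0L) .outcome ~ . else .outcome ~ 1
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (any(is.na(stats::coef(fit)))) {
    stop("singular design: predictors are linearly dependent", call. = FALSE)
  }
  b <- stats::coef(fit)
  if (ncol(predictors) > 0L) {
    # separation drives fitted probabilities to 0/1 while a coefficient
    # diverges (glm may even report "converged" once the deviance flatlines)
    extreme <- any(fit$fitted.values > 1 - 1e-7 | fit$fitted.values < 1e-7)
    scale_b <- abs(b[-1L]) * vapply(predictors, stats::sd, numeric(1))
    if ((sep_warned || extreme) && max(scale_b) > 8) {
      stop("complete or quasi-complete separation detected; predictor '",
           names(predictors)[which.max(scale_b)],
           "' perfectly (or almost perfectly) splits the outcome. ",
           "Consider a penalized (Firth) logistic model.", call. = FALSE)
    }
  }
  structure(
    list(predictor_names = names(predictors),
         coefficients = b,
         standard_errors = sqrt(diag(stats::vcov(fit))),
         log_likelihood = -fit$deviance / 2,
         null_log_likelihood = -fit$null.deviance / 2,
         n = n,
         converged = fit$converged,
         predictor_sd = vapply(predictors, stats::sd, numeric(1))),
    class = "logistic_fit"
  )
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic risk model (n = ", x$n, ", logLik = ",
      format(x$log_likelihood, digits = 6), ")\n", sep = "")
  tab <- data.frame(b = x$coefficients, SE = x$standard_errors)
  or <- exp(x$coefficients)
  tab$OR <- ifelse(names(x$coefficients) == "(Intercept)", NA, or)
  print(format(tab, digits = 4))
  invisible(x)
}

#' Backward elimination by likelihood-ratio tests
#'
#' Starting from the full model, repeatedly removes the predictor whose
#' single-term likelihood-ratio chi-square test has the largest p-value above
#' `removal_alpha`, refitting after each removal, until every remaining term
#' is significant at `removal_alpha`. This mirrors the stepwise "backward
#' (likelihood ratio)" selection routine of mainstream statistics software.
#'
#' @inheritParams fit_logistic
#' @param removal_alpha Removal threshold for the LR p-value; default 0.10,
#'   the conventional backward-LR removal criterion.
#' @return The final `logistic_fit`, with an `elimination_log` element: a
#'   `data.frame` of the removed terms (step, term, LR chi-square, p at
#'   removal).
#' @export
backward_eliminate_lr <- function(predictors, outcome, removal_alpha = 0.10) {
  predictors <- as.data.frame(predictors)
  current <- names(predictors)
  log_rows <- list()
  step <- 0L
  repeat {
    fit_cur <- fit_logistic(predictors[current], outcome)
    if (length(current) == 0L) break
    lr <- p <- numeric(length(current))
    for (i in seq_along(current)) {
      reduced <- fit_logistic(predictors[setdiff(current, current[i])], outcome)
      lr[i] <- 2 * (fit_cur$log_likelihood - reduced$log_likelihood)
      p[i] <- stats::pchisq(max(lr[i], 0), df = 1, lower.tail = FALSE)
    }
    worst <- which.max(p)
    if (p[worst] <= removal_alpha) break
    step <- step + 1L
    log_rows[[step]] <- data.frame(step = step, term = current[worst],
                                   lr_chisq = lr[worst], p_value = p[worst],
                                   stringsAsFactors = FALSE)
    current <- setdiff(current, current[worst])
  }
  fit_cur$elimination_log <- if (length(log_rows) > 0L) {
    do.call(rbind, log_rows)
  } else {
    data.frame(step = integer(), term = character(), lr_chisq = numeric(),
               p_value = numeric(), stringsAsFactors = FALSE)
  }
  fit_cur
}

#' Predicted probability of the outcome
#'
#' Inverse-logit of the linear predictor under a fitted (or imported) model.
#'
#' @param fit A `logistic_fit`.
#' @param newdata A `data.frame` containing all `fit$predictor_names` columns,
#'   or a named numeric vector for a single child.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_probability <- function(fit, newdata) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (is.numeric(newdata) && !is.data.frame(newdata)) {
    newdata <- as.data.frame(as.list(newdata))
  }
  missing_p <- setdiff(fit$predictor_names, names(newdata))
  if (length(missing_p) > 0L) {
    stop("newdata lacks predictors: ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  if (length(fit$predictor_names) == 0L) {
    return(rep(stats::plogis(fit$coefficients[["(Intercept)"]]),
               max(1L, nrow(as.data.frame(newdata)))))
  }
  x <- as.matrix(as.data.frame(lapply(newdata[fit$predictor_names], as.numeric)))
  lp <- drop(fit$coefficients[["(Intercept)"]] +
               x %*% fit$coefficients[fit$predictor_names])
  stats::plogis(lp)
}

#' Wald odds ratio with confidence interval
#'
#' `OR = exp(b)` with interval `exp(b +/- z * se)`.
#'
#' @param b Log-odds coefficient.
#' @param se Standard error (> 0).
#' @param level Confidence level, default 0.95.
#' @return A list with `odds_ratio`, `ci_low`, `ci_high`.
#' @export
wald_or_ci <- function(b, se, level = 0.95) {
  if (se <= 0) stop("'se' must be positive", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(odds_ratio = exp(b), ci_low = exp(b - z * se), ci_high = exp(b + z * se))
}

#' Nagelkerke pseudo R-squared
#'
#' Cox-Snell `R2 = 1 - exp((2/n) * (LL0 - LLm))`, normalized by its maximum
#' `1 - exp((2/n) * LL0)` to span `[0, 1]`.
#'
#' @param fit A `logistic_fit` carrying model and null log-likelihoods.
#' @return Nagelkerke R-squared.
#' @export
nagelkerke_r2 <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (is.null(fit$n) || fit$n == 0) stop("fit has no sample size", call. = FALSE)
  if (is.na(fit$log_likelihood) || is.na(fit$null_log_likelihood)) {
    stop("fit does not carry log-likelihoods (imported coefficient table?)",
         call. = FALSE)
  }
  cs <- 1 - exp((2 / fit$n) * (fit$null_log_likelihood - fit$log_likelihood))
  max_cs <- 1 - exp((2 / fit$n) * fit$null_log_likelihood)
  cs / max_cs
}

#' Standardized logistic coefficients
#'
#' x-standardization: `b_j * SD(x_j)`, the change in the log-odds per one
#' standard deviation of the predictor. This is the variant used throughout
#' the package when ranking predictors by predictive power. A latent-scale
#' variant that additionally divides by the standard deviation of the latent
#' outcome (`sqrt(var(linear predictor) + pi^2/3)`) is available via `method`.
#'
#' @param fit A `logistic_fit`.
#' @param data The fitting data (a `data.frame` with the predictor columns);
#'   defaults to the standard deviations stored in the fit.
#' @param method `"x_sd"` (default) or `"latent"`.
#' @return Named numeric vector of standardized coefficients, in model order,
#'   with a `ranking` attribute (predictor names by decreasing `|value|`).
#' @export
standardized_coefficients <- function(fit, data = NULL,
                                      method = c("x_sd", "latent")) {
  stopifnot(inherits(fit, "logistic_fit"))
  method <- match.arg(method)
  sds <- if (is.null(data)) {
    fit$predictor_sd
  } else {
    vapply(as.data.frame(data)[fit$predictor_names],
           function(v) stats::sd(as.numeric(v)), numeric(1))
  }
  if (any(sds == 0)) {
    stop("zero-variance predictor: ",
         paste(fit$predictor_names[sds == 0], collapse = ", "), call. = FALSE)
  }
  std_b <- fit$coefficients[fit$predictor_names] * sds
  if (method == "latent") {
    if (is.null(data)) stop("'latent' standardization needs the fitting data",
                            call. = FALSE)
    lp_var <- stats::var(
      as.matrix(as.data.frame(lapply(as.data.frame(data)[fit$predictor_names],
                                     as.numeric))) %*%
        fit$coefficients[fit$predictor_names]
    )[1, 1]
    std_b <- std_b / sqrt(lp_var + pi^2 / 3)
  }
  structure(std_b,
            ranking = fit$predictor_names[order(-abs(std_b))])
}

#' Export / import a fitted model as JSON
#'
#' The JSON carries predictor names, coefficients, standard errors,
#' log-likelihoods and n, enabling a new cohort to be scored with a published
#' coefficient table without refitting. Log-likelihoods may be absent when
#' the table comes from print (then [nagelkerke_r2()] is unavailable).
#'
#' @param fit A `logistic_fit`.
#' @param path Output JSON path.
#' @return `path` (export) or a `logistic_fit` (import).
#' @export
export_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "logistic_fit"))
  jsonlite::write_json(
    list(predictor_names = fit$predictor_names,
         coefficients = as.list(fit$coefficients),
         standard_errors = as.list(fit$standard_errors),
         log_likelihood = fit$log_likelihood,
         null_log_likelihood = fit$null_log_likelihood,
         n = fit$n, converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname export_fit_json
#' @export
import_fit_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  get_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  se <- unlist(raw$standard_errors)
  structure(
    list(predictor_names = raw$predictor_names,
         coefficients = unlist(raw$coefficients),
         standard_errors = se,
         log_likelihood = get_or_na(raw$log_likelihood),
         null_log_likelihood = get_or_na(raw$null_log_likelihood),
         n = if (is.null(raw$n)) NA_integer_ else as.integer(raw$n),
         converged = if (is.null(raw$converged)) TRUE else raw$converged,
         predictor_sd = NULL),
    class = "logistic_fit"
  )
}
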