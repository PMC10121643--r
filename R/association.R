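# Survey-weighted association scan of the diet score against outcome
# batteries: variance-stabilizing transforms, standardized coefficients,
# sample-size filtering and FDR control.

boxcox_values <- function(x, lambda) {
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' Estimate the Box-Cox exponent by profile maximum likelihood
#'
#' Maximizes the Box-Cox profile log-likelihood
#' `-(n/2) log(var(z)) + (lambda - 1) sum(log x)` over `lambda` in
#' `[-3, 3]` by golden-section search.
#'
#' @param x Positive values.
#' @return Scalar `lambda` estimate.
#' @export
estimate_boxcox_lambda <- function(x) {
  stopifnot(all(x > 0))
  n <- length(x)
  slx <- sum(log(x))
  prof <- function(l) {
    z <- boxcox_values(x, l)
    -n / 2 * log(stats::var(z) * (n - 1) / n) + (l - 1) * slx
  }
  stats::optimize(prof, interval = c(-3, 3), maximum = TRUE)$maximum
}

#' Box-Cox transform with automatic shift and exponent
#'
#' `(x^lambda - 1)/lambda` (`log x` at `lambda = 0`). Non-positive values
#' require a shift; when `shift` is `NULL` and `min(x) <= 0`, the shift
#' `-min(x) + 1e-6` is applied and recorded. `lambda` defaults to the
#' profile-likelihood estimate on the shifted data.
#'
#' @param x Numeric values.
#' @param lambda Box-Cox exponent, or `NULL` to estimate.
#' @param shift Additive offset enforcing positivity, or `NULL` to choose.
#' @return A `transform_spec`: list with `values`, `kind = "boxcox"`,
#'   `lambda`, `shift`, `mean`, `sd` (post-transform moments).
#' @export
boxcox_transform <- function(x, lambda = NULL, shift = NULL) {
  if (is.null(shift)) shift <- if (min(x) <= 0) -min(x) + 1e-6 else 0
  xs <- x + shift
  if (any(xs <= 0))
    stop_foodprox("non-positive values remain after shift",
                  class = "foodprox_validation_error")
  if (is.null(lambda)) lambda <- estimate_boxcox_lambda(xs)
  v <- boxcox_values(xs, lambda)
  structure(list(values = v, kind = "boxcox", lambda = lambda, shift = shift,
                 mean = mean(v), sd = stats::sd(v)),
            class = "transform_spec")
}

#' Logit transform for scores in (0, 1)
#'
#' `log(x / (1 - x))` after clamping to `(eps, 1 - eps)`; intended for
#' risk-score variables already expressed as probabilities.
#'
#' @param x Values in `[0, 1]`.
#' @param eps Clamping margin (default `1e-6`).
#' @return A `transform_spec` with `kind = "logit"`.
#' @export
logit_transform <- function(x, eps = 1e-6) {
  if (any(x < 0 | x > 1))
    stop_foodprox("logit transform needs values in [0, 1]",
                  class = "foodprox_validation_error")
  xc <- pmin(pmax(x, eps), 1 - eps)
  v <- log(xc / (1 - xc))
  structure(list(values = v, kind = "logit", lambda = NA_real_, shift = 0,
                 mean = mean(v), sd = stats::sd(v)),
            class = "transform_spec")
}

#' Z-score a variable
#'
#' Full standardization z-scores both sides of a linear model; for the
#' logistic family only the continuous exposure is z-scored (partial
#' standardization), keeping the odds-ratio interpretation per standard
#' deviation of the exposure.
#'
#' @param x Numeric values with positive spread.
#' @return List `values`, `center`, `scale`.
#' @export
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop_foodprox("cannot standardize a zero-variance variable",
                  class = "foodprox_validation_error")
  list(values = (x - mean(x)) / s, center = mean(x), scale = s)
}

#' Minimum-sample-size filter for regression
#'
#' An outcome is analyzed only when the ratio of covariates (model terms
#' excluding the intercept) to data points is at most `1/ratio` -- for
#' categorical outcomes, to the size of the smallest category.
#'
#' @param n Number of observations (continuous outcomes).
#' @param covariate_count Number of model covariates.
#' @param smallest_category Size of the smallest outcome category
#'   (categorical outcomes); `NULL` for continuous.
#' @param ratio Required observations per covariate (default 50).
#' @return `TRUE` when the outcome passes.
#' @export
sample_size_filter <- function(n, covariate_count, smallest_category = NULL,
                               ratio = 50) {
  denom <- if (is.null(smallest_category)) n else smallest_category
  covariate_count / denom <= 1 / ratio + 1e-12
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values (monotone enforced) with significance flags at
#' level `alpha`.
#'
#' @param p Raw p values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return List `p_adjusted`, `significant`.
#' @export
fdr_adjust <- function(p, alpha = 0.05) {
  if (length(p) == 0)
    stop_foodprox("empty p-value vector", class = "foodprox_validation_error")
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_foodprox("p values must lie in [0, 1]",
                  class = "foodprox_validation_error")
  adj <- stats::p.adjust(p, method = "BH")
  list(p_adjusted = adj, significant = !is.na(adj) & adj <= alpha)
}

#' Weighted association of one outcome with the diet score
#'
#' Fits a weighted generalized linear model of the outcome on the (already
#' transformed) diet score plus adjustment covariates, with
#' heteroskedasticity-robust (sandwich, HC0) standard errors. The score is
#' z-scored inside the fit; for the linear family the outcome is z-scored
#' too (fully standardized coefficient), for the logistic family the binary
#' outcome is left on the odds scale (partially standardized coefficient).
#' Weights are normalized to mean 1, so the fit is invariant to rescaling
#' all weights; robust variance is the practical weights-only stand-in for
#' full survey-design variance (see the methods vignette for the
#' limitation).
#'
#' P values: two-sided t for the linear family, two-sided Wald (normal) for
#' logistic.
#'
#' @param outcome Numeric outcome (binary 0/1 for logistic).
#' @param score Numeric exposure (diet score, transformed upstream).
#' @param covariates data.frame or matrix of adjustment covariates (may be
#'   `NULL`).
#' @param weights Positive survey weights (default equal).
#' @param family `"linear"` or `"logistic"`.
#' @return One-row data.frame: `family`, `beta`, `se`, `p_value`, `n_used`,
#'   `standardization`, `converged`.
#' @export
fit_association <- function(outcome, score, covariates = NULL,
                            weights = NULL, family = c("linear", "logistic")) {
  family <- match.arg(family)
  n <- length(outcome)
  stopifnot(length(score) == n)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(all(weights > 0))
  w <- weights / mean(weights)
  zs <- standardize(score)$values
  dat <- data.frame(.y = outcome, .score = zs)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    dat <- cbind(dat, covariates)
  }
  form <- stats::as.formula(paste(".y ~", paste(setdiff(names(dat), ".y"),
                                                collapse = " + ")))
  if (family == "linear") {
    dat$.y <- standardize(dat$.y)$values
    fit <- stats::glm(form, data = dat, weights = w, family = stats::gaussian())
  } else {
    if (!all(outcome %in% c(0, 1)))
      stop_foodprox("logistic family needs a 0/1 outcome",
                    class = "foodprox_validation_error")
    fit <- suppressWarnings(
      stats::glm(form, data = dat, weights = w,
                 family = stats::quasibinomial(link = "logit")))
  }
  alias <- is.na(stats::coef(fit))
  if (any(alias))
    stop_foodprox("rank-deficient design; aliased: ",
                  paste(names(which(alias)), collapse = ", "),
                  class = "foodprox_validation_error")
  vc <- sandwich::vcovHC(fit, type = "HC0")
  beta <- stats::coef(fit)[[".score"]]
  se <- sqrt(vc[".score", ".score"])
  p <- if (family == "linear")
    2 * stats::pt(abs(beta / se), df = fit$df.residual, lower.tail = FALSE)
  else
    2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  data.frame(family = family, beta = beta, se = se, p_value = p,
             n_used = n,
             standardization = if (family == "linear") "full" else "partial",
             converged = isTRUE(fit$converged),
             stringsAsFactors = FALSE)
}

#' Association scan of many outcomes against the diet score
#'
#' For every outcome column: decide the model family (binary 0/1 columns
#' are logistic; columns named in `logit_vars` are logit-transformed then
#' linear; other continuous columns are Box-Cox transformed then linear),
#' apply the sample-size filter, fit the weighted association with
#' covariate adjustment, and finally adjust p values across all fitted
#' outcomes by Benjamini-Hochberg. The diet score itself is Box-Cox
#' transformed once on the analysis population, so coefficients are per
#' standard deviation of the transformed score. Binary outcomes are never
#' transformed.
#'
#' @param outcomes data.frame with `individual_id` plus one column per
#'   outcome.
#' @param individuals data.frame from [score_population()] (needs
#'   `individual_id`, the score column, `survey_weight`, covariates).
#' @param score_col Name of the exposure column (default `"ifpro_wc"`).
#' @param covariate_cols Covariate column names in `individuals` (default:
#'   age, sex, ethnicity, BMI, SES and total caloric intake when present).
#' @param logit_vars Outcome columns to transform by logit (risk scores in
#'   `(0, 1)`).
#' @param alpha FDR level (default 0.05).
#' @param min_ratio Observations required per covariate (default 50).
#' @return data.frame, one row per outcome ordered by `outcome_id`, with
#'   columns `outcome_id`, `family`, `transform`, `beta`, `se`, `p_value`,
#'   `p_adjusted`, `significant`, `n_used`, `standardization`, `skipped`.
#'   The score's `transform_spec` is attached as `attr(, "score_transform")`.
#' @export
ewas <- function(outcomes, individuals, score_col = "ifpro_wc",
                 covariate_cols = NULL, logit_vars = character(0),
                 alpha = 0.05, min_ratio = 50) {
  merged <- merge(individuals, outcomes, by = "individual_id")
  if (nrow(merged) == 0)
    stop_foodprox("no individuals shared between scores and outcomes",
                  class = "foodprox_validation_error")
  if (is.null(covariate_cols))
    covariate_cols <- intersect(c("age", "sex", "ethnicity", "bmi", "ses",
                                  "total_kcal"), names(individuals))
  score_tr <- boxcox_transform(merged[[score_col]])
  score_z <- score_tr$values
  outcome_ids <- sort(setdiff(names(outcomes), "individual_id"))
  w <- merged$survey_weight %||% rep(1, nrow(merged))
  covs <- if (length(covariate_cols)) merged[covariate_cols] else NULL
  rows <- lapply(outcome_ids, function(oid) {
    y <- merged[[oid]]
    ok <- stats::complete.cases(y)
    base <- data.frame(outcome_id = oid, family = NA_character_,
                       transform = NA_character_, beta = NA_real_,
                       se = NA_real_, p_value = NA_real_,
                       p_adjusted = NA_real_, significant = FALSE,
                       n_used = sum(ok), standardization = NA_character_,
                       skipped = TRUE, stringsAsFactors = FALSE)
    yv <- y[ok]
    binary <- all(yv %in% c(0, 1))
    k <- 1 + if (is.null(covs)) 0 else ncol(covs)
    pass <- if (binary)
      sample_size_filter(sum(ok), k, smallest_category = min(table(yv)),
                         ratio = min_ratio)
    else sample_size_filter(sum(ok), k, ratio = min_ratio)
    if (!pass || (binary && length(unique(yv)) < 2)) return(base)
    tr_name <- if (binary) "none" else if (oid %in% logit_vars) "logit" else "boxcox"
    yt <- switch(tr_name,
                 none = yv,
                 logit = logit_transform(yv)$values,
                 boxcox = boxcox_transform(yv)$values)
    fit <- fit_association(yt, score_z[ok],
                           covariates = if (is.null(covs)) NULL
                                        else covs[ok, , drop = FALSE],
                           weights = w[ok],
                           family = if (binary) "logistic" else "linear")
    base$family <- fit$family
    base$transform <- tr_name
    base$beta <- fit$beta; base$se <- fit$se; base$p_value <- fit$p_value
    base$n_used <- fit$n_used
    base$standardization <- fit$standardization
    base$skipped <- FALSE
    base
  })
  out <- do.call(rbind, rows)
  fitted <- !out$skipped
  if (any(fitted)) {
    adj <- fdr_adjust(out$p_value[fitted], alpha = alpha)
    out$p_adjusted[fitted] <- adj$p_adjusted
    out$significant[fitted] <- adj$significant
  }
  rownames(out) <- NULL
  attr(out, "score_transform") <- score_tr
  out
}
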