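#' Read a dietary recall table
#'
#' One row per consumed item per individual per day. Required columns:
#' `individual_id`, `day`, `food_id`, `grams`, `kcal`, `survey_weight`;
#' any further columns are kept as covariates.
#'
#' @param path CSV path.
#' @return Validated data.frame.
#' @export
read_recall_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_recalls(tab)
}

validate_recalls <- function(tab) {
  req <- c("individual_id", "day", "food_id", "grams", "kcal", "survey_weight")
  for (col in req)
    if (!col %in% names(tab))
      stop_foodprox("missing required column '", col, "'",
                    class = "foodprox_schema_error")
  tab$individual_id <- as.character(tab$individual_id)
  tab$food_id <- as.character(tab$food_id)
  if (any(!is.finite(tab$grams) | tab$grams <= 0))
    stop_foodprox("grams must be positive", class = "foodprox_validation_error")
  if (any(!is.finite(tab$kcal) | tab$kcal < 0))
    stop_foodprox("kcal must be non-negative", class = "foodprox_validation_error")
  if (any(!is.finite(tab$survey_weight) | tab$survey_weight <= 0))
    stop_foodprox("survey_weight must be positive",
                  class = "foodprox_validation_error")
  tab
}

lookup_scores <- function(food_ids, scores) {
  if (is.data.frame(scores))
    scores <- stats::setNames(scores$fpro_mean, scores$food_id)
  miss <- setdiff(food_ids, names(scores))
  if (length(miss) > 0)
    stop_foodprox("no processing score for food_id '", miss[1], "'",
                  class = "foodprox_validation_error")
  unname(scores[food_ids])
}

#' Calorie-weighted diet processing score for one day
#'
#' `iFPro_WC = sum_k (c_k / C) FPro_k` over the items of one recall day:
#' the fraction of the day's calories supplied at each degree of processing.
#'
#' @param items data.frame of one day's items with columns `food_id`,
#'   `grams`, `kcal`.
#' @param scores Named numeric vector `food_id -> FPro`, or the data.frame
#'   from [score_food()].
#' @return Score in `[0, 1]`.
#' @export
ifpro_wc <- function(items, scores) {
  f <- lookup_scores(items$food_id, scores)
  C <- sum(items$kcal)
  if (C <= 0)
    stop_foodprox("total kcal is zero: calorie-weighted score undefined",
                  class = "foodprox_validation_error")
  sum(items$kcal / C * f)
}

#' Gram-weighted diet processing score for one day
#'
#' Like [ifpro_wc()] but weighted by each item's gram contribution, so
#' zero-calorie items (e.g. diet soft drinks) still count.
#'
#' @inheritParams ifpro_wc
#' @return Score in `[0, 1]`.
#' @export
ifpro_wg <- function(items, scores) {
  f <- lookup_scores(items$food_id, scores)
  G <- sum(items$grams)
  if (G <= 0)
    stop_foodprox("total grams is zero: gram-weighted score undefined",
                  class = "foodprox_validation_error")
  sum(items$grams / G * f)
}

#' Diet scores for one individual
#'
#' Computes per-day calorie- and gram-weighted scores and averages them over
#' the available recall days (typically 1 or 2): the daily average diet
#' processing score. Days with zero total kcal contribute no calorie-based
#' score (and likewise for grams); at least one valid day is required.
#'
#' @param diet data.frame of one individual's items with columns `day`,
#'   `food_id`, `grams`, `kcal`.
#' @param scores As in [ifpro_wc()].
#' @return List: `ifpro_wc`, `ifpro_wg`, `n_days_used`, `n_dishes_mean`.
#' @export
score_individual <- function(diet, scores) {
  days <- split(diet, diet$day)
  wc <- wg <- numeric(0)
  for (d in days) {
    if (sum(d$kcal) > 0) wc <- c(wc, ifpro_wc(d, scores))
    if (sum(d$grams) > 0) wg <- c(wg, ifpro_wg(d, scores))
  }
  if (length(wc) == 0 && length(wg) == 0)
    stop_foodprox("no recall day with positive totals",
                  class = "foodprox_validation_error")
  list(ifpro_wc = if (length(wc)) mean(wc) else NA_real_,
       ifpro_wg = if (length(wg)) mean(wg) else NA_real_,
       n_days_used = length(days),
       n_dishes_mean = mean(vapply(days, nrow, integer(1))))
}

#' Diet scores for a recall population
#'
#' Applies [score_individual()] to every individual in a recall table and
#' carries the survey weight and covariate columns through (taken from each
#' individual's first row).
#'
#' @param recalls Recall data.frame (see [read_recall_table()]).
#' @param scores As in [ifpro_wc()].
#' @return data.frame with columns `individual_id`, `ifpro_wc`, `ifpro_wg`,
#'   `n_days_used`, `n_dishes_mean`, `survey_weight`, plus covariates.
#' @export
score_population <- function(recalls, scores) {
  recalls <- validate_recalls(recalls)
  covar_cols <- setdiff(names(recalls),
                        c("individual_id", "day", "food_id", "grams", "kcal"))
  res <- lapply(split(recalls, recalls$individual_id), function(d) {
    s <- score_individual(d, scores)
    cbind(data.frame(individual_id = d$individual_id[1],
                     ifpro_wc = s$ifpro_wc, ifpro_wg = s$ifpro_wg,
                     n_days_used = s$n_days_used,
                     n_dishes_mean = s$n_dishes_mean,
                     stringsAsFactors = FALSE),
          d[1, covar_cols, drop = FALSE])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$individual_id), , drop = FALSE]
}

#' Survey-weighted quantile (lower-mass rule)
#'
#' The smallest observed value whose cumulative weight reaches the requested
#' fraction of total weight. With equal weights and odd n this is the
#' ordinary sample quantile of the same convention.
#'
#' @param x Numeric values.
#' @param w Positive weights.
#' @param probs Quantile levels in `[0, 1]`.
#' @return Numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w, probs = 0.5) {
  stopifnot(length(x) == length(w), all(w > 0), all(probs >= 0 & probs <= 1))
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

#' Survey-weighted population summary of diet scores
#'
#' Weighted median, weighted quartiles and a weighted histogram of the
#' individual scores, using each individual's survey weight so population
#' statistics reflect the sampling design. All statistics are invariant to
#' a common rescaling of the weights.
#'
#' @param x Numeric scores (e.g. `ifpro_wc` per individual).
#' @param weights Positive survey weights.
#' @param probs Quantile levels (default quartiles).
#' @param breaks Histogram bin edges covering the range of `x`
#'   (default 20 equal bins over `[0, 1]`).
#' @return List: `median`, `quantiles`, `histogram` (data.frame with `lo`,
#'   `hi`, `weight_fraction`), `n`.
#' @export
population_summary <- function(x, weights, probs = c(0.25, 0.5, 0.75),
                               breaks = seq(0, 1, length.out = 21)) {
  if (length(x) == 0)
    stop_foodprox("empty input", class = "foodprox_validation_error")
  stopifnot(length(weights) == length(x), all(weights > 0))
  bin <- cut(x, breaks = breaks, include.lowest = TRUE)
  wf <- tapply(weights, bin, sum, default = 0) / sum(weights)
  list(median = weighted_quantile(x, weights, 0.5),
       quantiles = stats::setNames(weighted_quantile(x, weights, probs),
                                   paste0("q", probs * 100)),
       histogram = data.frame(lo = utils::head(breaks, -1),
                              hi = utils::tail(breaks, -1),
                              weight_fraction = as.numeric(wf)),
       n = length(x))
}
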