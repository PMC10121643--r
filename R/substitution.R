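#' Substitution policy
#'
#' Controls the minimal-change diet substitution search. `margin` is the
#' minimum processing-score reduction an alternative must offer to count as
#' "significantly less processed" (default 0.1). Replacements always
#' preserve the replaced item's food category; with `isocaloric` (default)
#' the replacement grams are chosen so contributed calories are unchanged.
#'
#' @param margin Minimum FPro reduction in `(0, 1)` (default 0.1).
#' @param max_steps Default cap on substitution steps (default 10).
#' @param alternative_rule `"min_fpro"` (least processed admissible
#'   alternative, default) or `"random_below_margin"`.
#' @param isocaloric Match the replaced item's calories (default `TRUE`).
#' @return A `substitution_policy` list.
#' @export
substitution_policy <- function(margin = 0.1, max_steps = 10,
                                alternative_rule = c("min_fpro", "random_below_margin"),
                                isocaloric = TRUE) {
  stopifnot(is.numeric(margin), margin > 0, margin < 1,
            is_count(max_steps, min = 0))
  structure(list(margin = margin, max_steps = as.integer(max_steps),
                 alternative_rule = match.arg(alternative_rule),
                 isocaloric = isTRUE(isocaloric)),
            class = "substitution_policy")
}

#' Less processed alternatives within a food category
#'
#' Foods sharing the query food's category whose processing score is at
#' most `FPro(food) - margin`, in ascending score order.
#'
#' @param food A [food_record()] with a `wweia_category`.
#' @param catalog A [food_catalog()].
#' @param scores Named vector `food_id -> FPro` or [score_food()] output.
#' @param margin Minimum score reduction.
#' @return data.frame `food_id`, `fpro`, ascending; zero rows when none.
#' @export
find_alternatives <- function(food, catalog, scores, margin = 0.1) {
  if (is.na(food$wweia_category))
    stop_foodprox("food '", food$food_id, "' has no category",
                  class = "foodprox_validation_error")
  peers <- catalog$meta$food_id[
    !is.na(catalog$meta$wweia_category) &
      catalog$meta$wweia_category == food$wweia_category &
      catalog$meta$food_id != food$food_id]
  if (length(peers) == 0)
    return(data.frame(food_id = character(), fpro = numeric()))
  f_own <- lookup_scores(food$food_id, scores)
  f_peer <- lookup_scores(peers, scores)
  keep <- f_peer <= f_own - margin
  out <- data.frame(food_id = peers[keep], fpro = f_peer[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$fpro, out$food_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Pick the replacement for one item under the policy (or NULL).
pick_alternative <- function(food, catalog, scores, policy) {
  alts <- find_alternatives(food, catalog, scores, policy$margin)
  if (policy$isocaloric) {
    dens <- catalog$meta$kcal_per_100g[match(alts$food_id, catalog$meta$food_id)]
    alts <- alts[dens > 0, , drop = FALSE]
  }
  if (nrow(alts) == 0) return(NULL)
  if (policy$alternative_rule == "min_fpro") alts[1, ]
  else alts[sample.int(nrow(alts), 1), ]
}

#' Prioritize the next item to replace
#'
#' For each not-yet-replaced item with an admissible alternative, the
#' achievable gain is its calorie share times the score drop to its best
#' alternative: `g_k = (c_k / C) * (FPro_k - FPro_best(k))` -- items that
#' contribute many calories and have much less processed peers come first.
#' Ties go to the lexicographically lower food id.
#'
#' @param items data.frame of diet items (`food_id`, `grams`, `kcal`).
#' @param catalog A [food_catalog()].
#' @param scores As in [find_alternatives()].
#' @param policy A [substitution_policy()].
#' @param excluded Item row indices already replaced.
#' @return List `(item_row, replacement, gain)` or `NULL` when no item has
#'   an admissible alternative.
#' @export
prioritize <- function(items, catalog, scores, policy, excluded = integer(0)) {
  C <- sum(items$kcal)
  if (C <= 0) return(NULL)
  f <- lookup_scores(items$food_id, scores)
  best_row <- NULL; best_gain <- -Inf; best_alt <- NULL
  cand <- setdiff(seq_len(nrow(items)), excluded)
  # stable candidate order: by food_id so gain ties resolve lexicographically
  cand <- cand[order(items$food_id[cand])]
  for (i in cand) {
    food <- food_record(catalog, items$food_id[i])
    if (is.na(food$wweia_category)) next
    alt <- pick_alternative(food, catalog, scores, policy)
    if (is.null(alt)) next
    gain <- items$kcal[i] / C * (f[i] - alt$fpro)
    if (gain > best_gain + 1e-15) {
      best_gain <- gain; best_row <- i; best_alt <- alt
    }
  }
  if (is.null(best_row)) return(NULL)
  list(item_row = best_row, replacement = best_alt, gain = best_gain)
}

#' Greedy minimal-change diet substitution
#'
#' Repeatedly replaces the highest-gain item (see [prioritize()]) with its
#' least processed same-category alternative, up to `k_steps` times or until
#' no admissible item remains. Each original item is replaced at most once.
#' Under an isocaloric policy the replacement's grams are set to
#' `kcal_replaced / kcal_density(replacement)` so total calories are
#' conserved at every step; alternatives with zero energy density are
#' skipped with a warning in that mode.
#'
#' @param diet data.frame of one individual's items (`food_id`, `grams`,
#'   `kcal`; a `day` column is honoured when present for scoring).
#' @param catalog A [food_catalog()].
#' @param scores As in [find_alternatives()].
#' @param policy A [substitution_policy()].
#' @param k_steps Number of substitution steps (default `policy$max_steps`).
#' @return A `substitution_plan`: list with `steps` (data.frame `step`,
#'   `replaced`, `replacement`, `grams_new`, `score_before`, `score_after`),
#'   `initial_score`, `final_score`, and the modified `items`.
#' @export
substitute_diet <- function(diet, catalog, scores, policy = substitution_policy(),
                            k_steps = policy$max_steps) {
  stopifnot(is_count(k_steps, min = 0))
  items <- diet
  if (!"day" %in% names(items)) items$day <- 1L
  score_now <- function(it) {
    s <- score_individual(it, scores)
    s$ifpro_wc
  }
  initial <- score_now(items)
  current <- initial
  replaced_rows <- integer(0)
  steps <- list()
  for (st in seq_len(k_steps)) {
    sel <- prioritize(items, catalog, scores, policy, excluded = replaced_rows)
    if (is.null(sel)) break
    i <- sel$item_row
    alt_id <- sel$replacement$food_id
    dens <- catalog$meta$kcal_per_100g[match(alt_id, catalog$meta$food_id)]
    old_id <- items$food_id[i]
    if (policy$isocaloric) {
      grams_new <- items$kcal[i] / dens * 100
    } else {
      grams_new <- items$grams[i]
      items$kcal[i] <- grams_new * dens / 100
    }
    items$food_id[i] <- alt_id
    items$grams[i] <- grams_new
    after <- score_now(items)
    steps[[st]] <- data.frame(step = st, replaced = old_id,
                              replacement = alt_id, grams_new = grams_new,
                              score_before = current, score_after = after,
                              stringsAsFactors = FALSE)
    current <- after
    replaced_rows <- c(replaced_rows, i)
  }
  steps <- if (length(steps)) do.call(rbind, steps)
           else data.frame(step = integer(), replaced = character(),
                           replacement = character(), grams_new = numeric(),
                           score_before = numeric(), score_after = numeric())
  structure(list(steps = steps, initial_score = initial,
                 final_score = current, items = items),
            class = "substitution_plan")
}

#' @export
print.substitution_plan <- function(x, ...) {
  cat(sprintf("<substitution_plan: %d steps, iFPro_WC %.4f -> %.4f>\n",
              nrow(x$steps), x$initial_score, x$final_score))
  invisible(x)
}

#' Percent change between two values
#'
#' `100 * (new - old) / old`; a negative result is a reduction. Used to
#' express substitution effects on the diet score scale.
#'
#' @param old,new Numeric values, `old != 0`.
#' @return Percent change.
#' @export
percent_change <- function(old, new) {
  stopifnot(all(old != 0))
  100 * (new - old) / old
}

#' Project a diet-score change onto an associated outcome
#'
#' Expresses a substitution-induced score change as a percent change of an
#' outcome, using the outcome's standardized association coefficient. The
#' score change is first mapped to standard-deviation units of the
#' transformed score, `dz = (T(s_new) - T(s_old)) / sd_T`, with T the
#' population Box-Cox (or identity) transform. For a logistic association
#' with partially standardized beta the percent change in odds is
#' `(exp(beta * dz) - 1) * 100`; for a linear association with fully
#' standardized beta the percent change of the outcome about its mean is
#' `beta * dz * sd_y / mean_y * 100`.
#'
#' @param score_old,score_new Diet scores before and after substitution.
#' @param assoc One row of [ewas()] output (or a list with `family` and
#'   `beta`).
#' @param transform A `transform_spec` for the score (from
#'   [boxcox_transform()], carrying `lambda`, `shift`, `sd`), or `NULL` for
#'   identity with `sd = 1`.
#' @param outcome_sd,outcome_mean Needed for the linear family.
#' @return Percent change of odds (logistic) or of the outcome (linear).
#' @export
project_outcome_change <- function(score_old, score_new, assoc,
                                   transform = NULL,
                                   outcome_sd = NULL, outcome_mean = NULL) {
  if (is.null(transform)) {
    dz <- score_new - score_old
  } else {
    if (is.null(transform$lambda) || is.null(transform$sd))
      stop_foodprox("transform must carry lambda and sd",
                    class = "foodprox_validation_error")
    tv <- function(s) boxcox_values(s + (transform$shift %||% 0), transform$lambda)
    dz <- (tv(score_new) - tv(score_old)) / transform$sd
  }
  fam <- assoc$family
  if (fam == "logistic") return((exp(assoc$beta * dz) - 1) * 100)
  if (fam == "linear") {
    if (is.null(outcome_sd) || is.null(outcome_mean))
      stop_foodprox("linear projection needs outcome_sd and outcome_mean",
                    class = "foodprox_validation_error")
    return(assoc$beta * dz * outcome_sd / outcome_mean * 100)
  }
  stop_foodprox("unknown association family '", fam, "'",
                class = "foodprox_validation_error")
}
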