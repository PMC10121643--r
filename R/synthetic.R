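#' Synthetic-data generator configuration
#'
#' Study conditions for the synthetic benchmark: a labeled food catalog
#' with class-structured nutrient profiles, a recall population whose food
#' choices follow a latent processing propensity, and outcome tables with
#' known association coefficients.
#'
#' The catalog design mirrors the biology the classifier exploits: raw
#' profiles per food category are constrained within physiologic ranges;
#' processing multiplies a growing fraction of nutrients by log-normal
#' factors whose spread increases with NOVA class; culinary ingredients
#' (NOVA 2) are near-pure single-macronutrient profiles; ultra-processed
#' foods additionally receive fortification spikes. Energy density is
#' derived from the macronutrients by Atwater factors (4/4/9 kcal per g of
#' protein/carbohydrate/fat).
#'
#' @param n_foods Catalog size (default 800).
#' @param n_categories Number of food categories (default 12).
#' @param panel A [nutrient_panel()] (default `builtin_panel("fda12")`).
#' @param class_mix Proportions of NOVA 1--4 (default
#'   `c(0.25, 0.10, 0.30, 0.35)`: culinary ingredients rare, ultra-processed
#'   the largest class).
#' @param alteration_scale Per-class log-normal sigma of the processing
#'   alteration, strictly increasing 1 to 4 (default
#'   `c(0.05, 0.4, 0.8, 1.4)`).
#' @param altered_fraction Per-class fraction of nutrients altered
#'   (default `c(0.10, 0.40, 0.60, 0.85)`).
#' @param fortification_rate Probability that a NOVA 4 food receives
#'   additive fortification spikes (default 0.3).
#' @param n_individuals Population size (default 300).
#' @param dishes_per_day_mean Mean dishes per recall day (default 12).
#' @param propensity_sd Spread of the latent processing propensity
#'   (default 1).
#' @param true_betas Named list `outcome_id -> list(family, beta)` for
#'   [generate_outcomes()].
#' @param seed Integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_foods = 800, n_categories = 12,
                             panel = NULL,
                             class_mix = c(0.25, 0.10, 0.30, 0.35),
                             alteration_scale = c(0.05, 0.4, 0.8, 1.4),
                             altered_fraction = c(0.10, 0.40, 0.60, 0.85),
                             fortification_rate = 0.3,
                             n_individuals = 300,
                             dishes_per_day_mean = 12,
                             propensity_sd = 1,
                             true_betas = list(),
                             seed = 1L) {
  if (is.null(panel)) panel <- builtin_panel("fda12")
  if (length(class_mix) != 4 || any(class_mix < 0) ||
      abs(sum(class_mix) - 1) > 1e-8)
    stop_foodprox("class_mix must be 4 non-negative proportions summing to 1",
                  class = "foodprox_validation_error")
  if (length(alteration_scale) != 4 || any(diff(alteration_scale) <= 0))
    stop_foodprox("alteration_scale must be strictly increasing over classes",
                  class = "foodprox_validation_error")
  stopifnot(length(altered_fraction) == 4,
            all(altered_fraction >= 0 & altered_fraction <= 1),
            fortification_rate >= 0, fortification_rate <= 1,
            is_count(n_foods, 0), is_count(n_categories, 1),
            is_count(n_individuals, 0), dishes_per_day_mean > 0,
            propensity_sd >= 0)
  structure(list(n_foods = as.integer(n_foods),
                 n_categories = as.integer(n_categories), panel = panel,
                 class_mix = class_mix, alteration_scale = alteration_scale,
                 altered_fraction = altered_fraction,
                 fortification_rate = fortification_rate,
                 n_individuals = as.integer(n_individuals),
                 dishes_per_day_mean = dishes_per_day_mean,
                 propensity_sd = propensity_sd, true_betas = true_betas,
                 seed = as.integer(seed)),
            class = "generator_config")
}

MACROS <- c("protein", "carbohydrate", "total_fat")

atwater_kcal <- function(nutrients) {
  as.numeric(nutrients[, "protein"] * 4 + nutrients[, "carbohydrate"] * 4 +
               nutrients[, "total_fat"] * 9)
}

#' Generate a labeled synthetic food catalog
#'
#' Per category, a raw baseline profile is drawn log-normally within
#' category-specific ranges; each food inherits its category baseline and a
#' NOVA class from `class_mix`, then a class-dependent fraction of its
#' nutrients is altered by log-normal factors
#' `exp(dir_i * mu_c + Normal(0, sigma_c))`, where both the systematic
#' log-fold shift `mu_c` and its spread `sigma_c` grow with the NOVA class
#' (`sigma_c = alteration_scale[c]`, `mu_c = 1.5 * sigma_c`) and `dir_i` is
#' a fixed per-nutrient processing direction (sugars, fats and sodium up;
#' fiber, potassium and other micronutrients down) -- emulating the
#' combinatorial but reproducible way processing reshapes a profile. NOVA 2
#' foods are replaced by near-pure single-macronutrient profiles
#' (oil/sugar/salt analogues); NOVA 4 foods receive fortification spikes
#' with probability `fortification_rate`. Energy density follows the
#' macronutrients by Atwater arithmetic.
#'
#' @param config A [generator_config()].
#' @return A labeled [food_catalog()].
#' @export
generate_catalog <- function(config) {
  panel <- config$panel
  ids <- panel_ids(panel)
  if (!all(MACROS %in% ids))
    stop_foodprox("panel must contain ", paste(MACROS, collapse = ", "),
                  class = "foodprox_validation_error")
  p <- panel$size
  with_seed_(config$seed, {
    # category baselines: log-normal profiles on a physiologic gram scale,
    # micronutrients (declared mg/ug) proportionally smaller
    unit_scale <- c(g = 2, mg = 0.05, ug = 5e-4)[panel$nutrients$unit]
    base <- matrix(0, config$n_categories, p, dimnames = list(NULL, ids))
    for (g in seq_len(config$n_categories))
      base[g, ] <- stats::rlnorm(p, meanlog = log(unit_scale), sdlog = 0.8)
    # per-nutrient processing direction: refined-energy nutrients rise with
    # processing, fiber and micronutrients fall; unnamed nutrients split
    up_ids <- c("sugars", "total_fat", "saturated_fat", "sodium",
                "carbohydrate", "fa_16_0", "fa_18_0", "fa_18_1")
    down_ids <- c("fiber", "potassium", "water", "vitamin_c", "magnesium",
                  "folate_total", "vitamin_d", "calcium", "iron", "protein")
    dir_i <- ifelse(ids %in% up_ids, 1,
                    ifelse(ids %in% down_ids, -1,
                           rep_len(c(1, -1), p)))
    cls <- sample(1:4, config$n_foods, replace = TRUE, prob = config$class_mix)
    cat_of <- sample.int(config$n_categories, config$n_foods, replace = TRUE)
    nut <- matrix(0, config$n_foods, p, dimnames = list(NULL, ids))
    for (i in seq_len(config$n_foods)) {
      cl <- cls[i]
      v <- base[cat_of[i], ]
      if (cl == 2L) {
        # processed culinary ingredient: near-pure macronutrient
        v <- stats::setNames(rep(1e-4, p), ids)
        macro <- sample(MACROS, 1)
        v[macro] <- stats::runif(1, 85, 100)
        if (macro == "carbohydrate" && "sugars" %in% ids)
          v["sugars"] <- v["carbohydrate"] * stats::runif(1, 0.8, 1)
        if ("sodium" %in% ids && stats::runif(1) < 0.3)
          v["sodium"] <- stats::runif(1, 500, 4000)
      }
      n_alt <- round(config$altered_fraction[cl] * p)
      if (n_alt > 0) {
        j <- sample.int(p, n_alt)
        sig <- config$alteration_scale[cl]
        v[j] <- v[j] * stats::rlnorm(n_alt, dir_i[j] * 1.5 * sig, sig)
      }
      if (cl == 4L && stats::runif(1) < config$fortification_rate) {
        j <- sample.int(p, max(1, round(0.15 * p)))
        v[j] <- v[j] + stats::rlnorm(length(j), log(unit_scale[j] * 20), 0.5)
      }
      nut[i, ] <- v
    }
    meta <- data.frame(
      food_id = sprintf("food_%04d", seq_len(config$n_foods)),
      kcal_per_100g = atwater_kcal(nut),
      description = sprintf("synthetic food %d (NOVA %d)",
                            seq_len(config$n_foods), cls),
      wweia_category = sprintf("cat_%02d", cat_of),
      nova_label = cls, stringsAsFactors = FALSE)
    food_catalog(nut, meta, panel)
  })
}

#' Generate a synthetic recall population
#'
#' Each individual draws a latent processing propensity
#' `pi ~ Normal(0, propensity_sd)`; on each of two recall days the number
#' of dishes is Poisson (at least one) and dishes are drawn from the
#' catalog with probabilities tilted toward higher NOVA classes as `pi`
#' grows (softmax on `pi * (class - 2.5)`). Portion grams are log-normal;
#' kcal follow the food's energy density. Survey weights are positive
#' log-normal draws normalized to mean 1; age, sex, ethnicity, BMI and SES
#' covariates are drawn independently of `pi`.
#'
#' @param config A [generator_config()].
#' @param catalog A labeled [food_catalog()], typically from
#'   [generate_catalog()].
#' @return Recall data.frame (schema of [read_recall_table()]) with
#'   covariate columns `age`, `sex`, `ethnicity`, `bmi`, `ses`; the latent
#'   propensities are attached as `attr(, "propensity")`.
#' @export
generate_population <- function(config, catalog) {
  if (n_foods(catalog) == 0)
    stop_foodprox("empty catalog", class = "foodprox_validation_error")
  if (config$n_individuals == 0)
    return(structure(data.frame(), propensity = numeric(0)))
  cls <- catalog$meta$nova_label
  if (anyNA(cls))
    stop_foodprox("population generation needs a fully labeled catalog",
                  class = "foodprox_validation_error")
  with_seed_(config$seed + 1L, {
    n <- config$n_individuals
    pii <- stats::rnorm(n, 0, config$propensity_sd)
    sw <- stats::rlnorm(n, 0, 0.5); sw <- sw / mean(sw)
    age <- round(stats::runif(n, 18, 85))
    sex <- sample(c("F", "M"), n, replace = TRUE)
    eth <- sample(sprintf("eth%d", 1:4), n, replace = TRUE)
    bmi <- stats::rnorm(n, 27, 5)
    ses <- stats::rnorm(n, 0, 1)
    rows <- vector("list", n)
    for (j in seq_len(n)) {
      pr <- exp(pii[j] * (cls - 2.5))
      pr <- pr / sum(pr)
      per_day <- lapply(1:2, function(day) {
        nd <- max(1L, stats::rpois(1, config$dishes_per_day_mean))
        pick <- sample.int(n_foods(catalog), nd, replace = TRUE, prob = pr)
        grams <- stats::rlnorm(nd, log(120), 0.5)
        data.frame(individual_id = sprintf("ind_%05d", j), day = day,
                   food_id = catalog$meta$food_id[pick], grams = grams,
                   kcal = grams * catalog$meta$kcal_per_100g[pick] / 100,
                   stringsAsFactors = FALSE)
      })
      d <- do.call(rbind, per_day)
      d$survey_weight <- sw[j]; d$age <- age[j]; d$sex <- sex[j]
      d$ethnicity <- eth[j]; d$bmi <- bmi[j]; d$ses <- ses[j]
      rows[[j]] <- d
    }
    out <- do.call(rbind, rows)
    out$total_kcal <- stats::ave(out$kcal, out$individual_id, FUN = sum) / 2
    rownames(out) <- NULL
    attr(out, "propensity") <- pii
    out
  })
}

#' Generate outcome tables with known effects
#'
#' For each entry of `true_betas` an outcome column is simulated from the
#' z-scored diet score: continuous outcomes as
#' `y = beta * z + gamma * covariates + Normal(0, 1)` (so `beta` is the
#' standardized effect when the residual dominates); binary outcomes
#' through a logistic inverse link with partially standardized `beta`.
#' Entries with `beta = 0` give null outcomes for calibration.
#'
#' @param individuals data.frame from [score_population()] (needs
#'   `individual_id` and the score column).
#' @param true_betas Named list: each element
#'   `list(family = "linear"|"logistic", beta = effect)`, optionally
#'   `gamma` (covariate loading on `bmi`, default 0) and `intercept`.
#' @param score_col Exposure column (default `"ifpro_wc"`).
#' @param seed Integer seed.
#' @return data.frame `individual_id` + one column per outcome; the truth
#'   is attached as `attr(, "truth")`.
#' @export
generate_outcomes <- function(individuals, true_betas, score_col = "ifpro_wc",
                              seed = 1L) {
  z <- standardize(individuals[[score_col]])$values
  n <- length(z)
  with_seed_(seed, {
    out <- data.frame(individual_id = individuals$individual_id,
                      stringsAsFactors = FALSE)
    for (oid in names(true_betas)) {
      spec <- true_betas[[oid]]
      gamma <- spec$gamma %||% 0
      covpart <- if (gamma != 0 && "bmi" %in% names(individuals))
        gamma * standardize(individuals$bmi)$values else 0
      if (spec$family == "linear") {
        out[[oid]] <- spec$beta * z + covpart + stats::rnorm(n)
      } else if (spec$family == "logistic") {
        eta <- (spec$intercept %||% -0.5) + spec$beta * z + covpart
        out[[oid]] <- stats::rbinom(n, 1, stats::plogis(eta))
      } else {
        stop_foodprox("unknown outcome family '", spec$family, "'",
                      class = "foodprox_validation_error")
      }
    }
    attr(out, "truth") <- true_betas
    out
  })
}
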