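# Catalog with a controlled category structure for substitution tests:
# two "cereal" foods far apart in score, plus peers in other categories.
sub_catalog <- function() {
  nut <- matrix(1, 6, 6)
  meta <- data.frame(
    food_id = c("kix", "shredded", "candy", "provolone", "spraycheese", "water"),
    kcal_per_100g = c(380, 340, 500, 350, 290, 0),
    wweia_category = c("cereal", "cereal", "sweets", "cheese", "cheese",
                       "beverage"))
  food_catalog(nut, meta, mini_panel())
}

sub_scores <- c(kix = 0.9998, shredded = 0.5091, candy = 0.95,
                provolone = 0.5001, spraycheese = 0.9648, water = 0.01)

test_that("alternatives stay in category and clear the margin", {
  cat <- sub_catalog()
  alts <- find_alternatives(food_record(cat, "kix"), cat, sub_scores)
  expect_identical(alts$food_id, "shredded")
  # margin rule: a 0.05 drop is not "significantly less processed"
  near <- c(sub_scores, almost = 0.9598)
  cat2 <- food_catalog(
    matrix(1, 7, 6),
    data.frame(food_id = c(sub_catalog()$meta$food_id, "almost"),
               kcal_per_100g = c(sub_catalog()$meta$kcal_per_100g, 300),
               wweia_category = c(sub_catalog()$meta$wweia_category, "cereal")),
    mini_panel())
  expect_false("almost" %in%
    find_alternatives(food_record(cat2, "kix"), cat2, near, margin = 0.1)$food_id)
  # the category minimum has no alternatives
  expect_identical(
    nrow(find_alternatives(food_record(cat, "shredded"), cat, sub_scores)), 0L)
  rec <- food_record(cat, "kix"); rec$wweia_category <- NA_character_
  expect_error(find_alternatives(rec, cat, sub_scores),
               class = "foodprox_validation_error")
})

test_that("prioritization maximizes calorie-share times score drop", {
  cat <- sub_catalog()
  # item A: half the calories, achievable drop 0.4 -> gain 0.20
  # item B: 20% of calories, drop 0.8 -> gain 0.16
  scores <- c(a = 0.9, a_alt = 0.5, b = 0.9, b_alt = 0.1, filler = 0.5)
  nut <- matrix(1, 5, 6)
  meta <- data.frame(food_id = c("a", "a_alt", "b", "b_alt", "filler"),
                     kcal_per_100g = c(100, 100, 100, 100, 100),
                     wweia_category = c("ca", "ca", "cb", "cb", "cc"))
  cat2 <- food_catalog(nut, meta, mini_panel())
  diet <- data.frame(food_id = c("a", "b", "filler"),
                     grams = c(500, 200, 300),
                     kcal = c(500, 200, 300))
  sel <- prioritize(diet, cat2, scores, substitution_policy())
  expect_identical(diet$food_id[sel$item_row], "a")
  expect_equal(sel$gain, 0.5 * 0.4)
  # only one item has any alternative -> that item is chosen
  diet2 <- data.frame(food_id = c("b", "filler"), grams = c(10, 10),
                      kcal = c(100, 900))
  sel2 <- prioritize(diet2, cat2, scores, substitution_policy())
  expect_identical(diet2$food_id[sel2$item_row], "b")
})

test_that("substitution plans are monotone, isocaloric and capped", {
  cat <- sub_catalog()
  diet <- data.frame(food_id = c("kix", "spraycheese", "candy"),
                     grams = c(100, 50, 40),
                     kcal = c(380, 145, 200))
  plan <- substitute_diet(diet, cat, sub_scores, k_steps = 10)
  expect_lte(nrow(plan$steps), 3)
  expect_true(all(diff(c(plan$initial_score, plan$steps$score_after)) <= 1e-12))
  expect_equal(sum(plan$items$kcal), sum(diet$kcal))
  # isocaloric grams: replacement grams = kcal / density * 100
  s1 <- plan$steps[1, ]
  dens <- cat$meta$kcal_per_100g[match(s1$replacement, cat$meta$food_id)]
  orig_kcal <- diet$kcal[match(s1$replaced, diet$food_id)]
  expect_equal(s1$grams_new, orig_kcal / dens * 100, tolerance = 1e-9)
  # k_steps = 0 -> empty plan
  p0 <- substitute_diet(diet, cat, sub_scores, k_steps = 0)
  expect_identical(nrow(p0$steps), 0L)
  expect_equal(p0$final_score, p0$initial_score)
  # single-food diet collapses to the alternative's score
  p1 <- substitute_diet(data.frame(food_id = "kix", grams = 100, kcal = 380),
                        cat, sub_scores, k_steps = 1)
  expect_equal(p1$final_score, sub_scores[["shredded"]])
  # a wide margin forbids every substitution
  pwide <- substitute_diet(diet, cat, sub_scores,
                           policy = substitution_policy(margin = 0.99))
  expect_identical(nrow(pwide$steps), 0L)
})

test_that("each item is replaced at most once", {
  cat <- sub_catalog()
  diet <- data.frame(food_id = c("kix", "spraycheese"),
                     grams = c(100, 50), kcal = c(380, 145))
  plan <- substitute_diet(diet, cat, sub_scores, k_steps = 10)
  expect_lte(nrow(plan$steps), 2)
  expect_false(any(duplicated(plan$steps$replaced)))
})

test_that("outcome projection follows the association's family and scale", {
  assoc_log <- list(family = "logistic", beta = -0.2)
  # no score change, or a null coefficient -> 0%
  expect_equal(project_outcome_change(0.7, 0.7, assoc_log), 0)
  expect_equal(project_outcome_change(0.7, 0.5,
                                      list(family = "logistic", beta = 0)), 0)
  # identity transform: dz = -1 with beta = -0.2 raises odds by e^0.2 - 1
  expect_equal(project_outcome_change(1, 0, assoc_log),
               (exp(0.2) - 1) * 100, tolerance = 1e-12)
  # linear family needs the outcome moments
  assoc_lin <- list(family = "linear", beta = 0.5)
  expect_error(project_outcome_change(1, 0, assoc_lin),
               class = "foodprox_validation_error")
  expect_equal(project_outcome_change(1, 0, assoc_lin,
                                      outcome_sd = 2, outcome_mean = 10),
               0.5 * -1 * 2 / 10 * 100)
  # with a Box-Cox transform spec, dz uses the transformed scale
  tr <- boxcox_transform(runif(200, 0.2, 0.9), lambda = 1)
  got <- project_outcome_change(0.7, 0.6, assoc_log, transform = tr)
  dz <- ((0.6 - 1) - (0.7 - 1)) / tr$sd
  expect_equal(got, (exp(-0.2 * dz) - 1) * 100)
})

test_that("percent change is signed and anchored at the old value", {
  expect_equal(percent_change(0.7872, 0.6915), -12.157, tolerance = 1e-3)
  expect_equal(percent_change(2, 3), 50)
})
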