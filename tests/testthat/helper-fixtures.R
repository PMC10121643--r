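# Shared fixtures, built in code. The synthetic catalog/model pair is
# memoized so expensive training happens once per test run.

mini_panel <- function() {
  nutrient_panel("mini6",
                 c("protein", "carbohydrate", "total_fat",
                   "fiber", "sodium", "vitc"),
                 c("g", "g", "g", "g", "mg", "mg"))
}

# small hand-built catalog; rows are (protein, carb, fat, fiber, sodium, vitc)
mini_catalog <- function() {
  nut <- rbind(
    apple   = c(0.3, 14, 0.2, 2.4, 1, 4.6),
    bread   = c(9, 49, 3.2, 2.7, 490, 0.2),
    soda    = c(0, 10.6, 0, 0, 4, 0),
    cheese  = c(25, 1.3, 33, 0, 620, 0),
    oil     = c(0, 0, 100, 0, 2, 0),
    cereal  = c(7, 84, 2.7, 7, 500, 21))
  meta <- data.frame(
    food_id = rownames(nut),
    kcal_per_100g = nut[, 1] * 4 + nut[, 2] * 4 + nut[, 3] * 9,
    wweia_category = c("fruit", "grain", "beverage", "dairy", "fat", "grain"),
    nova_label = c(1, 3, 4, 3, 2, 4))
  food_catalog(nut, meta, mini_panel())
}

.sim_cache <- new.env(parent = emptyenv())

sim_config <- function() generator_config(n_foods = 300, n_individuals = 60,
                                          seed = 42L)

sim_catalog <- function() {
  if (is.null(.sim_cache$catalog))
    .sim_cache$catalog <- generate_catalog(sim_config())
  .sim_cache$catalog
}

sim_model <- function() {
  if (is.null(.sim_cache$model))
    .sim_cache$model <- train_ensemble(sim_catalog(),
                                       classifier_config(n_trees = 150,
                                                         seed = 42L))
  .sim_cache$model
}

sim_scores <- function() {
  if (is.null(.sim_cache$scores)) {
    sc <- score_food(sim_model(), sim_catalog())
    .sim_cache$scores <- stats::setNames(sc$fpro_mean, sc$food_id)
  }
  .sim_cache$scores
}

sim_recalls <- function() {
  if (is.null(.sim_cache$recalls))
    .sim_cache$recalls <- generate_population(sim_config(), sim_catalog())
  .sim_cache$recalls
}

# uniform draw from the 4-simplex (normalized exponentials)
random_simplex <- function(n) {
  e <- matrix(stats::rexp(4 * n), n, 4)
  e / rowSums(e)
}
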