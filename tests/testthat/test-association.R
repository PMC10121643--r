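test_that("Box-Cox transform matches its closed forms and shifts safely", {
  x <- c(0.5, 1, 2, 4)
  expect_equal(boxcox_transform(x, lambda = 1)$values, x - 1)
  expect_equal(boxcox_transform(exp(1), lambda = 0)$values, 1)
  # automatic shift makes the minimum slightly positive and is recorded
  tr <- boxcox_transform(c(-2, 0, 3), lambda = 1)
  expect_equal(tr$shift, 2 + 1e-6)
  expect_error(boxcox_transform(c(-1, 1), lambda = 1, shift = 0),
               class = "foodprox_validation_error")
})

test_that("profile-likelihood lambda agrees with the MASS oracle", {
  skip_if_not_installed("MASS")
  set.seed(21)
  x <- rlnorm(10000, 1, 0.6)          # log-normal: true lambda 0
  lam <- estimate_boxcox_lambda(x)
  expect_lt(abs(lam), 0.1)
  prof <- MASS::boxcox(x ~ 1, lambda = seq(-0.5, 0.5, 0.005), plotit = FALSE)
  lam_ref <- prof$x[which.max(prof$y)]
  expect_lt(abs(lam - lam_ref), 0.01)   # MASS profiles on a 0.005 grid
  # a squared-normal sample prefers lambda near 1/2
  y <- rnorm(10000, 8, 1)^2
  expect_lt(abs(estimate_boxcox_lambda(y) - 0.5), 0.15)
})

test_that("standardization yields exact z-scores and catches degeneracy", {
  set.seed(4)
  x <- rnorm(500, 10, 3)
  z <- standardize(x)
  expect_lt(abs(mean(z$values)), 1e-10)
  expect_equal(sd(z$values), 1, tolerance = 1e-10)
  expect_error(standardize(rep(2, 10)), class = "foodprox_validation_error")
})

test_that("partially standardized logistic beta scales with sd(exposure)", {
  set.seed(5)
  n <- 3000
  x <- rnorm(n, 0, 2.5)
  y <- rbinom(n, 1, plogis(-0.4 + 0.3 * x))
  fit <- fit_association(y, x, family = "logistic")
  raw <- glm(y ~ x, family = binomial())
  expect_equal(fit$beta, unname(coef(raw)["x"]) * sd(x), tolerance = 1e-6)
  expect_identical(fit$standardization, "partial")
})

test_that("weighted fits respect weight invariances", {
  set.seed(6)
  n <- 400
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  f1 <- fit_association(y, x, family = "linear")
  # all weights equal (any constant) reproduces the unweighted fit
  f2 <- fit_association(y, x, weights = rep(3.7, n), family = "linear")
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$se, f2$se, tolerance = 1e-8)
  # duplicating every row at half weight reproduces the point estimate
  f3 <- fit_association(c(y, y), c(x, x), weights = rep(0.5, 2 * n),
                        family = "linear")
  expect_equal(f1$beta, f3$beta, tolerance = 1e-8)
})

test_that("rank-deficient designs are reported, not silently dropped", {
  set.seed(7)
  n <- 100
  x <- rnorm(n); y <- rnorm(n)
  covs <- data.frame(c1 = rnorm(n))
  covs$c2 <- 2 * covs$c1
  expect_error(fit_association(y, x, covariates = covs, family = "linear"),
               "aliased", class = "foodprox_validation_error")
})

test_that("the sample-size filter is boundary inclusive", {
  expect_true(sample_size_filter(350, 7))
  expect_false(sample_size_filter(349, 7))
  expect_false(sample_size_filter(5000, 7, smallest_category = 100))
  expect_true(sample_size_filter(5000, 7, smallest_category = 350))
})

test_that("BH adjustment matches hand arithmetic and is order invariant", {
  adj <- fdr_adjust(c(0.01, 0.02, 0.04))
  expect_equal(adj$p_adjusted, c(0.03, 0.03, 0.04))
  expect_true(all(adj$significant))
  expect_equal(fdr_adjust(rep(1, 5))$p_adjusted, rep(1, 5))
  expect_false(any(fdr_adjust(rep(1, 5))$significant))
  expect_equal(fdr_adjust(0.2)$p_adjusted, 0.2)
  set.seed(8)
  p <- runif(50)
  ord <- sample(50)
  a1 <- fdr_adjust(p)$p_adjusted
  a2 <- fdr_adjust(p[ord])$p_adjusted
  expect_equal(a2, a1[ord])
  expect_true(all(diff(a1[order(p)]) >= -1e-15))
  expect_true(all(a1 >= p))
  expect_error(fdr_adjust(numeric(0)), class = "foodprox_validation_error")
  expect_error(fdr_adjust(c(0.5, 1.2)), class = "foodprox_validation_error")
})

test_that("the scan fits, skips and adjusts outcomes deterministically", {
  set.seed(9)
  n <- 600
  ind <- data.frame(individual_id = sprintf("i%04d", 1:n),
                    ifpro_wc = plogis(rnorm(n, 1, 0.8)),
                    survey_weight = rep(1, n),
                    age = round(runif(n, 18, 80)),
                    bmi = rnorm(n, 27, 4))
  truth <- list(eff = list(family = "linear", beta = 0.4),
                nul = list(family = "linear", beta = 0),
                bin = list(family = "logistic", beta = 0.5),
                rare = list(family = "logistic", beta = 0,
                            intercept = -6))  # tiny minority class
  outc <- generate_outcomes(ind, truth, seed = 10)
  res <- ewas(outc, ind, covariate_cols = c("age", "bmi"))
  expect_identical(res$outcome_id, sort(res$outcome_id))
  expect_identical(res$family[res$outcome_id == "bin"], "logistic")
  expect_identical(res$transform[res$outcome_id == "eff"], "boxcox")
  # the rare binary outcome fails the smallest-category filter -> skipped
  expect_true(res$skipped[res$outcome_id == "rare"])
  expect_true(is.na(res$beta[res$outcome_id == "rare"]))
  # the real effect is detected, the null is not
  expect_true(res$significant[res$outcome_id == "eff"])
  expect_false(res$significant[res$outcome_id == "nul"])
  expect_true(all(res$p_adjusted >= res$p_value, na.rm = TRUE))
  # determinism: identical call, identical table
  expect_identical(res, ewas(outc, ind, covariate_cols = c("age", "bmi")))
  expect_error(ewas(data.frame(individual_id = "zz", y = 1), ind),
               class = "foodprox_validation_error")
})
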