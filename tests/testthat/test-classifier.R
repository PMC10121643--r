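test_that("log preprocessing matches its closed form", {
  cfg <- classifier_config(log_epsilon = 1e-6)
  expect_equal(preprocess(0, cfg), log(1e-6))
  expect_equal(preprocess(exp(1) - 1e-6, cfg), 1)
  expect_equal(preprocess(rep(0, 12), cfg), rep(log(1e-6), 12))
  expect_error(preprocess(-1, cfg), class = "foodprox_validation_error")
})

test_that("ensemble members are trained on stratified complements", {
  cfg <- generator_config(n_foods = 400, class_mix = rep(0.25, 4), seed = 5)
  catalog <- generate_catalog(cfg)
  # class mix is multinomial; rebalance to exactly 100 per class for the
  # fold-arithmetic check
  idx <- unlist(lapply(1:4, function(cl)
    which(catalog$meta$nova_label == cl)[1:75]))
  catalog <- foodprox:::subset_catalog(catalog, idx)
  model <- train_ensemble(catalog, classifier_config(n_trees = 30, seed = 5))
  expect_length(model$members, 5)
  for (m in model$members) expect_equal(m$num.samples, 240)  # 4/5 of 300
  # every member predicts over exactly the 4 NOVA classes
  pr <- predict_proba(model, catalog)
  expect_identical(dim(pr$members), c(300L, 4L, 5L))
})

test_that("degenerate training inputs error clearly", {
  cat <- mini_catalog()
  cat$meta$nova_label <- rep(4L, 6)
  expect_error(train_ensemble(cat, classifier_config(n_trees = 10)),
               "absent", class = "foodprox_validation_error")
  cat2 <- mini_catalog()
  cat2$meta$nova_label <- rep(NA_integer_, 6)
  expect_error(train_ensemble(cat2, classifier_config(n_trees = 10)),
               class = "foodprox_validation_error")
})

test_that("training is reproducible and row-order invariant", {
  catalog <- sim_catalog()
  probe <- foodprox:::subset_catalog(catalog, 1:20)
  cfg <- classifier_config(n_trees = 60, seed = 9)
  m1 <- train_ensemble(catalog, cfg)
  m2 <- train_ensemble(catalog, cfg)
  expect_identical(predict_proba(m1, probe)$mean,
                   predict_proba(m2, probe)$mean)
  # permuting training rows changes nothing: folds key on food_id + seed
  perm <- foodprox:::subset_catalog(catalog, rev(seq_len(n_foods(catalog))))
  m3 <- train_ensemble(perm, cfg)
  expect_identical(predict_proba(m1, probe)$mean,
                   predict_proba(m3, probe)$mean)
})

test_that("mean probabilities live on the simplex and average members", {
  pr <- predict_proba(sim_model(), foodprox:::subset_catalog(sim_catalog(), 1:50))
  expect_true(all(abs(rowSums(pr$mean) - 1) < 1e-9))
  expect_true(all(pr$mean >= 0))
  hand_mean <- apply(pr$members, c(1, 2), mean)
  hand_mean <- hand_mean / rowSums(hand_mean)
  expect_equal(unname(pr$mean), unname(hand_mean))
})

test_that("classification takes the argmax with ties toward higher NOVA", {
  # synthetic probs via a stub model is overkill: exercise the rule directly
  p <- rbind(c(0.9651, 0.02, 0.01, 0.0049),
             c(0.25, 0.25, 0.25, 0.25),
             c(0.0039, 0.002, 0.002, 0.9921))
  lab <- apply(p, 1, function(r) max(which(r == max(r))))
  expect_identical(as.integer(lab), c(1L, 4L, 4L))
  # and end-to-end: classify() agrees with the mean-probability argmax
  catalog <- foodprox:::subset_catalog(sim_catalog(), 1:30)
  pr <- predict_proba(sim_model(), catalog)
  expect_identical(unname(classify(sim_model(), catalog, probs = pr)),
                   unname(apply(pr$mean, 1, function(r) max(which(r == max(r))))))
})

test_that("rank-statistic AUC equals the pairwise-comparison oracle", {
  pair_auc <- function(s, pos) {   # brute force over all (pos, neg) pairs
    sp <- s[pos]; sn <- s[!pos]
    cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(31)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    s <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    expect_equal(auc_rank(s, pos), pair_auc(s, pos))
  }
})

test_that("rank-statistic AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  s <- runif(300); pos <- runif(300) < 0.3
  ref <- as.numeric(pROC::auc(pROC::roc(pos, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_rank(s, pos), ref, tolerance = 1e-10)
})

test_that("SMOTE balances member class counts; off leaves raw counts", {
  set.seed(12)
  x <- matrix(rnorm(60 * 3), 60)
  y <- rep(c(1, 3, 4), times = c(40, 12, 8))
  bal <- smote_balance(x, y, k = 5)
  expect_identical(as.vector(table(bal$y)), rep(40L, 3))
  # synthetic points interpolate within the class hull per coordinate
  new_pts <- bal$x[-(1:60), , drop = FALSE]
  cls4 <- utils::tail(bal$y, nrow(new_pts)) == 4
  rng <- apply(x[y == 4, ], 2, range)
  expect_true(all(t(new_pts[cls4, ]) >= rng[1, ] - 1e-12))
  expect_true(all(t(new_pts[cls4, ]) <= rng[2, ] + 1e-12))
  # SMOTE inside training: per-member counts equal after resampling
  cat <- sim_catalog()
  cfg_on <- classifier_config(n_trees = 20, use_smote = TRUE, seed = 3)
  model <- train_ensemble(cat, cfg_on)
  counts <- table(labeled_subset(cat)$meta$nova_label)
  per_member <- ceiling(max(counts) * 4 / 5)
  for (m in model$members)
    expect_gte(m$num.samples, 4 * (per_member - 1))
})

test_that("cross-validation separates separable classes and not shuffled ones", {
  cv <- cross_validate(sim_catalog(), classifier_config(n_trees = 100, seed = 4))
  expect_identical(cv$class, 1:4)
  expect_true(all(cv$auc_mean > 0.9))
  expect_true(all(cv$aup_mean > 0.7))
  folds <- attr(cv, "folds")
  expect_true(all(folds$auc >= 0 & folds$auc <= 1))
})
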