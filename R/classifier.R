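#' Classifier configuration
#'
#' Settings for the NOVA ensemble classifier: an ensemble of `n_members`
#' probability random forests, each trained on all but one of `n_members`
#' stratified folds of the labeled data, predicting the four NOVA classes
#' from log-transformed nutrient amounts per 100 g.
#'
#' Defaults: 500 trees per member and unlimited depth favour stable class
#' probabilities over speed; `log_epsilon` is the pseudo-amount added before
#' the log (zeros are ubiquitous in nutrient tables); SMOTE oversampling of
#' minority classes is off by default and available behind `use_smote`.
#'
#' @param n_members Number of ensemble members (default 5).
#' @param n_trees Trees per member (default 500).
#' @param max_depth Optional depth bound (`NULL` = unlimited).
#' @param use_smote Oversample minority classes of each member's training
#'   part to the majority count by k-NN interpolation before fitting.
#' @param smote_k Neighbour count for SMOTE (default 5).
#' @param log_epsilon Positive pseudo-amount for the log transform
#'   (default `1e-6`, gram scale).
#' @param seed Integer seed; with identical input, training is reproducible.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(n_members = 5, n_trees = 500, max_depth = NULL,
                              use_smote = FALSE, smote_k = 5,
                              log_epsilon = 1e-6, seed = 1L) {
  stopifnot(is_count(n_members, min = 2), is_count(n_trees, min = 1),
            is.null(max_depth) || is_count(max_depth, min = 1),
            isTRUE(use_smote) || isFALSE(use_smote),
            is_count(smote_k, min = 1),
            is.numeric(log_epsilon), log_epsilon > 0,
            is_count(abs(seed)))
  structure(list(n_members = as.integer(n_members),
                 n_trees = as.integer(n_trees),
                 max_depth = if (is.null(max_depth)) NULL else as.integer(max_depth),
                 use_smote = use_smote, smote_k = as.integer(smote_k),
                 log_epsilon = log_epsilon, seed = as.integer(seed),
                 class_labels = 1:4),
            class = "classifier_config")
}

#' Log-transform a nutrient vector into classifier features
#'
#' `feature_i = ln(amount_i + log_epsilon)`; extra features (e.g. an
#' additive count) are appended unchanged.
#'
#' @param x Numeric vector or matrix of non-negative amounts per 100 g.
#' @param config A [classifier_config()].
#' @param extra Optional extra-feature vector/matrix appended unchanged.
#' @return Numeric vector/matrix of features.
#' @export
preprocess <- function(x, config, extra = NULL) {
  if (any(x < 0)) stop_foodprox("negative nutrient amount",
                                class = "foodprox_validation_error")
  out <- log(x + config$log_epsilon)
  if (!is.null(extra)) out <- cbind(out, extra)
  out
}

catalog_features <- function(catalog, config) {
  x <- preprocess(catalog$nutrients, config, extra = catalog$extra)
  colnames(x) <- c(panel_ids(catalog$panel),
                   if (!is.null(catalog$extra)) colnames(catalog$extra))
  x
}

# Deterministic stratified fold assignment: foods are ordered within each
# class by a hash of (food_id, seed) and dealt round-robin into k folds.
# Row order of the input therefore never changes fold membership.
stratified_folds <- function(food_ids, labels, k, seed) {
  fold <- integer(length(food_ids))
  h <- string_hash(paste0(food_ids, "#", seed))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    ord <- idx[order(h[idx], food_ids[idx])]
    fold[ord] <- rep_len(seq_len(k), length(ord))
  }
  fold
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Balances class counts by generating synthetic minority-class points:
#' each synthetic point interpolates a random minority sample towards one of
#' its `k` nearest same-class neighbours (Euclidean, in feature space) with
#' a uniform interpolation weight.
#'
#' @param x Numeric feature matrix.
#' @param y Class labels (vector, length `nrow(x)`).
#' @param k Neighbour count.
#' @return List with balanced `x` and `y` (original rows first).
#' @export
smote_balance <- function(x, y, k = 5) {
  x <- as.matrix(x)
  counts <- table(y)
  target <- max(counts)
  new_x <- list(); new_y <- list()
  for (cl in names(counts)) {
    need <- target - counts[[cl]]
    if (need == 0) next
    rows <- which(y == cl)
    xc <- x[rows, , drop = FALSE]
    if (nrow(xc) == 1) {            # lone point: replicate it
      new_x[[cl]] <- xc[rep(1, need), , drop = FALSE]
      new_y[[cl]] <- rep(cl, need)
      next
    }
    kk <- min(k, nrow(xc) - 1)
    d <- as.matrix(stats::dist(xc))
    diag(d) <- Inf
    nn <- apply(d, 1, function(r) order(r)[seq_len(kk)])
    nn <- matrix(nn, ncol = nrow(xc))  # kk x n
    base <- sample.int(nrow(xc), need, replace = TRUE)
    pick <- nn[cbind(sample.int(kk, need, replace = TRUE), base)]
    u <- stats::runif(need)
    new_x[[cl]] <- xc[base, , drop = FALSE] +
      u * (xc[pick, , drop = FALSE] - xc[base, , drop = FALSE])
    new_y[[cl]] <- rep(cl, need)
  }
  if (length(new_x) == 0) return(list(x = x, y = y))
  list(x = rbind(x, do.call(rbind, new_x)),
       y = c(y, unlist(new_y, use.names = FALSE)))
}

#' Train the NOVA ensemble classifier
#'
#' Splits the labeled subset of `catalog` into `n_members` stratified folds
#' (fold membership keyed to a hash of food id and seed) and trains one
#' probability random forest per member on the other `n_members - 1` folds.
#' With `use_smote`, each member's training part is first balanced by
#' [smote_balance()]. Per-member seeds are derived from `config$seed` so
#' retraining on identical input is bit-for-bit reproducible.
#'
#' @param catalog A [food_catalog()] whose labeled subset covers all four
#'   NOVA classes, each at least `n_members` times.
#' @param config A [classifier_config()].
#' @return A `foodprox_model` with fields `config`, `panel`, `members`,
#'   `feature_names`, `fold`, `training_fingerprint`.
#' @export
train_ensemble <- function(catalog, config = classifier_config()) {
  lab <- labeled_subset(catalog)
  if (n_foods(lab) == 0)
    stop_foodprox("no NOVA-labeled foods to train on",
                  class = "foodprox_validation_error")
  if (n_foods(lab) < config$n_members)
    stop_foodprox("fewer labeled foods than ensemble members",
                  class = "foodprox_validation_error")
  y <- lab$meta$nova_label
  missing_cl <- setdiff(config$class_labels, unique(y))
  if (length(missing_cl) > 0)
    stop_foodprox("NOVA class ", paste(missing_cl, collapse = ", "),
                  " absent from training labels",
                  class = "foodprox_validation_error")
  if (any(table(y) < config$n_members))
    stop_foodprox("every class must appear at least n_members times",
                  class = "foodprox_validation_error")
  x <- catalog_features(lab, config)
  fold <- stratified_folds(lab$meta$food_id, y, config$n_members, config$seed)
  # reorder to hash order so ranger sees a row order independent of input order
  ord <- order(string_hash(paste0(lab$meta$food_id, "#", config$seed)),
               lab$meta$food_id)
  x <- x[ord, , drop = FALSE]; y <- y[ord]; fold <- fold[ord]
  members <- vector("list", config$n_members)
  for (m in seq_len(config$n_members)) {
    tr <- fold != m
    xm <- x[tr, , drop = FALSE]; ym <- y[tr]
    if (config$use_smote) {
      bal <- with_seed_(config$seed * 1000L + m, smote_balance(xm, ym, config$smote_k))
      xm <- bal$x; ym <- bal$y
    }
    df <- as.data.frame(xm)
    df$.nova <- factor(ym, levels = config$class_labels)
    members[[m]] <- ranger::ranger(
      dependent.variable.name = ".nova", data = df,
      num.trees = config$n_trees,
      max.depth = if (is.null(config$max_depth)) 0 else config$max_depth,
      probability = TRUE, seed = config$seed + m, num.threads = 1,
      verbose = FALSE)
  }
  fingerprint <- sum(string_hash(apply(
    cbind(lab$meta$food_id, y, round(x, 10)), 1, paste, collapse = ",")))
  structure(list(config = config, panel = catalog$panel, members = members,
                 feature_names = colnames(x), fold = fold,
                 training_fingerprint = fingerprint),
            class = "foodprox_model")
}

#' @export
print.foodprox_model <- function(x, ...) {
  cat(sprintf("<foodprox_model: %d members x %d trees, panel '%s', %d features>\n",
              x$config$n_members, x$config$n_trees, x$panel$name,
              length(x$feature_names)))
  invisible(x)
}

#' Predict NOVA class probabilities
#'
#' Each ensemble member outputs a probability vector over the four NOVA
#' classes; the ensemble prediction is the arithmetic mean across members,
#' renormalized to sum exactly to 1.
#'
#' @param model A trained `foodprox_model`.
#' @param catalog A [food_catalog()] on the model's panel.
#' @return List with `mean` (foods x 4 matrix, columns `p1..p4`) and
#'   `members` (array foods x 4 x members).
#' @export
predict_proba <- function(model, catalog) {
  if (!same_panel(model$panel, catalog$panel))
    stop_foodprox("catalog panel does not match model panel",
                  class = "foodprox_validation_error")
  x <- catalog_features(catalog, model$config)
  if (!identical(colnames(x), model$feature_names))
    stop_foodprox("feature columns do not match the trained model",
                  class = "foodprox_validation_error")
  df <- as.data.frame(x)
  mem <- vapply(model$members, function(m) {
    p <- stats::predict(m, data = df, num.threads = 1, verbose = FALSE)$predictions
    p[, as.character(model$config$class_labels), drop = FALSE]
  }, matrix(0, nrow(x), 4))
  if (is.null(dim(mem))) dim(mem) <- c(1, 4, length(model$members))
  mean_p <- apply(mem, c(1, 2), mean)
  mean_p <- mean_p / rowSums(mean_p)
  dimnames(mean_p) <- list(catalog$meta$food_id, paste0("p", 1:4))
  dimnames(mem) <- list(catalog$meta$food_id, paste0("p", 1:4), NULL)
  list(mean = mean_p, members = mem)
}

#' Assign NOVA labels
#'
#' Argmax of the ensemble-mean probability vector. Ties are broken toward
#' the higher NOVA class, i.e. conservatively toward "more processed".
#'
#' @inheritParams predict_proba
#' @param probs Optional precomputed result of [predict_proba()].
#' @return Integer vector of NOVA labels (named by food_id).
#' @export
classify <- function(model, catalog, probs = NULL) {
  p <- (probs %||% predict_proba(model, catalog))$mean
  lab <- apply(p, 1, function(r) max(which(r == max(r))))
  stats::setNames(as.integer(lab), rownames(p))
}

#' One-vs-rest AUC by the rank statistic
#'
#' The probability that a random member of the positive class scores higher
#' than a random member of the rest, computed from mid-ranks (ties count
#' one half).
#'
#' @param scores Numeric scores.
#' @param positive Logical vector: class membership.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0)
    stop_foodprox("AUC needs both classes present",
                  class = "foodprox_validation_error")
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average-precision form: sum over positives, in decreasing score order,
#' of precision at each recall step.
#'
#' @inheritParams auc_rank
#' @return AUP in `(0, 1]`.
#' @export
aup <- function(scores, positive) {
  positive <- as.logical(positive)
  if (!any(positive))
    stop_foodprox("AUP needs at least one positive",
                  class = "foodprox_validation_error")
  ord <- order(scores, decreasing = TRUE)
  pos <- positive[ord]
  prec <- cumsum(pos) / seq_along(pos)
  sum(prec[pos]) / sum(pos)
}

#' Stratified cross-validation of the ensemble
#'
#' Splits the labeled subset into `n_folds` stratified folds; for each fold,
#' trains the full ensemble on the remainder and evaluates one-vs-rest AUC
#' (rank statistic) and AUP per NOVA class on the held-out fold.
#'
#' @param catalog A labeled [food_catalog()].
#' @param config A [classifier_config()].
#' @param n_folds Number of CV folds (default 5).
#' @return data.frame with one row per class: `class`, `auc_mean`, `auc_sd`,
#'   `aup_mean`, `aup_sd`; per-fold values in `attr(, "folds")`.
#' @export
cross_validate <- function(catalog, config = classifier_config(), n_folds = 5) {
  lab <- labeled_subset(catalog)
  y <- lab$meta$nova_label
  if (length(unique(y)) < 2)
    stop_foodprox("cross-validation needs at least two classes",
                  class = "foodprox_validation_error")
  fold <- stratified_folds(lab$meta$food_id, y, n_folds,
                           seed = config$seed + 7919L)
  per_fold <- list()
  for (f in seq_len(n_folds)) {
    tr <- subset_catalog(lab, which(fold != f))
    te <- subset_catalog(lab, which(fold == f))
    model <- train_ensemble(tr, config)
    p <- predict_proba(model, te)$mean
    yte <- te$meta$nova_label
    for (cl in config$class_labels) {
      if (!any(yte == cl)) next
      per_fold[[length(per_fold) + 1L]] <- data.frame(
        class = cl, fold = f,
        auc = auc_rank(p[, cl], yte == cl),
        aup = aup(p[, cl], yte == cl))
    }
  }
  folds <- do.call(rbind, per_fold)
  agg <- do.call(rbind, lapply(split(folds, folds$class), function(d)
    data.frame(class = d$class[1],
               auc_mean = mean(d$auc), auc_sd = stats::sd(d$auc),
               aup_mean = mean(d$aup), aup_sd = stats::sd(d$aup))))
  rownames(agg) <- NULL
  attr(agg, "folds") <- folds
  agg
}
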