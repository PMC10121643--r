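#' Food processing score from a probability vector
#'
#' `FPro = (1 - p1 + p4) / 2`: the orthogonal projection of the NOVA class
#' probability vector onto the line joining the pure minimally processed
#' vertex (1,0,0,0) and the pure ultra-processed vertex (0,0,0,1) of the
#' probability simplex. 0 for raw ingredients, 1 at the ultra-processed
#' vertex; p2 and p3 enter only through the simplex constraint.
#'
#' @param p Numeric vector of length 4, or a matrix with 4 columns
#'   (rows = foods), on the probability simplex.
#' @param tol Tolerance for the simplex check (default `1e-6`).
#' @return Numeric score(s) in `[0, 1]`.
#' @examples
#' fpro_from_probs(c(1, 0, 0, 0))   # 0
#' fpro_from_probs(c(0, 0, 0, 1))   # 1
#' @export
fpro_from_probs <- function(p, tol = 1e-6) {
  p <- check_simplex(p, tol)
  unname((1 - p[, 1] + p[, 4]) / 2)
}

check_simplex <- function(p, tol = 1e-6) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (ncol(p) != 4)
    stop_foodprox("probability vectors must have 4 components",
                  class = "foodprox_validation_error")
  if (any(p < -tol) || any(abs(rowSums(p) - 1) > tol))
    stop_foodprox("input is off the probability simplex beyond tolerance",
                  class = "foodprox_validation_error")
  p
}

#' Least-squares projection oracle for the processing score
#'
#' Computes, by explicit least squares, the parameter t minimizing
#' `|| p - ((1-t) v1 + t v4) ||` where v1 = (1,0,0,0) and v4 = (0,0,0,1):
#' `t = <p - v1, v4 - v1> / ||v4 - v1||^2`. Algebraically identical to
#' [fpro_from_probs()]; kept as an independent check of the closed form.
#'
#' @inheritParams fpro_from_probs
#' @return Numeric projection parameter(s).
#' @export
projection_oracle <- function(p, tol = 1e-6) {
  p <- check_simplex(p, tol)
  v1 <- c(1, 0, 0, 0); v4 <- c(0, 0, 0, 1)
  d <- v4 - v1
  unname(as.numeric((p - matrix(v1, nrow(p), 4, byrow = TRUE)) %*% d) / sum(d * d))
}

#' Score foods with a trained ensemble
#'
#' For each food, each ensemble member's probability vector is converted to
#' a processing score; the reported `fpro_mean` and `fpro_sd` are the mean
#' and (n-1) standard deviation across members, so the spread reflects
#' ensemble disagreement. The NOVA label is the argmax of the ensemble-mean
#' probabilities (ties toward the higher class).
#'
#' @param model A trained `foodprox_model`.
#' @param catalog A [food_catalog()] on the model's panel.
#' @return data.frame with columns `food_id`, `fpro_mean`, `fpro_sd`,
#'   `p1..p4`, `label`.
#' @export
score_food <- function(model, catalog) {
  pr <- predict_proba(model, catalog)
  member_scores <- apply(pr$members, c(1, 3), function(p) (1 - p[1] + p[4]) / 2)
  if (is.null(dim(member_scores)))
    member_scores <- matrix(member_scores, nrow = 1)
  out <- data.frame(food_id = catalog$meta$food_id,
                    fpro_mean = rowMeans(member_scores),
                    fpro_sd = apply(member_scores, 1, stats::sd),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(pr$mean, row.names = FALSE))
  out$label <- unname(classify(model, catalog, probs = pr))
  rownames(out) <- NULL
  out
}

#' PCA coordinates of the classifier decision space
#'
#' Mean-centered principal component analysis of the 4-D probability
#' vectors, returning the first two component scores and explained-variance
#' fractions. Sign convention: within each component, the loading of
#' largest magnitude is made positive, so plots are reproducible. Constant
#' input is flagged rather than an error.
#'
#' @param probs Matrix of probability vectors (rows = foods, 4 columns).
#' @return List with `scores` (n x 2), `loadings` (4 x 2), `var_explained`
#'   (length 2) and `zero_variance` flag.
#' @export
decision_space_pca <- function(probs) {
  probs <- check_simplex(probs)
  if (nrow(probs) < 3)
    stop_foodprox("PCA needs at least 3 probability vectors",
                  class = "foodprox_validation_error")
  if (all(apply(probs, 2, stats::sd) < 1e-12))
    return(list(scores = matrix(0, nrow(probs), 2),
                loadings = matrix(NA_real_, 4, 2),
                var_explained = c(NA_real_, NA_real_), zero_variance = TRUE))
  pc <- stats::prcomp(probs, center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scr <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; scr[, j] <- -scr[, j] }
  }
  if (k < 2) {  # degenerate rank; pad second component with zeros
    load <- cbind(load, 0); scr <- cbind(scr, 0)
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scr[, 1:2, drop = FALSE], loadings = load[, 1:2, drop = FALSE],
       var_explained = c(ve[1], if (length(ve) > 1) ve[2] else 0),
       zero_variance = FALSE)
}

#' Robustness of the processing score to nutrient perturbation
#'
#' Emulates real-world nutrient variability: for each food and repetition a
#' maximal relative change r is drawn uniformly up to `max_relative_change`,
#' each nutrient amount is multiplied by `(1 + u)` with
#' `u ~ Uniform(-r, +r)` (factors floored at 0 when r exceeds 100%), and the
#' food is rescored. Reports the per-food distribution of the absolute
#' score shift `|FPro(perturbed) - FPro(original)|`.
#'
#' @param model A trained `foodprox_model`.
#' @param catalog A [food_catalog()] on the model's panel.
#' @param max_relative_change Upper bound of the relative perturbation band
#'   (e.g. 0.5 = up to +/-50%).
#' @param n_reps Repetitions per food (default 100).
#' @param seed Integer seed.
#' @return data.frame with one row per food (`food_id`, `median`, `q1`,
#'   `q3` of the absolute shift); pooled quartiles in `attr(, "overall")`.
#' @export
stability_analysis <- function(model, catalog, max_relative_change = 0.5,
                               n_reps = 100, seed = 1L) {
  stopifnot(max_relative_change >= 0)
  if (!is_count(n_reps, min = 1))
    stop_foodprox("n_reps must be a positive count",
                  class = "foodprox_validation_error")
  base <- score_food(model, catalog)$fpro_mean
  nf <- n_foods(catalog)
  shifts <- matrix(NA_real_, nf, n_reps)
  with_seed_(seed, {
    for (rep in seq_len(n_reps)) {
      r <- stats::runif(nf, 0, max_relative_change)
      u <- matrix(stats::runif(nf * ncol(catalog$nutrients), -1, 1),
                  nf) * r
      fac <- pmax(1 + u, 0)
      pert <- catalog
      pert$nutrients <- catalog$nutrients * fac
      shifts[, rep] <- abs(score_food(model, pert)$fpro_mean - base)
    }
  })
  qs <- t(apply(shifts, 1, stats::quantile, probs = c(0.25, 0.5, 0.75),
                type = 7))
  out <- data.frame(food_id = catalog$meta$food_id,
                    median = qs[, 2], q1 = qs[, 1], q3 = qs[, 3],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "overall") <- stats::quantile(shifts, probs = c(0.25, 0.5, 0.75),
                                          type = 7)
  out
}
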