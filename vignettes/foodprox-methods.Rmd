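---
title: "Methods: classifying food processing and scoring diets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying food processing and scoring diets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

NOVA assigns foods to four discrete processing classes — unprocessed or
minimally processed (1), processed culinary ingredients (2), processed (3)
and ultra-processed (4) — by expert inspection of ingredients. That manual
labeling covers only part of any food supply, treats the large
ultra-processed class as homogeneous, and cannot grade the *degree* of
processing. The premise this package builds on is that processing leaves a
combinatorial but reproducible fingerprint in the nutrient profile per
100 g: raw foods sit within physiologic concentration ranges, and physical,
chemical and biological processing shifts many nutrients at once. A
classifier trained on the labeled part of a composition database can
therefore extend the classification to every food with a nutrient panel,
and its class *confidences* carry more information than the hard label.

# The classifier and the processing score

`train_ensemble()` fits an ensemble of `n_members` (default 5) probability
random forests on features `ln(amount + epsilon)` per nutrient. The labeled
foods are split into `n_members` stratified folds and member *m* is trained
on all folds except fold *m*, so members see overlapping but distinct
4/5-subsets of the data. Predictions (`predict_proba()`) average the member
probability vectors and renormalize; the hard label is the argmax, with
ties broken toward the higher NOVA class (conservative toward "more
processed" — the less defensible direction to understate).

For a probability vector $p = (p_1, p_2, p_3, p_4)$ on the 4-simplex the
continuous processing score is

$$\mathrm{FPro} = \frac{1 - p_1 + p_4}{2},$$

the orthogonal projection of $p$ onto the segment from the pure
minimally-processed vertex $(1,0,0,0)$ to the pure ultra-processed vertex
$(0,0,0,1)$. `projection_oracle()` implements the projection as explicit
least squares and is tested to agree with the closed form to $10^{-12}$;
`score_food()` computes the score per ensemble member and reports the mean
and (n−1) standard deviation, so `fpro_sd` measures ensemble disagreement.

Parameters that matter:

* `n_trees` (default 500) and unlimited depth: chosen for stable
  probabilities; halving tree count mostly widens `fpro_sd`.
* `log_epsilon` (default $10^{-6}$, gram scale): the pseudo-amount added
  before the log. Zero amounts are ubiquitous; the floor maps them to a
  finite feature value while keeping microgram-scale amounts ordered.
* `use_smote` (default off): minority-class oversampling by k-NN
  interpolation before fitting each member. Off by default because the
  ensemble's stratified design already controls imbalance on well-populated
  panels; the flag exists for heavily skewed labeled sets.
* Fold assignment hashes `food_id` together with the seed, so fold
  membership — and therefore the trained model — is invariant to the row
  order of the input table. This is tested bit-for-bit.

`cross_validate()` reports per-class one-vs-rest AUC by the rank statistic
(the probability that a random in-class food outscores a random
out-of-class food, mid-ranks for ties) and the area under the
precision–recall curve in average-precision form, per stratified fold.

# Diet scores

For one recall day, `ifpro_wc()` is the calorie-share-weighted mean of the
consumed foods' scores and `ifpro_wg()` the gram-share-weighted mean; both
are convex combinations, hence bounded by the constituent food scores. The
gram-weighted variant exists because highly processed zero-calorie items
(diet drinks) are invisible to a calorie weighting. `score_individual()`
averages day-level scores over the available recall days (one or two) —
averaging day scores, not pooling items across days, so a light-intake day
counts as much as a heavy one; the pooled alternative would weight days by
intake. Items without a score fail loudly: silently skipping them would
bias diets toward the scored subset. `population_summary()` uses survey
weights with a documented lower-mass weighted-quantile rule (smallest value
whose cumulative weight reaches the requested fraction).

# Substitution

`substitute_diet()` implements a minimal-change strategy: keep the diet,
swap single items for less processed versions within the same food
category. The prioritization gain for item *k* is
$g_k = (c_k / C)\,(\mathrm{FPro}_k - \mathrm{FPro}_{\text{best}(k)})$ —
calorie share times achievable score drop — which operationalizes "high
caloric contribution" and "significantly less processed alternative"
as a product; the margin (default 0.1) defines "significantly". The
replacement is the admissible alternative of minimum score, grams chosen to
conserve the item's calories exactly (isocaloric). Each slot is replaced at
most once, so plans are monotone non-increasing in the diet score; both
properties are tested. `project_outcome_change()` converts a score change
into a percent change of an associated outcome through the population
Box-Cox transform of the score (standard-deviation units), using
`exp(beta * dz) - 1` on the odds scale for logistic associations and the
fully standardized coefficient rescaled by the outcome's moments for
linear ones.

# Association scan

`ewas()` regresses each outcome on the Box-Cox-transformed, z-scored diet
score with covariate adjustment (age, sex, ethnicity, BMI, SES, total
caloric intake when present) under survey weights. Binary outcomes use
weighted logistic regression with *partially* standardized coefficients
(exposure z-scored, outcome on the odds scale); continuous outcomes are
Box-Cox transformed (or logit-transformed for variables already in (0,1),
e.g. risk scores) and z-scored, giving *fully* standardized coefficients.
Outcomes failing the 1-in-50 rule — more than one covariate per 50
observations, or per 50 members of the smallest category — are reported as
skipped, not fitted. P values use two-sided t (linear) and Wald (logistic)
tests; Benjamini–Hochberg adjustment runs across all fitted outcomes at
$\alpha = 0.05$.

One deliberate simplification: variance uses weights-only fits with HC0
sandwich standard errors, not full complex-survey design variance
(strata/PSU information is not modeled). With clustered designs the
reported standard errors are optimistic; treat borderline discoveries
accordingly.

Numerical choices: the Box-Cox exponent is estimated by profile likelihood
on $[-3, 3]$; non-positive variables are shifted by $-\min(x) + 10^{-6}$
and the shift is recorded; the logit transform clamps to
$(10^{-6}, 1 - 10^{-6})$; rank-deficient designs raise an error naming the
aliased columns rather than silently dropping them.

# The synthetic benchmark

The generator exists so every stage is testable with known ground truth
and no external downloads; it targets statistical structure, not numerical
realism of any real composition database.

* **Catalog** (`generate_catalog()`): each of `n_categories` food
  categories draws a log-normal baseline profile (scaled by declared unit,
  so mg-nutrients are smaller than g-nutrients). A food of NOVA class *c*
  alters a class-dependent fraction of nutrients by log-normal factors
  $\exp(d_i\,\mu_c + \sigma_c \varepsilon)$, where $\sigma_c$ =
  `alteration_scale[c]` grows with class, $\mu_c = 1.5\sigma_c$, and
  $d_i = \pm 1$ is a fixed per-nutrient direction (sugars, fats, sodium up;
  fiber, potassium, micronutrients down) — processing shifts profiles
  systematically, not just noisily. NOVA 2 foods are near-pure
  single-macronutrient profiles (oil/sugar/salt analogues); NOVA 4 foods
  receive fortification spikes with probability 0.3. Energy density is
  Atwater arithmetic (4/4/9 kcal per g protein/carbohydrate/fat), tested
  exactly. Default conditions: 800 foods, 12 categories, class mix
  (0.25, 0.10, 0.30, 0.35), `alteration_scale` (0.05, 0.4, 0.8, 1.4). At
  these defaults the stratified 5-fold one-vs-rest AUC exceeds 0.95 for
  every class and shuffled labels sit at 0.5 within 0.05.
* **Population** (`generate_population()`): a latent processing propensity
  $\pi \sim N(0, 1)$ tilts dish choice by $\exp(\pi(\text{class} - 2.5))$;
  two recall days, Poisson dish counts (mean 12), log-normal portions, and
  log-normal survey weights normalized to mean 1. Covariates are drawn
  independently of $\pi$, so associations with generated outcomes are
  confound-free by construction.
* **Outcomes** (`generate_outcomes()`): continuous outcomes
  $y = \beta z + \gamma\,\text{cov} + N(0,1)$ on the z-scored diet score;
  binary outcomes through a logistic link with partially standardized
  $\beta$; null outcomes for calibration.

What passing these tests does **not** show about real data: the generator
has clean class structure, no measurement error in nutrient panels, no
correlated covariates or confounding, no complex survey clustering, and no
category/class entanglement beyond sampling noise. Results on real
composition and recall data depend on label quality and panel coverage in
ways the benchmark cannot probe.

One degenerate limit is worth knowing: with `altered_fraction = 0` all
foods of classes 1/3/4 within a category are exact duplicates. Then
cross-validation itself leaks the finite-sample category/class composition
through the duplicates, and measured AUC drifts off 0.5 in either
direction. The no-signal tests therefore assert the substantive property —
predictions constant within a category — and the chance-level AUC control
uses shuffled labels on the default catalog.

# Problem sizes and determinism

The shipped tests run the full pipeline at reduced but non-trivial scale —
a 300-food shared catalog with a 150-tree ensemble for most properties, the
default 800-food catalog with 500 trees for the classifier floor, n = 5000
with 1000 null fits for regression calibration — sizes chosen so the whole
suite exercises every claim in well under an hour on one core while keeping
Monte-Carlo error far from the asserted bounds. Every stochastic function
takes an explicit seed, restores the caller's RNG state, and is tested to
be bit-for-bit reproducible; CLI outputs carry a JSON run manifest (config,
seed, package version, input hashes).

# Known limitations

* No full survey-design variance (above).
* The built-in 58/62/99 nutrient panels are representative manifests, not
  authoritative lists; edit the CSVs under `inst/extdata/panels/` to match
  your source database.
* The substitution search is greedy per step; it does not optimize over
  replacement sets, and uses no palatability, price or adequacy
  constraints.
* `FPro` ranks foods best within a food category; cross-category
  comparisons inherit whatever category structure the training labels
  encode.
* Categorical outcomes beyond binary are not expanded into one-vs-rest
  fits automatically; recode upstream.
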