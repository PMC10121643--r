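#' Food catalogs
#'
#' A food catalog holds one row per food: a nutrient vector per 100 g aligned
#' to a [nutrient_panel()], the energy density, and optional metadata (a
#' WWEIA-style category, a NOVA label in 1--4, free-text description, and
#' extra numeric features such as an additive count).
#'
#' @param nutrients Numeric matrix, foods x panel nutrients, amounts per
#'   100 g in the panel's declared units. Row names are ignored; `meta$food_id`
#'   identifies rows.
#' @param meta data.frame with columns `food_id` and `kcal_per_100g`;
#'   optionally `description`, `wweia_category`, `nova_label`.
#' @param panel The [nutrient_panel()] the columns are aligned to.
#' @param extra Optional numeric matrix of named extra features (same row
#'   count), appended unchanged to the classifier's feature vector.
#' @return An object of class `food_catalog`.
#' @export
food_catalog <- function(nutrients, meta, panel, extra = NULL) {
  stopifnot(inherits(panel, "nutrient_panel"))
  nutrients <- as.matrix(nutrients)
  if (ncol(nutrients) != panel$size)
    stop_foodprox("nutrient matrix has ", ncol(nutrients),
                  " columns but panel '", panel$name, "' declares ", panel$size,
                  class = "foodprox_validation_error")
  colnames(nutrients) <- panel_ids(panel)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  for (col in c("food_id", "kcal_per_100g"))
    if (!col %in% names(meta))
      stop_foodprox("meta lacks required column '", col, "'",
                    class = "foodprox_schema_error")
  meta$food_id <- as.character(meta$food_id)
  if (nrow(meta) != nrow(nutrients))
    stop_foodprox("meta and nutrient matrix row counts differ",
                  class = "foodprox_validation_error")
  if (anyDuplicated(meta$food_id))
    stop_foodprox("duplicated food_id: ",
                  paste(unique(meta$food_id[duplicated(meta$food_id)]), collapse = ", "),
                  class = "foodprox_validation_error")
  bad <- which(!is.finite(nutrients) | nutrients < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_foodprox("non-finite or negative nutrient amount at row ", bad[1, 1],
                  " ('", meta$food_id[bad[1, 1]], "')",
                  class = "foodprox_validation_error")
  if (any(!is.finite(meta$kcal_per_100g) | meta$kcal_per_100g < 0))
    stop_foodprox("kcal_per_100g must be finite and non-negative",
                  class = "foodprox_validation_error")
  if (!"description" %in% names(meta)) meta$description <- meta$food_id
  if (!"wweia_category" %in% names(meta)) meta$wweia_category <- NA_character_
  if (!"nova_label" %in% names(meta)) meta$nova_label <- NA_integer_
  lab <- meta$nova_label
  bad_lab <- which(!is.na(lab) & !(lab %in% 1:4))
  if (length(bad_lab) > 0)
    stop_foodprox("nova_label out of {1,2,3,4} at row ", bad_lab[1],
                  " ('", meta$food_id[bad_lab[1]], "')",
                  class = "foodprox_validation_error")
  meta$nova_label <- as.integer(lab)
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    stopifnot(nrow(extra) == nrow(nutrients), !is.null(colnames(extra)))
    if (any(!is.finite(extra) | extra < 0))
      stop_foodprox("extra features must be finite and non-negative",
                    class = "foodprox_validation_error")
  }
  rownames(nutrients) <- meta$food_id
  structure(list(panel = panel, nutrients = nutrients, meta = meta,
                 extra = extra),
            class = "food_catalog")
}

#' @export
print.food_catalog <- function(x, ...) {
  nlab <- sum(!is.na(x$meta$nova_label))
  cat(sprintf("<food_catalog: %d foods, panel '%s' (%d nutrients), %d NOVA-labeled>\n",
              nrow(x$meta), x$panel$name, x$panel$size, nlab))
  invisible(x)
}

#' Number of foods in a catalog
#' @param catalog A [food_catalog()].
#' @return Integer count.
#' @export
n_foods <- function(catalog) nrow(catalog$meta)

#' Subset of a catalog carrying NOVA labels
#' @param catalog A [food_catalog()].
#' @return A `food_catalog` restricted to labeled foods.
#' @export
labeled_subset <- function(catalog) {
  keep <- which(!is.na(catalog$meta$nova_label))
  subset_catalog(catalog, keep)
}

subset_catalog <- function(catalog, idx) {
  structure(list(panel = catalog$panel,
                 nutrients = catalog$nutrients[idx, , drop = FALSE],
                 meta = catalog$meta[idx, , drop = FALSE],
                 extra = if (is.null(catalog$extra)) NULL
                         else catalog$extra[idx, , drop = FALSE]),
            class = "food_catalog")
}

#' Extract one food from a catalog
#' @param catalog A [food_catalog()].
#' @param food_id Identifier of the food.
#' @return A list with fields `food_id`, `description`, `nutrients` (named
#'   vector), `kcal_per_100g`, `wweia_category`, `nova_label`, `panel`.
#' @export
food_record <- function(catalog, food_id) {
  i <- match(food_id, catalog$meta$food_id)
  if (is.na(i))
    stop_foodprox("unknown food_id '", food_id, "'",
                  class = "foodprox_validation_error")
  list(food_id = food_id,
       description = catalog$meta$description[i],
       nutrients = catalog$nutrients[i, ],
       kcal_per_100g = catalog$meta$kcal_per_100g[i],
       wweia_category = catalog$meta$wweia_category[i],
       nova_label = catalog$meta$nova_label[i],
       panel = catalog$panel)
}

#' Read a food composition table
#'
#' Reads a CSV with one row per food. Nutrient columns are named
#' `<nutrient_id>__<unit>`; when the column's unit suffix differs from the
#' panel's declared unit the amount is converted (`g`/`mg`/`ug` by exact
#' powers of 10^3). Required columns: `food_id`, `kcal_per_100g`, and every
#' panel nutrient. Optional: `description`, `wweia_category`, `nova_label`,
#' `additive_count` (stored as an extra feature).
#'
#' Missing nutrient values are a schema violation by default, mirroring
#' composition databases built for dietary analysis which ship complete;
#' `allow_missing = "zero_fill"` supports sparser branded-food tables.
#'
#' @param path CSV file path.
#' @param panel A [nutrient_panel()].
#' @param allow_missing `"reject"` (default) or `"zero_fill"`.
#' @return A [food_catalog()].
#' @export
read_food_table <- function(path, panel, allow_missing = c("reject", "zero_fill")) {
  allow_missing <- match.arg(allow_missing)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("food_id", "kcal_per_100g"))
    if (!col %in% names(tab))
      stop_foodprox("missing required column '", col, "'",
                    class = "foodprox_schema_error")
  ids <- panel_ids(panel)
  units <- panel$nutrients$unit
  nut <- matrix(NA_real_, nrow(tab), length(ids), dimnames = list(NULL, ids))
  nut_cols <- grep("__", names(tab), value = TRUE, fixed = TRUE)
  col_id <- sub("__[^_]+$", "", nut_cols)
  col_unit <- sub("^.*__", "", nut_cols)
  for (j in seq_along(ids)) {
    hit <- which(col_id == ids[j])
    if (length(hit) == 0) {
      if (allow_missing == "reject")
        stop_foodprox("missing required column '", ids[j], "__", units[j], "'",
                      class = "foodprox_schema_error")
      nut[, j] <- 0
      next
    }
    if (length(hit) > 1)
      stop_foodprox("nutrient '", ids[j], "' appears in more than one column",
                    class = "foodprox_schema_error")
    vals <- as.numeric(tab[[nut_cols[hit]]])
    vals <- vals * unit_factor(col_unit[hit], units[j])
    nut[, j] <- vals
  }
  if (anyNA(nut)) {
    if (allow_missing == "reject") {
      row <- which(rowSums(is.na(nut)) > 0)[1]
      stop_foodprox("missing nutrient value at row ", row,
                    class = "foodprox_validation_error")
    }
    nut[is.na(nut)] <- 0
  }
  meta <- data.frame(food_id = as.character(tab$food_id),
                     kcal_per_100g = as.numeric(tab$kcal_per_100g),
                     stringsAsFactors = FALSE)
  for (col in c("description", "wweia_category", "nova_label"))
    if (col %in% names(tab)) meta[[col]] <- tab[[col]]
  extra <- NULL
  if ("additive_count" %in% names(tab))
    extra <- cbind(additive_count = as.numeric(tab$additive_count))
  food_catalog(nut, meta, panel, extra = extra)
}

#' Write a food composition table
#'
#' Inverse of [read_food_table()]: columns are emitted in the panel's
#' declared units with `<nutrient_id>__<unit>` names, so a read/write cycle
#' reproduces amounts exactly.
#'
#' @param catalog A [food_catalog()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_food_table <- function(catalog, path) {
  out <- catalog$meta[c("food_id", "description", "kcal_per_100g",
                        "wweia_category", "nova_label")]
  nut <- as.data.frame(catalog$nutrients)
  names(nut) <- paste0(panel_ids(catalog$panel), "__", catalog$panel$nutrients$unit)
  out <- cbind(out, nut)
  if (!is.null(catalog$extra)) out <- cbind(out, as.data.frame(catalog$extra))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Nutrient fold changes between two foods
#'
#' Per-nutrient concentration ratios of food `b` relative to food `a`,
#' with a small floor added to both sides so that absent nutrients do not
#' produce divisions by zero. Also reports the fraction of nutrients whose
#' ratio departs from 1 by more than 10%, and the fraction altered by at
#' least an order of magnitude -- the two summaries used to show how
#' processing alters a raw ingredient's profile.
#'
#' @param food_a,food_b Records from [food_record()], on the same panel.
#' @param floor Positive pseudo-amount added to numerator and denominator
#'   (default `1e-6` g-scale, small enough that microgram-scale amounts stay
#'   distinguishable).
#' @return A list with `ratio` (named vector), `frac_changed_10pct` and
#'   `frac_order_of_magnitude`.
#' @export
nutrient_fold_change <- function(food_a, food_b, floor = 1e-6) {
  stopifnot(floor > 0)
  if (!same_panel(food_a$panel, food_b$panel))
    stop_foodprox("foods are on different nutrient panels",
                  class = "foodprox_validation_error")
  a <- food_a$nutrients
  b <- food_b$nutrients
  ratio <- (b + floor) / (a + floor)
  # 1e-3 relative slack keeps exact 10x scalings, which the floor nudges
  # just under the threshold, on the order-of-magnitude side
  list(ratio = ratio,
       frac_changed_10pct = mean(abs(ratio - 1) > 0.10),
       frac_order_of_magnitude = mean(ratio >= 10 * (1 - 1e-3) |
                                        ratio <= 0.1 * (1 + 1e-3)))
}

#' Box statistics of scores by food group
#'
#' Groups foods by a metadata field (typically `wweia_category`), keeps
#' groups with at least `min_group_size` members, and returns per-group box
#' statistics: median, quartiles (type-7 linear interpolation) and whisker
#' bounds under the 1.5 IQR convention (most extreme scores within
#' 1.5 IQR of the quartiles). Groups are ordered by increasing median, with
#' the group id breaking ties.
#'
#' @param catalog A [food_catalog()].
#' @param scores Named numeric vector of scores, names = food_id.
#' @param group_by Metadata column to group on (default `"wweia_category"`).
#' @param min_group_size Minimum members per reported group (default 20).
#' @return data.frame with columns `group`, `n`, `median`, `q1`, `q3`,
#'   `lo_whisker`, `hi_whisker`.
#' @export
summarize_by_group <- function(catalog, scores, group_by = "wweia_category",
                               min_group_size = 20) {
  if (!group_by %in% names(catalog$meta))
    stop_foodprox("unknown group_by field '", group_by, "'",
                  class = "foodprox_schema_error")
  grp <- catalog$meta[[group_by]]
  keep <- !is.na(grp)
  grp <- as.character(grp[keep])
  ids <- catalog$meta$food_id[keep]
  miss <- setdiff(ids, names(scores))
  if (length(miss) > 0)
    stop_foodprox("no score for food_id '", miss[1], "'",
                  class = "foodprox_validation_error")
  s <- scores[ids]
  res <- lapply(split(s, grp), function(v) {
    if (length(v) < min_group_size) return(NULL)
    q <- unname(stats::quantile(v, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    lo <- min(v[v >= q[1] - 1.5 * iqr])
    hi <- max(v[v <= q[3] + 1.5 * iqr])
    data.frame(n = length(v), median = q[2], q1 = q[1], q3 = q[3],
               lo_whisker = lo, hi_whisker = hi)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0)
    return(data.frame(group = character(), n = integer(), median = numeric(),
                      q1 = numeric(), q3 = numeric(), lo_whisker = numeric(),
                      hi_whisker = numeric()))
  out <- do.call(rbind, res)
  out <- cbind(group = names(res), out)
  out <- out[order(out$median, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}
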