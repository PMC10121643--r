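#' Nutrient panels
#'
#' A nutrient panel is an ordered list of nutrient identifiers, each with a
#' declared mass unit per 100 g of food (`g`, `mg` or `ug`). All food tables,
#' trained models and scores are tied to a panel: the order of its nutrients
#' is the feature order of the classifier and is persisted with any trained
#' model.
#'
#' @param name Short identifier for the panel.
#' @param nutrient_id Character vector of unique nutrient identifiers.
#' @param unit Character vector of units, one per nutrient, each one of
#'   `"g"`, `"mg"`, `"ug"`.
#' @return An object of class `nutrient_panel` with fields `name`,
#'   `nutrients` (data.frame with columns `nutrient_id`, `unit`) and `size`.
#' @examples
#' nutrient_panel("mini", c("protein", "vitc"), c("g", "mg"))
#' @export
nutrient_panel <- function(name, nutrient_id, unit) {
  nutrient_id <- as.character(nutrient_id)
  unit <- as.character(unit)
  if (length(nutrient_id) < 1L)
    stop_foodprox("a nutrient panel needs at least one nutrient",
                  class = "foodprox_validation_error")
  if (anyDuplicated(nutrient_id))
    stop_foodprox("duplicated nutrient ids: ",
                  paste(unique(nutrient_id[duplicated(nutrient_id)]), collapse = ", "),
                  class = "foodprox_validation_error")
  if (length(unit) != length(nutrient_id) || !all(unit %in% c("g", "mg", "ug")))
    stop_foodprox("units must be one of g, mg, ug (one per nutrient)",
                  class = "foodprox_validation_error")
  structure(list(name = as.character(name)[1],
                 nutrients = data.frame(nutrient_id = nutrient_id, unit = unit,
                                        stringsAsFactors = FALSE),
                 size = length(nutrient_id)),
            class = "nutrient_panel")
}

#' Built-in nutrient panels
#'
#' Four panels ship with the package as editable CSV manifests under
#' `inst/extdata/panels/`:
#' \describe{
#'   \item{fda12}{the 12 gram-based nutrients of the FDA nutrition-facts
#'     label (no energy, no trans fat).}
#'   \item{nhanes58}{a 58-nutrient panel of the kind available across all
#'     survey cycles.}
#'   \item{nhanes62}{a 62-nutrient superset commonly documented in recent
#'     cycles.}
#'   \item{fndds99}{a 99-nutrient panel including flavonoid measurements.}
#' }
#' The 58/62/99 manifests are representative stand-ins assembled from
#' standard food-composition nutrient lists; edit the CSVs to match an
#' authoritative source before production use. Every panel contains
#' `protein`, `carbohydrate` and `total_fat` in grams so that energy density
#' can be derived by Atwater factors.
#'
#' @param name One of `"fda12"`, `"nhanes58"`, `"nhanes62"`, `"fndds99"`.
#' @return A [nutrient_panel()].
#' @examples
#' builtin_panel("fda12")
#' @export
builtin_panel <- function(name = c("fda12", "nhanes58", "nhanes62", "fndds99")) {
  name <- match.arg(name)
  path <- system.file("extdata", "panels", paste0(name, ".csv"),
                      package = "foodprox", mustWork = TRUE)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  nutrient_panel(name, man$nutrient_id, man$unit)
}

#' @export
print.nutrient_panel <- function(x, ...) {
  cat(sprintf("<nutrient_panel '%s': %d nutrients>\n", x$name, x$size))
  cat("  ", paste(utils::head(x$nutrients$nutrient_id, 8), collapse = ", "),
      if (x$size > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# multiplicative factor converting an amount in `from` units to `to` units;
# the three supported prefixes differ by exact powers of 10^3
unit_factor <- function(from, to) {
  pow <- c(g = 0, mg = -3, ug = -6)
  if (any(!from %in% names(pow)) || any(!to %in% names(pow)))
    stop_foodprox("unsupported unit (use g, mg, ug)",
                  class = "foodprox_validation_error")
  unname(10^(pow[from] - pow[to]))
}

panel_ids <- function(panel) panel$nutrients$nutrient_id

same_panel <- function(a, b) {
  identical(a$nutrients$nutrient_id, b$nutrients$nutrient_id) &&
    identical(a$nutrients$unit, b$nutrients$unit)
}
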