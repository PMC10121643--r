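# Model bundle persistence: a versioned directory with a config manifest,
# the panel manifest, serialized ensemble members and the training
# fingerprint, so a saved model can be audited and reloaded safely.

BUNDLE_VERSION <- 1L

#' Save a trained model bundle
#'
#' Writes `manifest.json` (bundle version, config, feature names, training
#' fingerprint, panel hash), `panel.csv` and one `member_<m>.rds` per
#' ensemble member into `dir`.
#'
#' @param model A `foodprox_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  panel_df <- model$panel$nutrients
  utils::write.csv(panel_df, file.path(dir, "panel.csv"), row.names = FALSE)
  manifest <- list(
    bundle_version = BUNDLE_VERSION,
    panel_name = model$panel$name,
    panel_hash = sum(string_hash(paste(panel_df$nutrient_id, panel_df$unit))),
    feature_names = model$feature_names,
    training_fingerprint = model$training_fingerprint,
    config = model$config[setdiff(names(model$config), "class_labels")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (m in seq_along(model$members))
    saveRDS(model$members[[m]], file.path(dir, sprintf("member_%d.rds", m)))
  invisible(dir)
}

#' Load a model bundle
#'
#' Verifies the bundle version and that the stored panel manifest matches
#' its recorded hash before reassembling the model.
#'
#' @param dir Bundle directory written by [save_model()].
#' @return A `foodprox_model`.
#' @export
load_model <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path))
    stop_foodprox("no manifest.json in '", dir, "'",
                  class = "foodprox_schema_error")
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  if (!identical(as.integer(man$bundle_version), BUNDLE_VERSION))
    stop_foodprox("unsupported bundle version ", man$bundle_version,
                  class = "foodprox_schema_error")
  panel_df <- utils::read.csv(file.path(dir, "panel.csv"),
                              stringsAsFactors = FALSE)
  hash <- sum(string_hash(paste(panel_df$nutrient_id, panel_df$unit)))
  if (!isTRUE(all.equal(hash, man$panel_hash)))
    stop_foodprox("panel manifest does not match its recorded hash",
                  class = "foodprox_validation_error")
  panel <- nutrient_panel(man$panel_name, panel_df$nutrient_id, panel_df$unit)
  cfg <- man$config
  config <- classifier_config(
    n_members = cfg$n_members, n_trees = cfg$n_trees,
    max_depth = cfg$max_depth, use_smote = isTRUE(cfg$use_smote),
    smote_k = cfg$smote_k, log_epsilon = cfg$log_epsilon, seed = cfg$seed)
  members <- lapply(seq_len(config$n_members), function(m)
    readRDS(file.path(dir, sprintf("member_%d.rds", m))))
  structure(list(config = config, panel = panel, members = members,
                 feature_names = man$feature_names, fold = NULL,
                 training_fingerprint = man$training_fingerprint),
            class = "foodprox_model")
}
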