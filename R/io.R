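# Prediction interchange, checkpoints, configuration files.

#' Write predictions to the JSON interchange format
#'
#' Schema: per molecule `{molecule_id, smiles, shifts: [{atom_idx, nucleus,
#' value_ppm, uncertainty_ppm}], couplings: [{i, j, class, value_hz,
#' uncertainty_hz}]}`.  Atom indices are 0-based in input atom order;
#' coupling pairs are stored once with `i < j`.
#'
#' @param pred an `ss_predictions`
#' @param path output path
#' @param smiles optional named character vector (molecule_id -> SMILES)
#' @return `path`, invisibly
#' @export
write_predictions <- function(pred, path, smiles = NULL) {
  ids <- unique(c(pred$shifts$molecule_id, pred$couplings$molecule_id))
  docs <- lapply(ids, function(id) {
    sh <- pred$shifts[pred$shifts$molecule_id == id, ]
    cp <- pred$couplings[pred$couplings$molecule_id == id, ]
    list(molecule_id = id,
         smiles = if (!is.null(smiles)) smiles[[id]] %||% NA else NA,
         shifts = sh[, c("atom_idx", "nucleus", "value_ppm",
                         "uncertainty_ppm")],
         couplings = cp[, c("i", "j", "class", "value_hz",
                            "uncertainty_hz")])
  })
  res <- tryCatch(
    jsonlite::write_json(docs, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null"),
    error = function(e) {
      abort(paste0("failed to write predictions: ", conditionMessage(e)),
            class = "spinsys_error_io")
    }
  )
  invisible(path)
}

#' Read predictions from the JSON interchange format
#'
#' @param path JSON file written by [write_predictions()]
#' @return an `ss_predictions`
#' @export
read_predictions <- function(path) {
  docs <- jsonlite::read_json(path)
  sh <- list()
  cp <- list()
  for (doc in docs) {
    if (length(doc$shifts) > 0) {
      sh[[length(sh) + 1L]] <- bind_rows(lapply(doc$shifts, function(r) {
        tibble(molecule_id = doc$molecule_id,
               atom_idx = as.integer(r$atom_idx), nucleus = r$nucleus,
               value_ppm = as.numeric(r$value_ppm),
               uncertainty_ppm = as.numeric(r$uncertainty_ppm))
      }))
    }
    if (length(doc$couplings) > 0) {
      cp[[length(cp) + 1L]] <- bind_rows(lapply(doc$couplings, function(r) {
        tibble(molecule_id = doc$molecule_id, i = as.integer(r$i),
               j = as.integer(r$j), class = r$class,
               value_hz = as.numeric(r$value_hz),
               uncertainty_hz = as.numeric(r$uncertainty_hz))
      }))
    }
  }
  structure(list(
    shifts = bind_rows(sh) %|0|%
      tibble(molecule_id = character(), atom_idx = integer(),
             nucleus = character(), value_ppm = numeric(),
             uncertainty_ppm = numeric()),
    couplings = bind_rows(cp) %|0|%
      tibble(molecule_id = character(), i = integer(), j = integer(),
             class = character(), value_hz = numeric(),
             uncertainty_hz = numeric())),
    class = "ss_predictions")
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single-file archive holding the parameters, model
#' and feature configuration, standardization constants and the feature
#' config hash; loading refuses a checkpoint whose feature hash does not
#' match its stored feature configuration.
#'
#' @param fit an `ss_fit`
#' @param path checkpoint path
#' @return `path` invisibly / the restored `ss_fit`
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "ss_fit"))
  saveRDS(unclass(fit), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$feature_hash, feature_config_hash(obj$fcfg))) {
    abort("checkpoint feature-config hash mismatch",
          class = "spinsys_error_hash")
  }
  structure(obj, class = "ss_fit")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file
#' @return nested list
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @param config nested list
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
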