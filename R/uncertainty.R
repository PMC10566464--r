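# Bootstrap-head uncertainty quantification.
#
# All heads share the network trunk; each head has its own final layers.
# At train time every molecule is seen by a fixed, hash-determined subset of
# heads and the loss is computed on the subset mean; at test time all heads
# run and the prediction is their mean with the sample standard deviation as
# uncertainty.

#' Deterministic per-molecule bootstrap head subset
#'
#' Each head is included independently with probability `p_include`, driven
#' by a hash of (molecule_id, head, seed) so the assignment is stable across
#' runs and machines.  An empty draw falls back to the head with the
#' smallest hash, so every molecule trains at least one head.
#'
#' @param molecule_id opaque molecule identifier
#' @param b number of bootstrap heads
#' @param p_include inclusion probability in (0, 1]
#' @param seed integer seed
#' @return integer vector of head indices (sorted, nonempty)
#' @export
assign_bootstraps <- function(molecule_id, b, p_include = 0.5, seed = 1) {
  stopifnot(b >= 1, p_include > 0, p_include <= 1)
  u <- vapply(seq_len(b), function(head) {
    h <- rlang::hash(list(as.character(molecule_id), as.integer(head),
                          as.integer(seed)))
    strtoi(substr(h, 1, 7), base = 16L) / 16^7
  }, 0)
  subset <- which(u < p_include)
  if (length(subset) == 0) subset <- which.min(u)
  sort(subset)
}

#' Logical molecule x head inclusion matrix
#' @noRd
bootstrap_matrix <- function(molecule_ids, b, p_include, seed) {
  m <- vapply(molecule_ids, function(id) {
    seq_len(b) %in% assign_bootstraps(id, b, p_include, seed)
  }, logical(b))
  t(matrix(m, nrow = b))  # vapply drops to a vector when b == 1
}

#' Mean prediction over a bootstrap subset (train-time prediction)
#'
#' @param head_outputs numeric matrix with one column per head (rows =
#'   predictions), or a numeric vector of per-head values
#' @param subset integer head indices
#' @return numeric vector (or scalar) of subset means
#' @export
subset_train_prediction <- function(head_outputs, subset) {
  if (length(subset) == 0) {
    abort("bootstrap subset is empty", class = "spinsys_error_subset")
  }
  if (is.matrix(head_outputs)) {
    rowMeans(head_outputs[, subset, drop = FALSE])
  } else {
    mean(head_outputs[subset])
  }
}

#' Full-ensemble prediction with uncertainty (test time)
#'
#' Value = mean over all heads; uncertainty = sample standard deviation
#' (denominator B - 1; exactly 0 when B = 1).
#'
#' @param head_outputs numeric matrix with one column per head, or vector
#' @return tibble with columns `value` and `uncertainty`
#' @export
ensemble_predict <- function(head_outputs) {
  if (!is.matrix(head_outputs)) {
    head_outputs <- matrix(head_outputs, nrow = 1)
  }
  b <- ncol(head_outputs)
  value <- rowMeans(head_outputs)
  uncertainty <- if (b == 1) {
    rep(0, nrow(head_outputs))
  } else {
    sqrt(rowSums((head_outputs - value)^2) / (b - 1))
  }
  tibble(value = value, uncertainty = uncertainty)
}
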