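# Evaluation machinery: per-class MAE, uncertainty-sorted rolling error
# curves, error/uncertainty correlation, confidence-filtered MAE.

#' Rolling statistic over a sliding window
#'
#' Windows are the `n - w + 1` contiguous runs of length `w` in the given
#' order (no partial windows).
#' @param x numeric vector
#' @param w window length (>= 1)
#' @param fun summary function
#' @return numeric vector of length `n - w + 1`
#' @export
rolling_stat <- function(x, w, fun = mean) {
  n <- length(x)
  stopifnot(w >= 1, w <= n)
  vapply(seq_len(n - w + 1L), function(k) fun(x[k:(k + w - 1L)]), 0)
}

#' Metrics from a prediction-error table
#'
#' @param errors tibble with columns `parameter`, `error`, `uncertainty`
#' @param window_fraction rolling window size as a fraction of the number
#'   of predictions in the class (default 0.1)
#' @param top_fractions most-confident fractions for filtered MAE
#' @return list(metrics = per-parameter tibble, rolling = tibble of
#'   uncertainty-sorted rolling MAE / 95th-percentile-error curves)
#' @export
metrics_from_errors <- function(errors, window_fraction = 0.1,
                                top_fractions = c(0.5, 0.8, 1)) {
  stopifnot(all(c("parameter", "error", "uncertainty") %in% names(errors)))
  params <- unique(errors$parameter)
  met <- list()
  roll <- list()
  for (p in params) {
    e <- errors[errors$parameter == p, ]
    if (nrow(e) == 0) {
      warn(paste0("parameter class ", p, " has no predictions; omitted"))
      next
    }
    e <- e[order(e$uncertainty), ]
    ae <- abs(e$error)
    n <- nrow(e)
    corr <- if (n >= 3 && sd(ae) > 0 && sd(e$uncertainty) > 0) {
      cor(ae, e$uncertainty)
    } else {
      NA_real_
    }
    topq <- vapply(top_fractions, function(q) {
      mean(ae[seq_len(max(1L, floor(q * n)))])
    }, 0)
    met[[p]] <- tibble(parameter = p, n = n, mae = mean(ae),
                       rmse = sqrt(mean(e$error^2)),
                       cor_err_unc = corr,
                       !!!stats::setNames(as.list(topq),
                                          paste0("mae_top",
                                                 round(100 * top_fractions))))
    w <- max(2L, min(n, round(window_fraction * n)))
    if (n >= w) {
      rm_ <- rolling_stat(ae, w, mean)
      rq <- rolling_stat(ae, w, function(v) {
        unname(quantile(v, 0.95, type = 7))
      })
      ru <- rolling_stat(e$uncertainty, w, mean)
      roll[[p]] <- tibble(parameter = p, window = w,
                          position = seq_along(rm_),
                          mean_uncertainty = ru, rolling_mae = rm_,
                          rolling_q95 = rq)
    }
  }
  list(metrics = bind_rows(met), rolling = bind_rows(roll))
}

#' Evaluate a fitted model on labeled examples
#'
#' Predicts the full spin systems, joins against the requested label
#' channel and computes, per parameter class (1H, 13C, each coupling
#' class): MAE, RMSE, the Pearson correlation between absolute error and
#' the bootstrap uncertainty, MAE of the most-confident fractions, and the
#' uncertainty-sorted rolling MAE / rolling 95th-percentile error curves.
#'
#' @param fit an `ss_fit`
#' @param examples labeled examples tibble (as from [generate_fixtures()])
#' @param channel label channel to evaluate against (`"exp"` or `"ab"`)
#' @param window_fraction rolling window size as fraction of class size
#' @return an `ss_eval` object: `$errors`, `$metrics`, `$rolling`
#' @export
evaluate_spin_model <- function(fit, examples, channel = c("exp", "ab"),
                                window_fraction = 0.1) {
  channel <- match.arg(channel)
  pred_channel <- if (channel == "exp") "experimental" else "ab_initio"
  pred <- predict_spin_systems(fit, examples$graph, channel = pred_channel)
  errors <- prediction_errors(pred, examples, channel)
  mt <- metrics_from_errors(errors, window_fraction)
  structure(list(errors = errors, metrics = mt$metrics,
                 rolling = mt$rolling, channel = channel),
            class = "ss_eval")
}

#' Join predictions against labels into an error table
#'
#' @param pred an `ss_predictions`
#' @param examples labeled examples tibble
#' @param channel `"exp"` or `"ab"`
#' @return tibble with parameter, molecule_id, index columns, predicted,
#'   reference, error, uncertainty
#' @export
prediction_errors <- function(pred, examples, channel = "exp") {
  sh_lab <- bind_rows(purrr::map2(examples$shifts, examples$molecule_id,
                                  function(s, id) {
                                    mutate(s, molecule_id = id)
                                  }))
  sh_lab$reference <- sh_lab[[channel]]
  sh <- dplyr::inner_join(pred$shifts, sh_lab,
                          by = c("molecule_id", "atom_idx", "nucleus"))
  sh <- sh[!is.na(sh$reference), ]
  sh_err <- tibble(parameter = sh$nucleus, kind = "shift",
                   molecule_id = sh$molecule_id, i = sh$atom_idx,
                   j = NA_integer_, predicted = sh$value_ppm,
                   reference = sh$reference,
                   error = sh$value_ppm - sh$reference,
                   uncertainty = sh$uncertainty_ppm)
  cp_lab <- bind_rows(purrr::map2(examples$couplings, examples$molecule_id,
                                  function(s, id) {
                                    mutate(s, molecule_id = id)
                                  }))
  if (nrow(cp_lab) > 0) {
    cp_lab$reference <- cp_lab[[channel]]
    cp <- dplyr::inner_join(pred$couplings, cp_lab,
                            by = c("molecule_id", "i", "j", "class"))
    cp <- cp[!is.na(cp$reference), ]
    cp_err <- tibble(parameter = cp$class, kind = "coupling",
                     molecule_id = cp$molecule_id, i = cp$i, j = cp$j,
                     predicted = cp$value_hz, reference = cp$reference,
                     error = cp$value_hz - cp$reference,
                     uncertainty = cp$uncertainty_hz)
  } else {
    cp_err <- sh_err[0, ]
  }
  bind_rows(sh_err, cp_err)
}

#' @export
print.ss_eval <- function(x, ...) {
  cat("<ss_eval> ", nrow(x$errors), " predictions, channel: ", x$channel,
      "\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' Write a metrics report to JSON and CSV
#'
#' @param eval an `ss_eval`
#' @param path_json JSON output path (per-class metrics + rolling curves)
#' @param path_csv optional CSV output path for the per-class metrics
#' @return `path_json`, invisibly
#' @export
write_metrics_report <- function(eval, path_json, path_csv = NULL) {
  jsonlite::write_json(list(metrics = eval$metrics, rolling = eval$rolling),
                       path_json, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  if (!is.null(path_csv)) {
    utils::write.csv(eval$metrics, path_csv, row.names = FALSE)
  }
  invisible(path_json)
}
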