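# broom-style tidiers for fitted models, evaluations and DP4 reports.

#' Tidy a fitted spin-system model
#'
#' Returns the per-epoch training history.
#' @param x an `ss_fit`
#' @param ... unused
#' @export
tidy.ss_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted spin-system model
#'
#' @param x an `ss_fit`
#' @param ... unused
#' @export
glance.ss_fit <- function(x, ...) {
  tibble(n_parameters = tree_reduce(x$params, length),
         n_bootstraps = x$mcfg$n_bootstraps,
         hidden_dim = x$mcfg$hidden_dim,
         edge_dim = x$mcfg$edge_dim,
         epochs_run = nrow(x$history),
         best_epoch = x$best_epoch,
         best_val_loss = if (x$best_epoch > 0) {
           x$history$val_loss[x$best_epoch]
         } else {
           NA_real_
         },
         lambda = x$lcfg$lambda)
}

#' Tidy an evaluation: per-parameter-class metrics
#'
#' @param x an `ss_eval`
#' @param ... unused
#' @export
tidy.ss_eval <- function(x, ...) {
  x$metrics
}

#' One-row summary of an evaluation
#'
#' @param x an `ss_eval`
#' @param ... unused
#' @export
glance.ss_eval <- function(x, ...) {
  tibble(n = nrow(x$errors), mae = mean(abs(x$errors$error)),
         cor_err_unc = if (nrow(x$errors) >= 3) {
           cor(abs(x$errors$error), x$errors$uncertainty)
         } else {
           NA_real_
         },
         channel = x$channel)
}

#' Tidy a DP4 report
#'
#' @param x an `ss_dp4` (from [dp4_probability()])
#' @param ... unused
#' @export
tidy.ss_dp4 <- function(x, ...) {
  as_tibble(x)
}

#' Tidy a ring-partition experiment: the per-model, per-region MAE table
#'
#' @param x an `ss_ring_experiment`
#' @param ... unused
#' @export
tidy.ss_ring_experiment <- function(x, ...) {
  x$table
}
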