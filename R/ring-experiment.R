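# Small-ring / big-ring label-transfer experiment.
#
# Emulates the situation where one region of chemical space (molecules with
# 3-/4-membered rings) has no experimental labels, but ab initio labels
# (which carry a systematic offset against experiment) are available
# everywhere.  Four configurations are trained and compared on held-out
# experimental labels per region:
#   baseline              experimental labels in both regions
#   experimental_control  experimental labels in the big-ring region only
#   ab_initio_control     big-ring experimental + small-ring ab initio
#                         values trained directly as if they were
#                         experimental (single channel)
#   disagreement(lambda)  big-ring experimental on the experimental
#                         channel + ab initio everywhere on the ab initio
#                         channel, joint disagreement-regularized loss
#
# Only proton shifts are scored; couplings are carried through training
# unchanged.

#' Run the ring-partition label-transfer experiment
#'
#' @param examples labeled fixtures from [generate_fixtures()] with both
#'   regions present and an ab initio shift channel
#' @param lambda_grid disagreement weights to train (one model each)
#' @param mcfg,fcfg model / feature configuration shared by all runs
#' @param test_fraction held-out fraction per region
#' @param seed master seed (splits, training)
#' @param ... forwarded to [train_spin_model()] (epochs, lr, ...)
#' @return a `ss_ring_experiment`: `$table` with per-model, per-region
#'   held-out experimental 1H MAE; `$fits` the fitted models
#' @export
ring_partition_experiment <- function(examples, lambda_grid = c(1, 5, 10),
                                      mcfg = model_config(),
                                      fcfg = feature_config(),
                                      test_fraction = 0.2, seed = 1, ...) {
  regions <- unique(examples$region)
  if (!all(c("small_ring", "big_ring") %in% regions)) {
    abort("examples must contain both small_ring and big_ring molecules",
          class = "spinsys_error_region")
  }
  has_ab <- any(vapply(examples$shifts, function(s) any(!is.na(s$ab)),
                       TRUE))
  if (!has_ab) {
    abort("examples need an ab initio shift channel",
          class = "spinsys_error_region")
  }

  n <- nrow(examples)
  test_idx <- with_seed_(derive_seed(seed, "ring_split"), {
    unlist(lapply(c("small_ring", "big_ring"), function(rg) {
      idx <- which(examples$region == rg)
      sample(idx, max(1L, round(test_fraction * length(idx))))
    }))
  })
  test <- examples[test_idx, ]
  train <- examples[-test_idx, ]
  small <- train$region == "small_ring"

  # label-channel surgery per configuration
  strip_ab <- function(s) mutate(s, ab = NA_real_)
  keep_none <- function(s) mutate(s, exp = NA_real_, ab = NA_real_)
  ab_as_exp <- function(s) mutate(s, exp = .data$ab, ab = NA_real_)
  with_shifts <- function(d, f, rows) {
    d$shifts[rows] <- lapply(d$shifts[rows], f)
    d
  }
  drop_unlabeled <- function(d) {
    keep <- vapply(d$shifts, function(s) any(!is.na(s$exp) | !is.na(s$ab)),
                   TRUE)
    d[keep, ]
  }

  configs <- list(
    baseline = with_shifts(train, strip_ab, seq_len(nrow(train))),
    experimental_control =
      drop_unlabeled(with_shifts(with_shifts(train, strip_ab, which(!small)),
                                 keep_none, which(small))),
    ab_initio_control =
      with_shifts(with_shifts(train, strip_ab, which(!small)),
                  ab_as_exp, which(small))
  )
  lambdas <- c(baseline = NA, experimental_control = NA,
               ab_initio_control = NA)
  for (lam in lambda_grid) {
    nm <- paste0("disagreement_lambda", lam)
    # experimental channel only where experimentally labeled (big rings);
    # ab initio channel everywhere
    d <- train
    d$shifts[small] <- lapply(d$shifts[small],
                              function(s) mutate(s, exp = NA_real_))
    configs[[nm]] <- d
    lambdas[nm] <- lam
  }

  fits <- list()
  rows <- list()
  for (nm in names(configs)) {
    lam <- lambdas[nm]
    fit <- train_spin_model(configs[[nm]], mcfg, fcfg,
                            lambda = if (is.na(lam)) 0 else lam,
                            seed = derive_seed(seed, paste0("fit_", nm)),
                            ...)
    fits[[nm]] <- fit
    ev <- evaluate_spin_model(fit, test, channel = "exp")
    err <- ev$errors
    err <- err[err$parameter == "1H", ]
    reg <- test$region[match(err$molecule_id, test$molecule_id)]
    for (rg in c("big_ring", "small_ring")) {
      rows[[length(rows) + 1L]] <-
        tibble(model = nm, lambda = lam, region = rg,
               mae = mean(abs(err$error[reg == rg])),
               n = sum(reg == rg))
    }
  }
  structure(list(table = bind_rows(rows), fits = fits,
                 test_ids = test$molecule_id),
            class = "ss_ring_experiment")
}

#' @export
print.ss_ring_experiment <- function(x, ...) {
  cat("<ss_ring_experiment>\n")
  print(tidyr::pivot_wider(x$table, id_cols = c("model", "lambda"),
                           names_from = "region", values_from = "mae"))
  invisible(x)
}
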