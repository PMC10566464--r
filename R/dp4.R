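# DP4 stereoisomer identification: candidate enumeration and probabilistic
# ranking of stereoisomers against reference chemical shifts under a
# Student-t error model.

#' DP4 Student-t error-model parameters
#'
#' Defaults are the published DP4 constants (degrees of freedom nu and
#' scale sigma in ppm per nucleus).  `correction` selects the expectation
#' correction applied to predicted shifts before computing errors:
#' `"linear-rescale"` (canonical practice: remove systematic scale/offset
#' error by regressing predictions on the reference) or `"none"`.
#'
#' @param nu_1h,sigma_1h proton t parameters
#' @param nu_13c,sigma_13c carbon t parameters
#' @param correction `"linear-rescale"` or `"none"`
#' @return a `ss_dp4_params` list
#' @export
dp4_params <- function(nu_1h = 14.18, sigma_1h = 0.185,
                       nu_13c = 11.38, sigma_13c = 2.306,
                       correction = c("linear-rescale", "none")) {
  correction <- match.arg(correction)
  stopifnot(nu_1h > 0, sigma_1h > 0, nu_13c > 0, sigma_13c > 0)
  structure(list(`1H` = list(nu = nu_1h, sigma = sigma_1h),
                 `13C` = list(nu = nu_13c, sigma = sigma_13c),
                 correction = correction),
            class = "ss_dp4_params")
}

#' Enumerate candidate stereoisomers
#'
#' Returns the input structure first, then distinct stereo-assignments over
#' the invertible centers / double bonds in a deterministic order, capped
#' at `max_candidates`.
#'
#' @param mol an `ss_molecule` or a SMILES string
#' @param max_candidates cap on the number of candidates (default 8)
#' @return tibble with columns `candidate` (1-based) and `smiles`
#' @export
enumerate_stereoisomers <- function(mol, max_candidates = 8) {
  stopifnot(max_candidates >= 1)
  smiles <- if (inherits(mol, "ss_molecule")) mol$smiles else mol
  rec <- backend_stereoisomers(smiles, max_candidates)[[1]]
  if (!isTRUE(rec$ok)) {
    abort("stereoisomer enumeration failed", class = "spinsys_error_stereo")
  }
  cands <- unlist(rec$candidates)
  tibble(candidate = seq_along(cands), smiles = cands)
}

#' DP4 probabilities for candidate structures
#'
#' Per candidate, errors between (corrected) predicted shifts and the
#' reference shifts are scored under the Student-t error model: the
#' log-likelihood is the sum over atoms of `log(1 - T_nu(|e|/sigma))`,
#' accumulated across nuclei; candidate probabilities are the normalized
#' likelihoods (computed in log space).
#'
#' @param predictions list (one element per candidate) of numeric shift
#'   vectors, all in the same atom order as `reference`
#' @param reference numeric vector of reference shifts (ppm)
#' @param nucleus character vector ("1H"/"13C") per atom
#' @param params a [dp4_params()]
#' @return a `ss_dp4` tibble: candidate, log_likelihood, probability
#' @export
dp4_probability <- function(predictions, reference, nucleus,
                            params = dp4_params()) {
  n_at <- length(reference)
  stopifnot(length(nucleus) == n_at, n_at >= 1)
  if (!all(nucleus %in% c("1H", "13C"))) {
    abort("nucleus must be '1H' or '13C'", class = "spinsys_error_nucleus")
  }
  ll <- vapply(predictions, function(pred) {
    if (length(pred) != n_at) {
      abort("candidate prediction length does not match the reference",
            class = "spinsys_error_mismatch")
    }
    tot <- 0
    for (nuc in unique(nucleus)) {
      sel <- nucleus == nuc
      p <- pred[sel]
      r <- reference[sel]
      if (params$correction == "linear-rescale" && sum(sel) >= 2 &&
            sd(r) > 0) {
        ft <- stats::lm.fit(cbind(1, r), p)
        co <- ft$coefficients
        if (is.finite(co[2]) && abs(co[2]) > 1e-8) {
          p <- (p - co[1]) / co[2]
        }
      }
      e <- abs(p - r) / params[[nuc]]$sigma
      tot <- tot + sum(pt(e, df = params[[nuc]]$nu, lower.tail = FALSE,
                          log.p = TRUE))
    }
    tot
  }, 0)
  if (all(!is.finite(ll))) {
    warn("all candidate likelihoods are zero; returning uniform DP4")
    prob <- rep(1 / length(ll), length(ll))
  } else {
    m <- max(ll[is.finite(ll)])
    w <- exp(ll - m)
    w[!is.finite(ll)] <- 0
    prob <- w / sum(w)
  }
  structure(tibble(candidate = seq_along(ll), log_likelihood = ll,
                   probability = prob),
            class = c("ss_dp4", "tbl_df", "tbl", "data.frame"))
}

#' Stereoisomer identification benchmark
#'
#' For each case: enumerate candidate stereoisomers, obtain predicted
#' shifts for every candidate from `predict_fn`, rank candidates by DP4
#' probability against the reference shifts, and record the rank of the
#' true structure.  Reports top-1 / top-2 accuracy overall and stratified
#' by candidate count.  The predictor is pluggable, so oracle, random and
#' model-based predictors can be benchmarked identically.
#'
#' @param cases tibble with columns `smiles` (true structure, stereo
#'   assigned), `reference` (list-column: tibble with `nucleus`, `value`)
#' @param predict_fn function(candidate_smiles, case) returning a numeric
#'   vector of predicted shifts aligned with the case's reference rows
#' @param params a [dp4_params()]
#' @param max_candidates candidate cap (default 8)
#' @return a `ss_dp4_benchmark` list: `$results` per-case tibble,
#'   `$summary` overall and per-candidate-count accuracy tibble
#' @export
identification_benchmark <- function(cases, predict_fn,
                                     params = dp4_params(),
                                     max_candidates = 8) {
  res <- purrr::map(seq_len(nrow(cases)), function(r) {
    case <- cases[r, ]
    cands <- enumerate_stereoisomers(case$smiles[[1]], max_candidates)
    ref <- case$reference[[1]]
    preds <- lapply(cands$smiles, function(s) predict_fn(s, case))
    dp4 <- dp4_probability(preds, ref$value, ref$nucleus, params)
    true_idx <- match(case$smiles[[1]], cands$smiles)
    rank_true <- if (is.na(true_idx)) {
      NA_integer_
    } else {
      # rank among candidates, highest probability first
      as.integer(rank(-dp4$probability, ties.method = "min")[true_idx])
    }
    tibble(case = r, n_candidates = nrow(cands), rank_true = rank_true,
           p_true = if (is.na(true_idx)) NA_real_ else
             dp4$probability[true_idx])
  })
  results <- bind_rows(res)
  ok <- results[!is.na(results$rank_true), ]
  summarize_acc <- function(d, label) {
    tibble(stratum = label, n = nrow(d),
           top1 = mean(d$rank_true == 1),
           top2 = mean(d$rank_true <= 2))
  }
  summary <- bind_rows(
    summarize_acc(ok, "all"),
    bind_rows(lapply(sort(unique(ok$n_candidates)), function(k) {
      summarize_acc(ok[ok$n_candidates == k, ],
                    paste0(k, "_candidates"))
    }))
  )
  structure(list(results = results, summary = summary),
            class = "ss_dp4_benchmark")
}

#' @export
print.ss_dp4_benchmark <- function(x, ...) {
  cat("<ss_dp4_benchmark> ", nrow(x$results), " cases\n", sep = "")
  print(x$summary)
  invisible(x)
}
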