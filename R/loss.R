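# Losses: two-channel disagreement regularization and helpers.

#' Disagreement-regularized two-channel loss
#'
#' Joint loss for models with an experimental and an ab initio output
#' channel.  Per supervised entry: if only one channel's label exists the
#' loss is the base loss on that channel; if both exist it is
#' `L_a + w * L_e` with the agreement weight
#' `w = lambda / (|phi_a - phi_e| + offset)`, so strong agreement between
#' the two label sources up-weights the experimental channel and
#' disagreement (likely experimental noise or misassignment) down-weights
#' it.  With `lambda = 0` the loss reduces exactly to ab-initio-only
#' training on dual-labeled entries.  Returns the mean over supervised
#' entries.
#'
#' @param pred_a,pred_e predictions on the ab initio / experimental channel
#' @param phi_a,phi_e labels (NA marks an absent channel; at least one
#'   channel must be present per entry)
#' @param lambda nonnegative agreement weight scale
#' @param offset fixed offset in the denominator (1 ppm for shifts; use Hz
#'   for couplings)
#' @param base base loss: `"l1"` (absolute error) or `"huber"` (delta = 1)
#' @return scalar mean loss
#' @export
disagreement_loss <- function(pred_a, pred_e, phi_a, phi_e, lambda = 5,
                              offset = 1, base = c("l1", "huber")) {
  base <- match.arg(base)
  if (lambda < 0) {
    abort("lambda must be nonnegative", class = "spinsys_error_lambda")
  }
  has_a <- !is.na(phi_a)
  has_e <- !is.na(phi_e)
  if (any(!has_a & !has_e)) {
    abort("every supervised entry needs at least one channel",
          class = "spinsys_error_labels")
  }
  la <- ifelse(has_a, base_loss(pred_a - phi_a, base), 0)
  le <- ifelse(has_e, base_loss(pred_e - phi_e, base), 0)
  w <- ifelse(has_a & has_e, lambda / (abs(phi_a - phi_e) + offset), 0)
  per <- ifelse(has_a & has_e, la + w * le, ifelse(has_a, la, le))
  mean(per)
}

#' @noRd
base_loss <- function(d, base) {
  if (base == "l1") abs(d) else ifelse(abs(d) < 1, 0.5 * d^2, abs(d) - 0.5)
}

#' @noRd
base_loss_grad <- function(d, base) {
  if (base == "l1") sign(d) else ifelse(abs(d) < 1, d, sign(d))
}

#' Two-channel loss + gradient on standardized predictions
#'
#' pred/targ are n x 2 matrices (col 1 = experimental, col 2 = ab initio)
#' in standardized units; `raw` carries the labels in original units (ppm or
#' Hz) for the agreement weight.  Entries with no label in either channel
#' are ignored.  Returns mean loss over supervised rows and the gradient
#' wrt pred (same shape, already divided by the row count).
#' @noRd
channel_loss_grad <- function(pred, targ, raw, lambda, offset,
                              disagreement = TRUE, base = "l1") {
  has_e <- !is.na(targ[, 1])
  has_a <- !is.na(targ[, 2])
  sup <- has_e | has_a
  n_sup <- sum(sup)
  grad <- matrix(0, nrow(pred), 2)
  if (n_sup == 0) {
    return(list(loss = 0, grad = grad, n = 0))
  }
  de <- pred[, 1] - targ[, 1]
  da <- pred[, 2] - targ[, 2]
  le <- ifelse(has_e, base_loss(de, base), 0)
  la <- ifelse(has_a, base_loss(da, base), 0)
  ge <- ifelse(has_e, base_loss_grad(de, base), 0)
  ga <- ifelse(has_a, base_loss_grad(da, base), 0)

  both <- has_e & has_a
  if (disagreement) {
    w <- ifelse(both, lambda / (abs(raw[, 2] - raw[, 1]) + offset), 0)
    per <- ifelse(both, la + w * le, ifelse(has_e, le, la))
    grad[, 1] <- ifelse(both, w * ge, ifelse(has_e, ge, 0))
    grad[, 2] <- ifelse(both, ga, ifelse(has_e, 0, ga))
  } else {
    per <- ifelse(both, la + le, ifelse(has_e, le, la))
    grad[, 1] <- ge
    grad[, 2] <- ifelse(has_a, ga, 0)
  }
  grad[!sup, ] <- 0
  list(loss = sum(per[sup]) / n_sup, grad = grad / n_sup, n = n_sup)
}

# ---- standardization --------------------------------------------------------
# Targets are standardized per nucleus class (shifts) / coupling class
# before entering the loss; predictions are de-standardized at output.

#' @noRd
compute_standardization <- function(batches) {
  pool <- list(sh1 = c(), sh2 = c(), cp = vector("list", 8))
  sh_vals <- list(`1` = c(), `2` = c())
  cp_vals <- list()
  for (b in batches) {
    val <- ifelse(is.na(b$shift_target[, 1]), b$shift_target[, 2],
                  b$shift_target[, 1])
    for (cl in 1:2) {
      v <- val[b$nucleus == cl & !is.na(val)]
      sh_vals[[cl]] <- c(sh_vals[[cl]], v)
    }
    cval <- ifelse(is.na(b$coupling_target[, 1]), b$coupling_target[, 2],
                   b$coupling_target[, 1])
    for (cl in unique(b$cls[b$cls > 0])) {
      v <- cval[b$cls == cl & b$use_loss & !is.na(cval)]
      key <- as.character(cl)
      cp_vals[[key]] <- c(cp_vals[[key]], v)
    }
  }
  musd <- function(v) {
    if (length(v) == 0) return(c(mu = 0, sd = 1))
    c(mu = mean(v), sd = max(sd(v), 1e-6))
  }
  list(shift = lapply(sh_vals, musd),
       coupling = lapply(cp_vals, musd))
}

#' @noRd
std_shift <- function(std, nucleus) {
  mu <- rep(0, length(nucleus))
  s <- rep(1, length(nucleus))
  for (cl in 1:2) {
    st <- std$shift[[as.character(cl)]]
    if (!is.null(st)) {
      mu[nucleus == cl] <- st["mu"]
      s[nucleus == cl] <- st["sd"]
    }
  }
  list(mu = mu, sd = s)
}

#' @noRd
std_coupling <- function(std, cls) {
  mu <- rep(0, length(cls))
  s <- rep(1, length(cls))
  for (key in names(std$coupling)) {
    st <- std$coupling[[key]]
    sel <- cls == as.integer(key)
    mu[sel] <- st["mu"]
    s[sel] <- st["sd"]
  }
  list(mu = mu, sd = s)
}
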