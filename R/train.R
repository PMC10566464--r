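# Training loop: batched loss with bootstrap-head subsets, Adam updates,
# early stopping on validation loss.

#' @noRd
loss_config <- function(lambda = 5, offset_ppm = 1, offset_hz = 1,
                        disagreement_couplings = FALSE, base = "l1",
                        coupling_weight = 1) {
  stopifnot(lambda >= 0)
  list(lambda = lambda, offset_ppm = offset_ppm, offset_hz = offset_hz,
       disagreement_couplings = disagreement_couplings, base = base,
       coupling_weight = coupling_weight)
}

#' Loss (and optionally parameter gradients) for one batch
#' @noRd
batch_loss <- function(params, batch, mcfg, std, lcfg, bs_inc = NULL,
                       with_grad = FALSE) {
  fw <- spin_forward(params, batch, mcfg, need_cache = with_grad)
  b_heads <- mcfg$n_bootstraps

  # per-row head weights (train: molecule's subset mean; eval: full mean)
  if (is.null(bs_inc)) {
    wv <- matrix(1 / b_heads, batch$m_tot, b_heads)
    we <- matrix(1 / b_heads, batch$e_tot, b_heads)
  } else {
    wrow <- bs_inc / rowSums(bs_inc)
    wv <- wrow[batch$mol_of_vertex, , drop = FALSE]
    we <- wrow[batch$mol_of_edge, , drop = FALSE]
  }

  pred_sh <- matrix(0, batch$m_tot, mcfg$n_channels)
  for (b in seq_len(b_heads)) {
    pred_sh <- pred_sh + wv[, b] * fw$shift[[b]]
  }
  sv <- std_shift(std, batch$nucleus)
  sh_targ_std <- (batch$shift_target - sv$mu) / sv$sd
  sh <- channel_loss_grad(pred_sh, sh_targ_std, batch$shift_target,
                          lcfg$lambda, lcfg$offset_ppm,
                          disagreement = TRUE, base = lcfg$base)

  # couplings: select each edge's class columns
  sel <- which(batch$use_loss & (!is.na(batch$coupling_target[, 1]) |
                                   !is.na(batch$coupling_target[, 2])))
  cp <- list(loss = 0, n = 0)
  if (length(sel) > 0) {
    cls_sel <- batch$cls[sel]
    col_e <- (cls_sel - 1L) * mcfg$n_channels + 1L
    col_a <- col_e + (mcfg$n_channels > 1)
    pred_cp <- matrix(0, length(sel), 2)
    for (b in seq_len(b_heads)) {
      out <- fw$coupling[[b]]
      pred_cp[, 1] <- pred_cp[, 1] + we[sel, b] * out[cbind(sel, col_e)]
      pred_cp[, 2] <- pred_cp[, 2] + we[sel, b] * out[cbind(sel, col_a)]
    }
    sc <- std_coupling(std, cls_sel)
    cp_targ_std <- (batch$coupling_target[sel, , drop = FALSE] - sc$mu) /
      sc$sd
    cp <- channel_loss_grad(pred_cp, cp_targ_std,
                            batch$coupling_target[sel, , drop = FALSE],
                            lcfg$lambda, lcfg$offset_hz,
                            disagreement = lcfg$disagreement_couplings,
                            base = lcfg$base)
  }

  loss <- sh$loss + lcfg$coupling_weight * cp$loss
  if (!with_grad) {
    return(list(loss = loss, shift_loss = sh$loss, coupling_loss = cp$loss))
  }

  d_shift <- vector("list", b_heads)
  d_coupling <- vector("list", b_heads)
  cc <- length(mcfg$coupling_classes) * mcfg$n_channels
  for (b in seq_len(b_heads)) {
    d_shift[[b]] <- wv[, b] * sh$grad
    if (length(sel) > 0 && cp$n > 0) {
      dm <- matrix(0, batch$e_tot, cc)
      gsel <- lcfg$coupling_weight * cp$grad
      dm[cbind(sel, col_e)] <- we[sel, b] * gsel[, 1]
      dm[cbind(sel, col_a)] <- dm[cbind(sel, col_a)] + we[sel, b] * gsel[, 2]
      d_coupling[[b]] <- dm
    }
  }
  grads <- spin_backward(d_shift, d_coupling, fw, params, batch, mcfg)
  list(loss = loss, shift_loss = sh$loss, coupling_loss = cp$loss,
       grads = grads)
}

# ---- Adam -------------------------------------------------------------------

#' @noRd
adam_init <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)
}

#' @noRd
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m +
                         (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v +
                         (1 - beta2) * g * g)
  c1 <- 1 / (1 - beta1^state$t)
  c2 <- 1 / (1 - beta2^state$t)
  upd <- tree_map2(state$m, state$v, function(m, v) {
    lr * (m * c1) / (sqrt(v * c2) + eps)
  })
  params <- tree_map2(params, upd, `-`)
  list(params = params, state = state)
}

#' Train a full spin system model
#'
#' Fits the GNN on labeled examples: per-molecule bootstrap head subsets,
#' disagreement-regularized two-channel loss, Adam updates, early stopping
#' on validation loss.  Deterministic for a fixed seed.
#'
#' @param examples tibble with columns `molecule_id`, `graph` (list of
#'   `ss_graph`), `shifts` (list of tibbles: atom_idx, exp, ab) and
#'   `couplings` (list of tibbles: i, j, class, exp, ab); NA marks an
#'   absent label channel
#' @param mcfg a [model_config()]
#' @param fcfg the [feature_config()] the graphs were built with
#' @param lambda disagreement regularization weight (shift channels)
#' @param epochs maximum epochs
#' @param lr Adam learning rate
#' @param lr_decay multiplicative learning-rate decay applied per epoch
#'   (1 = constant)
#' @param batch_size molecules per batch
#' @param val_fraction fraction of molecules held out for early stopping
#'   (0 disables early stopping)
#' @param patience epochs without validation improvement before stopping
#' @param seed master seed for initialization, splits and head assignment
#' @param base_loss `"l1"` or `"huber"`
#' @param coupling_weight weight of the coupling loss term
#' @param offset_ppm,offset_hz disagreement denominators per unit
#' @param disagreement_couplings apply disagreement weighting to couplings
#' @param verbose print per-epoch losses
#' @return an `ss_fit` object (parameters, configs, standardization
#'   constants, training history)
#' @export
train_spin_model <- function(examples, mcfg = model_config(),
                             fcfg = feature_config(), lambda = 5,
                             epochs = 40, lr = 1e-3, lr_decay = 1,
                             batch_size = 32,
                             val_fraction = 0.1, patience = 20, seed = 1,
                             base_loss = "l1", coupling_weight = 1,
                             offset_ppm = 1, offset_hz = 1,
                             disagreement_couplings = FALSE,
                             verbose = FALSE) {
  stopifnot(nrow(examples) > 0)
  lcfg <- loss_config(lambda, offset_ppm, offset_hz,
                      disagreement_couplings, base_loss, coupling_weight)
  n <- nrow(examples)
  n_val <- if (val_fraction > 0) max(1L, round(val_fraction * n)) else 0L
  ord <- with_seed_(derive_seed(seed, "split"), sample.int(n))
  val_idx <- head(ord, n_val)
  train_idx <- setdiff(ord, val_idx)

  make_batches <- function(idx) {
    chunks <- split(idx, ceiling(seq_along(idx) / batch_size))
    lapply(chunks, function(ch) {
      b <- build_batch(examples$graph[ch], mcfg)
      attach_labels(b, examples$shifts[ch], examples$couplings[ch])
    })
  }
  train_batches <- make_batches(train_idx)
  val_batches <- if (n_val > 0) make_batches(val_idx) else list()
  std <- compute_standardization(train_batches)
  bs_mats <- lapply(train_batches, function(b) {
    bootstrap_matrix(b$molecule_ids, mcfg$n_bootstraps, mcfg$p_include,
                     seed)
  })

  params <- init_spin_params(mcfg, fcfg)
  state <- adam_init(params)
  history <- list()
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  stall <- 0L

  lr_epoch <- lr
  for (epoch in seq_len(epochs)) {
    batch_order <- with_seed_(derive_seed(seed, paste0("epoch", epoch)),
                              sample.int(length(train_batches)))
    tr_loss <- 0
    for (bi in batch_order) {
      res <- batch_loss(params, train_batches[[bi]], mcfg, std, lcfg,
                        bs_inc = bs_mats[[bi]], with_grad = TRUE)
      if (!is.finite(res$loss)) {
        abort(sprintf("training diverged at epoch %d (loss = %g)",
                      epoch, res$loss),
              class = "spinsys_error_divergence")
      }
      st <- adam_step(params, res$grads, state, lr = lr_epoch)
      params <- st$params
      state <- st$state
      tr_loss <- tr_loss + res$loss
    }
    tr_loss <- tr_loss / length(train_batches)
    val_loss <- NA_real_
    if (n_val > 0) {
      vl <- vapply(val_batches, function(b) {
        batch_loss(params, b, mcfg, std, lcfg, with_grad = FALSE)$loss
      }, 0)
      val_loss <- mean(vl)
      if (val_loss < best_val - 1e-9) {
        best_val <- val_loss
        best_params <- params
        best_epoch <- epoch
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
    }
    history[[epoch]] <- tibble(epoch = epoch, train_loss = tr_loss,
                               val_loss = val_loss)
    if (verbose) {
      cat(sprintf("epoch %3d  train %.4f  val %.4f\n", epoch, tr_loss,
                  val_loss))
    }
    if (n_val > 0 && stall >= patience) break
    lr_epoch <- lr_epoch * lr_decay
  }
  if (n_val == 0) {
    best_params <- params
    best_epoch <- length(history)
  }

  structure(list(params = best_params, mcfg = mcfg, fcfg = fcfg,
                 std = std, lcfg = lcfg,
                 history = bind_rows(history), best_epoch = best_epoch,
                 seed = seed,
                 feature_hash = feature_config_hash(fcfg)),
            class = "ss_fit")
}

#' @export
print.ss_fit <- function(x, ...) {
  np <- tree_reduce(x$params, length)
  cat("<ss_fit> spin-system GNN: ", np, " parameters, B=",
      x$mcfg$n_bootstraps, " bootstrap heads, best epoch ", x$best_epoch,
      "\n", sep = "")
  invisible(x)
}

#' Predict full spin systems with uncertainties
#'
#' Runs all bootstrap heads on the featurized molecules; predictions are
#' head means and uncertainties are sample standard deviations over heads.
#'
#' @param fit an `ss_fit`
#' @param graphs list of `ss_graph` objects, or the tibble from
#'   [featurize_molecules()]
#' @param channel which output channel to report: `"experimental"` or
#'   `"ab_initio"`
#' @param batch_size molecules per forward batch
#' @return an `ss_predictions` object: `$shifts` (molecule_id, atom_idx,
#'   nucleus, value_ppm, uncertainty_ppm) and `$couplings` (molecule_id,
#'   i, j, class, value_hz, uncertainty_hz); atom indices are 0-based and
#'   `i < j`
#' @export
predict_spin_systems <- function(fit, graphs,
                                 channel = c("experimental", "ab_initio"),
                                 batch_size = 64) {
  channel <- match.arg(channel)
  ch <- if (channel == "experimental") 1L else 2L
  if (fit$mcfg$n_channels == 1) ch <- 1L
  if (is.data.frame(graphs)) graphs <- graphs$graph[graphs$accepted]
  for (g in graphs) {
    if (!identical(g$config_hash, fit$feature_hash)) {
      abort("feature config hash mismatch between fit and graphs",
            class = "spinsys_error_hash")
    }
  }
  mcfg <- fit$mcfg
  b_heads <- mcfg$n_bootstraps
  chunks <- split(seq_along(graphs),
                  ceiling(seq_along(graphs) / batch_size))
  sh_rows <- list()
  cp_rows <- list()
  for (chunk in chunks) {
    batch <- build_batch(graphs[chunk], mcfg)
    fw <- spin_forward(fit$params, batch, mcfg, need_cache = FALSE)
    sv <- std_shift(fit$std, batch$nucleus)
    sh_heads <- vapply(seq_len(b_heads), function(b) {
      fw$shift[[b]][, ch] * sv$sd + sv$mu
    }, numeric(batch$m_tot))
    keep <- batch$nucleus > 0
    ep <- ensemble_predict(sh_heads[keep, , drop = FALSE])
    sh_rows[[length(sh_rows) + 1L]] <- tibble(
      molecule_id = batch$molecule_ids[batch$mol_of_vertex[keep]],
      atom_idx = (seq_len(batch$m_tot) -
                    batch$v_off[batch$mol_of_vertex] - 1L)[keep],
      nucleus = c("1H", "13C")[batch$nucleus[keep]],
      value_ppm = ep$value,
      uncertainty_ppm = ep$uncertainty
    )
    sel <- which(batch$use_loss)
    if (length(sel) > 0) {
      cls_sel <- batch$cls[sel]
      col <- (cls_sel - 1L) * mcfg$n_channels + ch
      sc <- std_coupling(fit$std, cls_sel)
      cp_heads <- vapply(seq_len(b_heads), function(b) {
        fw$coupling[[b]][cbind(sel, col)] * sc$sd + sc$mu
      }, numeric(length(sel)))
      if (length(sel) == 1) cp_heads <- matrix(cp_heads, nrow = 1)
      ep <- ensemble_predict(cp_heads)
      mo <- batch$mol_of_edge[sel]
      loc <- sel - batch$e_off[mo] - 1L
      nn <- batch$sizes[mo]
      cp_rows[[length(cp_rows) + 1L]] <- tibble(
        molecule_id = batch$molecule_ids[mo],
        i = loc %/% nn,
        j = loc %% nn,
        class = mcfg$coupling_classes[cls_sel],
        value_hz = ep$value,
        uncertainty_hz = ep$uncertainty
      )
    }
  }
  structure(list(shifts = bind_rows(sh_rows),
                 couplings = bind_rows(cp_rows) %|0|%
                   tibble(molecule_id = character(), i = integer(),
                          j = integer(), class = character(),
                          value_hz = numeric(),
                          uncertainty_hz = numeric())),
            class = "ss_predictions")
}

#' @export
print.ss_predictions <- function(x, ...) {
  cat("<ss_predictions> ", nrow(x$shifts), " shifts, ", nrow(x$couplings),
      " couplings across ",
      length(unique(c(x$shifts$molecule_id, x$couplings$molecule_id))),
      " molecules\n", sep = "")
  invisible(x)
}
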