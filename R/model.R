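# The spin-system GNN: configuration, initialization, forward and backward.

#' Model configuration
#'
#' @param hidden_dim width of the vertex hidden states
#' @param edge_dim width of the dense pairwise edge hidden state (the
#'   stacked adjacency + geometric features are lifted to this width before
#'   the first decode layer)
#' @param n_message_layers number of adjacency message passing layers
#' @param n_decode_layers number of GRU vertex/edge decode layers
#' @param adjacency_powers powers of the any-bond adjacency added to the
#'   message passing stack (subset of 1:4; 1 is the plain adjacency)
#' @param include_self_loops add an identity slice to the adjacency stack
#' @param aggregation reduction over the neighbor dimension feeding the
#'   vertex GRU: "mean" (default), "sum" or "max"
#' @param n_bootstraps number of bootstrap output heads B
#' @param p_include probability a head sees a given training molecule
#' @param head_hidden hidden width of each bootstrap head's residual block
#'   (multiplier on the head input width)
#' @param coupling_classes coupling classes predicted per edge
#' @param n_channels output channels per target (2 = experimental +
#'   ab initio, enabling disagreement regularization)
#' @param channel_coupling with two channels, parametrize the experimental
#'   output as ab initio + learned correction (see the methods vignette);
#'   FALSE gives two independent output columns
#' @param seed seed for weight initialization
#' @return a `ss_model_config`
#' @export
model_config <- function(hidden_dim = 64, edge_dim = 32,
                         n_message_layers = 2,
                         n_decode_layers = 2, adjacency_powers = c(1, 2, 3),
                         include_self_loops = TRUE,
                         aggregation = c("mean", "sum", "max"),
                         n_bootstraps = 4, p_include = 0.5,
                         head_hidden = 2,
                         coupling_classes = c("1JCH", "2JHH", "3JHH",
                                              "4JHH"),
                         n_channels = 2, channel_coupling = TRUE,
                         seed = 1) {
  aggregation <- match.arg(aggregation)
  stopifnot(hidden_dim >= 1, edge_dim >= 1, n_message_layers >= 0,
            n_decode_layers >= 0,
            all(adjacency_powers %in% 1:4), n_bootstraps >= 1,
            p_include > 0, p_include <= 1, n_channels >= 1)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 edge_dim = as.integer(edge_dim),
                 n_message_layers = as.integer(n_message_layers),
                 n_decode_layers = as.integer(n_decode_layers),
                 adjacency_powers = as.integer(adjacency_powers),
                 include_self_loops = include_self_loops,
                 aggregation = aggregation,
                 n_bootstraps = as.integer(n_bootstraps),
                 p_include = p_include,
                 head_hidden = head_hidden,
                 coupling_classes = coupling_classes,
                 n_channels = as.integer(n_channels),
                 channel_coupling = isTRUE(channel_coupling),
                 seed = as.integer(seed)),
            class = "ss_model_config")
}

#' Zero the experimental-correction (delta) output columns at init
#' @noRd
zero_delta_columns <- function(head, mcfg) {
  if (mcfg$n_channels == 2L && mcfg$channel_coupling) {
    idx_e <- seq(1L, ncol(head$w3), by = 2L)
    head$w3[, idx_e] <- 0
    head$b3[idx_e] <- 0
  }
  head
}

#' Residual channel coupling for two-channel readouts
#'
#' With two label channels, the raw head output holds the ab initio
#' prediction in each class's second column and a learned correction
#' (delta, zero-initialized) in the first; the reported experimental
#' channel is ab initio + delta.  Representation directions that carry no
#' experimental training signal therefore fall back to the ab initio
#' channel instead of staying at random initialization.
#' @noRd
channel_couple_fwd <- function(out, mcfg) {
  if (mcfg$n_channels != 2L || !mcfg$channel_coupling) return(out)
  idx_e <- seq(1L, ncol(out), by = 2L)
  out[, idx_e] <- out[, idx_e] + out[, idx_e + 1L]
  out
}

#' @noRd
channel_couple_bwd <- function(dout, mcfg) {
  if (mcfg$n_channels != 2L || !mcfg$channel_coupling) return(dout)
  idx_e <- seq(1L, ncol(dout), by = 2L)
  dout[, idx_e + 1L] <- dout[, idx_e + 1L] + dout[, idx_e]
  dout
}

#' @noRd
n_adj_slices <- function(mcfg) {
  5L + length(setdiff(mcfg$adjacency_powers, 1L)) +
    as.integer(mcfg$include_self_loops)
}

#' Initialize model parameters
#' @noRd
init_spin_params <- function(mcfg, fcfg) {
  d <- mcfg$hidden_dim
  e_d <- mcfg$edge_dim
  s <- n_adj_slices(mcfg)
  ge <- 5L + fcfg$f_e
  cc <- length(mcfg$coupling_classes) * mcfg$n_channels
  with_seed_(derive_seed(mcfg$seed, "init"), {
    list(
      vin = list(w = init_mat(fcfg$f_v, d), b = rep(0, d)),
      din = list(w = init_mat(fcfg$f_v, d), b = rep(0, d)),
      gin = list(w = init_mat(ge, e_d), b = rep(0, e_d)),
      mp = lapply(seq_len(mcfg$n_message_layers), function(l) {
        list(lift = lapply(seq_len(s), function(si) init_mat(d, d)),
             coll = init_mat(s * d, d), b = rep(0, d), ln = init_ln(d))
      }),
      dec = lapply(seq_len(mcfg$n_decode_layers), function(l) {
        list(gv = init_gru(3L * e_d, d), lnv = init_ln(d),
             pw1 = init_mat(d, e_d), pw2 = init_mat(d, e_d),
             pb = rep(0, e_d),
             ge = init_gru(e_d, e_d), lne = init_ln(e_d))
      }),
      heads = list(
        shift = lapply(seq_len(mcfg$n_bootstraps), function(b) {
          h <- init_head(2L * d, mcfg$n_channels,
                         hidden = round(mcfg$head_hidden * 2 * d))
          zero_delta_columns(h, mcfg)
        }),
        coupling = lapply(seq_len(mcfg$n_bootstraps), function(b) {
          h <- init_head(e_d, cc, hidden = round(mcfg$head_hidden * e_d))
          zero_delta_columns(h, mcfg)
        })
      )
    )
  })
}

#' Forward pass over a batch
#'
#' Runs the message passing stack and the decode stack on the same inputs,
#' concatenates their final vertex states for the per-head shift readout,
#' and feeds the final edge state to the per-head coupling readout.
#' Coupling outputs are exactly symmetrized by transpose-averaging.
#'
#' @return list(shift = list of B `M x n_channels` matrices (standardized),
#'   coupling = list of B `E x (n_classes*n_channels)` matrices, cache)
#' @noRd
spin_forward <- function(params, batch, mcfg, need_cache = FALSE,
                         engine = getOption("spinsys.engine", "cpp")) {
  if (engine == "cpp" && mcfg$aggregation != "max") {
    batch$agg_sp <- if (mcfg$aggregation == "mean") batch$agg_mean else
      batch$agg_sum
    batch$agg_bond_sp <- batch$agg_bond
    batch$agg_gem_sp <- batch$agg_gem
    fw <- cpp_model_forward(params, batch, mcfg, need_cache)
    fw$cache <- if (need_cache) list(handle = fw$handle) else NULL
    fw$handle <- NULL
    return(fw)
  }
  spin_forward_r(params, batch, mcfg, need_cache)
}

#' Reference R implementation of the forward pass
#' @noRd
spin_forward_r <- function(params, batch, mcfg, need_cache = FALSE) {
  cache <- if (need_cache) list() else NULL

  xv0 <- lin_fwd(batch$x, params$vin$w, params$vin$b)
  xd0 <- lin_fwd(batch$x, params$din$w, params$din$b)
  g0 <- lin_fwd(batch$edge_feat, params$gin$w, params$gin$b)

  # message passing stack
  xv <- xv0$out
  mp_caches <- vector("list", mcfg$n_message_layers)
  for (l in seq_len(mcfg$n_message_layers)) {
    p <- params$mp[[l]]
    lifts <- vector("list", length(batch$adj))
    msgs <- vector("list", length(batch$adj))
    for (si in seq_along(batch$adj)) {
      lifts[[si]] <- xv %*% p$lift[[si]]
      msgs[[si]] <- as.matrix(batch$adj[[si]] %*% lifts[[si]])
    }
    cat_m <- do.call(cbind, msgs)
    coll <- lin_fwd(cat_m, p$coll, p$b)
    act <- relu_fwd(coll$out)
    ln <- ln_fwd(act$out, p$ln$gamma, p$ln$beta)
    if (need_cache) {
      mp_caches[[l]] <- list(x_in = xv, coll = coll, act = act, ln = ln)
    }
    xv <- ln$out
  }

  # decode stack
  xd <- xd0$out
  g <- g0$out
  dec_caches <- vector("list", mcfg$n_decode_layers)
  for (l in seq_len(mcfg$n_decode_layers)) {
    p <- params$dec[[l]]
    agg <- agg_fwd(g, batch, mcfg$aggregation)
    gv <- gru_fwd(agg$out, xd, p$gv)
    av <- relu_fwd(gv$out)
    lnv <- ln_fwd(av$out, p$lnv$gamma, p$lnv$beta)
    xd_new <- lnv$out
    e_in <- cpp_pair_fwd(xd_new, p$pw1, p$pw2, p$pb, batch$e_i,
                         batch$e_j)
    gee <- gru_fwd(e_in, g, p$ge)
    sym <- cpp_sym(gee$out, batch$trans)
    ae <- relu_fwd(sym)
    lne <- ln_fwd(ae$out, p$lne$gamma, p$lne$beta)
    if (need_cache) {
      dec_caches[[l]] <- list(agg = agg, gv = gv, av = av, lnv = lnv,
                              gee = gee, ae = ae, lne = lne,
                              xd_new = xd_new)
    }
    xd <- xd_new
    g <- lne$out
  }

  vrep <- cbind(xv, xd)
  b_heads <- mcfg$n_bootstraps
  shift_out <- vector("list", b_heads)
  coupling_out <- vector("list", b_heads)
  sh_caches <- vector("list", b_heads)
  cp_caches <- vector("list", b_heads)
  for (b in seq_len(b_heads)) {
    hs <- head_fwd(vrep, params$heads$shift[[b]])
    shift_out[[b]] <- channel_couple_fwd(hs$out, mcfg)
    hc <- head_fwd(g, params$heads$coupling[[b]])
    coupling_out[[b]] <- channel_couple_fwd(cpp_sym(hc$out, batch$trans),
                                            mcfg)
    if (need_cache) {
      sh_caches[[b]] <- hs$cache
      cp_caches[[b]] <- hc$cache
    }
  }

  if (need_cache) {
    cache <- list(xv0 = xv0, xd0 = xd0, g0 = g0, mp = mp_caches,
                  dec = dec_caches, sh = sh_caches, cp = cp_caches,
                  vrep = vrep, g_final = g)
  }
  list(shift = shift_out, coupling = coupling_out, cache = cache)
}

#' Backward pass: gradients of a scalar loss wrt all parameters
#'
#' @param d_shift list of B `M x n_channels` gradients
#' @param d_coupling list of B `E x cc` gradients (wrt the symmetrized
#'   outputs)
#' @noRd
spin_backward <- function(d_shift, d_coupling, fw, params, batch, mcfg) {
  if (!is.null(fw$cache$handle)) {
    batch$agg_sp <- if (mcfg$aggregation == "mean") batch$agg_mean else
      batch$agg_sum
    batch$agg_bond_sp <- batch$agg_bond
    batch$agg_gem_sp <- batch$agg_gem
    raw <- cpp_model_backward(fw$cache$handle, params, batch, mcfg,
                              d_shift, d_coupling)
    return(normalize_grads(params, raw))
  }
  spin_backward_r(d_shift, d_coupling, fw, params, batch, mcfg)
}

#' Coerce the C++ gradient list onto the parameter tree (shapes, zeros for
#' heads that received no gradient)
#' @noRd
normalize_grads <- function(params, raw) {
  walk <- function(p, g) {
    if (is.list(p)) {
      out <- vector("list", length(p))
      names(out) <- names(p)
      for (k in seq_along(p)) {
        nm <- names(p)[k]
        gk <- if (is.null(g)) NULL else if (!is.null(nm) && nzchar(nm)) {
          g[[nm]]
        } else {
          g[[k]]
        }
        out[[k]] <- walk(p[[k]], gk)
      }
      out
    } else if (is.null(g)) {
      p * 0
    } else if (is.matrix(p)) {
      matrix(g, nrow(p), ncol(p))
    } else {
      as.numeric(g)
    }
  }
  walk(params, raw)
}

#' Reference R implementation of the backward pass
#' @noRd
spin_backward_r <- function(d_shift, d_coupling, fw, params, batch, mcfg) {
  cache <- fw$cache
  d <- mcfg$hidden_dim
  grads <- tree_zeros(params)

  dvrep <- matrix(0, batch$m_tot, 2L * d)
  dg <- matrix(0, batch$e_tot, mcfg$edge_dim)
  for (b in seq_len(mcfg$n_bootstraps)) {
    if (!is.null(d_shift[[b]])) {
      hb <- head_bwd(channel_couple_bwd(d_shift[[b]], mcfg),
                     cache$sh[[b]])
      dvrep <- dvrep + hb$dx
      grads$heads$shift[[b]] <- tree_map2(grads$heads$shift[[b]], hb$dp, `+`)
    }
    if (!is.null(d_coupling[[b]])) {
      draw <- cpp_sym(channel_couple_bwd(d_coupling[[b]], mcfg),
                      batch$trans)
      hb <- head_bwd(draw, cache$cp[[b]])
      dg <- dg + hb$dx
      grads$heads$coupling[[b]] <-
        tree_map2(grads$heads$coupling[[b]], hb$dp, `+`)
    }
  }

  dxv <- dvrep[, seq_len(d), drop = FALSE]
  dxd <- dvrep[, d + seq_len(d), drop = FALSE]

  # decode stack, reverse
  for (l in rev(seq_len(mcfg$n_decode_layers))) {
    p <- params$dec[[l]]
    cc <- cache$dec[[l]]
    gl <- grads$dec[[l]]

    lb <- ln_bwd(dg, cc$lne$cache)
    gl$lne$gamma <- gl$lne$gamma + lb$dgamma
    gl$lne$beta <- gl$lne$beta + lb$dbeta
    dae <- relu_bwd(lb$dx, cc$ae$cache)
    dgee_out <- cpp_sym(dae, batch$trans)
    gb <- gru_bwd(dgee_out, cc$gee$cache)
    gl$ge <- tree_map2(gl$ge, gb$dp, `+`)
    de_in <- gb$du
    dg_prev <- gb$dh

    pg <- cpp_pair_bwd(de_in, cc$xd_new, p$pw1, p$pw2, batch$e_i,
                       batch$e_j, batch$m_tot)
    dxd <- dxd + pg$dx
    gl$pw1 <- gl$pw1 + pg$dw1
    gl$pw2 <- gl$pw2 + pg$dw2
    gl$pb <- gl$pb + as.numeric(pg$db)

    lv <- ln_bwd(dxd, cc$lnv$cache)
    gl$lnv$gamma <- gl$lnv$gamma + lv$dgamma
    gl$lnv$beta <- gl$lnv$beta + lv$dbeta
    dav <- relu_bwd(lv$dx, cc$av$cache)
    gv <- gru_bwd(dav, cc$gv$cache)
    gl$gv <- tree_map2(gl$gv, gv$dp, `+`)
    du <- gv$du
    dxd <- gv$dh
    dg_prev <- dg_prev +
      agg_bwd(du, batch$e_tot, batch, mcfg$aggregation, cc$agg$cache)

    grads$dec[[l]] <- gl
    dg <- dg_prev
  }

  # message passing stack, reverse
  for (l in rev(seq_len(mcfg$n_message_layers))) {
    p <- params$mp[[l]]
    cc <- cache$mp[[l]]
    gl <- grads$mp[[l]]
    lb <- ln_bwd(dxv, cc$ln$cache)
    gl$ln$gamma <- gl$ln$gamma + lb$dgamma
    gl$ln$beta <- gl$ln$beta + lb$dbeta
    dact <- relu_bwd(lb$dx, cc$act$cache)
    cb <- lin_bwd(dact, cc$coll$cache)
    gl$coll <- gl$coll + cb$dw
    gl$b <- gl$b + cb$db
    dcat <- cb$dx
    dx_in <- matrix(0, batch$m_tot, d)
    for (si in seq_along(batch$adj)) {
      dmsg <- dcat[, (si - 1L) * d + seq_len(d), drop = FALSE]
      dlift <- as.matrix(Matrix::crossprod(batch$adj[[si]], dmsg))
      gl$lift[[si]] <- gl$lift[[si]] + crossprod(cc$x_in, dlift)
      dx_in <- dx_in + dlift %*% t(p$lift[[si]])
    }
    grads$mp[[l]] <- gl
    dxv <- dx_in
  }

  vb <- lin_bwd(dxv, cache$xv0$cache)
  grads$vin$w <- grads$vin$w + vb$dw
  grads$vin$b <- grads$vin$b + vb$db
  db <- lin_bwd(dxd, cache$xd0$cache)
  grads$din$w <- grads$din$w + db$dw
  grads$din$b <- grads$din$b + db$db
  gb <- lin_bwd(dg, cache$g0$cache)
  grads$gin$w <- grads$gin$w + gb$dw
  grads$gin$b <- grads$gin$b + gb$db

  grads
}
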