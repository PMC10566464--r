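# Neural-network primitives with hand-derived reverse-mode gradients.
#
# Each *_fwd returns list(out, cache); the matching *_bwd consumes the
# upstream gradient and the cache.  The dense kernels live in
# src/spinsys_ops.cpp (Armadillo); the wrappers here keep the cache
# contracts so every backward pass is verifiable against central finite
# differences from R (see the gradient tests).

#' @noRd
add_bias <- function(m, b) m + b[col(m)]

#' @noRd
lin_fwd <- function(x, w, b) {
  list(out = cpp_lin(x, w, b), cache = list(x = x, w = w))
}

#' @noRd
lin_bwd <- function(dout, cache) {
  list(dx = dout %*% t(cache$w),
       dw = crossprod(cache$x, dout),
       db = colSums(dout))
}

#' @noRd
relu_fwd <- function(x) {
  r <- cpp_relu_fwd(x)
  list(out = r$out, cache = r$mask)
}

#' @noRd
relu_bwd <- function(dout, cache) cpp_relu_bwd(dout, cache)

#' Per-row layer normalization with learned gain/offset
#' @noRd
ln_fwd <- function(x, gamma, beta, eps = 1e-5) {
  r <- cpp_ln_fwd(x, gamma, beta, eps)
  list(out = r$out,
       cache = list(xhat = r$xhat, inv = r$inv, gamma = gamma))
}

#' @noRd
ln_bwd <- function(dout, cache) {
  r <- cpp_ln_bwd(dout, cache$xhat, cache$inv, cache$gamma)
  list(dx = r$dx, dgamma = as.numeric(r$dgamma),
       dbeta = as.numeric(r$dbeta))
}

#' @noRd
sigmoid_ <- function(x) 1 / (1 + exp(-x))

#' Gated recurrent unit cell applied row-wise
#'
#' u: n x d_in input, h: n x d hidden state.  Gate weights are stored
#' merged (`w_all` = [Wz | Wr | Wn] on the input, `u_zr` = [Uz | Ur] on the
#' hidden state, `un` on the reset-gated hidden state).
#' @noRd
gru_fwd <- function(u, h, p) {
  r <- cpp_gru_fwd(u, h, p$w_all, p$u_zr, p$un, p$b_all)
  list(out = r$out,
       cache = list(u = u, h = h, z = r$z, r = r$r, rh = r$rh, nn = r$nn,
                    p = p))
}

#' @noRd
gru_bwd <- function(dout, cache) {
  p <- cache$p
  g <- cpp_gru_bwd(dout, cache$u, cache$h, cache$z, cache$r, cache$rh,
                   cache$nn, p$w_all, p$u_zr, p$un)
  list(du = g$du, dh = g$dh,
       dp = list(w_all = g$dw_all, u_zr = g$du_zr, un = g$dun,
                 b_all = as.numeric(g$db_all)))
}

#' Residual block + linear output head
#' @noRd
head_fwd <- function(x, p) {
  r <- cpp_head_fwd(x, p$w1, p$b1, p$w2, p$b2, p$w3, p$b3)
  list(out = r$out, cache = list(x = x, r1 = r$r1, res = r$res, p = p))
}

#' @noRd
head_bwd <- function(dout, cache) {
  p <- cache$p
  g <- cpp_head_bwd(dout, cache$x, cache$r1, cache$res, p$w1, p$w2, p$w3)
  list(dx = g$dx,
       dp = list(w1 = g$dw1, b1 = as.numeric(g$db1),
                 w2 = g$dw2, b2 = as.numeric(g$db2),
                 w3 = g$dw3, b3 = as.numeric(g$db3)))
}

# ---- parameter initializers -------------------------------------------------

#' @noRd
init_mat <- function(n_in, n_out) {
  matrix(rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))), n_in, n_out)
}

#' @noRd
init_gru <- function(d_in, d) {
  list(w_all = cbind(init_mat(d_in, d), init_mat(d_in, d),
                     init_mat(d_in, d)),
       u_zr = cbind(init_mat(d, d), init_mat(d, d)),
       un = init_mat(d, d),
       b_all = rep(0, 3 * d))
}

#' @noRd
init_head <- function(d_in, d_out, hidden = d_in) {
  list(w1 = init_mat(d_in, hidden), b1 = rep(0, hidden),
       w2 = init_mat(hidden, d_in) * 0.1, b2 = rep(0, d_in),
       w3 = init_mat(d_in, d_out), b3 = rep(0, d_out))
}

#' @noRd
init_ln <- function(d) list(gamma = rep(1, d), beta = rep(0, d))
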