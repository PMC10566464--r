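# Gradient correctness: every backward pass against central finite
# differences, and C++/R engine agreement on the full model gradient.

fd_check <- function(loss_fn, params_flat, grad_flat, n_probe = 20,
                     eps = 1e-5, tol = 1e-5, kink_fraction = 0) {
  set.seed(99)
  idx <- sample(length(params_flat), min(n_probe, length(params_flat)))
  num <- vapply(idx, function(k) {
    p1 <- params_flat
    p1[k] <- p1[k] + eps
    p2 <- params_flat
    p2[k] <- p2[k] - eps
    (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
  }, 0)
  rel <- abs(num - grad_flat[idx]) /
    pmax(1e-6, abs(num) + abs(grad_flat[idx]))
  if (kink_fraction > 0) {
    # a loss with ReLU/absolute-value kinks has isolated points where the
    # central difference straddles the kink; allow a small fraction of
    # probes to land there, but the bulk must match tightly
    expect_gte(mean(rel < tol), 1 - kink_fraction)
    expect_lt(stats::median(rel), tol)
  } else {
    expect_lt(max(rel), tol)
  }
}

test_that("GRU cell gradients match finite differences", {
  set.seed(1)
  n <- 7; din <- 5; d <- 4
  u <- matrix(rnorm(n * din), n)
  h <- matrix(rnorm(n * d), n)
  p <- spinsys:::init_gru(din, d)
  w <- matrix(rnorm(n * d), n)  # random projection to a scalar loss
  loss_of <- function(pv) {
    pp <- spinsys:::tree_unflatten(p, pv)
    sum(w * spinsys:::gru_fwd(u, h, pp)$out)
  }
  fw <- spinsys:::gru_fwd(u, h, p)
  bw <- spinsys:::gru_bwd(w, fw$cache)
  fd_check(loss_of, spinsys:::tree_flatten(p),
           spinsys:::tree_flatten(bw$dp), n_probe = 25)
  # input gradients
  fd_u <- vapply(1:5, function(k) {
    u1 <- u; u1[k] <- u1[k] + 1e-5
    u2 <- u; u2[k] <- u2[k] - 1e-5
    (sum(w * spinsys:::gru_fwd(u1, h, p)$out) -
       sum(w * spinsys:::gru_fwd(u2, h, p)$out)) / 2e-5
  }, 0)
  expect_equal(as.numeric(bw$du)[1:5], fd_u, tolerance = 1e-6)
})

test_that("layer norm gradients match finite differences", {
  set.seed(2)
  n <- 6; d <- 5
  x <- matrix(rnorm(n * d), n)
  gamma <- runif(d, 0.5, 1.5)
  beta <- rnorm(d)
  w <- matrix(rnorm(n * d), n)
  fw <- spinsys:::ln_fwd(x, gamma, beta)
  bw <- spinsys:::ln_bwd(w, fw$cache)
  fd_x <- vapply(1:8, function(k) {
    x1 <- x; x1[k] <- x1[k] + 1e-6
    x2 <- x; x2[k] <- x2[k] - 1e-6
    (sum(w * spinsys:::ln_fwd(x1, gamma, beta)$out) -
       sum(w * spinsys:::ln_fwd(x2, gamma, beta)$out)) / 2e-6
  }, 0)
  expect_equal(as.numeric(bw$dx)[1:8], fd_x, tolerance = 1e-4)
  fd_g <- vapply(1:d, function(k) {
    g1 <- gamma; g1[k] <- g1[k] + 1e-6
    g2 <- gamma; g2[k] <- g2[k] - 1e-6
    (sum(w * spinsys:::ln_fwd(x, g1, beta)$out) -
       sum(w * spinsys:::ln_fwd(x, g2, beta)$out)) / 2e-6
  }, 0)
  expect_equal(bw$dgamma, fd_g, tolerance = 1e-5)
})

test_that("full-model loss gradient matches finite differences (R engine)", {
  fx <- small_fixtures()
  mcfg <- model_config(hidden_dim = 8, edge_dim = 6, n_message_layers = 1,
                       n_decode_layers = 1, n_bootstraps = 2, seed = 3)
  fcfg <- feature_config(n_conformers = 3)
  b <- spinsys:::build_batch(fx$graph[1:3], mcfg)
  b <- spinsys:::attach_labels(b, fx$shifts[1:3], fx$couplings[1:3])
  std <- spinsys:::compute_standardization(list(b))
  # huber base: smooth a.e., so central differences are stable (the l1
  # path is covered by the engine-equivalence test below)
  lcfg <- spinsys:::loss_config(lambda = 5, base = "huber")
  params <- spinsys:::init_spin_params(mcfg, fcfg)
  bs <- spinsys:::bootstrap_matrix(b$molecule_ids, 2, 0.5, 7)
  withr::local_options(spinsys.engine = "r")
  res <- spinsys:::batch_loss(params, b, mcfg, std, lcfg, bs_inc = bs,
                              with_grad = TRUE)
  loss_of <- function(pv) {
    spinsys:::batch_loss(spinsys:::tree_unflatten(params, pv), b, mcfg,
                         std, lcfg, bs_inc = bs)$loss
  }
  fd_check(loss_of, spinsys:::tree_flatten(params),
           spinsys:::tree_flatten(res$grads), n_probe = 25, tol = 1e-4,
           kink_fraction = 0.1)
})

test_that("C++ and R engines agree on loss and every parameter gradient", {
  fx <- small_fixtures()
  mcfg <- model_config(hidden_dim = 12, edge_dim = 8, n_bootstraps = 3,
                       seed = 4)
  fcfg <- feature_config(n_conformers = 3)
  b <- spinsys:::build_batch(fx$graph[1:5], mcfg)
  b <- spinsys:::attach_labels(b, fx$shifts[1:5], fx$couplings[1:5])
  std <- spinsys:::compute_standardization(list(b))
  lcfg <- spinsys:::loss_config(lambda = 2)
  params <- spinsys:::init_spin_params(mcfg, fcfg)
  bs <- spinsys:::bootstrap_matrix(b$molecule_ids, 3, 0.5, 1)
  withr::local_options(spinsys.engine = "cpp")
  rc <- spinsys:::batch_loss(params, b, mcfg, std, lcfg, bs_inc = bs,
                             with_grad = TRUE)
  withr::local_options(spinsys.engine = "r")
  rr <- spinsys:::batch_loss(params, b, mcfg, std, lcfg, bs_inc = bs,
                             with_grad = TRUE)
  expect_equal(rc$loss, rr$loss, tolerance = 1e-12)
  expect_equal(spinsys:::tree_flatten(rc$grads),
               spinsys:::tree_flatten(rr$grads), tolerance = 1e-10)
})
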