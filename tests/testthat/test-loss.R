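# Disagreement-regularized loss: rules, limits, exact reductions.

test_that("single-channel entries use the base loss on that channel", {
  # only experimental label
  expect_equal(disagreement_loss(pred_a = 0, pred_e = 3, phi_a = NA,
                                 phi_e = 5, lambda = 5), 2)
  # only ab initio label
  expect_equal(disagreement_loss(pred_a = 1, pred_e = 99, phi_a = 4,
                                 phi_e = NA, lambda = 5), 3)
  expect_error(disagreement_loss(0, 0, NA, NA, lambda = 1),
               class = "spinsys_error_labels")
  expect_error(disagreement_loss(0, 0, 1, 1, lambda = -1),
               class = "spinsys_error_lambda")
})

test_that("dual-labeled entries weight the experimental channel by agreement", {
  # perfect agreement: w = lambda / (0 + 1) = lambda
  l <- disagreement_loss(pred_a = 1, pred_e = 2, phi_a = 3, phi_e = 3,
                         lambda = 5)
  expect_equal(l, abs(1 - 3) + 5 * abs(2 - 3))
  # huge disagreement: weight -> 0, loss -> L_a
  l_inf <- disagreement_loss(pred_a = 1, pred_e = 2, phi_a = 3,
                             phi_e = 3 + 1e9, lambda = 5)
  expect_equal(l_inf, abs(1 - 3) + 5 / (1e9 + 1) * abs(2 - 3 - 1e9))
  # lambda = 0 reduces exactly to ab-initio-only on dual-labeled entries
  set.seed(8)
  pa <- rnorm(20); pe <- rnorm(20); fa <- rnorm(20); fe <- rnorm(20)
  expect_identical(disagreement_loss(pa, pe, fa, fe, lambda = 0),
                   mean(abs(pa - fa)))
})

test_that("the experimental weight is continuous and monotone in |phi_a - phi_e|", {
  gaps <- seq(0, 10, by = 0.01)
  losses <- vapply(gaps, function(g) {
    disagreement_loss(pred_a = 0, pred_e = 1, phi_a = 0, phi_e = g + 1,
                      lambda = 5)
  }, 0)
  # weight = lambda / (|phi_a - phi_e| + 1) with |phi_a - phi_e| = g + 1
  w <- 5 / (gaps + 2)
  expect_equal(losses, 0 + w * abs(1 - (gaps + 1)), tolerance = 1e-12)
  # continuity: no jumps on a fine grid
  expect_lt(max(abs(diff(w))), 0.06)
  # monotone decreasing weight
  expect_true(all(diff(w) <= 0))
})

test_that("internal two-channel loss matches the reference form and grads", {
  set.seed(11)
  n <- 30
  pred <- matrix(rnorm(2 * n), n)
  targ <- matrix(rnorm(2 * n, sd = 3), n)
  targ[sample(n, 5), 1] <- NA
  targ[sample(n, 5), 2] <- NA
  keep <- !(is.na(targ[, 1]) & is.na(targ[, 2]))
  pred <- pred[keep, ]; targ <- targ[keep, ]
  raw <- targ  # loss and agreement weight read the same labels here
  res <- spinsys:::channel_loss_grad(pred, targ, raw, lambda = 3,
                                     offset = 1)
  # against the exported reference (note channel order: col1 = exp)
  expect_equal(res$loss,
               disagreement_loss(pred[, 2], pred[, 1], raw[, 2], raw[, 1],
                                 lambda = 3, offset = 1))
  # finite-difference gradient
  for (k in sample(length(pred), 8)) {
    p1 <- pred; p1[k] <- p1[k] + 1e-6
    p2 <- pred; p2[k] <- p2[k] - 1e-6
    fd <- (spinsys:::channel_loss_grad(p1, targ, raw, 3, 1)$loss -
             spinsys:::channel_loss_grad(p2, targ, raw, 3, 1)$loss) / 2e-6
    expect_equal(res$grad[k], fd, tolerance = 1e-5)
  }
})

test_that("huber base loss is selectable and behaves at the crossover", {
  expect_equal(disagreement_loss(0, 0.5, NA, 1, lambda = 1,
                                 base = "huber"), 0.125)
  expect_equal(disagreement_loss(0, -2, NA, 1, lambda = 1,
                                 base = "huber"), 2.5)
})
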