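# Bootstrap-head assignment and ensemble prediction.

test_that("bootstrap subsets are deterministic, nonempty and respect B", {
  expect_equal(assign_bootstraps("m1", b = 1), 1L)
  s1 <- assign_bootstraps("molA", b = 10, p_include = 0.5, seed = 3)
  s2 <- assign_bootstraps("molA", b = 10, p_include = 0.5, seed = 3)
  expect_identical(s1, s2)
  expect_gt(length(s1), 0)
  expect_true(all(s1 %in% 1:10))
  # different molecules get different subsets (overwhelmingly)
  subsets <- lapply(sprintf("mol%03d", 1:30), assign_bootstraps, b = 10,
                    p_include = 0.5, seed = 3)
  expect_gt(length(unique(subsets)), 5)
  # tiny p still yields a nonempty subset (forced fallback)
  expect_gt(length(assign_bootstraps("x", b = 5, p_include = 1e-6)), 0)
})

test_that("head inclusion frequency matches p_include over many molecules", {
  b <- 10
  ids <- sprintf("id%05d", 1:10000)
  inc <- spinsys:::bootstrap_matrix(ids, b, 0.5, seed = 17)
  frac <- colMeans(inc)
  expect_true(all(abs(frac - 0.5) < 0.02))
})

test_that("subset mean and ensemble prediction match direct computation", {
  expect_equal(subset_train_prediction(c(1, 3, 100), c(1, 2)), 2)
  expect_equal(subset_train_prediction(c(7, 1, 2), 2L), 1)
  expect_error(subset_train_prediction(c(1, 2), integer()),
               class = "spinsys_error_subset")
  set.seed(5)
  m <- matrix(rnorm(40), 8, 5)
  sub <- c(2, 4, 5)
  expect_equal(subset_train_prediction(m, sub),
               apply(m[, sub], 1, mean))

  ep <- ensemble_predict(matrix(c(1, 2, 3), 1))
  expect_equal(ep$value, 2)
  expect_equal(ep$uncertainty, 1)  # sample SD of {1,2,3}
  # identical heads give SD exactly 0
  same <- ensemble_predict(matrix(4.2, 3, 6))
  expect_identical(same$uncertainty, rep(0, 3))
  # B = 1 collapses to a single model with zero uncertainty
  one <- ensemble_predict(matrix(rnorm(5), 5, 1))
  expect_identical(one$uncertainty, rep(0, 5))
  # invariant to head ordering
  ep2 <- ensemble_predict(m[, sample(5)])
  expect_equal(sort(ep2$value), sort(ensemble_predict(m)$value))
})

test_that("out-of-distribution inputs carry higher mean uncertainty", {
  # hold out every sulfur-containing molecule from training: sulfur's
  # one-hot direction is then untrained, and once the model is converged
  # on the in-distribution chemistry, head disagreement is higher on the
  # unseen element composition
  fx <- cached("ood_fixtures", {
    generate_fixtures(fixture_spec(n_molecules = 130, seed = 77,
                                   n_conformers = 3))
  })
  has_s <- vapply(fx$molecule, function(m) any(m$atoms$element == "S"),
                  TRUE)
  train <- fx[!has_s, ]
  ood <- fx[has_s, ]
  expect_gte(nrow(ood), 10)
  n_tr <- nrow(train)
  mcfg <- model_config(hidden_dim = 24, edge_dim = 12, n_bootstraps = 4,
                       seed = 9)
  fit <- train_spin_model(train[seq_len(n_tr - 12), ], mcfg,
                          feature_config(n_conformers = 3),
                          epochs = 300, lr = 2e-3, lr_decay = 0.99,
                          seed = 4, val_fraction = 0)
  pred_in <- predict_spin_systems(fit, train$graph[(n_tr - 11):n_tr])
  pred_ood <- predict_spin_systems(fit, ood$graph)
  expect_gt(mean(pred_ood$shifts$uncertainty_ppm),
            mean(pred_in$shifts$uncertainty_ppm))
})
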