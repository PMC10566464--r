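# Training loop: learning, determinism, memorization, prediction plumbing.

test_that("a tiny model reduces the training loss and is seed-deterministic", {
  fx <- small_fixtures()
  mcfg <- model_config(hidden_dim = 12, edge_dim = 8, n_message_layers = 1,
                       n_decode_layers = 1, n_bootstraps = 2, seed = 1)
  fcfg <- feature_config(n_conformers = 3)
  fit1 <- train_spin_model(fx, mcfg, fcfg, epochs = 6, seed = 4,
                           val_fraction = 0.1)
  h <- tidy(fit1)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  fit2 <- train_spin_model(fx, mcfg, fcfg, epochs = 6, seed = 4,
                           val_fraction = 0.1)
  expect_identical(tidy(fit1), tidy(fit2))
  expect_identical(spinsys:::tree_flatten(fit1$params),
                   spinsys:::tree_flatten(fit2$params))
  g <- glance(fit1)
  expect_equal(g$n_bootstraps, 2)
  expect_gt(g$n_parameters, 0)
})

test_that("a tiny model can memorize a 10-molecule training set", {
  fx <- small_fixtures()[1:10, ]
  # experimental channel only: the memorization target is unambiguous
  fx$shifts <- lapply(fx$shifts, function(s) {
    dplyr::mutate(s, ab = NA_real_)
  })
  mcfg <- model_config(hidden_dim = 32, edge_dim = 16,
                       n_message_layers = 1, n_decode_layers = 1,
                       n_bootstraps = 1, seed = 2)
  fcfg <- feature_config(n_conformers = 3)
  fit <- train_spin_model(fx, mcfg, fcfg, epochs = 300, lr = 3e-3,
                          lr_decay = 0.995, seed = 7, val_fraction = 0,
                          coupling_weight = 0.2)
  ev <- evaluate_spin_model(fit, fx)
  sh <- ev$errors[ev$errors$kind == "shift", ]
  lab_sd <- sd(sh$reference)
  expect_lt(mean(abs(sh$error)), 0.05 * lab_sd)
})

test_that("non-finite losses abort with a named diagnostic", {
  fx <- small_fixtures()[1:8, ]
  mcfg <- model_config(hidden_dim = 8, edge_dim = 6, n_bootstraps = 1,
                       seed = 3)
  # an infinite learning rate destroys the parameters after one update,
  # so the next batch loss is non-finite and the guard must fire
  expect_error(
    train_spin_model(fx, mcfg, feature_config(n_conformers = 3),
                     epochs = 3, lr = Inf, seed = 1, val_fraction = 0),
    class = "spinsys_error_divergence"
  )
})

test_that("predictions are tidy, typed and hash-guarded", {
  fx <- small_fixtures()
  mcfg <- model_config(hidden_dim = 12, edge_dim = 8, n_bootstraps = 3,
                       seed = 5)
  fcfg <- feature_config(n_conformers = 3)
  fit <- train_spin_model(fx[1:20, ], mcfg, fcfg, epochs = 2, seed = 3,
                          val_fraction = 0)
  pred <- predict_spin_systems(fit, fx$graph[21:24])
  expect_s3_class(pred$shifts, "tbl_df")
  expect_true(all(pred$shifts$nucleus %in% c("1H", "13C")))
  expect_true(all(pred$couplings$i < pred$couplings$j))
  expect_true(all(pred$shifts$uncertainty_ppm >= 0))
  # every labeled nucleus of every molecule is predicted
  n_expected <- sum(vapply(fx$molecule[21:24], function(m) {
    sum(m$atoms$element %in% c("H", "C"))
  }, 0))
  expect_equal(nrow(pred$shifts), n_expected)
  # graphs built under a different feature config are refused
  g_alt <- molecule_graph(fx$molecule[[25]], fx$ensemble[[25]],
                          feature_config(n_conformers = 3,
                                         gauss_sigma = 0.7))
  expect_error(predict_spin_systems(fit, list(g_alt)),
               class = "spinsys_error_hash")
})

test_that("the evaluation report joins predictions and labels per class", {
  fx <- small_fixtures()
  mcfg <- model_config(hidden_dim = 12, edge_dim = 8, n_bootstraps = 2,
                       seed = 8)
  fcfg <- feature_config(n_conformers = 3)
  fit <- train_spin_model(fx[1:25, ], mcfg, fcfg, epochs = 2, seed = 3,
                          val_fraction = 0)
  ev <- evaluate_spin_model(fit, fx[26:40, ])
  expect_s3_class(ev, "ss_eval")
  expect_true(all(c("1H", "13C") %in% ev$metrics$parameter))
  expect_true(all(ev$metrics$mae > 0))
  expect_equal(tidy(ev), ev$metrics)
  # plots build without error
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(plot_prediction_scatter(ev), "ggplot")
})
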