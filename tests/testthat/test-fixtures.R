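# Synthetic fixture generator: determinism, label-model structure,
# channel semantics, region flags.

test_that("fixture generation is deterministic given the spec", {
  s <- fixture_spec(n_molecules = 12, seed = 77, n_conformers = 3)
  f1 <- generate_fixtures(s)
  f2 <- generate_fixtures(s)
  expect_identical(f1$smiles, f2$smiles)
  expect_identical(dplyr::bind_rows(f1$shifts), dplyr::bind_rows(f2$shifts))
  expect_identical(dplyr::bind_rows(f1$couplings),
                   dplyr::bind_rows(f2$couplings))
})

test_that("zero noise and zero offset make both channels equal the mean", {
  s <- fixture_spec(n_molecules = 6, seed = 5, n_conformers = 3,
                    noise_shift = c("1H" = 0, "13C" = 0),
                    noise_coupling = c("1JCH" = 0, "2JHH" = 0,
                                       "3JHH" = 0, "4JHH" = 0),
                    ab_offset = c("1H" = 0, "13C" = 0),
                    ab_sigma = c("1H" = 0, "13C" = 0))
  fx <- generate_fixtures(s)
  sh <- dplyr::bind_rows(fx$shifts)
  expect_equal(sh$exp, sh$mean, tolerance = 1e-12)
  expect_equal(sh$ab, sh$mean, tolerance = 1e-12)
  cp <- dplyr::bind_rows(fx$couplings)
  expect_equal(cp$exp, cp$mean, tolerance = 1e-12)
})

test_that("the ab initio channel carries the configured systematic offset", {
  s <- fixture_spec(n_molecules = 8, seed = 6, n_conformers = 3,
                    ab_offset = c("1H" = 0.7, "13C" = 3),
                    ab_sigma = c("1H" = 0, "13C" = 0))
  fx <- generate_fixtures(s)
  sh <- dplyr::bind_rows(fx$shifts)
  h <- sh[sh$nucleus == "1H", ]
  expect_equal(h$ab - h$mean, rep(0.7, nrow(h)), tolerance = 1e-12)
  c13 <- sh[sh$nucleus == "13C", ]
  expect_equal(c13$ab - c13$mean, rep(3, nrow(c13)), tolerance = 1e-12)
})

test_that("3JHH labels follow the Karplus cosine of the stored geometry", {
  fx <- small_fixtures()
  # recompute every label mean from the stored ensemble: must be exact
  for (r in seq_len(4)) {
    means <- fixture_label_means(fx$graph[[r]], fx$ensemble[[r]])
    stored <- fx$couplings[[r]]
    merged <- dplyr::inner_join(means$couplings, stored,
                                by = c("i", "j", "class"))
    expect_equal(merged$mean.x, merged$mean.y, tolerance = 1e-12)
    j3 <- merged[merged$class == "3JHH", ]
    if (nrow(j3) > 0) {
      # invert the Karplus form: J must lie within its attainable range
      kp <- spinsys:::karplus_coefficients
      theta <- seq(0, pi, length.out = 200)
      jr <- range(kp["A"] * cos(theta)^2 + kp["B"] * cos(theta) + kp["C"])
      expect_true(all(j3$mean.x >= jr[1] - 1e-9 &
                        j3$mean.x <= jr[2] + 1e-9))
    }
  }
})

test_that("region flags track small-ring membership and ratios", {
  s <- fixture_spec(n_molecules = 20, ring_fraction = 0.5, seed = 9,
                    n_conformers = 3)
  fx <- generate_fixtures(s)
  expect_equal(sum(fx$region == "small_ring"), 10)
  for (r in seq_len(nrow(fx))) {
    has_small <- any(fx$molecule[[r]]$atoms$ring3 == 1 |
                       fx$molecule[[r]]$atoms$ring4 == 1)
    expect_equal(fx$region[r] == "small_ring", has_small)
  }
})

test_that("infeasible specs are rejected", {
  expect_error(fixture_spec(n_molecules = 5, ring_fraction = 1,
                            size_range = c(1, 2)),
               class = "spinsys_error_spec")
})

test_that("heteroscedastic mode scales shift noise for the N/S population", {
  s <- fixture_spec(n_molecules = 60, seed = 33, n_conformers = 3,
                    heteroscedastic = TRUE, hetero_factor = 4)
  fx <- generate_fixtures(s)
  sh <- dplyr::bind_rows(purrr::map2(fx$shifts, fx$hetero,
                                     ~dplyr::mutate(.x, hetero = .y)))
  h <- sh[sh$nucleus == "1H", ]
  res <- abs(h$exp - h$mean)
  expect_gt(mean(res[h$hetero]), 2 * mean(res[!h$hetero]))
})
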