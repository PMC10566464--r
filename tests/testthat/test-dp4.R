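# DP4 stereoisomer ranking.

test_that("degenerate candidate sets behave as forced", {
  ref <- c(1.2, 3.4, 77)
  nuc <- c("1H", "1H", "13C")
  # single candidate
  one <- dp4_probability(list(ref + 0.1), ref, nuc,
                         dp4_params(correction = "none"))
  expect_equal(one$probability, 1)
  # identical candidates split evenly
  two <- dp4_probability(list(ref + 0.3, ref + 0.3), ref, nuc,
                         dp4_params(correction = "none"))
  expect_equal(two$probability, c(0.5, 0.5))
  expect_equal(sum(two$probability), 1, tolerance = 1e-12)
})

test_that("DP4 matches an independent t-density-product oracle", {
  # hand-sized case: 3 protons, 2 candidates, no expectation correction
  ref <- c(1.0, 2.0, 3.0)
  nuc <- rep("1H", 3)
  cand <- list(c(1.1, 1.9, 3.2), c(1.4, 2.5, 2.4))
  p <- dp4_params(correction = "none")
  got <- dp4_probability(cand, ref, nuc, p)
  # oracle: direct product of cumulative tail probabilities
  lik <- vapply(cand, function(cc) {
    prod(1 - pt(abs(cc - ref) / p$`1H`$sigma, df = p$`1H`$nu))
  }, 0)
  expect_equal(got$probability, lik / sum(lik), tolerance = 1e-9)
  # mixed nuclei multiply across classes
  ref2 <- c(1.0, 30)
  nuc2 <- c("1H", "13C")
  cand2 <- list(c(1.2, 32), c(0.8, 25))
  got2 <- dp4_probability(cand2, ref2, nuc2, p)
  lik2 <- vapply(cand2, function(cc) {
    (1 - pt(abs(cc[1] - ref2[1]) / p$`1H`$sigma, df = p$`1H`$nu)) *
      (1 - pt(abs(cc[2] - ref2[2]) / p$`13C`$sigma, df = p$`13C`$nu))
  }, 0)
  expect_equal(got2$probability, lik2 / sum(lik2), tolerance = 1e-9)
})

test_that("probabilities are invariant to candidate order and likelihood scale", {
  set.seed(12)
  ref <- rnorm(8, 3)
  nuc <- rep("1H", 8)
  cands <- lapply(1:4, function(k) ref + rnorm(8, sd = 0.3))
  p1 <- dp4_probability(cands, ref, nuc)$probability
  p2 <- dp4_probability(rev(cands), ref, nuc)$probability
  expect_equal(p1, rev(p2), tolerance = 1e-12)
})

test_that("a common additive error does not change ranking under rescale", {
  set.seed(13)
  ref <- rnorm(10, 4, 1.5)
  nuc <- rep("1H", 10)
  cands <- lapply(1:3, function(k) ref + rnorm(10, sd = 0.2 * k))
  base <- dp4_probability(cands, ref, nuc,
                          dp4_params(correction = "linear-rescale"))
  shifted <- dp4_probability(lapply(cands, `+`, 0.7), ref, nuc,
                             dp4_params(correction = "linear-rescale"))
  expect_equal(order(-base$probability), order(-shifted$probability))
  expect_equal(base$probability, shifted$probability, tolerance = 1e-6)
})

test_that("mismatched atom sets are rejected", {
  expect_error(dp4_probability(list(c(1, 2)), c(1, 2, 3), rep("1H", 3)),
               class = "spinsys_error_mismatch")
  expect_error(dp4_probability(list(c(1, 2)), c(1, 2), c("1H", "19F")),
               class = "spinsys_error_nucleus")
})

test_that("stereoisomer enumeration counts follow the center count and cap", {
  achiral <- enumerate_stereoisomers("CCO")
  expect_equal(nrow(achiral), 1)
  two <- enumerate_stereoisomers("C[C@H](F)[C@H](Cl)C")
  expect_equal(nrow(two), 4)
  expect_equal(two$smiles[1],
               parse_smiles("C[C@H](F)[C@H](Cl)C")$molecule[[1]]$smiles)
  many <- enumerate_stereoisomers("C[C@H](F)[C@H](Cl)[C@H](N)CO")
  expect_equal(nrow(many), 8)  # 2^3 capped at the default 8
  capped <- enumerate_stereoisomers("C[C@H](F)[C@H](Cl)C",
                                    max_candidates = 2)
  expect_equal(nrow(capped), 2)
})

test_that("extreme errors stay numerically well defined in log space", {
  ref <- c(1, 2)
  # t tails are polynomial, so even enormous errors keep finite
  # log-likelihoods; equal errors split evenly and larger errors lose
  far <- list(ref + 1e6, ref - 1e6, ref + 2e6)
  got <- dp4_probability(far, ref, rep("1H", 2),
                         dp4_params(correction = "none"))
  expect_false(any(is.na(got$probability)))
  expect_equal(sum(got$probability), 1, tolerance = 1e-12)
  expect_equal(got$probability[1], got$probability[2], tolerance = 1e-9)
  expect_lt(got$probability[3], got$probability[1])
  # infinite errors do trip the uniform fallback
  expect_warning(
    u <- dp4_probability(list(c(Inf, Inf), c(Inf, Inf)), ref,
                         rep("1H", 2), dp4_params(correction = "none")),
    "uniform"
  )
  expect_equal(u$probability, c(0.5, 0.5))
})
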