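# Network core: coupling masks, layer mechanics, shape contracts,
# permutation equivariance, engine equivalence.

test_that("coupling class masks match hand counts on reference molecules", {
  tb <- parse_smiles(c("CC", "C", "c1ccccc1"))
  eth <- coupling_class_masks(tb$molecule[[1]])
  expect_equal(sum(eth$`1JCH`) / 2, 6)
  expect_equal(sum(eth$`2JHH`) / 2, 6)   # 3 per methyl
  expect_equal(sum(eth$`3JHH`) / 2, 9)   # 3 x 3 across the C-C bond
  meth <- coupling_class_masks(tb$molecule[[2]])
  expect_equal(sum(meth$`2JHH`) / 2, choose(4, 2))
  expect_equal(sum(meth$`3JHH`), 0)
  benz <- coupling_class_masks(tb$molecule[[3]])
  expect_equal(sum(benz$`3JHH`) / 2, 6)  # ortho proton pairs only
})

test_that("coupling masks agree with a brute-force BFS oracle", {
  fx <- small_fixtures()
  set.seed(7)
  for (r in sample(nrow(fx), 8)) {
    mol <- fx$molecule[[r]]
    pl <- bfs_path_lengths(mol)
    is_h <- mol$atoms$element == "H"
    is_c <- mol$atoms$element == "C"
    masks <- coupling_class_masks(mol)
    expect_equal(masks$`1JCH`,
                 (outer(is_c, is_h) | outer(is_h, is_c)) & pl == 1)
    for (k in 2:4) {
      expect_equal(masks[[paste0(k, "JHH")]],
                   outer(is_h, is_h, `&`) & pl == k)
    }
    # masks are symmetric and mutually exclusive
    overlap <- Reduce(`+`, lapply(masks, function(m) m * 1))
    expect_true(all(overlap <= 1))
  }
})

test_that("adjacency power slices connect k-bond neighbors", {
  # path A-B-C: the squared any-bond adjacency has entry (A, C) = 1
  mol <- hand_molecule(c("O", "C", "O"), rbind(c(0, 1, 1), c(1, 2, 1)))
  a <- build_adjacency(mol)[, , "any"]
  a2 <- a %*% a
  expect_equal(a2[1, 3], 1)
  expect_equal(a2[1, 2], 0)
  # message passing by matrix multiplication: one-hot on A propagates to B
  x <- c(1, 0, 0)
  expect_equal(as.numeric(a %*% x), c(0, 1, 0))
  # batch builder exposes the same powers block-diagonally
  mcfg <- model_config(adjacency_powers = c(1, 2))
  fx <- small_fixtures()
  g <- fx$graph[[1]]
  b <- spinsys:::build_batch(list(g), mcfg)
  expect_equal(as.matrix(b$adj$pow2),
               unname(g$g_adj[, , 1] %*% g$g_adj[, , 1]),
               ignore_attr = TRUE)
})

test_that("forward pass honors shape contracts and degenerate inputs", {
  fx <- small_fixtures()
  mcfg <- model_config(hidden_dim = 16, edge_dim = 8, n_bootstraps = 2,
                       seed = 2)
  fcfg <- feature_config(n_conformers = 3)
  params <- spinsys:::init_spin_params(mcfg, fcfg)
  b <- spinsys:::build_batch(fx$graph[1:3], mcfg)
  fw <- spinsys:::spin_forward(params, b, mcfg)
  expect_length(fw$shift, 2)
  expect_equal(dim(fw$shift[[1]]), c(b$m_tot, 2))
  expect_equal(dim(fw$coupling[[1]]), c(b$e_tot, 8))
  # coupling outputs exactly symmetric under the pair transpose
  for (h in 1:2) {
    expect_identical(fw$coupling[[h]], fw$coupling[[h]][b$trans, ])
  }
  # single-atom molecule: valid output, no couplings defined
  mol1 <- hand_molecule("H")
  ens1 <- hand_ensemble(list(matrix(0, 1, 3)))
  g1 <- molecule_graph(mol1, ens1, fcfg)
  b1 <- spinsys:::build_batch(list(g1), mcfg)
  fw1 <- spinsys:::spin_forward(params, b1, mcfg)
  expect_equal(nrow(fw1$shift[[1]]), 1)
  expect_equal(sum(b1$use_loss), 0)
})

test_that("deterministic forward: same params + input give identical output", {
  fx <- small_fixtures()
  mcfg <- model_config(hidden_dim = 16, edge_dim = 8, n_bootstraps = 2,
                       seed = 2)
  params <- spinsys:::init_spin_params(mcfg, feature_config())
  b <- spinsys:::build_batch(fx$graph[1:2], mcfg)
  f1 <- spinsys:::spin_forward(params, b, mcfg)
  f2 <- spinsys:::spin_forward(params, b, mcfg)
  expect_identical(f1$shift, f2$shift)
  expect_identical(f1$coupling, f2$coupling)
})

test_that("C++ and R engines produce identical forward outputs", {
  fx <- small_fixtures()
  mcfg <- model_config(hidden_dim = 16, edge_dim = 8, n_bootstraps = 2,
                       seed = 5)
  params <- spinsys:::init_spin_params(mcfg, feature_config())
  b <- spinsys:::build_batch(fx$graph[1:4], mcfg)
  fc <- spinsys:::spin_forward(params, b, mcfg, engine = "cpp")
  fr <- spinsys:::spin_forward(params, b, mcfg, engine = "r")
  for (h in 1:2) {
    expect_equal(fc$shift[[h]], fr$shift[[h]], tolerance = 1e-12)
    expect_equal(fc$coupling[[h]], fr$coupling[[h]], tolerance = 1e-12)
  }
})

test_that("stereoisomers with identical topology get different predictions", {
  cfg <- feature_config(n_conformers = 8)
  fx <- featurize_molecules(c("C/C=C/C(F)CO", "C/C=C\\C(F)CO"), cfg,
                            seed = 4)
  expect_true(all(fx$accepted))
  g1 <- fx$graph[[1]]
  g2 <- fx$graph[[2]]
  # same topology-derived inputs ...
  expect_equal(g1$x, g2$x)
  expect_equal(g1$g_adj, g2$g_adj)
  # ... different geometry features
  expect_gt(max(abs(g1$g_feat - g2$g_feat)), 0.05)
  mcfg <- model_config(hidden_dim = 16, edge_dim = 8, n_bootstraps = 1,
                       seed = 6)
  params <- spinsys:::init_spin_params(mcfg, cfg)
  f1 <- spinsys:::spin_forward(params, spinsys:::build_batch(list(g1), mcfg),
                               mcfg)
  f2 <- spinsys:::spin_forward(params, spinsys:::build_batch(list(g2), mcfg),
                               mcfg)
  expect_gt(max(abs(f1$shift[[1]] - f2$shift[[1]])), 0)
})

test_that("aggregation variants run and differ", {
  fx <- small_fixtures()
  outs <- lapply(c("mean", "sum", "max"), function(agg) {
    mcfg <- model_config(hidden_dim = 8, edge_dim = 8, n_bootstraps = 1,
                        aggregation = agg, seed = 3)
    params <- spinsys:::init_spin_params(mcfg, feature_config())
    b <- spinsys:::build_batch(fx$graph[1:2], mcfg)
    spinsys:::spin_forward(params, b, mcfg)$shift[[1]]
  })
  expect_gt(max(abs(outs[[1]] - outs[[2]])), 1e-8)
  expect_gt(max(abs(outs[[1]] - outs[[3]])), 1e-8)
})
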