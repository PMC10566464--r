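# Featurization: vertex features, adjacency stack, Boltzmann weights,
# geometric pair features, and their invariances.

test_that("vertex features encode element, valence, charge and rings", {
  cfg <- feature_config()
  tb <- parse_smiles(c("C", "c1ccccc1", "[NH4+]"))
  x_meth <- build_vertex_features(tb$molecule[[1]], cfg)
  expect_equal(dim(x_meth), c(5, cfg$f_v))
  c_row <- x_meth[tb$molecule[[1]]$atoms$element == "C", ]
  expect_equal(unname(c_row["total_valence"]), 4)
  expect_equal(unname(c_row["elem_C"]), 1)

  benz <- tb$molecule[[2]]
  x_benz <- build_vertex_features(benz, cfg)
  carbons <- benz$atoms$element == "C"
  expect_true(all(x_benz[carbons, "aromatic"] == 1))
  expect_true(all(x_benz[carbons, "ring6"] == 1))

  amm <- tb$molecule[[3]]
  x_amm <- build_vertex_features(amm, cfg)
  expect_equal(unname(x_amm[amm$atoms$element == "N", "formal_charge"]), 1)

  # f_v identical across molecules
  expect_equal(ncol(x_meth), ncol(x_benz))
})

test_that("adjacency stack has the documented slice semantics", {
  tb <- parse_smiles(c("CC", "c1ccccc1", "C=C", "C#C"))
  eth <- build_adjacency(tb$molecule[[1]])
  expect_equal(sum(eth[, , "any"]), 14)  # 7 bonds, symmetric
  # single-bond-order molecule: slices 2..5 partition slice 1
  expect_equal(eth[, , "any"],
               eth[, , "single"] + eth[, , "double"] + eth[, , "triple"] +
                 eth[, , "aromatic"])
  benz <- build_adjacency(tb$molecule[[2]])
  expect_equal(sum(benz[, , "aromatic"]), 12)  # 6 aromatic ring bonds
  expect_equal(sum(build_adjacency(tb$molecule[[3]])[, , "double"]), 2)
  expect_equal(sum(build_adjacency(tb$molecule[[4]])[, , "triple"]), 2)
  # symmetric with zero diagonal, binary entries
  for (s in 1:5) {
    expect_equal(benz[, , s], t(benz[, , s]))
    expect_true(all(diag(benz[, , s]) == 0))
    expect_true(all(benz[, , s] %in% c(0, 1)))
  }
})

test_that("Boltzmann weights match the closed form and its invariances", {
  expect_equal(boltzmann_weights(5), 1)
  expect_equal(boltzmann_weights(c(3, 3)), c(0.5, 0.5))
  # Delta E = RT ln 2  =>  weights 2/3, 1/3
  rt <- 1.987204258e-3 * 298.15
  w <- boltzmann_weights(c(0, rt * log(2)))
  expect_equal(w, c(2 / 3, 1 / 3), tolerance = 1e-12)
  # invariant to constant energy shifts
  e <- c(0.3, 1.7, 0.9)
  expect_equal(boltzmann_weights(e), boltzmann_weights(e + 123.4),
               tolerance = 1e-12)
  expect_error(boltzmann_weights(numeric()), class = "spinsys_error_empty")
})

test_that("pair features match direct evaluation on hand-built geometry", {
  cfg <- feature_config(gauss_centers = c(1, 2, 3), gauss_sigma = 0.5)
  # two-conformer 'diatomic': distances 1 and 3 at weights 1/2, 1/2
  mol <- hand_molecule(c("H", "H"), cbind(0, 1, 1))
  ens <- hand_ensemble(list(rbind(c(0, 0, 0), c(1, 0, 0)),
                            rbind(c(0, 0, 0), c(3, 0, 0))))
  gf <- build_pair_features(mol, ens, cfg)
  expect_equal(unname(gf[1, 2, "mean_dist"]), 2)
  expect_equal(unname(gf[1, 1, "mean_dist"]), 0)
  # Gaussian basis: mean over conformers of exp(-(d - c)^2 / (2 sigma^2))
  for (g in 1:3) {
    expected <- mean(exp(-(c(1, 3) - c(1, 2, 3)[g])^2 / (2 * 0.25)))
    expect_equal(unname(gf[1, 2, 1 + g]), expected, tolerance = 1e-12)
  }
  # single-conformer distance 2.0 with centers 1,2,3: e^-2, 1, e^-2
  ens1 <- hand_ensemble(list(rbind(c(0, 0, 0), c(2, 0, 0))))
  gf1 <- build_pair_features(mol, ens1, cfg)
  expect_equal(unname(gf1[1, 2, 2:4]), c(exp(-2), 1, exp(-2)),
               tolerance = 1e-12)
})

test_that("angle features: linear triatomic has angle pi at terminal pair", {
  mol <- hand_molecule(c("O", "C", "O"), rbind(c(0, 1, 2), c(1, 2, 2)))
  ens <- hand_ensemble(list(rbind(c(-1.2, 0, 0), c(0, 0, 0),
                                  c(1.2, 0, 0))))
  gf <- build_pair_features(mol, ens)
  expect_equal(unname(gf[1, 3, "angle"]), pi, tolerance = 1e-9)
  expect_equal(unname(gf[1, 3, "angle_flag"]), 1)
  expect_equal(unname(gf[1, 2, "angle_flag"]), 0)  # bonded pair, no common neighbor
  expect_equal(gf[, , "angle"], t(gf[, , "angle"]))
})

test_that("featurization is equivariant under atom relabeling", {
  fx <- small_fixtures()
  set.seed(42)
  for (r in sample(nrow(fx), 5)) {
    mol <- fx$molecule[[r]]
    ens <- fx$ensemble[[r]]
    cfg <- feature_config(n_conformers = 3)
    n <- n_atoms(mol)
    perm <- sample(n)
    # build the permuted molecule + ensemble by hand
    atoms_p <- mol$atoms[perm, ]
    atoms_p$atom_idx <- seq_len(n) - 1L
    inv <- match(seq_len(n), perm)
    bonds_p <- tibble::tibble(i = inv[mol$bonds$i + 1L] - 1L,
                              j = inv[mol$bonds$j + 1L] - 1L,
                              order = mol$bonds$order)
    mol_p <- new_molecule(atoms_p, bonds_p, molecule_id = "perm",
                          smiles = mol$smiles)
    ens_p <- ens
    ens_p$coords <- ens$coords[, perm, , drop = FALSE]
    expect_equal(build_vertex_features(mol_p, cfg),
                 build_vertex_features(mol, cfg)[perm, ])
    expect_equal(build_adjacency(mol_p),
                 build_adjacency(mol)[perm, perm, ])
    expect_equal(build_pair_features(mol_p, ens_p, cfg),
                 build_pair_features(mol, ens, cfg)[perm, perm, ])
  }
})

test_that("conformer generation is deterministic and validates inputs", {
  mol <- parse_smiles("CCO")$molecule[[1]]
  e1 <- generate_conformers(mol, n_conformers = 3, seed = 9)
  e2 <- generate_conformers(mol, n_conformers = 3, seed = 9)
  expect_identical(e1$coords, e2$coords)
  expect_identical(e1$weights, e2$weights)
  expect_equal(sum(e1$weights), 1, tolerance = 1e-9)
  expect_error(generate_conformers(mol, n_conformers = 0))
})

test_that("flexible molecules show multimodal end-to-end distances", {
  # butane: anti vs gauche C1-C4 distances are distinct torsional modes
  mol <- parse_smiles("CCCC")$molecule[[1]]
  ens <- generate_conformers(mol, n_conformers = 50, seed = 3)
  carbons <- which(mol$atoms$element == "C")
  d14 <- apply(ens$coords, 1, function(xyz) {
    sqrt(sum((xyz[carbons[1], ] - xyz[carbons[4], ])^2))
  })
  modes <- unique(floor(d14 / 0.5))
  expect_gte(length(modes), 2)
})
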