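# Synthetic fixture generation: molecules from a small fragment grammar and
# spin-system labels from a smooth, deterministic function of the molecular
# graph and its conformer geometry.
#
# The label model is intentionally simple but physically shaped: proton and
# carbon shifts are linear in local electronic/topological descriptors
# (Gasteiger charge, aromaticity, heteroatom neighbors, small-ring
# membership) plus a geometric long-range term; vicinal proton couplings are
# Boltzmann ensemble averages of a Karplus-style cosine of the conformer
# dihedrals, so conformer-ensemble features are genuinely informative; the
# remaining coupling classes are smooth functions of mean distances/angles.  Two label channels are produced: the
# experimental channel adds sampling noise to the mean, the ab initio
# channel adds a systematic offset plus (small) noise to the mean.

#' Fixture generation specification
#'
#' @param n_molecules number of accepted molecules to generate
#' @param size_range heavy-atom count range (inclusive)
#' @param ring_fraction fraction of molecules carrying a 3- or 4-membered
#'   carbocycle (the "small ring" region)
#' @param stereo_fraction fraction of molecules with an explicit
#'   stereocenter
#' @param n_conformers conformers per molecule for geometry features and
#'   geometric label terms
#' @param noise_shift named experimental shift noise SD (ppm) per nucleus
#' @param noise_coupling named experimental coupling noise SD (Hz) per class
#' @param heteroscedastic if TRUE, molecules containing N or S get their
#'   experimental *shift* noise scaled by `hetero_factor` (a predictable
#'   high-noise subpopulation for uncertainty calibration studies;
#'   coupling noise stays homoscedastic so coupling noise floors remain
#'   well defined)
#' @param hetero_factor noise multiplier for the heteroatom subpopulation
#' @param ab_channel generate the ab initio label channel
#' @param ab_offset systematic ab-initio-minus-experimental offset per
#'   nucleus (ppm)
#' @param ab_region_extra additional offset applied in the small-ring
#'   region (ppm)
#' @param ab_sigma ab initio channel noise SD per nucleus (ppm)
#' @param seed master seed; generation is fully deterministic given the spec
#' @return a `ss_fixture_spec`
#' @export
fixture_spec <- function(n_molecules = 200, size_range = c(3, 7),
                         ring_fraction = 0.25, stereo_fraction = 0,
                         n_conformers = 5,
                         noise_shift = c("1H" = 0.08, "13C" = 0.8),
                         noise_coupling = c("1JCH" = 0.5, "2JHH" = 0.3,
                                            "3JHH" = 0.5, "4JHH" = 0.1),
                         heteroscedastic = FALSE, hetero_factor = 3,
                         ab_channel = TRUE,
                         ab_offset = c("1H" = 0.7, "13C" = 3),
                         ab_region_extra = c("1H" = 0, "13C" = 0),
                         ab_sigma = c("1H" = 0.03, "13C" = 0.3),
                         seed = 1) {
  stopifnot(n_molecules >= 1, length(size_range) == 2,
            size_range[1] >= 1, size_range[2] >= size_range[1],
            ring_fraction >= 0, ring_fraction <= 1,
            stereo_fraction >= 0, stereo_fraction <= 1)
  if (ring_fraction > 0 && size_range[2] < 3) {
    abort("ring_fraction > 0 needs a size range allowing >= 3 heavy atoms",
          class = "spinsys_error_spec")
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 size_range = as.integer(size_range),
                 ring_fraction = ring_fraction,
                 stereo_fraction = stereo_fraction,
                 n_conformers = as.integer(n_conformers),
                 noise_shift = noise_shift,
                 noise_coupling = noise_coupling,
                 heteroscedastic = heteroscedastic,
                 hetero_factor = hetero_factor,
                 ab_channel = ab_channel, ab_offset = ab_offset,
                 ab_region_extra = ab_region_extra, ab_sigma = ab_sigma,
                 seed = as.integer(seed)),
            class = "ss_fixture_spec")
}

#' Sample one SMILES string from the fragment grammar
#' @noRd
sample_fixture_smiles <- function(k, ring, stereo) {
  chain_pool <- c("C", "C", "C", "C", "O", "N", "S")
  sub_pool <- c("F", "Cl", "O", "N", "C")
  tokens <- character()
  remaining <- k
  if (ring) {
    ring_n <- if (remaining >= 4 && runif(1) < 0.5) 4L else 3L
    tokens <- c(tokens, if (ring_n == 3L) "C1CC1" else "C1CCC1")
    remaining <- remaining - ring_n
  }
  if (remaining > 0) {
    atoms <- c("C", sample(chain_pool, max(0, remaining - 1),
                           replace = TRUE))
    atoms <- atoms[seq_len(remaining)]
    # at most one branch, on a mid-chain carbon
    branch_at <- 0L
    if (remaining >= 3 && runif(1) < 0.5) {
      carbons <- which(atoms == "C")
      carbons <- carbons[carbons > 1 & carbons < remaining]
      if (length(carbons) > 0) branch_at <- sample(carbons, 1)
    }
    for (t in seq_len(remaining)) {
      if (stereo && t == branch_at) {
        tokens <- c(tokens, paste0("[C@H](", sample(c("F", "Cl"), 1), ")"))
      } else if (t == branch_at) {
        tokens <- c(tokens, paste0("C(", sample(sub_pool, 1), ")"))
      } else {
        tokens <- c(tokens, atoms[t])
      }
    }
  }
  paste(tokens, collapse = "")
}

#' @noRd
fixture_smiles_batch <- function(spec, n_ring, n_plain, round_seed) {
  with_seed_(round_seed, {
    ring_flags <- c(rep(TRUE, n_ring), rep(FALSE, n_plain))
    vapply(ring_flags, function(rg) {
      k <- sample(seq(max(spec$size_range[1], if (rg) 3L else 1L),
                      spec$size_range[2]), 1)
      stereo <- runif(1) < spec$stereo_fraction
      sample_fixture_smiles(k, rg, stereo)
    }, character(1))
  })
}

#' Dihedral angle (radians, in [0, pi]) between planes p1-p2-p3 and p2-p3-p4
#' @noRd
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  x <- sum(n1 * n2)
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  y <- sum(m1 * n2)
  abs(atan2(y, x))
}

#' Boltzmann-weighted mean |dihedral| over an ensemble (1-based indices)
#' @noRd
mean_dihedral <- function(ens, i1, i2, i3, i4) {
  k <- dim(ens$coords)[1]
  th <- 0
  for (c_i in seq_len(k)) {
    th <- th + ens$weights[c_i] *
      dihedral_angle(ens$coords[c_i, i1, ], ens$coords[c_i, i2, ],
                     ens$coords[c_i, i3, ], ens$coords[c_i, i4, ])
  }
  th
}

#' Boltzmann-weighted ensemble average of the Karplus coupling: the
#' conformer-wise J(theta) averaged with the population weights, which is
#' what the NMR experiment observes (parameters average over conformers,
#' not geometries)
#' @noRd
karplus_ensemble <- function(ens, i1, i2, i3, i4, kp) {
  k <- dim(ens$coords)[1]
  j <- 0
  for (c_i in seq_len(k)) {
    th <- dihedral_angle(ens$coords[c_i, i1, ], ens$coords[c_i, i2, ],
                         ens$coords[c_i, i3, ], ens$coords[c_i, i4, ])
    j <- j + ens$weights[c_i] *
      (kp["A"] * cos(th)^2 + kp["B"] * cos(th) + kp["C"])
  }
  unname(j)
}

# Karplus-style coefficients for the synthetic 3JHH label model (Hz)
karplus_coefficients <- c(A = 7.76, B = -1.1, C = 1.4)

#' Noiseless label means for one featurized molecule
#'
#' Returns the deterministic shift means (ppm) and coupling means (Hz) of
#' the synthetic label model, computed from the molecular graph and its
#' conformer ensemble.
#'
#' @param graph an `ss_graph`
#' @param ens the `ss_conformers` ensemble the graph was built from
#' @return list(shifts = tibble(atom_idx, nucleus, mean),
#'   couplings = tibble(i, j, class, mean)); indices 0-based, i < j
#' @export
fixture_label_means <- function(graph, ens) {
  mol <- graph$molecule
  a <- mol$atoms
  nbrs <- neighbor_list(mol)
  heavy <- a$element != "H"
  ring34 <- (a$ring3 | a$ring4) * 1
  n_on <- vapply(seq_len(nrow(a)), function(v) {
    sum(a$element[nbrs[[v]]] %in% c("O", "N"))
  }, 0)
  n_heavy_nb <- vapply(seq_len(nrow(a)), function(v) {
    sum(heavy[nbrs[[v]]])
  }, 0)

  # geometric term: Boltzmann-weighted mean distance to the farthest
  # atom.  It makes shift labels genuinely conformation- and
  # stereochemistry-dependent (diastereomers differ; enantiomers, whose
  # internal coordinates are identical, do not -- as in a real spectrum)
  r_far <- apply(matrix(graph$g_feat[, , "mean_dist"], nrow(a)), 1, max)

  sh <- list()
  for (v in seq_len(nrow(a))) {
    if (a$element[v] == "H") {
      nb <- nbrs[[v]][1]
      mu <- 1.0 + 16 * a$gasteiger[v] + 1.2 * (a$aromatic[nb] * 1) +
        0.6 * n_on[nb] - 1.2 * ring34[nb] + 0.35 * r_far[v]
      sh[[length(sh) + 1L]] <- tibble(atom_idx = v - 1L, nucleus = "1H",
                                      mean = mu)
    } else if (a$element[v] == "C") {
      mu <- 15 + 220 * a$gasteiger[v] + 105 * (a$aromatic[v] * 1) +
        9 * n_heavy_nb[v] + 14 * n_on[v] - 22 * ring34[v] + 3 * r_far[v]
      sh[[length(sh) + 1L]] <- tibble(atom_idx = v - 1L, nucleus = "13C",
                                      mean = mu)
    }
  }

  masks <- graph$pair_masks
  mean_dist <- graph$g_feat[, , "mean_dist"]
  angle <- graph$g_feat[, , "angle"]
  kp <- karplus_coefficients
  cp <- list()
  for (cl in names(masks)) {
    pairs <- which(masks[[cl]] & upper.tri(masks[[cl]]), arr.ind = TRUE)
    if (nrow(pairs) == 0) next
    mu <- vapply(seq_len(nrow(pairs)), function(r) {
      i <- pairs[r, 1]
      j <- pairs[r, 2]
      if (cl == "3JHH") {
        ai <- nbrs[[i]][1]
        aj <- nbrs[[j]][1]
        karplus_ensemble(ens, i, ai, aj, j, kp)
      } else if (cl == "2JHH") {
        -10.5 + 8 * (angle[i, j] - 1.9)
      } else if (cl == "1JCH") {
        h <- if (a$element[i] == "H") i else j
        c_at <- if (h == i) j else i
        124 + 180 * a$gasteiger[c_at] + 500 * (1.093 - mean_dist[i, j])
      } else {
        1.2 * exp(-1.5 * (mean_dist[i, j] - 2.5))
      }
    }, 0)
    cp[[cl]] <- tibble(i = pairs[, 1] - 1L, j = pairs[, 2] - 1L,
                       class = cl, mean = unname(mu))
  }
  list(shifts = bind_rows(sh), couplings = bind_rows(cp) %|0|%
         tibble(i = integer(), j = integer(), class = character(),
                mean = numeric()))
}

#' Generate a labeled synthetic fixture set
#'
#' Assembles molecules from a fragment grammar (chains with optional
#' branches and substituents over C/O/N/S/F/Cl, optionally fused to a 3- or
#' 4-membered carbocycle, optionally with a stereocenter), featurizes them,
#' and attaches two-channel spin-system labels from the deterministic label
#' model plus configurable noise.  Fully deterministic given the spec.
#'
#' @param spec a [fixture_spec()]
#' @param config a [feature_config()] (its `n_conformers` is overridden by
#'   the spec)
#' @return a tibble of labeled examples: `molecule_id`, `smiles`, `region`
#'   ("small_ring"/"big_ring"), `hetero` (noise subpopulation flag), and
#'   list-columns `molecule`, `ensemble`, `graph`, `shifts`, `couplings`.
#'   Label tibbles carry `exp`, `ab` channels plus the noiseless `mean`.
#' @export
generate_fixtures <- function(spec = fixture_spec(),
                              config = feature_config()) {
  config$n_conformers <- spec$n_conformers
  n_ring <- round(spec$ring_fraction * spec$n_molecules)
  n_plain <- spec$n_molecules - n_ring
  got_ring <- list()
  got_plain <- list()
  round_i <- 0L
  while ((length(got_ring) < n_ring || length(got_plain) < n_plain) &&
           round_i < 20L) {
    round_i <- round_i + 1L
    need_r <- n_ring - length(got_ring)
    need_p <- n_plain - length(got_plain)
    smiles <- fixture_smiles_batch(spec, ceiling(need_r * 1.3) + 1L,
                                   ceiling(need_p * 1.3) + 1L,
                                   derive_seed(spec$seed,
                                               paste0("round", round_i)))
    fx <- featurize_molecules(smiles, config,
                              n_conformers = spec$n_conformers,
                              seed = derive_seed(spec$seed,
                                                 paste0("emb", round_i)))
    fx <- fx[fx$accepted, ]
    if (nrow(fx) == 0) next
    is_ring <- vapply(fx$molecule, function(m) {
      any(m$atoms$ring3 == 1 | m$atoms$ring4 == 1)
    }, TRUE)
    for (r in seq_len(nrow(fx))) {
      if (is_ring[r] && length(got_ring) < n_ring) {
        got_ring[[length(got_ring) + 1L]] <- fx[r, ]
      } else if (!is_ring[r] && length(got_plain) < n_plain) {
        got_plain[[length(got_plain) + 1L]] <- fx[r, ]
      }
    }
  }
  if (length(got_ring) < n_ring || length(got_plain) < n_plain) {
    abort("fixture generation could not satisfy the spec (infeasible?)",
          class = "spinsys_error_spec")
  }
  fx <- bind_rows(c(got_ring, got_plain))
  fx$molecule_id <- sprintf("fix%05d_%s", seq_len(nrow(fx)),
                            substr(vapply(fx$smiles, rlang::hash, ""), 1, 6))
  for (r in seq_len(nrow(fx))) {
    fx$graph[[r]]$molecule_id <- fx$molecule_id[r]
  }
  fx$region <- ifelse(vapply(fx$molecule, function(m) {
    any(m$atoms$ring3 == 1 | m$atoms$ring4 == 1)
  }, TRUE), "small_ring", "big_ring")
  fx$hetero <- vapply(fx$molecule, function(m) {
    any(m$atoms$element %in% c("N", "S"))
  }, TRUE)

  labs <- purrr::map(seq_len(nrow(fx)), function(r) {
    fixture_labels_one(fx$graph[[r]], fx$ensemble[[r]],
                       fx$region[r] == "small_ring", fx$hetero[r], spec)
  })
  fx$shifts <- purrr::map(labs, "shifts")
  fx$couplings <- purrr::map(labs, "couplings")
  fx[, c("molecule_id", "smiles", "region", "hetero", "molecule",
         "ensemble", "graph", "shifts", "couplings")]
}

#' @noRd
fixture_labels_one <- function(graph, ens, small_ring, hetero, spec) {
  means <- fixture_label_means(graph, ens)
  sh <- means$shifts
  cp <- means$couplings
  fac <- if (spec$heteroscedastic && hetero) spec$hetero_factor else 1
  with_seed_(derive_seed(spec$seed, paste0("lab_", graph$molecule_id)), {
    sh$exp <- sh$mean +
      rnorm(nrow(sh)) * unname(spec$noise_shift[sh$nucleus]) * fac
    if (spec$ab_channel) {
      off <- unname(spec$ab_offset[sh$nucleus]) +
        if (small_ring) unname(spec$ab_region_extra[sh$nucleus]) else 0
      sh$ab <- sh$mean + off +
        rnorm(nrow(sh)) * unname(spec$ab_sigma[sh$nucleus])
    } else {
      sh$ab <- NA_real_
    }
    cp$exp <- cp$mean +
      rnorm(nrow(cp)) * unname(spec$noise_coupling[cp$class])
    cp$ab <- NA_real_
  })
  list(shifts = sh, couplings = cp)
}
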