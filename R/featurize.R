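# Featurization: per-vertex features, adjacency stack, conformer-ensemble
# geometric pair features.

#' Featurization configuration
#'
#' Controls the feature blocks fed to the network.  The geometric pair
#' features are: Boltzmann-weighted mean interatomic distance (Angstrom), a
#' Gaussian basis expansion of the distance distribution (`gauss_centers`,
#' shared width `gauss_sigma`), and for atom pairs sharing a bonded common
#' neighbor the weighted mean subtended angle (radians) plus a presence
#' flag.
#'
#' Pairs at bond-path length 3 additionally carry Boltzmann-averaged
#' torsion statistics (mean cos and cos^2 of the connecting dihedral, plus
#' a presence flag) -- the sufficient statistics of a Karplus-type vicinal
#' coupling, mirroring the angle features of path-2 pairs.
#'
#' @param max_atoms maximum atom count accepted (atoms, hydrogens included)
#' @param gauss_centers Gaussian basis centers in Angstrom
#' @param gauss_sigma shared Gaussian width in Angstrom
#' @param temperature Kelvin, used for Boltzmann conformer weights
#' @param n_conformers default number of distance-geometry conformers
#' @return a `ss_feature_config` list; its hash is stored in checkpoints so
#'   a model is never applied to features built under a different config
#' @export
feature_config <- function(max_atoms = 128,
                           gauss_centers = seq(0.5, 4.0, length.out = 8),
                           gauss_sigma = 0.5,
                           temperature = 298.15,
                           n_conformers = 50) {
  stopifnot(max_atoms >= 1, gauss_sigma > 0, temperature > 0,
            n_conformers >= 1)
  cfg <- list(max_atoms = as.integer(max_atoms),
              gauss_centers = as.numeric(gauss_centers),
              gauss_sigma = as.numeric(gauss_sigma),
              temperature = as.numeric(temperature),
              n_conformers = as.integer(n_conformers))
  # mean dist + basis + angle/flag + torsion cos, cos^2, flag
  cfg$f_e <- length(cfg$gauss_centers) + 6L
  cfg$f_v <- length(ss_element_whitelist) + 13L
  structure(cfg, class = "ss_feature_config")
}

#' @noRd
feature_config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' Build the per-vertex feature matrix
#'
#' One row per atom: element one-hot (8), scaled atomic number, default and
#' total valence, formal charge, Gasteiger partial charge, aromaticity flag,
#' ring-membership flags for ring sizes 3-8, and hydrogen count on the atom.
#'
#' @param mol an `ss_molecule`
#' @param config a [feature_config()]
#' @return numeric matrix `N x f_v`
#' @export
build_vertex_features <- function(mol, config = feature_config()) {
  a <- mol$atoms
  one_hot <- outer(a$element, ss_element_whitelist, `==`) * 1
  colnames(one_hot) <- paste0("elem_", ss_element_whitelist)
  x <- cbind(
    one_hot,
    atomic_num = a$atomic_num / 10,
    default_valence = a$default_valence,
    total_valence = a$total_valence,
    formal_charge = a$formal_charge,
    gasteiger = a$gasteiger,
    aromatic = a$aromatic * 1,
    ring3 = a$ring3, ring4 = a$ring4, ring5 = a$ring5,
    ring6 = a$ring6, ring7 = a$ring7, ring8 = a$ring8,
    n_h = a$n_h
  )
  storage.mode(x) <- "double"
  stopifnot(ncol(x) == config$f_v)
  x
}

#' Build the five-slice adjacency stack
#'
#' Slice order: any bond, single, double, triple, order-1.5 (aromatic).
#' Aromatic bonds populate the order-1.5 slice; no kekulization is applied.
#'
#' @param mol an `ss_molecule`
#' @return array `N x N x 5`, each slice symmetric with zero diagonal
#' @export
build_adjacency <- function(mol) {
  n <- n_atoms(mol)
  g <- array(0, dim = c(n, n, 5),
             dimnames = list(NULL, NULL,
                             c("any", "single", "double", "triple",
                               "aromatic")))
  b <- mol$bonds
  if (nrow(b) > 0) {
    slice_of <- c(`1` = 2L, `2` = 3L, `3` = 4L, `1.5` = 5L)
    s <- slice_of[as.character(b$order)]
    ii <- b$i + 1L
    jj <- b$j + 1L
    for (k in seq_len(nrow(b))) {
      g[ii[k], jj[k], 1] <- g[jj[k], ii[k], 1] <- 1
      g[ii[k], jj[k], s[k]] <- g[jj[k], ii[k], s[k]] <- 1
    }
  }
  g
}

#' Boltzmann weights of a conformer ensemble
#'
#' `w_k` proportional to `exp(-(E_k - min E) / (R T))`, computed with the
#' minimum-energy shift for numerical stability and normalized to sum to 1.
#'
#' @param energies conformer energies in kcal/mol
#' @param temperature Kelvin (default 298.15)
#' @return numeric vector of weights summing to 1
#' @export
boltzmann_weights <- function(energies, temperature = 298.15) {
  if (length(energies) == 0) {
    abort("empty energy vector", class = "spinsys_error_empty")
  }
  stopifnot(all(is.finite(energies)), temperature > 0)
  r_kcal <- 1.987204258e-3  # kcal / (mol K)
  z <- exp(-(energies - min(energies)) / (r_kcal * temperature))
  z / sum(z)
}

#' Generate a distance-geometry conformer ensemble
#'
#' Embeds up to `n_conformers` conformers with the knowledge-based
#' distance-geometry method (seeded, deterministic), applies exactly one
#' MMFF94 optimization step to each, records the MMFF94 energies and
#' derives Boltzmann weights.  If MMFF94 parameters are unavailable for the
#' molecule the ensemble is returned with uniform weights and a warning
#' flag.
#'
#' @param mol an `ss_molecule`
#' @param n_conformers requested number of conformers (>= 1)
#' @param seed integer seed
#' @param temperature Kelvin for the Boltzmann weights
#' @param mmff_max_iters MMFF94 optimization step cap per conformer (the
#'   method's default is a single step; rigid-geometry studies may want
#'   converged optimization)
#' @return an `ss_conformers` object: `coords` (array `K x N x 3`, Angstrom),
#'   `energies` (kcal/mol or NULL), `weights`, `uniform_weights` flag
#' @export
generate_conformers <- function(mol, n_conformers = 50, seed = 1,
                                temperature = 298.15, mmff_max_iters = 1) {
  stopifnot(n_conformers >= 1)
  rec <- backend_parse(smiles = mol$smiles, n_conformers = n_conformers,
                       seed = seed, mmff_max_iters = mmff_max_iters)[[1]]
  if (!isTRUE(rec$ok)) {
    abort(paste0("conformer embedding failed for ", mol$molecule_id, ": ",
                 rec$error %||% "unknown"),
          class = "spinsys_error_embedding")
  }
  conformers_from_backend(rec, temperature)
}

#' @noRd
conformers_from_backend <- function(rec, temperature = 298.15) {
  coords_list <- rec$coords
  k <- length(coords_list)
  n <- length(coords_list[[1]])
  coords <- array(0, dim = c(k, n, 3))
  for (c_i in seq_len(k)) {
    coords[c_i, , ] <- matrix(unlist(coords_list[[c_i]]), ncol = 3,
                              byrow = TRUE)
  }
  uniform <- identical(rec$warning %||% "", "mmff_unavailable")
  if (uniform) {
    energies <- NULL
    weights <- rep(1 / k, k)
    warn("MMFF94 parameters unavailable; using uniform conformer weights")
  } else {
    energies <- as.numeric(unlist(rec$energies))
    weights <- boltzmann_weights(energies, temperature)
  }
  structure(list(coords = coords, energies = energies, weights = weights,
                 uniform_weights = uniform),
            class = "ss_conformers")
}

#' @export
print.ss_conformers <- function(x, ...) {
  cat("<ss_conformers> ", dim(x$coords)[1], " conformers x ",
      dim(x$coords)[2], " atoms\n", sep = "")
  invisible(x)
}

#' @noRd
check_ensemble <- function(ens) {
  stopifnot(inherits(ens, "ss_conformers"))
  if (abs(sum(ens$weights) - 1) > 1e-9 || any(ens$weights < 0)) {
    abort("conformer weights must be nonnegative and sum to 1",
          class = "spinsys_error_weights")
  }
  if (!all(is.finite(ens$coords))) {
    abort("non-finite conformer coordinates", class = "spinsys_error_coords")
  }
}

#' Build the geometric pair-feature stack from a conformer ensemble
#'
#' For every atom pair: the Boltzmann-weighted mean distance, a Gaussian
#' basis expansion of the distance (each basis value averaged over
#' conformers with the ensemble weights), and, for pairs sharing a bonded
#' common neighbor, the weighted mean subtended angle with a presence flag.
#' All slices are symmetric; distance slices have zero diagonal.
#'
#' @param mol an `ss_molecule`
#' @param ens an `ss_conformers` ensemble for `mol`
#' @param config a [feature_config()]
#' @return array `N x N x f_e`
#' @export
build_pair_features <- function(mol, ens, config = feature_config()) {
  check_ensemble(ens)
  n <- n_atoms(mol)
  k <- dim(ens$coords)[1]
  stopifnot(dim(ens$coords)[2] == n)
  centers <- config$gauss_centers
  sig2 <- 2 * config$gauss_sigma^2
  w <- ens$weights

  mean_dist <- matrix(0, n, n)
  basis <- array(0, dim = c(n, n, length(centers)))
  for (c_i in seq_len(k)) {
    xyz <- matrix(ens$coords[c_i, , ], ncol = 3)
    d <- matrix(0, n, n)
    if (n > 1) d <- as.matrix(stats::dist(xyz))
    mean_dist <- mean_dist + w[c_i] * d
    for (g in seq_along(centers)) {
      basis[, , g] <- basis[, , g] +
        w[c_i] * exp(-(d - centers[g])^2 / sig2)
    }
  }
  diag(mean_dist) <- 0
  for (g in seq_along(centers)) {
    bg <- matrix(basis[, , g], n, n)
    diag(bg) <- 0
    basis[, , g] <- bg
  }

  ang <- angle_features(mol, ens)
  tor <- torsion_features(mol, ens)

  out <- array(0, dim = c(n, n, config$f_e))
  ng <- length(centers)
  out[, , 1] <- mean_dist
  out[, , 1 + seq_len(ng)] <- basis
  out[, , ng + 2L] <- ang$angle
  out[, , ng + 3L] <- ang$flag
  out[, , ng + 4L] <- tor$cos1
  out[, , ng + 5L] <- tor$cos2
  out[, , ng + 6L] <- tor$flag
  dimnames(out) <- list(NULL, NULL,
                        c("mean_dist", paste0("gauss_", seq_len(ng)),
                          "angle", "angle_flag",
                          "torsion_cos", "torsion_cos2", "torsion_flag"))
  out
}

#' Weighted mean angles for atom pairs sharing a bonded common neighbor
#' @noRd
angle_features <- function(mol, ens) {
  n <- n_atoms(mol)
  k <- dim(ens$coords)[1]
  w <- ens$weights
  angle <- matrix(0, n, n)
  count <- matrix(0L, n, n)
  nbrs <- neighbor_list(mol)
  for (m in seq_len(n)) {
    nb <- nbrs[[m]]
    if (length(nb) < 2) next
    pairs <- utils::combn(nb, 2)
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]
      j <- pairs[2, p]
      th <- 0
      for (c_i in seq_len(k)) {
        v1 <- ens$coords[c_i, i, ] - ens$coords[c_i, m, ]
        v2 <- ens$coords[c_i, j, ] - ens$coords[c_i, m, ]
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        th <- th + w[c_i] * acos(pmin(1, pmax(-1, cosang)))
      }
      angle[i, j] <- angle[i, j] + th
      angle[j, i] <- angle[i, j]
      count[i, j] <- count[j, i] <- count[i, j] + 1L
    }
  }
  nz <- count > 0
  angle[nz] <- angle[nz] / count[nz]
  list(angle = angle, flag = nz * 1)
}

#' Boltzmann-averaged torsion statistics for pairs at bond-path length 3
#'
#' For every pair (i, j) connected by a 3-bond path i-a-b-j: the weighted
#' means of cos(theta) and cos^2(theta) of the dihedral over the ensemble
#' (averaged over all connecting paths when a ring offers several), plus a
#' presence flag.  These are the sufficient statistics of a Karplus-type
#' angular dependence.
#' @noRd
torsion_features <- function(mol, ens) {
  n <- n_atoms(mol)
  k <- dim(ens$coords)[1]
  w <- ens$weights
  cos1 <- matrix(0, n, n)
  cos2 <- matrix(0, n, n)
  count <- matrix(0L, n, n)
  nbrs <- neighbor_list(mol)
  b <- mol$bonds
  for (r in seq_len(nrow(b))) {
    a1 <- b$i[r] + 1L
    a2 <- b$j[r] + 1L
    for (ends in list(c(a1, a2), c(a2, a1))) {
      a <- ends[1]
      bb <- ends[2]
      for (i in setdiff(nbrs[[a]], bb)) {
        for (j in setdiff(nbrs[[bb]], a)) {
          if (i == j || i > j) next
          c1 <- 0
          c2 <- 0
          for (c_i in seq_len(k)) {
            th <- dihedral_angle(ens$coords[c_i, i, ],
                                 ens$coords[c_i, a, ],
                                 ens$coords[c_i, bb, ],
                                 ens$coords[c_i, j, ])
            ct <- cos(th)
            c1 <- c1 + w[c_i] * ct
            c2 <- c2 + w[c_i] * ct * ct
          }
          cos1[i, j] <- cos1[i, j] + c1
          cos2[i, j] <- cos2[i, j] + c2
          count[i, j] <- count[i, j] + 1L
        }
      }
    }
  }
  nz <- count > 0
  cos1[nz] <- cos1[nz] / count[nz]
  cos2[nz] <- cos2[nz] / count[nz]
  cos1 <- cos1 + t(cos1)
  cos2 <- cos2 + t(cos2)
  flag <- (nz | t(nz)) * 1
  # only pairs whose shortest bond path is exactly 3 keep the feature
  list(cos1 = cos1 * (flag > 0), cos2 = cos2 * (flag > 0), flag = flag)
}

#' 1-based adjacency (neighbor) list
#' @noRd
neighbor_list <- function(mol) {
  n <- n_atoms(mol)
  nbrs <- vector("list", n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b$i[k] + 1L
    j <- b$j[k] + 1L
    nbrs[[i]] <- c(nbrs[[i]], j)
    nbrs[[j]] <- c(nbrs[[j]], i)
  }
  nbrs
}
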