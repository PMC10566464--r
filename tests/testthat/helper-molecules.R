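# Shared test helpers: hand-built molecules/ensembles (no chemistry
# backend needed) and session-cached featurized molecule sets.

# Hand-built molecule: atoms as element vector, bonds as (i, j, order)
# 0-based rows.  Gasteiger charges and valences are filled with plausible
# constants; fine for geometry/graph tests that never read them.
hand_molecule <- function(elements, bonds = NULL, id = "hand") {
  n <- length(elements)
  atoms <- tibble::tibble(
    atom_idx = seq_len(n) - 1L,
    element = elements,
    atomic_num = c(H = 1L, C = 6L, O = 8L, N = 7L, F = 9L, S = 16L,
                   P = 15L, Cl = 17L)[elements],
    formal_charge = 0L,
    gasteiger = seq(-0.1, 0.1, length.out = n),
    aromatic = FALSE,
    default_valence = c(H = 1L, C = 4L, O = 2L, N = 3L, F = 1L, S = 2L,
                        P = 3L, Cl = 1L)[elements],
    total_valence = c(H = 1L, C = 4L, O = 2L, N = 3L, F = 1L, S = 2L,
                      P = 3L, Cl = 1L)[elements],
    degree = 0L, n_h = 0L,
    ring3 = 0L, ring4 = 0L, ring5 = 0L, ring6 = 0L, ring7 = 0L, ring8 = 0L
  )
  bonds <- if (is.null(bonds)) {
    tibble::tibble(i = integer(), j = integer(), order = numeric())
  } else {
    tibble::tibble(i = bonds[, 1], j = bonds[, 2], order = bonds[, 3])
  }
  new_molecule(atoms, bonds, molecule_id = id)
}

# Hand-built conformer ensemble from a list of N x 3 coordinate matrices
hand_ensemble <- function(coord_list, weights = NULL) {
  k <- length(coord_list)
  n <- nrow(coord_list[[1]])
  coords <- array(0, dim = c(k, n, 3))
  for (ci in seq_len(k)) coords[ci, , ] <- coord_list[[ci]]
  structure(list(coords = coords, energies = NULL,
                 weights = weights %||% rep(1 / k, k),
                 uniform_weights = is.null(weights)),
            class = "ss_conformers")
}

`%||%` <- rlang::`%||%`

# Session-level cache so expensive featurizations/fits happen once
.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache)) {
    assign(key, force(expr), envir = .test_cache)
  }
  get(key, envir = .test_cache)
}

# A small, featurized fixture set most test files share
small_fixtures <- function() {
  cached("small_fixtures", {
    generate_fixtures(fixture_spec(n_molecules = 40, seed = 101,
                                   n_conformers = 3))
  })
}

# Apply an atom permutation (1-based vector: new index p[i] gets old atom
# ...: we define x_new = P x, i.e. x_new[k, ] = x[perm[k], ]) to a graph
permute_graph <- function(graph, perm) {
  g <- graph
  g$x <- graph$x[perm, , drop = FALSE]
  n <- length(perm)
  g$g_adj <- graph$g_adj[perm, perm, , drop = FALSE]
  g$g_feat <- graph$g_feat[perm, perm, , drop = FALSE]
  g$nucleus <- graph$nucleus[perm]
  g$pair_masks <- lapply(graph$pair_masks,
                         function(m) m[perm, perm, drop = FALSE])
  g
}

# Independent shortest-bond-path oracle (plain BFS; no igraph)
bfs_path_lengths <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k] + 1L
    j <- mol$bonds$j[k] + 1L
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[d[s, nxt] == Inf]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}
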