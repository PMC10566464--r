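# MoleculeGraph assembly: the three feature blocks plus masks and metadata.

#' Coupling class masks from connectivity
#'
#' `1JCH` marks bonded carbon-proton pairs; `2JHH`/`3JHH`/`4JHH` mark
#' proton-proton pairs whose shortest bond-path length is 2, 3 or 4.  Masks
#' are symmetric and mutually exclusive per pair.
#'
#' @param mol an `ss_molecule`
#' @return named list of `N x N` logical matrices
#' @export
coupling_class_masks <- function(mol) {
  n <- n_atoms(mol)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(mol$bonds) > 0) {
    edges <- rbind(mol$bonds$i + 1L, mol$bonds$j + 1L)
    g <- igraph::add_edges(g, as.vector(edges))
  }
  pl <- igraph::distances(g)
  is_h <- mol$atoms$element == "H"
  is_c <- mol$atoms$element == "C"
  hh <- outer(is_h, is_h, `&`)
  ch <- outer(is_c, is_h, `&`) | outer(is_h, is_c, `&`)
  list(
    `1JCH` = ch & pl == 1,
    `2JHH` = hh & pl == 2,
    `3JHH` = hh & pl == 3,
    `4JHH` = hh & pl == 4
  )
}

#' Assemble the model input graph for one molecule
#'
#' Combines the per-vertex feature matrix `x`, the 5-slice adjacency stack
#' and the conformer-ensemble geometric pair features, together with the
#' nucleus classes and coupling-class masks the readout needs.
#'
#' @param mol an `ss_molecule`
#' @param ens an `ss_conformers` ensemble (generated via
#'   [generate_conformers()] if omitted)
#' @param config a [feature_config()]
#' @param seed seed for conformer generation when `ens` is NULL
#' @return an `ss_graph` object
#' @export
molecule_graph <- function(mol, ens = NULL, config = feature_config(),
                           seed = 1) {
  if (is.null(ens)) {
    ens <- generate_conformers(mol, n_conformers = config$n_conformers,
                               seed = seed, temperature = config$temperature)
  }
  nucleus <- ifelse(mol$atoms$element == "H", "1H",
                    ifelse(mol$atoms$element == "C", "13C", NA_character_))
  structure(list(
    molecule_id = mol$molecule_id,
    molecule = mol,
    x = build_vertex_features(mol, config),
    g_adj = build_adjacency(mol),
    g_feat = build_pair_features(mol, ens, config),
    nucleus = nucleus,
    pair_masks = coupling_class_masks(mol),
    weights = ens$weights,
    config_hash = feature_config_hash(config)
  ), class = "ss_graph")
}

#' @export
print.ss_graph <- function(x, ...) {
  cat("<ss_graph> ", x$molecule_id, ": N=", nrow(x$x), ", f_v=", ncol(x$x),
      ", f_e=", dim(x$g_feat)[3], "\n", sep = "")
  invisible(x)
}

#' Featurize a batch of SMILES in one backend call
#'
#' Parses, filters, embeds conformers and assembles `ss_graph` objects for
#' many molecules with a single backend invocation.  Rejected records are
#' dropped with a logged reason.
#'
#' @param smiles character vector of SMILES strings
#' @param config a [feature_config()]
#' @param n_conformers conformers per molecule (default from `config`)
#' @param seed integer seed driving conformer embedding
#' @param ids optional molecule ids (default: stable hash-based ids)
#' @param mmff_max_iters MMFF94 optimization step cap per conformer
#' @return tibble with columns `molecule_id`, `smiles`, `accepted`, `reason`,
#'   and list-columns `molecule`, `ensemble`, `graph`
#' @export
featurize_molecules <- function(smiles, config = feature_config(),
                                n_conformers = NULL, seed = 1, ids = NULL,
                                mmff_max_iters = 1) {
  n_conformers <- n_conformers %||% config$n_conformers
  recs <- backend_parse(smiles = smiles, n_conformers = n_conformers,
                        seed = seed, mmff_max_iters = mmff_max_iters)
  rows <- purrr::imap(recs, function(rec, k) {
    id <- if (is.null(ids)) {
      stable_molecule_id(rec$canonical_smiles %||% smiles[[k]], k)
    } else {
      ids[[k]]
    }
    if (!isTRUE(rec$ok)) {
      return(tibble(molecule_id = id, smiles = smiles[[k]], accepted = FALSE,
                    reason = rec$error %||% "parse_error",
                    molecule = list(NULL), ensemble = list(NULL),
                    graph = list(NULL)))
    }
    mol <- tryCatch(molecule_from_backend(rec, id, config$max_atoms),
                    spinsys_error_element = function(e) "element",
                    spinsys_error_max_atoms = function(e) "max_atoms")
    if (is.character(mol)) {
      return(tibble(molecule_id = id, smiles = smiles[[k]], accepted = FALSE,
                    reason = mol, molecule = list(NULL),
                    ensemble = list(NULL), graph = list(NULL)))
    }
    ens <- conformers_from_backend(rec, config$temperature)
    gr <- molecule_graph(mol, ens, config)
    tibble(molecule_id = id, smiles = smiles[[k]], accepted = TRUE,
           reason = NA_character_, molecule = list(mol),
           ensemble = list(ens), graph = list(gr))
  })
  bind_rows(rows)
}

#' Save / load a feature cache
#'
#' Runtime cache of featurized graphs keyed by molecule id.
#'
#' @param graphs named list of `ss_graph` objects (names = molecule ids), or
#'   the tibble returned by [featurize_molecules()]
#' @param path cache file path
#' @return `path` invisibly for the writer; a named list for the reader
#' @export
write_feature_cache <- function(graphs, path) {
  if (is.data.frame(graphs)) {
    keep <- if ("accepted" %in% names(graphs)) graphs$accepted else
      rep(TRUE, nrow(graphs))
    graphs <- stats::setNames(graphs$graph[keep],
                              graphs$molecule_id[keep])
  }
  saveRDS(graphs, path)
  invisible(path)
}

#' @rdname write_feature_cache
#' @export
read_feature_cache <- function(path) {
  readRDS(path)
}
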