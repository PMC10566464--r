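# Bridge to the Python/RDKit cheminformatics backend.
#
# All calls are batched: one subprocess invocation handles an arbitrary
# number of molecules, exchanging JSON request/response files.  Only raw
# chemistry (atoms, bonds, coordinates, MMFF94 energies, stereoisomer
# SMILES) crosses this boundary; featurization and modelling are pure R.

backend_python <- function() {
  Sys.getenv("SPINSYS_PYTHON", unset = "python")
}

backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "spinsys")
  if (!nzchar(path)) {
    abort("chem_backend.py not found in the installed package",
          class = "spinsys_error_backend")
  }
  path
}

#' Low-level call into the chemistry backend
#' @noRd
call_backend <- function(req) {
  req_path <- tempfile(fileext = ".json")
  res_path <- tempfile(fileext = ".json")
  on.exit(unlink(c(req_path, res_path)), add = TRUE)
  jsonlite::write_json(req, req_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- system2(backend_python(), c(backend_script(), req_path, res_path),
                    stdout = FALSE, stderr = "")
  if (!identical(status, 0L) || !file.exists(res_path)) {
    abort(paste0("chemistry backend failed (exit status ", status, ")"),
          class = "spinsys_error_backend")
  }
  jsonlite::read_json(res_path)
}

#' Parse molecules (and optionally embed conformers) via the backend
#'
#' @param smiles character vector of SMILES, or NULL
#' @param molblocks character vector of V2000 MOL blocks, or NULL
#' @param n_conformers integer; 0 skips conformer embedding
#' @param seed integer seed forwarded to the distance-geometry embedder
#' @return list of per-molecule records (see inst/python/chem_backend.py)
#' @noRd
backend_parse <- function(smiles = NULL, molblocks = NULL, n_conformers = 0,
                          seed = 0, mmff_max_iters = 1) {
  req <- list(op = "parse",
              smiles = as.list(smiles %|0|% character()),
              molblocks = as.list(molblocks %|0|% character()),
              n_conformers = as.integer(n_conformers),
              seed = as.integer(seed),
              mmff_max_iters = as.integer(mmff_max_iters))
  call_backend(req)$molecules
}

#' @noRd
backend_stereoisomers <- function(smiles, max_candidates = 8) {
  req <- list(op = "stereoisomers", smiles = as.list(smiles),
              max_candidates = as.integer(max_candidates))
  call_backend(req)$molecules
}

#' @noRd
backend_write_sdf <- function(smiles) {
  req <- list(op = "write_sdf", smiles = as.list(smiles))
  blocks <- call_backend(req)$molblocks
  vapply(blocks, function(b) b %||% NA_character_, character(1))
}
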