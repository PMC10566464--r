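# Molecule container and input readers.

#' Elements accepted by the predictor
#'
#' The models target small organic molecules restricted to H, C, O, N, F, S,
#' P and Cl with explicit hydrogens and at most `max_atoms` atoms (hydrogens
#' included); inputs outside this envelope are rejected.
#' @export
ss_element_whitelist <- c("H", "C", "O", "N", "F", "S", "P", "Cl")

#' Construct a molecule object from backend tables
#'
#' A molecule is a pair of tidy tables: `atoms` (one row per atom, explicit
#' hydrogens included, 0-based `atom_idx` preserving input order) and `bonds`
#' (0-based endpoint indices `i < j`, `order` in {1, 1.5, 2, 3}).
#'
#' @param atoms tibble with columns element, atomic_num, formal_charge,
#'   gasteiger, aromatic, default_valence, total_valence, degree, n_h and
#'   ring-membership flags ring3..ring8
#' @param bonds tibble with columns i, j, order
#' @param molecule_id opaque identifier
#' @param smiles canonical (isomeric) SMILES of the molecule
#' @param max_atoms maximum atom count accepted (default 128)
#' @return an object of class `ss_molecule`
#' @export
new_molecule <- function(atoms, bonds, molecule_id = "mol",
                         smiles = NA_character_, max_atoms = 128) {
  atoms <- as_tibble(atoms)
  bonds <- as_tibble(bonds)
  n <- nrow(atoms)
  bad <- setdiff(unique(atoms$element), ss_element_whitelist)
  if (length(bad) > 0) {
    abort(paste0("element outside whitelist: ", paste(bad, collapse = ", ")),
          class = "spinsys_error_element")
  }
  if (n > max_atoms) {
    abort(paste0("molecule has ", n, " atoms; max_atoms is ", max_atoms),
          class = "spinsys_error_max_atoms")
  }
  if (nrow(bonds) > 0) {
    if (any(bonds$i < 0 | bonds$j < 0 | bonds$i >= n | bonds$j >= n)) {
      abort("bond references an atom index outside the molecule",
            class = "spinsys_error_bonds")
    }
    if (!all(bonds$order %in% c(1, 1.5, 2, 3))) {
      abort("unknown bond order (allowed: 1, 1.5, 2, 3)",
            class = "spinsys_error_bond_order")
    }
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]
    bonds$i[swap] <- bonds$j[swap]
    bonds$j[swap] <- tmp
  }
  structure(list(atoms = atoms, bonds = bonds, molecule_id = molecule_id,
                 smiles = smiles),
            class = "ss_molecule")
}

#' @export
print.ss_molecule <- function(x, ...) {
  cat("<ss_molecule> ", x$molecule_id, ": ", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds", sep = "")
  if (!is.na(x$smiles)) cat("  ", x$smiles, sep = "")
  cat("\n")
  invisible(x)
}

#' Number of atoms (explicit hydrogens included)
#' @param mol an `ss_molecule`
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' @noRd
atoms_from_backend <- function(rec) {
  a <- rec$atoms
  ring_flag <- function(at, k) as.integer(k %in% unlist(at$ring_sizes))
  tibble(
    atom_idx = seq_along(a) - 1L,
    element = vapply(a, `[[`, "", "element"),
    atomic_num = vapply(a, `[[`, 0L, "atomic_num"),
    formal_charge = vapply(a, `[[`, 0L, "formal_charge"),
    gasteiger = vapply(a, function(at) as.numeric(at$gasteiger), 0),
    aromatic = vapply(a, `[[`, FALSE, "aromatic"),
    default_valence = vapply(a, `[[`, 0L, "default_valence"),
    total_valence = vapply(a, `[[`, 0L, "total_valence"),
    degree = vapply(a, `[[`, 0L, "degree"),
    n_h = vapply(a, `[[`, 0L, "n_h"),
    ring3 = vapply(a, ring_flag, 0L, k = 3L),
    ring4 = vapply(a, ring_flag, 0L, k = 4L),
    ring5 = vapply(a, ring_flag, 0L, k = 5L),
    ring6 = vapply(a, ring_flag, 0L, k = 6L),
    ring7 = vapply(a, ring_flag, 0L, k = 7L),
    ring8 = vapply(a, ring_flag, 0L, k = 8L)
  )
}

#' @noRd
bonds_from_backend <- function(rec) {
  b <- rec$bonds
  tibble(
    i = vapply(b, `[[`, 0L, "i"),
    j = vapply(b, `[[`, 0L, "j"),
    order = vapply(b, function(x) as.numeric(x$order), 0)
  )
}

#' @noRd
molecule_from_backend <- function(rec, molecule_id, max_atoms = 128) {
  new_molecule(atoms_from_backend(rec), bonds_from_backend(rec),
               molecule_id = molecule_id,
               smiles = rec$canonical_smiles %||% NA_character_,
               max_atoms = max_atoms)
}

#' @noRd
stable_molecule_id <- function(smiles, record) {
  sprintf("m%05d_%s", record, substr(rlang::hash(smiles), 1, 8))
}

#' Read molecules from a SMILES or SDF file
#'
#' Parses each record, adds explicit hydrogens, applies the input filters
#' (element whitelist, atom-count cap) and assigns stable molecule ids.
#' Every record is logged as accepted or rejected with a reason.
#'
#' @param path file path: one SMILES per line, or a V2000 SDF
#' @param format `"smiles"` or `"sdf"`
#' @param max_atoms maximum atom count (default 128, hydrogens included)
#' @param strict if TRUE, abort on the first rejected record instead of
#'   logging and skipping it
#' @return a tibble with one row per input record: `record`, `molecule_id`,
#'   `accepted`, `reason` and a `molecule` list-column (`NULL` when rejected)
#' @export
read_molecules <- function(path, format = c("smiles", "sdf"),
                           max_atoms = 128, strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "spinsys_error_io")
  }
  if (format == "smiles") {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    recs <- backend_parse(smiles = lines)
    inputs <- lines
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    # split on record separators without touching the (possibly empty)
    # title line that starts each V2000 block
    blocks <- strsplit(txt, "\\$\\$\\$\\$ *\n?")[[1]]
    blocks <- blocks[vapply(blocks, function(b) nzchar(trimws(b)), TRUE)]
    recs <- backend_parse(molblocks = blocks)
    inputs <- paste0("sdf_record_", seq_along(blocks))
  }
  rows <- purrr::map2(recs, seq_along(recs), function(rec, k) {
    if (!isTRUE(rec$ok)) {
      return(list(accepted = FALSE, reason = rec$error %||% "parse_error",
                  molecule = list(NULL), molecule_id = NA_character_))
    }
    mol <- tryCatch(
      molecule_from_backend(
        rec, stable_molecule_id(rec$canonical_smiles, k), max_atoms),
      spinsys_error_element = function(e) "element",
      spinsys_error_max_atoms = function(e) "max_atoms"
    )
    if (is.character(mol)) {
      list(accepted = FALSE, reason = mol, molecule = list(NULL),
           molecule_id = NA_character_)
    } else {
      list(accepted = TRUE, reason = NA_character_, molecule = list(mol),
           molecule_id = mol$molecule_id)
    }
  })
  out <- tibble(
    record = seq_along(rows),
    input = inputs,
    molecule_id = vapply(rows, `[[`, "", "molecule_id"),
    accepted = vapply(rows, `[[`, TRUE, "accepted"),
    reason = vapply(rows, `[[`, "", "reason"),
    molecule = purrr::map(rows, function(r) r$molecule[[1]])
  )
  if (strict && any(!out$accepted)) {
    bad <- out[!out$accepted, ]
    abort(paste0("rejected record ", bad$record[1], ": ", bad$reason[1]),
          class = "spinsys_error_strict")
  }
  out
}

#' Parse molecules from SMILES strings
#'
#' Convenience wrapper over the same machinery as [read_molecules()].
#'
#' @param smiles character vector of SMILES strings
#' @inheritParams read_molecules
#' @return same shape as [read_molecules()]
#' @export
parse_smiles <- function(smiles, max_atoms = 128, strict = FALSE) {
  path <- tempfile(fileext = ".smi")
  on.exit(unlink(path))
  writeLines(smiles, path)
  read_molecules(path, format = "smiles", max_atoms = max_atoms,
                 strict = strict)
}

#' Write molecules to an SDF file
#'
#' Serializes via the chemistry backend (explicit hydrogens, 2D coordinates,
#' stereo wedges from the isomeric SMILES).
#'
#' @param molecules list of `ss_molecule` objects
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sdf <- function(molecules, path) {
  smiles <- vapply(molecules, function(m) m$smiles, character(1))
  blocks <- backend_write_sdf(smiles)
  con <- file(path, "w")
  on.exit(close(con))
  for (b in blocks) {
    writeLines(sub("\n$", "", b), con)
    writeLines("$$$$", con)
  }
  invisible(path)
}
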