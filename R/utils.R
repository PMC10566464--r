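# Internal helpers: parameter-tree arithmetic, seeded evaluation, hashing.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's RNG stream.
#' @noRd
with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a base seed and a string tag
#'
#' Keeps all derived seeds in the 32-bit integer range.
#' @noRd
derive_seed <- function(seed, tag) {
  h <- rlang::hash(list(as.integer(seed), as.character(tag)))
  # take 7 hex digits -> < 2^28, well inside .Machine$integer.max
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}

# ---- parameter trees --------------------------------------------------------
# Model parameters, gradients and Adam moments are nested lists whose leaves
# are numeric matrices/vectors.  These helpers walk two trees in lock step.

#' @noRd
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (k in seq_along(a)) out[[k]] <- tree_map2(a[[k]], b[[k]], f)
    out
  } else {
    f(a, b)
  }
}

#' @noRd
tree_map <- function(a, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (k in seq_along(a)) out[[k]] <- tree_map(a[[k]], f)
    out
  } else {
    f(a)
  }
}

#' Sum of f(leaf) over all leaves
#' @noRd
tree_reduce <- function(a, f) {
  if (is.list(a)) {
    s <- 0
    for (k in seq_along(a)) s <- s + tree_reduce(a[[k]], f)
    s
  } else {
    f(a)
  }
}

#' Zero tree with the same shapes
#' @noRd
tree_zeros <- function(a) tree_map(a, function(x) x * 0)

#' Flatten a tree's leaves to one numeric vector (fixed traversal order)
#' @noRd
tree_flatten <- function(a) {
  if (is.list(a)) {
    unlist(lapply(a, tree_flatten), use.names = FALSE)
  } else {
    as.numeric(a)
  }
}

#' Inverse of tree_flatten given a template tree
#' @noRd
tree_unflatten <- function(template, v) {
  pos <- 0L
  rebuild <- function(a) {
    if (is.list(a)) {
      out <- vector("list", length(a))
      names(out) <- names(a)
      for (k in seq_along(a)) out[[k]] <- rebuild(a[[k]])
      out
    } else {
      n <- length(a)
      leaf <- a
      leaf[] <- v[(pos + 1L):(pos + n)]
      pos <<- pos + n
      leaf
    }
  }
  rebuild(template)
}

#' @noRd
`%|0|%` <- function(x, y) if (length(x) == 0) y else x
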