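# Batch assembly: many molecule graphs packed into one block structure.
#
# Vertices of all molecules are stacked into an M x f matrix; adjacency
# slices become block-diagonal sparse matrices; the dense per-pair edge
# state keeps only within-molecule pairs, ordered row-major per molecule
# ((i,j) for i,j in 1..N including the diagonal), giving E = sum(N_b^2)
# rows.  Padding is never materialized: cross-molecule pairs simply do not
# exist, so they cannot leak into aggregation, normalization or loss.

#' @noRd
build_batch <- function(graphs, mcfg) {
  n_mol <- length(graphs)
  sizes <- vapply(graphs, function(g) nrow(g$x), 0L)
  v_off <- cumsum(c(0L, sizes))[seq_len(n_mol)]
  e_sizes <- sizes^2
  e_off <- cumsum(c(0L, e_sizes))[seq_len(n_mol)]
  m_tot <- sum(sizes)
  e_tot <- sum(e_sizes)

  x <- do.call(rbind, lapply(graphs, function(g) g$x))

  base <- lapply(1:5, function(s) {
    Matrix::bdiag(lapply(graphs, function(g) {
      methods::as(Matrix::Matrix(g$g_adj[, , s], sparse = TRUE), "CsparseMatrix")
    }))
  })
  names(base) <- c("any", "single", "double", "triple", "aromatic")
  adj <- base
  extra <- sort(setdiff(mcfg$adjacency_powers, 1L))
  a_pow <- base$any
  p_prev <- 1L
  for (p in extra) {
    for (k in seq_len(p - p_prev)) a_pow <- a_pow %*% base$any
    p_prev <- p
    adj[[paste0("pow", p)]] <- a_pow
  }
  if (mcfg$include_self_loops) {
    adj$identity <- Matrix::sparseMatrix(i = seq_len(m_tot),
                                         j = seq_len(m_tot), x = 1,
                                         dims = c(m_tot, m_tot))
  }
  adj <- lapply(adj, function(a) {
    methods::as(methods::as(a, "generalMatrix"), "CsparseMatrix")
  })

  e_i <- integer(e_tot)
  e_j <- integer(e_tot)
  trans <- integer(e_tot)
  cls <- integer(e_tot)
  edge_feat <- matrix(0, e_tot, 5L + dim(graphs[[1]]$g_feat)[3])
  nucleus <- integer(m_tot)
  mol_of_vertex <- integer(m_tot)
  mol_of_edge <- integer(e_tot)

  for (m in seq_len(n_mol)) {
    g <- graphs[[m]]
    n <- sizes[m]
    vi <- v_off[m]
    ei <- e_off[m]
    rows <- ei + seq_len(n * n)
    il <- rep(seq_len(n), each = n)
    jl <- rep(seq_len(n), times = n)
    e_i[rows] <- vi + il
    e_j[rows] <- vi + jl
    trans[rows] <- ei + (jl - 1L) * n + il
    feats <- cbind(
      do.call(cbind, lapply(1:5, function(s) as.vector(t(g$g_adj[, , s])))),
      do.call(cbind, lapply(seq_len(dim(g$g_feat)[3]),
                            function(s) as.vector(t(g$g_feat[, , s]))))
    )
    edge_feat[rows, ] <- feats
    cmat <- matrix(0L, n, n)
    for (ci in seq_along(mcfg$coupling_classes)) {
      msk <- g$pair_masks[[mcfg$coupling_classes[ci]]]
      if (!is.null(msk)) cmat[msk] <- ci
    }
    cls[rows] <- as.vector(t(cmat))
    nucleus[vi + seq_len(n)] <- match(g$nucleus, c("1H", "13C"),
                                      nomatch = 0L)[seq_len(n)]
    mol_of_vertex[vi + seq_len(n)] <- m
    mol_of_edge[rows] <- m
  }

  inv_n <- 1 / sizes[mol_of_edge]
  agg_mean <- Matrix::sparseMatrix(i = e_i, j = seq_len(e_tot), x = inv_n,
                                   dims = c(m_tot, e_tot))
  agg_sum <- Matrix::sparseMatrix(i = e_i, j = seq_len(e_tot), x = 1,
                                  dims = c(m_tot, e_tot))
  # local-neighborhood channels: normalized means over the pairs at bond
  # path exactly 1 (bonded) and exactly 2 (geminal) of each vertex; they
  # preserve the local bond/angle geometry that the all-pairs mean
  # dilutes by 1/N
  pair_channel <- function(mask) {
    ij <- as.matrix(Matrix::summary(
      methods::as(mask, "TsparseMatrix")))[, 1:2, drop = FALSE]
    if (nrow(ij) == 0) {
      return(Matrix::sparseMatrix(i = integer(), j = integer(),
                                  x = numeric(),
                                  dims = c(m_tot, e_tot)))
    }
    deg <- tabulate(ij[, 1], nbins = m_tot)
    brow <- ij[, 1]
    bmol <- mol_of_vertex[brow]
    bi_local <- brow - v_off[bmol]
    bj_local <- ij[, 2] - v_off[bmol]
    bedge <- e_off[bmol] + (bi_local - 1L) * sizes[bmol] + bj_local
    Matrix::sparseMatrix(i = brow, j = bedge, x = 1 / deg[brow],
                         dims = c(m_tot, e_tot))
  }
  a2 <- adj$any %*% adj$any
  gem_mask <- a2 > 0 & !(adj$any > 0)
  Matrix::diag(gem_mask) <- FALSE
  agg_bond <- pair_channel(adj$any > 0)
  agg_gem <- pair_channel(gem_mask)

  use_loss <- cls > 0L & e_i < e_j

  list(n_mol = n_mol, sizes = sizes, v_off = v_off, e_off = e_off,
       m_tot = m_tot, e_tot = e_tot,
       molecule_ids = vapply(graphs, function(g) g$molecule_id, ""),
       x = x, adj = adj, edge_feat = edge_feat,
       e_i = e_i, e_j = e_j, trans = trans, cls = cls,
       nucleus = nucleus, mol_of_vertex = mol_of_vertex,
       mol_of_edge = mol_of_edge,
       agg_mean = agg_mean, agg_sum = agg_sum, agg_bond = agg_bond,
       agg_gem = agg_gem,
       use_loss = use_loss)
}

#' Attach two-channel labels to a batch
#'
#' @param batch output of build_batch
#' @param shifts list (per molecule) of tibbles with atom_idx (0-based),
#'   exp, ab columns (NA = channel absent)
#' @param couplings list (per molecule) of tibbles with i, j (0-based,
#'   i < j), class, exp, ab
#' @noRd
attach_labels <- function(batch, shifts, couplings) {
  sh <- matrix(NA_real_, batch$m_tot, 2)
  cp <- matrix(NA_real_, batch$e_tot, 2)
  for (m in seq_len(batch$n_mol)) {
    st <- shifts[[m]]
    if (!is.null(st) && nrow(st) > 0) {
      rows <- batch$v_off[m] + st$atom_idx + 1L
      sh[rows, 1] <- st$exp
      sh[rows, 2] <- st$ab
    }
    ct <- couplings[[m]]
    if (!is.null(ct) && nrow(ct) > 0) {
      n <- batch$sizes[m]
      ii <- pmin(ct$i, ct$j)
      jj <- pmax(ct$i, ct$j)
      rows <- batch$e_off[m] + ii * n + jj + 1L
      cp[rows, 1] <- ct$exp
      cp[rows, 2] <- ct$ab
    }
  }
  batch$shift_target <- sh
  batch$coupling_target <- cp
  batch
}

#' Aggregation over the neighbor dimension of the edge state: the
#' configured all-pairs reduction, concatenated with the bonded-neighbor
#' mean channel
#' @noRd
agg_fwd <- function(g_edge, batch, mode) {
  base <- agg_fwd_all(g_edge, batch, mode)
  bond <- as.matrix(batch$agg_bond %*% g_edge)
  gem <- as.matrix(batch$agg_gem %*% g_edge)
  list(out = cbind(base$out, bond, gem), cache = base$cache)
}

#' @noRd
agg_fwd_all <- function(g_edge, batch, mode) {
  if (mode == "mean") {
    list(out = as.matrix(batch$agg_mean %*% g_edge), cache = NULL)
  } else if (mode == "sum") {
    list(out = as.matrix(batch$agg_sum %*% g_edge), cache = NULL)
  } else {
    out <- matrix(-Inf, batch$m_tot, ncol(g_edge))
    amax <- matrix(0L, batch$m_tot, ncol(g_edge))
    for (v in seq_len(batch$m_tot)) {
      m <- batch$mol_of_vertex[v]
      n <- batch$sizes[m]
      i_local <- v - batch$v_off[m]
      rows <- batch$e_off[m] + (i_local - 1L) * n + seq_len(n)
      blk <- g_edge[rows, , drop = FALSE]
      k <- max.col(t(blk), ties.method = "first")
      out[v, ] <- blk[cbind(k, seq_len(ncol(blk)))]
      amax[v, ] <- rows[k]
    }
    list(out = out, cache = amax)
  }
}

#' @noRd
agg_bwd <- function(dout, g_edge_dim, batch, mode, cache) {
  d <- ncol(dout) / 3L
  dall <- dout[, seq_len(d), drop = FALSE]
  dbond <- dout[, d + seq_len(d), drop = FALSE]
  dgem <- dout[, 2L * d + seq_len(d), drop = FALSE]
  agg_bwd_all(dall, g_edge_dim, batch, mode, cache) +
    as.matrix(Matrix::crossprod(batch$agg_bond, dbond)) +
    as.matrix(Matrix::crossprod(batch$agg_gem, dgem))
}

#' @noRd
agg_bwd_all <- function(dout, g_edge_dim, batch, mode, cache) {
  if (mode == "mean") {
    as.matrix(Matrix::crossprod(batch$agg_mean, dout))
  } else if (mode == "sum") {
    as.matrix(Matrix::crossprod(batch$agg_sum, dout))
  } else {
    dg <- matrix(0, g_edge_dim, ncol(dout))
    for (v in seq_len(nrow(dout))) {
      idx <- cbind(cache[v, ], seq_len(ncol(dout)))
      dg[idx] <- dg[idx] + dout[v, ]
    }
    dg
  }
}

#' Scatter-add edge-row gradients onto vertices
#' @noRd
scatter_vertex <- function(x, idx, m_tot) {
  out <- rowsum(x, group = idx)
  full <- matrix(0, m_tot, ncol(x))
  full[as.integer(rownames(out)), ] <- out
  full
}
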