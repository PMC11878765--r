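# Cell graph construction: Pearson similarity, network-enhancement
# denoising, KNN adjacency, and the high-order neighbour masks that feed
# the triplet loss.

#' Pearson similarity between cells
#'
#' Correlation of cell columns of a features x cells matrix.  Symmetric,
#' unit diagonal, entries in \[-1, 1\].
#'
#' @param y features x cells numeric matrix (e.g. the reduced model input
#'   or a latent embedding).
#' @return n x n similarity matrix.
#' @export
pearson_similarity <- function(y) {
  if (ncol(y) < 2) stop("need at least 2 cells")
  sdv <- apply(y, 2, stats::sd)
  if (any(sdv == 0)) {
    bad <- colnames(y)[sdv == 0]
    if (is.null(bad)) bad <- which(sdv == 0)
    stop("zero-variance cell(s): ", paste(bad, collapse = ", "))
  }
  s <- stats::cor(y)
  diag(s) <- 1
  s
}

#' Network-enhancement denoising of a similarity matrix
#'
#' Diffusion-based denoising that amplifies strong, transitively supported
#' edges and damps weak ones.  Each node's `k_ne` strongest partners (ties
#' at the threshold included) define a localized row-stochastic matrix `P`;
#' a transition `T` with `T_ij = sum_v P_iv P_jv / sum_u P_uv`
#' (self-transitions removed, rows renormalized) then drives the update
#' `W <- T W t(T)` for a fixed number of iterations.  Self-similarities on
#' the diagonal of `s` take part in the diffusion (they carry the
#' common-neighbour signal) but the returned diagonal is zero.  Denoising
#' presupposes `k_ne` below the typical community size; the pipeline
#' default `min(20, n - 1)` is tuned to data sets with hundreds of cells
#' or more.
#'
#' @param s symmetric non-negative similarity matrix (clip negative
#'   correlations to zero before calling).
#' @param k_ne neighbourhood size of the localization (default
#'   `min(20, n - 1)`).
#' @param iterations number of diffusion updates (default 2).
#' @return enhanced symmetric non-negative matrix, same dimensions.
#' @export
network_enhance <- function(s, k_ne = NULL, iterations = 2L) {
  n <- nrow(s)
  if (n != ncol(s)) stop("similarity matrix must be square")
  if (any(s < 0)) stop("network_enhance expects non-negative similarities")
  if (max(abs(s - t(s))) > 1e-8) stop("similarity matrix must be symmetric")
  w <- s                              # self-similarity kept during diffusion
  wo <- w
  diag(wo) <- 0
  if (all(wo == 0)) stop("all-zero similarity matrix")
  if (is.null(k_ne)) k_ne <- min(20L, n - 1L)
  k_ne <- max(1L, min(as.integer(k_ne), n - 1L))

  # localized graph: keep, per row, off-diagonal entries >= the k_ne-th
  # largest (ties included so permutation symmetry of the input survives)
  loc <- wo
  for (i in seq_len(n)) {
    row <- wo[i, ]
    thr <- sort(row, decreasing = TRUE)[k_ne]
    loc[i, row < thr | row == 0] <- 0
  }
  loc <- (loc + t(loc)) / 2
  rs <- rowSums(loc)
  if (any(rs == 0)) {
    # isolated node under localization: fall back to its full row
    for (i in which(rs == 0)) loc[i, ] <- wo[i, ]
    rs <- rowSums(loc)
    if (any(rs == 0)) stop("node(s) with no positive similarity to any other")
  }
  p <- loc / rs
  cs <- colSums(p)
  tr <- p %*% (t(p) / cs)           # T_ij = sum_v P_iv P_jv / colsum_v
  diag(tr) <- 0                     # drop self-transitions, renormalize
  tr <- tr / rowSums(tr)
  for (it in seq_len(iterations)) {
    w <- tr %*% w %*% t(tr)
  }
  w <- (w + t(w)) / 2
  diag(w) <- 0
  dimnames(w) <- dimnames(s)
  w
}

#' Threshold-denoise a similarity matrix
#'
#' Keeps the raw similarity wherever the enhanced similarity passes the
#' threshold: `E_ij = S_ij` if `Ehat_ij >= t`, else 0.
#'
#' @param s_raw raw similarity matrix S.
#' @param s_enh enhanced similarity matrix (same dimensions).
#' @param t threshold on the enhanced values (default `1e-5`, dropping
#'   numerically dead edges).
#' @param verbose log the fraction of entries zeroed.
#' @return denoised similarity matrix E.
#' @export
denoise_threshold <- function(s_raw, s_enh, t = 1e-5, verbose = FALSE) {
  if (!all(dim(s_raw) == dim(s_enh))) stop("dimension mismatch")
  keep <- s_enh >= t
  e <- s_raw * keep
  if (verbose) {
    off <- row(keep) != col(keep)
    message(sprintf("denoise_threshold: zeroed %.1f%% of off-diagonal entries",
                    100 * mean(!keep[off])))
  }
  e
}

#' Number of nearest neighbours for the cell graph
#'
#' `K = round(n_cells / (10 * n_clusters))`, clipped to \[6, 20\].
#'
#' @param n_cells number of cells.
#' @param n_clusters target number of clusters.
#' @return integer K.
#' @export
choose_K <- function(n_cells, n_clusters) {
  if (n_cells <= 0 || n_clusters <= 0) stop("counts must be positive")
  k <- round(n_cells / (10 * n_clusters))
  as.integer(min(20, max(6, k)))
}

#' K-nearest-neighbour adjacency from a similarity matrix
#'
#' Marks, for every cell, its `K` highest-similarity partners (self
#' excluded; ties at the K-th value broken by lowest cell index), then
#' symmetrizes by union.  Zero diagonal.
#'
#' @param e n x n similarity matrix.
#' @param K neighbours per cell, `1 <= K < n`.
#' @return binary n x n adjacency matrix.
#' @export
knn_adjacency <- function(e, K) {
  n <- nrow(e)
  if (K >= n) stop("K must be smaller than the number of cells")
  if (K < 1) stop("K must be >= 1")
  a <- matrix(0, n, n, dimnames = dimnames(e))
  for (i in seq_len(n)) {
    s <- e[i, ]
    s[i] <- -Inf
    top <- order(-s, seq_len(n))[seq_len(K)]   # stable: ties by low index
    a[i, top] <- 1
  }
  a <- pmax(a, t(a))                            # union symmetrization
  diag(a) <- 0
  a
}

#' High-order neighbour masks for the triplet loss
#'
#' Expands a first-order adjacency into masks over cell pairs: `A_prime`
#' holds positive pairs weighted by neighbour order (`omega[k]` for a pair
#' at shortest-path distance k, k = 1..r), `C` marks all pairs within
#' distance r, and `B = 1 - C` (zero diagonal) marks the negative pairs.
#' A pair enters order k exactly when a walk of length k exists but none
#' shorter, i.e. its shortest-path distance is k; the k-th binarized
#' matrix power minus the running cumulative adjacency realizes this.
#' Diagonals are forced to zero at every step: a cell is never its own
#' positive or negative.
#'
#' @param A binary symmetric adjacency with zero diagonal.
#' @param r maximum neighbour order (>= 1).
#' @param omega numeric vector of per-order weights `omega[1..r]`
#'   (`omega[1]` weights direct neighbours; default `c(1, 0.5)`).
#' @return list with `A_prime` (weighted positive mask), `C` (binary
#'   cumulative adjacency), `B` (binary negative mask), `orders` (list of
#'   binary matrices, one per order k), `r`, `omega`.
#' @export
high_order_adjacency <- function(A, r = 2L, omega = c(1, 0.5)) {
  n <- nrow(A)
  if (n != ncol(A)) stop("adjacency must be square")
  if (any(A != t(A))) stop("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency must have zero diagonal")
  if (r < 1) stop("r must be >= 1")
  if (length(omega) < r) {
    stop("omega must supply a weight for every order 1..r")
  }
  A <- (A > 0) * 1
  a_prime <- omega[1] * A
  cum <- A
  ak <- A
  orders <- vector("list", r)
  orders[[1]] <- A
  if (r >= 2) {
    for (k in 2:r) {
      ak <- (ak %*% A > 0) * 1       # walks of length k, binarized
      diag(ak) <- 0
      new_k <- ak * (1 - cum)        # first reached at order k
      orders[[k]] <- new_k
      a_prime <- a_prime + omega[k] * new_k
      cum <- ((ak + cum) > 0) * 1
      diag(cum) <- 0
    }
  }
  b <- 1 - cum
  diag(b) <- 0
  dimnames(a_prime) <- dimnames(cum) <- dimnames(b) <- dimnames(A)
  list(A_prime = a_prime, C = cum, B = b, orders = orders,
       r = as.integer(r), omega = omega[seq_len(r)])
}

#' Build the denoised cell graph and triplet masks in one call
#'
#' Pearson similarity on the model input, network enhancement on the
#' non-negative part, threshold denoising, KNN adjacency with `K` chosen
#' by [choose_K()] unless given, and high-order masks.
#'
#' @param y features x cells matrix (reduced model input).
#' @param n_clusters target cluster count (drives the default K).
#' @param K neighbours per cell; `NULL` for the [choose_K()] rule.
#' @param t threshold for [denoise_threshold()].
#' @param r,omega passed to [high_order_adjacency()].
#' @param k_ne,ne_iterations passed to [network_enhance()].
#' @param verbose log intermediate statistics.
#' @return list with `S` (raw similarity), `E` (denoised), `A`
#'   (adjacency), `masks` (high-order masks), `K`.
#' @export
build_cell_graph <- function(y, n_clusters, K = NULL, t = 1e-5, r = 2L,
                             omega = c(1, 0.5), k_ne = NULL,
                             ne_iterations = 2L, verbose = FALSE) {
  s <- pearson_similarity(y)
  enh <- network_enhance(pmax(s, 0), k_ne = k_ne, iterations = ne_iterations)
  e <- denoise_threshold(s, enh, t = t, verbose = verbose)
  if (is.null(K)) K <- choose_K(ncol(y), n_clusters)
  a <- knn_adjacency(e, K)
  masks <- high_order_adjacency(a, r = r, omega = omega)
  if (verbose) {
    message(sprintf(
      "cell graph: n=%d K=%d edges=%d positives(nnz A')=%d negatives=%d",
      ncol(y), K, sum(a) / 2, sum(masks$A_prime > 0), sum(masks$B > 0)))
  }
  list(S = s, E = e, A = a, masks = masks, K = as.integer(K))
}

#' Export an adjacency or weighted mask as an edge list
#'
#' @param m square matrix (adjacency or weighted mask).
#' @param path output TSV path (`cell_i`, `cell_j`, `weight`), upper
#'   triangle only.
#' @export
write_edge_list <- function(m, path) {
  idx <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  ids_i <- if (is.null(rownames(m))) idx[, 1] else rownames(m)[idx[, 1]]
  ids_j <- if (is.null(colnames(m))) idx[, 2] else colnames(m)[idx[, 2]]
  df <- data.frame(cell_i = ids_i, cell_j = ids_j, weight = m[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
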