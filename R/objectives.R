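# Loss components: high-order triplet loss on the embedding similarity,
# DEC-style soft assignments / target distribution / KL clustering loss,
# center updates, and the joint loss.

#' High-order triplet loss on embedding similarities
#'
#' Computes the Pearson similarity matrix `S'` of the embedding columns,
#' then the mean similarity over positive pairs (`s+`, weighted by the
#' high-order mask `A'`, averaged over the count `n+` of nonzero `A'`
#' entries) and over negative pairs (`s-`, mask `B`, count `n-`), and
#' returns `max(s- - s+ + margin, 0)`: positives must be more similar than
#' negatives by at least the margin.  `as_printed = TRUE` flips the sign
#' convention to `max(s+ - s- + margin, 0)` for comparison.
#'
#' @param Z d x n embedding matrix.
#' @param masks list with `A_prime` and `B` from [high_order_adjacency()].
#' @param margin triplet margin (default 0.2).
#' @param as_printed use the alternate sign convention.
#' @return scalar loss in `[0, 2 + margin]`.
#' @export
triplet_loss <- function(Z, masks, margin = 0.2, as_printed = FALSE) {
  triplet_loss_impl(Z, masks, margin, as_printed)$loss
}

triplet_loss_impl <- function(Z, masks, margin, as_printed = FALSE) {
  ap <- masks$A_prime
  b <- masks$B
  n <- ncol(Z)
  if (nrow(ap) != n) stop("mask dimensions do not match the embedding")
  n_pos <- sum(ap > 0)
  n_neg <- sum(b > 0)
  if (n_pos == 0) {
    stop("no positive pairs (A' is empty): increase K or the order r")
  }
  if (n_neg == 0) {
    stop("no negative pairs (C covers all pairs): decrease K or the order r")
  }
  zc <- sweep(Z, 2, colMeans(Z))
  nrm <- sqrt(colSums(zc^2))
  if (any(nrm == 0)) stop("constant embedding column(s); cannot correlate")
  zh <- sweep(zc, 2, nrm, `/`)
  sim <- crossprod(zh)
  s_pos <- sum(ap * sim) / n_pos
  s_neg <- sum(b * sim) / n_neg
  gap <- if (as_printed) s_pos - s_neg else s_neg - s_pos
  loss <- max(gap + margin, 0)
  list(loss = loss, s_pos = s_pos, s_neg = s_neg, sim = sim,
       zh = zh, zc = zc, nrm = nrm, n_pos = n_pos, n_neg = n_neg,
       active = gap + margin > 0, as_printed = as_printed)
}

# Gradient of triplet_loss with respect to Z (d x n).
triplet_grad <- function(Z, masks, margin = 0.2, as_printed = FALSE) {
  tl <- triplet_loss_impl(Z, masks, margin, as_printed)
  if (!tl$active) return(matrix(0, nrow(Z), ncol(Z)))
  sgn <- if (as_printed) -1 else 1
  dS <- sgn * (masks$B / tl$n_neg - masks$A_prime / tl$n_pos)
  dzh <- tl$zh %*% (dS + t(dS))
  # through column normalization zh = zc / |zc|
  proj <- colSums(tl$zh * dzh)
  dzc <- sweep(dzh - sweep(tl$zh, 2, proj, `*`), 2, tl$nrm, `/`)
  # through column centering zc = z - mean(z)
  sweep(dzc, 2, colMeans(dzc))
}

#' Student's-t soft cluster assignments
#'
#' `q_ji = (1 + ||z_i - u_j||^2)^-1`, normalized over clusters for each
#' cell (DEC soft assignment).
#'
#' @param Z d x n embedding matrix (cells in columns).
#' @param U c x d matrix of cluster centers (one per row).
#' @return c x n matrix `Q`; each cell's column sums to 1.
#' @export
soft_assign <- function(Z, U) {
  f <- student_kernel(Z, U)
  sweep(f, 2, colSums(f), `/`)
}

# unnormalized kernel f_ji = 1 / (1 + ||z_i - u_j||^2), c x n
student_kernel <- function(Z, U) {
  if (ncol(U) != nrow(Z)) stop("center width does not match embedding")
  d2 <- outer(rowSums(U^2), colSums(Z^2), `+`) - 2 * U %*% Z
  1 / (1 + pmax(d2, 0))
}

#' DEC target distribution
#'
#' Squares each membership, divides by its cluster's total mass
#' `f_j = sum_i q_ji`, and renormalizes per cell — sharpening confident
#' assignments while balancing cluster size.
#'
#' @param Q c x n soft-assignment matrix.
#' @return c x n target matrix `P`, columns summing to 1.
#' @export
target_distribution <- function(Q) {
  f <- rowSums(Q)
  if (any(f == 0)) {
    stop("empty cluster (zero total mass) at index: ",
         paste(which(f == 0), collapse = ", "))
  }
  w <- Q^2 / f
  sweep(w, 2, colSums(w), `/`)
}

#' KL clustering loss
#'
#' `L_c = sum_ji p_ji log(p_ji / q_ji)`, the KL divergence of the soft
#' assignments from the (fixed) target distribution; terms with
#' `p_ji = 0` contribute 0.
#'
#' @param P target distribution (c x n).
#' @param Q soft assignments (c x n).
#' @return scalar, `>= 0`, zero iff `P == Q`.
#' @export
clustering_loss <- function(P, Q) {
  if (!all(dim(P) == dim(Q))) stop("shape mismatch")
  pos <- P > 0
  if (any(Q[pos] == 0)) stop("q = 0 where p > 0: degenerate assignment")
  sum(P[pos] * log(P[pos] / Q[pos]))
}

# Gradient of clustering_loss wrt Z, holding P and U fixed:
# dL/dz_i = 2 * sum_j f_ji (p_ji - q_ji) (z_i - u_j)
clustering_grad <- function(Z, U, P) {
  f <- student_kernel(Z, U)
  Q <- sweep(f, 2, colSums(f), `/`)
  g <- matrix(0, nrow(Z), ncol(Z))
  for (j in seq_len(nrow(U))) {
    w <- 2 * f[j, ] * (P[j, ] - Q[j, ])
    g <- g + sweep(Z - U[j, ], 2, w, `*`)
  }
  g
}

#' Update cluster centers from hard labels and soft weights
#'
#' `u_j` becomes the `q`-weighted mean of the embeddings of cells whose
#' current hard label (argmax of their column of `Q`) is `j`.  A cluster
#' that has lost all its cells keeps its previous center (with a warning).
#'
#' @param Z d x n embedding matrix.
#' @param Q c x n soft assignments.
#' @param U_prev previous centers (c x d), kept for empty clusters.
#' @return c x d matrix of updated centers.
#' @export
update_centers <- function(Z, Q, U_prev = NULL) {
  cc <- nrow(Q)
  lab <- apply(Q, 2, which.max)
  U <- matrix(NA_real_, cc, nrow(Z))
  for (j in seq_len(cc)) {
    in_j <- lab == j
    if (!any(in_j)) {
      if (is.null(U_prev)) stop("cluster ", j, " is empty at initialization")
      warning("cluster ", j, " is empty; keeping previous center")
      U[j, ] <- U_prev[j, ]
    } else {
      w <- Q[j, in_j]
      U[j, ] <- as.vector(Z[, in_j, drop = FALSE] %*% w) / sum(w)
    }
  }
  U
}

#' Joint loss
#'
#' `L = L_r + alpha * L_c + beta * L_triplet` — reconstruction, clustering
#' and triplet components balanced by `alpha` and `beta` (both default 1).
#'
#' @param L_r,L_c,L_triplet the three components.
#' @param alpha weight of the clustering loss.
#' @param beta weight of the triplet loss.
#' @return scalar joint loss.
#' @export
joint_loss <- function(L_r, L_c, L_triplet, alpha = 1, beta = 1) {
  stopifnot(is.finite(L_r), is.finite(L_c), is.finite(L_triplet))
  L_r + alpha * L_c + beta * L_triplet
}
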