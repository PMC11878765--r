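# Training orchestration: MAE pretraining, K-means initialization,
# joint self-optimizing training with silhouette-guided early stopping,
# and clustering evaluation.

# Deterministic sub-seed derivation from one master seed: the master seed
# indexes a stream of independent draws below 2^31.
derive_seeds <- function(seed, names) {
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, length(names))
  stats::setNames(as.integer(s), names)
}

#' Pretrain the autoencoder with the reconstruction loss
#'
#' Adam on `L_r` only, for at most `epochs` epochs with a loss-plateau
#' early stop (relative improvement below `tol` for `patience` epochs).
#'
#' @param Y D x n reduced input.
#' @param A binary adjacency of the cell graph.
#' @param epochs maximum epochs (default 100).
#' @param lr learning rate (default 2e-4).
#' @param d,hidden,heads architecture, passed to [gat_init()].
#' @param seed initialization seed.
#' @param patience,tol plateau early-stopping controls.
#' @param verbose print the loss every 10 epochs.
#' @return list with `model`, `Z` (final embedding), `history`
#'   (data.frame epoch/L_r), `L_r_first`, `L_r_final`.
#' @export
pretrain <- function(Y, A, epochs = 100L, lr = 2e-4, d = 64L,
                     hidden = 256L, heads = 4L, seed = 0L,
                     patience = 10L, tol = 1e-4, verbose = FALSE) {
  graph <- graph_edges(A)
  model <- gat_init(nrow(Y), d = d, hidden = hidden, heads = heads,
                    seed = seed)
  state <- adam_init(model)
  hist <- data.frame(epoch = integer(), L_r = numeric())
  fw <- gat_forward(model, Y, graph)
  if (epochs < 1) {
    warning("epochs_pretrain = 0: returning randomly-initialized embedding")
    return(list(model = model, Z = fw$Z, history = hist,
                L_r_first = NA_real_, L_r_final = NA_real_))
  }
  best <- Inf
  stall <- 0L
  lr_first <- NA_real_
  for (ep in seq_len(epochs)) {
    fw <- gat_forward(model, Y, graph)
    L_r <- reconstruction_loss(Y, fw$Y_prime)
    if (!is.finite(L_r)) stop("non-finite reconstruction loss at epoch ", ep)
    if (ep == 1) lr_first <- L_r
    hist <- rbind(hist, data.frame(epoch = ep, L_r = L_r))
    if (verbose && ep %% 10 == 0) {
      message(sprintf("pretrain epoch %d: L_r = %.4f", ep, L_r))
    }
    grads <- gat_backward(model, fw, reconstruction_grad(Y, fw$Y_prime))
    up <- adam_step(model, grads, state, lr, ep)
    model <- up$model
    state <- up$state
    if (L_r < best * (1 - tol)) {
      best <- L_r
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  fw <- gat_forward(model, Y, graph)
  L_final <- reconstruction_loss(Y, fw$Y_prime)
  list(model = model, Z = fw$Z, history = hist,
       L_r_first = lr_first, L_r_final = L_final)
}

#' K-means initialization of the cluster centers
#'
#' @param Z d x n embedding.
#' @param c number of clusters (`<= n`).
#' @param seed RNG seed.
#' @param restarts number of K-means restarts (default 20).
#' @return list with `labels` (integer in 1..c) and `centers` (c x d).
#' @export
init_clusters <- function(Z, c, seed = 0L, restarts = 20L) {
  n <- ncol(Z)
  if (c > n) stop("more clusters than cells")
  set.seed(as.integer(seed))
  if (c == n) {
    return(list(labels = seq_len(n), centers = t(Z)))
  }
  km <- stats::kmeans(t(Z), centers = c, nstart = restarts,
                      iter.max = 100L)
  list(labels = as.integer(km$cluster), centers = km$centers)
}

#' Mean silhouette score of a labelled embedding
#'
#' Per cell, `s_i = (b_i - a_i) / max(a_i, b_i)` with `a_i` the mean
#' Euclidean distance to its own cluster and `b_i` the smallest mean
#' distance to another cluster; cells in singleton clusters score 0.
#' Large `n` is handled by scoring a seeded subsample.
#'
#' @param Z d x n embedding (distances between columns).
#' @param labels integer cluster labels, length n; at least two distinct.
#' @param max_cells subsample ceiling (default 2000).
#' @param seed subsample seed.
#' @return mean silhouette over (sub)sampled cells.
#' @export
silhouette_score <- function(Z, labels, max_cells = 2000L, seed = 0L) {
  n <- ncol(Z)
  if (length(labels) != n) stop("label length mismatch")
  if (length(unique(labels)) < 2) stop("need at least 2 clusters")
  if (n > max_cells) {
    set.seed(as.integer(seed))
    keep <- sort(sample.int(n, max_cells))
    Z <- Z[, keep, drop = FALSE]
    labels <- labels[keep]
    if (length(unique(labels)) < 2) stop("subsample lost all but one cluster")
    n <- max_cells
  }
  dm <- as.matrix(stats::dist(t(Z)))
  sizes <- table(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    li <- labels[i]
    if (sizes[[as.character(li)]] == 1) {
      s[i] <- 0
      next
    }
    a_i <- sum(dm[i, labels == li]) / (sizes[[as.character(li)]] - 1)
    b_i <- min(vapply(setdiff(names(sizes), as.character(li)), function(g) {
      mean(dm[i, labels == as.integer(g)])
    }, numeric(1)))
    s[i] <- if (max(a_i, b_i) == 0) 0 else (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}

#' Joint self-optimizing training
#'
#' Starting from a pretrained model and K-means centers, optimizes
#' `L = L_r + alpha * L_c + beta * L_triplet` with Adam.  The target
#' distribution `P` and the centers are refreshed every
#' `p_refresh_interval` epochs (P is held fixed in between, standard DEC
#' practice); at each refresh the mean silhouette of the current embedding
#' under the current hard labels is recorded, and training stops after
#' `patience` refreshes without improvement.  The returned labels come
#' from the best-silhouette checkpoint.
#'
#' @param Y,A reduced input and adjacency.
#' @param masks high-order masks from [high_order_adjacency()].
#' @param c number of clusters.
#' @param pre result of [pretrain()].
#' @param epochs maximum joint epochs (default 2000).
#' @param lr learning rate (default 5e-4).
#' @param alpha,beta,margin loss weights and triplet margin.
#' @param p_refresh_interval epochs between P/center refreshes
#'   (default 10).
#' @param patience refreshes without silhouette improvement before
#'   stopping (default 5).
#' @param seed seed for K-means initialization and silhouette subsampling.
#' @param as_printed alternate triplet sign convention.
#' @param verbose print progress at refreshes.
#' @return list with `labels`, `Z` (best-checkpoint embedding), `centers`,
#'   `model`, `history` (epoch, L_r, L_c, L_triplet, L, silhouette),
#'   `silhouette_best`.
#' @export
train_joint <- function(Y, A, masks, c, pre, epochs = 2000L, lr = 5e-4,
                        alpha = 1, beta = 1, margin = 0.2,
                        p_refresh_interval = 10L, patience = 5L,
                        seed = 0L, as_printed = FALSE, verbose = FALSE) {
  graph <- graph_edges(A)
  seeds <- derive_seeds(seed, c("kmeans", "sil"))
  model <- pre$model
  state <- adam_init(model)
  init <- init_clusters(pre$Z, c, seed = seeds[["kmeans"]])
  U <- init$centers
  fw <- gat_forward(model, Y, graph)
  Q <- soft_assign(fw$Z, U)
  P <- target_distribution(Q)
  hist <- vector("list", epochs)
  best_sil <- -Inf
  best <- list(labels = init$labels, Z = pre$Z, centers = U, model = model)
  stall <- 0L
  for (ep in seq_len(epochs)) {
    fw <- gat_forward(model, Y, graph)
    refresh <- (ep %% p_refresh_interval == 0) || ep == 1
    if (refresh) {
      Qd <- soft_assign(fw$Z, U)
      U <- update_centers(fw$Z, Qd, U_prev = U)
      Qd <- soft_assign(fw$Z, U)
      P <- target_distribution(Qd)
    }
    Q <- soft_assign(fw$Z, U)
    L_r <- reconstruction_loss(Y, fw$Y_prime)
    L_c <- clustering_loss(P, Q)
    tl <- triplet_loss_impl(fw$Z, masks, margin, as_printed)
    L <- joint_loss(L_r, L_c, tl$loss, alpha, beta)
    if (!is.finite(L)) stop("non-finite joint loss at epoch ", ep)
    sil <- NA_real_
    if (refresh) {
      lab <- apply(Q, 2, which.max)
      sil <- if (length(unique(lab)) < 2) -1 else {
        silhouette_score(fw$Z, lab, seed = seeds[["sil"]])
      }
      if (sil > best_sil) {
        best_sil <- sil
        best <- list(labels = as.integer(lab), Z = fw$Z, centers = U,
                     model = model)
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      if (verbose) {
        message(sprintf(
          "joint epoch %d: L_r=%.3f L_c=%.4f L_t=%.4f silhouette=%.4f",
          ep, L_r, L_c, tl$loss, sil))
      }
    }
    hist[[ep]] <- data.frame(epoch = ep, L_r = L_r, L_c = L_c,
                             L_triplet = tl$loss, L = L, silhouette = sil)
    if (stall >= patience) break
    dZ <- alpha * clustering_grad(fw$Z, U, P) +
      beta * triplet_grad(fw$Z, masks, margin, as_printed)
    grads <- gat_backward(model, fw, reconstruction_grad(Y, fw$Y_prime),
                          dZ_extra = dZ)
    up <- adam_step(model, grads, state, lr, ep)
    model <- up$model
    state <- up$state
  }
  list(labels = best$labels, Z = best$Z, centers = best$centers,
       model = best$model, history = do.call(rbind, hist),
       silhouette_best = best_sil)
}

#' Clustering agreement with a reference partition
#'
#' Adjusted Rand Index and Normalized Mutual Information between two
#' labelings (label-permutation invariant).
#'
#' @param labels predicted cluster labels.
#' @param truth reference labels, same length.
#' @return named list with `ari` and `nmi`.
#' @export
evaluate_clustering <- function(labels, truth) {
  if (length(labels) != length(truth)) stop("length mismatch")
  lab <- as.integer(factor(labels))
  tru <- as.integer(factor(truth))
  list(ari = mclust::adjustedRandIndex(lab, tru),
       nmi = igraph::compare(lab, tru, method = "nmi"))
}
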