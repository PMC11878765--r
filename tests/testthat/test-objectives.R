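# Loss components: triplet loss, DEC soft assignment / target
# distribution / KL loss, center updates, joint loss.

test_that("triplet loss follows the mean-similarity margin contract", {
  # all pairwise similarities equal -> s+ = s- -> loss = margin
  set.seed(1)
  base <- rnorm(5)
  Z <- sapply(1:6, function(i) 2 * base + i)   # all columns perfectly correlated
  A <- adjacency_from_edges(6, list(c(1, 2), c(3, 4)))
  masks <- high_order_adjacency(A, r = 1, omega = 1)
  expect_equal(triplet_loss(Z, masks, margin = 0.2), 0.2)

  # perfect separation: positives at +1, negatives at -1
  v <- rnorm(5)
  Z2 <- cbind(v, v, -v, -v)
  A2 <- adjacency_from_edges(4, list(c(1, 2), c(3, 4)))
  masks2 <- high_order_adjacency(A2, r = 1, omega = 1)
  expect_equal(triplet_loss(Z2, masks2, margin = 0.2), 0)
  # literal sign convention: max{s+ - s- + margin, 0} = 2.2
  expect_equal(triplet_loss(Z2, masks2, margin = 0.2, as_printed = TRUE),
               2.2)

  # seeded 8-cell instance vs a pair-enumeration oracle
  set.seed(8)
  Z3 <- matrix(rnorm(4 * 8), 4, 8)
  A3 <- random_adjacency(8, 0.3, 77)
  masks3 <- high_order_adjacency(A3, r = 2, omega = c(1, 0.5))
  sim <- cor(Z3)
  sp <- 0; sn <- 0; np <- 0; nn <- 0
  for (i in 1:8) for (j in 1:8) {
    if (masks3$A_prime[i, j] > 0) {
      sp <- sp + masks3$A_prime[i, j] * sim[i, j]; np <- np + 1
    }
    if (masks3$B[i, j] > 0) { sn <- sn + sim[i, j]; nn <- nn + 1 }
  }
  oracle <- max(sn / nn - sp / np + 0.2, 0)
  expect_lt(abs(triplet_loss(Z3, masks3, margin = 0.2) - oracle), 1e-10)

  # degenerate masks are rejected with guidance
  empty <- list(A_prime = matrix(0, 8, 8), B = masks3$B)
  expect_error(triplet_loss(Z3, empty, 0.2), "positive pairs")
  full <- list(A_prime = masks3$A_prime, B = matrix(0, 8, 8))
  expect_error(triplet_loss(Z3, full, 0.2), "negative pairs")
})

test_that("triplet loss is bounded and its gradient closes the gap", {
  ns <- asNamespace("scTripletClust")
  set.seed(31)
  for (rep in 1:5) {
    Z <- matrix(rnorm(3 * 7), 3, 7)
    A <- random_adjacency(7, 0.4, rep)
    if (all(A == 0)) next
    masks <- high_order_adjacency(A, r = 2, omega = c(1, 0.5))
    if (sum(masks$B) == 0 || sum(masks$A_prime) == 0) next
    l <- triplet_loss(Z, masks, margin = 0.2)
    expect_gte(l, 0)
    expect_lte(l, 2.2)
    # one small gradient step must not widen s- - s+
    gap <- function(Z) {
      tl <- ns$triplet_loss_impl(Z, masks, 0.2)
      tl$s_neg - tl$s_pos
    }
    g <- ns$triplet_grad(Z, masks, 0.2)
    expect_lte(gap(Z - 1e-4 * g), gap(Z) + 1e-12)
    # and the analytic gradient matches finite differences
    eps <- 1e-6
    for (idx in sample(length(Z), 3)) {
      Zp <- Z; Zp[idx] <- Zp[idx] + eps
      Zm <- Z; Zm[idx] <- Zm[idx] - eps
      num <- (triplet_loss(Zp, masks, 0.2) -
                triplet_loss(Zm, masks, 0.2)) / (2 * eps)
      expect_lt(abs(num - g[idx]), 1e-6)
    }
  }
})

test_that("soft assignment is the normalized Student's-t kernel", {
  Z <- matrix(c(0, 0, 1, 1, 3, 3), 2, 3)
  # c = 1: every cell fully assigned
  expect_equal(soft_assign(Z, matrix(c(1, 1), 1, 2)),
               matrix(1, 1, 3), ignore_attr = TRUE)
  # equidistant -> 1/2 each
  U <- rbind(c(0, 0), c(2, 2))
  q <- soft_assign(matrix(c(1, 1), 2, 1), U)
  expect_equal(as.vector(q), c(0.5, 0.5))
  # distances 0 and 1 -> (2/3, 1/3)
  U2 <- rbind(c(0, 0), c(1, 0))
  q2 <- soft_assign(matrix(c(0, 0), 2, 1), U2)
  expect_equal(as.vector(q2), c(2 / 3, 1 / 3))
  # columns always sum to 1
  set.seed(14)
  q3 <- soft_assign(matrix(rnorm(20), 4, 5), matrix(rnorm(12), 3, 4))
  expect_lt(max(abs(colSums(q3) - 1)), 1e-8)
})

test_that("target distribution sharpens memberships per cell", {
  # one-hot Q is a fixed point
  Q <- rbind(c(1, 0), c(0, 1))
  expect_equal(target_distribution(Q), Q)
  # uniform Q stays uniform
  Qu <- matrix(0.5, 2, 2)
  expect_equal(target_distribution(Qu), Qu)
  # column (2/3, 1/3) with equal cluster masses -> (4/5, 1/5)
  Qe <- cbind(c(2 / 3, 1 / 3), c(1 / 3, 2 / 3))
  P <- target_distribution(Qe)
  expect_equal(P[, 1], c(4 / 5, 1 / 5))
  expect_lt(max(abs(colSums(P) - 1)), 1e-8)
  expect_error(target_distribution(rbind(c(1, 1), c(0, 0))), "empty cluster")
  # sharpening never flips a confident (one-hot) assignment: a one-hot Q
  # covering every cluster is a fixed point, so argmax labels agree
  hard <- cbind(diag(3), c(0, 0, 1))
  expect_equal(apply(target_distribution(hard), 2, which.max),
               apply(hard, 2, which.max))
})

test_that("clustering loss is the KL divergence with Gibbs properties", {
  Q <- cbind(c(0.5, 0.5), c(0.9, 0.1))
  expect_equal(clustering_loss(Q, Q), 0)
  P <- cbind(c(1, 0), c(0.5, 0.5))
  expect_gte(clustering_loss(P, Q), 0)
  # single-cell case P=(1,0), Q=(1/2,1/2) -> log 2
  expect_equal(clustering_loss(matrix(c(1, 0), 2, 1),
                               matrix(c(0.5, 0.5), 2, 1)), log(2))
  expect_error(clustering_loss(matrix(c(1, 0), 2, 1),
                               matrix(c(0, 1), 2, 1)), "degenerate")
  expect_error(clustering_loss(P, Q[, 1, drop = FALSE]), "mismatch")
  # and the Z-gradient (P fixed) matches finite differences
  ns <- asNamespace("scTripletClust")
  set.seed(16)
  Z <- matrix(rnorm(12), 3, 4)
  U <- matrix(rnorm(6), 2, 3)
  Pf <- target_distribution(soft_assign(Z, U))
  g <- ns$clustering_grad(Z, U, Pf)
  eps <- 1e-6
  for (idx in sample(length(Z), 5)) {
    Zp <- Z; Zp[idx] <- Zp[idx] + eps
    Zm <- Z; Zm[idx] <- Zm[idx] - eps
    num <- (clustering_loss(Pf, soft_assign(Zp, U)) -
              clustering_loss(Pf, soft_assign(Zm, U))) / (2 * eps)
    expect_lt(abs(num - g[idx]), 1e-6)
  }
})

test_that("center updates are Q-weighted means over hard assignments", {
  Z <- matrix(c(1, 1, 3, 3, 5, 5), 2, 3)
  # all cells in one cluster with equal q -> arithmetic mean
  Q <- rbind(c(0.6, 0.6, 0.6), c(0.4, 0.4, 0.4))
  U <- suppressWarnings(update_centers(Z, Q, U_prev = matrix(0, 2, 2)))
  expect_equal(U[1, ], c(3, 3))
  expect_warning(update_centers(Z, Q, U_prev = matrix(7, 2, 2)), "empty")
  # single cell per cluster -> that cell's embedding
  Q2 <- diag(3)
  U2 <- update_centers(matrix(c(1, 2, 3, 4, 5, 6), 2, 3), Q2)
  expect_equal(U2, rbind(c(1, 2), c(3, 4), c(5, 6)))
  # weighted 3-cell case vs loop oracle
  set.seed(17)
  Z3 <- matrix(rnorm(8), 2, 4)
  Q3 <- sweep(matrix(runif(8), 2, 4), 2, colSums(matrix(runif(8), 2, 4)), "/")
  Q3 <- sweep(matrix(runif(8, 0.1, 1), 2, 4), 2, 1, "/")
  Q3 <- sweep(Q3, 2, colSums(Q3), "/")
  lab <- apply(Q3, 2, which.max)
  U3 <- suppressWarnings(update_centers(Z3, Q3, U_prev = matrix(0, 2, 2)))
  for (j in unique(lab)) {
    cells <- which(lab == j)
    num <- rep(0, 2); den <- 0
    for (i in cells) {
      num <- num + Q3[j, i] * Z3[, i]
      den <- den + Q3[j, i]
    }
    expect_lt(max(abs(U3[j, ] - num / den)), 1e-12)
  }
})

test_that("joint loss combines components linearly", {
  expect_equal(joint_loss(1.5, 9, 9, alpha = 0, beta = 0), 1.5)
  expect_equal(joint_loss(1, 2, 3), 6)
  expect_equal(joint_loss(1.5, 0.25, 0.5, alpha = 2, beta = 4), 4)
  expect_error(joint_loss(Inf, 0, 0), "finite")
})
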