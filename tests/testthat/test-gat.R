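# Graph-attentional autoencoder: attention operations, forward shapes,
# analytic gradients, and equivariance.

test_that("attention scores are a symmetric Gaussian kernel on edges", {
  set.seed(4)
  n <- 4; D <- 3
  h <- matrix(rnorm(D * n), D, n)
  h[, 2] <- h[, 1]                       # identical cells
  W <- matrix(rnorm(2 * D), 2, D)
  a <- rnorm(2)
  A <- 1 - diag(n)
  e <- attention_scores(h, W, a, A)
  expect_equal(e[1, 2], 1)               # exp(0)
  expect_true(all(e[A > 0] > 0 & e[A > 0] <= 1))
  expect_equal(e, t(e))
  # scalar-by-scalar recomputation
  s <- as.vector(t(a) %*% (W %*% h))
  for (i in 1:n) for (j in 1:n) {
    if (A[i, j] > 0) {
      expect_lt(abs(e[i, j] - exp(-(s[i] - s[j])^2)), 1e-10)
    } else {
      expect_equal(e[i, j], 0)
    }
  }
  expect_error(attention_scores(h, W[, 1:2], a, A), "mismatch")
})

test_that("attention coefficients are a neighbourhood softmax", {
  A <- adjacency_from_edges(3, list(c(1, 2), c(2, 3)))
  e <- matrix(0, 3, 3)
  expect_equal(attention_coefficients(e, A)[1, 2], 1)   # single neighbour
  # equal scores -> uniform
  A4 <- 1 - diag(4)
  alpha <- attention_coefficients(matrix(0.3, 4, 4), A4)
  expect_true(all(abs(alpha[A4 > 0] - 1 / 3) < 1e-12))
  expect_equal(rowSums(alpha), rep(1, 4))
  # scores {0, ln 2} -> (1/3, 2/3)
  A2 <- adjacency_from_edges(3, list(c(1, 2), c(1, 3)))
  e2 <- matrix(0, 3, 3); e2[1, 3] <- log(2)
  alpha2 <- attention_coefficients(e2, A2)
  expect_equal(alpha2[1, 2], 1 / 3)
  expect_equal(alpha2[1, 3], 2 / 3)
  # isolated cell
  Aiso <- matrix(0, 3, 3); Aiso[1, 2] <- Aiso[2, 1] <- 1
  expect_error(attention_coefficients(e, Aiso), "isolated")
})

test_that("layer forward aggregates neighbours and matches a loop oracle", {
  set.seed(6)
  D <- 4
  # all neighbours share one feature vector -> output is ELU(W v)
  v <- rnorm(D)
  h <- cbind(v, v, v, rnorm(D))
  A <- matrix(0, 4, 4); A[4, 1:3] <- 1; A[1:3, 4] <- 1
  A[1, 2] <- A[2, 1] <- 1
  W <- matrix(rnorm(2 * D), 2, D)
  a <- rnorm(2)
  params <- list(W = list(W), a = list(a), combine = "concat")
  out <- attention_layer_forward(h, params, A)
  elu_ref <- function(x) ifelse(x > 0, x, exp(x) - 1)
  expect_equal(out[, 4], elu_ref(as.vector(W %*% v)))

  # two-cell graph, one head: output is ELU of the neighbour's transform
  h2 <- matrix(rnorm(2 * D), D, 2)
  A2 <- matrix(c(0, 1, 1, 0), 2, 2)
  out2 <- attention_layer_forward(h2, params, A2)
  expect_equal(out2[, 1], elu_ref(as.vector(W %*% h2[, 2])))

  # dense multi-head forward vs an explicit per-cell loop
  tg <- tiny_graph_input(n = 6, D = 5, seed = 12)
  params3 <- list(
    W = list(matrix(rnorm(15), 3, 5), matrix(rnorm(15), 3, 5)),
    a = list(rnorm(3), rnorm(3)), combine = "average"
  )
  out3 <- attention_layer_forward(tg$Y, params3, tg$A)
  pre <- matrix(0, 3, 6)
  for (t in 1:2) {
    W <- params3$W[[t]]; a <- params3$a[[t]]
    s <- as.vector(t(a) %*% (W %*% tg$Y))
    for (i in 1:6) {
      nb <- which(tg$A[i, ] > 0)
      w <- exp(exp(-(s[i] - s[nb])^2))
      w <- w / sum(w)
      pre[, i] <- pre[, i] + as.vector((W %*% tg$Y[, nb]) %*% w) / 2
    }
  }
  expect_lt(max(abs(out3 - elu_ref(pre))), 1e-8)
})

test_that("autoencoder forward has the contracted shapes and is deterministic", {
  n <- 20L
  set.seed(2)
  Y <- matrix(rnorm(512 * n), 512, n)
  A <- knn_adjacency(pearson_similarity(Y), 6)
  model <- gat_init(512, d = 64, hidden = 256, heads = 4, seed = 3)
  fw <- gat_forward(model, Y, A)
  expect_identical(dim(fw$Z), c(64L, n))
  expect_identical(dim(fw$Y_prime), c(512L, as.integer(n)))
  fw2 <- gat_forward(model, Y, A)
  expect_identical(fw$Z, fw2$Z)
  expect_identical(fw$Y_prime, fw2$Y_prime)
  model2 <- gat_init(512, seed = 3)
  expect_identical(model$layers[[1]]$W[[1]], model2$layers[[1]]$W[[1]])
  expect_error(gat_forward(model, Y[1:100, ], A), "does not match")
  expect_error(gat_forward(model, Y[, 1, drop = FALSE],
                           matrix(0, 1, 1)), "isolated")
})

test_that("reconstruction loss is the summed absolute error", {
  set.seed(13)
  Y <- matrix(rnorm(12), 3, 4)
  expect_equal(reconstruction_loss(Y, Y), 0)
  expect_equal(reconstruction_loss(Y, Y + 1), 12)
  Yp <- matrix(rnorm(12), 3, 4)
  acc <- 0
  for (i in 1:3) for (j in 1:4) acc <- acc + abs(Y[i, j] - Yp[i, j])
  expect_equal(reconstruction_loss(Y, Yp), acc)
  expect_error(reconstruction_loss(Y, Yp[, 1:2]), "shape")
})

test_that("the autoencoder is permutation-equivariant in the cells", {
  tg <- tiny_graph_input(n = 9, D = 7, seed = 21)
  model <- gat_init(7, d = 3, hidden = 4, heads = 2, seed = 5)
  fw <- gat_forward(model, tg$Y, tg$A)
  set.seed(22)
  perm <- sample(9)
  fw_p <- gat_forward(model, tg$Y[, perm], tg$A[perm, perm])
  expect_equal(fw_p$Z, fw$Z[, perm], tolerance = 1e-12)
  expect_equal(fw_p$Y_prime, fw$Y_prime[, perm], tolerance = 1e-12)
})

test_that("analytic gradients agree with central finite differences", {
  ns <- asNamespace("scTripletClust")
  tg <- tiny_graph_input(n = 8, D = 6, seed = 42)
  Y <- tg$Y
  graph <- ns$graph_edges(tg$A)
  model <- gat_init(6, d = 3, hidden = 4, heads = 2, seed = 1)
  masks <- high_order_adjacency(tg$A, r = 2, omega = c(1, 0.5))
  set.seed(2)
  U <- matrix(rnorm(6), 2, 3)
  fw0 <- gat_forward(model, Y, graph)
  P_fix <- target_distribution(soft_assign(fw0$Z, U))
  loss_all <- function(m) {
    fw <- gat_forward(m, Y, graph)
    Q <- soft_assign(fw$Z, U)
    reconstruction_loss(Y, fw$Y_prime) + clustering_loss(P_fix, Q) +
      triplet_loss(fw$Z, masks, margin = 0.5)
  }
  fw <- gat_forward(model, Y, graph)
  dZ <- ns$clustering_grad(fw$Z, U, P_fix) +
    ns$triplet_grad(fw$Z, masks, 0.5)
  grads <- ns$gat_backward(model, fw,
                           ns$reconstruction_grad(Y, fw$Y_prime),
                           dZ_extra = dZ)
  eps <- 1e-6
  set.seed(3)
  for (l in 1:4) for (t in 1:2) {
    W <- model$layers[[l]]$W[[t]]
    for (idx in sample(length(W), 3)) {
      mp <- model; mp$layers[[l]]$W[[t]][idx] <- W[idx] + eps
      mm <- model; mm$layers[[l]]$W[[t]][idx] <- W[idx] - eps
      num <- (loss_all(mp) - loss_all(mm)) / (2 * eps)
      expect_lt(abs(num - grads[[l]]$W[[t]][idx]) / max(1, abs(num)), 1e-5)
    }
    a <- model$layers[[l]]$a[[t]]
    for (idx in seq_along(a)) {
      mp <- model; mp$layers[[l]]$a[[t]][idx] <- a[idx] + eps
      mm <- model; mm$layers[[l]]$a[[t]][idx] <- a[idx] - eps
      num <- (loss_all(mp) - loss_all(mm)) / (2 * eps)
      expect_lt(abs(num - grads[[l]]$a[[t]][idx]) / max(1, abs(num)), 1e-5)
    }
  }
})

test_that("attention rows sum to one at every layer and head", {
  ns <- asNamespace("scTripletClust")
  tg <- tiny_graph_input(n = 10, D = 6, seed = 31)
  graph <- ns$graph_edges(tg$A)
  model <- gat_init(6, d = 3, hidden = 4, heads = 2, seed = 7)
  H <- tg$Y
  for (l in 1:4) {
    fwl <- ns$layer_forward_edges(model$layers[[l]], H, graph)
    for (t in seq_along(fwl$cache$heads)) {
      alpha <- fwl$cache$heads[[t]]$alpha
      sums <- ns$group_sum(alpha, graph$ei, graph$n)
      expect_lt(max(abs(sums - 1)), 1e-8)
    }
    H <- fwl$out
  }
})

test_that("model parameters survive a save/load round trip", {
  model <- gat_init(6, d = 3, hidden = 4, heads = 2, seed = 9)
  path <- tempfile(fileext = ".yaml")
  gat_save(model, path)
  back <- gat_load(path)
  tg <- tiny_graph_input(n = 6, D = 6, seed = 2)
  fw1 <- gat_forward(model, tg$Y, tg$A)
  fw2 <- gat_forward(back, tg$Y, tg$A)
  expect_equal(fw1$Y_prime, fw2$Y_prime, tolerance = 1e-12)
})
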