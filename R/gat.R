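# Multi-head graph-attentional autoencoder.
#
# The encoder/decoder are written directly in base R + Matrix: forward
# passes keep attention on the edge list of the cell graph (sparse), and
# every layer caches what its analytic backward pass needs.  Gradients are
# validated against finite differences in the test suite.

elu <- function(x) {
  neg <- x < 0
  x[neg] <- exp(x[neg]) - 1
  x
}
elu_grad <- function(x) {
  g <- x
  neg <- x < 0
  g[!neg] <- 1
  g[neg] <- exp(x[neg])
  g
}

# ---- exported, dense reference operations --------------------------------

#' Gaussian-kernel attention scores on graph edges
#'
#' For every edge (i, j) of `A`:
#' `e_ij = exp(-(a . (W h_i) - a . (W h_j))^2)`, a Gaussian kernel on the
#' difference of the cells' projected features.  Non-edges carry no score
#' (zero in the returned matrix).
#'
#' @param h features x cells matrix.
#' @param W transformation matrix (out_dim x in_dim).
#' @param a attention projection vector (length out_dim), shared across
#'   cells.
#' @param A binary adjacency.
#' @return n x n matrix of edge scores, in (0, 1\] on edges.
#' @export
attention_scores <- function(h, W, a, A) {
  if (ncol(W) != nrow(h)) stop("W/h dimension mismatch")
  if (length(a) != nrow(W)) stop("a/W dimension mismatch")
  g <- W %*% h
  s <- as.vector(crossprod(matrix(a, ncol = 1), g))
  e <- exp(-(outer(s, s, `-`))^2)
  e * (A > 0)
}

#' Softmax-normalized attention coefficients
#'
#' `alpha_ij = exp(e_ij) / sum_{k in N_i} exp(e_ik)` over each cell's
#' neighbourhood; rows sum to 1 over the neighbourhood.
#'
#' @param e edge-score matrix from [attention_scores()].
#' @param A binary adjacency; every cell must have at least one neighbour.
#' @return n x n coefficient matrix (zero off-edges).
#' @export
attention_coefficients <- function(e, A) {
  deg <- rowSums(A > 0)
  if (any(deg == 0)) {
    stop("isolated cell(s) at index: ",
         paste(which(deg == 0), collapse = ", "))
  }
  w <- exp(e) * (A > 0)
  w / rowSums(w)
}

#' Forward pass of one multi-head graph-attentional layer (dense reference)
#'
#' Per head: aggregate neighbours' transformed features weighted by the
#' attention coefficients, then apply the activation.  Heads are combined
#' by concatenation (hidden layers) or by averaging pre-activations
#' (bottleneck/output layers).
#'
#' @param h in_dim x n feature matrix.
#' @param params list with `W` (list of per-head matrices), `a` (list of
#'   per-head vectors), `combine` (`"concat"` or `"average"`), and
#'   optional `activation` (`"elu"`, default, or `"linear"`).
#' @param A binary adjacency.
#' @return out x n feature matrix.
#' @export
attention_layer_forward <- function(h, params, A) {
  act <- if (identical(params$activation, "linear")) identity else elu
  heads <- length(params$W)
  outs <- vector("list", heads)
  for (t in seq_len(heads)) {
    e <- attention_scores(h, params$W[[t]], params$a[[t]], A)
    alpha <- attention_coefficients(e, A)
    g <- params$W[[t]] %*% h
    outs[[t]] <- g %*% t(alpha)        # column i = sum_j alpha_ij g_j
  }
  if (identical(params$combine, "average")) {
    act(Reduce(`+`, outs) / heads)
  } else {
    do.call(rbind, lapply(outs, act))
  }
}

# ---- edge-list machinery used for training -------------------------------

# Edge representation of a binary adjacency: for A[i, j] = 1, edge (i <- j)
# with target ei and source ej; every cell must have >= 1 neighbour.
graph_edges <- function(A) {
  deg <- rowSums(A > 0)
  if (any(deg == 0)) {
    stop("isolated cell(s) in the graph: ",
         paste(which(deg == 0), collapse = ", "))
  }
  idx <- which(A > 0, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  list(ei = idx[ord, 1], ej = idx[ord, 2], n = nrow(A))
}

group_sum <- function(x, g, n) {
  out <- numeric(n)
  out[unique(g)] <- rowsum(x, g, reorder = FALSE)
  out
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

new_layer <- function(in_dim, head_out, heads, combine, activation) {
  list(
    W = lapply(seq_len(heads), function(t) glorot(head_out, in_dim)),
    a = lapply(seq_len(heads), function(t) {
      as.vector(glorot(head_out, 1))
    }),
    heads = heads, combine = combine, activation = activation,
    in_dim = in_dim, head_out = head_out,
    out_dim = if (combine == "concat") head_out * heads else head_out
  )
}

#' Initialize a graph-attentional autoencoder
#'
#' Two attentional layers in the encoder and two symmetric layers in the
#' decoder.  With the defaults the widths chain D -> 256 -> 64 -> 256 -> D
#' ("(512, 256, 64)" with D = 512): the first encoder/decoder layers
#' concatenate `heads` heads of width `hidden / heads`; the bottleneck and
#' output layers average their heads so that the embedding has width `d`
#' and the reconstruction matches `D`.  The output layer is linear
#' (z-scored inputs are signed); all other activations are ELU.
#' Glorot-uniform initialization under the given seed.
#'
#' @param D input width (features of the reduced matrix).
#' @param d bottleneck width (default 64).
#' @param hidden hidden width (default 256; must be divisible by `heads`).
#' @param heads attention heads per layer (default 4).
#' @param seed RNG seed for the initialization.
#' @return model object (list of 4 layer parameter sets).
#' @export
gat_init <- function(D, d = 64L, hidden = 256L, heads = 4L, seed = 0L) {
  if (hidden %% heads != 0) stop("hidden width must be divisible by heads")
  set.seed(seed)
  structure(list(
    layers = list(
      new_layer(D, hidden %/% heads, heads, "concat", "elu"),
      new_layer(hidden, d, heads, "average", "elu"),
      new_layer(d, hidden %/% heads, heads, "concat", "elu"),
      new_layer(hidden, D, heads, "average", "linear")
    ),
    D = as.integer(D), d = as.integer(d), hidden = as.integer(hidden),
    heads = as.integer(heads)
  ), class = "gat_model")
}

layer_forward_edges <- function(layer, H, graph) {
  ei <- graph$ei; ej <- graph$ej; n <- graph$n
  heads <- layer$heads
  hc <- vector("list", heads)
  for (t in seq_len(heads)) {
    G <- layer$W[[t]] %*% H
    s <- as.vector(crossprod(matrix(layer$a[[t]], ncol = 1), G))
    ediff <- s[ei] - s[ej]
    esc <- exp(-ediff^2)
    ew <- exp(esc)
    denom <- group_sum(ew, ei, n)
    alpha <- ew / denom[ei]
    amat <- matrix(0, n, n)            # amat[j, i] = alpha_ij
    amat[cbind(ej, ei)] <- alpha
    M <- G %*% amat
    hc[[t]] <- list(G = G, s = s, ediff = ediff, esc = esc,
                    alpha = alpha, amat = amat, M = M)
  }
  if (layer$combine == "average") {
    pre <- Reduce(`+`, lapply(hc, `[[`, "M")) / heads
    out <- if (layer$activation == "linear") pre else elu(pre)
    cache <- list(H = H, heads = hc, pre = pre)
  } else {
    out <- do.call(rbind, lapply(hc, function(x) elu(x$M)))
    cache <- list(H = H, heads = hc)
  }
  list(out = out, cache = cache)
}

layer_backward_edges <- function(layer, cache, dOut, graph) {
  ei <- graph$ei; ej <- graph$ej; n <- graph$n
  heads <- layer$heads
  H <- cache$H
  dH <- matrix(0, nrow(H), ncol(H))
  gW <- vector("list", heads)
  ga <- vector("list", heads)
  if (layer$combine == "average") {
    dpre <- if (layer$activation == "linear") dOut else dOut * elu_grad(cache$pre)
  }
  for (t in seq_len(heads)) {
    hc <- cache$heads[[t]]
    if (layer$combine == "average") {
      dM <- dpre / heads
    } else {
      rows <- ((t - 1) * layer$head_out + 1):(t * layer$head_out)
      dM <- dOut[rows, , drop = FALSE] * elu_grad(hc$M)
    }
    G <- hc$G
    # aggregation: M = G %*% amat with amat[j, i] = alpha_ij
    dG <- tcrossprod(dM, hc$amat)
    dalpha <- crossprod(dM, G)[cbind(ei, ej)]
    # softmax over each target cell's neighbourhood
    srow <- group_sum(hc$alpha * dalpha, ei, n)
    desc <- hc$alpha * (dalpha - srow[ei])
    dediff <- desc * hc$esc * (-2 * hc$ediff)
    ds <- group_sum(dediff, ei, n) - group_sum(dediff, ej, n)
    ga[[t]] <- as.vector(G %*% ds)
    dG <- dG + outer(layer$a[[t]], ds)
    gW[[t]] <- tcrossprod(dG, H)
    dH <- dH + crossprod(layer$W[[t]], dG)
  }
  list(dH = dH, W = gW, a = ga)
}

#' Full forward pass of the autoencoder
#'
#' @param model from [gat_init()].
#' @param Y D x n reduced input matrix.
#' @param graph edge list from the binary adjacency (internally built from
#'   `A` when a matrix is passed).
#' @return list with `Z` (d x n bottleneck embedding), `Y_prime` (D x n
#'   reconstruction), and `caches` for the backward pass.
#' @export
gat_forward <- function(model, Y, graph) {
  if (is.matrix(graph)) graph <- graph_edges(graph)
  if (nrow(Y) != model$D) stop("input width does not match model D")
  H <- Y
  caches <- vector("list", 4)
  outs <- vector("list", 4)
  for (l in 1:4) {
    fw <- layer_forward_edges(model$layers[[l]], H, graph)
    caches[[l]] <- fw$cache
    outs[[l]] <- fw$out
    H <- fw$out
  }
  list(Z = outs[[2]], Y_prime = outs[[4]], caches = caches, graph = graph)
}

# Backward pass: dY_prime is the gradient at the reconstruction, dZ_extra
# any additional gradient applied directly at the bottleneck (clustering
# and triplet losses).  Returns per-layer parameter gradients.
gat_backward <- function(model, fw, dY_prime, dZ_extra = NULL) {
  graph <- fw$graph
  grads <- vector("list", 4)
  d <- dY_prime
  for (l in 4:3) {
    bk <- layer_backward_edges(model$layers[[l]], fw$caches[[l]], d, graph)
    grads[[l]] <- list(W = bk$W, a = bk$a)
    d <- bk$dH
  }
  if (!is.null(dZ_extra)) d <- d + dZ_extra
  for (l in 2:1) {
    bk <- layer_backward_edges(model$layers[[l]], fw$caches[[l]], d, graph)
    grads[[l]] <- list(W = bk$W, a = bk$a)
    d <- bk$dH
  }
  grads
}

#' Mean-absolute-error reconstruction loss
#'
#' `L_r = sum_ij |Y_ij - Y'_ij|` — the summed absolute error between the
#' input and its reconstruction.
#'
#' @param Y D x n input matrix.
#' @param Y_prime reconstruction of the same shape.
#' @return scalar loss.
#' @export
reconstruction_loss <- function(Y, Y_prime) {
  if (!all(dim(Y) == dim(Y_prime))) stop("shape mismatch")
  sum(abs(Y - Y_prime))
}

reconstruction_grad <- function(Y, Y_prime) {
  -sign(Y - Y_prime)
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(model) {
  lapply(model$layers, function(l) list(
    mW = lapply(l$W, function(w) w * 0),
    vW = lapply(l$W, function(w) w * 0),
    ma = lapply(l$a, function(a) a * 0),
    va = lapply(l$a, function(a) a * 0)
  ))
}

adam_step <- function(model, grads, state, lr, step,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^step
  bc2 <- 1 - beta2^step
  for (l in seq_along(model$layers)) {
    for (t in seq_len(model$layers[[l]]$heads)) {
      gW <- grads[[l]]$W[[t]]
      state[[l]]$mW[[t]] <- beta1 * state[[l]]$mW[[t]] + (1 - beta1) * gW
      state[[l]]$vW[[t]] <- beta2 * state[[l]]$vW[[t]] + (1 - beta2) * gW^2
      model$layers[[l]]$W[[t]] <- model$layers[[l]]$W[[t]] -
        lr * (state[[l]]$mW[[t]] / bc1) /
          (sqrt(state[[l]]$vW[[t]] / bc2) + eps)
      ga <- grads[[l]]$a[[t]]
      state[[l]]$ma[[t]] <- beta1 * state[[l]]$ma[[t]] + (1 - beta1) * ga
      state[[l]]$va[[t]] <- beta2 * state[[l]]$va[[t]] + (1 - beta2) * ga^2
      model$layers[[l]]$a[[t]] <- model$layers[[l]]$a[[t]] -
        lr * (state[[l]]$ma[[t]] / bc1) /
          (sqrt(state[[l]]$va[[t]] / bc2) + eps)
    }
  }
  list(model = model, state = state)
}

#' Save / load model parameters
#'
#' Serializes the parameter tensors and architecture to a plain-text YAML
#' file (numbers at full precision).
#'
#' @param model a `gat_model`.
#' @param path file path.
#' @export
gat_save <- function(model, path) {
  ser <- list(
    D = model$D, d = model$d, hidden = model$hidden, heads = model$heads,
    layers = lapply(model$layers, function(l) list(
      W = lapply(l$W, function(w) list(dim = dim(w), x = as.vector(w))),
      a = l$a
    ))
  )
  yaml::write_yaml(ser, path, precision = 17)
  invisible(path)
}

#' @rdname gat_save
#' @export
gat_load <- function(path) {
  ser <- yaml::read_yaml(path)
  model <- gat_init(ser$D, ser$d, ser$hidden, ser$heads, seed = 0L)
  for (l in seq_along(model$layers)) {
    for (t in seq_len(model$layers[[l]]$heads)) {
      w <- ser$layers[[l]]$W[[t]]
      model$layers[[l]]$W[[t]] <- matrix(unlist(w$x), w$dim[[1]], w$dim[[2]])
      model$layers[[l]]$a[[t]] <- as.numeric(unlist(ser$layers[[l]]$a[[t]]))
    }
  }
  model
}
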