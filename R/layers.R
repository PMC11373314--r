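# Graph-convolutional building blocks: symmetric-normalized GCN
# propagation and node-edge co-embedding (CensNet-style) layers, built on
# the autodiff ops so the identical code serves training (with gradients)
# and generation (plain matrices).

# Block-diagonal structural constants for a batch of graphs.
#
# graphs: list of list(n = atom count, bonds = m x 3 matrix).  Returns the
# normalized node adjacency (self-loops, D^-1/2 (A+I) D^-1/2), the
# node-edge incidence, the normalized line-graph adjacency, one-hot edge
# features, pooling matrix (graph means), nonzero triplets for the
# co-embedding gradients, and index maps.
graph_conv_constants <- function(graphs) {
  n_g <- length(graphs)
  ns <- vapply(graphs, function(g) as.integer(g$n), 1L)
  offs <- cumsum(c(0L, ns))[seq_len(n_g)]
  N <- sum(ns)
  # single small graphs (the generation path re-encodes one molecule per
  # step) use plain dense matrices: the sparse S4 dispatch overhead
  # dominates at this size
  if (N <= 64L) return(.graph_conv_constants_dense(graphs, ns, offs, N))
  bonds_all <- do.call(rbind, lapply(seq_len(n_g), function(k) {
    b <- graphs[[k]]$bonds
    if (NROW(b) == 0) return(NULL)
    cbind(b[, 1] + offs[k], b[, 2] + offs[k], b[, 3], k)
  }))
  M <- if (is.null(bonds_all)) 0L else nrow(bonds_all)
  node_graph <- rep(seq_len(n_g), ns)

  if (M > 0) {
    A <- Matrix::sparseMatrix(
      i = c(bonds_all[, 1], bonds_all[, 2]),
      j = c(bonds_all[, 2], bonds_all[, 1]),
      x = 1, dims = c(N, N)
    )
  } else {
    A <- Matrix::Matrix(0, N, N, sparse = TRUE)
  }
  deg <- Matrix::rowSums(A) + 1
  Dh <- Matrix::Diagonal(x = 1 / sqrt(deg))
  Ahat_v <- Dh %*% (A + Matrix::Diagonal(N)) %*% Dh
  Ahat_v <- methods::as(Ahat_v, "generalMatrix")

  if (M > 0) {
    Tm <- Matrix::sparseMatrix(
      i = c(bonds_all[, 1], bonds_all[, 2]),
      j = rep(seq_len(M), 2L),
      x = 1, dims = c(N, M)
    )
    C <- Matrix::crossprod(Tm)    # shared-endpoint counts; off-diag 0/1
    Ae <- C
    Matrix::diag(Ae) <- 0
    Ae <- Matrix::drop0(Ae)
    dege <- Matrix::rowSums(Ae) + 1
    Dhe <- Matrix::Diagonal(x = 1 / sqrt(dege))
    Ahat_e <- Dhe %*% (Ae + Matrix::Diagonal(M)) %*% Dhe
    Ahat_e <- methods::as(Ahat_e, "generalMatrix")
    xe <- matrix(0, M, 3)
    xe[cbind(seq_len(M), bonds_all[, 3])] <- 1
    edge_graph <- bonds_all[, 4]
  } else {
    Tm <- Matrix::Matrix(0, N, 0, sparse = TRUE)
    Ahat_e <- Matrix::Matrix(0, 0, 0, sparse = TRUE)
    xe <- matrix(0, 0, 3)
    edge_graph <- integer(0)
  }

  P <- Matrix::sparseMatrix(i = node_graph, j = seq_len(N),
                            x = 1 / ns[node_graph], dims = c(n_g, N))

  trip_v <- Matrix::mat2triplet(Ahat_v)
  node_const <- list(S = Tm, Ahat = Ahat_v,
                     ai = trip_v$i, aj = trip_v$j, ax = trip_v$x)
  if (M > 0) {
    trip_e <- Matrix::mat2triplet(Ahat_e)
    edge_const <- list(S = Matrix::t(Tm), Ahat = Ahat_e,
                       ai = trip_e$i, aj = trip_e$j, ax = trip_e$x)
  } else {
    edge_const <- list(S = Matrix::t(Tm), Ahat = Ahat_e,
                       ai = integer(0), aj = integer(0), ax = numeric(0))
  }
  list(n_graphs = n_g, ns = ns, offsets = offs, N = N, M = M,
       bonds = bonds_all, node_graph = node_graph, edge_graph = edge_graph,
       Ahat_v = Ahat_v, Tm = Tm, Ahat_e = Ahat_e, edge_features = xe,
       pool = P, node_const = node_const, edge_const = edge_const)
}

# dense-matrix variant of the structural constants (same fields)
.graph_conv_constants_dense <- function(graphs, ns, offs, N) {
  n_g <- length(graphs)
  bonds_all <- do.call(rbind, lapply(seq_len(n_g), function(k) {
    b <- graphs[[k]]$bonds
    if (NROW(b) == 0) return(NULL)
    cbind(b[, 1] + offs[k], b[, 2] + offs[k], b[, 3], k)
  }))
  M <- if (is.null(bonds_all)) 0L else nrow(bonds_all)
  node_graph <- rep(seq_len(n_g), ns)
  A <- matrix(0, N, N)
  if (M > 0) {
    A[bonds_all[, 1:2, drop = FALSE]] <- 1
    A[bonds_all[, 2:1, drop = FALSE]] <- 1
  }
  dh <- 1 / sqrt(rowSums(A) + 1)
  Ahat_v <- (A + diag(N)) * outer(dh, dh)
  if (M > 0) {
    Tm <- matrix(0, N, M)
    Tm[cbind(bonds_all[, 1], seq_len(M))] <- 1
    Tm[cbind(bonds_all[, 2], seq_len(M))] <- 1
    C <- crossprod(Tm)
    Ae <- C; diag(Ae) <- 0
    dhe <- 1 / sqrt(rowSums(Ae) + 1)
    Ahat_e <- (Ae + diag(M)) * outer(dhe, dhe)
    xe <- matrix(0, M, 3)
    xe[cbind(seq_len(M), bonds_all[, 3])] <- 1
    edge_graph <- bonds_all[, 4]
  } else {
    Tm <- matrix(0, N, 0)
    Ahat_e <- matrix(0, 0, 0)
    xe <- matrix(0, 0, 3)
    edge_graph <- integer(0)
  }
  P <- matrix(0, n_g, N)
  P[cbind(node_graph, seq_len(N))] <- 1 / ns[node_graph]
  wh_v <- which(Ahat_v != 0, arr.ind = TRUE)
  node_const <- list(S = Tm, Ahat = Ahat_v, ai = wh_v[, 1], aj = wh_v[, 2],
                     ax = Ahat_v[wh_v])
  if (M > 0) {
    wh_e <- which(Ahat_e != 0, arr.ind = TRUE)
    edge_const <- list(S = t(Tm), Ahat = Ahat_e, ai = wh_e[, 1],
                       aj = wh_e[, 2], ax = Ahat_e[wh_e])
  } else {
    edge_const <- list(S = t(Tm), Ahat = Ahat_e, ai = integer(0),
                       aj = integer(0), ax = numeric(0))
  }
  list(n_graphs = n_g, ns = ns, offsets = offs, N = N, M = M,
       bonds = bonds_all, node_graph = node_graph, edge_graph = edge_graph,
       Ahat_v = Ahat_v, Tm = Tm, Ahat_e = Ahat_e, edge_features = xe,
       pool = P, node_const = node_const, edge_const = edge_const)
}

.dropout <- function(h, rate, training) {
  if (!training || rate <= 0) return(h)
  keep <- matrix(stats::rbinom(prod(dim(ad_val(h))), 1L, 1 - rate),
                 nrow(ad_val(h))) / (1 - rate)
  ad_mul(h, keep)
}

# one GCN propagation on prebuilt constants
.gcn_prop <- function(const, h, W, b, gamma = NULL, beta = NULL,
                      activation = "relu", dropout = 0, training = FALSE) {
  y <- ad_add(ad_mm(const$Ahat_v, ad_mm(h, W)), b)
  if (activation == "relu") y <- ad_relu(y)
  if (!is.null(gamma)) y <- ad_layernorm(y, gamma, beta)
  .dropout(y, dropout, training)
}

# one co-embedding node update on prebuilt constants
.cens_node_prop <- function(const, h_v, h_e, W, b, p, gamma = NULL,
                            beta = NULL, activation = "relu", dropout = 0,
                            training = FALSE) {
  lam <- if (const$M > 0) {
    ad_add(ad_mm(h_e, p), matrix(1, 1, 1))
  } else {
    matrix(0, 0, 1)
  }
  y <- ad_add(ad_censprop(h_v, lam, W, const$node_const), b)
  if (activation == "relu") y <- ad_relu(y)
  if (!is.null(gamma)) y <- ad_layernorm(y, gamma, beta)
  .dropout(y, dropout, training)
}

# one co-embedding edge update (propagation over the line graph)
.cens_edge_prop <- function(const, h_v, h_e, W, b, p, gamma = NULL,
                            beta = NULL, activation = "relu", dropout = 0,
                            training = FALSE) {
  if (const$M == 0) {
    return(matrix(0, 0, ncol(ad_val(W))))
  }
  lam <- ad_add(ad_mm(h_v, p), matrix(1, 1, 1))
  y <- ad_add(ad_censprop(h_e, lam, W, const$edge_const), b)
  if (activation == "relu") y <- ad_relu(y)
  if (!is.null(gamma)) y <- ad_layernorm(y, gamma, beta)
  .dropout(y, dropout, training)
}

.const_single <- function(t) {
  graph_conv_constants(list(list(n = nrow(t$node_features), bonds = t$bonds)))
}

#' Graph convolution layer
#'
#' Symmetric-normalized propagation with self-loops,
#' `act(D^-1/2 (A + I) D^-1/2 H W + b)`, optionally followed by layer
#' normalization and dropout (training mode only).
#'
#' @param t A `graph_tensors` object ([to_tensors()]).
#' @param h Node-feature matrix (n x d_in).
#' @param w Weight matrix (d_in x d_out).
#' @param b Bias row vector (default zeros).
#' @param activation `"relu"` or `"linear"`.
#' @param gamma,beta Optional layer-normalization gain/bias (length d_out).
#' @param dropout Dropout rate, applied only when `training = TRUE`.
#' @param training Logical.
#' @return Updated node-feature matrix (n x d_out).
#' @export
gcn_layer <- function(t, h, w, b = NULL, activation = "relu",
                      gamma = NULL, beta = NULL, dropout = 0,
                      training = FALSE) {
  stopifnot(inherits(t, "graph_tensors"))
  if (nrow(ad_val(h)) != nrow(t$node_features)) {
    stop("node feature row count does not match the graph", call. = FALSE)
  }
  if (ncol(ad_val(h)) != nrow(ad_val(w))) stop("shape mismatch", call. = FALSE)
  if (is.null(b)) b <- matrix(0, 1, ncol(ad_val(w)))
  .gcn_prop(.const_single(t), h, w, b, gamma, beta, activation,
            dropout, training)
}

#' Node-edge co-embedding layers
#'
#' CensNet-style convolutions in which node and edge embeddings enrich each
#' other.  The node layer propagates node features over the normalized
#' adjacency, with each neighbour message gated by a scalar learned from
#' the connecting edge's embedding
#' (`M = (T diag(h_e p + 1) T' + I) * Ahat`); the edge layer is the same
#' update with roles switched, propagating edge features over the
#' normalized line graph gated by shared-endpoint node embeddings.  The
#' identity term keeps the self-loop active on edgeless graphs.
#'
#' @param t A `graph_tensors` object.
#' @param h_v Node-feature matrix (n x d_v).
#' @param h_e Edge-feature matrix (m x d_e), rows in bond-list order.
#' @param w Weight matrix for the updated side.
#' @param p Gating vector mapping the other side's features to scalars.
#' @param b,activation,gamma,beta,dropout,training As in [gcn_layer()].
#' @return Updated node (`censnet_node_layer`) or edge
#'   (`censnet_edge_layer`) feature matrix.
#' @export
censnet_node_layer <- function(t, h_v, h_e, w, p = NULL, b = NULL,
                               activation = "relu", gamma = NULL,
                               beta = NULL, dropout = 0, training = FALSE) {
  stopifnot(inherits(t, "graph_tensors"))
  if (nrow(ad_val(h_v)) != nrow(t$node_features) ||
      nrow(ad_val(h_e)) != nrow(t$bonds)) {
    stop("feature row counts do not match the graph", call. = FALSE)
  }
  if (ncol(ad_val(h_v)) != nrow(ad_val(w))) stop("shape mismatch", call. = FALSE)
  if (is.null(p)) p <- matrix(0, ncol(ad_val(h_e)), 1)
  if (is.null(b)) b <- matrix(0, 1, ncol(ad_val(w)))
  .cens_node_prop(.const_single(t), h_v, h_e, w, b, p, gamma, beta,
                  activation, dropout, training)
}

#' @rdname censnet_node_layer
#' @export
censnet_edge_layer <- function(t, h_v, h_e, w, p = NULL, b = NULL,
                               activation = "relu", gamma = NULL,
                               beta = NULL, dropout = 0, training = FALSE) {
  stopifnot(inherits(t, "graph_tensors"))
  if (nrow(ad_val(h_v)) != nrow(t$node_features) ||
      nrow(ad_val(h_e)) != nrow(t$bonds)) {
    stop("feature row counts do not match the graph", call. = FALSE)
  }
  if (nrow(t$bonds) > 0 && ncol(ad_val(h_e)) != nrow(ad_val(w))) {
    stop("shape mismatch", call. = FALSE)
  }
  if (is.null(p)) p <- matrix(0, ncol(ad_val(h_v)), 1)
  if (is.null(b)) b <- matrix(0, 1, ncol(ad_val(w)))
  .cens_edge_prop(.const_single(t), h_v, h_e, w, b, p, gamma, beta,
                  activation, dropout, training)
}
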