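# Minimal reverse-mode automatic differentiation over matrices.
#
# The graph VAE is trained with exact gradients computed on a tape of matrix
# operations.  Nodes are environments carrying a value, their parent nodes,
# and a backward closure; constants stay plain matrices so the same forward
# code runs gradient-free at generation time (every op falls through to
# plain arithmetic when no input is a tape node).

.ad_env <- new.env(parent = emptyenv())
.ad_env$counter <- 0L

ad_is <- function(x) inherits(x, "adnode")

#' @keywords internal
ad_val <- function(x) if (ad_is(x)) x$val else x

ad_node <- function(val, parents = list(), bw = NULL) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$parents <- parents
  e$bw <- bw
  e$grad <- NULL
  .ad_env$counter <- .ad_env$counter + 1L
  e$id <- .ad_env$counter
  class(e) <- "adnode"
  e
}

# a leaf whose gradient is requested (a trainable parameter)
ad_leaf <- function(val) ad_node(val)

.any_ad <- function(...) {
  for (x in list(...)) if (ad_is(x)) return(TRUE)
  FALSE
}

# matrix product (either side may be a constant, including sparse Matrix)
ad_mm <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  v <- as.matrix(av %*% bv)
  if (!.any_ad(a, b)) return(v)
  parents <- list(); slots <- c(a = FALSE, b = FALSE)
  if (ad_is(a)) { parents <- c(parents, list(a)); slots["a"] <- TRUE }
  if (ad_is(b)) { parents <- c(parents, list(b)); slots["b"] <- TRUE }
  ad_node(v, parents, function(g) {
    out <- list()
    if (slots["a"]) out <- c(out, list(as.matrix(Matrix::tcrossprod(g, bv))))
    if (slots["b"]) out <- c(out, list(as.matrix(Matrix::crossprod(av, g))))
    out
  })
}

# addition; b may be a length-ncol(a) bias vector broadcast over rows
ad_add <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  bias <- is.null(dim(bv)) || nrow(as.matrix(bv)) == 1L
  v <- if (bias) sweep(av, 2L, as.vector(bv), "+") else av + bv
  if (!.any_ad(a, b)) return(v)
  parents <- list(); slots <- c(a = FALSE, b = FALSE)
  if (ad_is(a)) { parents <- c(parents, list(a)); slots["a"] <- TRUE }
  if (ad_is(b)) { parents <- c(parents, list(b)); slots["b"] <- TRUE }
  ad_node(v, parents, function(g) {
    out <- list()
    if (slots["a"]) out <- c(out, list(g))
    if (slots["b"]) {
      gb <- if (bias) matrix(colSums(g), 1L) else g
      out <- c(out, list(gb))
    }
    out
  })
}

# elementwise product of same-shape matrices (either side constant)
ad_mul <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  v <- av * bv
  if (!.any_ad(a, b)) return(v)
  parents <- list(); slots <- c(a = FALSE, b = FALSE)
  if (ad_is(a)) { parents <- c(parents, list(a)); slots["a"] <- TRUE }
  if (ad_is(b)) { parents <- c(parents, list(b)); slots["b"] <- TRUE }
  ad_node(v, parents, function(g) {
    out <- list()
    if (slots["a"]) out <- c(out, list(g * bv))
    if (slots["b"]) out <- c(out, list(g * av))
    out
  })
}

# multiply by a scalar (plain number or 1x1 tape node, e.g. a learned gate)
ad_scale <- function(a, s) {
  av <- ad_val(a); sv <- as.vector(ad_val(s))[1]
  v <- av * sv
  if (!.any_ad(a, s)) return(v)
  parents <- list(); slots <- c(a = FALSE, s = FALSE)
  if (ad_is(a)) { parents <- c(parents, list(a)); slots["a"] <- TRUE }
  if (ad_is(s)) { parents <- c(parents, list(s)); slots["s"] <- TRUE }
  ad_node(v, parents, function(g) {
    out <- list()
    if (slots["a"]) out <- c(out, list(g * sv))
    if (slots["s"]) out <- c(out, list(matrix(sum(g * av), 1L, 1L)))
    out
  })
}

ad_relu <- function(a) {
  av <- ad_val(a)
  v <- pmax(av, 0)
  if (!ad_is(a)) return(v)
  ad_node(v, list(a), function(g) list(g * (av > 0)))
}

ad_exp <- function(a) {
  v <- exp(ad_val(a))
  if (!ad_is(a)) return(v)
  ad_node(v, list(a), function(g) list(g * v))
}

ad_log <- function(a) {
  av <- ad_val(a)
  v <- log(av)
  if (!ad_is(a)) return(v)
  ad_node(v, list(a), function(g) list(g / av))
}

ad_sum <- function(a) {
  av <- ad_val(a)
  v <- sum(av)
  if (!ad_is(a)) return(v)
  ad_node(matrix(v, 1, 1), list(a), function(g) {
    list(array(as.vector(g)[1], dim = dim(av)))
  })
}

# row gather; backward scatter-adds duplicate rows
ad_rows <- function(a, idx) {
  av <- ad_val(a)
  idx <- as.integer(idx)
  v <- av[idx, , drop = FALSE]
  if (!ad_is(a)) return(v)
  ad_node(v, list(a), function(g) {
    acc <- rowsum(g, group = idx)
    out <- matrix(0, nrow(av), ncol(av))
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

# column concatenation
ad_cbind <- function(...) {
  args <- list(...)
  vals <- lapply(args, ad_val)
  v <- do.call(cbind, vals)
  if (!any(vapply(args, ad_is, TRUE))) return(v)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  is_node <- vapply(args, ad_is, TRUE)
  parents <- args[is_node]
  ad_node(v, parents, function(g) {
    lapply(which(is_node), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

# layer normalization over the feature dimension with learned gain/bias
ad_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  av <- ad_val(a)
  d <- ncol(av)
  mu <- rowMeans(av)
  xc <- av - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gv <- as.vector(ad_val(gamma)); bv <- as.vector(ad_val(beta))
  v <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  if (!.any_ad(a, gamma, beta)) return(v)
  parents <- list(); slots <- c(a = FALSE, gamma = FALSE, beta = FALSE)
  if (ad_is(a)) { parents <- c(parents, list(a)); slots["a"] <- TRUE }
  if (ad_is(gamma)) { parents <- c(parents, list(gamma)); slots["gamma"] <- TRUE }
  if (ad_is(beta)) { parents <- c(parents, list(beta)); slots["beta"] <- TRUE }
  ad_node(v, parents, function(g) {
    out <- list()
    if (slots["a"]) {
      dxhat <- sweep(g, 2L, gv, "*")
      s1 <- rowSums(dxhat)
      s2 <- rowSums(dxhat * xhat)
      dx <- inv * (dxhat - s1 / d - xhat * s2 / d)
      out <- c(out, list(dx))
    }
    if (slots["gamma"]) out <- c(out, list(matrix(colSums(g * xhat), 1L)))
    if (slots["beta"]) out <- c(out, list(matrix(colSums(g), 1L)))
    out
  })
}

# co-embedding propagation: Y = ((S diag(lam) S' + I) * Ahat) %*% h %*% W.
# `const` holds the fixed structure: S (incidence-like sparse), Ahat
# (normalized adjacency with self-loops, sparse), and Ahat's triplet
# (ai, aj, ax).  For a node layer S is the node-edge incidence and lam is
# one gate per edge; for an edge layer S is its transpose and lam one gate
# per node.
ad_censprop <- function(h, lam, W, const) {
  hv <- ad_val(h); lv <- as.vector(ad_val(lam)); Wv <- ad_val(W)
  S <- const$S; Ahat <- const$Ahat
  dense <- is.matrix(Ahat)
  if (dense) {
    Q <- if (length(lv) > 0) {
      tcrossprod(sweep(S, 2L, lv, "*"), S)
    } else {
      matrix(0, nrow(Ahat), ncol(Ahat))
    }
    M <- (Q + diag(nrow(Ahat))) * Ahat
  } else {
    Q <- if (length(lv) > 0) {
      S %*% Matrix::Diagonal(x = lv) %*% Matrix::t(S)
    } else {
      Matrix::Matrix(0, nrow(Ahat), ncol(Ahat), sparse = TRUE)
    }
    M <- (Q + Matrix::Diagonal(nrow(Ahat))) * Ahat
  }
  Z <- hv %*% Wv
  v <- as.matrix(M %*% Z)
  if (!.any_ad(h, lam, W)) return(v)
  parents <- list(); slots <- c(h = FALSE, lam = FALSE, W = FALSE)
  if (ad_is(h)) { parents <- c(parents, list(h)); slots["h"] <- TRUE }
  if (ad_is(lam)) { parents <- c(parents, list(lam)); slots["lam"] <- TRUE }
  if (ad_is(W)) { parents <- c(parents, list(W)); slots["W"] <- TRUE }
  ad_node(v, parents, function(g) {
    out <- list()
    dZ <- NULL
    if (slots["h"] || slots["W"]) dZ <- as.matrix(Matrix::t(M) %*% g)
    if (slots["h"]) out <- c(out, list(dZ %*% t(Wv)))
    if (slots["lam"]) {
      # restricted gradient over Ahat's nonzero pattern
      dq <- rowSums(g[const$ai, , drop = FALSE] *
                      Z[const$aj, , drop = FALSE]) * const$ax
      Dq <- if (dense) {
        m0 <- matrix(0, nrow(Ahat), ncol(Ahat))
        m0[cbind(const$ai, const$aj)] <- dq
        m0
      } else {
        Matrix::sparseMatrix(i = const$ai, j = const$aj, x = dq,
                             dims = dim(Ahat))
      }
      dlam <- Matrix::colSums(S * (Dq %*% S))
      out <- c(out, list(matrix(dlam, ncol = 1L)))
    }
    if (slots["W"]) out <- c(out, list(crossprod(hv, dZ)))
    out
  })
}

# multiply each row of a by a (possibly learned) 1 x d gate vector
ad_rowmul <- function(a, v) {
  av <- ad_val(a); vv <- as.vector(ad_val(v))
  y <- sweep(av, 2L, vv, "*")
  if (!.any_ad(a, v)) return(y)
  parents <- list(); slots <- c(a = FALSE, v = FALSE)
  if (ad_is(a)) { parents <- c(parents, list(a)); slots["a"] <- TRUE }
  if (ad_is(v)) { parents <- c(parents, list(v)); slots["v"] <- TRUE }
  ad_node(y, parents, function(g) {
    out <- list()
    if (slots["a"]) out <- c(out, list(sweep(g, 2L, vv, "*")))
    if (slots["v"]) out <- c(out, list(matrix(colSums(g * av), 1L)))
    out
  })
}

# free-bits clamp: given per-(example, dimension) divergence terms, sums
# B * max(column mean, floor); dimensions whose batch-mean divergence sits
# below the floor contribute a constant and pass no gradient
ad_freebits <- function(a, floor) {
  av <- ad_val(a)
  B <- nrow(av)
  cm <- colMeans(av)
  active <- cm > floor
  v <- B * sum(pmax(cm, floor))
  if (!ad_is(a)) return(v)
  ad_node(matrix(v, 1, 1), list(a), function(g) {
    gv <- as.vector(g)[1]
    list(matrix(rep(as.numeric(active), each = B), B) * gv)
  })
}

# negative log-likelihood of masked categorical decisions, one row per
# decision; target is the column index of the true class per row.  The
# node's `extra` field records per-row argmax correctness.
ad_masked_nll <- function(logits, mask, target) {
  lv <- ad_val(logits)
  lv_m <- lv
  lv_m[!mask] <- -Inf
  m <- apply(lv_m, 1L, max)
  ex <- exp(lv_m - m)
  ex[!is.finite(ex)] <- 0
  Z <- rowSums(ex)
  tgt <- lv_m[cbind(seq_len(nrow(lv)), target)]
  nll <- sum(log(Z) + m - tgt)
  correct <- max.col(lv_m, ties.method = "first") == target
  if (!ad_is(logits)) {
    return(structure(nll, correct = correct))
  }
  node <- ad_node(matrix(nll, 1, 1), list(logits), function(g) {
    p <- ex / Z
    p[cbind(seq_len(nrow(p)), target)] <-
      p[cbind(seq_len(nrow(p)), target)] - 1
    list(p * as.vector(g)[1])
  })
  node$extra <- correct
  node
}

# negative log-likelihood of the edge decisions: candidate (v, order)
# logits grouped per decision plus one stop logit per decision, masked
# softmax over the surviving entries plus stop.  `target_row` is the
# candidate row of the true edge (NA for stop) and `target_order` its bond
# order.  The node's `extra` records per-decision argmax correctness.
ad_edge_nll <- function(cand_logits, stop_logits, group, mask,
                        target_row, target_order, n_decisions) {
  cv <- ad_val(cand_logits)
  sv <- as.vector(ad_val(stop_logits))
  cv_m <- cv
  cv_m[!mask] <- -Inf
  row_max <- do.call(pmax, c(as.data.frame(cv_m), list(-Inf)))
  dec_max <- rep(-Inf, n_decisions)
  if (length(group) > 0) {
    agg <- tapply(row_max, group, max)
    dec_max[as.integer(names(agg))] <- pmax(dec_max[as.integer(names(agg))], agg)
  }
  dec_max <- pmax(dec_max, sv)
  ex_c <- exp(cv_m - dec_max[group])
  ex_c[!is.finite(ex_c)] <- 0
  ex_s <- exp(sv - dec_max)
  denom <- ex_s
  if (length(group) > 0) {
    sums <- rowsum(rowSums(ex_c), group = group)
    denom[as.integer(rownames(sums))] <-
      denom[as.integer(rownames(sums))] + sums
  }
  is_stop <- is.na(target_row)
  tgt_logit <- ifelse(is_stop, sv,
                      cv_m[cbind(ifelse(is_stop, 1L, target_row),
                                 ifelse(is_stop, 1L, target_order))])
  nll <- sum(log(denom) + dec_max - tgt_logit)
  # argmax correctness per decision
  best_c <- rep(-Inf, n_decisions)
  best_at <- rep(NA_integer_, n_decisions)
  best_ord <- rep(NA_integer_, n_decisions)
  if (nrow(cv_m) > 0) {
    flat <- as.vector(cv_m)                 # column-major: rows x 3
    fgroup <- rep(group, 3L)
    ford <- rep(1:3, each = nrow(cv_m))
    frow <- rep(seq_len(nrow(cv_m)), 3L)
    o <- order(fgroup, -flat)
    first <- o[!duplicated(fgroup[o])]
    best_c[fgroup[first]] <- flat[first]
    best_at[fgroup[first]] <- frow[first]
    best_ord[fgroup[first]] <- ford[first]
  }
  pick_stop <- sv >= best_c
  correct <- ifelse(is_stop, pick_stop,
                    !pick_stop & best_at == target_row &
                      best_ord == target_order)
  correct[is.na(correct)] <- FALSE
  if (!.any_ad(cand_logits, stop_logits)) {
    return(structure(nll, correct = correct))
  }
  parents <- list(); slots <- c(c = FALSE, s = FALSE)
  if (ad_is(cand_logits)) { parents <- c(parents, list(cand_logits)); slots["c"] <- TRUE }
  if (ad_is(stop_logits)) { parents <- c(parents, list(stop_logits)); slots["s"] <- TRUE }
  node <- ad_node(matrix(nll, 1, 1), parents, function(g) {
    gs <- as.vector(g)[1]
    p_c <- ex_c / denom[group]
    p_s <- ex_s / denom
    if (any(!is_stop)) {
      rows <- which(!is_stop)
      p_c[cbind(target_row[rows], target_order[rows])] <-
        p_c[cbind(target_row[rows], target_order[rows])] - 1
    }
    p_s[is_stop] <- p_s[is_stop] - 1
    out <- list()
    if (slots["c"]) out <- c(out, list(p_c * gs))
    if (slots["s"]) out <- c(out, list(matrix(p_s * gs, ncol = 1L)))
    out
  })
  node$extra <- correct
  node
}

# reverse sweep: accumulate gradients of `root` (scalar node) into every
# reachable leaf's $grad
ad_backward <- function(root) {
  stopifnot(ad_is(root))
  nodes <- new.env(parent = emptyenv())
  stack <- list(root)
  while (length(stack) > 0) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(nodes[[key]])) next
    nodes[[key]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  all_nodes <- as.list(nodes)
  ord <- order(vapply(all_nodes, function(n) n$id, 1L), decreasing = TRUE)
  for (nd in all_nodes) nd$grad <- NULL
  root$grad <- matrix(1, 1, 1)
  for (nd in all_nodes[ord]) {
    if (is.null(nd$bw) || is.null(nd$grad)) next
    gs <- nd$bw(nd$grad)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[[k]]
      if (is.null(p$grad)) p$grad <- gs[[k]] else p$grad <- p$grad + gs[[k]]
    }
  }
  invisible(root)
}
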