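# The tape must agree with central finite differences; these checks cover
# every op the model uses, composed the way the model composes them.

fd_grad <- function(f, x, i, j, h = 1e-5) {
  xp <- x; xp[i, j] <- xp[i, j] + h
  xm <- x; xm[i, j] <- xm[i, j] - h
  (f(xp) - f(xm)) / (2 * h)
}

test_that("gradients of composed matrix ops match finite differences", {
  ad <- fraglinkr:::ad_leaf
  set.seed(1)
  W1 <- matrix(rnorm(12), 4, 3)
  W2 <- matrix(rnorm(9), 3, 3)
  b <- matrix(rnorm(3), 1, 3)
  gam <- matrix(runif(3, 0.5, 1.5), 1, 3)
  bet <- matrix(rnorm(3), 1, 3)
  X <- matrix(rnorm(20), 5, 4)
  forward <- function(W1, W2, b, gam, bet) {
    h <- fraglinkr:::ad_relu(
      fraglinkr:::ad_add(fraglinkr:::ad_mm(X, W1), b))
    h <- fraglinkr:::ad_layernorm(h, gam, bet)
    h <- fraglinkr:::ad_mm(h, W2)
    h <- fraglinkr:::ad_rows(h, c(1, 3, 3, 5))
    fraglinkr:::ad_sum(fraglinkr:::ad_mul(h, h))
  }
  leaves <- list(W1 = ad(W1), W2 = ad(W2), b = ad(b), gam = ad(gam),
                 bet = ad(bet))
  out <- do.call(forward, leaves)
  fraglinkr:::ad_backward(out)
  for (nm in names(leaves)) {
    x0 <- get(nm)
    i <- 1L; j <- min(2L, ncol(x0))
    f <- function(x) {
      args <- list(W1 = W1, W2 = W2, b = b, gam = gam, bet = bet)
      args[[nm]] <- x
      as.vector(fraglinkr:::ad_val(do.call(forward, args)))
    }
    expect_equal(leaves[[nm]]$grad[i, j], fd_grad(f, x0, i, j),
                 tolerance = 1e-5, label = paste("grad", nm))
  }
})

test_that("co-embedding propagation gradients match finite differences", {
  set.seed(2)
  g <- parse_smiles("CCOC(N)C")
  const <- fraglinkr:::graph_conv_constants(
    list(list(n = length(g$elements), bonds = g$bonds)))
  H <- matrix(rnorm(length(g$elements) * 4), ncol = 4)
  lam <- matrix(rnorm(nrow(g$bonds)), ncol = 1)
  W <- matrix(rnorm(12), 4, 3)
  forward <- function(H, lam, W) {
    y <- fraglinkr:::ad_censprop(H, lam, W, const$node_const)
    fraglinkr:::ad_sum(fraglinkr:::ad_mul(y, y))
  }
  leaves <- list(H = fraglinkr:::ad_leaf(H),
                 lam = fraglinkr:::ad_leaf(lam),
                 W = fraglinkr:::ad_leaf(W))
  out <- do.call(forward, leaves)
  fraglinkr:::ad_backward(out)
  for (nm in names(leaves)) {
    x0 <- list(H = H, lam = lam, W = W)[[nm]]
    f <- function(x) {
      args <- list(H = H, lam = lam, W = W)
      args[[nm]] <- x
      as.vector(fraglinkr:::ad_val(do.call(forward, args)))
    }
    expect_equal(leaves[[nm]]$grad[1, 1], fd_grad(f, x0, 1, 1),
                 tolerance = 1e-5, label = paste("censprop grad", nm))
  }
})

test_that("masked decision losses match direct softmax computation", {
  set.seed(3)
  logits <- matrix(rnorm(12), 4, 3)
  mask <- matrix(TRUE, 4, 3); mask[2, 3] <- FALSE
  target <- c(1L, 2L, 3L, 1L)
  node <- fraglinkr:::ad_masked_nll(fraglinkr:::ad_leaf(logits), mask,
                                    target)
  direct <- 0
  for (r in 1:4) {
    l <- logits[r, ]; l[!mask[r, ]] <- -Inf
    direct <- direct - (l[target[r]] - log(sum(exp(l))))
  }
  expect_equal(as.vector(fraglinkr:::ad_val(node)), direct,
               tolerance = 1e-10)
  fraglinkr:::ad_backward(node)
  # gradient = masked softmax minus one-hot
  p <- exp(logits[1, ]) / sum(exp(logits[1, ]))
  expect_equal(node$parents[[1]]$grad[1, ], p - c(1, 0, 0),
               tolerance = 1e-10)
})

test_that("gradients of a five-parameter training slice match finite differences", {
  # end-to-end: the full teacher-forced loss as a function of single
  # weights, matched against central differences at 1e-4 relative
  cfg <- fx_config()
  params <- fx_params(seed = 21)
  ds <- fx_dataset()
  ex <- ds$example[[2]]
  tr <- fraglinkr:::build_trajectory(ex, cfg)
  pack <- fraglinkr:::pack_trajectories(list(tr), cfg)
  mu_f <- encode_fragment_pair(ex$fragment_1, ex$fragment_2, params, cfg)$mu
  Z <- matrix(mu_f, 1)
  loss_fn <- function(p) {
    r <- fraglinkr:::packed_recon_loss(p, pack, Z, cfg)
    as.vector(r$edge_nll) + as.vector(r$lab_nll)
  }
  leaves <- fraglinkr:::.wrap_leaves(params)
  r <- fraglinkr:::packed_recon_loss(leaves, pack, Z, cfg)
  total <- fraglinkr:::ad_add(r$edge_nll, r$lab_nll)
  fraglinkr:::ad_backward(total)
  slice <- list(c("dec", "Wv1", 1, 2), c("dec", "pv2", 3, 1),
                c("mlp_e", "W1", 10, 5), c("mlp_stop", "W1", 4, 2),
                c("mlp_n", "W2", 2, 3))
  for (s in slice) {
    i <- as.integer(s[3]); j <- as.integer(s[4])
    an <- leaves[[s[1]]][[s[2]]]$grad[i, j]
    p2 <- params; p2[[s[1]]][[s[2]]][i, j] <- p2[[s[1]]][[s[2]]][i, j] + 1e-5
    fp <- loss_fn(p2)
    p2[[s[1]]][[s[2]]][i, j] <- p2[[s[1]]][[s[2]]][i, j] - 2e-5
    fm <- loss_fn(p2)
    num <- (fp - fm) / 2e-5
    expect_equal(an, num, tolerance = 1e-4,
                 label = paste("slice", s[1], s[2]))
  }
})
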