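test_that("gcn_layer hand cases", {
  # isolated node, identity weights, linear: output = input
  t1 <- to_tensors(mol_graph("C"))
  h <- matrix(c(2, -1), 1, 2)
  expect_equal(gcn_layer(t1, h, diag(2), activation = "linear"), h)
  # two nodes, one edge: each row is the average of both before activation
  t2 <- to_tensors(parse_smiles("CC"))
  h2 <- matrix(c(1, 0, 0, 2), 2, 2)
  expect_equal(gcn_layer(t2, h2, diag(2), activation = "linear"),
               matrix(c(0.5, 0.5, 1, 1), 2, 2))
  expect_error(gcn_layer(t2, h2, diag(3)), "mismatch")
})

test_that("gcn_layer equals the brute-force oracle exhaustively (<= 4 nodes)", {
  set.seed(5)
  for (n in 2:4) {
    pairs <- t(combn(n, 2))
    for (mask in 0:(2^nrow(pairs) - 1)) {
      sel <- which(bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1)) > 0)
      bonds <- if (length(sel) > 0) {
        cbind(pairs[sel, , drop = FALSE], 1L)
      } else {
        matrix(integer(0), ncol = 3)
      }
      h <- matrix(rnorm(n * 2), n, 2)
      w <- matrix(rnorm(4), 2, 2)
      got <- gcn_layer(mk_graph_tensors(n, bonds), h, w,
                       activation = "linear")
      expect_equal(got, gcn_oracle(bonds, n, h, w), tolerance = 1e-6)
    }
  }
})

test_that("gcn_layer equals the brute-force oracle on random 12-node graphs", {
  set.seed(6)
  for (rep in 1:50) {
    n <- 12
    bonds <- fx_random_topology(n)
    h <- matrix(rnorm(n * 3), n, 3)
    w <- matrix(rnorm(9), 3, 3)
    got <- gcn_layer(mk_graph_tensors(n, bonds), h, w,
                     activation = "linear")
    expect_equal(got, gcn_oracle(bonds, n, h, w), tolerance = 1e-6)
  }
})

test_that("co-embedding node layer reduces to gated propagation", {
  # graph with zero edges: only the self-loop term survives
  t0 <- to_tensors(mol_graph(c("C", "C")))
  h <- matrix(rnorm(4), 2, 2)
  w <- matrix(rnorm(4), 2, 2)
  he <- matrix(0, 0, 3)
  expect_equal(
    censnet_node_layer(t0, h, he, w, activation = "linear"),
    h %*% w)
  # all-equal edge features on a 3-node path: neighbour messages are the
  # GCN messages rescaled by the common edge gate
  t3 <- to_tensors(parse_smiles("CCC"))
  he3 <- matrix(1, 2, 3) * 0.5
  p <- matrix(c(0.4, 0.1, 0.2), 3, 1)
  gate <- as.vector(he3[1, , drop = FALSE] %*% p) + 1
  h3 <- matrix(rnorm(9), 3, 3)
  w3 <- matrix(rnorm(9), 3, 3)
  plain <- gcn_layer(t3, h3, w3, activation = "linear")
  gated <- censnet_node_layer(t3, h3, he3, w3, p = p,
                              activation = "linear")
  Ahat <- as.matrix(fraglinkr:::graph_conv_constants(
    list(list(n = 3, bonds = t3$bonds)))$Ahat_v)
  hw <- h3 %*% w3
  deg <- c(1, 2, 1)
  plain_nb <- plain - diag(Ahat) * hw
  gated_nb <- gated - (gate * deg + 1) * diag(Ahat) * hw
  expect_equal(gated_nb, gate * plain_nb, tolerance = 1e-8)
})

test_that("co-embedding edge layer degenerate cases", {
  # single edge: line graph has no neighbours, self-loop only
  t1 <- to_tensors(parse_smiles("CC"))
  hv <- matrix(rnorm(4), 2, 2)
  he <- matrix(rnorm(3), 1, 3)
  w <- matrix(rnorm(6), 3, 2)
  out <- censnet_edge_layer(t1, hv, he, w, activation = "linear")
  # p defaults to zeros so each endpoint gate is 1; the diagonal carries
  # the sum of the two endpoint gates plus the identity term
  expect_equal(out, (1 + 1 + 1) * he %*% w, tolerance = 1e-8)
  # triangle with all-equal inputs: symmetry forces all-equal outputs
  tri <- to_tensors(mol_graph(c("C", "C", "C"),
                              rbind(c(1, 2, 1), c(2, 3, 1), c(1, 3, 1))))
  hv3 <- matrix(1, 3, 2)
  he3 <- matrix(1, 3, 3)
  o <- censnet_edge_layer(tri, hv3, he3, matrix(rnorm(6), 3, 2))
  expect_equal(o[1, ], o[2, ])
  expect_equal(o[2, ], o[3, ])
})

test_that("co-embedding layers are permutation-equivariant", {
  set.seed(8)
  cfg <- fx_config()
  for (rep in 1:100) {
    g <- fx_random_graph(10)
    n <- length(g$elements)
    if (n < 2) next
    t <- to_tensors(g)
    m <- nrow(g$bonds)
    hv <- matrix(rnorm(n * 4), n, 4)
    he <- matrix(rnorm(max(m, 0) * 3), max(m, 0), 3)
    w <- matrix(rnorm(16), 4, 4)
    we <- matrix(rnorm(12), 3, 4)
    p_e <- matrix(rnorm(3), 3, 1)
    p_v <- matrix(rnorm(4), 4, 1)
    out_v <- censnet_node_layer(t, hv, he, w, p = p_e)
    out_e <- censnet_edge_layer(t, hv, he, we, p = p_v)
    perm <- sample(n)
    gp <- fx_permute_graph(g, perm)
    tp <- to_tensors(gp)
    # row r of the permuted graph's features = row inv(r) of the original
    inv <- integer(n); inv[perm] <- seq_len(n)
    out_vp <- censnet_node_layer(tp, hv[inv, , drop = FALSE],
                                 he[fx_edge_map(g, gp, perm), , drop = FALSE],
                                 w, p = p_e)
    expect_equal(out_vp, out_v[inv, , drop = FALSE], tolerance = 1e-6)
    # edge layer: compare via the edge map
    emap <- fx_edge_map(g, gp, perm)
    out_ep <- censnet_edge_layer(tp, hv[inv, , drop = FALSE],
                                 he[emap, , drop = FALSE], we, p = p_v)
    expect_equal(out_ep, out_e[emap, , drop = FALSE], tolerance = 1e-6)
  }
})
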