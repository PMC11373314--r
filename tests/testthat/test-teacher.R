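test_that("the forced trajectory rebuilds the molecule and stays in budget", {
  cfg <- fx_config()
  ds <- fx_dataset()
  for (ex in ds$example[1:15]) {
    tr <- fraglinkr:::build_trajectory(ex, cfg)
    # all cross bonds scheduled exactly once
    expect_equal(nrow(tr$cross_bonds),
                 sum(!is.na(vapply(tr$decisions, `[[`, 1L, "target_v"))))
    # rebuilt graph matches the molecule
    full <- rbind(tr$frag_bonds, tr$cross_bonds)
    rebuilt <- mol_graph(tr$true_elements, full)
    expect_true(graphs_isomorphic(rebuilt, ex$molecule))
    # label targets always feasible under their masks
    expect_true(all(tr$label_mask[cbind(seq_along(tr$label_target),
                                        tr$label_target)]))
  }
})

test_that("uniform logits contribute exactly log K per decision", {
  # zeroed parameters make every surviving logit equal, so each decision
  # contributes log(number of unmasked actions)
  cfg <- fx_config()
  ds <- fx_dataset()
  ex <- ds$example[[3]]
  params <- fx_params()
  zero <- function(grp) lapply(grp, function(m) {m[] <- 0; m})
  p0 <- params
  p0$mlp_e <- zero(p0$mlp_e)
  p0$mlp_stop <- zero(p0$mlp_stop)
  p0$mlp_n <- zero(p0$mlp_n)
  tr <- fraglinkr:::build_trajectory(ex, cfg)
  pack <- fraglinkr:::pack_trajectories(list(tr), cfg)
  res <- fraglinkr:::packed_recon_loss(p0, pack, matrix(0, 1, cfg$d_z),
                                       cfg)
  expected_edge <- sum(vapply(tr$decisions, function(dc)
    log(sum(dc$mask) + 1), 0))   # +1 for the stop action
  expected_lab <- sum(log(rowSums(tr$label_mask)))
  expect_equal(as.vector(res$edge_nll), expected_edge, tolerance = 1e-10)
  expect_equal(as.vector(res$lab_nll), expected_lab, tolerance = 1e-10)
})

test_that("batched teacher loss equals stepping the decoder with forced actions", {
  # independent route: replay the ground-truth trajectory through the
  # sequential decoder ops, accumulating -log p of each forced action
  cfg <- fx_config()
  params <- fx_params()
  ds <- fx_dataset()
  ex <- NULL
  for (cand in ds$example) {
    if (length(cand$linker_atoms) == 3) { ex <- cand; break }
  }
  skip_if(is.null(ex), "no 3-atom linker example in fixture set")
  enc_f <- encode_fragment_pair(ex$fragment_1, ex$fragment_2, params, cfg)
  tr <- fraglinkr:::build_trajectory(ex, cfg)
  enc_m <- encode(ex$molecule, params, cfg, role = "molecule",
                  positions = tr$mol_positions)
  eps <- rep(0.1, cfg$d_m)
  init <- make_initial_representation(enc_f$mu, enc_m, params, cfg,
                                      "train", eps = eps)
  got <- teacher_forced_recon_loss(ex, params, cfg, eps = eps)
  st <- init_state(ex$fragment_1, ex$fragment_2, init, tr$nl, cfg)
  oracle <- 0
  for (dc in tr$decisions) {
    st$H <- NULL
    st <- reencode(st, params, cfg)
    el <- edge_logits(st, dc$u, params, cfg)
    if (is.na(dc$target_v)) {
      p <- el$probs$prob[nrow(el$probs)]
    } else {
      row <- which(el$probs$v == dc$target_v &
                     el$probs$order == dc$target_order)
      p <- el$probs$prob[row]
    }
    oracle <- oracle - log(p)
    if (!is.na(dc$target_v)) {
      v <- dc$target_v; o <- dc$target_order
      st$bonds <- rbind(st$bonds, c(min(dc$u, v), max(dc$u, v), o))
      st$budget[dc$u] <- st$budget[dc$u] - o
      st$budget[v] <- st$budget[v] - o
    }
  }
  # node-label cross-entropy from the final hidden states
  st$H <- NULL
  st <- reencode(st, params, cfg)
  linker <- which(st$linker_flag)
  lab_in <- cbind(st$H[linker, , drop = FALSE],
                  matrix(init$z, length(linker), cfg$d_z, byrow = TRUE),
                  st$pos_tag[linker])
  logits <- sweep(pmax(sweep(lab_in %*% params$mlp_n$W1, 2,
                             as.vector(params$mlp_n$b1), "+"), 0) %*%
                    params$mlp_n$W2, 2, as.vector(params$mlp_n$b2), "+")
  for (k in seq_along(linker)) {
    l <- logits[k, ]
    l[!tr$label_mask[k, ]] <- -Inf
    oracle <- oracle - (l[tr$label_target[k]] - log(sum(exp(l))))
  }
  expect_equal(got$loss, oracle, tolerance = 1e-8)
})

test_that("near-perfect logits drive the loss towards zero", {
  # craft an edge NLL where the target entries dominate by a large margin
  cand_logits <- matrix(-50, 4, 3)
  cand_logits[1, 1] <- 50   # decision 1 target: candidate 1, order 1
  stop_logits <- matrix(c(-50, 50), 2, 1)  # decision 2 target: stop
  mask <- matrix(TRUE, 4, 3)
  nll <- fraglinkr:::ad_edge_nll(cand_logits, stop_logits,
                                 group = c(1L, 1L, 2L, 2L), mask = mask,
                                 target_row = c(1L, NA),
                                 target_order = c(1L, NA),
                                 n_decisions = 2L)
  expect_lt(as.vector(nll), 1e-10)
  expect_true(all(attr(nll, "correct")))
})
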