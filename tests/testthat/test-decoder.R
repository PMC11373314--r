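fx_pair <- function() {
  ds <- fx_dataset()
  ds$example[[1]]
}

test_that("init_state lays out fragments, linker nodes, queue and budgets", {
  cfg <- fx_config()
  ex <- fx_pair()
  z <- rnorm(cfg$d_z)
  st <- init_state(ex$fragment_1, ex$fragment_2, z, 3, cfg)
  n_frag <- length(ex$fragment_1$elements) + length(ex$fragment_2$elements)
  expect_equal(st$n, n_frag + 3)
  # linker nodes start isolated
  expect_true(all(st$bonds[, 1] <= n_frag & st$bonds[, 2] <= n_frag))
  # focus queue seeded with the two attachment atoms
  expect_equal(st$queue, c(st$anchor1, st$anchor2))
  # linker nodes carry the provisional budget of 4
  expect_true(all(st$budget[st$linker_flag] == 4))
  expect_true(all(st$budget >= 0))
  expect_error(init_state(ex$fragment_1, ex$fragment_2, z, 2, cfg),
               "between 3 and 12")
  expect_error(init_state(ex$fragment_1, ex$fragment_2, z, 13, cfg),
               "between 3 and 12")
})

test_that("re-encoding is deterministic and sensitive to new edges", {
  cfg <- fx_config(); params <- fx_params()
  ex <- fx_pair()
  st <- init_state(ex$fragment_1, ex$fragment_2, rnorm(cfg$d_z), 4, cfg)
  s1 <- reencode(st, params, cfg)
  s2 <- reencode(st, params, cfg)
  expect_identical(s1$H, s2$H)
  # add an edge between the two attachment atoms and re-encode
  st2 <- st
  st2$bonds <- rbind(st2$bonds, c(min(st$anchor1, st$anchor2),
                                  max(st$anchor1, st$anchor2), 1L))
  s3 <- reencode(st2, params, cfg)
  expect_gt(max(abs(s3$H[st$anchor1, ] - s1$H[st$anchor1, ])), 0)
  expect_gt(max(abs(s3$H[st$anchor2, ] - s1$H[st$anchor2, ])), 0)
})

test_that("edge scores respect valence masks and normalize", {
  cfg <- fx_config(); params <- fx_params()
  f1 <- parse_smiles("*OC")   # attachment O already bonded once: budget 1
  f2 <- parse_smiles("*C")
  st <- init_state(f1, f2, rnorm(cfg$d_z), 3, cfg)
  st <- reencode(st, params, cfg)
  el <- edge_logits(st, st$queue[1], params, cfg)
  expect_equal(sum(el$probs$prob), 1, tolerance = 1e-12)
  # the focus atom has budget 1: double/triple entries must be masked
  expect_true(all(!el$mask[, 2:3]))
  expect_true(all(el$probs$prob[el$probs$order %in% 2:3] == 0,
                  na.rm = TRUE))
  # saturate every candidate: only stop survives
  st2 <- st
  st2$budget[] <- 0L
  el2 <- edge_logits(st2, st2$queue[1], params, cfg)
  expect_length(el2$v, 0)
  expect_equal(el2$probs$prob[nrow(el2$probs)], 1)
})

test_that("decoder steps keep the queue and budgets consistent", {
  cfg <- fx_config(); params <- fx_params()
  ex <- fx_pair()
  set.seed(30)
  st <- init_state(ex$fragment_1, ex$fragment_2, rnorm(cfg$d_z), 4, cfg)
  frag_bonds0 <- st$bonds
  total_budget <- sum(st$budget)
  while (length(st$queue) > 0 && !st$truncated) {
    q_before <- st$queue
    b_before <- nrow(st$bonds)
    st <- decoder_step(st, params, cfg)
    if (nrow(st$bonds) > b_before) {
      # an edge was added: total budget decreases by 2x its order
      o <- st$bonds[nrow(st$bonds), 3]
      expect_equal(sum(st$budget), total_budget - 2 * o)
      total_budget <- total_budget - 2 * o
    } else {
      # stop: the focus node was popped
      expect_false(st$queue[1] %in% q_before[1] &&
                     length(st$queue) >= length(q_before))
    }
  }
  expect_lte(st$step, st$max_steps)
  # fragment-internal bonds were never modified
  expect_identical(st$bonds[seq_len(nrow(frag_bonds0)), , drop = FALSE],
                   frag_bonds0)
})

test_that("sampled trajectories are reproducible under a seed", {
  cfg <- fx_config(); params <- fx_params()
  ex <- fx_pair()
  run <- function() {
    set.seed(77)
    st <- init_state(ex$fragment_1, ex$fragment_2, rep(0.2, cfg$d_z), 3,
                     cfg)
    while (length(st$queue) > 0 && !st$truncated) {
      st <- decoder_step(st, params, cfg, policy = "sample")
    }
    st$bonds
  }
  expect_identical(run(), run())
})

test_that("graph-distance features match a BFS oracle", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    bonds <- fx_random_topology(n, p = 0.25)
    u <- sample(n, 1)
    got <- fraglinkr:::.dists_from(n, bonds, u)
    ig <- igraph::make_empty_graph(n, directed = FALSE)
    if (nrow(bonds) > 0) {
      ig <- igraph::add_edges(ig, t(bonds[, 1:2, drop = FALSE]))
    }
    oracle <- as.vector(igraph::distances(ig, v = u))
    oracle[!is.finite(oracle)] <- 20
    oracle <- pmin(oracle, 20)
    expect_equal(got, as.integer(oracle))
  }
})

test_that("node labels respect realized valence and fragment labels persist", {
  cfg <- fx_config(); params <- fx_params()
  ex <- fx_pair()
  st <- init_state(ex$fragment_1, ex$fragment_2, rnorm(cfg$d_z), 3, cfg)
  # wire one linker node with four single bonds: element must be carbon
  ln <- which(st$linker_flag)
  targets <- which(!st$linker_flag & st$budget > 0)
  k <- 0L
  for (v in targets) {
    if (k >= 4) break
    st$bonds <- rbind(st$bonds, c(min(ln[1], v), max(ln[1], v), 1L))
    st$budget[v] <- st$budget[v] - 1L
    k <- k + 1L
  }
  st$budget[ln[1]] <- 4L - k
  labels <- predict_node_labels(st, params, cfg)
  if (k == 4) expect_equal(labels[1], "C")
  # fragment atoms keep their input elements in the finalized molecule
  fin <- finalize(st, labels)
  expect_true(has_subgraph(fin, ex$fragment_1) ||
                length(fin$elements) < length(ex$fragment_1$elements))
})

test_that("finalize keeps the largest component and drops leftovers", {
  cfg <- fx_config()
  f1 <- parse_smiles("*CCC"); f2 <- parse_smiles("*CC")
  st <- init_state(f1, f2, rnorm(cfg$d_z), 3, cfg)
  # connect the two fragments through one linker node; leave two isolated
  ln <- which(st$linker_flag)
  st$bonds <- rbind(st$bonds,
                    c(min(st$anchor1, ln[1]), max(st$anchor1, ln[1]), 1L),
                    c(min(st$anchor2, ln[1]), max(st$anchor2, ln[1]), 1L))
  mol <- finalize(st, c("C", "C", "C"))
  expect_equal(length(mol$elements), 6)  # 5 fragment atoms + 1 linker
  expect_silent(validate_mol_graph(mol))
})

test_that("generation yields the requested count, valence-valid by construction", {
  cfg <- fx_config(); params <- fx_params()
  ex <- fx_pair()
  gen <- generate_linkers(ex$fragment_1, ex$fragment_2, params, cfg,
                          n_samples = 30, seed = 5)
  expect_equal(nrow(gen), 30)
  expect_true(all(gen$n_linker >= 3 & gen$n_linker <= 12))
  for (m in gen$molecule) expect_silent(validate_mol_graph(m))
  # whenever both attachment atoms survive, both fragments are present
  for (k in which(gen$both_fragments)) {
    expect_true(has_subgraph(gen$molecule[[k]], ex$fragment_1))
    expect_true(has_subgraph(gen$molecule[[k]], ex$fragment_2))
  }
  # seeded reproducibility
  gen2 <- generate_linkers(ex$fragment_1, ex$fragment_2, params, cfg,
                           n_samples = 30, seed = 5)
  expect_identical(gen$smiles, gen2$smiles)
  # fixed linker size is honoured
  gen3 <- generate_linkers(ex$fragment_1, ex$fragment_2, params, cfg,
                           n_samples = 3, seed = 1, n_linker = 5)
  expect_true(all(gen3$n_linker == 5))
})
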