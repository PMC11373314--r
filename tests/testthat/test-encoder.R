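test_that("encode produces positive-sigma Gaussians of the configured width", {
  cfg <- fx_config()
  params <- fx_params()
  g <- parse_smiles("CCOC(=O)CN")
  em <- encode(g, params, cfg, role = "molecule")
  ef <- encode(g, params, cfg, role = "fragment")
  expect_length(em$mu, cfg$d_m)
  expect_length(ef$mu, cfg$d_z)
  expect_true(all(em$sigma > 0) && all(ef$sigma > 0))
  expect_error(encode(mol_graph(character(0)), params, cfg), "empty")
})

test_that("encode is invariant under atom relabelling (both backbones)", {
  set.seed(12)
  for (backbone in c("censnet", "gcn")) {
    cfg <- fx_config(backbone)
    params <- fx_params(backbone)
    for (rep in 1:50) {
      g <- fx_random_graph(10)
      e1 <- encode(g, params, cfg, role = "molecule")
      perm <- sample(length(g$elements))
      e2 <- encode(fx_permute_graph(g, perm), params, cfg,
                   role = "molecule")
      expect_equal(e1$mu, e2$mu, tolerance = 1e-6)
      expect_equal(e1$sigma, e2$sigma, tolerance = 1e-6)
    }
  }
})

test_that("fragment-pair encoding averages the two fragment Gaussians", {
  cfg <- fx_config(); params <- fx_params()
  f1 <- parse_smiles("*CCO"); f2 <- parse_smiles("*CN")
  e1 <- encode(f1, params, cfg, "fragment")
  e2 <- encode(f2, params, cfg, "fragment")
  pair <- encode_fragment_pair(f1, f2, params, cfg)
  expect_equal(pair$mu, (e1$mu + e2$mu) / 2)
  expect_equal(pair$sigma, (e1$sigma + e2$sigma) / 2)
})

test_that("initial representation follows z = mu_f + a_f [z_m, tau]", {
  cfg <- fx_config()
  params <- fx_params()
  mu_f <- rnorm(cfg$d_z)
  # a_f = 0 degenerates to mu_f exactly
  p0 <- params; p0$head$a_f[] <- 0
  init <- make_initial_representation(mu_f, NULL, p0, cfg,
                                      mode = "generate")
  expect_equal(init$z, mu_f)
  # zero tau weights and z_m = 0 also give mu_f
  p1 <- params
  p1$head$Wtau[] <- 0; p1$head$btau[] <- 0
  init1 <- make_initial_representation(mu_f, NULL, p1, cfg,
                                       mode = "generate",
                                       eps = rep(0, cfg$d_m))
  expect_equal(init1$z, mu_f)
  # explicit draw reproducibility
  i1 <- make_initial_representation(mu_f, NULL, params, cfg, "generate",
                                    eps = rep(0.7, cfg$d_m))
  i2 <- make_initial_representation(mu_f, NULL, params, cfg, "generate",
                                    eps = rep(0.7, cfg$d_m))
  expect_identical(i1$z, i2$z)
  # training mode requires the molecule encoding
  expect_error(
    make_initial_representation(mu_f, NULL, params, cfg, mode = "train"),
    "molecule encoding")
  # reparameterization uses mu_m + sigma_m * eps
  enc_m <- list(mu = rep(1, cfg$d_m), sigma = rep(2, cfg$d_m))
  it <- make_initial_representation(mu_f, enc_m, params, cfg, "train",
                                    eps = rep(0.5, cfg$d_m))
  expect_equal(it$z_m, rep(2, cfg$d_m))
})

test_that("gradients flow from the encoding into every parameter group", {
  cfg <- fx_config()
  params <- fx_params()
  g <- parse_smiles("NCC(=O)OC")
  const <- fraglinkr:::graph_conv_constants(
    list(list(n = length(g$elements), bonds = g$bonds)))
  X <- fraglinkr:::.encoder_node_features(g)
  leaves <- fraglinkr:::.wrap_leaves(params)
  enc <- fraglinkr:::.encode_block(leaves, const, X, "molecule",
                                   backbone = cfg$backbone)
  loss <- fraglinkr:::ad_sum(fraglinkr:::ad_mul(enc$mu, enc$mu))
  fraglinkr:::ad_backward(loss)
  for (nm in c("Wv1", "bv1", "Wv2", "gv2")) {
    gr <- leaves$enc[[nm]]$grad
    expect_false(is.null(gr), label = nm)
    expect_true(all(is.finite(gr)), label = nm)
  }
  expect_true(any(leaves$enc$Wv1$grad != 0))
})
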