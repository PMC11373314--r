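test_that("a one-component fit recovers the sample moments", {
  set.seed(14)
  x <- matrix(rnorm(600, mean = 2, sd = 1.5), ncol = 3)
  d <- fit_density(x, k = 1, seed = 0)
  expect_equal(as.vector(d$means), colMeans(x), tolerance = 1e-8)
  # maximum-likelihood (1/n) variances
  expect_equal(as.vector(d$vars),
               apply(x, 2, function(c) mean((c - mean(c))^2)),
               tolerance = 1e-6)
})

test_that("a two-component mixture is recovered from simulation", {
  set.seed(15)
  x <- matrix(c(rnorm(2500, -3), rnorm(2500, 3)), ncol = 1)
  d <- fit_density(x, k = 2, seed = 0)
  expect_equal(sort(as.vector(d$means)), c(-3, 3), tolerance = 0.1)
  expect_equal(sum(d$weights), 1, tolerance = 1e-9)
  # identical seed, identical fit
  d2 <- fit_density(x, k = 2, seed = 0)
  expect_identical(d$means, d2$means)
  expect_error(fit_density(x[1:2, , drop = FALSE], k = 5), "more samples")
})

test_that("attribute classifiers learn separable labels and stay calibrated", {
  set.seed(16)
  z <- matrix(rnorm(400), ncol = 2)
  z <- z[abs(z[, 1]) > 0.2, , drop = FALSE]  # separable with a margin
  labels <- z[, 1] > 0
  sp <- train_attribute_classifier(z, NULL, labels,
                                   attribute_spec("toy", 0, "greater"))
  expect_equal(sp$train_accuracy, 1.0)
  p <- fraglinkr:::.spec_prob(sp, z)
  expect_true(all(p >= 0 & p <= 1))
  # labels independent of features: accuracy near the majority rate
  shuffled <- sample(labels)
  sp2 <- train_attribute_classifier(z, NULL, shuffled,
                                    attribute_spec("null", 0, "greater"))
  maj <- max(mean(shuffled), 1 - mean(shuffled))
  expect_lt(abs(sp2$train_accuracy - maj), 0.12)
  expect_error(
    train_attribute_classifier(z, NULL, rep(TRUE, nrow(z)),
                               attribute_spec("one", 0, "greater")),
    "both classes")
})

test_that("acceptance probability is the product of classifier scores", {
  mk <- function(p) {
    attribute_spec(paste0("c", p), 0, "greater",
                   classifier = function(z, mu) rep(p, nrow(z)))
  }
  expect_equal(acceptance_probability(0, NULL, list(mk(0.5), mk(0.5))),
               0.25)
  expect_equal(acceptance_probability(0, NULL, list(mk(0.3), mk(0))), 0)
  expect_equal(acceptance_probability(0, NULL, list(mk(0.7))), 0.7)
  expect_error(acceptance_probability(0, NULL, list()), "no attribute")
})

test_that("rejection sampling reproduces analytic acceptance behaviour", {
  std_density <- structure(
    list(k = 1L, weights = 1, means = matrix(0, 1, 1),
         vars = matrix(1, 1, 1), d = 1L),
    class = "latent_density")
  pass <- attribute_spec("always", 0, "greater",
                         classifier = function(z, mu) rep(1, nrow(z)))
  rs <- rejection_sample(std_density, list(pass), 500, seed = 1)
  expect_equal(rs$acceptance_rate, 1)
  # hard half-space classifier: rate 0.5 within 3 MC standard errors and
  # every accepted sample on the positive side
  hard <- attribute_spec("pos", 0, "greater",
                         classifier = function(z, mu) as.numeric(z[, 1] > 0))
  n <- 10000
  rs2 <- rejection_sample(std_density, list(hard), n, seed = 2,
                          max_draws = 50 * n)
  expect_true(all(rs2$samples > 0))
  expect_lt(abs(rs2$acceptance_rate - 0.5), 3 * sqrt(0.25 / rs2$n_draws))
  # constant zero: nothing accepted, warning raised
  never <- attribute_spec("never", 0, "greater",
                          classifier = function(z, mu) rep(0, nrow(z)))
  expect_warning(
    rs3 <- rejection_sample(std_density, list(never), 5, seed = 3,
                            max_draws = 200),
    "exhausted")
  expect_equal(nrow(rs3$samples), 0)
  expect_true(rs3$exhausted)
})

test_that("accepted samples follow the tilted density Q(z) sigma(z)", {
  # soft classifier sigma(z): the accepted-sample law has density
  # proportional to phi(z) sigma(z); compare with a grid-normalized CDF
  std_density <- structure(
    list(k = 1L, weights = 1, means = matrix(0, 1, 1),
         vars = matrix(1, 1, 1), d = 1L),
    class = "latent_density")
  soft <- attribute_spec("soft", 0, "greater",
                         classifier = function(z, mu) stats::plogis(z[, 1]))
  rs <- rejection_sample(std_density, list(soft), 20000, seed = 4,
                         max_draws = 2e6)
  grid <- seq(-6, 6, length.out = 4001)
  dens <- stats::dnorm(grid) * stats::plogis(grid)
  cdf <- cumsum(dens) / sum(dens)
  target_cdf <- stats::approxfun(grid, cdf, yleft = 0, yright = 1)
  ks <- suppressWarnings(stats::ks.test(as.vector(rs$samples), target_cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("joint acceptance cannot beat the tightest single attribute", {
  std_density <- structure(
    list(k = 1L, weights = 1, means = matrix(0, 1, 1),
         vars = matrix(1, 1, 1), d = 1L),
    class = "latent_density")
  a1 <- attribute_spec("a1", 0, "greater",
                       classifier = function(z, mu) as.numeric(z[, 1] > 0))
  a2 <- attribute_spec("a2", 0, "greater",
                       classifier = function(z, mu)
                         as.numeric(abs(z[, 1]) < 1))
  rate <- function(specs, seed) {
    rs <- rejection_sample(std_density, specs, 2000, seed = seed,
                           max_draws = 1e5)
    rs$acceptance_rate
  }
  r1 <- rate(list(a1), 5)
  r2 <- rate(list(a2), 6)
  r12 <- rate(list(a1, a2), 7)
  mc_slack <- 3 * sqrt(0.25 / 2000)
  expect_lte(r12, min(r1, r2) + mc_slack)
})
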