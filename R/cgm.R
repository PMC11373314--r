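# Controllable generation module: an explicit Gaussian-mixture density over
# the learned molecule latent space, independent per-attribute classifiers
# on (latent, fragment encoding), and multi-attribute rejection sampling
# whose acceptance probability is the product of the classifier scores.

#' Fit a Gaussian mixture density over latent samples
#'
#' Expectation-maximization fit (diagonal covariances) of a k-component
#' mixture over encoded molecules, used as the explicit sampling density
#' of the controllable generation module.  Seeded and deterministic.
#'
#' @param latents Numeric matrix (n x d) of latent embeddings.
#' @param k Number of mixture components (default 10), or an integer
#'   vector of candidate counts selected by BIC.
#' @param seed Integer seed.
#' @return An object of class `latent_density`: `k`, `weights`, `means`
#'   (k x d), `vars` (k x d diagonal covariances), `loglik`, `bic`.
#' @export
fit_density <- function(latents, k = 10L, seed = 0L) {
  latents <- as.matrix(latents)
  n <- nrow(latents); d <- ncol(latents)
  if (n <= max(k)) stop("need more samples than mixture components",
                        call. = FALSE)
  .with_seed(seed, {
    model_names <- if (d == 1) "V" else "VVI"
    # Mclust resolves helper functions in the calling frame, so run the
    # call in an environment parented to the mclust namespace
    call_env <- new.env(parent = asNamespace("mclust"))
    call_env$.data <- latents
    call_env$.G <- k
    call_env$.mn <- model_names
    fit <- eval(quote(Mclust(.data, G = .G, modelNames = .mn,
                             verbose = FALSE)), call_env)
    if (is.null(fit)) stop("mixture fit failed", call. = FALSE)
    pm <- fit$parameters
    kk <- fit$G
    means <- t(matrix(pm$mean, nrow = d))
    vars <- if (d == 1) {
      matrix(pm$variance$sigmasq, kk, 1)
    } else {
      t(apply(pm$variance$sigma, 3L, diag))
    }
    if (any(vars < 1e-8)) {
      warning("degenerate component variance; flooring at 1e-8")
      vars <- pmax(vars, 1e-8)
    }
    structure(list(k = kk, weights = as.vector(pm$pro), means = means,
                   vars = vars, loglik = fit$loglik, bic = fit$bic,
                   d = d),
              class = "latent_density")
  })
}

#' @export
print.latent_density <- function(x, ...) {
  cat("<latent_density> ", x$k, " diagonal Gaussian components over ",
      x$d, " dims (loglik ", round(x$loglik, 1), ")\n", sep = "")
  invisible(x)
}

#' Sample from a fitted latent density
#'
#' @param density A `latent_density`.
#' @param n Number of draws.
#' @return Numeric matrix (n x d).
#' @export
sample_density <- function(density, n) {
  comp <- sample.int(density$k, n, replace = TRUE, prob = density$weights)
  mu <- density$means[comp, , drop = FALSE]
  sd <- sqrt(density$vars[comp, , drop = FALSE])
  mu + matrix(stats::rnorm(n * density$d), n) * sd
}

#' Define a controllable-generation attribute
#'
#' An attribute is a named property with a threshold and direction
#' (`greater`/`less`) plus a classifier scoring the probability that a
#' latent seed will decode into a molecule satisfying it.  The classifier
#' is either fitted ([train_attribute_classifier()]) or a custom function
#' `f(z, fragment_mu)` returning probabilities in \[0, 1\].
#'
#' @param name Attribute name (`"qed"`, `"sa"`, `"pic50"`, or custom).
#' @param threshold Numeric threshold.
#' @param direction `"greater"` or `"less"`.
#' @param classifier Optional classifier (function or fitted list).
#' @return An object of class `attribute_spec`.
#' @export
attribute_spec <- function(name, threshold,
                           direction = c("greater", "less"),
                           classifier = NULL) {
  direction <- match.arg(direction)
  structure(list(name = name, threshold = threshold,
                 direction = direction, classifier = classifier,
                 train_accuracy = NA_real_),
            class = "attribute_spec")
}

#' @export
print.attribute_spec <- function(x, ...) {
  cat("<attribute_spec> ", x$name,
      if (x$direction == "greater") " > " else " < ", x$threshold,
      if (!is.na(x$train_accuracy))
        sprintf(" (classifier train accuracy %.3f)", x$train_accuracy),
      "\n", sep = "")
  invisible(x)
}

#' Train a latent-space attribute classifier
#'
#' Logistic regression predicting whether the molecule decoded from a
#' latent seed satisfies the attribute, on features
#' `[z, fragment_mu]`.
#'
#' @param latents Numeric matrix (n x d_m) of molecule latents.
#' @param fragment_mus Numeric matrix (n x d_z) of fragment-pair means
#'   (or `NULL` to classify on the latent alone).
#' @param labels Logical (or 0/1) vector; both classes must be present.
#' @param spec An [attribute_spec()].
#' @return The spec with a fitted `classifier` and `train_accuracy`.
#' @export
train_attribute_classifier <- function(latents, fragment_mus, labels,
                                       spec) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2) {
    stop("labels must contain both classes", call. = FALSE)
  }
  X <- as.matrix(latents)
  if (!is.null(fragment_mus)) X <- cbind(X, as.matrix(fragment_mus))
  # ridge-penalized logistic regression: under complete separation plain
  # maximum likelihood saturates the scores at exactly 0/1, which can
  # zero the acceptance probability over the whole sampling density
  fit <- glmnet::glmnet(X, labels, family = "binomial", alpha = 0,
                        lambda = 1e-2, standardize = FALSE)
  co <- as.vector(stats::coef(fit))
  pr <- as.vector(1 / (1 + exp(-(co[1] + X %*% co[-1]))))
  spec$classifier <- list(type = "logistic", coef = co,
                          use_fragment = !is.null(fragment_mus),
                          d_latent = ncol(as.matrix(latents)))
  spec$train_accuracy <- mean((pr > 0.5) == (labels > 0.5))
  spec
}

# classifier score q(a | z, mu_f) for a matrix of latents
.spec_prob <- function(spec, z, fragment_mu = NULL) {
  z <- as.matrix(z)
  cl <- spec$classifier
  if (is.null(cl)) stop("attribute '", spec$name, "' has no classifier",
                        call. = FALSE)
  if (is.function(cl)) {
    p <- cl(z, fragment_mu)
  } else if (identical(cl$type, "logistic")) {
    X <- z
    if (isTRUE(cl$use_fragment)) {
      if (is.null(fragment_mu)) {
        stop("classifier for '", spec$name, "' needs fragment_mu",
             call. = FALSE)
      }
      fm <- matrix(as.numeric(fragment_mu), nrow(z),
                   length(as.numeric(fragment_mu)), byrow = TRUE)
      X <- cbind(X, fm)
    }
    co <- cl$coef
    co[is.na(co)] <- 0
    eta <- co[1] + X %*% co[-1]
    p <- as.vector(1 / (1 + exp(-eta)))
  } else {
    stop("unknown classifier type", call. = FALSE)
  }
  if (any(p < -1e-9 | p > 1 + 1e-9, na.rm = TRUE)) {
    stop("classifier probabilities outside [0, 1]", call. = FALSE)
  }
  pmin(pmax(p, 0), 1)
}

#' Multi-attribute acceptance probability
#'
#' The acceptance probability of a latent seed is the product of the
#' per-attribute classifier scores (the attributes are treated as
#' conditionally independent).
#'
#' @param z Latent vector or matrix (rows = seeds).
#' @param fragment_mu Fragment-pair mean (or `NULL`).
#' @param specs List of [attribute_spec()]s with classifiers.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
acceptance_probability <- function(z, fragment_mu, specs) {
  if (length(specs) == 0) stop("no attribute specs", call. = FALSE)
  if (inherits(specs, "attribute_spec")) specs <- list(specs)
  z <- if (is.null(dim(z))) matrix(z, 1) else as.matrix(z)
  p <- rep(1, nrow(z))
  for (sp in specs) p <- p * .spec_prob(sp, z, fragment_mu)
  p
}

#' Rejection-sample latent seeds against attribute classifiers
#'
#' Draws latents from the explicit density and accepts each with
#' probability equal to its product classifier score (a Bernoulli accept;
#' valid since the scores are bounded by 1), until `n_accept` seeds are
#' accepted or `max_draws` draws are exhausted.
#'
#' @param density A `latent_density`.
#' @param specs List of [attribute_spec()]s.
#' @param n_accept Number of accepted seeds wanted.
#' @param seed Integer seed (`NULL`: ambient RNG).
#' @param max_draws Draw budget (default `1000 * n_accept`).
#' @param fragment_mu Fragment-pair mean passed to the classifiers.
#' @return List with `samples` (accepted latents, possibly fewer than
#'   requested), `acceptance_rate`, `n_draws`, and `exhausted` (with a
#'   warning when the budget ran out).
#' @export
rejection_sample <- function(density, specs, n_accept, seed = NULL,
                             max_draws = 1000 * n_accept,
                             fragment_mu = NULL) {
  stopifnot(n_accept >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  accepted <- matrix(numeric(0), 0, density$d)
  n_draws <- 0L
  chunk <- max(64L, 2L * n_accept)
  while (nrow(accepted) < n_accept && n_draws < max_draws) {
    m <- min(chunk, max_draws - n_draws)
    z <- sample_density(density, m)
    p <- acceptance_probability(z, fragment_mu, specs)
    keep <- stats::runif(m) < p
    accepted <- rbind(accepted, z[keep, , drop = FALSE])
    n_draws <- n_draws + m
  }
  n_accepted <- nrow(accepted)
  exhausted <- n_accepted < n_accept
  if (exhausted) {
    warning("draw budget exhausted: ", n_accepted, "/", n_accept,
            " accepted")
  }
  if (n_accepted > n_accept) {
    accepted <- accepted[seq_len(n_accept), , drop = FALSE]
  }
  list(samples = accepted, acceptance_rate = n_accepted / n_draws,
       n_draws = n_draws, exhausted = exhausted)
}

#' Fit the controllable generation module
#'
#' Encodes the training molecules with the fitted VAE, fits the Gaussian
#' mixture density over their latents, computes attribute labels (QED and
#' SA by the published RDKit algorithms on the training molecules;
#' activity from the dataset's labels or the surrogate oracle), and trains
#' one logistic classifier per requested attribute on
#' `[latent, fragment mean]`.
#'
#' @param fit A `linker_fit`.
#' @param dataset The training dataset tibble.
#' @param attributes Character subset of `c("qed", "sa", "pic50")`.
#' @param thresholds Named list of thresholds (defaults QED > 0.6,
#'   SA < 3, pIC50 > 6).
#' @param k Mixture components (default 10).
#' @param seed Integer seed.
#' @return An object of class `cgm_fit`: `density`, `specs`, plus the
#'   encoded `latents` and `fragment_mus`.
#' @export
cgm_fit <- function(fit, dataset, attributes = c("qed", "sa", "pic50"),
                    thresholds = list(qed = 0.6, sa = 3, pic50 = 6),
                    k = 10L, seed = 0L) {
  stopifnot(inherits(fit, "linker_fit"))
  attributes <- match.arg(attributes, several.ok = TRUE)
  enc <- encode_dataset(dataset, fit)
  props <- NULL
  if (any(attributes %in% c("qed", "sa"))) {
    props <- chem_properties(dataset$molecule_smiles)
  }
  activity <- if (!is.null(dataset$activity)) {
    dataset$activity
  } else {
    vapply(dataset$molecule_smiles, surrogate_activity, 0, USE.NAMES = FALSE)
  }
  specs <- list()
  for (a in attributes) {
    sp <- switch(a,
      qed = attribute_spec("qed", thresholds$qed, "greater"),
      sa = attribute_spec("sa", thresholds$sa, "less"),
      pic50 = attribute_spec("pic50", thresholds$pic50, "greater"))
    labels <- switch(a,
      qed = props$qed > thresholds$qed,
      sa = props$sa < thresholds$sa,
      pic50 = activity > thresholds$pic50)
    specs[[a]] <- train_attribute_classifier(enc$latents,
                                             enc$fragment_mus, labels, sp)
  }
  density <- fit_density(enc$latents, k = k, seed = seed)
  structure(list(density = density, specs = specs,
                 latents = enc$latents, fragment_mus = enc$fragment_mus,
                 thresholds = thresholds),
            class = "cgm_fit")
}

#' @export
print.cgm_fit <- function(x, ...) {
  cat("<cgm_fit> density with ", x$density$k, " components; attributes: ",
      paste(vapply(x$specs, function(s) sprintf(
        "%s (acc %.2f)", s$name, s$train_accuracy), ""), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Encode a dataset into latent space
#'
#' Molecule latents (`mu_m`) and fragment-pair means (`mu_f`) for every
#' example, as consumed by the controllable generation module.
#'
#' @param dataset Dataset tibble with an `example` list-column.
#' @param fit A `linker_fit`.
#' @return List with matrices `latents` (n x d_m) and `fragment_mus`
#'   (n x d_z).
#' @export
encode_dataset <- function(dataset, fit) {
  examples <- dataset$example
  lat <- t(vapply(examples, function(e) {
    tr <- build_trajectory(e, fit$config)
    encode(e$molecule, fit$params, fit$config, role = "molecule",
           positions = tr$mol_positions)$mu
  }, numeric(fit$config$d_m)))
  fm <- t(vapply(examples, function(e)
    encode_fragment_pair(e$fragment_1, e$fragment_2, fit$params,
                         fit$config)$mu,
    numeric(fit$config$d_z)))
  list(latents = lat, fragment_mus = fm)
}

#' Controllable generation for one fragment pair
#'
#' Under `mode = "rejection"`, latent seeds are rejection-sampled from the
#' fitted density against the attribute classifiers and decoded; under
#' `mode = "random"` the decoder's standard-normal sampling is used
#' unchanged.  The returned log records each molecule's product
#' acceptance score and the draw budget used.
#'
#' @param fit A `linker_fit`.
#' @param cgm A `cgm_fit` (required for rejection mode).
#' @param fragment_1,fragment_2 Fragments (SMILES or `mol_graph`).
#' @param n_molecules Molecules to generate (default 10 per pair).
#' @param seed Integer seed.
#' @param mode `"rejection"` or `"random"`.
#' @param max_draws Rejection draw budget.
#' @return A tibble: `smiles`, `mode`, `accept_score`, `n_draws`, plus
#'   the [generate_linkers()] columns.
#' @export
controlled_generate <- function(fit, cgm, fragment_1, fragment_2,
                                n_molecules = 10L, seed = NULL,
                                mode = c("rejection", "random"),
                                max_draws = 1000 * n_molecules) {
  mode <- match.arg(mode)
  if (is.character(fragment_1)) fragment_1 <- parse_smiles(fragment_1)
  if (is.character(fragment_2)) fragment_2 <- parse_smiles(fragment_2)
  if (!is.null(seed)) set.seed(as.integer(seed))
  mu_f <- encode_fragment_pair(fragment_1, fragment_2, fit$params,
                               fit$config)$mu
  if (mode == "rejection") {
    if (is.null(cgm) || length(cgm$specs) == 0) {
      stop("rejection mode needs a cgm_fit with at least one attribute",
           call. = FALSE)
    }
    rs <- rejection_sample(cgm$density, cgm$specs, n_molecules,
                           max_draws = max_draws, fragment_mu = mu_f)
    lat <- rs$samples
    if (nrow(lat) == 0) stop("no latents accepted", call. = FALSE)
    scores <- acceptance_probability(lat, mu_f, cgm$specs)
    out <- generate_linkers(fragment_1, fragment_2, fit$params, fit$config,
                            n_samples = nrow(lat), latents = lat)
    out$mode <- "rejection"
    out$accept_score <- scores
    out$n_draws <- rs$n_draws
  } else {
    out <- generate_linkers(fragment_1, fragment_2, fit$params, fit$config,
                            n_samples = n_molecules)
    out$mode <- "random"
    out$accept_score <- NA_real_
    out$n_draws <- n_molecules
  }
  out
}
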