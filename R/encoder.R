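# Variational graph encoder: GCN or node-edge co-embedding backbone,
# graph-level (mu, sigma) heads for fragments and molecules, and the
# decoder's initial latent representation.

.glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

.ln_pair <- function(d) list(gamma = matrix(1, 1, d), beta = matrix(0, 1, d))

# parameters of one graph backbone (3 GCN layers, or node/edge/node
# co-embedding layers), for given input feature widths
.make_backbone_params <- function(in_node, in_edge, d_h, backbone) {
  if (backbone == "gcn") {
    list(
      W1 = .glorot(in_node, d_h), b1 = matrix(0, 1, d_h),
      g1 = matrix(1, 1, d_h), e1 = matrix(0, 1, d_h),
      W2 = .glorot(d_h, d_h), b2 = matrix(0, 1, d_h),
      g2 = matrix(1, 1, d_h), e2 = matrix(0, 1, d_h),
      W3 = .glorot(d_h, d_h), b3 = matrix(0, 1, d_h),
      g3 = matrix(1, 1, d_h), e3 = matrix(0, 1, d_h)
    )
  } else {
    list(
      Wv1 = .glorot(in_node, d_h), bv1 = matrix(0, 1, d_h),
      pv1 = matrix(0, in_edge, 1),
      gv1 = matrix(1, 1, d_h), ev1 = matrix(0, 1, d_h),
      We1 = .glorot(in_edge, d_h), be1 = matrix(0, 1, d_h),
      pe1 = matrix(0, d_h, 1),
      ge1 = matrix(1, 1, d_h), ee1 = matrix(0, 1, d_h),
      Wv2 = .glorot(d_h, d_h), bv2 = matrix(0, 1, d_h),
      pv2 = matrix(0, d_h, 1),
      gv2 = matrix(1, 1, d_h), ev2 = matrix(0, 1, d_h)
    )
  }
}

#' Model configuration
#'
#' Collects the architectural hyperparameters of the linker VAE: latent
#' width `d_z` (fragment latent and decoder input), molecule latent width
#' `d_m` (`d_m < d_z`; the remaining `d_z - d_m` dimensions come from a
#' linear map of the molecule latent), hidden width `d_h`, backbone family,
#' dropout rate, and the element vocabulary.
#'
#' @param backbone `"censnet"` (node-edge co-embedding, default) or
#'   `"gcn"`.
#' @param d_z,d_m,d_h Integer widths (defaults 32, 16, 32).
#' @param dropout Dropout rate used during training (default 0.1).
#' @param mlp_width Hidden width of the edge/stop decision MLPs
#'   (default 256).
#' @return A list of class `linker_config`.
#' @export
linker_config <- function(backbone = c("censnet", "gcn"), d_z = 32L,
                          d_m = 16L, d_h = 32L, dropout = 0.1,
                          mlp_width = 256L) {
  backbone <- match.arg(backbone)
  stopifnot(d_m < d_z)
  structure(list(backbone = backbone, d_z = as.integer(d_z),
                 d_m = as.integer(d_m), d_h = as.integer(d_h),
                 dropout = dropout, mlp_width = as.integer(mlp_width),
                 vocab = element_vocabulary()),
            class = "linker_config")
}

# full parameter set: encoder backbone + heads, decoder re-encoder backbone
# + MLP heads.  Node input widths: encoder sees [element one-hot,
# attachment]; the decoder re-encoder sees [z row, label one-hot (+
# "unlabeled"), attachment, linker flag, positional tag].
make_model_params <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  nv <- length(config$vocab)
  d_h <- config$d_h; d_z <- config$d_z; d_m <- config$d_m
  mw <- if (is.null(config$mlp_width)) 128L else config$mlp_width
  # encoder node inputs: [element one-hot, attachment, linker position
  # tag, pos * element one-hot].  The position-modulated block lets the
  # molecule posterior write position-indexed linker content into the
  # latent (the decoder reads it back through its own z * pos features);
  # fragment atoms carry zeros there
  enc_in <- nv + 1L + 1L + nv
  # decoder node inputs: [z, label one-hot(+unlabeled), attachment,
  # linker flag, pos tag, z * pos] - the positional modulation of the
  # broadcast latent makes per-position readout first-order accessible
  dec_in <- d_z + (nv + 1L) + 3L + d_z
  d_lab <- nv + 1L
  d_s <- d_h + d_lab
  d_phi <- 2L * d_s + 1L + d_z + d_h + 2L
  d_psi <- d_s + d_z + d_h + 2L
  list(
    enc = .make_backbone_params(enc_in, 3L, d_h, config$backbone),
    dec = .make_backbone_params(dec_in, 3L, d_h, config$backbone),
    head = list(
      Wmu_f = .glorot(d_h, d_z), bmu_f = matrix(0, 1, d_z),
      Wsig_f = .glorot(d_h, d_z), bsig_f = matrix(0, 1, d_z),
      Wmu_m = .glorot(d_h, d_m), bmu_m = matrix(0, 1, d_m),
      Wsig_m = .glorot(d_h, d_m), bsig_m = matrix(0, 1, d_m),
      Wtau = .glorot(d_m, d_z - d_m), btau = matrix(0, 1, d_z - d_m),
      # per-dimension gate on the molecule-latent pathway; a scalar gate
      # couples useful and noisy latent channels, which lets the
      # optimizer silence the whole pathway to suppress sampling noise
      a_f = matrix(1, 1, d_z)
    ),
    mlp_e = list(
      W1 = .glorot(d_phi, mw), b1 = matrix(0, 1, mw),
      W2 = .glorot(mw, mw), b2 = matrix(0, 1, mw),
      W3 = .glorot(mw, 3L), b3 = matrix(0, 1, 3L)
    ),
    mlp_stop = list(
      W1 = .glorot(d_psi, mw), b1 = matrix(0, 1, mw),
      W2 = .glorot(mw, 1L), b2 = matrix(0, 1, 1L)
    ),
    mlp_n = list(
      # label head sees the hidden state, the initial representation,
      # and the positional tag directly
      W1 = .glorot(d_h + d_z + 1L, 64L), b1 = matrix(0, 1, 64L),
      W2 = .glorot(64L, nv), b2 = matrix(0, 1, nv)
    )
  )
}

# run a backbone over prebuilt block constants; X: node inputs.  Edge
# inputs are the one-hot bond orders from the constants.
backbone_forward <- function(bb, const, X, backbone, dropout = 0,
                             training = FALSE) {
  if (backbone == "gcn") {
    h <- .gcn_prop(const, X, bb$W1, bb$b1, bb$g1, bb$e1,
                   dropout = dropout, training = training)
    h <- .gcn_prop(const, h, bb$W2, bb$b2, bb$g2, bb$e2,
                   dropout = dropout, training = training)
    h <- .gcn_prop(const, h, bb$W3, bb$b3, bb$g3, bb$e3,
                   dropout = dropout, training = training)
    h
  } else {
    xe <- const$edge_features
    hv <- .cens_node_prop(const, X, xe, bb$Wv1, bb$bv1, bb$pv1,
                          bb$gv1, bb$ev1, dropout = dropout,
                          training = training)
    he <- .cens_edge_prop(const, hv, xe, bb$We1, bb$be1, bb$pe1,
                          bb$ge1, bb$ee1, dropout = dropout,
                          training = training)
    hv <- .cens_node_prop(const, hv, he, bb$Wv2, bb$bv2, bb$pv2,
                          bb$gv2, bb$ev2, dropout = dropout,
                          training = training)
    hv
  }
}

# encoder node input features for a mol_graph; `positions` are the
# canonical linker position tags (zero for fragment atoms and at
# fragment-encoding time)
.encoder_node_features <- function(g, vocab = element_vocabulary(),
                                   positions = NULL) {
  n <- length(g$elements)
  if (is.null(positions)) positions <- rep(0, n)
  onehot <- matrix(0, n, length(vocab))
  onehot[cbind(seq_len(n), match(g$elements, vocab))] <- 1
  cbind(onehot, as.numeric(g$attachment), positions, onehot * positions)
}

# batched encode over prebuilt constants; returns (mu, sigma) matrices
.encode_block <- function(params, const, X, role, dropout = 0,
                          training = FALSE, backbone) {
  H <- backbone_forward(params[["enc"]], const, X, backbone,
                        dropout = dropout, training = training)
  pooled <- ad_mm(const$pool, H)
  hd <- params$head
  if (role == "fragment") {
    mu <- ad_add(ad_mm(pooled, hd$Wmu_f), hd$bmu_f)
    sigma <- ad_exp(ad_add(ad_mm(pooled, hd$Wsig_f), hd$bsig_f))
  } else {
    mu <- ad_add(ad_mm(pooled, hd$Wmu_m), hd$bmu_m)
    sigma <- ad_exp(ad_add(ad_mm(pooled, hd$Wsig_m), hd$bsig_m))
  }
  list(mu = mu, sigma = sigma)
}

#' Encode a molecular graph to a latent Gaussian
#'
#' Runs the graph backbone, mean-pools node embeddings to a graph-level
#' vector, and projects to the mean and (exponentiated) log standard
#' deviation of a diagonal Gaussian.  Fragments and molecules use separate
#' projection heads: fragments encode to width `d_z`, molecules to width
#' `d_m`.  Deterministic given parameters; invariant to atom relabelling.
#'
#' @param g A `mol_graph`.
#' @param params Model parameters (from a fit, or [make_model_params()]
#'   internally).
#' @param config A [linker_config()].
#' @param role `"molecule"` or `"fragment"` (selects the projection head).
#' @param positions Optional per-atom canonical linker position tags
#'   (molecule role, training side); zeros when omitted.
#' @return A `latent_encoding`: list with numeric vectors `mu` and `sigma`
#'   (elementwise positive).
#' @export
encode <- function(g, params, config, role = c("molecule", "fragment"),
                   positions = NULL) {
  role <- match.arg(role)
  stopifnot(inherits(g, "mol_graph"))
  if (length(g$elements) == 0) stop("empty graph", call. = FALSE)
  const <- graph_conv_constants(list(list(n = length(g$elements),
                                          bonds = g$bonds)))
  X <- .encoder_node_features(g, config$vocab, positions)
  enc <- .encode_block(params, const, X, role, backbone = config$backbone)
  structure(list(mu = as.vector(ad_val(enc$mu)),
                 sigma = as.vector(ad_val(enc$sigma))),
            class = "latent_encoding")
}

#' Encode a fragment pair
#'
#' Each fragment is encoded separately with the fragment head and the two
#' graph-level Gaussians are averaged with equal weight 1/2.
#'
#' @param fragment_1,fragment_2 `mol_graph` fragments.
#' @inheritParams encode
#' @return A `latent_encoding` of width `d_z`.
#' @export
encode_fragment_pair <- function(fragment_1, fragment_2, params, config) {
  e1 <- encode(fragment_1, params, config, role = "fragment")
  e2 <- encode(fragment_2, params, config, role = "fragment")
  structure(list(mu = (e1$mu + e2$mu) / 2,
                 sigma = (e1$sigma + e2$sigma) / 2),
            class = "latent_encoding")
}

#' Build the decoder's initial latent representation
#'
#' Combines the fragment-pair mean with a molecule-latent sample:
#' `z = mu_f + a_f * [z_m, tau]`, where `z_m` is drawn from the molecule
#' encoder's Gaussian (reparameterized; training mode) or from a standard
#' normal (generation mode), `tau` is a linear map of `z_m` filling the
#' remaining `d_z - d_m` dimensions, and `a_f` is a learned per-dimension
#' gate on the molecule-latent pathway (broadcast if scalar).
#'
#' @param mu_f Numeric fragment-pair mean (length `d_z`).
#' @param enc_m Molecule `latent_encoding` (required in training mode).
#' @param params Model parameters.
#' @param config A [linker_config()].
#' @param mode `"train"` or `"generate"`.
#' @param eps Optional standard-normal draw (length `d_m`) for
#'   reproducibility; drawn from the current RNG when `NULL`.
#' @return List of class `initial_representation` with `z`, `z_m`, `tau`,
#'   `a_f`.
#' @export
make_initial_representation <- function(mu_f, enc_m = NULL, params, config,
                                        mode = c("train", "generate"),
                                        eps = NULL) {
  mode <- match.arg(mode)
  d_m <- config$d_m
  if (is.null(eps)) eps <- stats::rnorm(d_m)
  if (mode == "train") {
    if (is.null(enc_m)) {
      stop("training mode requires the molecule encoding", call. = FALSE)
    }
    z_m <- enc_m$mu + enc_m$sigma * eps
  } else {
    z_m <- eps
  }
  hd <- params$head
  tau <- as.vector(matrix(z_m, 1) %*% hd$Wtau) + as.vector(hd$btau)
  a_f <- as.vector(hd$a_f)
  if (length(a_f) == 1) a_f <- rep(a_f, length(mu_f))
  z <- mu_f + a_f * c(z_m, tau)
  structure(list(z = z, z_m = z_m, tau = tau, a_f = a_f),
            class = "initial_representation")
}
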