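# Sequential bond-by-bond linker construction between two fragments under
# valency constraints.  The decoder keeps a partial graph (fragment atoms
# plus initialized linker nodes), re-encodes it with the graph backbone at
# every step, scores candidate edges with an MLP over node/graph-level
# features, and finishes each focus node with an explicit stop action.

.UNLABELED <- "?"
.D_SENTINEL <- 20L  # graph distance for disconnected pairs

# label one-hot over (vocabulary, unlabeled)
.label_onehot <- function(elements, vocab = element_vocabulary()) {
  n <- length(elements)
  x <- matrix(0, n, length(vocab) + 1L)
  idx <- match(elements, vocab)
  idx[is.na(idx)] <- length(vocab) + 1L
  x[cbind(seq_len(n), idx)] <- 1
  x
}

# BFS graph distances from u over a bond list (sentinel for unreachable)
.dists_from <- function(n, bonds, u, sentinel = .D_SENTINEL) {
  adj <- vector("list", n)
  if (NROW(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  d <- rep(NA_integer_, n)
  d[u] <- 0L
  frontier <- u
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (x in frontier) {
      for (y in adj[[x]]) {
        if (is.na(d[y])) {
          d[y] <- d[x] + 1L
          nxt <- c(nxt, y)
        }
      }
    }
    frontier <- nxt
  }
  d[is.na(d)] <- sentinel
  pmin(d, sentinel)
}

#' Initialize a decoder state
#'
#' Lays out the two fragments followed by `n_linker` isolated linker nodes.
#' Every node carries the broadcast initial representation `z`; linker
#' nodes additionally get distinct positional tags to break symmetry.  The
#' focus queue is seeded with the two attachment atoms.  Valence budgets
#' come from the valence table for fragment atoms (current bonds counted)
#' and a provisional budget of 4 (the vocabulary's maximum) for linker
#' nodes, whose element is only assigned after edge generation.
#'
#' @param fragment_1,fragment_2 `mol_graph` fragments with one attachment
#'   atom each.
#' @param z Initial representation: an `initial_representation` or a
#'   numeric vector of length `d_z`.
#' @param n_linker Number of linker nodes (3 to 12).
#' @param config A [linker_config()].
#' @param descriptor Optional 3D fragment-pair descriptor (length 2).
#' @return An object of class `decoder_state`.
#' @export
init_state <- function(fragment_1, fragment_2, z, n_linker, config,
                       descriptor = c(0, 0)) {
  if (n_linker < 3 || n_linker > 12) {
    stop("n_linker must be between 3 and 12", call. = FALSE)
  }
  if (sum(fragment_1$attachment) != 1 || sum(fragment_2$attachment) != 1) {
    stop("each fragment needs exactly one attachment atom", call. = FALSE)
  }
  if (inherits(z, "initial_representation")) z <- z$z
  n1 <- length(fragment_1$elements)
  n2 <- length(fragment_2$elements)
  n <- n1 + n2 + n_linker
  elements <- c(fragment_1$elements, fragment_2$elements,
                rep(.UNLABELED, n_linker))
  bonds <- rbind(
    fragment_1$bonds,
    cbind(fragment_2$bonds[, 1, drop = TRUE] + n1,
          fragment_2$bonds[, 2, drop = TRUE] + n1,
          fragment_2$bonds[, 3, drop = TRUE])
  )
  bonds <- matrix(as.integer(bonds), ncol = 3)
  vt <- valence_table()
  sums <- integer(n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      sums[bonds[k, 1]] <- sums[bonds[k, 1]] + bonds[k, 3]
      sums[bonds[k, 2]] <- sums[bonds[k, 2]] + bonds[k, 3]
    }
  }
  budget <- integer(n)
  frag_idx <- seq_len(n1 + n2)
  budget[frag_idx] <- vt[elements[frag_idx]] - sums[frag_idx]
  budget[(n1 + n2 + 1):n] <- 4L
  a1 <- which(fragment_1$attachment)
  a2 <- n1 + which(fragment_2$attachment)
  seen <- rep(FALSE, n)
  seen[c(a1, a2)] <- TRUE
  structure(list(
    elements = elements, bonds = bonds, budget = budget,
    n1 = n1, n2 = n2, n_linker = n_linker, n = n,
    n_frag_bonds = nrow(bonds),
    attach = c(fragment_1$attachment, fragment_2$attachment,
               rep(FALSE, n_linker)),
    linker_flag = c(rep(FALSE, n1 + n2), rep(TRUE, n_linker)),
    pos_tag = c(rep(0, n1 + n2), seq_len(n_linker) / 12),
    anchor1 = a1, anchor2 = a2,
    queue = c(a1, a2), seen = seen, visited = rep(FALSE, n),
    z = as.numeric(z), descriptor = as.numeric(descriptor),
    step = 0L, max_steps = 2L * choose(n, 2L),
    truncated = FALSE, H = NULL,
    edge_log = matrix(integer(0), ncol = 3)
  ), class = "decoder_state")
}

#' @export
print.decoder_state <- function(x, ...) {
  cat("<decoder_state> ", x$n, " nodes (", x$n_linker, " linker), ",
      nrow(x$bonds), " bonds, step ", x$step, ", queue length ",
      length(x$queue), "\n", sep = "")
  invisible(x)
}

# node input features of the current partial graph for the re-encoder:
# [z row, label one-hot (+unlabeled), attachment, linker flag, pos tag]
.state_node_features <- function(state, config) {
  zb <- matrix(state$z, state$n, config$d_z, byrow = TRUE)
  cbind(
    zb,
    .label_onehot(state$elements, config$vocab),
    as.numeric(state$attach), as.numeric(state$linker_flag), state$pos_tag,
    zb * state$pos_tag
  )
}

#' Re-encode the partial graph
#'
#' Recomputes the per-node hidden matrix from the current partial graph
#' with the decoder's graph backbone (deterministic; no dropout).
#'
#' @param state A `decoder_state`.
#' @param params Model parameters.
#' @param config A [linker_config()].
#' @return The state with an updated hidden matrix `H`.
#' @export
reencode <- function(state, params, config) {
  const <- graph_conv_constants(list(list(n = state$n, bonds = state$bonds)))
  X <- .state_node_features(state, config)
  H <- backbone_forward(params$dec, const, X, config$backbone)
  state$H <- ad_val(H)
  state
}

# candidate targets for focus node u: any other node with remaining
# budget, not already bonded to u; per-order feasibility mask
.candidates <- function(state, u) {
  if (state$budget[u] <= 0) {
    return(list(v = integer(0), mask = matrix(FALSE, 0, 3)))
  }
  bonded <- integer(0)
  b <- state$bonds
  if (nrow(b) > 0) {
    bonded <- c(b[b[, 1] == u, 2], b[b[, 2] == u, 1])
  }
  v <- setdiff(which(state$budget > 0), c(u, bonded))
  v <- sort(v)
  cap <- pmin(state$budget[v], state$budget[u], 3L)
  mask <- outer(cap, 1:3, ">=")
  list(v = v, mask = mask)
}

# assemble the edge-candidate (Phi) and stop (Psi) feature matrices.
# Column layout (shared with the teacher-forcing batch path):
# Phi = [s_u, s_v, d_uv/10, H0, Ht, D]; Psi = [s_u, H0, Ht, D]
.phi_features <- function(H, z, labels8, u, v, d_uv, D) {
  Ht <- colMeans(H)
  s_u <- c(H[u, ], labels8[u, ])
  n_c <- length(v)
  if (n_c > 0) {
    S_v <- cbind(H[v, , drop = FALSE], labels8[v, , drop = FALSE])
    phi <- cbind(matrix(s_u, n_c, length(s_u), byrow = TRUE), S_v,
                 d_uv / 10, matrix(z, n_c, length(z), byrow = TRUE),
                 matrix(Ht, n_c, length(Ht), byrow = TRUE),
                 matrix(D, n_c, 2, byrow = TRUE))
  } else {
    phi <- matrix(0, 0, 2 * length(s_u) + 1 + length(z) + length(Ht) + 2)
  }
  psi <- matrix(c(s_u, z, Ht, D), 1)
  list(phi = phi, psi = psi)
}

.mlp_e_forward <- function(mlp, phi) {
  h <- ad_relu(ad_add(ad_mm(phi, mlp$W1), mlp$b1))
  h <- ad_relu(ad_add(ad_mm(h, mlp$W2), mlp$b2))
  ad_add(ad_mm(h, mlp$W3), mlp$b3)
}

.mlp_stop_forward <- function(mlp, psi) {
  h <- ad_relu(ad_add(ad_mm(psi, mlp$W1), mlp$b1))
  ad_add(ad_mm(h, mlp$W2), mlp$b2)
}

#' Score candidate edges for the focus node
#'
#' Builds the per-candidate feature vector (focus and candidate hidden
#' states with atomic labels, their graph distance, the average initial and
#' current graph representations, and the 3D descriptor), scores every
#' feasible (candidate, bond order) with the edge MLP and the stop action
#' with the stop head, and returns the masked softmax over the surviving
#' actions.  Entries violating valence budgets or duplicating an existing
#' bond are masked out; if the focus node is saturated only stop survives.
#'
#' @param state A `decoder_state` (re-encoded; [reencode()] is called if
#'   the hidden matrix is missing).
#' @param u Focus node index (head of the queue).
#' @param params Model parameters.
#' @param config A [linker_config()].
#' @return List with `v` (candidate indices), `mask` (candidates x 3),
#'   `logits` (candidates x 3), `stop_logit`, and `probs`: a tibble of
#'   actions (`v`, `order`, `prob`; the stop row has `v = NA`) summing
#'   to 1.
#' @export
edge_logits <- function(state, u, params, config) {
  if (is.null(state$H)) state <- reencode(state, params, config)
  cand <- .candidates(state, u)
  labels8 <- .label_onehot(state$elements, config$vocab)
  d_all <- .dists_from(state$n, state$bonds, u)
  f <- .phi_features(state$H, state$z, labels8, u, cand$v, d_all[cand$v],
                     state$descriptor)
  logits <- if (length(cand$v) > 0) {
    ad_val(.mlp_e_forward(params$mlp_e, f$phi))
  } else {
    matrix(0, 0, 3)
  }
  stop_logit <- as.vector(ad_val(.mlp_stop_forward(params$mlp_stop, f$psi)))
  lm <- logits
  lm[!cand$mask] <- -Inf
  all_l <- c(as.vector(t(lm)), stop_logit)  # (v1 o1..3, v2 o1..3, ..., stop)
  mx <- max(all_l)
  ex <- exp(all_l - mx)
  ex[!is.finite(ex)] <- 0
  pr <- ex / sum(ex)
  probs <- tibble::tibble(
    v = c(rep(cand$v, each = 3L), NA_integer_),
    order = c(rep(1:3, length(cand$v)), NA_integer_),
    prob = pr
  )
  list(v = cand$v, mask = cand$mask, logits = logits,
       stop_logit = stop_logit, probs = probs)
}

#' Advance the decoder by one action
#'
#' Scores the focus node's actions and commits one: an edge addition
#' (argmax probability, ties broken by lowest candidate index then lowest
#' bond order; or a draw from the action distribution under
#' `policy = "sample"`) decrements both valence budgets and enqueues the
#' new neighbour if never seen; stop retires the focus node and enqueues
#' its not-yet-seen neighbours in index order.
#'
#' @param state A `decoder_state`.
#' @param params Model parameters.
#' @param config A [linker_config()].
#' @param policy `"argmax"` or `"sample"`.
#' @return The updated state (field `truncated` set when the step budget
#'   is exhausted).
#' @export
decoder_step <- function(state, params, config,
                         policy = c("argmax", "sample")) {
  policy <- match.arg(policy)
  if (length(state$queue) == 0) stop("focus queue is empty", call. = FALSE)
  if (state$step >= state$max_steps) {
    state$truncated <- TRUE
    return(state)
  }
  if (is.null(state$H)) state <- reencode(state, params, config)
  u <- state$queue[1]
  el <- edge_logits(state, u, params, config)
  pr <- el$probs$prob
  pick <- if (policy == "argmax") {
    which.max(pr)  # action rows ordered by (v, order); stop last
  } else {
    sample.int(length(pr), 1L, prob = pr)
  }
  act <- el$probs[pick, ]
  if (is.na(act$v)) {
    # stop: retire the focus node, move on to its unseen neighbours
    state$visited[u] <- TRUE
    state$queue <- state$queue[-1]
    b <- state$bonds
    nb <- sort(unique(c(b[b[, 1] == u, 2], b[b[, 2] == u, 1])))
    nb <- nb[!state$seen[nb]]
    if (length(nb) > 0) {
      state$queue <- c(state$queue, nb)
      state$seen[nb] <- TRUE
    }
  } else {
    v <- act$v; o <- act$order
    state$bonds <- rbind(state$bonds, c(min(u, v), max(u, v), o))
    state$budget[u] <- state$budget[u] - o
    state$budget[v] <- state$budget[v] - o
    state$edge_log <- rbind(state$edge_log, c(u, v, o))
    if (!state$seen[v]) {
      state$queue <- c(state$queue, v)
      state$seen[v] <- TRUE
    }
    state$H <- NULL  # graph changed; hidden matrix is stale
  }
  state$step <- state$step + 1L
  state
}

#' Predict element symbols for the linker nodes
#'
#' After the edge phase, assigns each linker node an element by the node
#' MLP over its final hidden state, masked to elements whose maximum
#' valence covers the node's realized bond-order sum.  Fragment atoms keep
#' their input labels.
#'
#' @param state A `decoder_state` with the edge phase finished.
#' @param params Model parameters.
#' @param config A [linker_config()].
#' @return Character vector of element symbols, one per linker node.
#' @export
predict_node_labels <- function(state, params, config) {
  state <- reencode(state, params, config)
  vt <- valence_table()[config$vocab]
  linker <- which(state$linker_flag)
  sums <- integer(state$n)
  b <- state$bonds
  if (nrow(b) > 0) {
    for (k in seq_len(nrow(b))) {
      sums[b[k, 1]] <- sums[b[k, 1]] + b[k, 3]
      sums[b[k, 2]] <- sums[b[k, 2]] + b[k, 3]
    }
  }
  lab_in <- cbind(state$H[linker, , drop = FALSE],
                  matrix(state$z, length(linker), config$d_z,
                         byrow = TRUE),
                  state$pos_tag[linker])
  logits <- ad_val(ad_add(
    ad_mm(ad_relu(ad_add(ad_mm(lab_in, params$mlp_n$W1),
                         params$mlp_n$b1)),
          params$mlp_n$W2), params$mlp_n$b2))
  out <- character(length(linker))
  for (k in seq_along(linker)) {
    feasible <- vt >= sums[linker[k]]
    l <- logits[k, ]
    l[!feasible] <- -Inf
    out[k] <- config$vocab[which.max(l)]
  }
  out
}

#' Finalize a decoder state into a molecule
#'
#' Commits the predicted linker labels and returns the largest connected
#' component of the partial graph (ties broken in favour of the component
#' containing fragment 1's attachment atom, then by lowest minimum atom
#' index).  Unconnected leftover linker nodes are dropped.  The result is
#' valence-valid by construction of the edge masks.
#'
#' @param state A `decoder_state`.
#' @param labels Linker element symbols ([predict_node_labels()]).
#' @return A `mol_graph`.
#' @export
finalize <- function(state, labels) {
  .finalize_info(state, labels)$molecule
}

# finalize plus bookkeeping: whether both attachment atoms survived in
# the kept component
.finalize_info <- function(state, labels) {
  elements <- state$elements
  elements[state$linker_flag] <- labels
  comp <- .components_fast(state$n, state$bonds)
  sizes <- tabulate(comp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1 && comp[state$anchor1] %in% best) {
    keep_comp <- comp[state$anchor1]
  } else {
    mins <- vapply(best, function(cc) min(which(comp == cc)), 1L)
    keep_comp <- best[which.min(mins)]
  }
  keep <- which(comp == keep_comp)
  tmp <- mol_graph(elements, state$bonds, validate = FALSE)
  tmp$attachment <- rep(FALSE, state$n)
  tmp$charges <- rep(0L, state$n)
  list(molecule = induced_mol_subgraph(tmp, keep),
       both_fragments = comp[state$anchor1] == keep_comp &&
         comp[state$anchor2] == keep_comp)
}

#' Generate linked molecules for a fragment pair
#'
#' Full generation protocol: encode the fragment pair, draw the molecule
#' latent from a standard normal (or use supplied latents, e.g. accepted
#' rejection samples from the controllable generation module), build the
#' initial representation, run the sequential decoder to completion, label
#' linker nodes, and return the largest connected component of each
#' outcome.
#'
#' @param fragment_1,fragment_2 `mol_graph` fragments (or SMILES strings
#'   with `*` attachment markers).
#' @param params Model parameters (e.g. `fit$params`).
#' @param config A [linker_config()] (e.g. `fit$config`).
#' @param n_samples Number of molecules to generate.
#' @param seed Integer seed (ignored when `NULL`: ambient RNG is used).
#' @param n_linker `NULL` to draw linker sizes uniformly from 3-12 per
#'   sample, or a fixed size.
#' @param latents Optional matrix (`n_samples` x `d_m`) of molecule
#'   latents overriding the standard-normal draw.
#' @param policy Edge selection policy, `"argmax"` (default) or
#'   `"sample"`.
#' @param descriptor Fragment-pair 3D descriptor (length 2, default
#'   zeros).
#' @return A tibble with one row per sample: `smiles`, `n_linker`,
#'   `steps`, `n_edges`, `truncated`, `both_fragments` (did both
#'   attachment atoms survive in the largest component?), and the
#'   `mol_graph` in list-column `molecule`.
#' @export
generate_linkers <- function(fragment_1, fragment_2, params, config,
                             n_samples = 1L, seed = NULL, n_linker = NULL,
                             latents = NULL, policy = "argmax",
                             descriptor = c(0, 0)) {
  if (is.character(fragment_1)) fragment_1 <- parse_smiles(fragment_1)
  if (is.character(fragment_2)) fragment_2 <- parse_smiles(fragment_2)
  if (!is.null(seed)) set.seed(as.integer(seed))
  mu_f <- encode_fragment_pair(fragment_1, fragment_2, params, config)$mu
  rows <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    eps <- if (is.null(latents)) stats::rnorm(config$d_m) else latents[s, ]
    init <- make_initial_representation(mu_f, NULL, params, config,
                                        mode = "generate", eps = eps)
    nl <- if (is.null(n_linker)) sample(3:12, 1L) else as.integer(n_linker)
    st <- init_state(fragment_1, fragment_2, init, nl, config,
                     descriptor = descriptor)
    while (length(st$queue) > 0 && !st$truncated) {
      st <- decoder_step(st, params, config, policy = policy)
    }
    labels <- predict_node_labels(st, params, config)
    fin <- .finalize_info(st, labels)
    rows[[s]] <- tibble::tibble(
      smiles = write_smiles(fin$molecule, keep_attachment = FALSE),
      n_linker = nl, steps = st$step, n_edges = nrow(st$edge_log),
      truncated = st$truncated, both_fragments = fin$both_fragments,
      molecule = list(fin$molecule)
    )
  }
  dplyr::bind_rows(rows)
}
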