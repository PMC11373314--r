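# Teacher forcing: derive the ground-truth edge-addition trajectory of a
# training example under the decoder's focus discipline, and score every
# decision (edge/stop and node labels) with masked cross-entropy.  All
# decision snapshots of a minibatch are packed into one block-diagonal
# graph so the re-encoder runs once per batch rather than once per step.

# breadth-first ordering of the linker atoms, rooted at the linker atom
# bonded to `anchor`, ties by ascending molecule index
.bfs_linker_order <- function(mol, linker_atoms, anchor) {
  b <- mol$bonds
  in_linker <- seq_len(n_atoms(mol)) %in% linker_atoms
  nb_of <- function(a) {
    sort(unique(c(b[b[, 1] == a, 2], b[b[, 2] == a, 1])))
  }
  root <- intersect(nb_of(anchor), linker_atoms)
  order_out <- integer(0)
  seen <- logical(n_atoms(mol))
  queue <- sort(root)
  seen[queue] <- TRUE
  while (length(queue) > 0) {
    x <- queue[1]; queue <- queue[-1]
    order_out <- c(order_out, x)
    nxt <- setdiff(intersect(nb_of(x), linker_atoms),
                   which(seen))
    nxt <- nxt[in_linker[nxt] & !seen[nxt]]
    if (length(nxt) > 0) {
      queue <- c(queue, sort(nxt))
      seen[nxt] <- TRUE
    }
  }
  # any linker atoms not reached (cannot happen for a connected middle
  # component, kept for safety) are appended in index order
  c(order_out, setdiff(linker_atoms, order_out))
}

# ground-truth action trajectory for one linker example
build_trajectory <- function(ex, config) {
  f1 <- ex$fragment_1; f2 <- ex$fragment_2
  n1 <- length(f1$elements); n2 <- length(f2$elements)
  nl <- length(ex$linker_atoms)
  n <- n1 + n2 + nl
  mol <- ex$molecule
  # canonical linker indexing: breadth-first from the atom attached to
  # fragment 1's anchor (ties by molecule index).  This aligns linker
  # indices - and hence the decoder's positional tags - with generation
  # order, so "connect to the lowest-index target first" becomes a
  # consistent, learnable policy instead of an arbitrary permutation.
  linker <- .bfs_linker_order(mol, ex$linker_atoms, ex$anchor1)
  state_of <- integer(n_atoms(mol))
  state_of[ex$frag1_atoms] <- seq_len(n1)
  state_of[ex$frag2_atoms] <- n1 + seq_len(n2)
  state_of[linker] <- n1 + n2 + seq_len(nl)
  true_elements <- character(n)
  true_elements[state_of] <- mol$elements
  frag_bonds <- rbind(
    f1$bonds,
    cbind(f2$bonds[, 1, drop = TRUE] + n1, f2$bonds[, 2, drop = TRUE] + n1,
          f2$bonds[, 3, drop = TRUE])
  )
  frag_bonds <- matrix(as.integer(frag_bonds), ncol = 3)
  # cross bonds: molecule bonds touching the linker, in state indices
  in_f1 <- seq_len(n_atoms(mol)) %in% ex$frag1_atoms
  in_f2 <- seq_len(n_atoms(mol)) %in% ex$frag2_atoms
  mb <- mol$bonds
  is_cross <- !((in_f1[mb[, 1]] & in_f1[mb[, 2]]) |
                  (in_f2[mb[, 1]] & in_f2[mb[, 2]]))
  cross <- mb[is_cross, , drop = FALSE]
  cross_state <- cbind(state_of[cross[, 1]], state_of[cross[, 2]],
                       cross[, 3])

  vt <- valence_table()
  elements_in <- c(f1$elements, f2$elements, rep(.UNLABELED, nl))
  budget <- integer(n)
  sums0 <- integer(n)
  if (nrow(frag_bonds) > 0) {
    for (k in seq_len(nrow(frag_bonds))) {
      sums0[frag_bonds[k, 1]] <- sums0[frag_bonds[k, 1]] + frag_bonds[k, 3]
      sums0[frag_bonds[k, 2]] <- sums0[frag_bonds[k, 2]] + frag_bonds[k, 3]
    }
  }
  fi <- seq_len(n1 + n2)
  budget[fi] <- vt[elements_in[fi]] - sums0[fi]
  budget[(n1 + n2 + 1):n] <- 4L
  if (any(budget < 0)) stop("molecule violates the valence table", call. = FALSE)

  a1 <- which(f1$attachment)
  a2 <- n1 + which(f2$attachment)
  queue <- c(a1, a2)
  seen <- rep(FALSE, n); seen[queue] <- TRUE
  bonds_now <- frag_bonds
  pending <- rep(TRUE, nrow(cross_state))
  added_order <- integer(0)   # indices into cross_state in addition order
  decisions <- list()

  mk_state <- function() {
    list(bonds = bonds_now, budget = budget, n = n)
  }
  while (length(queue) > 0) {
    u <- queue[1]
    repeat {
      inc <- which(pending &
                     (cross_state[, 1] == u | cross_state[, 2] == u))
      cand <- .candidates(mk_state(), u)
      d_all <- .dists_from(n, bonds_now, u)
      if (length(inc) == 0) {
        decisions[[length(decisions) + 1L]] <- list(
          k = length(added_order), u = u, v = cand$v, mask = cand$mask,
          d = d_all[cand$v], target_v = NA_integer_,
          target_order = NA_integer_)
        break
      }
      others <- ifelse(cross_state[inc, 1] == u, cross_state[inc, 2],
                       cross_state[inc, 1])
      pick <- inc[which.min(others)]     # lower-index targets first
      v <- others[which.min(others)]
      o <- cross_state[pick, 3]
      ci <- match(v, cand$v)
      if (is.na(ci) || !cand$mask[ci, o]) {
        stop("ground-truth edge is masked; inconsistent example",
             call. = FALSE)
      }
      decisions[[length(decisions) + 1L]] <- list(
        k = length(added_order), u = u, v = cand$v, mask = cand$mask,
        d = d_all[cand$v], target_v = v, target_order = o)
      bonds_now <- rbind(bonds_now, c(min(u, v), max(u, v), o))
      budget[u] <- budget[u] - o
      budget[v] <- budget[v] - o
      pending[pick] <- FALSE
      added_order <- c(added_order, pick)
      if (!seen[v]) { queue <- c(queue, v); seen[v] <- TRUE }
    }
    # stop: retire u, enqueue unseen neighbours in index order
    queue <- queue[-1]
    b <- bonds_now
    nb <- sort(unique(c(b[b[, 1] == u, 2], b[b[, 2] == u, 1])))
    nb <- nb[!seen[nb]]
    if (length(nb) > 0) { queue <- c(queue, nb); seen[nb] <- TRUE }
  }
  stopifnot(!any(pending))

  sums_final <- integer(n)
  for (k in seq_len(nrow(bonds_now))) {
    sums_final[bonds_now[k, 1]] <- sums_final[bonds_now[k, 1]] + bonds_now[k, 3]
    sums_final[bonds_now[k, 2]] <- sums_final[bonds_now[k, 2]] + bonds_now[k, 3]
  }
  vt_voc <- vt[config$vocab]
  linker_idx <- (n1 + n2 + 1):n
  label_mask <- t(vapply(linker_idx,
                         function(i) vt_voc >= sums_final[i],
                         logical(length(config$vocab))))
  label_target <- match(true_elements[linker_idx], config$vocab)

  mol_positions <- numeric(n_atoms(mol))
  mol_positions[linker] <- seq_len(nl) / 12
  list(n = n, n1 = n1, n2 = n2, nl = nl, mol_positions = mol_positions,
       elements_in = elements_in, true_elements = true_elements,
       attach = c(f1$attachment, f2$attachment, rep(FALSE, nl)),
       linker_flag = c(rep(FALSE, n1 + n2), rep(TRUE, nl)),
       pos_tag = c(rep(0, n1 + n2), seq_len(nl) / 12),
       frag_bonds = frag_bonds,
       cross_bonds = cross_state[added_order, , drop = FALSE],
       decisions = decisions,
       label_mask = label_mask, label_target = label_target,
       descriptor = ex$descriptor)
}

# pack trajectories into block tensors; returns constants reused across
# epochs (everything except z and dropout is fixed under teacher forcing)
pack_trajectories <- function(trajs, config) {
  nv <- length(config$vocab)
  graphs <- list(); snap_ex <- integer(0)
  dec_snap <- integer(0); dec_ex <- integer(0); dec_u <- integer(0)
  cand_dec <- integer(0); cand_v <- integer(0); cand_u <- integer(0)
  cand_d <- numeric(0)
  mask_rows <- list()
  target_row <- integer(0); target_order <- integer(0)
  lab_snap <- integer(0); lab_node <- integer(0); lab_ex <- integer(0)
  n_dec <- 0L
  for (e in seq_along(trajs)) {
    tr <- trajs[[e]]
    cross <- tr$cross_bonds
    # one snapshot per distinct partial graph (k cross bonds added);
    # decisions taken at the same graph share the snapshot and its
    # re-encoding
    snap_of_k <- integer(nrow(cross) + 1L)
    for (k in 0:nrow(cross)) {
      graphs[[length(graphs) + 1L]] <- list(
        n = tr$n,
        bonds = rbind(tr$frag_bonds, cross[seq_len(k), , drop = FALSE]))
      snap_ex <- c(snap_ex, e)
      snap_of_k[k + 1L] <- length(graphs)
    }
    for (d in seq_along(tr$decisions)) {
      dc <- tr$decisions[[d]]
      snap <- snap_of_k[dc$k + 1L]
      n_dec <- n_dec + 1L
      dec_snap <- c(dec_snap, snap); dec_ex <- c(dec_ex, e)
      dec_u <- c(dec_u, dc$u)        # local; offset applied later
      nc <- length(dc$v)
      if (nc > 0) {
        cand_dec <- c(cand_dec, rep(n_dec, nc))
        cand_v <- c(cand_v, dc$v + 0L)
        cand_u <- c(cand_u, rep(dc$u, nc))
        cand_d <- c(cand_d, dc$d)
        mask_rows[[length(mask_rows) + 1L]] <- dc$mask
      }
      if (is.na(dc$target_v)) {
        target_row <- c(target_row, NA_integer_)
        target_order <- c(target_order, NA_integer_)
      } else {
        pos <- length(cand_v) - nc + match(dc$target_v, dc$v)
        target_row <- c(target_row, pos)
        target_order <- c(target_order, dc$target_order)
      }
    }
    # node labels read from the final graph's snapshot
    lab_snap <- c(lab_snap, rep(snap_of_k[nrow(cross) + 1L], tr$nl))
    lab_node <- c(lab_node, (tr$n1 + tr$n2) + seq_len(tr$nl))
    lab_ex <- c(lab_ex, rep(e, tr$nl))
  }
  const <- graph_conv_constants(graphs)
  offs <- const$offsets
  # per-snapshot local->global row offsets
  dec_u_row <- offs[dec_snap] + dec_u
  # candidate rows: offset of the candidate's decision snapshot
  cand_row <- offs[dec_snap[cand_dec]] + cand_v
  cand_u_row <- offs[dec_snap[cand_dec]] + cand_u
  lab_row <- offs[lab_snap] + lab_node
  # constant node inputs: [label8, attachment, linker flag, pos tag]
  Xconst <- do.call(rbind, lapply(seq_along(graphs), function(s) {
    tr <- trajs[[snap_ex[s]]]
    cbind(.label_onehot(tr$elements_in, config$vocab),
          as.numeric(tr$attach), as.numeric(tr$linker_flag), tr$pos_tag)
  }))
  mask <- if (length(mask_rows) > 0) do.call(rbind, mask_rows) else
    matrix(FALSE, 0, 3)
  label_mask <- do.call(rbind, lapply(trajs, `[[`, "label_mask"))
  label_target <- unlist(lapply(trajs, `[[`, "label_target"))
  Dmat <- do.call(rbind, lapply(trajs, `[[`, "descriptor"))
  n_edge_dec <- sum(!is.na(target_row))
  list(const = const, n_examples = length(trajs),
       ex_of_node = snap_ex[const$node_graph], Xconst = Xconst,
       dec_snap = dec_snap, dec_ex = dec_ex, dec_u_row = dec_u_row,
       cand_dec = cand_dec, cand_row = cand_row, cand_u_row = cand_u_row,
       cand_d = cand_d, cand_ex = dec_ex[cand_dec],
       cand_snap = dec_snap[cand_dec], mask = mask,
       target_row = target_row, target_order = target_order,
       n_decisions = n_dec, n_edge_decisions = n_edge_dec,
       lab_row = lab_row, lab_ex = lab_ex,
       label_mask = label_mask, label_target = label_target,
       Dmat = Dmat)
}

# reconstruction loss over a packed batch given per-example latent rows Z
# (B x d_z, tape node during training).  Returns the summed edge/stop and
# label cross-entropies plus per-decision accuracy bookkeeping.
packed_recon_loss <- function(params, pack, Z, config, dropout = 0,
                              training = FALSE) {
  nv <- length(config$vocab)
  Zn <- ad_rows(Z, pack$ex_of_node)
  pos_col <- pack$Xconst[, nv + 4L]
  X <- ad_cbind(Zn, pack$Xconst,
                ad_mul(Zn, matrix(pos_col, length(pos_col), config$d_z)))
  H <- backbone_forward(params$dec, pack$const, X, config$backbone,
                        dropout = dropout, training = training)
  Ht <- ad_mm(pack$const$pool, H)
  lab_cols <- seq_len(nv + 1L)
  phi <- ad_cbind(
    ad_rows(H, pack$cand_u_row),
    pack$Xconst[pack$cand_u_row, lab_cols, drop = FALSE],
    ad_rows(H, pack$cand_row),
    pack$Xconst[pack$cand_row, lab_cols, drop = FALSE],
    matrix(pack$cand_d / 10, ncol = 1),
    ad_rows(Z, pack$cand_ex),
    ad_rows(Ht, pack$cand_snap),
    pack$Dmat[pack$cand_ex, , drop = FALSE]
  )
  psi <- ad_cbind(
    ad_rows(H, pack$dec_u_row),
    pack$Xconst[pack$dec_u_row, lab_cols, drop = FALSE],
    ad_rows(Z, pack$dec_ex),
    ad_rows(Ht, pack$dec_snap),
    pack$Dmat[pack$dec_ex, , drop = FALSE]
  )
  cand_logits <- .mlp_e_forward(params$mlp_e, phi)
  stop_logits <- .mlp_stop_forward(params$mlp_stop, psi)
  edge_nll <- ad_edge_nll(cand_logits, stop_logits, pack$cand_dec,
                          pack$mask, pack$target_row, pack$target_order,
                          pack$n_decisions)
  Hl <- ad_cbind(ad_rows(H, pack$lab_row), ad_rows(Z, pack$lab_ex),
                 matrix(pack$Xconst[pack$lab_row, nv + 4L], ncol = 1))
  lab_logits <- ad_add(
    ad_mm(ad_relu(ad_add(ad_mm(Hl, params$mlp_n$W1), params$mlp_n$b1)),
          params$mlp_n$W2), params$mlp_n$b2)
  lab_nll <- ad_masked_nll(lab_logits, pack$label_mask, pack$label_target)
  edge_correct <- if (ad_is(edge_nll)) edge_nll$extra else
    attr(edge_nll, "correct")
  lab_correct <- if (ad_is(lab_nll)) lab_nll$extra else
    attr(lab_nll, "correct")
  list(edge_nll = edge_nll, lab_nll = lab_nll,
       n_decisions = pack$n_decisions + length(pack$label_target),
       n_correct = sum(edge_correct) + sum(lab_correct))
}

#' Teacher-forced reconstruction loss of one example
#'
#' Derives the ground-truth edge-addition trajectory of the example under
#' the decoder's focus discipline (breadth-first from the two attachment
#' atoms, edges to lower-index targets first), conditions every decision on
#' the forced history, and sums the masked cross-entropies of each
#' edge/stop decision and of the linker node labels.  The latent `z` is
#' built from the fragment-pair and molecule encodings with a
#' reparameterized draw.
#'
#' @param example A `linker_example`.
#' @param params Model parameters.
#' @param config A [linker_config()].
#' @param eps Optional standard-normal draw (length `d_m`); drawn from the
#'   ambient RNG when `NULL`.
#' @return List with `loss` (summed cross-entropy), `accuracy`
#'   (fraction of decisions where the argmax matches the forced truth),
#'   and `n_decisions`.
#' @export
teacher_forced_recon_loss <- function(example, params, config, eps = NULL) {
  stopifnot(inherits(example, "linker_example"))
  enc_f <- encode_fragment_pair(example$fragment_1, example$fragment_2,
                                params, config)
  tr <- build_trajectory(example, config)
  enc_m <- encode(example$molecule, params, config, role = "molecule",
                  positions = tr$mol_positions)
  init <- make_initial_representation(enc_f$mu, enc_m, params, config,
                                      mode = "train", eps = eps)
  pack <- pack_trajectories(list(tr), config)
  res <- packed_recon_loss(params, pack, matrix(init$z, 1), config)
  loss <- as.vector(res$edge_nll) + as.vector(res$lab_nll)
  list(loss = loss, accuracy = res$n_correct / res$n_decisions,
       n_decisions = res$n_decisions)
}
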