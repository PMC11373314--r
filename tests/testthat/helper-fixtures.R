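# Shared lazily-built fixtures, memoized for the test process.

.fx <- new.env(parent = emptyenv())

fx_config <- function(backbone = "censnet") {
  key <- paste0("cfg_", backbone)
  if (is.null(.fx[[key]])) .fx[[key]] <- linker_config(backbone)
  .fx[[key]]
}

fx_params <- function(backbone = "censnet", seed = 11) {
  key <- paste0("par_", backbone, "_", seed)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- fraglinkr:::make_model_params(fx_config(backbone),
                                                seed = seed)
  }
  .fx[[key]]
}

# small toy dataset shared across files
fx_dataset <- function(n = 120, seed = 3) {
  key <- paste0("ds_", n, "_", seed)
  if (is.null(.fx[[key]])) .fx[[key]] <- generate_toy_dataset(n, seed = seed)
  .fx[[key]]
}

# random valid mol_graph over the vocabulary (for property tests)
fx_random_graph <- function(n_max = 12) {
  repeat {
    g <- tryCatch(
      fraglinkr:::.random_molecule(sample(2:n_max, 1),
                                   default_element_weights()),
      error = function(e) NULL)
    if (!is.null(g)) return(g)
  }
}

# random undirected simple graph as a bond list (all single bonds)
fx_random_topology <- function(n, p = 0.3) {
  bonds <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) bonds <- rbind(bonds, c(i, j, 1L))
    }
  }
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 3)
  bonds
}

# brute-force symmetric-normalized neighbour aggregation (GCN oracle)
gcn_oracle <- function(bonds, n, h, w) {
  A <- matrix(0, n, n)
  if (NROW(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      A[bonds[k, 1], bonds[k, 2]] <- 1
      A[bonds[k, 2], bonds[k, 1]] <- 1
    }
  }
  At <- A + diag(n)
  d <- rowSums(At)
  out <- matrix(0, n, ncol(w))
  hw <- h %*% w
  for (i in 1:n) {
    for (j in 1:n) {
      if (At[i, j] > 0) {
        out[i, ] <- out[i, ] + hw[j, ] / sqrt(d[i] * d[j])
      }
    }
  }
  out
}

# graph tensors for an abstract (all-carbon, unvalidated) topology
mk_graph_tensors <- function(n, bonds) {
  to_tensors(mol_graph(rep("C", n), bonds, validate = FALSE),
             validate = FALSE)
}

# map from the permuted graph's (sorted) edge order back to the original
# graph's edge indices: row k of gp$bonds corresponds to original edge
# fx_edge_map(...)[k]
fx_edge_map <- function(g, gp, perm) {
  if (nrow(g$bonds) == 0) return(integer(0))
  orig_key <- paste(pmin(perm[g$bonds[, 1]], perm[g$bonds[, 2]]),
                    pmax(perm[g$bonds[, 1]], perm[g$bonds[, 2]]))
  perm_key <- paste(gp$bonds[, 1], gp$bonds[, 2])
  match(perm_key, orig_key)
}

# relabel a mol_graph's atoms by a permutation (perm[i] = new index of i)
fx_permute_graph <- function(g, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  b <- g$bonds
  if (nrow(b) > 0) {
    b <- cbind(perm[b[, 1]], perm[b[, 2]], b[, 3])
  }
  mol_graph(g$elements[inv], b, attachment = g$attachment[inv],
            charges = g$charges[inv])
}
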