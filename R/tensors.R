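# Tensorization of molecular graphs for the graph-convolutional layers,
# including the line-graph structures that node-edge co-embedding needs.

#' Convert a molecular graph to dense tensors
#'
#' Produces the matrix form the encoders consume: one-hot node features,
#' per-order adjacency matrices, one-hot edge (bond order) features, the
#' line-graph adjacency (edges adjacent when they share exactly one
#' endpoint), and the node-edge incidence matrix.  Edge ordering follows the
#' graph's bond list, which is fixed as lexicographically sorted
#' (min index, max index) pairs.
#'
#' @param g A `mol_graph`.
#' @param validate Re-check the molecular-graph invariants first
#'   (default `TRUE`; disable for abstract test topologies).
#' @return An object of class `graph_tensors`: list with `node_features`
#'   (n x vocabulary), `node_adjacency` (list of three n x n matrices, one
#'   per bond order), `edge_features` (m x 3), `edge_adjacency` (m x m),
#'   `incidence` (n x m), and `bonds` (the m x 3 bond table).
#' @examples
#' t <- to_tensors(parse_smiles("CCC"))
#' t$edge_adjacency
#' @export
to_tensors <- function(g, validate = TRUE) {
  if (validate) validate_mol_graph(g)
  n <- length(g$elements)
  vocab <- element_vocabulary()
  x <- matrix(0, n, length(vocab), dimnames = list(NULL, vocab))
  x[cbind(seq_len(n), match(g$elements, vocab))] <- 1
  b <- g$bonds
  m <- nrow(b)
  adj <- lapply(1:3, function(o) matrix(0, n, n))
  xe <- matrix(0, m, 3)
  te <- matrix(0, n, m)
  if (m > 0) {
    for (k in seq_len(m)) {
      o <- b[k, "order"]
      adj[[o]][b[k, "i"], b[k, "j"]] <- 1
      adj[[o]][b[k, "j"], b[k, "i"]] <- 1
      xe[k, o] <- 1
      te[b[k, "i"], k] <- 1
      te[b[k, "j"], k] <- 1
    }
  }
  ea <- matrix(0, m, m)
  if (m > 1) {
    for (e in seq_len(m - 1)) {
      for (f in (e + 1):m) {
        shared <- length(intersect(b[e, 1:2], b[f, 1:2]))
        if (shared == 1) {
          ea[e, f] <- 1
          ea[f, e] <- 1
        }
      }
    }
  }
  structure(
    list(node_features = x, node_adjacency = adj, edge_features = xe,
         edge_adjacency = ea, incidence = te, bonds = b),
    class = "graph_tensors"
  )
}
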