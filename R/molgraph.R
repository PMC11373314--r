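#' Element vocabulary and valence table
#'
#' The package works over a fixed drug-like element vocabulary with implicit
#' hydrogens and neutral formal charges.  The valence table gives the maximum
#' bond-order sum allowed per element; it is used both to validate parsed
#' molecules and to mask infeasible actions during sequential decoding.
#'
#' @return `element_vocabulary()` returns a character vector of element
#'   symbols; `valence_table()` a named integer vector of maximum valences.
#' @export
element_vocabulary <- function() c("C", "N", "O", "F", "S", "Cl", "Br")

#' @rdname element_vocabulary
#' @export
valence_table <- function() {
  c(C = 4L, N = 3L, O = 2L, F = 1L, S = 2L, Cl = 1L, Br = 1L)
}

#' Construct a molecular graph
#'
#' A `mol_graph` is the package's universal molecule representation: a
#' labelled graph with per-atom element symbols and formal charges, typed
#' bonds (orders 1, 2, 3; aromatic systems are kekulized on input), and a
#' per-atom attachment flag marking fragment exit atoms (the atoms where a
#' cut bond was removed and a linker must connect).  Hydrogens are implicit
#' and never appear as nodes.  Atom indices are 1-based and contiguous.
#'
#' @param elements Character vector of element symbols (see
#'   [element_vocabulary()]).
#' @param bonds Integer matrix with columns `i`, `j`, `order` (one row per
#'   bond, `i != j`, at most one bond per atom pair, orders in 1:3).  May
#'   have zero rows.
#' @param attachment Logical vector marking attachment (exit) atoms.
#' @param charges Integer vector of formal charges (default all zero; only
#'   neutral atoms are supported by the default vocabulary).
#' @param validate Check the graph invariants (valence, duplicate bonds)?
#' @return An object of class `mol_graph`.
#' @examples
#' g <- mol_graph(c("C", "C", "O"), rbind(c(1, 2, 1), c(2, 3, 1)))
#' n_atoms(g)
#' @export
mol_graph <- function(elements, bonds = NULL, attachment = NULL,
                      charges = NULL, validate = TRUE) {
  elements <- as.character(elements)
  n <- length(elements)
  if (is.null(bonds) || NROW(bonds) == 0) {
    bonds <- matrix(integer(0), ncol = 3L)
  } else {
    bonds <- matrix(as.integer(as.matrix(bonds)), ncol = 3L)
  }
  colnames(bonds) <- c("i", "j", "order")
  # normalize: i < j, lexicographic edge order
  if (nrow(bonds) > 0) {
    ij <- t(apply(bonds[, 1:2, drop = FALSE], 1L, sort))
    bonds <- cbind(ij, bonds[, 3L])
    colnames(bonds) <- c("i", "j", "order")
    bonds <- bonds[order(bonds[, 1L], bonds[, 2L]), , drop = FALSE]
  }
  if (is.null(attachment)) attachment <- rep(FALSE, n)
  if (is.null(charges)) charges <- rep(0L, n)
  g <- structure(
    list(elements = elements, bonds = bonds,
         attachment = as.logical(attachment), charges = as.integer(charges)),
    class = "mol_graph"
  )
  if (validate) validate_mol_graph(g)
  g
}

#' Validate molecular-graph invariants
#'
#' Checks the `mol_graph` contract: known elements, no self-loops, no
#' duplicate bonds, bond orders in 1:3, indices in range, and every atom's
#' bond-order sum within its element's maximum valence.
#'
#' @param g A `mol_graph`.
#' @return `g`, invisibly; errors on violation.
#' @export
validate_mol_graph <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  n <- length(g$elements)
  vt <- valence_table()
  bad <- setdiff(unique(g$elements), names(vt))
  if (length(bad) > 0) {
    stop("element(s) outside vocabulary: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(g$attachment) != n || length(g$charges) != n) {
    stop("attachment/charge vectors must match atom count", call. = FALSE)
  }
  b <- g$bonds
  if (nrow(b) > 0) {
    if (any(b[, "i"] < 1L) || any(b[, "j"] > n)) {
      stop("bond index out of range", call. = FALSE)
    }
    if (any(b[, "i"] == b[, "j"])) stop("self-loop bond", call. = FALSE)
    if (anyDuplicated(b[, 1:2, drop = FALSE])) {
      stop("duplicate bond between an atom pair", call. = FALSE)
    }
    if (any(!b[, "order"] %in% 1:3)) stop("bond order outside 1:3", call. = FALSE)
  }
  vs <- bond_order_sums(g)
  over <- vs > vt[g$elements]
  if (any(over)) {
    stop("valence exceeded at atom(s) ", paste(which(over), collapse = ", "),
         call. = FALSE)
  }
  invisible(g)
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", length(x$elements), " atoms, ", nrow(x$bonds),
      " bonds", if (any(x$attachment)) paste0(
        ", attachment at ", paste(which(x$attachment), collapse = ",")),
      "\n", sep = "")
  cat("  ", write_smiles(x, keep_attachment = TRUE), "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a molecular graph
#' @param g A `mol_graph`.
#' @return Integer atom count.
#' @export
n_atoms <- function(g) length(g$elements)

#' Per-atom bond-order sums
#' @param g A `mol_graph`.
#' @return Integer vector: the sum of bond orders incident to each atom.
#' @export
bond_order_sums <- function(g) {
  n <- length(g$elements)
  vs <- integer(n)
  b <- g$bonds
  if (nrow(b) > 0) {
    for (k in seq_len(nrow(b))) {
      vs[b[k, 1L]] <- vs[b[k, 1L]] + b[k, 3L]
      vs[b[k, 2L]] <- vs[b[k, 2L]] + b[k, 3L]
    }
  }
  vs
}

#' Remaining valence of an atom
#'
#' The number of additional bond-order units the atom can accept:
#' the element's maximum valence minus the current bond-order sum, minus the
#' absolute formal charge (charges are zero under the default vocabulary).
#' During decoding this is the valence budget that masks infeasible edges.
#'
#' @param g A `mol_graph`.
#' @param atom Atom index (1-based).
#' @return Non-negative integer for any valid graph.
#' @examples
#' g <- parse_smiles("N")
#' valence_remaining(g, 1) # 3
#' @export
valence_remaining <- function(g, atom) {
  n <- length(g$elements)
  if (!is.numeric(atom) || atom < 1 || atom > n) {
    stop("atom index out of range: ", atom, call. = FALSE)
  }
  atom <- as.integer(atom)
  vt <- valence_table()
  as.integer(vt[g$elements[atom]] - bond_order_sums(g)[atom] -
               abs(g$charges[atom]))
}

#' Convert a molecular graph to an igraph object
#'
#' Vertices carry the element symbol (`element`) and bonds the order
#' (`order`), so colored isomorphism checks see full chemistry.
#'
#' @param g A `mol_graph`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph_mol <- function(g) {
  ig <- igraph::make_empty_graph(n = length(g$elements), directed = FALSE)
  igraph::V(ig)$element <- g$elements
  if (nrow(g$bonds) > 0) {
    ig <- igraph::add_edges(ig, t(g$bonds[, 1:2, drop = FALSE]))
    igraph::E(ig)$order <- g$bonds[, "order"]
  }
  ig
}

.element_color <- function(els) as.integer(factor(els, levels = element_vocabulary()))

#' Test two molecular graphs for isomorphism
#'
#' Colored (element + bond order) graph isomorphism via VF2.
#'
#' @param g1,g2 `mol_graph` objects.
#' @return Logical.
#' @export
graphs_isomorphic <- function(g1, g2) {
  if (length(g1$elements) != length(g2$elements)) return(FALSE)
  if (nrow(g1$bonds) != nrow(g2$bonds)) return(FALSE)
  i1 <- as_igraph_mol(g1); i2 <- as_igraph_mol(g2)
  igraph::isomorphic(
    i1, i2, method = "vf2",
    vertex.color1 = .element_color(g1$elements),
    vertex.color2 = .element_color(g2$elements),
    edge.color1 = if (nrow(g1$bonds)) g1$bonds[, "order"] else NULL,
    edge.color2 = if (nrow(g2$bonds)) g2$bonds[, "order"] else NULL
  )
}

#' Test whether one graph contains another as a substructure
#'
#' Colored subgraph monomorphism (`pattern` inside `target`): every pattern
#' atom maps to a distinct target atom of the same element and every pattern
#' bond to a target bond of the same order.  Extra target bonds between
#' mapped atoms are allowed, matching the usual chemistry substructure
#' convention.
#'
#' @param target,pattern `mol_graph` objects.
#' @return Logical.
#' @export
has_subgraph <- function(target, pattern) {
  if (length(pattern$elements) > length(target$elements)) return(FALSE)
  # igraph passes (pattern, target) through to vf2 as (graph1 = target,
  # graph2 = pattern), so the color1 arguments describe the target
  args <- list(
    as_igraph_mol(pattern), as_igraph_mol(target), method = "vf2",
    vertex.color1 = .element_color(target$elements),
    vertex.color2 = .element_color(pattern$elements)
  )
  # edge colors only when both graphs have edges (igraph rejects
  # one-sided coloring); an edgeless pattern matches on elements alone
  if (nrow(pattern$bonds) > 0 && nrow(target$bonds) > 0) {
    args$edge.color1 <- target$bonds[, "order"]
    args$edge.color2 <- pattern$bonds[, "order"]
  }
  do.call(igraph::subgraph_isomorphic, args)
}

#' Connected components of a molecular graph
#' @param g A `mol_graph`.
#' @param drop_bonds Optional integer vector of bond rows to ignore.
#' @return Integer membership vector (component id per atom).
#' @keywords internal
mol_components <- function(g, drop_bonds = NULL) {
  b <- g$bonds
  if (!is.null(drop_bonds) && length(drop_bonds) > 0) {
    b <- b[-drop_bonds, , drop = FALSE]
  }
  .components_fast(length(g$elements), b)
}

# union-find connected components; edges is a matrix with columns i, j
.components_fast <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (NROW(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      ri <- find(edges[k, 1L]); rj <- find(edges[k, 2L])
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  as.integer(factor(roots, levels = unique(roots)))
}

#' Extract the induced subgraph on a set of atoms
#' @param g A `mol_graph`.
#' @param atoms Integer atom indices to keep.
#' @param attachment Optional logical vector (length of `atoms`) overriding
#'   the attachment flags of the extracted graph.
#' @return A `mol_graph` on the selected atoms (indices remapped, order of
#'   `atoms` preserved).
#' @export
induced_mol_subgraph <- function(g, atoms, attachment = NULL) {
  atoms <- as.integer(atoms)
  remap <- integer(length(g$elements))
  remap[atoms] <- seq_along(atoms)
  b <- g$bonds
  keep <- b[, "i"] %in% atoms & b[, "j"] %in% atoms
  b <- b[keep, , drop = FALSE]
  if (nrow(b) > 0) {
    b[, "i"] <- remap[b[, "i"]]
    b[, "j"] <- remap[b[, "j"]]
  }
  mol_graph(g$elements[atoms], b,
            attachment = if (is.null(attachment)) g$attachment[atoms] else attachment,
            charges = g$charges[atoms])
}
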