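# Double-cut fragmentation of whole molecules into
# (fragment 1, linker, fragment 2) training examples.

#' Construct a linker example
#'
#' A `linker_example` records one (fragment pair, molecule) training or
#' generation record: the two fragments (each with exactly one attachment
#' atom), the full molecule, the set of molecule atoms forming the linker,
#' the index maps from fragment atoms to molecule atoms, and an optional
#' two-number 3D descriptor of the fragment pair (attachment distance in
#' angstroms, exit-vector angle in radians; zeros when no conformer is
#' available).
#'
#' @param fragment_1,fragment_2 `mol_graph` fragments with one attachment
#'   atom each.
#' @param molecule The full `mol_graph`.
#' @param linker_atoms Integer indices (into `molecule`) of linker atoms.
#' @param frag1_atoms,frag2_atoms Integer indices (into `molecule`) of the
#'   atoms of each fragment, ordered to match the fragment graphs.
#' @param anchor1,anchor2 Molecule indices of the two attachment atoms.
#' @param descriptor Numeric length-2 vector, default zeros.
#' @return An object of class `linker_example`.
#' @export
linker_example <- function(fragment_1, fragment_2, molecule, linker_atoms,
                           frag1_atoms, frag2_atoms, anchor1, anchor2,
                           descriptor = c(0, 0)) {
  ex <- structure(
    list(fragment_1 = fragment_1, fragment_2 = fragment_2,
         molecule = molecule, linker_atoms = as.integer(linker_atoms),
         frag1_atoms = as.integer(frag1_atoms),
         frag2_atoms = as.integer(frag2_atoms),
         anchor1 = as.integer(anchor1), anchor2 = as.integer(anchor2),
         descriptor = as.numeric(descriptor)),
    class = "linker_example"
  )
  ex
}

#' @export
print.linker_example <- function(x, ...) {
  cat("<linker_example> linker size ", length(x$linker_atoms), "\n",
      "  fragment_1: ", write_smiles(x$fragment_1), "\n",
      "  fragment_2: ", write_smiles(x$fragment_2), "\n",
      "  molecule:   ", write_smiles(x$molecule), "\n", sep = "")
  invisible(x)
}

#' Validate a linker example
#'
#' Checks the contract: linker size within 3-12 atoms, the fragment and
#' linker atoms partition the molecule, removing the linker atoms leaves
#' exactly two components isomorphic to the two fragments, and each
#' fragment carries exactly one attachment atom.
#'
#' @param ex A `linker_example`.
#' @return `TRUE` (errors otherwise).
#' @export
validate_linker_example <- function(ex) {
  stopifnot(inherits(ex, "linker_example"))
  nl <- length(ex$linker_atoms)
  if (nl < 3 || nl > 12) stop("linker size outside 3-12", call. = FALSE)
  n <- n_atoms(ex$molecule)
  all_atoms <- sort(c(ex$linker_atoms, ex$frag1_atoms, ex$frag2_atoms))
  if (!identical(all_atoms, seq_len(n))) {
    stop("fragment and linker atoms do not partition the molecule",
         call. = FALSE)
  }
  if (sum(ex$fragment_1$attachment) != 1 || sum(ex$fragment_2$attachment) != 1) {
    stop("each fragment must have exactly one attachment atom", call. = FALSE)
  }
  rest <- setdiff(seq_len(n), ex$linker_atoms)
  sub <- induced_mol_subgraph(ex$molecule, rest)
  comp <- mol_components(sub)
  if (max(comp) != 2) {
    stop("removing the linker must leave exactly two components",
         call. = FALSE)
  }
  g1 <- induced_mol_subgraph(sub, which(comp == 1))
  g2 <- induced_mol_subgraph(sub, which(comp == 2))
  ok <- (graphs_isomorphic(g1, ex$fragment_1) && graphs_isomorphic(g2, ex$fragment_2)) ||
    (graphs_isomorphic(g1, ex$fragment_2) && graphs_isomorphic(g2, ex$fragment_1))
  if (!ok) stop("components do not match the fragments", call. = FALSE)
  TRUE
}

#' Enumerate fragment-pair/linker decompositions of a molecule
#'
#' Performs every double cut of two distinct acyclic (bridge) single bonds
#' whose removal yields exactly three connected components: two non-empty
#' terminal fragments and a middle linker of 3-12 atoms.  Ordered cut pairs
#' are enumerated (so each decomposition appears with both fragment
#' orderings) and deduplicated by the canonical SMILES of the
#' (fragment 1, fragment 2, molecule) triple.
#'
#' @param g A `mol_graph` (attachment flags are ignored).
#' @param min_linker,max_linker Linker size bounds (defaults 3 and 12).
#' @return A list of `linker_example` objects (possibly empty).
#' @examples
#' exs <- fragment_molecule(parse_smiles("CCCCCCCC"))
#' length(exs)
#' @export
fragment_molecule <- function(g, min_linker = 3L, max_linker = 12L) {
  validate_mol_graph(g)
  b <- g$bonds
  if (nrow(b) < 2) return(list())
  ig <- as_igraph_mol(g)
  bridge_ids <- igraph::bridges(ig)
  cuttable <- intersect(as.integer(bridge_ids), which(b[, "order"] == 1L))
  out <- list()
  make_ex <- function(comp, mid, a1_out, a2_out) {
    lk <- which(comp == mid)
    f1_atoms <- which(comp == comp[a1_out])
    f2_atoms <- which(comp == comp[a2_out])
    f1 <- induced_mol_subgraph(g, f1_atoms, attachment = f1_atoms == a1_out)
    f2 <- induced_mol_subgraph(g, f2_atoms, attachment = f2_atoms == a2_out)
    linker_example(f1, f2, g, lk, f1_atoms, f2_atoms, a1_out, a2_out)
  }
  if (length(cuttable) >= 2) {
    pairs <- utils::combn(cuttable, 2)
    for (p in seq_len(ncol(pairs))) {
      c1 <- pairs[1, p]; c2 <- pairs[2, p]
      comp <- mol_components(g, drop_bonds = c(c1, c2))
      if (max(comp) != 3) next
      e1 <- b[c1, 1:2]; e2 <- b[c2, 1:2]
      # the middle component touches one endpoint of each cut bond
      mid <- intersect(comp[e1], comp[e2])
      if (length(mid) != 1) next
      a1_out <- e1[comp[e1] != mid]  # fragment-side endpoint (anchor)
      a2_out <- e2[comp[e2] != mid]
      if (length(a1_out) != 1 || length(a2_out) != 1) next
      lk_n <- sum(comp == mid)
      if (lk_n < min_linker || lk_n > max_linker) next
      if (sum(comp == comp[a1_out]) == 0 || sum(comp == comp[a2_out]) == 0) next
      # both fragment orderings of the same double cut
      out[[length(out) + 1L]] <- make_ex(comp, mid, a1_out, a2_out)
      out[[length(out) + 1L]] <- make_ex(comp, mid, a2_out, a1_out)
    }
  }
  if (length(out) > 1) {
    # deduplicate by canonical SMILES of the (fragment_1, fragment_2,
    # molecule) triple, in one batched conversion
    f1s <- write_smiles_batch(lapply(out, `[[`, "fragment_1"))
    f2s <- write_smiles_batch(lapply(out, `[[`, "fragment_2"))
    ms <- write_smiles(g, keep_attachment = FALSE)
    keys <- paste(f1s, f2s, ms, sep = "|")
    out <- out[!duplicated(keys)]
  }
  out
}
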