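# Synthetic fragment-linker data: random valence-respecting molecules,
# double-cut decompositions, and a deterministic surrogate activity oracle.
# Stands in for curated training extracts so the whole pipeline is
# exercisable without downloads.

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Default element sampling weights for the toy generator
#'
#' Biased towards carbon with enough nitrogen/oxygen that the surrogate
#' activity labels (a heteroatom-fraction score) straddle the pIC50 = 6
#' decision threshold, so latent-space attribute classifiers see both
#' classes.
#'
#' @return Named numeric vector of probabilities summing to 1.
#' @export
default_element_weights <- function() {
  c(C = 0.45, N = 0.25, O = 0.25, F = 0.03, S = 0.015, Cl = 0.004,
    Br = 0.001)
}

# Random valence-respecting molecule: a random tree grown by budgeted
# attachment plus occasional 5/6-ring closures.  Heteroatom pairing
# follows drug-like practice: N may bond N or O (pyrazole/isoxazole-like
# motifs), but O-O (peroxides) and S/halogen-heteroatom bonds are not
# grown, so those elements attach to carbon (or nitrogen) only.
.random_molecule <- function(n_heavy, element_weights,
                             ring_prob = 0.2) {
  vt <- valence_table()
  els <- names(element_weights)
  elements <- character(n_heavy)
  budget <- integer(n_heavy)
  elements[1] <- "C"
  budget[1] <- vt["C"]
  bonds <- matrix(integer(0), ncol = 3)
  for (k in seq_len(n_heavy)[-1]) {
    open <- which(budget[seq_len(k - 1)] > 0)
    if (length(open) == 0) break
    u <- if (length(open) == 1) open else sample(open, 1)
    el <- if (elements[u] == "C") {
      sample(els, 1, prob = element_weights)
    } else if (elements[u] == "N") {
      ok <- els %in% c("C", "N", "O")
      sample(els[ok], 1, prob = element_weights[ok])
    } else {
      "C"
    }
    max_o <- min(budget[u], vt[el], 3L)
    ow <- c(0.85, 0.13, 0.02)[seq_len(max_o)]
    o <- sample.int(max_o, 1, prob = ow)
    elements[k] <- el
    budget[k] <- vt[el] - o
    budget[u] <- budget[u] - o
    bonds <- rbind(bonds, c(u, k, o))
  }
  elements <- elements[nzchar(elements)]
  n <- length(elements)
  budget <- budget[seq_len(n)]
  # ring closures between atoms at tree distance 4 or 5 (5/6-membered rings)
  g <- mol_graph(elements, bonds, validate = FALSE)
  d <- igraph::distances(as_igraph_mol(g))
  cand <- which(d >= 4 & d <= 5 & upper.tri(d), arr.ind = TRUE)
  if (nrow(cand) > 0) {
    # ring closures obey the same heteroatom pairing rules
    pair_ok <- function(a, b) {
      ea <- elements[a]; eb <- elements[b]
      ea == "C" || eb == "C" ||
        (ea == "N" && eb %in% c("N", "O")) ||
        (eb == "N" && ea %in% c("N", "O"))
    }
    keep <- vapply(seq_len(nrow(cand)),
                   function(r) pair_ok(cand[r, 1], cand[r, 2]), TRUE)
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(cand) > 0) {
    cand <- cand[budget[cand[, 1]] > 0 & budget[cand[, 2]] > 0, , drop = FALSE]
    while (nrow(cand) > 0 && stats::runif(1) < ring_prob) {
      r <- if (nrow(cand) == 1) 1 else sample.int(nrow(cand), 1)
      u <- cand[r, 1]; v <- cand[r, 2]
      bonds <- rbind(bonds, c(u, v, 1L))
      budget[u] <- budget[u] - 1L
      budget[v] <- budget[v] - 1L
      cand <- cand[budget[cand[, 1]] > 0 & budget[cand[, 2]] > 0 &
                     !(cand[, 1] == u & cand[, 2] == v), , drop = FALSE]
    }
  }
  mol_graph(elements, bonds)
}

#' Surrogate activity oracle
#'
#' A deterministic pseudo-pIC50 used in place of measured binding
#' affinities: `4 + 4 * (number of N and O atoms) / (number of heavy
#' atoms)`, bounded in \[4, 8\] and invariant under graph isomorphism.  It
#' gives latent-space classifiers a real (composition-driven) signal to
#' learn while remaining exactly computable for evaluation.
#'
#' @param g A `mol_graph`, or a SMILES string.
#' @return Numeric scalar in \[4, 8\].
#' @examples
#' surrogate_activity("CCCC") # 4
#' surrogate_activity("CCO")  # 4 + 4/3
#' @export
surrogate_activity <- function(g) {
  if (is.character(g)) g <- parse_smiles(g)
  stopifnot(inherits(g, "mol_graph"))
  n <- length(g$elements)
  if (n == 0) stop("empty graph", call. = FALSE)
  4 + 4 * sum(g$elements %in% c("N", "O")) / n
}

#' Generate a synthetic fragment-linker dataset
#'
#' Builds random valence-respecting molecules (random trees over the element
#' vocabulary with occasional 5/6-ring closures), decomposes each with
#' [fragment_molecule()], samples one decomposition per molecule, and labels
#' it with the [surrogate_activity()] oracle.  Every example satisfies the
#' linker-size (3-12 atoms) and valence invariants by construction, and the
#' same seed reproduces the identical dataset.
#'
#' @param n_examples Number of examples to produce.
#' @param seed Integer seed.
#' @param max_heavy_atoms Maximum heavy atoms per molecule (default 20).
#' @param element_weights Named element sampling probabilities
#'   (default [default_element_weights()]); must sum to 1.
#' @param ring_prob Per-opportunity ring closure probability (default 0.2).
#' @return A tibble with columns `fragment_1_smiles`, `fragment_2_smiles`,
#'   `molecule_smiles`, `dist`, `angle`, `activity`, and a list-column
#'   `example` of `linker_example` objects.
#' @examples
#' \donttest{
#' ds <- generate_toy_dataset(10, seed = 1)
#' ds$molecule_smiles
#' }
#' @export
generate_toy_dataset <- function(n_examples, seed = 0,
                                 max_heavy_atoms = 20,
                                 element_weights = default_element_weights(),
                                 ring_prob = 0.2) {
  if (!is.numeric(n_examples) || n_examples < 1) {
    stop("n_examples must be >= 1", call. = FALSE)
  }
  if (max_heavy_atoms < 5) {
    stop("max_heavy_atoms < 5 cannot host a 3-atom linker plus two fragments",
         call. = FALSE)
  }
  if (abs(sum(element_weights) - 1) > 1e-8) {
    stop("element_weights must sum to 1", call. = FALSE)
  }
  bad <- setdiff(names(element_weights), element_vocabulary())
  if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  .with_seed(seed, {
    examples <- vector("list", n_examples)
    got <- 0L
    tries <- 0L
    while (got < n_examples) {
      tries <- tries + 1L
      if (tries > 200L * n_examples) {
        stop("could not generate enough decomposable molecules", call. = FALSE)
      }
      nh <- sample(8:max_heavy_atoms, 1)
      g <- tryCatch(.random_molecule(nh, element_weights, ring_prob),
                    error = function(e) NULL)
      if (is.null(g)) next
      exs <- fragment_molecule(g)
      if (length(exs) == 0) next
      ex <- exs[[if (length(exs) == 1) 1 else sample.int(length(exs), 1)]]
      got <- got + 1L
      examples[[got]] <- ex
    }
    tibble::tibble(
      fragment_1_smiles = write_smiles_batch(lapply(examples, `[[`, "fragment_1")),
      fragment_2_smiles = write_smiles_batch(lapply(examples, `[[`, "fragment_2")),
      molecule_smiles = write_smiles_batch(lapply(examples, `[[`, "molecule"),
                                           keep_attachment = FALSE),
      dist = vapply(examples, function(e) e$descriptor[1], 0),
      angle = vapply(examples, function(e) e$descriptor[2], 0),
      activity = vapply(examples, function(e) surrogate_activity(e$molecule), 0),
      example = examples
    )
  })
}

#' Write / read a linker dataset as CSV
#'
#' The on-disk format is the plain CSV schema `fragment_1_smiles,
#' fragment_2_smiles, molecule_smiles, dist, angle, activity`.  Reading
#' reconstructs the `example` list-column by re-deriving the matching
#' double-cut decomposition of each molecule.
#'
#' @param dataset A dataset tibble (see [generate_toy_dataset()]).
#' @param path File path.
#' @return `write_linker_dataset()` returns `path` invisibly;
#'   `read_linker_dataset()` returns the dataset tibble.
#' @export
write_linker_dataset <- function(dataset, path) {
  df <- dataset[, c("fragment_1_smiles", "fragment_2_smiles",
                    "molecule_smiles", "dist", "angle", "activity")]
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_linker_dataset
#' @export
read_linker_dataset <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("fragment_1_smiles", "fragment_2_smiles", "molecule_smiles")
  if (!all(need %in% names(df))) {
    stop("dataset must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$dist)) df$dist <- 0
  if (is.null(df$angle)) df$angle <- 0
  df$example <- purrr::pmap(
    list(df$fragment_1_smiles, df$fragment_2_smiles, df$molecule_smiles,
         df$dist, df$angle),
    function(f1, f2, m, d, a) {
      ex <- match_linker_example(f1, f2, m)
      ex$descriptor <- c(d, a)
      ex
    }
  )
  if (is.null(df$activity)) {
    df$activity <- vapply(df$example,
                          function(e) surrogate_activity(e$molecule), 0)
  }
  tibble::as_tibble(df)
}

#' Recover the linker decomposition matching a fragment pair
#'
#' Given fragment and molecule SMILES (fragments with `*` attachment
#' markers), finds the double-cut decomposition of the molecule whose
#' fragments match the given pair, in order.
#'
#' @param fragment_1_smiles,fragment_2_smiles,molecule_smiles SMILES strings.
#' @return A `linker_example`.
#' @export
match_linker_example <- function(fragment_1_smiles, fragment_2_smiles,
                                 molecule_smiles) {
  mol <- parse_smiles(molecule_smiles)
  want1 <- write_smiles(parse_smiles(fragment_1_smiles))
  want2 <- write_smiles(parse_smiles(fragment_2_smiles))
  for (ex in fragment_molecule(mol)) {
    if (identical(write_smiles(ex$fragment_1), want1) &&
        identical(write_smiles(ex$fragment_2), want2)) {
      return(ex)
    }
  }
  stop("no double-cut decomposition of '", molecule_smiles,
       "' matches the given fragments", call. = FALSE)
}
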