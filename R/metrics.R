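# Generative-molecule evaluation: structural usefulness (validity,
# uniqueness, novelty) and chemical usefulness (synthetic accessibility,
# ring aromaticity, PAINS), plus the multi-property pass-rate protocol.

#' Validity of a generated molecule set
#'
#' A generated molecule counts as valid when its SMILES parses, the graph
#' respects the valence table, and both input fragments are contained as
#' substructures (the fragment-linking convention: an output that lost a
#' fragment is not a valid linking of the pair).
#'
#' @param generated Character vector of SMILES.
#' @param fragment_1,fragment_2 Fragment SMILES (with `*` markers) or
#'   `mol_graph`s.
#' @return List with `fraction`, the logical per-molecule vector `valid`,
#'   and `valid_smiles`.
#' @export
validity <- function(generated, fragment_1, fragment_2) {
  if (inherits(fragment_1, "mol_graph")) fragment_1 <- write_smiles(fragment_1)
  if (inherits(fragment_2, "mol_graph")) fragment_2 <- write_smiles(fragment_2)
  n <- length(generated)
  if (n == 0) return(list(fraction = NaN, valid = logical(0),
                          valid_smiles = character(0)))
  parse_ok <- vapply(generated, function(s) {
    g <- tryCatch(parse_smiles(s), error = function(e) NULL)
    !is.null(g)
  }, logical(1), USE.NAMES = FALSE)
  has <- rep(FALSE, n)
  if (any(parse_ok)) {
    p <- chem_properties(generated[parse_ok], fragment_1, fragment_2)
    has[parse_ok] <- p$parsed & p$has_frag1 & p$has_frag2
  }
  valid <- parse_ok & has
  list(fraction = mean(valid), valid = valid,
       valid_smiles = generated[valid])
}

#' Uniqueness of a valid molecule set
#'
#' Number of distinct canonical SMILES over the number of valid molecules.
#'
#' @param valid Character vector of SMILES (the valid subset).
#' @return Fraction in (0, 1].
#' @export
uniqueness <- function(valid) {
  if (length(valid) == 0) stop("empty molecule set", call. = FALSE)
  can <- canonical_smiles(valid)
  length(unique(can[!is.na(can)])) / length(valid)
}

#' Novelty of a valid molecule set
#'
#' Fraction of the distinct valid molecules that do not appear in the
#' training set (both sides canonicalized).
#'
#' @param valid Character vector of SMILES (the valid subset).
#' @param training_set Character vector of training SMILES.
#' @return Fraction in \[0, 1\].
#' @export
novelty <- function(valid, training_set) {
  if (length(valid) == 0) stop("empty molecule set", call. = FALSE)
  if (length(training_set) == 0) {
    warning("empty training set: everything is novel")
    return(1)
  }
  can <- unique(canonical_smiles(valid))
  can <- can[!is.na(can)]
  ref <- canonical_smiles(training_set)
  mean(!can %in% ref)
}

#' Property pass rates under thresholds
#'
#' The multi-property protocol: for a molecule set, the fraction passing
#' each single condition (QED above, SA below, activity above their
#' thresholds) and the conjunction of all three.
#'
#' @param smiles Character vector of SMILES.
#' @param thresholds Named list, default `list(qed = 0.6, sa = 3,
#'   pic50 = 6)`.
#' @param activity_fn Function mapping a SMILES string to an activity
#'   (default [surrogate_activity()]).
#' @return A tibble with columns `condition` and `pass_rate`.
#' @export
pass_rates <- function(smiles,
                       thresholds = list(qed = 0.6, sa = 3, pic50 = 6),
                       activity_fn = surrogate_activity) {
  if (length(smiles) == 0) stop("empty molecule set", call. = FALSE)
  p <- chem_properties(smiles)
  act <- vapply(smiles, function(s) {
    tryCatch(activity_fn(s), error = function(e) NA_real_)
  }, numeric(1), USE.NAMES = FALSE)
  q <- p$parsed & !is.na(p$qed) & p$qed > thresholds$qed
  s <- p$parsed & !is.na(p$sa) & p$sa < thresholds$sa
  a <- !is.na(act) & act > thresholds$pic50
  tibble::tibble(
    condition = c(sprintf("qed>%g", thresholds$qed),
                  sprintf("sa<%g", thresholds$sa),
                  sprintf("pic50>%g", thresholds$pic50),
                  "conjunction"),
    pass_rate = c(mean(q), mean(s), mean(a), mean(q & s & a))
  )
}

#' Evaluate a generated molecule set
#'
#' Runs the six-metric evaluation suite: validity (parse + valence +
#' fragment containment), uniqueness and novelty among the valid set, and
#' the chemical filters (SA < 3, ring aromaticity, PAINS) as fractions of
#' the valid set.  Metrics are invariant to the input order.
#'
#' @param generated Character vector of SMILES (or tibble from
#'   [generate_linkers()]).
#' @param fragment_1,fragment_2 The input fragments (SMILES or
#'   `mol_graph`).
#' @param training_set Character vector of training SMILES for novelty
#'   (empty: novelty is reported as `NA`).
#' @param sa_threshold SA pass threshold (default 3).
#' @return A one-row tibble of class `linker_eval` with columns
#'   `validity`, `uniqueness`, `novelty`, `sa_pass`, `aromatic_ring_pass`,
#'   `pains_pass`, `n_generated`, `n_valid`; the per-molecule table is in
#'   `attr(, "molecules")`.
#' @export
evaluate_molecules <- function(generated, fragment_1, fragment_2,
                               training_set = character(0),
                               sa_threshold = 3) {
  if (is.data.frame(generated)) generated <- generated$smiles
  val <- validity(generated, fragment_1, fragment_2)
  vs <- val$valid_smiles
  uni <- if (length(vs) > 0) uniqueness(vs) else NA_real_
  nov <- if (length(vs) > 0 && length(training_set) > 0) {
    novelty(vs, training_set)
  } else {
    NA_real_
  }
  if (length(vs) > 0) {
    p <- chem_properties(vs)
    sa_pass <- mean(p$sa < sa_threshold, na.rm = TRUE)
    arom <- mean(p$arom_ring_pass, na.rm = TRUE)
    pains <- mean(p$pains_pass, na.rm = TRUE)
    per_mol <- p
  } else {
    sa_pass <- arom <- pains <- NA_real_
    per_mol <- tibble::tibble()
  }
  out <- tibble::tibble(
    validity = val$fraction, uniqueness = uni, novelty = nov,
    sa_pass = sa_pass, aromatic_ring_pass = arom, pains_pass = pains,
    n_generated = length(generated), n_valid = length(vs)
  )
  attr(out, "molecules") <- per_mol
  class(out) <- c("linker_eval", class(out))
  out
}
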