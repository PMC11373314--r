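# Subprocess bridge to the RDKit property oracle (QED, Ertl-Schuffenhauer
# synthetic accessibility, PAINS catalogue, ring aromaticity, substructure
# containment).  Batched: one interpreter start per call, so callers should
# pass molecule sets, not single molecules.

.bridge_script <- function() {
  p <- system.file("python", "chem_props.py", package = "fraglinkr")
  if (!nzchar(p)) {
    # source tree (tests run before installation)
    p <- file.path("inst", "python", "chem_props.py")
  }
  if (!file.exists(p)) stop("chem_props.py not found", call. = FALSE)
  p
}

#' Compute chemistry properties for a set of molecules
#'
#' Batched evaluation of the standard property suite via RDKit: QED
#' (weighted-desirability drug-likeness), the Ertl-Schuffenhauer synthetic
#' accessibility (SA) score, PAINS substructure screening, and the
#' ring-aromaticity filter (a molecule fails if any non-aromatic ring
#' contains a double bond).  Optionally also tests containment of two
#' query fragments (attachment `*` atoms are ignored for matching).
#'
#' @param smiles Character vector of SMILES.
#' @param fragment_1,fragment_2 Optional fragment SMILES for substructure
#'   checks.
#' @return A tibble with one row per input: `smiles`, `parsed`,
#'   `canonical`, `qed`, `sa`, `arom_ring_pass`, `pains_pass`, and (when
#'   fragments are given) `has_frag1`, `has_frag2`.
#' @export
chem_properties <- function(smiles, fragment_1 = NULL, fragment_2 = NULL) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) {
    return(tibble::tibble(smiles = character(0)))
  }
  if (any(grepl("[[:space:]]", smiles))) {
    stop("SMILES must not contain whitespace", call. = FALSE)
  }
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(smiles, fin)
  cli_args <- c(.bridge_script(), "--infile", fin, "--outfile", fout)
  if (!is.null(fragment_1)) cli_args <- c(cli_args, "--frag1", fragment_1)
  if (!is.null(fragment_2)) cli_args <- c(cli_args, "--frag2", fragment_2)
  status <- system2("python", shQuote(cli_args), stdout = FALSE,
                    stderr = FALSE)
  if (status != 0 || !file.exists(fout)) {
    stop("chemistry property oracle failed (python/rdkit unavailable?)",
         call. = FALSE)
  }
  df <- utils::read.csv(fout, stringsAsFactors = FALSE)
  out <- tibble::tibble(
    smiles = smiles,
    parsed = df$parsed == 1,
    canonical = ifelse(df$parsed == 1, df$canonical, NA_character_),
    qed = suppressWarnings(as.numeric(df$qed)),
    sa = suppressWarnings(as.numeric(df$sa)),
    arom_ring_pass = df$arom_ring_pass == 1,
    pains_pass = df$pains_pass == 1
  )
  if (!is.null(fragment_1)) out$has_frag1 <- df$has_frag1 == 1
  if (!is.null(fragment_2)) out$has_frag2 <- df$has_frag2 == 1
  out
}

# parse SMILES through the RDKit bridge into raw atom/bond tables; used
# as a fallback for molecules OpenBabel's converter cannot handle (dense
# fused cages make it throw).  Returns a list (NULL where unparseable).
.bridge_parse_graphs <- function(smiles) {
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".csv")
  fgra <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout, fgra)), add = TRUE)
  writeLines(smiles, fin)
  status <- system2("python", shQuote(c(.bridge_script(), "--infile", fin,
                                        "--outfile", fout,
                                        "--graphfile", fgra)),
                    stdout = FALSE, stderr = FALSE)
  out <- vector("list", length(smiles))
  if (status != 0 || !file.exists(fgra)) return(out)
  df <- utils::read.csv(fgra, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(df))) {
    if (df$ok[r] != 1) next
    syms <- strsplit(df$atoms[r], " ", fixed = TRUE)[[1]]
    bonds <- matrix(integer(0), ncol = 3)
    if (nzchar(df$bonds[r])) {
      parts <- strsplit(strsplit(df$bonds[r], ";", fixed = TRUE)[[1]],
                        "-", fixed = TRUE)
      bonds <- do.call(rbind, lapply(parts, as.integer))
    }
    out[[df$index[r]]] <- list(symbols = syms, bonds = bonds)
  }
  out
}

#' Chemistry filters for one molecule
#'
#' Convenience wrapper around [chem_properties()] for a single molecule,
#' returning the SA score with its pass flag (SA < 3), the
#' ring-aromaticity and PAINS flags, and QED.
#'
#' @param mol A `mol_graph` or SMILES string.
#' @param sa_threshold SA pass threshold (default 3).
#' @return List with `sa_score`, `sa_pass`, `aromatic_ring_pass`,
#'   `pains_pass`, `qed`.
#' @export
chem_filters <- function(mol, sa_threshold = 3) {
  smi <- if (inherits(mol, "mol_graph")) {
    write_smiles(mol, keep_attachment = FALSE)
  } else {
    as.character(mol)
  }
  p <- chem_properties(smi)
  if (!p$parsed[1]) stop("unparseable molecule: ", smi, call. = FALSE)
  list(sa_score = p$sa[1], sa_pass = p$sa[1] < sa_threshold,
       aromatic_ring_pass = p$arom_ring_pass[1],
       pains_pass = p$pains_pass[1], qed = p$qed[1])
}
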