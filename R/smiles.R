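# SMILES ingestion and writing.  Conversion, kekulization and
# canonicalization are delegated to OpenBabel (ChemmineOB); a strict lexical
# validator runs first because OpenBabel silently repairs some malformed
# strings (e.g. "C(" parses as methane).

.smiles_token_re <- paste0(
  "\\[[^\\]]*\\]|Cl|Br|B|C|N|O|P|S|F|I|b|c|n|o|p|s|",
  "\\*|=|#|-|/|\\\\|\\(|\\)|%[0-9]{2}|[0-9]"
)

#' Check SMILES syntax
#'
#' Lexical and structural validation of a SMILES string: known tokens only,
#' balanced parentheses, no empty branches, paired ring-closure digits, no
#' leading/trailing bond symbols, single component (no `.`).  Semantic
#' validity (valence, kekulizability) is checked downstream by
#' [parse_smiles()].
#'
#' @param smiles A single SMILES string.
#' @return `TRUE` if well-formed, otherwise a character scalar describing
#'   the problem.
#' @export
smiles_syntax_ok <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles)) {
    return("not a single string")
  }
  if (!nzchar(smiles)) return("empty string")
  if (grepl("[[:space:]]", smiles)) return("contains whitespace")
  if (grepl("\\.", smiles)) return("multi-component SMILES not supported")
  toks <- regmatches(smiles, gregexpr(.smiles_token_re, smiles, perl = TRUE))[[1]]
  if (sum(nchar(toks)) != nchar(smiles)) return("unrecognized token")
  depth <- 0L
  ring_open <- character(0)
  prev <- ""
  for (tk in toks) {
    if (tk == "(") {
      if (prev == "" || prev %in% c("(", "=", "#", "-")) {
        return("branch opened without preceding atom")
      }
      depth <- depth + 1L
    } else if (tk == ")") {
      depth <- depth - 1L
      if (depth < 0L) return("unbalanced parentheses")
      if (prev == "(") return("empty branch")
      if (prev %in% c("=", "#", "-")) return("dangling bond in branch")
    } else if (grepl("^[0-9]$|^%[0-9]{2}$", tk)) {
      if (prev == "" || prev == "(") return("ring closure without atom")
      if (tk %in% ring_open) {
        ring_open <- setdiff(ring_open, tk)
      } else {
        ring_open <- c(ring_open, tk)
      }
    }
    prev <- tk
  }
  if (depth != 0L) return("unbalanced parentheses")
  if (prev %in% c("=", "#", "-")) return("dangling bond symbol")
  if (length(ring_open) > 0) return("unclosed ring bond")
  TRUE
}

.ob_convert <- function(from, to, text) {
  out <- suppressWarnings(ChemmineOB::convertFormat(from, to, text))
  if (is.null(out)) out <- ""
  out
}

# Parse one V2000 molblock (already kekulized by OpenBabel) into raw
# atom/bond tables, keeping "*" dummy atoms.
.parse_molblock <- function(mb) {
  lines <- strsplit(mb, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) stop("empty molblock", call. = FALSE)
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na)) stop("bad molblock counts line", call. = FALSE)
  atom_lines <- lines[4 + seq_len(na)]
  sym <- trimws(substr(atom_lines, 32, 34))
  bonds <- matrix(integer(0), ncol = 3)
  if (nb > 0) {
    bl <- lines[4 + na + seq_len(nb)]
    bonds <- cbind(
      as.integer(substr(bl, 1, 3)),
      as.integer(substr(bl, 4, 6)),
      as.integer(substr(bl, 7, 9))
    )
  }
  chg <- rep(0L, na)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    flds <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- flds[1]
    for (q in seq_len(k)) chg[flds[2 * q]] <- flds[2 * q + 1]
  }
  list(symbols = sym, bonds = bonds, charges = chg)
}

#' Parse a SMILES string into a molecular graph
#'
#' The string is validated, canonicalized and kekulized (aromatic bonds
#' resolved to alternating single/double orders), so the resulting atom
#' order is deterministic under re-parsing.  Dummy atoms (`*` or `[*]`)
#' mark attachment points: each must have exactly one single bond, the dummy
#' atom is removed, and its neighbour is flagged as an attachment atom.
#'
#' @param smiles A single SMILES string.
#' @return A `mol_graph`.
#' @examples
#' g <- parse_smiles("CCO")
#' g$elements
#' @export
parse_smiles <- function(smiles) {
  ok <- smiles_syntax_ok(smiles)
  if (!isTRUE(ok)) {
    stop("cannot parse SMILES '", smiles, "': ", ok, call. = FALSE)
  }
  can <- .ob_convert("SMI", "CAN", paste0(smiles, "\tm\n"))
  can <- sub("\\s+$", "", sub("\tm$", "", trimws(can)))
  raw <- NULL
  if (nzchar(can)) {
    mb <- .ob_convert("SMI", "SDF", paste0(can, "\tm\n"))
    if (nzchar(mb)) raw <- .parse_molblock(mb)
  }
  if (is.null(raw)) {
    # OpenBabel failed; try the RDKit bridge (kekulized graph dump)
    bg <- .bridge_parse_graphs(smiles)[[1]]
    if (is.null(bg)) {
      stop("cannot parse SMILES '", smiles, "'", call. = FALSE)
    }
    raw <- list(symbols = bg$symbols, bonds = bg$bonds,
                charges = rep(0L, length(bg$symbols)))
  }
  sym <- raw$symbols
  if (any(raw$charges != 0)) {
    stop("charged atoms are outside the supported vocabulary in '", smiles,
         "'", call. = FALSE)
  }
  dummy <- sym %in% c("*", "R", "R#", "Du")
  real_sym <- sym[!dummy]
  bad <- setdiff(unique(real_sym), element_vocabulary())
  if (length(bad) > 0) {
    stop("element(s) outside vocabulary in '", smiles, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  attach <- rep(FALSE, length(sym))
  b <- raw$bonds
  if (any(dummy)) {
    for (d in which(dummy)) {
      inc <- which(b[, 1] == d | b[, 2] == d)
      if (length(inc) != 1 || b[inc, 3] != 1L) {
        stop("attachment dummy atom must have exactly one single bond in '",
             smiles, "'", call. = FALSE)
      }
      nb <- setdiff(b[inc, 1:2], d)
      attach[nb] <- TRUE
    }
    keep <- which(!dummy)
    remap <- integer(length(sym)); remap[keep] <- seq_along(keep)
    drop_rows <- which(b[, 1] %in% which(dummy) | b[, 2] %in% which(dummy))
    if (length(drop_rows)) b <- b[-drop_rows, , drop = FALSE]
    if (nrow(b)) { b[, 1] <- remap[b[, 1]]; b[, 2] <- remap[b[, 2]] }
    sym <- sym[keep]; attach <- attach[keep]
  }
  if (length(sym) == 0) stop("no atoms in '", smiles, "'", call. = FALSE)
  if (nrow(b) > 0 && any(!b[, 3] %in% 1:3)) {
    stop("unsupported bond type in '", smiles, "'", call. = FALSE)
  }
  out <- try(mol_graph(sym, b, attachment = attach), silent = TRUE)
  if (inherits(out, "try-error")) {
    stop("invalid molecule '", smiles, "': ",
         attr(out, "condition")$message, call. = FALSE)
  }
  out
}

# Render a mol_graph as a V2000 molblock (zero coordinates), optionally
# re-adding "*" dummy atoms at flagged attachment positions.
.to_molblock <- function(g, keep_attachment = TRUE) {
  sym <- g$elements
  b <- g$bonds
  if (keep_attachment && any(g$attachment)) {
    for (a in which(g$attachment)) {
      sym <- c(sym, "*")
      b <- rbind(b, c(a, length(sym), 1L))
    }
  }
  na <- length(sym); nb <- nrow(b)
  hdr <- c("", " fraglinkr", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, sym)
  bl <- if (nb > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", b[, 1], b[, 2], b[, 3])
  } else character(0)
  paste(c(hdr, atoms, bl, "M  END", "$$$$"), collapse = "\n")
}

# plain depth-first SMILES emitter.  Not canonical; used as a fallback
# when OpenBabel's converter throws (dense fused ring cages).  Output is
# deterministic for a given graph and readable by standard toolkits.
.smiles_fallback <- function(g, keep_attachment = TRUE) {
  sym <- g$elements
  b <- g$bonds
  if (keep_attachment && any(g$attachment)) {
    for (a in which(g$attachment)) {
      sym <- c(sym, "*")
      b <- rbind(b, c(a, length(sym), 1L))
    }
  }
  n <- length(sym)
  adj <- vector("list", n)
  if (NROW(b) > 0) {
    for (k in seq_len(nrow(b))) {
      adj[[b[k, 1]]] <- rbind(adj[[b[k, 1]]], c(b[k, 2], b[k, 3]))
      adj[[b[k, 2]]] <- rbind(adj[[b[k, 2]]], c(b[k, 1], b[k, 3]))
    }
  }
  bond_chr <- c("", "=", "#")
  visited <- rep(FALSE, n)
  tree_parent <- rep(NA_integer_, n)
  ring_digit <- 0L
  ring_open <- list()   # per atom: vector of "digit tokens with bond"
  ring_edges <- new.env(parent = emptyenv())
  # first pass: DFS to mark tree edges and assign ring-closure digits
  order_visit <- integer(0)
  dfs1 <- function(u) {
    visited[u] <<- TRUE
    order_visit <<- c(order_visit, u)
    if (!is.null(adj[[u]])) {
      for (r in seq_len(nrow(adj[[u]]))) {
        v <- adj[[u]][r, 1]
        is_tree <- (!is.na(tree_parent[u]) && v == tree_parent[u]) ||
          (!is.na(tree_parent[v]) && tree_parent[v] == u)
        if (!visited[v]) {
          tree_parent[v] <<- u
          dfs1(v)
        } else if (!is_tree) {
          key <- paste(min(u, v), max(u, v))
          if (is.null(ring_edges[[key]])) {
            ring_digit <<- ring_digit + 1L
            tok <- if (ring_digit < 10) as.character(ring_digit) else
              sprintf("%%%02d", ring_digit)
            o <- adj[[u]][r, 2]
            ring_edges[[key]] <- TRUE
            ring_open[[as.character(u)]] <<-
              c(ring_open[[as.character(u)]], paste0(bond_chr[o], tok))
            ring_open[[as.character(v)]] <<-
              c(ring_open[[as.character(v)]], tok)
          }
        }
      }
    }
  }
  emit <- function(u, via_order) {
    s <- paste0(bond_chr[via_order], sym[u],
                paste0(ring_open[[as.character(u)]], collapse = ""))
    kids <- list()
    if (!is.null(adj[[u]])) {
      for (r in seq_len(nrow(adj[[u]]))) {
        v <- adj[[u]][r, 1]
        if (!is.na(tree_parent[v]) && tree_parent[v] == u) {
          kids[[length(kids) + 1L]] <- c(v, adj[[u]][r, 2])
        }
      }
    }
    if (length(kids) > 0) {
      for (k in seq_len(length(kids) - 1L)) {
        s <- paste0(s, "(", emit(kids[[k]][1], kids[[k]][2]), ")")
      }
      last <- kids[[length(kids)]]
      s <- paste0(s, emit(last[1], last[2]))
    }
    s
  }
  pieces <- character(0)
  for (root in seq_len(n)) {
    if (!visited[root]) {
      dfs1(root)
      pieces <- c(pieces, emit(root, 1L))
    }
  }
  out <- paste(pieces, collapse = ".")
  # two-letter symbols and * need brackets only outside the organic set;
  # our vocabulary (C,N,O,F,S,Cl,Br,*) is entirely in it
  out
}

#' Write a molecular graph as canonical SMILES
#'
#' Produces the OpenBabel canonical SMILES, so isomorphic graphs map to the
#' identical string and `parse_smiles(write_smiles(g))` is graph-isomorphic
#' to `g`.  Attachment atoms are serialized as `*` dummy neighbours when
#' `keep_attachment = TRUE`.
#'
#' @param g A `mol_graph`.
#' @param keep_attachment Re-emit `*` markers at attachment atoms?
#' @return A canonical SMILES string.
#' @export
write_smiles <- function(g, keep_attachment = TRUE) {
  stopifnot(inherits(g, "mol_graph"))
  if (length(g$elements) == 0) stop("empty graph", call. = FALSE)
  mb <- .to_molblock(g, keep_attachment = keep_attachment)
  out <- .ob_convert("SDF", "CAN", mb)
  out <- trimws(sub("\\s.*$", "", trimws(out)))
  if (!nzchar(out)) {
    # OpenBabel throws on some dense fused cages; fall back to the
    # deterministic depth-first writer (valid, not canonical)
    out <- .smiles_fallback(g, keep_attachment = keep_attachment)
  }
  out
}

#' Write canonical SMILES for a list of graphs in one conversion
#'
#' Batched companion to [write_smiles()]: one OpenBabel call for many
#' graphs, preserving order.
#'
#' @param graphs List of `mol_graph` objects.
#' @param keep_attachment Re-emit `*` markers at attachment atoms?
#' @return Character vector of canonical SMILES.
#' @export
write_smiles_batch <- function(graphs, keep_attachment = TRUE) {
  n <- length(graphs)
  if (n == 0) return(character(0))
  blocks <- vapply(graphs, .to_molblock, "",
                   keep_attachment = keep_attachment)
  # tag each record with its index via the molblock title line
  blocks <- vapply(seq_len(n), function(i) {
    sub("^\n", paste0("id", i, "\n"), blocks[i])
  }, "")
  out <- .ob_convert("SDF", "CAN", paste(blocks, collapse = "\n"))
  res <- rep(NA_character_, n)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  for (ln in lines[nzchar(lines)]) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 2 && grepl("^id[0-9]+$", parts[2])) {
      res[as.integer(sub("id", "", parts[2]))] <- parts[1]
    }
  }
  for (k in which(is.na(res))) {
    res[k] <- .smiles_fallback(graphs[[k]], keep_attachment = keep_attachment)
  }
  res
}

#' Canonicalize a vector of SMILES strings
#'
#' Batched canonicalization through OpenBabel.  Strings that fail either the
#' syntax validator or conversion come back as `NA`.
#'
#' @param smiles Character vector.
#' @return Character vector of canonical SMILES (`NA` where unparseable).
#' @export
canonical_smiles <- function(smiles) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  if (n == 0) return(out)
  ok <- vapply(smiles, function(s) isTRUE(smiles_syntax_ok(s)), logical(1))
  idx <- which(ok)
  if (length(idx) == 0) return(out)
  batch <- paste0(smiles[idx], "\tid", idx, collapse = "\n")
  res <- .ob_convert("SMI", "CAN", paste0(batch, "\n"))
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 2 && grepl("^id[0-9]+$", parts[2])) {
      out[as.integer(sub("id", "", parts[2]))] <- parts[1]
    }
  }
  # syntactically fine but OpenBabel-unconvertible (e.g. dense cages):
  # fall back to the RDKit canonical form so isomorphic inputs still
  # collapse to one key
  miss <- which(ok & is.na(out))
  if (length(miss) > 0) {
    p <- tryCatch(chem_properties(smiles[miss]), error = function(e) NULL)
    if (!is.null(p)) out[miss] <- p$canonical
  }
  out
}
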