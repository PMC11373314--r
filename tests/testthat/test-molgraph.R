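test_that("parse_smiles reads simple molecules and rejects bad input", {
  g <- parse_smiles("CCO")
  expect_s3_class(g, "mol_graph")
  expect_equal(sort(g$elements), c("C", "C", "O"))
  expect_equal(nrow(g$bonds), 2L)
  expect_true(all(g$bonds[, "order"] == 1L))

  expect_error(parse_smiles("C("), "unbalanced")
  expect_error(parse_smiles(""), "empty")
  expect_error(parse_smiles("C1CC"), "ring")
  expect_error(parse_smiles("[Si](C)(C)C"), "vocabulary|token")
  expect_error(parse_smiles("CC(C)(C)(C)C"), "valence")
})

test_that("aromatic input is kekulized to alternating bond orders", {
  g <- parse_smiles("c1ccccc1")
  expect_equal(g$elements, rep("C", 6))
  expect_equal(sort(as.integer(table(g$bonds[, "order"]))), c(3L, 3L))
  # alternation: every atom carries exactly one single and one double bond
  for (a in 1:6) {
    inc <- g$bonds[g$bonds[, "i"] == a | g$bonds[, "j"] == a, "order"]
    expect_equal(sort(inc), c(1, 2))
  }
})

test_that("attachment dummies are absorbed into flags", {
  g <- parse_smiles("*CCN")
  expect_equal(sum(g$attachment), 1L)
  expect_equal(length(g$elements), 3L)
  expect_match(write_smiles(g), "\\*")
  # round trip keeps the attachment
  g2 <- parse_smiles(write_smiles(g))
  expect_equal(sum(g2$attachment), 1L)
})

test_that("write_smiles is canonical and round trips", {
  g <- parse_smiles("CCO")
  expect_equal(write_smiles(g), "CCO")
  # two relabelings of the same molecule give the identical string
  s1 <- write_smiles(parse_smiles("OCC"))
  s2 <- write_smiles(parse_smiles("C(O)C"))
  expect_identical(s1, s2)
  # kekulized benzene re-parses isomorphic
  b <- parse_smiles("c1ccccc1")
  expect_true(graphs_isomorphic(b, parse_smiles(write_smiles(b))))
  expect_error(write_smiles(mol_graph(character(0))), "empty")
})

test_that("parse-write-parse preserves graph isomorphism on a fixture set", {
  ds <- fx_dataset()
  graphs <- c(lapply(ds$example[1:60], `[[`, "molecule"),
              lapply(ds$example[1:60], `[[`, "fragment_1"),
              lapply(ds$example[1:60], `[[`, "fragment_2"))
  smi <- write_smiles_batch(graphs)
  smi2 <- vapply(smi, function(s) write_smiles(parse_smiles(s)), "",
                 USE.NAMES = FALSE)
  expect_identical(smi, smi2)
  # spot-check actual isomorphism, not just string equality
  for (k in seq(1, length(graphs), by = 30)) {
    expect_true(graphs_isomorphic(graphs[[k]], parse_smiles(smi[k])))
  }
})

test_that("valence_remaining follows the valence table", {
  # canonical parsing may reorder atoms: locate them by structure
  neo <- parse_smiles("C(C)(C)(C)C")
  central <- which(bond_order_sums(neo) == 4)
  expect_equal(valence_remaining(neo, central), 0L)
  mn <- parse_smiles("NC")
  expect_equal(valence_remaining(mn, which(mn$elements == "N")), 2L)
  oc <- parse_smiles("O=C")
  expect_equal(valence_remaining(oc, which(oc$elements == "O")), 0L)
  expect_error(valence_remaining(parse_smiles("C"), 5), "range")
})

test_that("mol_graph invariants are enforced", {
  expect_error(mol_graph("C", rbind(c(1, 1, 1))), "self-loop")
  expect_error(mol_graph(c("C", "C"), rbind(c(1, 2, 1), c(2, 1, 2))),
               "duplicate")
  expect_error(mol_graph(c("O", "O"), rbind(c(1, 2, 3))), "valence")
  expect_error(mol_graph("Xx"), "vocabulary")
})
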