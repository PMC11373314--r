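test_that("validity requires parseability and both fragments", {
  v <- validity(c("CCOCC", "C(", "CCNCC"), "*CC", "*C")
  expect_equal(v$fraction, 2 / 3)
  expect_equal(v$valid_smiles, c("CCOCC", "CCNCC"))
  # a molecule missing fragment 2 is invalid
  v2 <- validity(c("CCOCC", "CCCl"), "*CC", "*N")
  expect_equal(v2$fraction, 0)
})

test_that("uniqueness and novelty match hash-set oracles", {
  expect_equal(uniqueness(c("CCO", "OCC", "CCC")), 2 / 3)
  expect_equal(uniqueness(rep("CC", 5)), 1 / 5)
  expect_error(uniqueness(character(0)), "empty")

  expect_equal(novelty(c("CCO", "CCC"), c("OCC", "CCC")), 0)
  expect_equal(novelty(c("CCO", "CCC"), c("CCN")), 1)
  expect_warning(nv <- novelty("CCO", character(0)), "novel")
  expect_equal(nv, 1)

  # randomized fixture vs independent set arithmetic
  set.seed(18)
  pool <- unique(fx_dataset()$molecule_smiles)
  mols <- sample(pool, 60, replace = TRUE)
  train <- sample(pool, 30)
  can <- canonical_smiles(mols)
  expect_equal(uniqueness(mols), length(unique(can)) / length(mols))
  expect_equal(novelty(mols, train),
               mean(!unique(can) %in% canonical_smiles(train)))
})

test_that("chemical filters reproduce reference values", {
  f <- chem_filters("CCO")
  # frozen reference-implementation values for ethanol
  expect_equal(f$sa_score, 1.9802570386, tolerance = 1e-6)
  expect_equal(f$qed, 0.4068079657, tolerance = 1e-6)
  expect_true(f$sa_pass)
  expect_true(f$aromatic_ring_pass)
  expect_true(f$pains_pass)
  # acyclic alkane: no rings, filter passes
  expect_true(chem_filters("CCCCC")$aromatic_ring_pass)
  # cyclohexene: a double bond inside a non-aromatic ring fails
  expect_false(chem_filters("C1CCC=CC1")$aromatic_ring_pass)
  # aromatic benzene passes
  expect_true(chem_filters("c1ccccc1")$aromatic_ring_pass)
  expect_error(chem_filters("C("), "unparseable|parse")
})

test_that("pass rates follow the thresholds and set inclusion", {
  smiles <- c("CCCCCCCC", "NCCO", "CC(=O)Nc1ccc(O)cc1", "OCC(O)CO",
              "NCCN", "c1ccccc1O")
  pr <- pass_rates(smiles)
  expect_setequal(pr$condition, c("qed>0.6", "sa<3", "pic50>6",
                                  "conjunction"))
  conj <- pr$pass_rate[pr$condition == "conjunction"]
  expect_true(all(conj <= pr$pass_rate))
  # brute-force recount
  p <- chem_properties(smiles)
  act <- vapply(smiles, surrogate_activity, 0, USE.NAMES = FALSE)
  expect_equal(pr$pass_rate[pr$condition == "qed>0.6"],
               mean(p$qed > 0.6))
  expect_equal(pr$pass_rate[pr$condition == "sa<3"], mean(p$sa < 3))
  expect_equal(pr$pass_rate[pr$condition == "pic50>6"], mean(act > 6))
  expect_equal(conj, mean(p$qed > 0.6 & p$sa < 3 & act > 6))
  # all molecules failing one condition zero the conjunction
  pr0 <- pass_rates("CCCCCCCC")
  expect_equal(pr0$pass_rate[pr0$condition == "conjunction"], 0)
  expect_error(pass_rates(character(0)), "empty")
})

test_that("the metric report is order-invariant", {
  ds <- fx_dataset()
  ex <- ds$example[[2]]
  smi <- c(ds$molecule_smiles[1:6], ds$molecule_smiles[1:2])
  f1 <- write_smiles(ex$fragment_1); f2 <- write_smiles(ex$fragment_2)
  r1 <- evaluate_molecules(smi, f1, f2, ds$molecule_smiles[1:10])
  r2 <- evaluate_molecules(rev(smi), f1, f2, ds$molecule_smiles[1:10])
  expect_equal(r1$validity, r2$validity)
  expect_equal(r1$uniqueness, r2$uniqueness)
  expect_equal(r1$novelty, r2$novelty)
  expect_true(all(unlist(r1[, c("validity", "uniqueness", "novelty")])
                  >= 0, na.rm = TRUE))
})
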