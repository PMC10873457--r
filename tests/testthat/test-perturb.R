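test_that("perturbations are local, pure edits", {
  m <- parse_smiles("CCO")
  p <- perturbation("set_element", atom = 3, value = 16)
  m2 <- apply_perturbation(m, p)
  expect_equal(m2$Z, c(6L, 6L, 16L))
  expect_equal(m$Z, c(6L, 6L, 8L))            # input untouched
  expect_equal(m2$H, m$H)
  expect_equal(m2$bonds, m$bonds)

  # insert_bond bookkeeping: D and V of both endpoints rise
  m3 <- apply_perturbation(parse_smiles("CCCC"),
                           perturbation("insert_bond", bond = c(1, 4), order = 1))
  ak <- molautofix:::cpp_atom_keys(m3)
  expect_equal(ak[c(1, 4), "D"], c(2L, 2L))
  expect_equal(ak[c(1, 4), "V"], c(2L, 2L))

  # delete_atom removes incident bonds and reindexes contiguously
  m4 <- apply_perturbation(parse_smiles("CC(C)O"),
                           perturbation("delete_atom", atom = 1))
  expect_equal(n_atoms(m4), 3L)
  expect_equal(n_bonds(m4), 2L)
  expect_true(all(m4$bonds[, 1:2] %in% 1:3))
})

test_that("invertible perturbations undo exactly", {
  m <- parse_smiles("CC(N)=O")
  cases <- list(
    list(perturbation("set_hydrogens", atom = 3, value = 0),
         perturbation("set_hydrogens", atom = 3, value = m$H[3])),
    list(perturbation("set_charge", atom = 3, value = 1),
         perturbation("set_charge", atom = 3, value = 0)),
    list(perturbation("set_element", atom = 4, value = 16),
         perturbation("set_element", atom = 4, value = 8)),
    list(perturbation("set_bond_type", bond = c(2, 4), value = 1),
         perturbation("set_bond_type", bond = c(2, 4), value = 2)))
  for (cs in cases)
    expect_identical(apply_perturbation(apply_perturbation(m, cs[[1]]), cs[[2]]), m)
})

test_that("deletions keep the largest fragment", {
  # propane minus its first bond: the 2-atom fragment survives
  m <- apply_perturbation(parse_smiles("CCC"),
                          perturbation("delete_bond", bond = c(1, 2)))
  expect_equal(n_atoms(m), 2L)
  # deleting the centre of a star keeps the largest piece (here: any
  # single atom; the lowest-index fragment wins ties)
  m2 <- apply_perturbation(parse_smiles("CC(C)C"),
                           perturbation("delete_atom", atom = 2))
  expect_equal(n_atoms(m2), 1L)
})

test_that("perturbation errors: dangling targets and duplicate bonds", {
  m <- parse_smiles("CCO")
  expect_error(apply_perturbation(m, perturbation("set_element", atom = 9, value = 6)),
               "out of range")
  expect_error(apply_perturbation(m, perturbation("delete_bond", bond = c(1, 3))),
               "no such bond")
  expect_error(apply_perturbation(m, perturbation("insert_bond", bond = c(1, 2))),
               "already exists")
})

test_that("sanitization resets hydrogens toward standard valences", {
  # two disconnected sp3 carbons, as if an ethane C-C bond just broke
  m <- molgraph(Z = c(6, 6), H = c(3, 3))
  s <- sanitize_after_perturbation(m, touched_atoms = 1:2)
  expect_equal(s$H, c(4L, 4L))

  # disabled: identity
  expect_identical(sanitize_after_perturbation(m, 1:2, enabled = FALSE), m)

  # hexavalent carbon exceeds the table maximum: left untouched
  hexa <- parse_smiles("CC(C)(C)(C)(C)C")
  s2 <- sanitize_after_perturbation(hexa, touched_atoms = 2)
  expect_identical(s2, hexa)

  # multi-valence elements step to the next standard valence
  so <- molgraph(Z = 16, H = 0)                  # bare S
  expect_equal(sanitize_after_perturbation(so, 1)$H, 2L)
  so3 <- parse_smiles("OS(O)=O")                 # S with V = 4
  expect_equal(sanitize_after_perturbation(so3, 2)$H[2L], 0L)
})

test_that("the breaker is seeded, sequential and kind-uniform", {
  m <- ref_mols[[10]]
  s1 <- random_perturbation_sequence(m, 10, seed = 123)
  s2 <- random_perturbation_sequence(m, 10, seed = 123)
  expect_identical(s1, s2)
  expect_length(s1, 10L)
  s3 <- random_perturbation_sequence(m, 10, seed = 124)
  expect_false(identical(s1, s3))
  expect_error(random_perturbation_sequence(m, 0, seed = 1), "n_steps")
})

test_that("random perturbations degrade familiarity on average", {
  set.seed(11)
  picks <- sample(seq_along(ref_mols), 50)
  steps <- 6L
  f1 <- matrix(NA_real_, length(picks), steps)
  for (k in seq_along(picks)) {
    ser <- random_perturbation_sequence(ref_mols[[picks[k]]], steps,
                                        seed = 1000 + k)
    f1[k, ] <- vapply(ser, function(m) familiarity_report(m, ref_dict)$f1, 1)
  }
  trend <- colMeans(f1)
  # aggregate trend: strictly lower at the end, decreasing rank correlation
  expect_lt(trend[steps], trend[1L])
  expect_lt(cor(seq_len(steps), trend, method = "spearman"), 0)
})
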