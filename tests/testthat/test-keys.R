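test_that("atom keys follow the (D, V, Z, Q, H) definitions", {
  methane <- molgraph(Z = 6, H = 4)
  expect_equal(unname(unclass(compute_atom_key(methane, 1))), c(0L, 0L, 6L, 0L, 4L))

  sulfone <- parse_smiles("CS(C)(=O)=O")
  expect_equal(unname(unclass(compute_atom_key(sulfone, 2))),
               c(4L, 6L, 16L, 0L, 0L))

  expect_error(compute_atom_key(methane, 2), "out of range")
})

test_that("partial atom keys are the four significance-ordered prefixes", {
  pk <- enumerate_partial_atom_keys(c(4L, 6L, 16L, 0L, 0L))
  expect_length(pk, 4L)
  expect_equal(lapply(pk, function(x) unname(unclass(x))),
               list(4L, c(4L, 6L), c(4L, 6L, 16L), c(4L, 6L, 16L, 0L)))
  # each prefix extends the previous by one property
  for (j in 2:4)
    expect_equal(unclass(pk[[j]])[seq_len(j - 1L)], unclass(pk[[j - 1L]]),
                 ignore_attr = TRUE)
  expect_length(enumerate_partial_atom_keys(compute_atom_key(molgraph(6, H = 4), 1))[[1L]], 1L)
})

test_that("bond keys are canonical and carry one partial bond key", {
  ethane <- parse_smiles("CC")
  bk <- compute_bond_key(ethane, 1)
  expect_equal(unname(unclass(bk$ak1)), c(1L, 1L, 6L, 0L, 3L))
  expect_equal(unname(unclass(bk$ak2)), c(1L, 1L, 6L, 0L, 3L))
  expect_equal(unname(bk$order), 1L)

  # endpoint order never matters: O listed first or last gives the same key
  co1 <- molgraph(Z = c(6, 8), H = c(3, 1), bonds = rbind(c(1, 2, 1)))
  co2 <- molgraph(Z = c(8, 6), H = c(1, 3), bonds = rbind(c(1, 2, 1)))
  expect_equal(molautofix:::key_string(compute_bond_key(co1, 1)),
               molautofix:::key_string(compute_bond_key(co2, 1)))

  pb <- partial_bond_key(bk)
  expect_s3_class(pb, "partial_bond_key")
  expect_equal(molautofix:::key_string(pb), "1,1,6,0,3;1,1,6,0,3")
  expect_error(compute_bond_key(ethane, c(1, 3)), "no such bond")
})

test_that("environment keys hash equivalent environments identically", {
  benzene <- parse_smiles("c1ccccc1")
  keys <- vapply(1:6, function(i) compute_environment_key(benzene, i, 1)$hash,
                 character(1))
  # all six carbons are NOT equivalent at r=1 after kekulization? they are:
  # each has one single and one double ring bond
  expect_length(unique(keys), 1L)

  # radius 0 depends only on the atom's own key
  k1 <- compute_environment_key(parse_smiles("CC"), 1, 0)$hash
  k2 <- compute_environment_key(parse_smiles("CCC"), 1, 0)$hash   # also (1,1,6,0,3)
  expect_identical(k1, k2)

  # changing a neighbour's element changes the center's r=1 key
  eth <- parse_smiles("CCO")
  etn <- parse_smiles("CCN")
  expect_false(identical(compute_environment_key(eth, 2, 1)$hash,
                         compute_environment_key(etn, 2, 1)$hash))

  # members are all atoms within the radius
  expect_equal(compute_environment_key(eth, 2, 1)$members, 1:3)
  expect_equal(compute_environment_key(eth, 1, 1)$members, 1:2)
})

test_that("hashes are stable across calls and frozen across versions", {
  m <- parse_smiles("CCO")
  k1 <- featurize_molecule(m, 1)
  k2 <- featurize_molecule(m, 1)
  expect_identical(k1, k2)
  # frozen value: guards the advertised fnv1a64/v1 scheme; a change here
  # invalidates every persisted dictionary
  expect_identical(compute_environment_key(parse_smiles("CC"), 1, 0)$hash,
                   "041566dd1738c826")
})

test_that("featurization counts satisfy n = n_a + n_b + n_e", {
  ks <- featurize_molecule(parse_smiles("CC"), 1)
  expect_equal(ks$n_a, 2L)
  expect_equal(ks$n_b, 1L)
  expect_equal(ks$n_e, 2L)
  expect_equal(ks$n, 5L)

  empty <- molgraph(integer(0))
  expect_equal(featurize_molecule(empty, 1)$n, 0L)

  single <- molgraph(Z = 8, H = 2)
  ks1 <- featurize_molecule(single, 1)
  expect_equal(c(ks1$n_a, ks1$n_b, ks1$n_e), c(1L, 0L, 1L))
})

test_that("keys are invariant under atom renumbering and satisfy V >= D", {
  set.seed(7)
  picks <- sample(seq_along(ref_mols), 25)
  n_checked <- 0L
  for (i in picks) {
    m <- ref_mols[[i]]
    ak <- molautofix:::cpp_atom_keys(m)
    expect_true(all(ak[, "V"] >= ak[, "D"]))
    # partial-key containment for every atom
    for (a in seq_len(min(n_atoms(m), 5))) {
      pk <- enumerate_partial_atom_keys(ak[a, ])
      for (j in 2:4)
        expect_equal(unclass(pk[[j]])[seq_len(j - 1L)], unclass(pk[[j - 1L]]),
                     ignore_attr = TRUE)
      n_checked <- n_checked + 1L
    }
    perm <- sample(n_atoms(m))
    expect_equal(all_key_strings(permute_molgraph(m, perm)), all_key_strings(m))
  }
  expect_gte(n_checked, 50L)
})
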