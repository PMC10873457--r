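test_that("dictionary counts key occurrences with multiplicity", {
  d <- chemical_dictionary(list(parse_smiles("CC")), radius = 1)
  expect_equal(key_count(d, c(1, 1, 6, 0, 3)), 2)       # two equivalent carbons
  expect_equal(key_count(d, compute_bond_key(parse_smiles("CC"), 1)), 1)

  # duplicating a reference molecule doubles every count it contributes
  d2 <- chemical_dictionary(list(parse_smiles("CC"), parse_smiles("CC")), radius = 1)
  e1 <- molautofix:::cpp_dict_export(d$ptr)
  e2 <- molautofix:::cpp_dict_export(d2$ptr)
  for (cat_i in 1:5) {
    expect_identical(e1[[cat_i]]$key, e2[[cat_i]]$key)
    expect_equal(2 * e1[[cat_i]]$count, e2[[cat_i]]$count)
  }
  expect_error(chemical_dictionary(list()), "non-empty")
})

test_that("stored environment keys imply stored member atom keys", {
  d <- chemical_dictionary(ref_mols[1:30], radius = 1)
  # dependency: every environment in the dictionary was counted alongside
  # the atom keys of its member atoms, so scoring any reference molecule
  # never finds a familiar environment over a foreign atom
  for (m in ref_mols[1:30]) {
    rep <- familiarity_report(m, d)
    for (i in seq_len(n_atoms(m))) {
      if (rep$env_familiar[i])
        expect_true(all(rep$atom_familiar[rep$env_members[[i]]]))
    }
  }
})

test_that("classification is a strict threshold on counts", {
  d0 <- chemical_dictionary(list(parse_smiles("CCO")), radius = 1)
  expect_equal(classify_key(d0, c(1, 1, 8, 0, 1)), "familiar")  # count 1 > t = 0
  expect_equal(classify_key(d0, c(1, 1, 7, 0, 2)), "foreign")   # absent -> count 0

  # count 5 with threshold 5 is foreign ("surpasses" is strict)
  d5 <- chemical_dictionary(rep(list(parse_smiles("CCO")), 5), radius = 1,
                            threshold = 5)
  expect_equal(key_count(d5, c(1, 1, 8, 0, 1)), 5)
  expect_equal(classify_key(d5, c(1, 1, 8, 0, 1)), "foreign")
  d4 <- chemical_dictionary(rep(list(parse_smiles("CCO")), 5), radius = 1,
                            threshold = 4)
  expect_equal(classify_key(d4, c(1, 1, 8, 0, 1)), "familiar")
})

test_that("successor values rank extensions by reference frequency", {
  d <- chemical_dictionary(c("CS(C)(=O)=O", "CS(C)(=O)=O", "C[Se](C)(=O)=O"),
                           radius = 1)
  sv <- successor_values(d, c(4, 6), "Z")
  expect_equal(sv$value, c(16L, 34L))
  expect_equal(sv$count, c(2, 1))

  expect_equal(nrow(successor_values(d, c(9, 9), "Z")), 0L)   # unseen prefix

  # ordering equals a brute-force recount over the reference set
  sub <- ref_mols[31:60]
  dd <- chemical_dictionary(sub, radius = 1)
  aks <- do.call(rbind, lapply(sub, molautofix:::cpp_atom_keys))
  sel <- aks[, "D"] == 2L & aks[, "V"] == 2L
  recount <- sort(table(aks[sel, "Z"]), decreasing = TRUE)
  sv2 <- successor_values(dd, c(2, 2), "Z")
  expect_equal(sv2$count, as.numeric(recount))
  # tie-break: descending count then ascending value
  expect_false(is.unsorted(rev(sv2$count)))
})

test_that("familiarity follows f1 = nf/n and f2 = 1/(n - nf + 1)", {
  # dictionary {CCO, CCCC} scored against OCCO: both central-carbon
  # environments are the only foreign keys (hand-derived)
  d <- chemical_dictionary(c("CCO", "CCCC"), radius = 1)
  rep <- familiarity_report(parse_smiles("OCCO"), d)
  expect_equal(rep$n, 11L)                 # 4 atoms + 3 bonds + 4 environments
  expect_equal(rep$nf, 9L)
  expect_true(all(rep$atom_familiar))
  expect_true(all(rep$bond_familiar))
  expect_equal(rep$env_familiar, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(rep$f1, 9 / 11)
  expect_equal(rep$f2, 1 / 3)

  # a reference molecule scored against its own dictionary is correct
  own <- familiarity_report(parse_smiles("CCO"), d)
  expect_equal(own$f1, 1)
  expect_equal(own$f2, 1)

  expect_error(familiarity_report(molgraph(integer(0)), d), "empty")
})

test_that("dictionary TSV round-trips exactly and guards its scheme", {
  d <- chemical_dictionary(ref_mols[1:10], radius = 1, threshold = 2)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_dictionary(d, tmp)
  d2 <- read_dictionary(tmp)
  expect_true(dict_equal(d, d2))
  expect_equal(d2$threshold, 2)
  expect_equal(d2$radius, 1L)

  lines <- readLines(tmp)
  lines[3] <- "#hash_scheme\tsomething_else/v9"
  writeLines(lines, tmp)
  expect_error(read_dictionary(tmp), "hash scheme")

  write_dictionary(d, tmp)
  lines <- readLines(tmp)
  lines[10] <- "atom\tgarbage-without-count"
  writeLines(lines, tmp)
  expect_error(read_dictionary(tmp), "line 10")
})

test_that("building is order-independent", {
  da <- chemical_dictionary(ref_mols[1:15], radius = 1)
  db <- chemical_dictionary(rev(ref_mols[1:15]), radius = 1)
  expect_true(dict_equal(da, db))
})

test_that("ablating keys cascades foreignness to dependent keys", {
  m <- parse_smiles("CCO")
  d <- chemical_dictionary(list(m), radius = 1)
  # drop the oxygen atom key: its bond and environments must turn foreign
  d2 <- dict_drop_keys(d, "atom", "1,1,8,0,1")
  rep <- familiarity_report(m, d2)
  expect_false(rep$atom_familiar[3L])
  expect_false(rep$bond_familiar[2L])             # C-O bond contains the O
  expect_false(rep$env_familiar[3L])              # O's own environment
  expect_false(rep$env_familiar[2L])              # middle C's environment holds O
  expect_true(rep$atom_familiar[1L])
  expect_true(rep$env_familiar[1L])               # methyl environment has no O
})
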