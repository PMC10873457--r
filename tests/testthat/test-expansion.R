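test_that("foreign-environment membership counts containing environments", {
  # a foreign-element centre with three neighbours: all four radius-1
  # environments contain it
  d <- chemical_dictionary(c("CC", "CCC", "CC(C)C"), radius = 1)
  m <- parse_smiles("C[Se](C)C")
  mm <- foreign_environment_membership(m, d)
  expect_equal(mm$atom[2L], 4L)
  expect_true(all(mm$atom[c(1, 3, 4)] >= 1L))

  # all-familiar molecule: all zero
  mm0 <- foreign_environment_membership(parse_smiles("CCC"), d)
  expect_equal(mm0$atom, rep(0L, 3))
  expect_equal(mm0$bond, rep(0L, 2))
})

test_that("diagnosis walks the partial-key ladder to the culprit property", {
  # hexavalent carbon whose (D,V) = (4,6) is familiar from sulfones:
  # the atomic number is the culprit, with (4,6) the familiar predecessor
  d <- chemical_dictionary(c("CS(C)(=O)=O", "CS(C)(=O)=O", "C[Se](C)(=O)=O"),
                           radius = 1)
  hexa <- parse_smiles("CC(C)(=O)=O")
  diag <- diagnose(hexa, d)
  expect_equal(diag$target_type, "atom")
  expect_equal(diag$target, 2L)
  expect_equal(diag$culprit, "Z")
  expect_equal(diag$foreign_key, "4,6,6")
  expect_equal(diag$predecessor, "4,6")

  expect_error(diagnose(parse_smiles("CS(C)(=O)=O"), d), "fully familiar")
})

test_that("a foreign pairing of familiar atom keys blames the bond", {
  # C appears in CC, O appears in OO, but the C-O bond key pair is unseen
  d <- chemical_dictionary(c("CC", "OO"), radius = 1)
  diag <- diagnose(parse_smiles("CO"), d)
  expect_equal(diag$target_type, "bond")
  expect_equal(diag$culprit, "AK-pair")
})

test_that("environment-only defects target maximal membership, rarest key", {
  # OCCO against {CCO, CCCC}: only the two central environments are
  # foreign; the C-C bond sits in both and its key is rarer (count 1)
  # than the carbon atom key (count 3)
  d <- chemical_dictionary(c("CCO", "CCCC"), radius = 1)
  diag <- diagnose(parse_smiles("OCCO"), d)
  expect_equal(diag$target_type, "bond")
  expect_equal(unname(sort(diag$target)), c(2L, 3L))
  expect_equal(diag$culprit, "environment")
})

test_that("culprit-targeted candidates lead, ranked by successor frequency", {
  d <- chemical_dictionary(c("CS(C)(=O)=O", "CS(C)(=O)=O", "C[Se](C)(=O)=O"),
                           radius = 1)
  hexa <- parse_smiles("CC(C)(=O)=O")
  s <- candidate_perturbations(hexa, d, diagnose(hexa, d))
  p1 <- stream_next(s)
  p2 <- stream_next(s)
  expect_equal(p1$kind, "set_element")
  expect_equal(p1$atom, 2L)
  expect_equal(p1$value, 16L)      # sulfur before selenium
  expect_equal(p2$kind, "set_element")
  expect_equal(p2$value, 34L)
})

test_that("environment culprits try perturbation kinds by significance", {
  d <- chemical_dictionary(c("CCO", "CCCC"), radius = 1)
  m <- parse_smiles("OCCC")
  # make an environment-only defect on an atom: score OCCC; its O-side
  # middle carbon env is foreign while atoms/bonds are familiar
  rep <- familiarity_report(m, d)
  diag <- diagnose(m, d)
  s <- candidate_perturbations(m, d, diag)
  kinds <- vapply(stream_collect(s, 200), function(p) p$kind, "")
  # hydrogen edits appear before charge edits before element edits
  expect_lt(match("set_hydrogens", kinds), match("set_charge", kinds))
  expect_lt(match("set_charge", kinds), match("set_element", kinds))
})

test_that("the exhausted stream equals the brute-force 1-edit neighbourhood", {
  d <- chemical_dictionary(ref_mols[1:40], radius = 1)
  for (smi in c("NC(N)=O", "CS(C)=O", "OCC(O)CO")) {
    m <- parse_smiles(smi)
    diag <- tryCatch(diagnose(m, d), error = function(e) NULL)
    s <- candidate_perturbations(m, d, diag)
    got <- sort(vapply(stream_collect(s), perturbation_string, ""))
    expect_false(any(duplicated(got)))
    want <- sort(oracle_neighborhood(m, d))
    expect_identical(got, want)
  }
  # with insertions disabled the stream shrinks accordingly
  m <- parse_smiles("CCO")
  s0 <- candidate_perturbations(m, d, NULL, allow_insertions = FALSE)
  got0 <- vapply(stream_collect(s0), perturbation_string, "")
  expect_false(any(grepl("^insert", got0)))
  expect_setequal(got0, oracle_neighborhood(m, d, allow_insertions = FALSE))
})

test_that("streams are deterministic for identical inputs", {
  d <- chemical_dictionary(ref_mols[1:40], radius = 1)
  m <- parse_smiles("CC(C)(=O)=O")
  diag <- diagnose(m, d)
  a <- vapply(stream_collect(candidate_perturbations(m, d, diag)),
              perturbation_string, "")
  b <- vapply(stream_collect(candidate_perturbations(m, d, diag)),
              perturbation_string, "")
  expect_identical(a, b)
})

test_that("diagnosis soundness: predecessor familiar, extension foreign", {
  set.seed(3)
  checked <- 0L
  for (i in sample(seq_along(ref_mols), 40)) {
    broken <- random_perturbation_sequence(ref_mols[[i]], 2, seed = i)[[2L]]
    rep <- familiarity_report(broken, ref_dict)
    if (rep$f1 == 1) next
    diag <- diagnose(broken, ref_dict)
    if (diag$culprit %in% c("D", "V", "Z", "Q", "H")) {
      expect_lte(key_count(ref_dict, diag$foreign_key), ref_dict$threshold)
      if (nzchar(diag$predecessor))
        expect_gt(key_count(ref_dict, diag$predecessor), ref_dict$threshold)
      checked <- checked + 1L
    } else if (diag$culprit == "B") {
      expect_gt(key_count(ref_dict, diag$predecessor), ref_dict$threshold)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 10L)
})
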