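test_that("printed names parse into the expected structures", {
  a <- parse_entity_name("GRB2:SOS1")
  expect_s3_class(a, "cv_assembly")
  expect_equal(a$kind, "complex")
  expect_equal(vapply(a$parts, function(p) p$member$gene_symbol, ""),
               c("GRB2", "SOS1"))

  b <- parse_entity_name("[[ABC1:ABC2]:[ABC3:ABC4]]:XYZ1")
  expect_equal(b$kind, "complex")
  expect_s3_class(b$parts[[1]]$member, "cv_assembly")
  expect_equal(length(b$parts[[1]]$member$parts), 2L)
  expect_equal(name_entity(b)$text, "[[ABC1:ABC2]:[ABC3:ABC4]]:XYZ1")

  cs <- parse_entity_name("HRH2,HRH3,(HRH6,HRH8)")
  expect_equal(cs$kind, "candidate_set")
  expect_equal(vapply(cs$parts, function(p) p$candidate, TRUE),
               c(FALSE, FALSE, TRUE, TRUE))
})

test_that("maximal munch binds phospho tokens to the peptide, not the set", {
  p <- parse_entity_name("p-Y150,S343,T346-WASF2")
  expect_s3_class(p, "cv_peptide")
  expect_length(p$ptms, 3L)
  expect_equal(p$gene_symbol, "WASF2")
  # and inside a set the peptide still wins
  s <- parse_entity_name("GRB2,p-Y150,S343-WASF2")
  expect_equal(s$kind, "defined_set")
  expect_length(s$parts, 2L)
  expect_length(s$parts[[2]]$member$ptms, 2L)
})

test_that("stoichiometry and PTM multiplicity disambiguate by prefix lookup", {
  x <- parse_entity_name("2xPPOX:FAD")
  expect_equal(x$parts[[1]]$stoichiometry, 2L)
  y <- parse_entity_name("2xPalmC-MyrG-p-S1177-NOS3(2-1203)")
  expect_s3_class(y, "cv_peptide")
  expect_equal(y$ptms[[1]]$multiplicity, 2L)
  expect_equal(name_entity(y)$text, "2xPalmC-MyrG-p-S1177-NOS3(2-1203)")
})

test_that("the parser accepts tolerated variants", {
  # en dash in coordinate ranges
  expect_equal(name_entity(parse_entity_name("CASP9(1–315)"))$text,
               "CASP9(1-315)")
  # spaces after commas
  expect_equal(name_entity(parse_entity_name("HRH2, HRH3, (HRH6)"))$text,
               "HRH2,HRH3,(HRH6)")
  # homomer words
  d <- parse_entity_name("PPOX dimer")
  expect_s3_class(d, "cv_assembly")
  expect_equal(name_entity(d)$text, "2xPPOX")
})

test_that("unknown tokens become opaque leaves, never failures", {
  m <- parse_entity_name("I(1,3,4,5,6)P5")
  expect_s3_class(m, "cv_molecule")
  x <- parse_entity_name("GRB2:some-unknown-ligand")
  expect_s3_class(x$parts[[2]]$member, "cv_molecule")
})

test_that("rejected strings report a character offset", {
  err <- tryCatch(parse_entity_name("GRB2:SOS1]"), condition = function(c) c)
  expect_s3_class(err, "cv_parse_error")
  expect_true(is.numeric(err$offset))
  expect_match(conditionMessage(err), "at character")
  expect_error(parse_entity_name("A1:B1,C1"), "mixed")
  expect_error(parse_entity_name("[GRB2:SOS1"), "unbalanced")
  expect_error(parse_entity_name("GRB2::SOS1"), "empty item")
  expect_error(parse_entity_name(""), "empty")
  expect_error(parse_entity_name("(HRH6,HRH8)"), "member")
})

test_that("ambiguity regression: bracket structure separates histories", {
  t1 <- parse_entity_name("[ABC1:ABC2]:[ABC3:ABC4]")
  t2 <- parse_entity_name("[ABC1:ABC2:ABC3]:ABC4")
  expect_false(identical(t1, t2))
  expect_false(identical(name_entity(t1)$text, name_entity(t2)$text))
})

test_that("round-trip holds over a seeded fixture corpus", {
  ents <- generate_fixture_entities(seed = 13, n = 250, max_depth = 3)
  for (e in ents) {
    s <- name_entity(e)$text
    e2 <- parse_entity_name(s)
    expect_identical(e2, e)
    expect_identical(name_entity(e2)$text, s)
  }
})

test_that("round-trip holds on an exhaustive small-tree enumeration", {
  trees <- enumerate_assembly_trees(canonical_leaves(), max_leaves = 3,
                                    max_depth = 2)
  expect_gt(length(trees), 100)
  for (tr in trees) {
    s <- name_entity(tr)$text
    expect_identical(parse_entity_name(s), tr)
  }
})
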