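test_that("coordinate suffix follows the chain-agreement rule", {
  # coordinates matching the single chain are unnecessary
  expect_equal(coordinate_suffix(pep("CASP9", 1, 416, 1, 416)), "")
  expect_equal(coordinate_suffix(pep("CASP9", 316, 416, 1, 416)),
               "(316-416)")
  expect_equal(coordinate_suffix(pep("ACAN", 17, NA, 17, 2415)), "(17-?)")
  # no chain feature: coordinates always added, even when they look default
  expect_equal(coordinate_suffix(pep("CASP9", 1, 416, chain_count = 0)),
               "(1-416)")
  expect_equal(coordinate_suffix(pep("CASP9", 1, 416, 1, 416,
                                     chain_count = 2)), "(1-416)")
})

test_that("phosphorylation prefixes order by coordinate, not subtype", {
  expect_equal(ptm_prefix(list(phos("Y", 139))), "p-Y139-")
  expect_equal(ptm_prefix(list(phos("S", 343), phos("Y", 150),
                               phos("T", 346))), "p-Y150,S343,T346-")
  expect_equal(ptm_prefix(list(phos("Y", 55), phos("S", 112),
                               phos("S", 121), phos("Y", 227))),
               "p-Y55,S112,S121,Y227-")
  expect_equal(ptm_prefix(list(phos("Y"))), "p-Y-")
  expect_equal(ptm_prefix(list(cv_ptm("MOD:00696"))), "p-")
  expect_equal(ptm_prefix(list()), "")
})

test_that("non-phospho prefixes precede the phospho block, ordered by site", {
  nos3 <- list(cv_ptm("MOD:00115", coordinate = 15),
               cv_ptm("MOD:00115", coordinate = 26),
               cv_ptm("MOD:00068", coordinate = 2),
               phos("S", 1177))
  expect_equal(ptm_prefix(nos3), "2xPalmC-MyrG-p-S1177-")
  # the merged "nx" form with unknown sites renders the same order
  expect_equal(ptm_prefix(list(cv_ptm("MOD:00115", multiplicity = 2),
                               cv_ptm("MOD:00068"), phos("S", 1177))),
               "2xPalmC-MyrG-p-S1177-")
  # coordinate-bearing prefix classes keep their site in the name
  expect_equal(ptm_prefix(list(cv_ptm("MOD:01148", coordinate = 48))),
               "Ub48-")
})

test_that("prefix rendering is canonical under input permutation", {
  base <- list(cv_ptm("MOD:00115", coordinate = 15),
               cv_ptm("MOD:00115", coordinate = 26),
               cv_ptm("MOD:00068", coordinate = 2),
               phos("S", 1177), phos("Y", 3))
  ref <- ptm_prefix(base)
  set.seed(42)
  for (i in 1:25) expect_equal(ptm_prefix(sample(base)), ref)
})

test_that("duplicate and malformed modification lists are rejected", {
  expect_error(ptm_prefix(list(phos("Y", 139), phos("Y", 139))), "twice")
  expect_error(ptm_prefix(list(cv_ptm("MOD:99999"))), "MOD:99999")
  # subtype letters are a phosphorylation-only device
  expect_error(ptm_prefix(list(cv_ptm("MOD:00115", subtype = "S"))),
               "phospho")
})

test_that("the printed peptide examples reproduce byte-exactly", {
  ex <- cv_worked_examples()$peptides
  expected <- c(casp9_precursor = "CASP9",
                casp9_large = "CASP9(1-315)",
                casp9_small = "CASP9(316-416)",
                acan_nterm = "ACAN(17-?)",
                dapp1_py = "p-Y139-DAPP1",
                wasf2_multi = "p-Y150,S343,T346-WASF2",
                spry2_multi = "p-Y55,S112,S121,Y227-SPRY2",
                gab2_py_unknown = "p-Y-GAB2",
                gli3_p_unknown = "p-GLI3",
                nos3_lipidated = "2xPalmC-MyrG-p-S1177-NOS3(2-1203)")
  for (nm in names(expected))
    expect_identical(name_peptide(ex[[nm]])$text, unname(expected[nm]))
})

test_that("exemption codes are detected in fixed priority order", {
  expect_equal(check_exemption(pep("TP53", disease_mutation = TRUE,
                                   hla = TRUE)), "DISEASE_MUTATION")
  expect_equal(check_exemption(pep("VEGFA", isoform_variant = 2)),
               "NONCANONICAL_ISOFORM")
  expect_equal(check_exemption(pep("COL1A1", cross_link = TRUE)),
               "COMPLEX_MODIFICATION")
  expect_equal(check_exemption(pep("INS", chain_count = 3)),
               "MULTI_OR_NO_CHAIN")
  expect_equal(check_exemption(pep("HLA1", hla = TRUE)), "HLA")
  expect_equal(check_exemption(pep("GRB2")), "NONE")
})

test_that("blocking exemptions stop naming unless overridden", {
  mut <- pep("TP53", disease_mutation = TRUE)
  err <- tryCatch(name_peptide(mut), condition = function(c) c)
  expect_s3_class(err, "cv_exemption_error")
  expect_equal(err$code, "DISEASE_MUTATION")
  expect_equal(name_peptide(mut, override = TRUE)$text, "TP53")
  # multi/no-chain means "manual coordinate choice", not "unnameable"
  expect_equal(name_peptide(pep("INS", 25, 54, chain_count = 3))$text,
               "INS(25-54)")
})

test_that("the Active prefix marks activated conformations", {
  expect_equal(name_peptide(pep("CASP9", active = TRUE))$text,
               "Active CASP9")
  expect_equal(name_peptide(pep("NOS3", ptms = list(phos("S", 1177)),
                                active = TRUE))$text,
               "Active p-S1177-NOS3")
})

test_that("equal peptides yield byte-identical names", {
  a <- pep("WASF2", ptms = list(phos("S", 343), phos("Y", 150)))
  b <- pep("WASF2", ptms = list(phos("Y", 150), phos("S", 343)))
  expect_identical(name_peptide(a)$text, name_peptide(b)$text)
})
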