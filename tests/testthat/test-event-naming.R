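test_that("GO molecular function terms map to verbs and templates", {
  expect_equal(verb_for_gomf("esterase activity"),
               list(verb = "hydrolyses", template = "catalyzes"))
  expect_equal(verb_for_gomf("alpha-1,2-mannosyltransferase activity"),
               list(verb = "transfers", template = "transfers"))
  # substring fallback covers the whole hydrolase family
  for (t in c("cGMP phosphodiesterase activity",
              "retinyl-palmitate esterase activity",
              "phospholipase A2 activity",
              "fumarylacetoacetase activity", "GTPase activity"))
    expect_equal(verb_for_gomf(t)$verb, "hydrolyses")
  # a miss is a defined result selecting the generic template
  expect_equal(verb_for_gomf("made-up activity"),
               list(verb = NA_character_, template = "catalyzes"))
  expect_equal(verb_for_gomf(NA)$template, "catalyzes")
})

test_that("reactions classify by the documented precedence", {
  grb2 <- pep("GRB2"); sos1 <- pep("SOS1")
  cplx <- cv_complex(grb2, sos1)
  expect_equal(classify_reaction(cv_reaction(list(grb2, sos1),
                                             list(cplx))), "BINDING")
  expect_equal(classify_reaction(cv_reaction(list(cplx),
                                             list(grb2, sos1))),
               "DISSOCIATION")
  expect_equal(classify_reaction(cv_reaction(
    list(cv_participant(grb2, "cytosol")),
    list(cv_participant(grb2, "nucleoplasm")))), "TRANSLOCATION")
  expect_equal(classify_reaction(cv_reaction(
    list(cv_participant(grb2, "cytosol")),
    list(cv_participant(grb2, "cytosol")))), "ACTIVATION")
  kin <- cv_reaction(list(cv_molecule("beta-D-fructose"),
                          cv_molecule("adenosine 5'-triphosphate")),
                     list(cv_molecule("beta-D-fructose 1-phosphate"),
                          cv_molecule("adenosine 5'-diphosphate")),
                     catalyst = pep("KHK"),
                     catalyst_gomf = "fructokinase activity")
  expect_equal(classify_reaction(kin), "CATALYSIS")
  poly <- cv_reaction(list(pep("FGA")), list(cv_complex(cv_part(pep("FGA"), 4))),
                      explicit_class = "polymerization")
  expect_equal(classify_reaction(poly), "POLYMERIZATION")
  # a same-size substrate swap with no catalyst is the default category
  expect_equal(classify_reaction(cv_reaction(list(pep("A1")),
                                             list(pep("B1")))),
               "TRANSFORMATION")
  # empty sides need an explicit class
  expect_error(cv_reaction(list(pep("A1")), list()), "input")
})

test_that("the printed reaction sentences reproduce byte-exactly", {
  ex <- cv_worked_examples()$reactions
  expected <- c(
    hlcs_biotinylation = "HLCS biotinylates ACACA",
    plb1_hydrolysis = "PLB1 hydrolyses RPALM to atROL",
    ptgds_isomerization = "PTGDS isomerizes PGH2 to PGD2",
    alg9_mannosyl_transfer =
      "ALG9 transfers Man to (GlcNAc)2 (Man)6 (PP-Dol)1 (to form (GlcNAc)2 (Man)7 (PP-Dol)1)",
    nmt_myristoyl_transfer =
      "NMT1,2 transfer MYS to GNAT1 (to form N-(C14:0)-GNAT1)",
    slc9a9_antiport =
      "SLC9A9 exchanges Na+ for H+ (across the late endosome membrane)",
    slc17a5_symport = "SLC17A5 cotransports Neu5Ac with H+",
    slc6a12_symport = "SLC6A12 cotransports GABA with 3Na+ and 2Cl-")
  for (nm in names(expected))
    expect_identical(name_reaction(ex[[nm]])$text, unname(expected[nm]))
})

test_that("template details: lists, translocation brackets, activation number", {
  tri <- cv_reaction(list(pep("A1"), pep("B1"), pep("C1")),
                     list(cv_complex(pep("A1"), pep("B1"), pep("C1"))))
  expect_equal(name_reaction(tri)$text, "A1 binds B1 and C1 forming A1:B1:C1")
  tr <- cv_reaction(list(cv_participant(pep("RBP1"), "cytosol",
                                        cell_type = "hepatocyte")),
                    list(cv_participant(pep("RBP1"), "cytosol",
                                        cell_type = "hepatic stellate cell")))
  expect_equal(name_reaction(tr)$text,
               paste0("RBP1 translocates from [cytosol of hepatocyte]",
                      " to [cytosol of hepatic stellate cell]"))
  act <- cv_reaction(list(cv_participant(pep("IRAK1"), "cytosol")),
                     list(cv_participant(pep("IRAK1"), "cytosol")))
  expect_equal(name_reaction(act)$text, "IRAK1 is activated")
  act2 <- cv_reaction(
    list(cv_participant(cv_set(pep("IRAK1"), pep("IRAK4")), "cytosol")),
    list(cv_participant(cv_set(pep("IRAK1"), pep("IRAK4")), "cytosol")))
  expect_match(name_reaction(act2)$text, " are activated$")
  tp <- cv_reaction(list(cv_participant(cv_molecule("hydron"),
                                        "extracellular region")),
                    list(cv_participant(cv_molecule("hydron"), "cytosol")),
                    catalyst = pep("SLC9A1"),
                    catalyst_gomf = "transmembrane transporter activity")
  expect_equal(name_reaction(tp)$text,
               "SLC9A1 transports H+ (from extracellular region to cytosol)")
})

test_that("regulation renders as a separate statement", {
  r <- cv_reaction(list(pep("GRB2"), pep("SOS1")),
                   list(cv_complex(pep("GRB2"), pep("SOS1"))),
                   regulator = pep("SPRY2"), regulator_sign = "negative")
  expect_equal(name_regulation(r)$text,
               "SPRY2 negatively regulates GRB2 binds SOS1 forming GRB2:SOS1")
  expect_error(name_regulation(cv_reaction(list(pep("A1")),
                                           list(pep("B1")))),
               "regulator")
})

test_that("catalyst-requiring templates refuse a missing catalyst", {
  r <- cv_reaction(list(pep("A1")), list(pep("B1")))
  expect_error(name_reaction(r, category = "CATALYSIS"), "catalyst")
  expect_error(name_reaction(r, category = "EXCHANGE"), "catalyst")
})

test_that("generated reactions classify as intended and are verb-searchable", {
  rxns <- generate_fixture_reactions(seed = 8, n = 150)
  signature <- c(TRANSFORMATION = " transforms to ", BINDING = " binds ",
                 DISSOCIATION = " dissociates to ",
                 POLYMERIZATION = " polymerize to ",
                 DEPOLYMERIZATION = " depolymerizes to ",
                 TRANSLOCATION = " translocates from ",
                 ACTIVATION = " activated",
                 TRANSFER = " transfers? ", TRANSPORT = " transports? ",
                 EXCHANGE = " exchanges? ", COTRANSPORT = " cotransports? ",
                 CATALYSIS = " (catalyzes|phosphorylates|hydrolyses) ")
  cats <- character(length(rxns))
  texts <- character(length(rxns))
  for (i in seq_along(rxns)) {
    r <- rxns[[i]]
    cats[i] <- classify_reaction(r)
    expect_equal(cats[i], attr(r, "intended"))
    texts[i] <- name_reaction(r, category = cats[i])$text
    expect_match(texts[i], signature[[cats[i]]])
  }
  # searching the corpus by signature retrieves exactly that category
  for (k in unique(cats)) {
    hits <- grepl(signature[[k]], texts)
    expect_identical(which(hits), which(cats == k))
  }
})

test_that("classifier agrees with the independent clause oracle on samples", {
  universe <- list(pep("GRB2"), pep("SOS1"),
                   cv_complex(pep("GRB2"), pep("SOS1")), cv_molecule("ATP"))
  rxns <- enumerate_reactions(universe, max_size = 2L)
  for (r in rxns) expect_identical(classify_reaction(r), classify_oracle(r))
})
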