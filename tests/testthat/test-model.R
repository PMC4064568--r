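test_that("type invariants are enforced at construction", {
  expect_error(cv_peptide("CASP9", start = 400, end = 300), "start")
  expect_error(cv_ptm("MOD:00048", coordinate = 5, multiplicity = 2),
               "multiplicity")
  expect_error(cv_assembly("complex", list()), "at least one part")
  expect_error(cv_complex(cv_part(pep("A1"), candidate = TRUE)),
               "candidate")
  expect_error(cv_assembly("candidate_set", list(cv_part(pep("A1")))),
               "candidate")
  expect_error(cv_reaction(list(), list(pep("A1"))), "input")
  expect_error(cv_molecule(""), "non-empty")
})

test_that("candidate parts canonicalize to the end of the part list", {
  a <- cv_assembly("candidate_set",
                   list(cv_part(pep("HRH6"), candidate = TRUE),
                        cv_part(pep("HRH2")),
                        cv_part(pep("HRH3"))))
  expect_equal(vapply(a$parts, function(p) p$member$gene_symbol, ""),
               c("HRH2", "HRH3", "HRH6"))
  expect_equal(name_assembly(a)$text, "HRH2,HRH3,(HRH6)")
})

test_that("fixture generation is a pure function of seed, n and depth", {
  a <- generate_fixture_entities(seed = 1, n = 50, max_depth = 2)
  b <- generate_fixture_entities(seed = 1, n = 50, max_depth = 2)
  expect_identical(a, b)
  c2 <- generate_fixture_entities(seed = 2, n = 50, max_depth = 2)
  expect_false(identical(a, c2))
  # the caller's RNG stream is untouched
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(generate_fixture_entities(1, 5, 1)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("depth 0 forces leaf entities", {
  ents <- generate_fixture_entities(seed = 1, n = 10, max_depth = 0)
  expect_length(ents, 10)
  expect_false(any(vapply(ents, inherits, TRUE, "cv_assembly")))
})

test_that("a moderate corpus exercises every grammar branch", {
  ents <- generate_fixture_entities(seed = 2, n = 200, max_depth = 3)
  all_nodes <- function(e) {
    if (!inherits(e, "cv_assembly")) return(list(e))
    c(list(e), unlist(lapply(e$parts, function(p) all_nodes(p$member)),
                      recursive = FALSE))
  }
  nodes <- unlist(lapply(ents, all_nodes), recursive = FALSE)
  kinds <- vapply(nodes, function(n)
    if (inherits(n, "cv_assembly")) n$kind else class(n)[1], "")
  expect_true("candidate_set" %in% kinds)
  expect_true("complex" %in% kinds)
  expect_true("defined_set" %in% kinds)
  expect_true("cv_molecule" %in% kinds)
  # stoichiometry > 1 somewhere
  stoich <- unlist(lapply(nodes, function(n)
    if (inherits(n, "cv_assembly"))
      vapply(n$parts, function(p) p$stoichiometry, 1L) else integer()))
  expect_true(any(stoich > 1L))
  # a phosphorylated peptide and a coordinate-suffixed fragment
  peps <- Filter(function(n) inherits(n, "cv_peptide"), nodes)
  has_phos <- vapply(peps, function(p)
    any(vapply(p$ptms, function(m) m$subtype != "none", TRUE)), TRUE)
  expect_true(any(has_phos))
  expect_true(any(vapply(peps, function(p)
    nzchar(coordinate_suffix(p)), TRUE)))
})

test_that("entity documents round-trip losslessly", {
  tmp <- withr::local_tempfile(fileext = ".json")
  # empty document
  write_entity_document(list(entities = list(), reactions = list()), tmp)
  doc <- read_entity_document(tmp)
  expect_length(doc$entities, 0)
  expect_length(doc$reactions, 0)
  # fixture corpus
  ents <- generate_fixture_entities(seed = 1, n = 50, max_depth = 2)
  write_entity_document(list(entities = ents), tmp)
  back <- read_entity_document(tmp)
  expect_identical(back$entities, ents)
  # reactions too
  rxns <- generate_fixture_reactions(seed = 3, n = 20)
  rxns <- lapply(rxns, function(r) { attr(r, "intended") <- NULL; r })
  write_entity_document(list(entities = list(), reactions = rxns), tmp)
  back <- read_entity_document(tmp)
  expect_identical(back$reactions, rxns)
})

test_that("invalid documents are rejected naming the offending field", {
  tmp <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "version": "1.0",
    "entities": [
      {"id": "e1", "type": "peptide", "gene_symbol": "CASP9",
       "start": 400, "end": 300}
    ]
  }', tmp)
  expect_error(read_entity_document(tmp), "entities\\[1\\]")
  writeLines('{"version": "1.0", "entities": [{"id": "e1"}]}', tmp)
  expect_error(read_entity_document(tmp), "type")
  writeLines('{"version": "1.0"}', tmp)
  expect_error(read_entity_document(tmp), "entities")
})

test_that("shared sub-complexes can be written by reference", {
  tmp <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "version": "1.0",
    "entities": [
      {"id": "g", "type": "peptide", "gene_symbol": "GRB2"},
      {"id": "s", "type": "peptide", "gene_symbol": "SOS1"},
      {"id": "c", "type": "complex",
       "parts": [{"entity": {"ref": "g"}}, {"entity": {"ref": "s"}}]}
    ]
  }', tmp)
  doc <- read_entity_document(tmp)
  expect_equal(name_entity(doc$entities[[3]])$text, "GRB2:SOS1")
})
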