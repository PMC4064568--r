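# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# symbol stems deliberately avoid PTM prefixes, table abbreviations and the
# [STY]<digits> shape that would collide with phosphorylation tokens
SYMBOL_STEMS <- c("ABC", "CASP", "CCR", "DAPP", "GAB", "GLI", "GRB", "HRH",
                  "ILR", "JAK", "KDR", "MAPK", "NOS", "PLC", "PPOX", "RAF",
                  "SOS", "SPRY", "VAV", "WASF")

gen_peptide <- function(tables) {
  sym <- paste0(sample(SYMBOL_STEMS, 1L), sample.int(60L, 1L))
  start <- NA_integer_; end <- NA_integer_
  if (runif(1) < 0.35) {  # cleaved fragment: coordinate suffix form
    start <- sample.int(800L, 1L)
    end <- if (runif(1) < 0.15) NA_integer_ else start + sample(5:900, 1L)
  }
  nptm <- sample(0:3, 1L, prob = c(0.45, 0.30, 0.15, 0.10))
  ptms <- list()
  if (nptm > 0L) {
    used_coords <- integer()
    np_rows <- tables$mod_prefixes[!tables$mod_prefixes$phospho, ,
                                   drop = FALSE]
    used_prefixes <- character()
    for (k in seq_len(nptm)) {
      if (runif(1) < 0.5) {  # phosphorylation
        subtype <- sample(c("S", "T", "Y"), 1L)
        coord <- if (runif(1) < 0.85) {
          cc <- sample.int(1200L, 1L)
          while (cc %in% used_coords) cc <- sample.int(1200L, 1L)
          used_coords <- c(used_coords, cc)
          cc
        } else NA_integer_
        ptms[[length(ptms) + 1L]] <-
          cv_ptm(phospho_id_for_subtype(subtype), subtype = subtype,
                 coordinate = coord)
      } else {
        avail <- setdiff(np_rows$prefix, used_prefixes)
        if (!length(avail)) next
        pref <- sample(avail, 1L)
        used_prefixes <- c(used_prefixes, pref)
        row <- np_rows[match(pref, np_rows$prefix), ]
        if (row$includes_coordinate && runif(1) < 0.8) {
          cc <- sample.int(1200L, 1L)
          while (cc %in% used_coords) cc <- sample.int(1200L, 1L)
          used_coords <- c(used_coords, cc)
          ptms[[length(ptms) + 1L]] <- cv_ptm(row$psimod_id, coordinate = cc)
        } else {
          ptms[[length(ptms) + 1L]] <-
            cv_ptm(row$psimod_id,
                   multiplicity = sample(1:3, 1L, prob = c(0.7, 0.2, 0.1)))
        }
      }
    }
    # drop phospho combinations the grammar cannot write unambiguously
    blank <- vapply(ptms, function(p) p$subtype == "none" &&
                      is.na(p$coordinate), TRUE)
    if (sum(blank) && length(ptms) > 1L) ptms <- ptms[!blank]
    ptms <- canonicalize_ptms(ptms, tables)
  }
  cv_peptide(sym, start = start, end = end, chain_count = 1L, ptms = ptms,
             active = runif(1) < 0.05)
}

gen_molecule <- function(tables) {
  cv_molecule(sample(tables$molecule_abbrev$abbreviation, 1L))
}

gen_leaf <- function(tables) {
  if (runif(1) < 0.65) gen_peptide(tables) else gen_molecule(tables)
}

gen_node <- function(depth, tables) {
  if (depth > 0L && runif(1) < 0.55) gen_assembly(depth, tables)
  else gen_leaf(tables)
}

gen_assembly <- function(depth, tables) {
  kind <- sample(c("complex", "defined_set", "candidate_set"), 1L,
                 prob = c(0.55, 0.30, 0.15))
  k <- sample(2:4, 1L)
  members <- lapply(seq_len(k), function(i) gen_node(depth - 1L, tables))
  parts <- lapply(members, function(m) {
    ptm_free <- !inherits(m, "cv_peptide") || length(m$ptms) == 0L
    stoich <- if (ptm_free && runif(1) < 0.20) sample(2:3, 1L) else 1L
    cv_part(m, stoich)
  })
  if (kind == "candidate_set") {
    nc <- sample.int(k - 1L, 1L)
    for (i in (k - nc + 1L):k)
      parts[[i]] <- cv_part(parts[[i]]$member, parts[[i]]$stoichiometry,
                            candidate = TRUE)
  }
  cv_assembly(kind, parts)
}

#' Generate synthetic entity trees for property testing
#'
#' A deterministic corpus generator exercising every branch of the naming
#' grammar: bare peptides, coordinate-suffixed cleavage fragments, every
#' PTM prefix class in the shipped table, nested complexes, defined and
#' candidate sets, and stoichiometry greater than one. Trees are emitted in
#' canonical form (PTM lists render-ordered, molecules drawn from the
#' abbreviation column, chain coordinates unset), so parsing a generated
#' name reproduces the tree exactly.
#'
#' @param seed Integer seed; output is a pure function of
#'   `(seed, n, max_depth)` and the caller's RNG stream is left untouched.
#' @param n Number of entities to generate.
#' @param max_depth Maximum assembly nesting depth; 0 forces leaves.
#' @param tables Lookup tables from [cv_tables()].
#' @return A list of `n` entities.
#' @export
#' @examples
#' ents <- generate_fixture_entities(seed = 1, n = 5, max_depth = 2)
#' vapply(ents, function(e) name_entity(e)$text, "")
generate_fixture_entities <- function(seed, n, max_depth,
                                      tables = default_cv_tables()) {
  stopifnot(n > 0, max_depth >= 0)
  with_seed(seed, function()
    lapply(seq_len(n), function(i) gen_node(max_depth, tables)))
}

#' Generate synthetic reactions for property testing
#'
#' Builds reactions of every event category (the intended category is
#' attached as attribute `"intended"` for classifier checks), over small
#' generated entities, with occasional regulators.
#'
#' @inheritParams generate_fixture_entities
#' @param n Number of reactions.
#' @return A list of `cv_reaction` objects.
#' @export
generate_fixture_reactions <- function(seed, n,
                                       tables = default_cv_tables()) {
  stopifnot(n > 0)
  with_seed(seed, function() lapply(seq_len(n), function(i) {
    a <- gen_leaf(tables)
    # b must be a different entity, or substrate-swap patterns degenerate
    b <- gen_leaf(tables)
    while (identical(name_entity(b, tables)$text,
                     name_entity(a, tables)$text)) b <- gen_leaf(tables)
    pep <- gen_peptide(tables)
    kind <- sample(c("BINDING", "DISSOCIATION", "TRANSLOCATION",
                     "ACTIVATION", "CATALYSIS", "TRANSFER", "TRANSPORT",
                     "EXCHANGE", "COTRANSPORT", "TRANSFORMATION",
                     "POLYMERIZATION", "DEPOLYMERIZATION"), 1L)
    rxn <- switch(kind,
      BINDING = cv_reaction(list(a, b), list(cv_complex(a, b))),
      DISSOCIATION = cv_reaction(list(cv_complex(a, b)), list(a, b)),
      TRANSLOCATION = cv_reaction(
        list(cv_participant(a, "cytosol")),
        list(cv_participant(a, "nucleoplasm"))),
      ACTIVATION = cv_reaction(list(cv_participant(a, "cytosol")),
                               list(cv_participant(a, "cytosol"))),
      CATALYSIS = cv_reaction(list(a), list(b), catalyst = pep,
                              catalyst_gomf = sample(
                                c("protein tyrosine kinase activity",
                                  "esterase activity", NA), 1L)),
      TRANSFER = cv_reaction(list(a), list(b), catalyst = pep,
                             catalyst_gomf =
                               "alpha-1,2-mannosyltransferase activity",
                             transferred = gen_molecule(tables)),
      TRANSPORT = cv_reaction(
        list(cv_participant(a, "extracellular region")),
        list(cv_participant(a, "cytosol")), catalyst = pep,
        catalyst_gomf = "transmembrane transporter activity"),
      EXCHANGE = cv_reaction(
        list(cv_participant(a, "cytosol"), cv_participant(b, "lumen")),
        list(cv_participant(a, "lumen"), cv_participant(b, "cytosol")),
        catalyst = pep, catalyst_gomf = "sodium:proton antiporter activity",
        membrane = if (runif(1) < 0.5) "late endosome" else NA),
      COTRANSPORT = cv_reaction(
        list(cv_participant(a, "extracellular region"),
             cv_participant(b, "extracellular region",
                            count = sample(1:3, 1L))),
        list(cv_participant(a, "cytosol"), cv_participant(b, "cytosol")),
        catalyst = pep,
        catalyst_gomf = "sialic acid:proton symporter activity"),
      TRANSFORMATION = cv_reaction(list(a), list(b)),
      POLYMERIZATION = cv_reaction(list(a), list(cv_complex(
        cv_part(a, 4L))), explicit_class = "polymerization"),
      DEPOLYMERIZATION = cv_reaction(list(cv_complex(cv_part(a, 4L))),
                                     list(a),
                                     explicit_class = "depolymerization"))
    if (runif(1) < 0.15) {
      rxn$regulator <- gen_peptide(tables)
      rxn$regulator_sign <- sample(c("positive", "negative"), 1L)
    }
    attr(rxn, "intended") <- kind
    rxn
  }))
}

#' Exhaustively enumerate small assembly trees
#'
#' All assemblies buildable over ordered, non-repeating selections from
#' `leaves`, with at most `max_leaves` leaves and nesting depth at most
#' `max_depth`, every node having at least two parts, each node taking each
#' of the three kinds (candidate sets with every feasible trailing
#' candidate count). Used for exhaustive round-trip verification.
#'
#' @param leaves List of leaf entities (canonical form).
#' @param max_leaves Maximum number of leaves per tree.
#' @param max_depth Maximum nesting depth (a leaf has depth 0).
#' @return A list of entities (leaves and assemblies).
#' @export
enumerate_assembly_trees <- function(leaves, max_leaves = 4L,
                                     max_depth = 2L) {
  compositions <- function(k) {
    if (k < 2L) return(list())
    out <- list()
    recurse <- function(remaining, acc) {
      if (remaining == 0L) {
        if (length(acc) >= 2L) out[[length(out) + 1L]] <<- acc
        return()
      }
      for (take in seq_len(remaining))
        recurse(remaining - take, c(acc, take))
    }
    recurse(k, integer())
    out
  }
  node_variants <- function(parts_list) {
    k <- length(parts_list)
    parts <- lapply(parts_list, cv_part)
    out <- list(cv_assembly("complex", parts),
                cv_assembly("defined_set", parts))
    for (nc in seq_len(k - 1L)) {
      cp <- parts
      for (i in (k - nc + 1L):k)
        cp[[i]] <- cv_part(cp[[i]]$member, candidate = TRUE)
      out[[length(out) + 1L]] <- cv_assembly("candidate_set", cp)
    }
    out
  }
  trees_for <- function(seq_leaves, depth) {
    if (length(seq_leaves) == 1L) return(list(seq_leaves[[1]]))
    if (depth < 1L) return(list())
    out <- list()
    for (comp in compositions(length(seq_leaves))) {
      idx <- cumsum(c(0L, comp))
      block_trees <- lapply(seq_along(comp), function(j)
        trees_for(seq_leaves[(idx[j] + 1L):idx[j + 1L]], depth - 1L))
      if (any(lengths(block_trees) == 0L)) next
      grid <- do.call(expand.grid,
                      c(lapply(block_trees, seq_along),
                        list(KEEP.OUT.ATTRS = FALSE)))
      for (r in seq_len(nrow(grid))) {
        parts_list <- lapply(seq_along(comp), function(j)
          block_trees[[j]][[grid[r, j]]])
        out <- c(out, node_variants(parts_list))
      }
    }
    out
  }
  sequences <- function(k) {
    if (k == 1L) return(lapply(seq_along(leaves), function(i) list(leaves[[i]])))
    shorter <- sequences(k - 1L)
    out <- list()
    for (s in shorter) {
      used <- vapply(s, function(e) name_entity(e)$text, "")
      for (i in seq_along(leaves)) {
        nm <- name_entity(leaves[[i]])$text
        if (!(nm %in% used)) out[[length(out) + 1L]] <- c(s, list(leaves[[i]]))
      }
    }
    out
  }
  out <- list()
  for (k in seq_len(min(max_leaves, length(leaves))))
    for (s in sequences(k))
      out <- c(out, trees_for(s, max_depth))
  out
}

#' Exhaustively enumerate small reactions over an entity universe
#'
#' Input and output multisets of size 1 to `max_size` drawn (with
#' repetition) from `universe`, crossed with a set of catalyst options (one
#' per phrase template plus none) and with/without an output compartment
#' change. Used for exhaustive classifier verification.
#'
#' @param universe List of entities; include at least one complex of two
#'   others so the component-containment clauses are exercised.
#' @param max_size Maximum multiset size per side.
#' @param compartments Length-2 character vector: the input compartment and
#'   the changed output compartment.
#' @return A list of `cv_reaction` objects.
#' @export
enumerate_reactions <- function(universe, max_size = 3L,
                                compartments = c("cytosol",
                                                 "nucleoplasm")) {
  msets <- unique(unlist(lapply(seq_len(max_size), function(k) {
    g <- do.call(expand.grid, rep(list(seq_along(universe)), k))
    lapply(seq_len(nrow(g)), function(i) sort(as.integer(g[i, ])))
  }), recursive = FALSE))
  catalysts <- list(
    list(e = NULL, g = NA_character_),
    list(e = cv_peptide("ENZ1"), g = "uncharacterized activity"),
    list(e = cv_peptide("ENZ2"),
         g = "alpha-1,2-mannosyltransferase activity"),
    list(e = cv_peptide("ENZ3"), g = "transmembrane transporter activity"),
    list(e = cv_peptide("ENZ4"), g = "sodium:proton antiporter activity"),
    list(e = cv_peptide("ENZ5"), g = "sialic acid:proton symporter activity"))
  out <- vector("list",
                length(msets)^2 * length(catalysts) * 2L)
  n <- 0L
  for (ins in msets) for (outs in msets)
    for (ct in catalysts) for (moved in c(FALSE, TRUE)) {
      rin <- lapply(ins, function(i)
        cv_participant(universe[[i]], compartments[1]))
      rout <- lapply(outs, function(i)
        cv_participant(universe[[i]],
                       if (moved) compartments[2] else compartments[1]))
      n <- n + 1L
      out[[n]] <- cv_reaction(rin, rout, catalyst = ct$e,
                              catalyst_gomf = ct$g)
    }
  out[seq_len(n)]
}
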