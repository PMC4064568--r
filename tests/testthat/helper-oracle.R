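# Independent clause-by-clause classification oracle. Each precedence
# clause is an independent predicate over the reaction; the oracle picks
# the first that fires. Component containment is implemented by its own
# flattening (iterative stack walk over part lists), not by the package's
# recursive test.

oracle_flatten_names <- function(entity, tables) {
  out <- character()
  stack <- list(entity)
  while (length(stack)) {
    e <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (inherits(e, "cv_assembly")) {
      for (p in e$parts) {
        out <- c(out, name_entity(p$member, tables, override = TRUE)$text)
        stack[[length(stack) + 1L]] <- p$member
      }
    }
  }
  out
}

classify_oracle <- function(rxn, tables = default_cv_tables()) {
  nm <- function(e) name_entity(e, tables, override = TRUE)$text
  exp_names <- function(ps) unlist(lapply(ps, function(p)
    rep(nm(p$entity), p$count)))
  exp_pairs <- function(ps) unlist(lapply(ps, function(p)
    rep(paste(nm(p$entity), p$compartment, p$cell_type, sep = "\r"),
        p$count)))

  clause_poly <- function() rxn$explicit_class == "polymerization"
  clause_depoly <- function() rxn$explicit_class == "depolymerization"
  tmpl <- if (!is.null(rxn$catalyst))
    verb_for_gomf(rxn$catalyst_gomf, tables)$template else NA_character_
  clause_exchange <- function() !is.null(rxn$catalyst) && tmpl == "exchanges"
  clause_cotransport <- function() !is.null(rxn$catalyst) &&
    tmpl == "cotransports"
  clause_transport <- function() !is.null(rxn$catalyst) &&
    tmpl == "transports"
  same_entities <- identical(sort(exp_names(rxn$inputs)),
                             sort(exp_names(rxn$outputs)))
  same_pairs <- identical(sort(exp_pairs(rxn$inputs)),
                          sort(exp_pairs(rxn$outputs)))
  clause_transloc <- function() is.null(rxn$catalyst) && same_entities &&
    !same_pairs
  clause_transfer <- function() !is.null(rxn$catalyst) && tmpl == "transfers"
  clause_catalysis <- function() !is.null(rxn$catalyst)
  n_in <- length(exp_names(rxn$inputs))
  n_out <- length(exp_names(rxn$outputs))
  in_names <- vapply(rxn$inputs, function(p) nm(p$entity), "")
  out_names <- vapply(rxn$outputs, function(p) nm(p$entity), "")
  out_flat <- lapply(rxn$outputs, function(p)
    oracle_flatten_names(p$entity, tables))
  in_flat <- lapply(rxn$inputs, function(p)
    oracle_flatten_names(p$entity, tables))
  clause_binding <- function() n_in > n_out &&
    any(vapply(in_names, function(x)
      any(vapply(out_flat, function(f) x %in% f, TRUE)), TRUE))
  clause_dissoc <- function() n_out > n_in &&
    any(vapply(out_names, function(x)
      any(vapply(in_flat, function(f) x %in% f, TRUE)), TRUE))
  clause_activation <- function() same_entities && same_pairs

  if (clause_poly()) return("POLYMERIZATION")
  if (clause_depoly()) return("DEPOLYMERIZATION")
  if (clause_exchange()) return("EXCHANGE")
  if (clause_cotransport()) return("COTRANSPORT")
  if (clause_transport()) return("TRANSPORT")
  if (clause_transloc()) return("TRANSLOCATION")
  if (clause_transfer()) return("TRANSFER")
  if (clause_catalysis()) return("CATALYSIS")
  if (clause_binding()) return("BINDING")
  if (clause_dissoc()) return("DISSOCIATION")
  if (clause_activation()) return("ACTIVATION")
  "TRANSFORMATION"
}
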