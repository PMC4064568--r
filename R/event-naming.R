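EVENT_CATEGORIES <- c("TRANSFORMATION", "BINDING", "DISSOCIATION",
                      "POLYMERIZATION", "DEPOLYMERIZATION", "CATALYSIS",
                      "TRANSFER", "TRANSLOCATION", "TRANSPORT", "EXCHANGE",
                      "COTRANSPORT", "ACTIVATION")

# GO molecular function terms containing any of these words all describe
# hydrolysis reactions
HYDROLYSIS_TRIGGERS <- c("phosphodiesterase", "esterase", "lipase",
                         "fumarylacetoacetase", "GTPase")

#' Derive the naming verb for a GO molecular function term
#'
#' Exact (case-insensitive) match against the `gomf_verbs` table first, then
#' a substring fallback for the hydrolase family (any term containing
#' "phosphodiesterase", "esterase", "lipase", "fumarylacetoacetase" or
#' "GTPase" maps to "hydrolyses"). A miss is a defined result: the verb is
#' `NA` and the generic `catalyzes` template applies.
#'
#' @param term GO molecular function term label (or `NA`).
#' @param tables Lookup tables from [cv_tables()].
#' @return `list(verb =, template =)`.
#' @export
#' @examples
#' verb_for_gomf("esterase activity")
verb_for_gomf <- function(term, tables = default_cv_tables()) {
  if (is.null(term) || is.na(term))
    return(list(verb = NA_character_, template = "catalyzes"))
  i <- match(tolower(trimws(term)), tolower(tables$gomf_verbs$gomf_term))
  if (!is.na(i))
    return(list(verb = tables$gomf_verbs$verb[i],
                template = tables$gomf_verbs$template[i]))
  hit <- any(vapply(HYDROLYSIS_TRIGGERS,
                    function(t) grepl(t, term, ignore.case = TRUE), TRUE))
  if (hit) return(list(verb = "hydrolyses", template = "catalyzes"))
  list(verb = NA_character_, template = "catalyzes")
}

entity_name_text <- function(entity, tables) {
  name_entity(entity, tables, override = TRUE)$text
}

# participant names expanded by stoichiometric count
expanded_names <- function(ps, tables) {
  unlist(lapply(ps, function(p)
    rep(entity_name_text(p$entity, tables), p$count)))
}

expanded_pairs <- function(ps, tables) {
  unlist(lapply(ps, function(p)
    rep(paste0(entity_name_text(p$entity, tables), "@",
               p$compartment %||% NA, "|", p$cell_type),
        p$count)))
}

# is target_name the name of a component of container, at any depth?
contains_component <- function(container, target_name, tables) {
  if (!inherits(container, "cv_assembly")) return(FALSE)
  for (part in container$parts) {
    if (entity_name_text(part$member, tables) == target_name) return(TRUE)
    if (inherits(part$member, "cv_assembly") &&
        contains_component(part$member, target_name, tables)) return(TRUE)
  }
  FALSE
}

#' Classify a reaction into its event category
#'
#' Applies a fixed precedence so that the most specific, attribute-gated
#' classes win: (1) the explicit polymerization/depolymerization class; (2)
#' a catalyst whose GO molecular function maps to the exchange, cotransport
#' or transport template; (3) unchanged entities changing compartment with
#' no catalyst — translocation; (4) any other catalyst — transfer when the
#' transferase template applies, otherwise catalysis; (5) more inputs than
#' outputs with an input becoming a component of an output — binding (the
#' containment test doubles as a stoichiometric-balance check); (6) the
#' mirror case — dissociation; (7) identical entities and compartments —
#' activation; (8) otherwise the default, transformation.
#'
#' @param rxn A [cv_reaction()].
#' @param tables Lookup tables from [cv_tables()].
#' @return A category string: one of TRANSFORMATION, BINDING, DISSOCIATION,
#'   POLYMERIZATION, DEPOLYMERIZATION, CATALYSIS, TRANSFER, TRANSLOCATION,
#'   TRANSPORT, EXCHANGE, COTRANSPORT, ACTIVATION.
#' @export
classify_reaction <- function(rxn, tables = default_cv_tables()) {
  if (!inherits(rxn, "cv_reaction"))
    stop("rxn must be a cv_reaction", call. = FALSE)
  if (rxn$explicit_class == "polymerization") return("POLYMERIZATION")
  if (rxn$explicit_class == "depolymerization") return("DEPOLYMERIZATION")
  if (!length(rxn$inputs) || !length(rxn$outputs))
    stop("a reaction with no explicit class needs at least one input and one output",
         call. = FALSE)

  has_cat <- !is.null(rxn$catalyst)
  tmpl <- if (has_cat) verb_for_gomf(rxn$catalyst_gomf, tables)$template
          else NA_character_
  if (has_cat && tmpl == "exchanges") return("EXCHANGE")
  if (has_cat && tmpl == "cotransports") return("COTRANSPORT")
  if (has_cat && tmpl == "transports") return("TRANSPORT")

  in_names <- expanded_names(rxn$inputs, tables)
  out_names <- expanded_names(rxn$outputs, tables)
  same_entities <- identical(sort(in_names), sort(out_names))
  same_pairs <- identical(sort(expanded_pairs(rxn$inputs, tables)),
                          sort(expanded_pairs(rxn$outputs, tables)))
  if (!has_cat && same_entities && !same_pairs) return("TRANSLOCATION")
  if (has_cat) return(if (tmpl == "transfers") "TRANSFER" else "CATALYSIS")

  n_in <- length(in_names); n_out <- length(out_names)
  if (n_in > n_out) {
    bound <- any(vapply(rxn$inputs, function(p) {
      nm <- entity_name_text(p$entity, tables)
      any(vapply(rxn$outputs, function(q)
        contains_component(q$entity, nm, tables), TRUE))
    }, TRUE))
    if (bound) return("BINDING")
  }
  if (n_out > n_in) {
    freed <- any(vapply(rxn$outputs, function(q) {
      nm <- entity_name_text(q$entity, tables)
      any(vapply(rxn$inputs, function(p)
        contains_component(p$entity, nm, tables), TRUE))
    }, TRUE))
    if (freed) return("DISSOCIATION")
  }
  if (same_entities && same_pairs) return("ACTIVATION")
  "TRANSFORMATION"
}

join_and <- function(xs) {
  n <- length(xs)
  if (n == 0L) stop("nothing to join", call. = FALSE)
  if (n == 1L) return(xs)
  if (n == 2L) return(paste(xs, collapse = " and "))
  paste0(paste(xs[-n], collapse = ", "), " and ", xs[n])
}

# a set catalyst takes a diagram short label and a plural verb
catalyst_is_set <- function(entity) {
  inherits(entity, "cv_assembly") &&
    entity$kind %in% c("defined_set", "candidate_set")
}

catalyst_display <- function(entity, tables) {
  if (catalyst_is_set(entity)) shorten_label(entity, tables)
  else entity_name_text(entity, tables)
}

pluralize_verb <- function(verb, plural) {
  if (plural) sub("s$", "", verb) else verb
}

compartment_label <- function(p) {
  if (is.na(p$cell_type)) p$compartment
  else paste0(p$compartment, " of ", p$cell_type)
}

# gene-symbol "core" used to decide whether a product is just the modified
# form of a substrate (in which case the product clause is left out, as in
# "HLCS biotinylates ACACA")
entity_core <- function(entity, tables) {
  if (inherits(entity, "cv_peptide")) entity$gene_symbol
  else entity_name_text(entity, tables)
}

#' Render the CV name of a reaction
#'
#' Fills the category's phrase template with the participants' CV names.
#' Verbs are lower case (the vocabulary is case-insensitive) and agree in
#' number with a set catalyst ("NMT1,2 transfer ..."); entity lists are
#' joined as "a, b and c"; optional clauses (compartments, membranes, the
#' "to form" product of a transferase) appear when the data carries them,
#' and the product list of a catalysis is left out when every product is
#' simply the modified form of a substrate.
#'
#' @param rxn A [cv_reaction()].
#' @param tables Lookup tables from [cv_tables()].
#' @param category Event category; defaults to [classify_reaction()].
#' @return A [cv_name()] in the `"reactions"` namespace.
#' @export
name_reaction <- function(rxn, tables = default_cv_tables(),
                          category = classify_reaction(rxn, tables)) {
  in_names <- if (length(rxn$inputs)) expanded_names(rxn$inputs, tables)
              else character()
  out_names <- if (length(rxn$outputs)) expanded_names(rxn$outputs, tables)
               else character()
  need_catalyst <- category %in% c("CATALYSIS", "TRANSFER", "TRANSPORT",
                                   "EXCHANGE", "COTRANSPORT")
  if (need_catalyst && is.null(rxn$catalyst))
    stop(sprintf("category %s requires a catalyst", category), call. = FALSE)
  cat_disp <- if (!is.null(rxn$catalyst))
    catalyst_display(rxn$catalyst, tables) else NULL
  plural <- !is.null(rxn$catalyst) && catalyst_is_set(rxn$catalyst)

  text <- switch(category,
    TRANSFORMATION = paste0(join_and(in_names), " transforms to ",
                            join_and(out_names)),
    BINDING = paste0(in_names[1], " binds ", join_and(in_names[-1]),
                     " forming ", join_and(out_names)),
    DISSOCIATION = paste0(join_and(in_names), " dissociates to ",
                          join_and(out_names)),
    POLYMERIZATION = paste0(join_and(in_names), " polymerize to ",
                            join_and(out_names)),
    DEPOLYMERIZATION = paste0(join_and(in_names), " depolymerizes to ",
                              join_and(out_names)),
    TRANSLOCATION = {
      cin <- compartment_label(rxn$inputs[[1]])
      cout <- compartment_label(rxn$outputs[[1]])
      paste0(join_and(unique(in_names)), " translocates from [", cin,
             "] to [", cout, "]")
    },
    ACTIVATION = {
      subj <- unique(in_names)
      many <- length(subj) > 1L ||
        any(vapply(rxn$inputs, function(p) catalyst_is_set(p$entity), TRUE))
      paste0(join_and(subj), if (many) " are activated" else " is activated")
    },
    CATALYSIS = {
      vt <- verb_for_gomf(rxn$catalyst_gomf, tables)
      verb <- pluralize_verb(if (is.na(vt$verb)) "catalyzes" else vt$verb,
                             plural)
      in_cores <- vapply(rxn$inputs, function(p)
        entity_core(p$entity, tables), "")
      implied <- all(vapply(rxn$outputs, function(q)
        entity_core(q$entity, tables) %in% in_cores, TRUE))
      paste0(cat_disp, " ", verb, " ", join_and(in_names),
             if (!implied) paste0(" to ", join_and(out_names)))
    },
    TRANSFER = {
      if (is.null(rxn$transferred))
        stop("a transferase event needs the transferred entity",
             call. = FALSE)
      y <- entity_name_text(rxn$transferred, tables)
      a1 <- in_names[1]
      a2 <- if (length(out_names)) out_names[1] else NA_character_
      paste0(cat_disp, " ", pluralize_verb("transfers", plural), " ", y,
             " to ", a1,
             if (!is.na(a2) && a2 != a1) paste0(" (to form ", a2, ")"))
    },
    TRANSPORT = {
      cin <- compartment_label(rxn$inputs[[1]])
      cout <- compartment_label(rxn$outputs[[1]])
      paste0(cat_disp, " ", pluralize_verb("transports", plural), " ",
             join_and(unique(in_names)),
             if (!is.na(cin) && !is.na(cout) && cin != cout)
               paste0(" (from ", cin, " to ", cout, ")"))
    },
    EXCHANGE = {
      a <- in_names[1]
      b <- if (length(in_names) >= 2L) in_names[2] else out_names[1]
      paste0(cat_disp, " ", pluralize_verb("exchanges", plural), " ", a,
             " for ", b,
             if (!is.na(rxn$membrane))
               paste0(" (across the ", rxn$membrane, " membrane)"))
    },
    COTRANSPORT = {
      if (length(rxn$inputs) < 2L)
        stop("a cotransport event needs at least two inputs", call. = FALSE)
      disp <- vapply(rxn$inputs, function(p) {
        paste0(if (p$count > 1L) p$count, entity_name_text(p$entity, tables))
      }, "")
      paste0(cat_disp, " ", pluralize_verb("cotransports", plural), " ",
             disp[1], " with ", join_and(disp[-1]))
    },
    stop(sprintf("unknown event category '%s'", category), call. = FALSE))
  cv_name(text, source = rxn, namespace = "reactions")
}

#' Render the regulation statement of a reaction
#'
#' Regulation attaches to an event additively; it is rendered as a separate
#' statement: `"<regulator> positively|negatively regulates <event name>"`.
#'
#' @param rxn A [cv_reaction()] with a regulator.
#' @param tables Lookup tables from [cv_tables()].
#' @param event_name Name of the regulated event; defaults to the
#'   reaction's own CV name.
#' @return A [cv_name()] in the `"reactions"` namespace.
#' @export
name_regulation <- function(rxn, tables = default_cv_tables(),
                            event_name = name_reaction(rxn, tables)$text) {
  if (is.null(rxn$regulator))
    stop("reaction has no regulator", call. = FALSE)
  word <- if (rxn$regulator_sign == "positive") "positively" else "negatively"
  cv_name(paste0(entity_name_text(rxn$regulator, tables), " ", word,
                 " regulates ", event_name),
          source = rxn, namespace = "reactions")
}
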