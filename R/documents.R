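# JSON entity-document serialization. One top-level object with "entities"
# and "reactions" arrays; top-level entities carry local ids and may be
# referenced from parts/participants as {"ref": id}, so shared sub-complexes
# need only be written once. Coordinates serialize as integers with "?" for
# unknown, mirroring the printed "(17-?)" convention.

DOCUMENT_VERSION <- "1.0"

ser_coord <- function(x) if (is.na(x)) "?" else x

ser_opt <- function(x) if (is.null(x) || (length(x) == 1L && is.na(x))) NULL else x

entity_to_list <- function(e) {
  alias <- attr(e, "alias", exact = TRUE)
  base <- if (inherits(e, "cv_peptide")) {
    list(type = "peptide", gene_symbol = e$gene_symbol,
         start = ser_coord(e$start), end = ser_coord(e$end),
         chain_start = ser_opt(e$chain_start),
         chain_end = ser_opt(e$chain_end),
         chain_count = e$chain_count,
         ptms = lapply(e$ptms, function(p) list(
           psimod_id = p$psimod_id,
           subtype = if (p[["subtype"]] == "none") NULL else p[["subtype"]],
           coordinate = ser_coord(p[["coordinate"]]),
           multiplicity = p[["multiplicity"]])),
         isoform_variant = e$isoform_variant, active = e$active,
         disease_mutation = e$disease_mutation, cross_link = e$cross_link,
         hla = e$hla)
  } else if (inherits(e, "cv_molecule")) {
    list(type = "molecule", reference_name = e$reference_name,
         chebi_id = ser_opt(e$chebi_id))
  } else if (inherits(e, "cv_assembly")) {
    list(type = e$kind,
         functional_label = ser_opt(e$functional_label),
         parts = lapply(e$parts, function(p) list(
           entity = entity_to_list(p$member),
           stoichiometry = p[["stoichiometry"]], candidate = p[["candidate"]])))
  } else stop("not a CV entity", call. = FALSE)
  if (!is.null(alias)) base$name <- alias
  base
}

participant_to_list <- function(p) {
  list(entity = entity_to_list(p$entity),
       compartment = ser_opt(p[["compartment"]]), count = p[["count"]],
       cell_type = ser_opt(p[["cell_type"]]))
}

reaction_to_list <- function(r) {
  alias <- attr(r, "alias", exact = TRUE)
  out <- list(inputs = lapply(r$inputs, participant_to_list),
              outputs = lapply(r$outputs, participant_to_list),
              catalyst = if (!is.null(r$catalyst))
                entity_to_list(r$catalyst),
              catalyst_gomf = ser_opt(r$catalyst_gomf),
              regulator = if (!is.null(r$regulator)) list(
                entity = entity_to_list(r$regulator),
                sign = r$regulator_sign),
              explicit_class = if (r$explicit_class != "none")
                r$explicit_class,
              transferred = if (!is.null(r$transferred))
                entity_to_list(r$transferred),
              membrane = ser_opt(r$membrane))
  if (!is.null(alias)) out$name <- alias
  out[!vapply(out, is.null, TRUE)]
}

schema_error <- function(field, msg) {
  stop(sprintf("invalid entity document: %s (%s)", msg, field),
       call. = FALSE)
}

req <- function(x, field, nm) {
  if (is.null(x[[nm]])) schema_error(paste0(field, ".", nm),
                                     "missing required field")
  x[[nm]]
}

list_to_entity <- function(x, field, idmap = NULL) {
  if (!is.list(x)) schema_error(field, "entity must be an object")
  if (!is.null(x[["ref"]])) {
    if (is.null(idmap) || !exists(x[["ref"]], envir = idmap, inherits = FALSE))
      schema_error(paste0(field, ".ref"),
                   sprintf("unknown entity id '%s'", x[["ref"]]))
    return(get(x[["ref"]], envir = idmap, inherits = FALSE))
  }
  type <- req(x, field, "type")
  e <- build_entity_from_list(type, x, field, idmap)
  if (!is.null(x[["name"]])) attr(e, "alias") <- x[["name"]]
  e
}

build_entity_from_list <- function(type, x, field, idmap) {
  wrap <- function(expr) {
    tryCatch(expr, error = function(err) {
      if (inherits(err, "cv_document_error")) stop(err)
      schema_error(field, conditionMessage(err))
    })
  }
  if (type == "peptide") {
    return(wrap(cv_peptide(
      gene_symbol = req(x, field, "gene_symbol"),
      start = int_or_na(x[["start"]]), end = int_or_na(x[["end"]]),
      chain_start = int_or_na(x[["chain_start"]]),
      chain_end = int_or_na(x[["chain_end"]]),
      chain_count = x[["chain_count"]] %||% 1L,
      ptms = lapply(seq_along(x[["ptms"]] %||% list()), function(i) {
        p <- x[["ptms"]][[i]]
        cv_ptm(req(p, paste0(field, ".ptms[", i, "]"), "psimod_id"),
               subtype = p[["subtype"]] %||% "none",
               coordinate = int_or_na(p[["coordinate"]]),
               multiplicity = p[["multiplicity"]] %||% 1L)
      }),
      isoform_variant = x[["isoform_variant"]] %||% 1L,
      active = isTRUE(x[["active"]]),
      disease_mutation = isTRUE(x[["disease_mutation"]]),
      cross_link = isTRUE(x[["cross_link"]]), hla = isTRUE(x[["hla"]]))))
  }
  if (type == "molecule") {
    return(wrap(cv_molecule(req(x, field, "reference_name"),
                            chebi_id = x[["chebi_id"]] %||% NA)))
  }
  if (type %in% c("complex", "defined_set", "candidate_set")) {
    parts <- lapply(seq_along(req(x, field, "parts")), function(i) {
      p <- x[["parts"]][[i]]
      pf <- paste0(field, ".parts[", i, "]")
      cv_part(list_to_entity(req(p, pf, "entity"), paste0(pf, ".entity"),
                             idmap),
              stoichiometry = p[["stoichiometry"]] %||% 1L,
              candidate = isTRUE(p[["candidate"]]))
    })
    return(wrap(cv_assembly(type, parts,
                            functional_label = x[["functional_label"]] %||% NA)))
  }
  schema_error(paste0(field, ".type"),
               sprintf("unknown entity type '%s'", type))
}

list_to_participant <- function(x, field, idmap) {
  cv_participant(list_to_entity(req(x, field, "entity"),
                                paste0(field, ".entity"), idmap),
                 compartment = x[["compartment"]] %||% NA,
                 count = x[["count"]] %||% 1L,
                 cell_type = x[["cell_type"]] %||% NA)
}

list_to_reaction <- function(x, field, idmap) {
  r <- cv_reaction(
    inputs = lapply(seq_along(x[["inputs"]] %||% list()), function(i)
      list_to_participant(x[["inputs"]][[i]], paste0(field, ".inputs[", i, "]"),
                          idmap)),
    outputs = lapply(seq_along(x[["outputs"]] %||% list()), function(i)
      list_to_participant(x[["outputs"]][[i]],
                          paste0(field, ".outputs[", i, "]"), idmap)),
    catalyst = if (!is.null(x[["catalyst"]]))
      list_to_entity(x[["catalyst"]], paste0(field, ".catalyst"), idmap),
    catalyst_gomf = x[["catalyst_gomf"]] %||% NA,
    regulator = if (!is.null(x[["regulator"]]))
      list_to_entity(req(x[["regulator"]], paste0(field, ".regulator"),
                         "entity"),
                     paste0(field, ".regulator.entity"), idmap),
    regulator_sign = (x[["regulator"]]$sign %||% "positive"),
    explicit_class = x[["explicit_class"]] %||% "none",
    transferred = if (!is.null(x[["transferred"]]))
      list_to_entity(x[["transferred"]], paste0(field, ".transferred"), idmap),
    membrane = x[["membrane"]] %||% NA)
  if (!is.null(x[["name"]])) attr(r, "alias") <- x[["name"]]
  r
}

#' Write an entity document
#'
#' Serializes entities and reactions to the package's JSON document format
#' (schema shipped at `inst/extdata/entity-document-schema.json`).
#'
#' @param doc A list with elements `entities` and `reactions` (either may
#'   be empty), or a bare list of entities.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_entity_document()]
#' @export
write_entity_document <- function(doc, path) {
  if (is.null(doc[["entities"]]) && is.null(doc[["reactions"]]))
    doc <- list(entities = doc, reactions = list())
  entities <- doc[["entities"]] %||% list()
  reactions <- doc[["reactions"]] %||% list()
  ids <- if (length(entities)) paste0("e", seq_along(entities))
         else character()
  ents <- lapply(seq_along(entities), function(i) {
    x <- entity_to_list(entities[[i]])
    c(list(id = ids[i]), x)
  })
  out <- list(version = DOCUMENT_VERSION, entities = ents,
              reactions = lapply(reactions, reaction_to_list))
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an entity document
#'
#' Parses and validates a JSON entity document. Validation failures report
#' the offending field, e.g. `entities[2].start`. Reading a document
#' written by [write_entity_document()] reproduces the entity and reaction
#' trees exactly.
#'
#' @param path Path to a JSON entity document.
#' @return A list with elements `entities` and `reactions`.
#' @export
read_entity_document <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.list(doc) || is.null(doc[["entities"]]))
    schema_error("entities", "missing top-level entities array")
  idmap <- new.env(parent = emptyenv())
  entities <- vector("list", length(doc[["entities"]]))
  for (i in seq_along(doc[["entities"]])) {
    x <- doc[["entities"]][[i]]
    field <- sprintf("entities[%d]", i)
    e <- list_to_entity(x[setdiff(names(x), "id")], field, idmap)
    entities[[i]] <- e
    if (!is.null(x[["id"]])) assign(x[["id"]], e, envir = idmap)
  }
  reactions <- lapply(seq_along(doc[["reactions"]] %||% list()), function(i)
    list_to_reaction(doc[["reactions"]][[i]], sprintf("reactions[%d]", i),
                     idmap))
  list(entities = entities, reactions = reactions)
}
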