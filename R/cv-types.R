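#' @importFrom stats runif
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce a coordinate to integer, mapping NULL / NA / "?" to NA (unknown)
int_or_na <- function(x) {
  if (is.null(x) || length(x) == 0) return(NA_integer_)
  if (is.character(x) && identical(x, "?")) return(NA_integer_)
  if (is.na(x)) return(NA_integer_)
  as.integer(x)
}

chr_or_na <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x)) NA_character_ else as.character(x)
}

#' Post-translational modification
#'
#' One modification of a peptide residue, identified by a PSI-MOD ontology
#' accession. The prefix used in CV names is looked up from the
#' `mod_prefixes` table at naming time, so a `cv_ptm` stays valid when the
#' table is extended.
#'
#' @param psimod_id PSI-MOD accession string, e.g. `"MOD:00046"`.
#' @param subtype Phosphorylation subtype letter (`"S"`, `"T"`, `"Y"`) or
#'   `"none"`. Only meaningful for phosphorylation-class prefixes.
#' @param coordinate 1-based residue index of the modified residue, or `NA`
#'   when unknown.
#' @param multiplicity Number of occurrences of the modification. Values
#'   greater than one are only allowed when the coordinate is unknown (the
#'   "nx" form of the name grammar).
#' @return An object of class `cv_ptm`.
#' @export
#' @examples
#' cv_ptm("MOD:00048", subtype = "Y", coordinate = 139)
cv_ptm <- function(psimod_id, subtype = c("none", "S", "T", "Y"),
                   coordinate = NA, multiplicity = 1L) {
  subtype <- match.arg(subtype)
  coordinate <- int_or_na(coordinate)
  multiplicity <- as.integer(multiplicity)
  if (is.na(multiplicity) || multiplicity < 1L)
    stop("ptm multiplicity must be a positive integer", call. = FALSE)
  if (multiplicity > 1L && !is.na(coordinate))
    stop("ptm multiplicity > 1 requires an unknown coordinate (the 'nx' form)",
         call. = FALSE)
  structure(list(psimod_id = as.character(psimod_id), subtype = subtype,
                 coordinate = coordinate, multiplicity = multiplicity),
            class = "cv_ptm")
}

#' Peptide entity
#'
#' A translated (and possibly cleaved) peptide, the most abundant class of
#' pathway entity. The CV name is built around the HGNC gene symbol; start
#' and end coordinates are 1-based, inclusive, and always refer to the
#' reference record's Chain feature.
#'
#' @param gene_symbol HGNC-style gene symbol forming the core of the name.
#' @param start,end 1-based residue coordinates of the peptide, `NA` when
#'   unknown.
#' @param chain_start,chain_end Coordinates of the reference Chain feature,
#'   `NA` when absent or unknown.
#' @param chain_count Number of Chain features on the reference record.
#'   When this differs from one, coordinates are always included in the name
#'   and the peptide is flagged for manual coordinate choice.
#' @param ptms List of [cv_ptm()] modifications.
#' @param isoform_variant Isoform variant number; 1 is the canonical
#'   isoform. Non-canonical isoforms are exempt from CV naming.
#' @param active Whether the peptide is an activated conformation of a
#'   covalently unchanged precursor; named with an `"Active "` prefix.
#' @param disease_mutation,cross_link,hla Exemption flags: disease-associated
#'   mutation, non-simple residue modification (e.g. internal cross-link),
#'   and HLA locus (which has its own allele nomenclature).
#' @return An object of class `cv_peptide`.
#' @export
#' @examples
#' cv_peptide("CASP9", start = 316, end = 416, chain_start = 1,
#'            chain_end = 416)
cv_peptide <- function(gene_symbol, start = NA, end = NA,
                       chain_start = NA, chain_end = NA, chain_count = 1L,
                       ptms = list(), isoform_variant = 1L, active = FALSE,
                       disease_mutation = FALSE, cross_link = FALSE,
                       hla = FALSE) {
  if (!is.character(gene_symbol) || length(gene_symbol) != 1L ||
      !nzchar(gene_symbol))
    stop("gene_symbol must be a non-empty string", call. = FALSE)
  start <- int_or_na(start); end <- int_or_na(end)
  chain_start <- int_or_na(chain_start); chain_end <- int_or_na(chain_end)
  chain_count <- as.integer(chain_count)
  if (is.na(chain_count) || chain_count < 0L)
    stop("chain_count must be a non-negative integer", call. = FALSE)
  if (!is.na(start) && !is.na(end) && start > end)
    stop(sprintf("peptide start (%d) must not exceed end (%d)", start, end),
         call. = FALSE)
  if (!all(vapply(ptms, inherits, TRUE, "cv_ptm")))
    stop("ptms must be a list of cv_ptm objects", call. = FALSE)
  isoform_variant <- as.integer(isoform_variant)
  if (is.na(isoform_variant) || isoform_variant < 1L)
    stop("isoform_variant must be a positive integer", call. = FALSE)
  structure(list(gene_symbol = gene_symbol, start = start, end = end,
                 chain_start = chain_start, chain_end = chain_end,
                 chain_count = chain_count, ptms = ptms,
                 isoform_variant = isoform_variant,
                 active = isTRUE(active),
                 disease_mutation = isTRUE(disease_mutation),
                 cross_link = isTRUE(cross_link), hla = isTRUE(hla)),
            class = "cv_peptide")
}

#' Small molecule entity
#'
#' @param reference_name Full reference chemical name (ChEBI style).
#' @param chebi_id Optional ChEBI accession.
#' @return An object of class `cv_molecule`.
#' @export
cv_molecule <- function(reference_name, chebi_id = NA) {
  if (!is.character(reference_name) || length(reference_name) != 1L ||
      !nzchar(trimws(reference_name)))
    stop("reference_name must be a non-empty string", call. = FALSE)
  structure(list(reference_name = reference_name,
                 chebi_id = chr_or_na(chebi_id)),
            class = "cv_molecule")
}

is_cv_entity <- function(x) {
  inherits(x, "cv_peptide") || inherits(x, "cv_molecule") ||
    inherits(x, "cv_assembly")
}

#' Assembly part
#'
#' One slot of a complex or set: a member entity together with its
#' stoichiometry and, in candidate sets, its candidate status.
#'
#' @param member A `cv_peptide`, `cv_molecule` or `cv_assembly`.
#' @param stoichiometry Positive integer number of occurrences.
#' @param candidate Whether the member is an unverified candidate (only
#'   legal inside a candidate set).
#' @return An object of class `cv_part`.
#' @export
cv_part <- function(member, stoichiometry = 1L, candidate = FALSE) {
  if (!is_cv_entity(member))
    stop("part member must be a CV entity", call. = FALSE)
  stoichiometry <- as.integer(stoichiometry)
  if (is.na(stoichiometry) || stoichiometry < 1L)
    stop("stoichiometry must be a positive integer", call. = FALSE)
  structure(list(member = member, stoichiometry = stoichiometry,
                 candidate = isTRUE(candidate)), class = "cv_part")
}

as_cv_part <- function(x) {
  if (inherits(x, "cv_part")) x else cv_part(x)
}

#' Complex or set assembly
#'
#' A recursive assembly node. Complexes concatenate member names with
#' colons, sets with commas; candidate sets additionally group their
#' unverified candidates in a trailing round-bracket group. Candidate parts
#' are canonicalized to the end of the part list (their relative order is
#' preserved), matching the rendered name.
#'
#' @param kind `"complex"`, `"defined_set"` or `"candidate_set"`.
#' @param parts List of [cv_part()] objects (bare entities are wrapped with
#'   stoichiometry 1).
#' @param functional_label Optional curator-supplied collective label used
#'   by [shorten_label()] (e.g. `"CCR2 ligands"`).
#' @return An object of class `cv_assembly`.
#' @seealso [cv_complex()], [cv_set()], [cv_candidate_set()]
#' @export
cv_assembly <- function(kind = c("complex", "defined_set", "candidate_set"),
                        parts, functional_label = NA) {
  kind <- match.arg(kind)
  if (!is.list(parts) || length(parts) == 0)
    stop("an assembly needs at least one part", call. = FALSE)
  parts <- lapply(parts, as_cv_part)
  cand <- vapply(parts, function(p) p$candidate, TRUE)
  if (kind != "candidate_set" && any(cand))
    stop("candidate parts are only valid in a candidate_set", call. = FALSE)
  if (kind == "candidate_set") {
    if (!any(cand) || all(cand))
      stop("a candidate_set needs at least one member and one candidate",
           call. = FALSE)
    parts <- c(parts[!cand], parts[cand])  # candidates trail, order kept
  }
  structure(list(kind = kind, parts = parts,
                 functional_label = chr_or_na(functional_label)),
            class = "cv_assembly")
}

#' @rdname cv_assembly
#' @param ... Member entities or [cv_part()] objects, in curator order.
#' @export
cv_complex <- function(..., functional_label = NA) {
  cv_assembly("complex", list(...), functional_label)
}

#' @rdname cv_assembly
#' @export
cv_set <- function(..., functional_label = NA) {
  cv_assembly("defined_set", list(...), functional_label)
}

#' @rdname cv_assembly
#' @param members,candidates Lists of entities/parts for the verified
#'   members and the unverified candidates of a candidate set.
#' @export
cv_candidate_set <- function(members, candidates, functional_label = NA) {
  mk <- function(x, flag) {
    p <- as_cv_part(x)
    cv_part(p$member, p$stoichiometry, candidate = flag)
  }
  cv_assembly("candidate_set",
              c(lapply(members, mk, FALSE), lapply(candidates, mk, TRUE)),
              functional_label)
}

#' Reaction participant
#'
#' @param entity A CV entity.
#' @param compartment Optional cellular compartment label.
#' @param count Participant stoichiometric count.
#' @param cell_type Optional cell-type label, used for cross-cell
#'   translocation phrasing.
#' @return An object of class `cv_participant`.
#' @export
cv_participant <- function(entity, compartment = NA, count = 1L,
                           cell_type = NA) {
  if (!is_cv_entity(entity))
    stop("participant entity must be a CV entity", call. = FALSE)
  count <- as.integer(count)
  if (is.na(count) || count < 1L)
    stop("participant count must be a positive integer", call. = FALSE)
  structure(list(entity = entity, compartment = chr_or_na(compartment),
                 count = count, cell_type = chr_or_na(cell_type)),
            class = "cv_participant")
}

as_cv_participant <- function(x) {
  if (inherits(x, "cv_participant")) x else cv_participant(x)
}

#' Reaction (pathway event)
#'
#' Inputs, outputs and optional attributes of one pathway event. Bare
#' entities in `inputs`/`outputs` are wrapped into participants with count 1
#' and no compartment. Polymerization and depolymerization are explicit
#' reaction classes in the source data model and are carried here as
#' `explicit_class` rather than inferred.
#'
#' @param inputs,outputs Lists of [cv_participant()] (or bare entities).
#'   Each must be non-empty unless `explicit_class` is set.
#' @param catalyst Optional catalyst entity.
#' @param catalyst_gomf Optional GO molecular function term attached to the
#'   catalyst, used to derive the naming verb.
#' @param regulator Optional regulating entity.
#' @param regulator_sign `"positive"` or `"negative"`.
#' @param explicit_class `"none"`, `"polymerization"` or
#'   `"depolymerization"`.
#' @param transferred For transferase events, the chemical group/entity that
#'   is transferred to the recipient.
#' @param membrane For antiporter events, the membrane name used in the
#'   "across the ... membrane" clause.
#' @return An object of class `cv_reaction`.
#' @export
cv_reaction <- function(inputs = list(), outputs = list(), catalyst = NULL,
                        catalyst_gomf = NA, regulator = NULL,
                        regulator_sign = c("positive", "negative"),
                        explicit_class = c("none", "polymerization",
                                           "depolymerization"),
                        transferred = NULL, membrane = NA) {
  explicit_class <- match.arg(explicit_class)
  regulator_sign <- match.arg(regulator_sign)
  inputs <- lapply(inputs, as_cv_participant)
  outputs <- lapply(outputs, as_cv_participant)
  if (explicit_class == "none" && (!length(inputs) || !length(outputs)))
    stop("a reaction with no explicit class needs at least one input and one output",
         call. = FALSE)
  if (explicit_class != "none" && !length(inputs) && !length(outputs))
    stop("an explicit-class reaction still needs participants", call. = FALSE)
  if (!is.null(catalyst) && !is_cv_entity(catalyst))
    stop("catalyst must be a CV entity", call. = FALSE)
  if (!is.null(regulator) && !is_cv_entity(regulator))
    stop("regulator must be a CV entity", call. = FALSE)
  if (!is.null(transferred) && !is_cv_entity(transferred))
    stop("transferred must be a CV entity", call. = FALSE)
  structure(list(inputs = inputs, outputs = outputs, catalyst = catalyst,
                 catalyst_gomf = chr_or_na(catalyst_gomf),
                 regulator = regulator, regulator_sign = regulator_sign,
                 explicit_class = explicit_class, transferred = transferred,
                 membrane = chr_or_na(membrane)),
            class = "cv_reaction")
}

brackets_balanced <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  rd <- 0L; sq <- 0L
  for (ch in chars) {
    if (ch == "(") rd <- rd + 1L else if (ch == ")") rd <- rd - 1L
    else if (ch == "[") sq <- sq + 1L else if (ch == "]") sq <- sq - 1L
    if (rd < 0L || sq < 0L) return(FALSE)
  }
  rd == 0L && sq == 0L
}

#' CV name
#'
#' A generated name string together with the entity or reaction tree it was
#' derived from, retained for round-trip verification and namespace
#' validation.
#'
#' @param text The name string.
#' @param source The entity/reaction the name was generated from.
#' @param namespace Identifier of the collection the name must be unique
#'   within (`"entities"` or `"reactions"`).
#' @return An object of class `cv_name`.
#' @export
cv_name <- function(text, source = NULL, namespace = NA) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("a CV name must be a non-empty string", call. = FALSE)
  if (!brackets_balanced(text))
    stop(sprintf("unbalanced brackets in CV name '%s'", text), call. = FALSE)
  structure(list(text = text, source = source,
                 namespace = chr_or_na(namespace)), class = "cv_name")
}

#' @export
as.character.cv_name <- function(x, ...) x$text

#' @export
print.cv_name <- function(x, ...) {
  cat(x$text, "\n", sep = "")
  invisible(x)
}

#' @export
format.cv_name <- function(x, ...) x$text
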