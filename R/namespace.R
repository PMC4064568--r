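#' Validate a namespace of CV names
#'
#' Quality-control pass over a collection of names that must be unique
#' within one namespace: reports duplicate name groups (with the indices of
#' their source entities), bracket-balance failures, and exempted source
#' peptides. The documented duplication mode — fragments from cleavage of a
#' peptide with uncertain coordinates sharing a name like `"ACAN(17-?)"` —
#' is flagged for manual naming, never silently renamed. Duplicates among
#' exempt entities do not fail the check, since those names are curated
#' manually.
#'
#' @param names List of [cv_name()] objects (bare strings are accepted but
#'   carry no exemption information).
#' @param tables Lookup tables from [cv_tables()] (reserved for future
#'   checks).
#' @return A `cv_namespace_report`: list with `duplicates` (list of integer
#'   index vectors, named by the duplicated text), `unbalanced` (indices),
#'   `exempt` (data frame of index and code) and `ok` (`TRUE` iff there are
#'   no duplicates among non-exempt entities and no unbalanced names).
#' @export
validate_namespace <- function(names, tables = default_cv_tables()) {
  txt <- vapply(names, function(n)
    if (inherits(n, "cv_name")) n$text else as.character(n), "")
  codes <- vapply(names, function(n) {
    s <- if (inherits(n, "cv_name")) n$source else NULL
    if (inherits(s, "cv_peptide")) check_exemption(s) else "NONE"
  }, "")
  unbalanced <- which(!vapply(txt, brackets_balanced, TRUE,
                              USE.NAMES = FALSE))
  nonex <- which(codes == "NONE")
  groups <- split(nonex, txt[nonex])
  dup <- groups[lengths(groups) > 1L]
  exempt <- data.frame(index = which(codes != "NONE"),
                       code = codes[codes != "NONE"],
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(list(duplicates = dup, unbalanced = unbalanced,
                 exempt = exempt,
                 ok = length(dup) == 0L && length(unbalanced) == 0L),
            class = "cv_namespace_report")
}

#' @export
print.cv_namespace_report <- function(x, ...) {
  cat(sprintf("CV namespace report: %s\n",
              if (x$ok) "OK" else "PROBLEMS FOUND"))
  if (length(x$duplicates)) {
    cat(sprintf("  %d duplicate name group(s) needing manual naming:\n",
                length(x$duplicates)))
    for (nm in names(x$duplicates))
      cat(sprintf("    '%s' x%d (entities %s)\n", nm,
                  length(x$duplicates[[nm]]),
                  paste(x$duplicates[[nm]], collapse = ", ")))
  }
  if (length(x$unbalanced))
    cat(sprintf("  unbalanced brackets in name(s): %s\n",
                paste(x$unbalanced, collapse = ", ")))
  if (nrow(x$exempt))
    cat(sprintf("  %d exempted entit(ies)\n", nrow(x$exempt)))
  invisible(x)
}

#' Batch-rename a document, producing an audit table
#'
#' Applies the CV retrospectively to every entity and reaction of a
#' document. Previous names (the document's `name` fields) are retained as
#' aliases in the `old_name` column; each record receives either a new CV
#' name or an exemption code; reactions also receive their event category.
#' Per-record failures are recorded in the `note` column and never abort
#' the batch. The operation is deterministic and idempotent: re-running on
#' a renamed document changes nothing.
#'
#' @param document A list with `entities` and `reactions`, as returned by
#'   [read_entity_document()].
#' @param tables Lookup tables from [cv_tables()].
#' @return A data frame with columns `id`, `kind`, `old_name`, `new_name`,
#'   `exemption_code`, `category`, `note`.
#' @export
rename_batch <- function(document, tables = default_cv_tables()) {
  ent_row <- function(i) {
    e <- document$entities[[i]]
    alias <- attr(e, "alias", exact = TRUE) %||% NA_character_
    new_name <- NA_character_; code <- NA_character_; note <- NA_character_
    tryCatch({
      new_name <- name_entity(e, tables)$text
    }, cv_exemption_error = function(err) {
      code <<- err$code
    }, error = function(err) {
      note <<- conditionMessage(err)
    })
    data.frame(id = paste0("e", i), kind = class(e)[1], old_name = alias,
               new_name = new_name, exemption_code = code,
               category = NA_character_, note = note,
               stringsAsFactors = FALSE)
  }
  rxn_row <- function(i) {
    r <- document$reactions[[i]]
    alias <- attr(r, "alias", exact = TRUE) %||% NA_character_
    new_name <- NA_character_; category <- NA_character_
    note <- NA_character_
    tryCatch({
      category <- classify_reaction(r, tables)
      new_name <- name_reaction(r, tables, category)$text
    }, error = function(err) {
      note <<- conditionMessage(err)
    })
    data.frame(id = paste0("r", i), kind = "cv_reaction", old_name = alias,
               new_name = new_name, exemption_code = NA_character_,
               category = category, note = note, stringsAsFactors = FALSE)
  }
  rows <- c(lapply(seq_along(document$entities %||% list()), ent_row),
            lapply(seq_along(document$reactions %||% list()), rxn_row))
  if (!length(rows))
    return(data.frame(id = character(), kind = character(),
                      old_name = character(), new_name = character(),
                      exemption_code = character(), category = character(),
                      note = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write a rename audit table as TSV
#'
#' @param audit Data frame from [rename_batch()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audit <- function(audit, path) {
  utils::write.table(audit, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
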