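norm_chem <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Generate the CV name of a small molecule
#'
#' Short familiar abbreviations are used in preference to the full
#' reference chemical name: when the reference name matches a `full_name`
#' key of the abbreviation table (case-insensitively, with whitespace
#' collapsed) the abbreviation is returned, otherwise the reference name is
#' returned verbatim. Abbreviations never appear as table keys, so naming an
#' already-abbreviated name is the identity.
#'
#' @param mol A [cv_molecule()].
#' @param tables Lookup tables from [cv_tables()].
#' @param strict Fail on a lookup miss instead of falling back to the
#'   reference name (names that already are table abbreviations still pass).
#' @return A [cv_name()].
#' @export
#' @examples
#' name_molecule(cv_molecule("flavin adenine dinucleotide"))$text
name_molecule <- function(mol, tables = default_cv_tables(), strict = FALSE) {
  if (!inherits(mol, "cv_molecule"))
    stop("mol must be a cv_molecule", call. = FALSE)
  i <- match(norm_chem(mol$reference_name),
             norm_chem(tables$molecule_abbrev$full_name))
  if (!is.na(i)) {
    text <- tables$molecule_abbrev$abbreviation[i]
  } else {
    if (strict && !(mol$reference_name %in% tables$molecule_abbrev$abbreviation))
      stop(sprintf("no abbreviation found for '%s'", mol$reference_name),
           call. = FALSE)
    text <- mol$reference_name
  }
  cv_name(text, source = mol, namespace = "entities")
}
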