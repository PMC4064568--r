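#' Load the CV lookup tables
#'
#' The naming rules are table-driven. Three tab-separated tables (one header
#' row, UTF-8) are read from `dir`:
#'
#' * `mod_prefixes.tsv` — `psimod_id`, `prefix`, `includes_coordinate`,
#'   `phospho`: maps PSI-MOD accessions to name prefixes, and records
#'   whether the residue coordinate is written into the name (it is for
#'   di-/tri-lysine and arginine methylation, lysine acetylation,
#'   ubiquitination and phosphorylation) and whether the prefix belongs to
#'   the phosphorylation class (which uses S/T/Y subtype letters and is
#'   always rendered last).
#' * `molecule_abbrev.tsv` — `full_name`, `abbreviation`: short familiar
#'   abbreviations used in preference to the full reference chemical name.
#'   Abbreviations never appear as keys, so abbreviation is idempotent.
#' * `gomf_verbs.tsv` — `gomf_term`, `verb`, `template`: maps GO molecular
#'   function terms to naming verbs and to one of the phrase templates
#'   `catalyzes`, `transfers`, `transports`, `exchanges`, `cotransports`.
#'
#' The shipped tables are extensible seeds covering the published prefix,
#' abbreviation and verb examples; installations can point `dir` at an
#' extended copy.
#'
#' @param dir Directory containing the three TSV files.
#' @return A list of three data frames with class `cv_tables`.
#' @export
cv_tables <- function(dir = system.file("extdata", package = "pathwaycv")) {
  read_tsv <- function(file, cols) {
    path <- file.path(dir, file)
    if (!file.exists(path))
      stop(sprintf("lookup table not found: %s", path), call. = FALSE)
    d <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", fileEncoding = "UTF-8")
    missing <- setdiff(cols, names(d))
    if (length(missing))
      stop(sprintf("table %s is missing column(s): %s", file,
                   paste(missing, collapse = ", ")), call. = FALSE)
    d
  }
  mp <- read_tsv("mod_prefixes.tsv",
                 c("psimod_id", "prefix", "includes_coordinate", "phospho"))
  mp$includes_coordinate <- as.logical(mp$includes_coordinate)
  mp$phospho <- as.logical(mp$phospho)
  ab <- read_tsv("molecule_abbrev.tsv", c("full_name", "abbreviation"))
  gv <- read_tsv("gomf_verbs.tsv", c("gomf_term", "verb", "template"))
  bad <- setdiff(gv$template,
                 c("catalyzes", "transfers", "transports", "exchanges",
                   "cotransports"))
  if (length(bad))
    stop(sprintf("gomf_verbs.tsv has unknown template(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  structure(list(mod_prefixes = mp, molecule_abbrev = ab, gomf_verbs = gv),
            class = "cv_tables")
}

.table_cache <- new.env(parent = emptyenv())

#' Default (shipped) lookup tables, loaded once per session
#' @return A `cv_tables` object.
#' @export
default_cv_tables <- function() {
  if (is.null(.table_cache$tables)) .table_cache$tables <- cv_tables()
  .table_cache$tables
}
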