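#' Generate the CV name of any entity
#'
#' Dispatches to [name_peptide()], [name_molecule()] or [name_assembly()].
#'
#' @param entity A CV entity.
#' @param tables Lookup tables from [cv_tables()].
#' @param override Passed through to [name_peptide()].
#' @return A [cv_name()].
#' @export
name_entity <- function(entity, tables = default_cv_tables(),
                        override = FALSE) {
  if (inherits(entity, "cv_peptide"))
    return(name_peptide(entity, tables, override = override))
  if (inherits(entity, "cv_molecule"))
    return(name_molecule(entity, tables))
  if (inherits(entity, "cv_assembly"))
    return(name_assembly(entity, tables, override = override))
  stop("not a CV entity", call. = FALSE)
}

#' Generate the CV name of a complex or set
#'
#' Member names are concatenated with `":"` for complexes and `","` for
#' sets; the composition, read left to right in curator order, is the name.
#' A part occurring n > 1 times is rendered `"nx"` + name. In a candidate
#' set the unverified candidates are grouped in one trailing round-bracket
#' group. Any member that is itself an assembly of two or more parts is
#' wrapped in square brackets, so that the assembly history — not just the
#' flat composition — is recoverable from the name: `[ABC1:ABC2]:[ABC3:ABC4]`
#' and `[ABC1:ABC2:ABC3]:ABC4` stay distinct.
#'
#' @param node A [cv_assembly()].
#' @inheritParams name_entity
#' @return A [cv_name()].
#' @export
#' @examples
#' name_assembly(cv_complex(cv_part(cv_peptide("PPOX"), 2),
#'                          cv_molecule("FAD")))$text
name_assembly <- function(node, tables = default_cv_tables(),
                          override = FALSE) {
  render(node, tables, override, 0L)
}

render <- function(node, tables, override, depth) {
  if (depth > 200L)
    stop("assembly nesting exceeds 200 levels: cyclic structure?",
         call. = FALSE)
  render_part <- function(part) {
    m <- part$member
    inner <- if (inherits(m, "cv_assembly")) {
      s <- render(m, tables, override, depth + 1L)$text
      if (length(m$parts) >= 2L) paste0("[", s, "]") else s
    } else {
      name_entity(m, tables, override)$text
    }
    if (part$stoichiometry > 1L) paste0(part$stoichiometry, "x", inner)
    else inner
  }
  txts <- vapply(node$parts, render_part, "")
  cand <- vapply(node$parts, function(p) p$candidate, TRUE)
  text <- switch(node$kind,
    complex = paste(txts, collapse = ":"),
    defined_set = paste(txts, collapse = ","),
    candidate_set = paste0(paste(txts[!cand], collapse = ","),
                           ",(", paste(txts[cand], collapse = ","), ")"))
  cv_name(text, source = node, namespace = "entities")
}

# "1,3-5"-style compression: runs of three or more consecutive integers
# collapse to "a-b", shorter runs are written out
compress_ranges <- function(nums) {
  nums <- sort(unique(nums))
  runs <- split(nums, cumsum(c(1L, diff(nums) != 1L)))
  chunks <- vapply(runs, function(r) {
    if (length(r) >= 3L) paste0(r[1], "-", r[length(r)])
    else paste(r, collapse = ",")
  }, "")
  paste(chunks, collapse = ",")
}

#' Shortened diagram label for a set
#'
#' Full composition names can be too long for pathway-diagram labels. In
#' priority order: (1) a curator-supplied `functional_label` is used
#' verbatim; (2) when every member is a leaf peptide whose symbol is a
#' common stem plus a trailing integer and the integers run unbroken from
#' the minimum, the plural stem (`"VAVs"`) is used — but only when the
#' caller asserts via `family_complete` that the set covers the full family
#' and is not anticipated to grow (a curation judgement the code cannot
#' make); (3) otherwise the stem plus compressed integer ranges
#' (`"CCR1-5"`, `"CCR1,3-5"`); (4) fall back to the full CV name.
#'
#' @param node A [cv_assembly()] set.
#' @param tables Lookup tables from [cv_tables()].
#' @param family_complete Assert that the members are the complete protein
#'   family, permitting the plural-stem form.
#' @return A label string (plural for forms 1-3).
#' @export
#' @examples
#' vavs <- cv_set(cv_peptide("VAV1"), cv_peptide("VAV2"), cv_peptide("VAV3"))
#' shorten_label(vavs, family_complete = TRUE)
#' shorten_label(vavs)
shorten_label <- function(node, tables = default_cv_tables(),
                          family_complete = FALSE) {
  if (!inherits(node, "cv_assembly"))
    stop("node must be a cv_assembly", call. = FALSE)
  if (!is.na(node$functional_label)) return(node$functional_label)
  leafpep <- vapply(node$parts, function(p)
    inherits(p$member, "cv_peptide") && p$stoichiometry == 1L, TRUE)
  if (all(leafpep)) {
    syms <- vapply(node$parts, function(p) p$member$gene_symbol, "")
    m <- regmatches(syms, regexec("^(.*[^0-9])([0-9]+)$", syms))
    ok <- lengths(m) == 3L
    if (all(ok)) {
      stems <- vapply(m, `[`, "", 2L)
      nums <- as.integer(vapply(m, `[`, "", 3L))
      if (length(unique(stems)) == 1L && !anyDuplicated(nums)) {
        nums <- sort(nums)
        if (family_complete &&
            identical(nums, seq(min(nums), max(nums))))
          return(paste0(stems[1], "s"))
        return(paste0(stems[1], compress_ranges(nums)))
      }
    }
  }
  name_assembly(node, tables)$text
}
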