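fmt_coord <- function(x) if (is.na(x)) "?" else as.character(x)

# PSI-MOD accessions used when (re)constructing phospho modifications from a
# subtype letter alone (O-phospho-Ser/Thr/Tyr, generic phosphorylated residue)
PHOSPHO_SUBTYPE_IDS <- c(S = "MOD:00046", T = "MOD:00047", Y = "MOD:00048",
                         none = "MOD:00696")

phospho_id_for_subtype <- function(subtype) PHOSPHO_SUBTYPE_IDS[[subtype]]

lookup_mod <- function(psimod_id, tables) {
  i <- match(psimod_id, tables$mod_prefixes$psimod_id)
  if (is.na(i))
    stop(sprintf("unknown PSI-MOD identifier '%s' (not in mod_prefixes table)",
                 psimod_id), call. = FALSE)
  tables$mod_prefixes[i, , drop = FALSE]
}

# Layout engine shared by the renderer and the canonicalizer. Non-phospho
# modifications are rendered first, one hyphen-terminated unit each:
# coordinate-bearing prefixes individually ("Ub48-"), coordinate-less ones
# grouped per prefix with summed multiplicity ("2xPalmC-"). Units are ordered
# by descending first-modified-residue coordinate; units with no known
# coordinate come last, in descending alphabetical prefix order (so the
# coordinate-stripped form of a name keeps its order when re-rendered). The
# phosphorylation block comes after everything else as "p-" plus
# comma-separated subtype/coordinate tokens sorted ascending by coordinate,
# unknown coordinates last.
ptm_layout <- function(ptms, tables) {
  if (!length(ptms)) return(list(text = "", ptms = list()))
  info <- lapply(ptms, function(p) {
    if (!inherits(p, "cv_ptm")) stop("ptms must be cv_ptm objects", call. = FALSE)
    row <- lookup_mod(p$psimod_id, tables)
    if (p$subtype != "none" && !row$phospho)
      stop(sprintf("subtype letters are only valid for phosphorylation prefixes (got %s on %s)",
                   p$subtype, row$prefix), call. = FALSE)
    list(p = p, prefix = row$prefix, inc = row$includes_coordinate,
         phospho = row$phospho)
  })

  keys <- vapply(info, function(x) {
    if (is.na(x$p$coordinate)) NA_character_
    else paste(x$prefix, x$p$subtype, x$p$coordinate)
  }, "")
  keys <- keys[!is.na(keys)]
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)][1]
    stop(sprintf("the same modification is listed twice (%s)", dup),
         call. = FALSE)
  }

  ph <- Filter(function(x) x$phospho, info)
  np <- Filter(function(x) !x$phospho, info)

  units <- list()
  for (x in np) {
    if (x$inc && !is.na(x$p$coordinate)) {
      units[[length(units) + 1L]] <- list(
        text = paste0(x$prefix, x$p$coordinate), key = x$p$coordinate,
        prefix = x$prefix, ptms = list(x$p))
    }
  }
  noc <- Filter(function(x) !(x$inc && !is.na(x$p$coordinate)), np)
  if (length(noc)) {
    by_prefix <- split(noc, vapply(noc, function(x) x$prefix, ""))
    for (pref in names(by_prefix)) {
      grp <- by_prefix[[pref]]
      mult <- sum(vapply(grp, function(x) x$p$multiplicity, 1L))
      coords <- vapply(grp, function(x) x$p$coordinate, 1L)
      key <- if (all(is.na(coords))) NA_integer_ else min(coords, na.rm = TRUE)
      canon <- cv_ptm(grp[[1]]$p$psimod_id, coordinate = NA,
                      multiplicity = mult)
      units[[length(units) + 1L]] <- list(
        text = paste0(if (mult > 1L) paste0(mult, "x"), pref), key = key,
        prefix = pref, ptms = list(canon))
    }
  }
  if (length(units)) {
    keynum <- vapply(units, function(u) u$key, 1L)
    prefs <- vapply(units, function(u) u$prefix, "")
    ord <- order(is.na(keynum),
                 -ifelse(is.na(keynum), 0L, keynum),
                 -xtfrm(prefs))
    units <- units[ord]
  }

  ph_text <- ""
  ph_ptms <- list()
  if (length(ph)) {
    blank <- vapply(ph, function(x) x$p$subtype == "none" &&
                      is.na(x$p$coordinate), TRUE)
    if (length(ph) > 1L && any(blank))
      stop("a phosphorylation with unknown subtype and position cannot be combined with other phosphorylations",
           call. = FALSE)
    coords <- vapply(ph, function(x) x$p$coordinate, 1L)
    letters_ <- vapply(ph, function(x) x$p$subtype, "")
    ph <- ph[order(is.na(coords), coords, letters_)]
    toks <- vapply(ph, function(x) {
      paste0("",
             if (x$p$multiplicity > 1L) paste0(x$p$multiplicity, "x"),
             if (x$p$subtype != "none") x$p$subtype,
             if (!is.na(x$p$coordinate)) x$p$coordinate)
    }, "")
    toks <- toks[nzchar(toks)]
    ph_text <- if (length(toks)) paste0("p-", paste(toks, collapse = ","), "-")
               else "p-"
    ph_ptms <- lapply(ph, function(x) {
      cv_ptm(phospho_id_for_subtype(x$p$subtype), subtype = x$p$subtype,
             coordinate = x$p$coordinate, multiplicity = x$p$multiplicity)
    })
  }

  np_text <- if (length(units))
    paste0(vapply(units, function(u) u$text, ""), "-", collapse = "") else ""
  list(text = paste0(np_text, ph_text),
       ptms = c(unlist(lapply(units, function(u) u$ptms), recursive = FALSE),
                ph_ptms))
}

#' Render the PTM prefix string of a peptide CV name
#'
#' Produces the hyphen-terminated modification prefix that precedes the gene
#' symbol, e.g. `"p-Y139-"` or `"2xPalmC-MyrG-p-S1177-"`. The result is
#' canonical: permuting the input list never changes the output.
#'
#' @param ptms List of [cv_ptm()] objects.
#' @param tables Lookup tables from [cv_tables()].
#' @return A string, `""` for an empty list.
#' @export
#' @examples
#' ptm_prefix(list(cv_ptm("MOD:00048", subtype = "Y", coordinate = 139)))
ptm_prefix <- function(ptms, tables = default_cv_tables()) {
  ptm_layout(ptms, tables)$text
}

# canonical, render-ordered form of a PTM list (used by the fixture
# generator so that parse(generate(x)) reproduces x exactly). Not exported:
# merging coordinate-less groups discards hidden coordinates, so this is
# name-equivalent only for lists whose coordinate-less PTMs carry no
# coordinates.
canonicalize_ptms <- function(ptms, tables = default_cv_tables()) {
  ptm_layout(ptms, tables)$ptms
}

#' Render the coordinate suffix of a peptide CV name
#'
#' Coordinates are omitted only when the reference record has exactly one
#' Chain feature and the peptide coordinates agree with it; otherwise both
#' coordinates are added in round brackets, with `"?"` for unknown values.
#' When the record has no or multiple Chain features the suffix is always
#' added.
#'
#' @inheritParams check_exemption
#' @return A string, `""` when the coordinates are deemed unnecessary.
#' @export
coordinate_suffix <- function(peptide) {
  same <- function(a, b) (is.na(a) && is.na(b)) ||
    (!is.na(a) && !is.na(b) && a == b)
  if (peptide$chain_count == 1L &&
      same(peptide$start, peptide$chain_start) &&
      same(peptide$end, peptide$chain_end)) return("")
  paste0("(", fmt_coord(peptide$start), "-", fmt_coord(peptide$end), ")")
}

#' Exemption screening for peptide CV naming
#'
#' Some peptides are exempt from automatic naming: disease-associated
#' mutants (a dedicated extension of the vocabulary), non-canonical
#' isoforms (whose reference coordinates would mislead), modifications that
#' are not simple residue modifications (e.g. internal cross-links), records
#' with no or multiple Chain features (which need a manual coordinate
#' choice, but remain nameable), and HLA loci (which have their own allele
#' nomenclature). The first matching code in that fixed order is returned.
#'
#' @param peptide A [cv_peptide()].
#' @return One of `"DISEASE_MUTATION"`, `"NONCANONICAL_ISOFORM"`,
#'   `"COMPLEX_MODIFICATION"`, `"MULTI_OR_NO_CHAIN"`, `"HLA"` or `"NONE"`.
#' @export
check_exemption <- function(peptide) {
  if (peptide$disease_mutation) return("DISEASE_MUTATION")
  if (peptide$isoform_variant > 1L) return("NONCANONICAL_ISOFORM")
  if (peptide$cross_link) return("COMPLEX_MODIFICATION")
  if (peptide$chain_count != 1L) return("MULTI_OR_NO_CHAIN")
  if (peptide$hla) return("HLA")
  "NONE"
}

BLOCKING_EXEMPTIONS <- c("DISEASE_MUTATION", "NONCANONICAL_ISOFORM",
                         "COMPLEX_MODIFICATION", "HLA")

cv_exemption_error <- function(peptide, code) {
  structure(
    class = c("cv_exemption_error", "error", "condition"),
    list(message = sprintf("peptide '%s' is exempt from CV naming (%s)",
                           peptide$gene_symbol, code),
         call = NULL, code = code))
}

#' Generate the CV name of a peptide
#'
#' Assembles `[Active ] + <PTM prefix> + <gene symbol> + <coordinate
#' suffix>`. Peptides carrying a blocking exemption (disease mutation,
#' non-canonical isoform, complex modification, HLA) raise a
#' `cv_exemption_error` unless `override = TRUE`; a multi-/no-chain record
#' is named (with coordinates forced) but flagged by [check_exemption()] as
#' needing a manual coordinate choice.
#'
#' @inheritParams check_exemption
#' @param tables Lookup tables from [cv_tables()].
#' @param override Name the peptide even if a blocking exemption applies.
#' @return A [cv_name()].
#' @export
#' @examples
#' name_peptide(cv_peptide("CASP9", 316, 416, 1, 416))$text
name_peptide <- function(peptide, tables = default_cv_tables(),
                         override = FALSE) {
  code <- check_exemption(peptide)
  if (code %in% BLOCKING_EXEMPTIONS && !override)
    stop(cv_exemption_error(peptide, code))
  text <- paste0(if (peptide$active) "Active ",
                 ptm_prefix(peptide$ptms, tables),
                 peptide$gene_symbol,
                 coordinate_suffix(peptide))
  cv_name(text, source = peptide, namespace = "entities")
}
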