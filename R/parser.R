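# Recursive parser for entity CV names.
#
# Grammar (informal):
#   assembly := item ((":" | ",") item)*     -- uniform separator per level
#   item     := "[" assembly "]" | "(" candidates ")" | stoich? leaf
#   leaf     := "Active "? ptm_prefix* phospho_block? NAME coords?
#
# The comma collision between phosphorylation token lists and set
# separators is resolved by maximal munch: after "p-", tokens of the shape
# [STY]?digits bind to the phospho block, not to the enclosing set. An
# "nx" prefix followed by a known non-phospho PTM prefix binds to the PTM
# ("2xPalmC-..."), otherwise it is part stoichiometry ("2xPPOX").

parse_error <- function(msg, pos) {
  stop(structure(
    class = c("cv_parse_error", "error", "condition"),
    list(message = sprintf("%s (at character %d)", msg, pos),
         call = NULL, offset = pos)))
}

PHOSPHO_BLOCK_RE <-
  "p-(?:[0-9]+x)?(?:[STY][0-9]*|[0-9]+)(?:,(?:[0-9]+x)?(?:[STY][0-9]*|[0-9]+))*-"

# positions (in s) of commas that belong to a phosphorylation token list
protected_comma_positions <- function(s) {
  prot <- integer()
  m <- gregexpr(PHOSPHO_BLOCK_RE, s)[[1]]
  if (m[1] == -1) return(prot)
  lens <- attr(m, "match.length")
  for (k in seq_along(m)) {
    st <- m[k]
    if (st > 1L) {
      prev <- substr(s, st - 1L, st - 1L)
      # a block can only start a leaf: after a separator, bracket, another
      # prefix's hyphen, a stoichiometry "x" or the "Active " space
      if (!prev %in% c(":", ",", "[", "(", "-", "x", " ")) next
    }
    span <- st:(st + lens[k] - 1L)
    commas <- span[substring(s, span, span) == ","]
    prot <- c(prot, commas)
  }
  prot
}

non_phospho_prefix_re <- function(tables) {
  np <- tables$mod_prefixes[!tables$mod_prefixes$phospho, , drop = FALSE]
  prefixes <- unique(np$prefix)
  prefixes <- prefixes[order(-nchar(prefixes))]  # maximal munch
  paste0("^(?:([0-9]+)x)?(",
         paste(vapply(prefixes, function(p)
           gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", p), ""),
           collapse = "|"),
         ")([0-9]+)?-")
}

psimod_for_prefix <- function(prefix, tables) {
  np <- tables$mod_prefixes[!tables$mod_prefixes$phospho, , drop = FALSE]
  i <- match(prefix, np$prefix)
  list(psimod_id = np$psimod_id[i], includes_coordinate =
         np$includes_coordinate[i])
}

HOMOMER_WORDS <- c(dimer = 2L, trimer = 3L, tetramer = 4L, pentamer = 5L,
                   hexamer = 6L)

#' Parse a CV entity name into an entity tree
#'
#' Inverts the naming grammar: complexes and sets are recovered from their
#' separators and bracket structure, peptides from their PTM prefixes,
#' symbol and coordinate suffix (PSI-MOD accessions are recovered by
#' reverse prefix lookup), and small molecules from the abbreviation table.
#' Bare tokens that are neither table abbreviations nor gene-symbol shaped
#' (upper-case alphanumeric) are returned as opaque small-molecule leaves
#' rather than rejected, since names may contain abbreviations outside the
#' seed table. The parser is tolerant of the en dash in coordinate ranges,
#' of spaces after commas, and of homomer words ("PPOX dimer" reads as
#' 2xPPOX); the generator always emits the strict canonical form, so
#' `name_entity(parse_entity_name(s))` reproduces every canonical `s`.
#'
#' Rejected strings (unbalanced brackets, mixed ":" and "," at one level,
#' empty items) raise a `cv_parse_error` carrying a character offset.
#'
#' @param text The name to parse.
#' @param tables Lookup tables from [cv_tables()].
#' @return A `cv_peptide`, `cv_molecule` or `cv_assembly`.
#' @export
#' @examples
#' parse_entity_name("GRB2:SOS1")
#' parse_entity_name("HRH2,HRH3,(HRH6,HRH8)")
parse_entity_name <- function(text, tables = default_cv_tables()) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    parse_error("empty name", 1L)
  s <- gsub("–", "-", text)
  st <- list(s = s, prot = protected_comma_positions(s),
             np_re = non_phospho_prefix_re(tables), tables = tables)
  node <- parse_level(st, 1L, nchar(s))
  node
}

# split s[from..to] at depth-0 unprotected separators; returns items and sep
split_level <- function(st, from, to) {
  depth <- 0L
  sep <- NA_character_
  breaks <- integer()
  chars <- substring(st$s, from:to, from:to)
  for (k in seq_along(chars)) {
    ch <- chars[k]
    pos <- from + k - 1L
    if (ch %in% c("[", "(")) depth <- depth + 1L
    else if (ch %in% c("]", ")")) {
      depth <- depth - 1L
      if (depth < 0L) parse_error("unbalanced closing bracket", pos)
    } else if (depth == 0L && (ch == ":" ||
               (ch == "," && !(pos %in% st$prot)))) {
      if (is.na(sep)) sep <- ch
      else if (sep != ch)
        parse_error("mixed ':' and ',' separators at one level", pos)
      breaks <- c(breaks, pos)
    }
  }
  if (depth != 0L) parse_error("unbalanced opening bracket", to)
  starts <- c(from, breaks + 1L)
  ends <- c(breaks - 1L, to)
  if (any(ends < starts)) parse_error("empty item", starts[ends < starts][1])
  list(sep = sep, starts = starts, ends = ends)
}

parse_level <- function(st, from, to) {
  sp <- split_level(st, from, to)
  items <- mapply(function(a, b) parse_item(st, a, b, sp$sep),
                  sp$starts, sp$ends, SIMPLIFY = FALSE)
  if (is.na(sp$sep)) {
    it <- items[[1]]
    if (it$group)
      parse_error("a candidate group needs at least one set member", from)
    if (it$stoich > 1L)
      return(cv_assembly("complex", list(cv_part(it$entity, it$stoich))))
    return(it$entity)
  }
  grp <- vapply(items, function(i) i$group, TRUE)
  if (sp$sep == ":") {
    if (any(grp))
      parse_error("candidate groups are only valid in sets",
                  sp$starts[grp][1])
    parts <- lapply(items, function(i) cv_part(i$entity, i$stoich))
    return(cv_assembly("complex", parts))
  }
  members <- lapply(items[!grp], function(i) cv_part(i$entity, i$stoich))
  if (!any(grp)) return(cv_assembly("defined_set", members))
  cands <- unlist(lapply(items[grp], function(i)
    lapply(i$candidates, function(c)
      cv_part(c$entity, c$stoich, candidate = TRUE))),
    recursive = FALSE)
  if (!length(members))
    parse_error("a candidate set needs at least one verified member", from)
  cv_assembly("candidate_set", c(members, cands))
}

parse_item <- function(st, from, to, sep) {
  # tolerate spaces after separators
  while (from <= to && substr(st$s, from, from) == " ") from <- from + 1L
  while (to >= from && substr(st$s, to, to) == " ") to <- to - 1L
  if (from > to) parse_error("empty item", from)
  first <- substr(st$s, from, from)

  if (first == "(") {
    if (substr(st$s, to, to) != ")")
      parse_error("candidate group does not span the whole item", to)
    inner <- split_level(st, from + 1L, to - 1L)
    if (!is.na(inner$sep) && inner$sep != ",")
      parse_error("candidates must be comma-separated", from + 1L)
    cands <- mapply(function(a, b) parse_item(st, a, b, ","),
                    inner$starts, inner$ends, SIMPLIFY = FALSE)
    if (any(vapply(cands, function(c) c$group, TRUE)))
      parse_error("nested candidate groups are not allowed", from)
    return(list(entity = NULL, stoich = 1L, group = TRUE,
                candidates = cands))
  }

  stoich <- 1L
  txt <- substr(st$s, from, to)
  m <- regmatches(txt, regexec("^([0-9]+)x", txt))[[1]]
  if (length(m)) {
    rest <- substr(txt, nchar(m[1]) + 1L, nchar(txt))
    # "2xPalmC-..." is a PTM multiplicity, not part stoichiometry
    if (!grepl(st$np_re, rest)) {
      stoich <- as.integer(m[2])
      from <- from + nchar(m[1])
      first <- substr(st$s, from, from)
    }
  }

  if (first == "[") {
    if (substr(st$s, to, to) != "]")
      parse_error("bracketed assembly does not span the whole item", to)
    entity <- parse_level(st, from + 1L, to - 1L)
    return(list(entity = entity, stoich = stoich, group = FALSE))
  }

  # homomer alias: "PPOX dimer" etc.
  leaf_txt <- substr(st$s, from, to)
  hm <- regmatches(leaf_txt,
                   regexec("^(.*\\S) (dimer|trimer|tetramer|pentamer|hexamer)$",
                           leaf_txt))[[1]]
  if (length(hm) && !startsWith(leaf_txt, "Active ")) {
    inner <- parse_leaf(st, from, from + nchar(hm[2]) - 1L)
    return(list(entity = cv_assembly("complex",
                                     list(cv_part(inner,
                                                  HOMOMER_WORDS[[hm[3]]]))),
                stoich = stoich, group = FALSE))
  }

  list(entity = parse_leaf(st, from, to), stoich = stoich, group = FALSE)
}

parse_leaf <- function(st, from, to) {
  txt <- substr(st$s, from, to)
  off <- from
  active <- FALSE
  if (startsWith(txt, "Active ")) {
    active <- TRUE
    off <- off + 7L
    txt <- substr(txt, 8L, nchar(txt))
  }
  ptms <- list()
  had_ptm <- FALSE
  repeat {
    m <- regmatches(txt, regexec(st$np_re, txt))[[1]]
    if (length(m)) {
      mult <- if (nzchar(m[2])) as.integer(m[2]) else 1L
      coord <- if (nzchar(m[4])) as.integer(m[4]) else NA_integer_
      if (mult > 1L && !is.na(coord))
        parse_error("multiplicity and coordinate cannot combine on one prefix",
                    off)
      mod <- psimod_for_prefix(m[3], st$tables)
      ptms[[length(ptms) + 1L]] <- cv_ptm(mod$psimod_id, coordinate = coord,
                                          multiplicity = mult)
      off <- off + nchar(m[1])
      txt <- substr(txt, nchar(m[1]) + 1L, nchar(txt))
      had_ptm <- TRUE
      next
    }
    pm <- regmatches(txt, regexec(paste0("^", PHOSPHO_BLOCK_RE), txt))[[1]]
    if (length(pm)) {
      toks <- strsplit(substr(pm[1], 3L, nchar(pm[1]) - 1L), ",",
                       fixed = TRUE)[[1]]
      for (tk in toks) {
        g <- regmatches(tk,
                        regexec("^(?:([0-9]+)x)?([STY])?([0-9]+)?$", tk))[[1]]
        mult <- if (nzchar(g[2])) as.integer(g[2]) else 1L
        subtype <- if (nzchar(g[3])) g[3] else "none"
        coord <- if (nzchar(g[4])) as.integer(g[4]) else NA_integer_
        ptms[[length(ptms) + 1L]] <-
          cv_ptm(phospho_id_for_subtype(subtype), subtype = subtype,
                 coordinate = coord, multiplicity = mult)
      }
      off <- off + nchar(pm[1])
      txt <- substr(txt, nchar(pm[1]) + 1L, nchar(txt))
      had_ptm <- TRUE
      break  # phosphorylations are rendered last; the symbol follows
    }
    # bare "p-" (subtype and position unknown) directly before the symbol
    if (grepl("^p-[A-Z]", txt) && !grepl("^p-[STY][0-9,STYx-]*-", txt)) {
      ptms[[length(ptms) + 1L]] <- cv_ptm(phospho_id_for_subtype("none"))
      off <- off + 2L
      txt <- substr(txt, 3L, nchar(txt))
      had_ptm <- TRUE
    }
    break
  }
  if (!nzchar(txt)) parse_error("modification prefix without a symbol", off)

  cm <- regmatches(txt,
                   regexec("^(.+)\\(([0-9]+|\\?)-([0-9]+|\\?)\\)$", txt))[[1]]
  had_coords <- length(cm) > 0L
  if (had_coords) {
    sym <- cm[2]
    start <- int_or_na(cm[3])
    end <- int_or_na(cm[4])
  } else {
    sym <- txt
    start <- NA_integer_
    end <- NA_integer_
  }

  if (had_ptm || had_coords || active)
    return(cv_peptide(sym, start = start, end = end, chain_count = 1L,
                      ptms = ptms, active = active))
  if (sym %in% st$tables$molecule_abbrev$abbreviation)
    return(cv_molecule(sym))
  if (grepl("^[A-Z][A-Z0-9]*$", sym))
    return(cv_peptide(sym, chain_count = 1L))
  cv_molecule(sym)  # opaque leaf: an abbreviation outside the seed table
}
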