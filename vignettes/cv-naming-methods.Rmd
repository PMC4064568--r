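---
title: "Controlled vocabulary naming for pathway entities and events: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlled vocabulary naming for pathway entities and events: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pathwaycv)
```

## The problem

Curated pathway databases are full of molecular species that have no name
in the literature: cleavage fragments, multiply phosphorylated forms,
transient complexes, curator-defined sets of interchangeable proteins, and
the reactions connecting them. Free-text names for these objects are
ambiguous, inconsistent, and hostile to text search — a user searching for
"phosphorylates" will not find a reaction named "Conversion of Glycerol to
Glycerol-3-phosphate". `pathwaycv` implements a controlled vocabulary (CV)
in the style used by the Reactome knowledgebase: names are *derived* from
the structure of the entity, deterministically and table-driven, so that
equal structures always get byte-identical names and the name alone
describes the composition.

The package does three things:

1. **generates** CV names for peptides, small molecules, complexes, sets
   and reactions;
2. **parses** entity CV names back into structured trees, which is what
   makes "unambiguous" an operational claim rather than a slogan; and
3. **classifies** reactions into a small set of event categories with
   fixed phrase templates.

## Peptide names

A peptide name is `[Active ] + <PTM prefix> + <HGNC symbol> +
<coordinate suffix>`.

**Gene symbol core.** The HGNC gene symbol is the only broadly recognized
source of short unambiguous human protein names, so it anchors every
peptide name.

**Coordinate suffix.** Start/end coordinates are 1-based, inclusive, and
always refer to the reference record's Chain feature (even where the
literature renumbers after signal-peptide removal). When the record has
exactly one Chain and the peptide coordinates agree with it, the suffix is
omitted (`CASP9`); otherwise both coordinates are appended in round
brackets, with `?` for unknown values (`CASP9(316-416)`, `ACAN(17-?)`).
With no Chain or multiple Chains the suffix is always added and
`check_exemption()` reports `MULTI_OR_NO_CHAIN`, meaning "a manual
coordinate choice is required", not "unnameable".

**PTM prefixes.** Modifications are identified by PSI-MOD accession and
rendered through the `mod_prefixes.tsv` table, which also records whether
the residue coordinate is written into the name (it is for di-/tri-lysine
and arginine methylation, lysine acetylation, ubiquitination and
phosphorylation — the classes where omitting it would create duplicate
names). Phosphorylation is special: it carries an S/T/Y subtype letter,
its sites are listed comma-separated in ascending coordinate order, and
the whole phospho block is always rendered *after* every other prefix:

```{r}
name_peptide(cv_peptide("NOS3", 2, 1203, 1, 1203,
  ptms = list(cv_ptm("MOD:00115", coordinate = 15),
              cv_ptm("MOD:00115", coordinate = 26),
              cv_ptm("MOD:00068", coordinate = 2),
              cv_ptm("MOD:00046", subtype = "S", coordinate = 1177))))
```

Two ordering decisions were genuinely open and are worth recording:

* **Non-phospho prefix order.** Prefixes whose first modified residue is
  known are ordered by *descending* coordinate (palmitoylated cysteines
  15/26 before the myristoylated glycine 2, reproducing
  `2xPalmC-MyrG-...`). Prefixes with no known site sort after those, in
  *descending* alphabetical order. Descending alphabetical — rather than
  ascending — was chosen so that the coordinate-stripped form of a name
  (what a parser can recover: `PalmC` > `MyrG`) re-renders in the same
  order, keeping generate∘parse an identity on canonical strings.
* **Multiplicity.** `n` occurrences of a coordinate-less modification
  render as `nx` + prefix. Two representations produce the same name
  (two single entries with hidden coordinates, or one merged entry with
  multiplicity 2); the fixture generator always emits the merged form so
  that parsing is an exact inverse on generated corpora.

**Exemptions.** Disease mutations, non-canonical isoforms, non-simple
modifications (e.g. internal cross-links) and HLA loci are excluded from
automatic naming; `name_peptide()` raises a typed `cv_exemption_error`
unless `override = TRUE`. Activated conformations with unchanged covalent
structure get an `Active ` prefix instead. When cleavage of a peptide with
uncertain coordinates produces fragments with identical names (two
`ACAN(17-?)` fragments), the package flags the group via
`validate_namespace()` for manual naming — it never invents an index
suffix, because a tailored manual name is the prescribed resolution for
this rare case.

## Small molecules

`name_molecule()` prefers a short familiar abbreviation
(`molecule_abbrev.tsv`) over the full reference chemical name, matching
case-insensitively with whitespace collapsed, and falls back to the
reference name verbatim. Abbreviations never appear as keys, so the map is
idempotent. The shipped table is a seed covering the published examples
(`I(1,3,4,5,6)P5`, `4-Di-2-ASP`, `Na+`, `Man`, ...); real deployments
extend it. The canonical abbreviation contains no internal spaces; the
parser tolerates the spaced variant.

## Complexes and sets

Composition is the name: members joined by `:` for complexes and `,` for
sets, in curator order (sorting would break established names such as
`IL3:IL3RA:IL3RB:JAK2`). A part occurring *n* > 1 times renders as `nx` +
name (`2xPPOX:FAD`); homomer words like "dimer" are accepted on parse but
never generated, resolving the vocabulary's optional familiar form toward
the machine-friendly one. Candidate sets append their unverified members
in one trailing round-bracket group (`HRH2,HRH3,(HRH6,HRH8)`); the
constructor canonicalizes candidate parts to the end, preserving relative
order, since the single published example shows them trailing and a fixed
position makes names deterministic.

Flat concatenation describes composition but not assembly history:
`ABC1:ABC2:ABC3:ABC4` could arise from `[ABC1:ABC2]` + `[ABC3:ABC4]` or
from `[ABC1:ABC2:ABC3]` + `ABC4`. Any member that is itself an assembly of
two or more parts is therefore wrapped in square brackets, which keeps the
two histories distinct at every nesting level. A nested assembly with a
single part is *not* bracketed (it is indistinguishable from its only
member in name terms and collapses).

**Diagram labels.** `shorten_label()` provides the shortened plural forms
used where a full composition name will not fit: a curator-supplied
functional label wins; otherwise a common stem with trailing integers
compresses to ranges (`CCR1-5`, `CCR1,3-5` — runs shorter than three stay
comma-separated, which is why a two-member set reads `NMT1,2`). The plural
stem form (`VAVs`) additionally requires `family_complete = TRUE`: whether
a set covers the whole family and will not grow is a curation judgement
the code cannot make, so it is exposed as a flag rather than guessed.

## Reactions

`classify_reaction()` applies a fixed precedence so that the most
specific, attribute-gated classes win; the vocabulary defines the
categories but not an evaluation order, and overlaps are real (transport
reactions also have a catalyst):

1. explicit polymerization/depolymerization class (carried in the source
   data model, never inferred);
2. catalyst whose GO molecular function maps to the *exchange*,
   *cotransport* or *transport* template;
3. unchanged entities changing compartment with no catalyst →
   translocation;
4. any other catalyst → transfer (transferase template) or catalysis;
5. more inputs than outputs with an input becoming a component of an
   output → binding (the containment test doubles as a stoichiometric
   balance check);
6. the mirror case → dissociation;
7. identical entities and compartments → activation;
8. otherwise transformation, the default category.

Verbs come from `gomf_verbs.tsv` (exact match first, then a substring
fallback mapping the hydrolase family — any term containing
"phosphodiesterase", "esterase", "lipase", "fumarylacetoacetase" or
"GTPase" — to *hydrolyses*); a miss is a defined result selecting the
generic *catalyzes* template. Verbs are lower case (the vocabulary is
case-insensitive) and agree in number with a set catalyst:

```{r}
ex <- cv_worked_examples()
name_reaction(ex$reactions$nmt_myristoyl_transfer)
name_reaction(ex$reactions$slc6a12_symport)
```

Template details that were open and how they were resolved:

* The product clause of a catalysis (`... to PGD2`) is omitted when every
  output is a peptide or complex whose gene-symbol core matches an input
  core — i.e. the product is just the modified form of the substrate, as
  in `HLCS biotinylates ACACA`.
* Cotransport stoichiometry renders as a count prefix with no space
  (`3Na+`), following the published symporter phrasing.
* Compartment clauses follow each template literally: square brackets for
  translocation (`from [cytosol] to [nucleoplasm]`, with
  `[compartment of cell type]` for cross-cell movement), a parenthesized
  `(across the ... membrane)` for exchangers, `(from ... to ...)` for
  transporters.
* Regulation attaches to an event additively and composes as a separate
  statement (`name_regulation()`): "*regulator* positively|negatively
  regulates *event name*".

## The parser, and what "unambiguous" means here

`parse_entity_name()` is a recursive-descent parser over the entity
grammar: a uniform separator (`:` or `,`) per bracket level, square
brackets for pre-existing sub-assemblies, round brackets for candidate
groups and coordinate suffixes, and leaf tokens carrying PTM prefixes.
Three disambiguation rules carry the weight:

* **Maximal munch for phospho tokens.** In `p-Y150,S343,T346-WASF2` the
  commas belong to the phosphorylation list, not to an enclosing set;
  after `p-`, tokens of shape `[STY]?digits` bind to the phospho block.
  The residual ambiguity (a set whose first member is a multiply
  phosphorylated peptide) is resolved in favour of the peptide reading,
  which is the only reading that yields a well-formed name.
* **`nx` binding.** `2x` followed by a known non-phospho PTM prefix and a
  hyphen is a modification multiplicity (`2xPalmC-...`); otherwise it is
  part stoichiometry (`2xPPOX`). The fixture generator never applies
  stoichiometry > 1 to a modified peptide, so generated names avoid the
  collision entirely.
* **Leaf typing.** A bare token with PTM prefixes, coordinates or an
  `Active ` prefix is a peptide; a token found in the abbreviation table
  is a small molecule; an upper-case alphanumeric token is presumed a gene
  symbol; anything else becomes an *opaque* small-molecule leaf rather
  than an error, since names may legitimately contain abbreviations
  outside the seed table.

The parser accepts the en dash variant of coordinate ranges, spaces after
commas, and homomer words; the generator always emits the strict canonical
form. Errors (unbalanced brackets, mixed separators at one level, empty
items) carry a character offset.

Unbracketed flat names of multiply-assembled complexes remain genuinely
ambiguous — the square-bracket rule exists precisely because composition
alone cannot distinguish assembly histories — and such names parse as
flat. Parsing recovers exactly what the name encodes: a bare symbol parses
to a peptide with unknown coordinates and a single presumed chain, not to
the original record's chain annotation; round-trip identity is therefore
stated (and tested) on the generator's canonical forms, while the
chain-agreement logic is tested separately with full chain coordinates.

## The synthetic-data generator

`generate_fixture_entities()` emulates the population of entities a
curated human-pathway database holds: ~65% peptides among leaves (the
dominant class), about a third of peptides being cleavage fragments with
coordinate suffixes, 0–3 modifications per peptide biased toward
phosphorylation with known sites, small molecules drawn from the
abbreviation table, and assemblies of 2–4 parts (complexes more common
than defined sets, candidate sets rarest) with occasional stoichiometry of
2–3, nested to a requested depth. Output is a pure function of
`(seed, n, max_depth)` and leaves the caller's RNG stream untouched.

What it deliberately does **not** emulate: real UniProt chain annotations
(generated peptides carry a single presumed chain so trees are
parser-canonical), shared sub-complexes (each occurrence is an identical
tree — names depend only on composition, so a DAG adds nothing to naming),
entities exempt from naming, and free-text legacy aliases. Passing the
round-trip and uniqueness suites on this corpus therefore demonstrates the
grammar's internal consistency — injectivity of naming on distinct
structures and invertibility of canonical names — not coverage of every
chemical name string found in the wild; opaque-leaf parsing is the escape
hatch for those.

`generate_fixture_reactions()` builds reactions of every event category
with the intended category attached, so classifier tests can check
construction against classification; `enumerate_assembly_trees()` and
`enumerate_reactions()` provide the exhaustive small spaces (all trees
with ≤ 4 leaves and depth ≤ 2 over fixed canonical leaves — 2,776 trees;
all reactions over a 4-entity universe with multisets of size ≤ 3 per
side, six catalyst options and an optional compartment change — 13,872
reactions) used by the verification suites. These sizes run in a couple
of minutes on one core and exhaust the branch combinations of the
grammar and the classifier precedence; larger bounds multiply runtime
without adding new structural cases.

## Numerical and degenerate-input choices

* Coordinates are integers with `NA` as the unknown value, serialized as
  `"?"` in documents (mirroring the printed `(17-?)` convention); chain
  coordinates serialize as `null` when absent.
* `start > end` (both known) is rejected at construction; `start = end`
  is legal (single-residue peptides).
* Duplicate modifications — the same prefix/subtype at the same known
  coordinate — are rejected; unknown-site duplicates merge into the `nx`
  form instead, since "listed twice with unknown sites" and "multiplicity
  two" are the same statement.
* A phosphorylation with unknown subtype *and* position (`p-`) cannot be
  combined with other phosphorylations: the grammar has no slot for an
  empty token in a comma list.
* Assemblies are trees; construction cannot create cycles, and the
  renderer additionally guards nesting depth (200) against hand-built
  pathological structures.
* Namespace validation treats duplicates among *exempt* entities as
  non-fatal: their names are curated manually by definition.

## Known limitations

* The shipped tables are seeds, not the full production tables (1,463 GO
  molecular function terms mapping to 61 verbs; the complete abbreviation
  list); the code paths are table-driven precisely so installations can
  extend them without code changes.
* Event (reaction) sentences are generated but not parsed back; only
  entity names round-trip.
* Molecule names containing the grammar's metacharacters in unusual
  positions (a leading round bracket, a literal `:`) can only appear as
  opaque leaves in *parsed* trees if they are bracketed or table-known;
  the generator avoids emitting them inside assemblies.
* The disease-mutation extension of the vocabulary and automatic HLA
  allele naming are out of scope by design; both are reported as
  exemptions.
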