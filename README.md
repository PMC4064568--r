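# pathwaycv

Controlled vocabulary (CV) names for pathway entities and events.

Curated pathway databases (Reactome-style) are full of molecular species
with no literature name: cleavage fragments, phosphorylated forms,
transient complexes, curator-defined sets, and the reactions that connect
them. Free-text names for these objects are ambiguous and unsearchable.
`pathwaycv` derives names *from structure*, deterministically and
table-driven:

* **Peptides** — `[Active ] + <PTM prefix> + <HGNC symbol> + <coordinate
  suffix>`: `CASP9(316-416)`, `ACAN(17-?)`,
  `2xPalmC-MyrG-p-S1177-NOS3(2-1203)`. Phosphorylation sites are listed in
  ascending coordinate order after all other prefixes; coordinates always
  refer to the reference Chain feature; disease mutants, non-canonical
  isoforms, cross-linked forms and HLA loci are exempted with typed codes.
* **Small molecules** — short familiar abbreviations in preference to the
  full chemical name (`I(1,3,4,5,6)P5`, `Na+`), falling back verbatim.
* **Complexes and sets** — composition is the name: `GRB2:SOS1`,
  `2xPPOX:FAD`, `HRH2,HRH3,(HRH6,HRH8)` (candidates in round brackets),
  with square brackets preserving assembly history:
  `[ABC1:ABC2]:[ABC3:ABC4]` ≠ `[ABC1:ABC2:ABC3]:ABC4`. Diagram labels
  compress protein families (`VAVs`, `CCR1-5`, `CCR1,3-5`).
* **Reactions** — a rule-based classifier assigns one of twelve event
  categories (binding, dissociation, translocation, transport, exchange,
  cotransport, transfer, catalysis, ...) by fixed precedence, and renders
  the category's phrase template with GO-molecular-function-derived verbs:
  `HLCS biotinylates ACACA`, `SLC6A12 cotransports GABA with 3Na+ and
  2Cl-`, `NMT1,2 transfer MYS to GNAT1 (to form N-(C14:0)-GNAT1)`.
* **A parser** — `parse_entity_name()` inverts the entity grammar, so
  "unambiguous" is operational: canonical names round-trip to their
  entity trees.

## Worked example

```r
library(pathwaycv)

# a lipidated, phosphorylated cleavage fragment
nos3 <- cv_peptide("NOS3", 2, 1203, 1, 1203,
  ptms = list(cv_ptm("MOD:00115", coordinate = 15),   # palmitoyl-Cys
              cv_ptm("MOD:00115", coordinate = 26),
              cv_ptm("MOD:00068", coordinate = 2),    # myristoyl-Gly
              cv_ptm("MOD:00046", subtype = "S", coordinate = 1177)))
name_peptide(nos3)
#> 2xPalmC-MyrG-p-S1177-NOS3(2-1203)
```

The prefix reads: two palmitoylated cysteines (sites not written for this
modification class, so they merge to `2x`), one myristoylated glycine,
then the phosphorylation block last; the suffix appears because the
fragment (2–1203) differs from the reference chain (1–1203).

```r
ex <- cv_worked_examples()          # curated demonstration corpus
name_assembly(ex$assemblies$abc_hrh)$text
#> [1] "[[[[ABC1:ABC2]:[ABC3:ABC4]]:XYZ1]:MNO1]:[HRH2,HRH3,(HRH6)]"

classify_reaction(ex$reactions$slc9a9_antiport)
#> [1] "EXCHANGE"
name_reaction(ex$reactions$slc9a9_antiport)
#> SLC9A9 exchanges Na+ for H+ (across the late endosome membrane)

# names invert: parse, then regenerate
tree <- parse_entity_name("p-Y150,S343,T346-WASF2")
length(tree$ptms)        # one peptide with three phosphorylations,
#> [1] 3                  # not a three-member set (maximal munch)
name_entity(tree)$text
#> [1] "p-Y150,S343,T346-WASF2"
```

Batch curation tools: `rename_batch()` produces a TSV audit (old name
kept as alias, new CV name or exemption code, event category per
reaction); `validate_namespace()` reports duplicate name groups — e.g.
two `ACAN(17-?)` fragments from cleavage at an unknown site — for manual
naming rather than silently suffixing them. A thin command-line wrapper
ships at `inst/cli/pathwaycv` (subcommands `name-entity`,
`name-reaction`, `classify`, `parse`, `validate`, `rename`, `fixtures`).

The lookup tables under `inst/extdata/` (PSI-MOD prefix map,
small-molecule abbreviations, GO molecular function → verb map) are
extensible seeds; point `cv_tables(dir)` at an extended copy to grow the
vocabulary without code changes.

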