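pep <- function(sym, ...) cv_peptide(sym, ...)

phos <- function(subtype, coord = NA) {
  ids <- c(S = "MOD:00046", T = "MOD:00047", Y = "MOD:00048")
  cv_ptm(ids[[subtype]], subtype = subtype, coordinate = coord)
}

# small canonical leaves reused by parser and enumeration tests
canonical_leaves <- function() {
  list(pep("GRB2"),
       pep("CASP9", start = 316, end = 416),
       pep("DAPP1", ptms = list(phos("Y", 139))),
       cv_molecule("ATP"))
}
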