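#' Classic worked examples as structured fixtures
#'
#' A curated demonstration corpus: structured encodings of well-known
#' pathway entities and events (caspase-9 processing, NOS3 lipidation,
#' receptor complexes and sets, transferase/antiporter/symporter events)
#' whose CV names are established reference points for the vocabulary.
#' Useful as a smoke test of the full naming stack and as input to
#' [rename_batch()].
#'
#' @return A list with elements `peptides`, `assemblies`, `label_sets` and
#'   `reactions`, each a named list of structures.
#' @export
#' @examples
#' ex <- cv_worked_examples()
#' name_peptide(ex$peptides$casp9_large)$text
cv_worked_examples <- function() {
  pep <- function(sym, ...) cv_peptide(sym, ...)
  p_y <- function(coord) cv_ptm("MOD:00048", subtype = "Y",
                                coordinate = coord)
  p_s <- function(coord) cv_ptm("MOD:00046", subtype = "S",
                                coordinate = coord)
  p_t <- function(coord) cv_ptm("MOD:00047", subtype = "T",
                                coordinate = coord)

  peptides <- list(
    # caspase-9 precursor and its two cleavage subunits
    casp9_precursor = pep("CASP9", 1, 416, 1, 416),
    casp9_large = pep("CASP9", 1, 315, 1, 416),
    casp9_small = pep("CASP9", 316, 416, 1, 416),
    # aggrecan N-terminal fragment, second cleavage site unknown
    acan_nterm = pep("ACAN", 17, NA, 17, 2415),
    dapp1_py = pep("DAPP1", ptms = list(p_y(139))),
    wasf2_multi = pep("WASF2", ptms = list(p_s(343), p_y(150), p_t(346))),
    spry2_multi = pep("SPRY2",
                      ptms = list(p_y(55), p_s(112), p_s(121), p_y(227))),
    gab2_py_unknown = pep("GAB2",
                          ptms = list(cv_ptm("MOD:00048", subtype = "Y"))),
    gli3_p_unknown = pep("GLI3", ptms = list(cv_ptm("MOD:00696"))),
    # NOS3 fragment with two palmitoylated cysteines (15, 26), one
    # myristoylated glycine (2) and phospho-serine 1177
    nos3_lipidated = pep("NOS3", 2, 1203, 1, 1203,
                         ptms = list(cv_ptm("MOD:00115", coordinate = 15),
                                     cv_ptm("MOD:00115", coordinate = 26),
                                     cv_ptm("MOD:00068", coordinate = 2),
                                     p_s(1177))))

  abc_pair <- cv_complex(cv_complex(pep("ABC1"), pep("ABC2")),
                         cv_complex(pep("ABC3"), pep("ABC4")))
  abc_xyz <- cv_complex(abc_pair, pep("XYZ1"))
  abc_mno <- cv_complex(abc_xyz, pep("MNO1"))
  assemblies <- list(
    grb2_sos1 = cv_complex(pep("GRB2"), pep("SOS1")),
    il3_receptor = cv_complex(pep("IL3"), pep("IL3RA"), pep("IL3RB"),
                              pep("JAK2")),
    ppox_fad = cv_complex(cv_part(pep("PPOX"), 2),
                          cv_molecule("flavin adenine dinucleotide")),
    il3_set = cv_set(pep("IL3"), pep("IL3RA"), pep("CSF2RB")),
    hrh_candidates = cv_candidate_set(list(pep("HRH2"), pep("HRH3")),
                                      list(pep("HRH6"), pep("HRH8"))),
    abc_pair = abc_pair,
    abc_xyz = abc_xyz,
    abc_mno = abc_mno,
    abc_hrh = cv_complex(abc_mno,
                         cv_candidate_set(list(pep("HRH2"), pep("HRH3")),
                                          list(pep("HRH6")))),
    # the flat alternative assembly history the square brackets distinguish
    abc_flat_history = cv_complex(cv_complex(pep("ABC1"), pep("ABC2"),
                                             pep("ABC3")), pep("ABC4")))

  label_sets <- list(
    vav_family = cv_set(pep("VAV1"), pep("VAV2"), pep("VAV3")),
    ccr_full = cv_set(pep("CCR1"), pep("CCR2"), pep("CCR3"), pep("CCR4"),
                      pep("CCR5")),
    ccr_partial = cv_set(pep("CCR1"), pep("CCR3"), pep("CCR4"),
                         pep("CCR5")))

  reactions <- list(
    hlcs_biotinylation = cv_reaction(
      inputs = list(pep("ACACA")),
      outputs = list(pep("ACACA", ptms = list(cv_ptm("MOD:00126")))),
      catalyst = pep("HLCS"),
      catalyst_gomf = "biotin-protein ligase activity"),
    plb1_hydrolysis = cv_reaction(
      inputs = list(cv_molecule("retinyl palmitate")),
      outputs = list(cv_molecule("all-trans-retinol")),
      catalyst = pep("PLB1"),
      catalyst_gomf = "retinyl-palmitate esterase activity"),
    ptgds_isomerization = cv_reaction(
      inputs = list(cv_molecule("prostaglandin H2")),
      outputs = list(cv_molecule("prostaglandin D2")),
      catalyst = pep("PTGDS"),
      catalyst_gomf = "prostaglandin-D synthase activity"),
    alg9_mannosyl_transfer = cv_reaction(
      inputs = list(cv_molecule("(GlcNAc)2 (Man)6 (PP-Dol)1")),
      outputs = list(cv_molecule("(GlcNAc)2 (Man)7 (PP-Dol)1")),
      catalyst = pep("ALG9"),
      catalyst_gomf = "alpha-1,2-mannosyltransferase activity",
      transferred = cv_molecule("alpha-D-mannose")),
    nmt_myristoyl_transfer = cv_reaction(
      inputs = list(pep("GNAT1")),
      outputs = list(cv_molecule("N-(C14:0)-GNAT1")),
      catalyst = cv_set(pep("NMT1"), pep("NMT2")),
      catalyst_gomf = "glycylpeptide N-tetradecanoyltransferase activity",
      transferred = cv_molecule("myristic acid")),
    slc9a9_antiport = cv_reaction(
      inputs = list(cv_participant(cv_molecule("sodium(1+)"), "cytosol"),
                    cv_participant(cv_molecule("hydron"),
                                   "late endosome lumen")),
      outputs = list(cv_participant(cv_molecule("sodium(1+)"),
                                    "late endosome lumen"),
                     cv_participant(cv_molecule("hydron"), "cytosol")),
      catalyst = pep("SLC9A9"),
      catalyst_gomf = "sodium:proton antiporter activity",
      membrane = "late endosome"),
    slc17a5_symport = cv_reaction(
      inputs = list(cv_participant(cv_molecule("N-acetylneuraminic acid"),
                                   "lysosomal lumen"),
                    cv_participant(cv_molecule("hydron"),
                                   "lysosomal lumen")),
      outputs = list(cv_participant(cv_molecule("N-acetylneuraminic acid"),
                                    "cytosol"),
                     cv_participant(cv_molecule("hydron"), "cytosol")),
      catalyst = pep("SLC17A5"),
      catalyst_gomf = "sialic acid:proton symporter activity"),
    slc6a12_symport = cv_reaction(
      inputs = list(cv_participant(cv_molecule("gamma-aminobutyric acid"),
                                   "extracellular region"),
                    cv_participant(cv_molecule("sodium(1+)"),
                                   "extracellular region", count = 3),
                    cv_participant(cv_molecule("chloride"),
                                   "extracellular region", count = 2)),
      outputs = list(cv_participant(cv_molecule("gamma-aminobutyric acid"),
                                    "cytosol"),
                     cv_participant(cv_molecule("sodium(1+)"), "cytosol",
                                    count = 3),
                     cv_participant(cv_molecule("chloride"), "cytosol",
                                    count = 2)),
      catalyst = pep("SLC6A12"),
      catalyst_gomf = "GABA:sodium:chloride symporter activity"))

  list(peptides = peptides, assemblies = assemblies,
       label_sets = label_sets, reactions = reactions)
}
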