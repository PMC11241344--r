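# Physicochemical constants used by the descriptor engine.
#
# The seven three-class property partitions are the canonical Dubchak-style
# groupings used by standard CTD implementations (Dubchak et al. 1995;
# PROFEAT / propy conventions). Each partition assigns every one of the 20
# natural residues to exactly one of three classes; coverage and disjointness
# are enforced by tests.

PROPERTY_PARTITIONS <- list(
  hydrophobicity = list(
    "1" = c("R", "K", "E", "D", "Q", "N"),            # polar
    "2" = c("G", "A", "S", "T", "P", "H", "Y"),       # neutral
    "3" = c("C", "L", "V", "I", "M", "F", "W")        # hydrophobic
  ),
  normalized_vdw_volume = list(
    "1" = c("G", "A", "S", "C", "T", "P", "D"),       # 0-2.78
    "2" = c("N", "V", "E", "Q", "I", "L"),            # 2.95-4.0
    "3" = c("M", "H", "K", "F", "R", "Y", "W")        # 4.03-8.08
  ),
  polarity = list(
    "1" = c("L", "I", "F", "W", "C", "M", "V", "Y"),  # 4.9-6.2
    "2" = c("P", "A", "T", "G", "S"),                 # 8.0-9.2
    "3" = c("H", "Q", "R", "K", "N", "E", "D")        # 10.4-13.0
  ),
  polarizability = list(
    "1" = c("G", "A", "S", "D", "T"),                 # 0-0.108
    "2" = c("C", "P", "N", "V", "E", "Q", "I", "L"),  # 0.128-0.186
    "3" = c("K", "M", "H", "F", "R", "Y", "W")        # 0.219-0.409
  ),
  charge = list(
    "1" = c("K", "R"),                                # positive
    "2" = c("A", "N", "C", "Q", "G", "H", "I", "L",
            "M", "F", "P", "S", "T", "W", "Y", "V"),  # neutral
    "3" = c("D", "E")                                 # negative
  ),
  secondary_structure = list(
    "1" = c("E", "A", "L", "M", "Q", "K", "R", "H"),  # helix
    "2" = c("V", "I", "Y", "C", "W", "F", "T"),       # strand
    "3" = c("G", "N", "P", "S", "D")                  # coil
  ),
  solvent_accessibility = list(
    "1" = c("A", "L", "F", "C", "G", "I", "V", "W"),  # buried
    "2" = c("R", "K", "Q", "E", "N", "D"),            # exposed
    "3" = c("M", "S", "P", "T", "H", "Y")             # intermediate
  )
)

# pKa values (EMBOSS set) for ionizable groups; used by the net-charge and
# isoelectric-point descriptors.
PKA_SET <- c(
  nterm = 8.6, cterm = 3.6,
  C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1
)

# Average residue masses (Da); molecular weight = sum + one water.
RESIDUE_MASS <- c(
  A = 71.0788,  C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519,  H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167,  Q = 128.1307, R = 156.1875,
  S = 87.0782,  T = 101.1051, V = 99.1326,  W = 186.2132, Y = 163.1760
)
WATER_MASS <- 18.01524

# Residue sets for the simple global descriptors.
AROMATIC_SET <- c("F", "W", "Y")
HYDROPHOBIC_SET <- c("C", "L", "V", "I", "M", "F", "W")  # hydrophobicity class 3

#' Reference peptides
#'
#' Named amino-acid sequences of three peptides commonly used as controls in
#' cell-penetration assays: penetratin (a canonical cell-penetrating peptide),
#' melittin (the membrane-lytic bee-venom peptide), and the jellyfish-derived
#' peptide CpRE12, which has been printed in two variants differing by one
#' glutamine; both are included.
#'
#' @format Named character vector of length 4.
#' @export
reference_peptides <- c(
  penetratin = "RQIKIWFQNRRMKWKK",
  melittin   = "GIGAVLKVLTTGLPALISWIKRKRQQ",
  cpre12     = "SYQWQIFYRSLDGSGAKE",
  cpre12_alt = "SYQWQQIFYRSLDGSGAKE"
)
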