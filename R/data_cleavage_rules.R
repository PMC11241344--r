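# Registry of 35 ExPASy-style enzymatic cleavage rules. Each pattern is a
# Perl-compatible regex whose consumed text is the single residue after which
# the peptide bond is cleaved; lookarounds encode the site context (e.g.
# trypsin: after K/R, not before P). Patterns follow the standard registry
# shipped with common proteomics parsers; reassembly of fragments is
# verified by tests.
CLEAVAGE_RULES <- c(
  "arg-c" = "R",
  "asp-n" = "\\w(?=D)",
  "bnps-skatole" = "W",
  "caspase 1" = "(?<=[FWYL]\\w[HAT])D(?=[^PEDQKR])",
  "caspase 10" = "(?<=IEA)D",
  "caspase 2" = "(?<=DVA)D(?=[^PEDQKR])",
  "caspase 3" = "(?<=DMQ)D(?=[^PEDQKR])",
  "caspase 4" = "(?<=LEV)D(?=[^PEDQKR])",
  "caspase 5" = "(?<=[LW]EH)D",
  "caspase 6" = "(?<=VE[HI])D(?=[^PEDQKR])",
  "caspase 7" = "(?<=DEV)D(?=[^PEDQKR])",
  "caspase 8" = "(?<=[IL]ET)D(?=[^PEDQKR])",
  "caspase 9" = "(?<=LEH)D",
  "chymotrypsin high specificity" = "([FY](?=[^P]))|(W(?=[^MP]))",
  "chymotrypsin low specificity" = "([FLY](?=[^P]))|(W(?=[^MP]))|(M(?=[^PY]))|(H(?=[^DMPW]))",
  "clostripain" = "R",
  "cnbr" = "M",
  "enterokinase" = "(?<=[DE]{3})K",
  "factor xa" = "(?<=[AFGILTVM][DE]G)R",
  "formic acid" = "D",
  "glutamyl endopeptidase" = "E",
  "granzyme b" = "(?<=IEP)D",
  "hydroxylamine" = "N(?=G)",
  "iodosobenzoic acid" = "W",
  "lysc" = "K",
  "ntcb" = "\\w(?=C)",
  "pepsin ph1.3" = "((?<=[^HKR][^P])[^R](?=[FL][^P]))|((?<=[^HKR][^P])[FL](?=\\w[^P]))",
  "pepsin ph2.0" = "((?<=[^HKR][^P])[^R](?=[FLWY][^P]))|((?<=[^HKR][^P])[FLWY](?=\\w[^P]))",
  "proline endopeptidase" = "(?<=[HKR])P(?=[^P])",
  "proteinase k" = "[AEFILTVWY]",
  "staphylococcal peptidase i" = "(?<=[^E])E",
  "thermolysin" = "[^DE](?=[AFILMV][^P])",
  "thrombin" = "((?<=G)R(?=G))|((?<=[AFGILTVM][AFGILTVWA]P)R(?=[^DE][^DE]))",
  "trypsin" = "([KR](?=[^P]))|((?<=W)K(?=P))|((?<=M)R(?=P))",
  "trypsin_exception" = "((?<=[CD])K(?=D))|((?<=C)K(?=[HY]))|((?<=C)R(?=K))|((?<=R)R(?=[HR]))"
)
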