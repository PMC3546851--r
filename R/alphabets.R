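# Alphabet tables shared across the package: IUPAC nucleotide codes, their
# complements, the protein alphabet, Kyte-Doolittle hydropathies and the
# standard genetic code.

# IUPAC (IUB) nucleotide code -> set of unambiguous DNA bases
IUB_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# reverse lookup: sorted base set -> single IUPAC letter
IUB_FROM_BASES <- local({
  keys <- vapply(IUB_EXPANSION, function(b) paste(sort(b), collapse = ""), "")
  stats::setNames(names(IUB_EXPANSION), keys)
})

NUCLEIC_LETTERS <- c(names(IUB_EXPANSION), "U")

IUB_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", U = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

DNA_BASES <- c("A", "C", "G", "T")

# The 20 standard amino acids, alphabetical one-letter order
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
PROTEIN_LETTERS <- c(AMINO_ACIDS, "X", "*", "-")

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  END = "*", TER = "*", STP = "*", `***` = "*"
)

# Kyte & Doolittle hydropathy index
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# 64 DNA codons in TCAG nested order (the layout used by translation tables)
CODONS_TCAG <- local({
  b <- c("T", "C", "A", "G")
  as.vector(vapply(b, function(x) vapply(b, function(y)
    paste0(x, y, b), character(4)), matrix("", 4, 4)))
})

STANDARD_CODE_AAS <- paste0(
  "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
  "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"
)
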