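# Shared amino-acid tables (loaded first; other files use them at load
# time).

# Amino acids with a measured insertion profile. Pro gets a zero profile
# and a flag (its insertion signal reflects backbone perturbation, not
# sidechain lipophilicity).
AA_ONE <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Positive-inside residues: profiles stay asymmetric across the leaflets.
ASYMMETRIC_AA <- c("R", "H", "K")

# Three-letter <-> one-letter residue codes (standard 20).
AA_THREE_TO_ONE <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y"
)

AA_ONE_TO_THREE <- stats::setNames(names(AA_THREE_TO_ONE),
                                   unname(AA_THREE_TO_ONE))
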