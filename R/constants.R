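# Shared chemical reference tables.

#' @keywords internal
AA1 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

AA1_TO_3 <- structure(names(AA3_TO_1), names = unname(AA3_TO_1))

# Bondi-style van der Waals radii (Angstrom), heavy atoms only.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' Theoretical maximum accessible surface area per residue type
#'
#' Gly-X-Gly based theoretical maxima (Angstrom^2) used as the denominator of
#' relative solvent accessibility (Tien et al. 2013 values).
#'
#' @return Named numeric vector over the 20 one-letter amino-acid codes.
#' @export
max_asa_reference <- function() {
  c(A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
    E = 223.0, Q = 225.0, G = 104.0, H = 224.0, I = 197.0,
    L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
    S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0)
}

#' Controlled vocabulary of modification types
#' @return Character vector of the nine recognised modification names.
#' @export
ptm_vocabulary <- function() names(ptm_rules())

#' Side-chain chemical compatibility rules
#'
#' Which residue types can carry which modification. The ruleset is this
#' package's codification of standard side-chain chemistry: phosphorylation
#' needs a hydroxyl (S/T/Y), acetylation and ubiquitination a lysine
#' epsilon-amine, methylation lysine or arginine, the cysteine chemistries a
#' thiol, O-glucosylation a serine hydroxyl, ethanolamination a glutamate
#' carboxyl, and carbonylation follows the standard metal-catalysed-oxidation
#' targets (K/R/P/T). N-terminal acetylation is deliberately out of scope:
#' only side-chain events are modelled.
#'
#' @return Named list mapping modification type to a character vector of
#'   compatible one-letter residue codes. Editable: pass a modified copy to
#'   [modification_compatibility()].
#' @export
ptm_rules <- function() {
  list(
    phosphorylation     = c("S", "T", "Y"),
    acetylation         = "K",
    methylation         = c("K", "R"),
    ubiquitination      = "K",
    `S-nitrosylation`   = "C",
    `S-glutathionylation` = "C",
    `O-glucosylation`   = "S",
    ethanolamination    = "E",
    carbonylation       = c("K", "R", "P", "T"))
}

# Conservative-substitution groups used for alignment conservation calls.
SUBSTITUTION_GROUPS <- list(
  c("A", "G"), c("S", "T"), c("D", "E"), c("N", "Q"),
  c("K", "R", "H"), c("I", "L", "V", "M"), c("F", "W", "Y"),
  "C", "P")

# Residue charge signs used by charge_environment().
RESIDUE_CHARGE <- c(D = -1L, E = -1L, K = 1L, R = 1L)

backbone_atom_names <- c("N", "CA", "C", "O", "OXT")
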