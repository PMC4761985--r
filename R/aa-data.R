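# Amino-acid reference data: standard residue codes, side-chain heavy-atom
# names, and the named atom selectors used by the shell filters.

#' Standard amino-acid three-letter codes
#'
#' The 20 standard residue types recognised by the structure reader. All
#' other residue names (MSE, waters, ligands) are excluded from analysis.
#'
#' @format Character vector of length 20.
#' @export
STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

# Backbone heavy atoms; everything else (CB included) counts as side chain.
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# Side-chain heavy-atom names per residue type (PDB v3 nomenclature).
SIDECHAIN_ATOM_NAMES <- list(
  ALA = c("CB"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

# The 19 neighbour types tallied in the count tables (glycine has no
# side-chain heavy atom and is never a neighbour).
NONGLY_AA <- setdiff(STANDARD_AA, "GLY")

#' Infer the element symbol from a PDB atom name
#'
#' Used when the element columns of an ATOM record are blank. Digits are
#' stripped and the leading letter taken, so "NH1" -> "N", "CD1" -> "C",
#' "OG1" -> "O", "SD" -> "S". Names beginning with a digit followed by H
#' (e.g. "1HB") are hydrogens.
#'
#' @param name Character vector of PDB atom names.
#' @return Character vector of element symbols.
#' @export
element_from_name <- function(name) {
  nm <- toupper(trimws(name))
  out <- substr(gsub("[0-9]", "", nm), 1, 1)
  out[grepl("^[0-9]*H", nm)] <- "H"
  out
}

# Named atom-class selectors per residue type, mirroring the atom classes
# reported in the figure legends (carboxylate oxygens, amide O/N, hydroxyl
# oxygens, thioether sulphur, indole nitrogen).
ATOM_SELECTOR_REGISTRY <- list(
  "carboxylate-O" = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")),
  "amide-O"       = list(ASN = "OD1", GLN = "OE1"),
  "amide-N"       = list(ASN = "ND2", GLN = "NE2"),
  "hydroxyl-O"    = list(SER = "OG", THR = "OG1", TYR = "OH"),
  "thioether-S"   = list(MET = "SD"),
  "thiol-S"       = list(CYS = "SG"),
  "indole-N"      = list(TRP = "NE1")
)

#' List the available named atom selectors
#'
#' @return Character vector of selector names accepted by [shell_filter()]
#'   in addition to the element classes `"heavy"`, `"carbon"`, `"nitrogen"`,
#'   `"oxygen"`, `"sulfur"` and explicit atom-name vectors.
#' @export
atom_selectors <- function() {
  c(names(ATOM_SELECTOR_REGISTRY),
    "heavy", "carbon", "nitrogen", "oxygen", "sulfur")
}

# Resolve a selector to the matching side-chain atom names of one residue
# type. Returns character(0) when the class does not occur in that type.
resolve_selector <- function(selector, res_type) {
  sc <- SIDECHAIN_ATOM_NAMES[[res_type]]
  if (is.null(sc)) return(character(0))
  if (length(selector) > 1 ||
      (length(selector) == 1 && grepl("^[A-Z][A-Z0-9]{0,3}$", selector) &&
       !selector %in% atom_selectors() &&
       selector %in% unlist(SIDECHAIN_ATOM_NAMES, use.names = FALSE))) {
    return(intersect(selector, sc))        # explicit atom-name set
  }
  elem <- element_from_name(sc)
  switch(selector,
    heavy    = sc,
    carbon   = sc[elem == "C"],
    nitrogen = sc[elem == "N"],
    oxygen   = sc[elem == "O"],
    sulfur   = sc[elem == "S"],
    {
      entry <- ATOM_SELECTOR_REGISTRY[[selector]]
      if (is.null(entry))
        stop("unknown atom selector: ", paste(selector, collapse = ","),
             call. = FALSE)
      atoms <- entry[[res_type]]
      if (is.null(atoms)) character(0) else intersect(atoms, sc)
    }
  )
}
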