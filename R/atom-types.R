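#' Residue-specific heavy-atom typing
#'
#' The potentials in this package are defined over a residue-specific
#' heavy-atom alphabet: every heavy atom of the 20 standard amino acids gets
#' its own type, except that chemically indistinguishable symmetric pairs
#' within a residue share one type (PHE/TYR CD1/CD2 and CE1/CE2, ASP
#' OD1/OD2, GLU OE1/OE2, ARG NH1/NH2, LEU CD1/CD2, VAL CG1/CG2).  The 167
#' distinct heavy-atom names collapse to 158 types after these 9 merges.
#' Hydrogens, terminal OXT and non-standard residues carry no type.
#'
#' @name atom-typing
NULL

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.BACKBONE <- c("N", "CA", "C", "O")

.SIDECHAIN <- list(
  ALA = c("CB"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(),
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

# symmetric side-chain pairs merged onto one type (key -> representative)
.SYM_MERGE <- c(
  "PHE|CD2" = "CD1", "PHE|CE2" = "CE1",
  "TYR|CD2" = "CD1", "TYR|CE2" = "CE1",
  "ASP|OD2" = "OD1", "GLU|OE2" = "OE1",
  "ARG|NH2" = "NH1", "LEU|CD2" = "CD1",
  "VAL|CG2" = "CG1"
)

# legacy / variant atom-name aliases accepted on input (residue-keyed)
.NAME_ALIAS <- c(
  "ILE|CD" = "CD1",   # PDB v2 dialect
  "MSE|SE" = "SD",    # selenomethionine selenium, treated as MET SD
  "MET|SE" = "SD"
)

.typing_env <- new.env(parent = emptyenv())

#' Canonicalise a PDB atom name within a residue
#'
#' Upper-cases and strips blanks, resolves legacy aliases (`ILE CD` to
#' `CD1`, `OT1` to `O`), and folds symmetric side-chain partners onto their
#' representative name.  `OXT`/`OT2` and hydrogen names return `NA`.
#'
#' @param residue_name 3-letter residue code (vectorised).
#' @param atom_name PDB atom name (vectorised).
#' @param merge_symmetric Fold symmetric partners onto one name (default
#'   `TRUE`); with `FALSE` only aliasing and filtering are applied, so
#'   distinct atoms keep distinct names.
#' @return Character vector of canonical names, `NA` where the atom carries
#'   no type.
#' @export
canonical_atom_name <- function(residue_name, atom_name,
                                merge_symmetric = TRUE) {
  res <- toupper(trimws(residue_name))
  atm <- toupper(trimws(atom_name))
  atm[atm == "OT1"] <- "O"                       # terminal-oxygen variant
  atm[atm %in% c("OXT", "OT2")] <- NA_character_
  # hydrogens / deuteriums: names starting with H/D, or digit-prefixed (1HB2)
  atm[!is.na(atm) & grepl("^[0-9]*[HD]", atm)] <- NA_character_
  keyed <- unname(.NAME_ALIAS[paste(res, atm, sep = "|")])
  atm <- ifelse(is.na(keyed), atm, keyed)
  if (!merge_symmetric) return(atm)
  merged <- unname(.SYM_MERGE[paste(res, atm, sep = "|")])
  ifelse(is.na(merged), atm, merged)
}

#' The full heavy-atom typing table
#'
#' Enumerates every (residue, heavy atom) of the 20 standard amino acids with
#' its integer type id.  Symmetric partners appear as separate rows sharing
#' one `type_id`; the table has 167 rows and exactly 158 distinct ids.
#'
#' @return A tibble with columns `residue_name`, `atom_name`,
#'   `canonical_name`, `type_id` (integer in 1..158).
#' @export
#' @examples
#' tab <- atom_type_table()
#' length(unique(tab$type_id)) # 158
atom_type_table <- function() {
  if (!is.null(.typing_env$table)) return(.typing_env$table)
  rows <- purrr::map_dfr(.AA3, function(res) {
    atoms <- c(.BACKBONE, .SIDECHAIN[[res]])
    tibble::tibble(residue_name = res, atom_name = atoms)
  })
  rows$canonical_name <- canonical_atom_name(rows$residue_name, rows$atom_name)
  key <- paste(rows$residue_name, rows$canonical_name, sep = "|")
  rows$type_id <- as.integer(match(key, unique(key)))
  .typing_env$table <- rows
  .typing_env$lookup <- stats::setNames(rows$type_id, key)
  rows
}

#' Map a (residue, atom) pair to its type id
#'
#' @inheritParams canonical_atom_name
#' @return Integer vector of type ids in 1..158; `NA` for hydrogens, OXT,
#'   and unknown residues or atoms.
#' @export
#' @examples
#' atom_type("PHE", "CD1") == atom_type("PHE", "CD2")
#' atom_type("GLY", "CA") != atom_type("ALA", "CA")
atom_type <- function(residue_name, atom_name) {
  atom_type_table()
  res <- toupper(trimws(residue_name))
  res[res == "MSE"] <- "MET"
  canon <- canonical_atom_name(res, atom_name)
  unname(.typing_env$lookup[paste(res, canon, sep = "|")])
}

#' Number of atom types in the typing scheme
#' @return Integer scalar (158).
#' @export
n_atom_types <- function() length(unique(atom_type_table()$type_id))

#' Stamp identifying the typing scheme
#'
#' A deterministic hash over the typing table, written into saved potential
#' tables so that tables trained under a different scheme are rejected on
#' load.
#' @return Character scalar.
#' @export
typing_hash <- function() {
  if (is.null(.typing_env$hash)) {
    tab <- atom_type_table()
    .typing_env$hash <- .hash_strings(paste(tab$residue_name, tab$canonical_name,
                                            tab$type_id, sep = ":"))
  }
  .typing_env$hash
}

#' Write the typing table for auditing
#' @param path Output path (tab-separated text).
#' @return `path`, invisibly.
#' @export
write_typing_table <- function(path) {
  write.table(atom_type_table(), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
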