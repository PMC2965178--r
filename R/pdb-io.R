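#' Typed protein structures
#'
#' A `typed_structure` is a tibble of typed heavy atoms — one row per atom
#' with columns `residue_index` (1-based, contiguous along the chain),
#' `residue_name`, `atom_name` (canonical PDB v3), `type_id` and `x`, `y`,
#' `z` in Angstrom — plus attributes `chain_id` and `n_res`.  All potential
#' training and scoring consumes this form; nothing downstream reads raw
#' PDB text.
#'
#' @name typed_structure
NULL

.new_typed_structure <- function(atoms, chain_id = "A") {
  atoms <- tibble::as_tibble(atoms)
  structure(atoms,
            chain_id = chain_id,
            n_res = if (nrow(atoms)) max(atoms$residue_index) else 0L,
            class = c("typed_structure", class(tibble::tibble())))
}

#' Number of residues in a typed structure
#' @param x A `typed_structure`.
#' @return Integer scalar.
#' @export
n_residues <- function(x) attr(x, "n_res", exact = TRUE) %||% 0L

#' @export
print.typed_structure <- function(x, ...) {
  cat(sprintf("<typed_structure> chain %s, %d residues, %d heavy atoms\n",
              attr(x, "chain_id") %||% "?", n_residues(x), nrow(x)))
  NextMethod()
}

# coordinate matrix (n_atoms x 3)
.coords <- function(x) cbind(x$x, x$y, x$z)

#' Parse a PDB file into a typed structure
#'
#' Reads ATOM records (plus MSE HETATM records, remapped to MET) of one
#' protein chain and assigns the 158-type heavy-atom alphabet.  Hydrogens,
#' waters, other hetero groups, terminal OXT and alternate-location
#' duplicates are removed (altloc ' ' or 'A' kept); residues missing any of
#' the backbone N/CA/C are dropped with a warning.  Surviving residues are
#' re-indexed contiguously in file order, so sequence separation is always
#' computed on the cleaned chain.
#'
#' @param path Path to a PDB file.
#' @param chain Optional chain identifier; default takes the first chain
#'   containing standard protein residues.
#' @return A [typed_structure].
#' @export
read_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) abort(sprintf("PDB file not found: %s", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) abort(sprintf("cannot read PDB file %s: %s",
                                      path, conditionMessage(e))))
  at <- pdb$atom
  at <- at[at$type == "ATOM" | (at$type == "HETATM" & at$resid == "MSE"), ,
           drop = FALSE]
  at$resid[at$resid == "MSE"] <- "MET"
  at <- at[at$resid %in% .AA3, , drop = FALSE]
  if (!nrow(at)) abort(sprintf("no standard protein residues in %s", path))
  at$chain[is.na(at$chain)] <- " "
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain == chain, , drop = FALSE]
  if (!nrow(at)) abort(sprintf("chain '%s' has no standard residues in %s",
                               chain, path))
  # altloc: bio3d already keeps ' '/'A'; guard against remaining duplicates
  # by keeping the highest-occupancy record per (residue, atom)
  ins <- at$insert
  ins[is.na(ins)] <- ""
  rkey <- paste(at$resno, ins, sep = "_")
  occ <- at$o
  occ[is.na(occ)] <- 1
  akey <- paste(rkey, at$elety, sep = "|")
  pos <- seq_len(nrow(at))
  keep_pos <- vapply(split(pos, akey), function(ii) ii[which.max(occ[ii])],
                     integer(1L))
  at <- at[sort(unname(keep_pos)), , drop = FALSE]
  rkey <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert), sep = "_")
  ridx <- match(rkey, unique(rkey))
  type_id <- atom_type(at$resid, at$elety)
  keep <- !is.na(type_id)
  atoms <- tibble::tibble(
    residue_index = ridx[keep],
    residue_name = at$resid[keep],
    atom_name = canonical_atom_name(at$resid[keep], at$elety[keep],
                                    merge_symmetric = FALSE),
    type_id = type_id[keep],
    x = at$x[keep], y = at$y[keep], z = at$z[keep])
  # drop residues with incomplete backbone
  ok <- vapply(split(atoms$atom_name, atoms$residue_index),
               function(a) all(c("N", "CA", "C") %in% a), logical(1L))
  bad <- as.integer(names(ok))[!ok]
  if (length(bad)) {
    warn(sprintf("%s: dropped %d residue(s) with incomplete backbone",
                 basename(path), length(bad)))
    atoms <- atoms[!(atoms$residue_index %in% bad), , drop = FALSE]
  }
  if (!nrow(atoms)) abort(sprintf("no complete standard residues in %s", path))
  atoms$residue_index <- match(atoms$residue_index, unique(atoms$residue_index))
  .new_typed_structure(atoms, chain_id = chain)
}

#' Write a typed structure as PDB text
#'
#' Emits plain ATOM records (wwPDB v3 columns) for the typed heavy atoms.
#' Coordinates are written at 3 decimals, so structures whose coordinates
#' are already rounded to 0.001 Angstrom round-trip exactly through
#' [read_pdb()].
#'
#' @param x A [typed_structure].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  stopifnot(inherits(x, "typed_structure"))
  chain <- substr(attr(x, "chain_id") %||% "A", 1L, 1L)
  if (chain == " " || !nzchar(chain)) chain <- "A"
  name4 <- ifelse(nchar(x$atom_name) < 4L,
                  sprintf(" %-3s", x$atom_name), x$atom_name)
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(x)), name4, x$residue_name, chain, x$residue_index,
    x$x, x$y, x$z, 1, 0, substr(x$atom_name, 1L, 1L))
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}
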