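# Minimal atomic-structure container on top of bio3d's PDB parser.
# Atoms keep chain, residue number + insertion code, residue and atom
# names, element, coordinates and the ATOM/HETATM record kind. Only the
# first model of a multi-model file is retained; alternate locations are
# collapsed to the highest-occupancy conformer (ties alphabetical).

WATER_RESIDUES <- c("HOH", "WAT", "DOD")

new_pdb_structure <- function(atoms, model = 1L) {
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, model = model), class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<pdb_structure> %d atoms, chains: %s, %d residue(s)\n",
              nrow(a), paste(sort(unique(a$chain)), collapse = ", "),
              length(unique(paste(a$chain, a$resno, a$icode)))))
  invisible(x)
}

#' Read a PDB file
#'
#' Parses ATOM and HETATM records (first model only) via bio3d and
#' collapses alternate locations to the highest-occupancy conformer, with
#' ties broken alphabetically by altloc id.
#'
#' @param path Path to a PDB-format file.
#' @return A `pdb_structure` with an `atoms` data frame (`chain`, `resno`,
#'   `icode`, `resid`, `elety`, `element`, `x`, `y`, `z`, `type`) in file
#'   order.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  icode <- ifelse(is.na(a$insert), "", a$insert)
  elem <- toupper(trimws(ifelse(is.na(a$elesy) | a$elesy == "",
                                substring(trimws(a$elety), 1, 1), a$elesy)))
  atoms <- data.frame(chain = ifelse(is.na(a$chain), " ", a$chain),
                      resno = a$resno, icode = icode, resid = a$resid,
                      elety = trimws(a$elety), element = elem,
                      x = a$x, y = a$y, z = a$z, type = a$type,
                      occ = ifelse(is.na(a$o), 1, a$o),
                      alt = ifelse(is.na(a$alt), "", a$alt),
                      stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in ", path, call. = FALSE)
  }
  # collapse altlocs: keep highest occupancy, ties alphabetical
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$elety)
  if (anyDuplicated(key[atoms$alt != ""])) {
    keep <- rep(TRUE, nrow(atoms))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      best <- idx[order(-atoms$occ[idx], atoms$alt[idx])][1]
      keep[setdiff(idx, best)] <- FALSE
    }
    atoms <- atoms[keep, , drop = FALSE]
  }
  atoms$occ <- NULL
  atoms$alt <- NULL
  new_pdb_structure(atoms)
}

#' Write a structure to PDB format
#'
#' @param s A `pdb_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "pdb_structure"))
  a <- s$atoms
  name4 <- ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety)
  lines <- sprintf(
    "%-6s%5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$type, seq_len(nrow(a)), name4, a$resid, a$chain, a$resno,
    ifelse(a$icode == "", " ", a$icode), a$x, a$y, a$z, 1, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Strip a structure to a single chain
#'
#' Keeps only the ATOM records of the given chain, removing waters,
#' heteroatoms and all other chains — the monomer on which folding ddG is
#' defined.
#'
#' @param s A `pdb_structure`.
#' @param chain Chain identifier present in `s`.
#' @return A `pdb_structure` holding one chain.
#' @export
strip_to_chain <- function(s, chain) {
  stopifnot(inherits(s, "pdb_structure"))
  if (!chain %in% s$atoms$chain) {
    stop("chain not present in structure: ", chain, call. = FALSE)
  }
  keep <- s$atoms$chain == chain & s$atoms$type == "ATOM" &
    !(s$atoms$resid %in% WATER_RESIDUES)
  new_pdb_structure(s$atoms[keep, , drop = FALSE], s$model)
}

# atoms of one residue; position is string-matched against resno+icode
residue_atoms <- function(s, chain, position) {
  a <- s$atoms
  pos <- paste0(a$resno, a$icode)
  sel <- a$chain == chain & pos == as.character(position) & a$type == "ATOM"
  if (!any(sel)) {
    stop(sprintf("residue %s in chain %s not found", position, chain),
         call. = FALSE)
  }
  a[sel, , drop = FALSE]
}

is_heavy <- function(atoms) !(atoms$element %in% c("H", "D"))

#' Does a residue contact another chain or a ligand?
#'
#' TRUE when any heavy atom of the residue lies within `cutoff` of a heavy
#' atom that is either on a different chain or a non-water HETATM (on any
#' chain). Water (HOH/WAT/DOD) never counts as a contact partner. Used to
#' exclude mutations whose energetics would mix monomer folding with
#' binding.
#'
#' @param s A `pdb_structure` (the full, un-stripped structure).
#' @param chain,position Chain id and residue position (with optional
#'   insertion-code suffix) of the mutated residue.
#' @param cutoff Distance cutoff in Angstrom (default 5).
#' @return Logical scalar.
#' @export
has_foreign_contact <- function(s, chain, position, cutoff = 5.0) {
  stopifnot(inherits(s, "pdb_structure"), cutoff > 0)
  res <- residue_atoms(s, chain, position)
  res <- res[is_heavy(res), , drop = FALSE]
  a <- s$atoms
  foreign <- (a$chain != chain |
                (a$type == "HETATM" & !(a$resid %in% WATER_RESIDUES))) &
    !(a$resid %in% WATER_RESIDUES) & is_heavy(a)
  if (!any(foreign) || nrow(res) == 0) return(FALSE)
  fa <- a[foreign, , drop = FALSE]
  rm_ <- as.matrix(res[, c("x", "y", "z")])
  fm <- as.matrix(fa[, c("x", "y", "z")])
  d2 <- outer(rowSums(rm_^2), rowSums(fm^2), "+") - 2 * rm_ %*% t(fm)
  min(d2) <= cutoff^2
}
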