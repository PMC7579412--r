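# Solvent accessible surface area by Shrake-Rupley sphere sampling and
# the derived relative-SASA burial classification.

# van der Waals radii (Angstrom) by element; heavy atoms only are used.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
VDW_DEFAULT <- 1.70

# Theoretical maximum SASA per residue (Angstrom^2), Tien et al. (2013),
# used as the denominator of relative SASA.
MAX_SASA <- c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0,
              CYS = 167.0, GLU = 223.0, GLN = 225.0, GLY = 104.0,
              HIS = 224.0, ILE = 197.0, LEU = 201.0, LYS = 236.0,
              MET = 224.0, PHE = 240.0, PRO = 159.0, SER = 155.0,
              THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

# Burial threshold on relative SASA: strictly greater than 20% exposed
# counts as Surface, at or below as Buried.
BURIAL_THRESHOLD <- 0.20

# Deterministic quasi-uniform points on the unit sphere (Fibonacci spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = cos(theta) * sin(phi), y = sin(theta) * sin(phi), z = cos(phi))
}

atom_radii <- function(elements) {
  r <- VDW_RADII[elements]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

#' Per-atom solvent accessible surface area
#'
#' Shrake-Rupley rolling-probe SASA: each heavy atom's solvent sphere
#' (van der Waals radius + probe radius) is sampled with a deterministic
#' quasi-uniform point set and a point counts as accessible when it falls
#' outside every other heavy atom's solvent sphere. Hydrogens are ignored
#' entirely.
#'
#' @param s A `pdb_structure`.
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points Sample points per atom (default 960).
#' @return Numeric vector of SASA values (Angstrom^2), one per heavy atom,
#'   with the corresponding rows of `s$atoms` as attribute `"atoms"`.
#' @export
structure_sasa <- function(s, probe = 1.4, n_points = 960) {
  stopifnot(inherits(s, "pdb_structure"), probe >= 0, n_points >= 60)
  atoms <- s$atoms[is_heavy(s$atoms), , drop = FALSE]
  n <- nrow(atoms)
  if (n == 0) stop("structure has no heavy atoms", call. = FALSE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- atom_radii(atoms$element) + probe
  pts <- fibonacci_sphere(n_points)
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    neigh <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    sp <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in neigh) {
      dj <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      acc <- acc & dj > rad[j]^2
      if (!any(acc)) break
    }
    sasa[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_points
  }
  attr(sasa, "atoms") <- atoms
  sasa
}

#' Relative solvent accessibility and burial label of a residue
#'
#' Sums the Shrake-Rupley SASA of the residue's heavy atoms and divides by
#' the residue's theoretical maximum exposure (Tien et al. 2013 table);
#' the ratio is truncated to \[0, 1\]. A residue is `"Buried"` when its
#' relative SASA is at or below 20% and `"Surface"` when strictly above.
#' By default the structure is first stripped to the residue's chain, so
#' burial reflects the isolated monomer.
#'
#' @param s A `pdb_structure`.
#' @param chain,position Chain id and residue position.
#' @param strip Strip `s` to `chain` before computing (default `TRUE`).
#' @param probe,n_points Passed to [structure_sasa()].
#' @return List with `relative_sasa` (fraction in \[0, 1\]), `sasa`
#'   (Angstrom^2), and `label` (`"Buried"` or `"Surface"`).
#' @export
relative_sasa <- function(s, chain, position, strip = TRUE,
                          probe = 1.4, n_points = 960) {
  if (strip) s <- strip_to_chain(s, chain)
  res <- residue_atoms(s, chain, position)
  res <- res[is_heavy(res), , drop = FALSE]
  if (nrow(res) == 0) {
    stop("residue has no heavy atoms", call. = FALSE)
  }
  resid <- res$resid[1]
  if (!resid %in% names(MAX_SASA)) {
    stop("no reference maximum SASA for residue type ", resid,
         call. = FALSE)
  }
  sasa <- structure_sasa(s, probe = probe, n_points = n_points)
  atoms <- attr(sasa, "atoms")
  pos <- paste(atoms$chain, paste0(atoms$resno, atoms$icode))
  want <- paste(chain, as.character(position))
  tot <- sum(sasa[pos == want])
  rel <- min(1, max(0, tot / MAX_SASA[[resid]]))
  list(relative_sasa = rel, sasa = tot,
       label = if (rel > BURIAL_THRESHOLD) "Surface" else "Buried")
}

#' Burial labels for a table of mutations
#'
#' Convenience wrapper computing [relative_sasa()] for every record whose
#' parent structure is available.
#'
#' @param records A `mutation_table`.
#' @param structures Named list of `pdb_structure` objects keyed by
#'   `pdb_id`.
#' @param ... Passed to [relative_sasa()].
#' @return Named character vector `record_id` -> `"Buried"`/`"Surface"`;
#'   records without a structure are omitted.
#' @export
burial_labels <- function(records, structures, ...) {
  out <- character(0)
  for (i in seq_len(nrow(records))) {
    st <- structures[[records$pdb_id[i]]]
    if (is.null(st)) next
    lab <- tryCatch(
      relative_sasa(st, records$chain[i], records$position[i], ...)$label,
      error = function(e) NA_character_)
    if (!is.na(lab)) out[records$record_id[i]] <- lab
  }
  out
}
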