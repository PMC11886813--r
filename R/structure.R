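#' Protein structure records and chi-angle sets
#'
#' `chi_structure()` is the package's container for one (possibly multi-chain)
#' protein: residue codes, chain labels, atom14 coordinates and masks.
#' `chi_set()` holds per-residue chi angles (up to 4), their existence mask and
#' pi-symmetry flags; it is the state the flow operates on. Symmetry-reduced
#' angles are stored in `[0, pi)`; all other angles in `[-pi, pi)`.
#'
#' @param aa character vector of residue codes (1- or 3-letter; `"UNK"`
#'   allowed).
#' @param atom14 numeric array `R x 14 x 3` of heavy-atom coordinates
#'   (Angstrom) in the atom14 layout (slots 1:4 are N, CA, C, O).
#' @param atom_mask logical `R x 14`; `TRUE` where the slot holds an atom.
#' @param chain character vector of chain identifiers (default single chain
#'   `"A"`).
#' @param resno integer author residue numbering (default `1:R` per chain).
#' @return an object of class `"chi_structure"`.
#' @export
chi_structure <- function(aa, atom14, atom_mask, chain = NULL, resno = NULL) {
  aa <- aa_three(aa)
  R <- length(aa)
  stopifnot(identical(dim(atom14), c(R, 14L, 3L)),
            identical(dim(atom_mask), c(R, 14L)))
  if (is.null(chain)) chain <- rep("A", R)
  if (is.null(resno)) {
    resno <- stats::ave(seq_len(R), chain, FUN = seq_along)
  }
  stopifnot(length(chain) == R, length(resno) == R)
  structure(list(aa = aa, chain = as.character(chain),
                 resno = as.integer(resno), atom14 = atom14,
                 atom_mask = atom_mask),
            class = "chi_structure")
}

#' @export
print.chi_structure <- function(x, ...) {
  cat(sprintf("<chi_structure> %d residues, %d chain(s) [%s]\n",
              length(x$aa), length(unique(x$chain)),
              paste(unique(x$chain), collapse = ",")))
  cat(sprintf("  sequence: %s\n",
              paste(aa_one(x$aa), collapse = "")))
  invisible(x)
}

#' @export
length.chi_structure <- function(x) length(x$aa)

#' Number of residues in a structure
#' @param structure a [chi_structure()].
#' @return integer residue count.
#' @export
n_residues <- function(structure) length(structure$aa)

#' Backbone coordinates of a structure
#' @param structure a [chi_structure()].
#' @param atoms subset of `c("N", "CA", "C", "O")`.
#' @return numeric array `R x length(atoms) x 3`.
#' @export
backbone_coords <- function(structure, atoms = c("N", "CA", "C", "O")) {
  idx <- match(atoms, c("N", "CA", "C", "O"))
  structure$atom14[, idx, , drop = FALSE]
}

#' Subset a structure to a residue index range
#' @param structure a [chi_structure()].
#' @param idx integer residue indices (kept in order).
#' @return a [chi_structure()].
#' @export
subset_structure <- function(structure, idx) {
  chi_structure(structure$aa[idx],
                structure$atom14[idx, , , drop = FALSE],
                structure$atom_mask[idx, , drop = FALSE],
                chain = structure$chain[idx],
                resno = structure$resno[idx])
}

#' @rdname chi_structure
#' @param angles numeric `R x 4` matrix of chi angles (radians); entries where
#'   `exists` is `FALSE` are ignored and stored as 0.
#' @param exists logical `R x 4` existence mask.
#' @param symmetric logical `R x 4` pi-symmetry flags.
#' @export
chi_set <- function(angles, exists, symmetric) {
  stopifnot(is.matrix(angles), ncol(angles) == 4,
            identical(dim(exists), dim(angles)),
            identical(dim(symmetric), dim(angles)))
  angles[!exists] <- 0
  angles[exists] <- torus_wrap(angles[exists],
                               ifelse(symmetric[exists], pi, 2 * pi))
  structure(list(angles = angles, exists = exists, symmetric = symmetric),
            class = "chi_set")
}

#' @export
print.chi_set <- function(x, ...) {
  cat(sprintf("<chi_set> %d residues, %d chi angles (%d pi-symmetric)\n",
              nrow(x$angles), sum(x$exists), sum(x$symmetric & x$exists)))
  invisible(x)
}

#' Per-angle periods of a chi set
#' @param chi a [chi_set()].
#' @return numeric `R x 4` matrix: `pi` for symmetry-reduced angles, `2*pi`
#'   otherwise.
#' @export
chi_periods <- function(chi) {
  ifelse(chi$symmetric, pi, 2 * pi)
}

#' Restrict pi-symmetric angles to their reduced chart
#'
#' Maps every flagged angle mod `pi` into `[0, pi)`; all other angles are
#' left untouched.
#' @param chi a [chi_set()].
#' @return a [chi_set()] in the reduced chart.
#' @export
reduce_symmetry <- function(chi) {
  a <- chi$angles
  flag <- chi$symmetric & chi$exists
  a[flag] <- a[flag] %% pi
  chi_set(a, chi$exists, chi$symmetric)
}
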