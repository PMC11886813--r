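#' Idealized residue templates (atom14)
#'
#' Heavy-atom geometry for the 20 canonical amino acids in the fixed atom14
#' layout: 14 coordinate slots per residue, the first four always N, CA, C, O,
#' then CB and the remaining side-chain atoms in a fixed per-residue order.
#' Ideal coordinates, within-residue bonds and chi-angle definitions (atom
#' quadruples plus pi-symmetry flags) are vendored as plain-text tables under
#' `inst/extdata` and parsed once per session. Chi rotations are nested: the
#' set of atoms moved by chi_k contains the set moved by chi_(k+1), and the
#' rotating sets are derived here from the bond graph (atoms on the distal
#' side of the chi_k rotation axis).
#'
#' @section pi-symmetry convention:
#' The default pi-symmetric set is chi2 of ASP, PHE, TYR and chi3 of GLU (the
#' standard crystallographic convention for indistinguishable terminal atom
#' pairs/rings). Amide/imidazole flips (ASN, GLN, HIS) are *not* treated as
#' symmetric by default.
#'
#' @name residue_templates
#' @keywords internal
NULL

.chiflow_env <- new.env(parent = emptyenv())

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")

#' Convert between one- and three-letter amino-acid codes
#' @param x character vector of codes; unknown codes map to `"UNK"`/`"X"`.
#' @return character vector of the same length.
#' @export
aa_three <- function(x) {
  out <- ifelse(nchar(x) == 1, AA3[match(toupper(x), AA1)], toupper(x))
  out[is.na(out) | !(out %in% c(AA3, "UNK"))] <- "UNK"
  out
}

#' @rdname aa_three
#' @export
aa_one <- function(x) {
  x <- aa_three(x)
  out <- AA1[match(x, AA3)]
  out[is.na(out)] <- "X"
  out
}

# distal connected component after cutting the a2-a3 bond; excludes backbone
.rotating_set <- function(bonds, n_atoms, a2, a3) {
  adj <- vector("list", n_atoms)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- rep(FALSE, n_atoms)
  seen[c(a2, a3)] <- TRUE
  queue <- setdiff(adj[[a3]], a2)
  moved <- logical(n_atoms)
  while (length(queue)) {
    a <- queue[[1]]; queue <- queue[-1]
    if (seen[a]) next
    seen[a] <- TRUE
    moved[a] <- TRUE
    queue <- c(queue, adj[[a]])
  }
  which(moved)
}

#' Load the vendored residue template set
#'
#' Parsed lazily and cached for the session. Returned as a named list (one
#' entry per three-letter code) with elements `atom_names`, `elements`,
#' `coords` (14 x 3, `NA` rows for unused slots), `mask` (length-14 logical),
#' `bonds` (slot-index pairs), `n_chi`, `chi_atoms` (n_chi x 4 slot indices),
#' `chi_symmetric` (logical), and `chi_rotating` (list of slot-index vectors,
#' nested decreasing).
#'
#' @return named list of 20 residue templates.
#' @export
residue_templates <- function() {
  if (!is.null(.chiflow_env$templates)) {
    return(.chiflow_env$templates)
  }
  path <- function(f) system.file("extdata", f, package = "chiflow",
                                  mustWork = TRUE)
  atoms <- utils::read.delim(path("residue_atoms.tsv"),
                             stringsAsFactors = FALSE)
  chis <- utils::read.delim(path("residue_chi.tsv"), stringsAsFactors = FALSE)
  bonds <- utils::read.delim(path("residue_bonds.tsv"),
                             stringsAsFactors = FALSE)
  # pi-symmetric terminal groups must be exactly symmetric under the 180
  # degree flip for the symmetry-reduced parameterisation to be lossless;
  # the raw ideal coordinates carry sub-0.01 A asymmetries, so the distal
  # group is averaged with its flipped image (an exact involution)
  symmetrize <- list(
    ASP = list(chi = 2, pairs = list(c("OD1", "OD2"))),
    GLU = list(chi = 3, pairs = list(c("OE1", "OE2"))),
    PHE = list(chi = 2, pairs = list(c("CD1", "CD2"), c("CE1", "CE2"))),
    TYR = list(chi = 2, pairs = list(c("CD1", "CD2"), c("CE1", "CE2"))))
  tmpl <- lapply(AA3, function(aa) {
    at <- atoms[atoms$aa == aa, ]
    at <- at[order(at$slot), ]
    n <- nrow(at)
    coords <- matrix(NA_real_, 14, 3,
                     dimnames = list(NULL, c("x", "y", "z")))
    coords[at$slot, ] <- as.matrix(at[, c("x", "y", "z")])
    names14 <- rep(NA_character_, 14)
    names14[at$slot] <- at$atom
    elem14 <- rep(NA_character_, 14)
    elem14[at$slot] <- at$element
    bd <- bonds[bonds$aa == aa, ]
    bmat <- cbind(match(bd$atom1, names14), match(bd$atom2, names14))
    # rotating sets must not traverse backbone closures (proline N-CD): only
    # the CA-CB bond connects backbone and side chain for chi kinematics
    side <- which(!(names14 %in% c("N", "CA", "C", "O")))
    keep <- (bmat[, 1] %in% side & bmat[, 2] %in% side) |
      (names14[bmat[, 1]] %in% c("CA", "CB") &
         names14[bmat[, 2]] %in% c("CA", "CB"))
    bchi <- bmat[keep, , drop = FALSE]
    ch <- chis[chis$aa == aa, ]
    ch <- ch[order(ch$chi), , drop = FALSE]
    n_chi <- nrow(ch)
    chi_atoms <- matrix(NA_integer_, max(n_chi, 0), 4)
    rotating <- vector("list", n_chi)
    if (n_chi > 0) {
      for (k in seq_len(n_chi)) {
        chi_atoms[k, ] <- match(unlist(ch[k, c("a1", "a2", "a3", "a4")]),
                                names14)
        rotating[[k]] <- .rotating_set(bchi, 14, chi_atoms[k, 2],
                                       chi_atoms[k, 3])
      }
    }
    sym <- symmetrize[[aa]]
    if (!is.null(sym)) {
      k <- sym$chi
      a2 <- chi_atoms[k, 2]; a3 <- chi_atoms[k, 3]
      axis <- coords[a3, ] - coords[a2, ]
      axis <- axis / sqrt(sum(axis^2))
      rot <- .rotating_set(bchi, 14, a2, a3)
      flip <- function(P) {
        v <- sweep(P, 2, coords[a3, ])
        dot <- as.vector(v %*% axis)
        # rotation by pi about the bond axis: v -> 2(v.u)u - v
        sweep(2 * outer(dot, axis) - v, 2, coords[a3, ], "+")
      }
      perm <- seq_len(14)
      for (p in sym$pairs) {
        ij <- match(p, names14)
        perm[ij] <- rev(perm[ij])
      }
      flipped <- coords
      flipped[rot, ] <- flip(coords[perm[rot], , drop = FALSE])
      coords[rot, ] <- (coords[rot, , drop = FALSE] +
                          flipped[rot, , drop = FALSE]) / 2
    }
    # bond-graph distances to the backbone C (slot 3) and N (slot 1), used by
    # the clash counter to span the peptide bond
    bfs_dist <- function(from) {
      d <- rep(Inf, 14)
      d[from] <- 0
      repeat {
        changed <- FALSE
        for (r in seq_len(nrow(bmat))) {
          a <- bmat[r, 1]; b <- bmat[r, 2]
          if (d[a] + 1 < d[b]) { d[b] <- d[a] + 1; changed <- TRUE }
          if (d[b] + 1 < d[a]) { d[a] <- d[b] + 1; changed <- TRUE }
        }
        if (!changed) break
      }
      d
    }
    list(aa = aa, atom_names = names14, elements = elem14, coords = coords,
         mask = !is.na(names14), bonds = bmat,
         dist_to_C = bfs_dist(3), dist_to_N = bfs_dist(1), n_chi = n_chi,
         chi_atoms = chi_atoms,
         chi_symmetric = if (n_chi) as.logical(ch$symmetric) else logical(0),
         chi_rotating = rotating)
  })
  names(tmpl) <- AA3
  .chiflow_env$templates <- tmpl
  tmpl
}

#' Per-residue chi metadata for a sequence
#'
#' @param aa character vector of residue codes (1- or 3-letter).
#' @return list with `n_chi` (integer vector), `exists` (R x 4 logical) and
#'   `symmetric` (R x 4 logical, `FALSE` where no chi exists); unknown
#'   residues have zero chi angles.
#' @export
chi_metadata <- function(aa) {
  aa <- aa_three(aa)
  tmpl <- residue_templates()
  R <- length(aa)
  exists <- matrix(FALSE, R, 4)
  symmetric <- matrix(FALSE, R, 4)
  for (i in seq_len(R)) {
    tp <- tmpl[[aa[i]]]
    if (!is.null(tp) && tp$n_chi > 0) {
      exists[i, seq_len(tp$n_chi)] <- TRUE
      symmetric[i, seq_len(tp$n_chi)] <- tp$chi_symmetric
    }
  }
  list(n_chi = rowSums(exists), exists = exists, symmetric = symmetric)
}

#' Van der Waals radii used by the clash counter (Angstrom)
#' @return named numeric vector for elements C, N, O, S.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
}
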