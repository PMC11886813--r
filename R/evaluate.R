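#' Side-chain packing evaluation metrics
#'
#' The standard rotamer-recovery suite: per-chi angular MAE via the minimum
#' arc on the circle (period pi for pi-symmetric angles, so their error never
#' exceeds 90 degrees), the fraction of angles within 20 degrees of the
#' reference, per-residue side-chain heavy-atom RMSD without superposition
#' (the backbone frame is shared) with symmetric terminal atoms matched to
#' minimise the RMSD, burial classes from C-beta neighbour counts (core: at
#' least 20 C-beta within 10 Angstrom; surface: at most 15), and a
#' steric-clash count. The clash criterion is a standard van der Waals
#' overlap rule: two non-bonded heavy atoms clash when their distance falls
#' below the sum of their van der Waals radii minus 0.4 Angstrom, with
#' same-residue pairs and 1-2/1-3 neighbours across the peptide bond
#' excluded; the overlap tolerance is configurable.
#'
#' @name evaluate
#' @keywords internal
NULL

#' Minimum-arc angular error in degrees
#'
#' @param pred,ref angles in radians (vectors, recycled).
#' @param symmetric logical (recycled): use period pi instead of 2*pi.
#' @return absolute errors in degrees (`<= 180`, or `<= 90` when symmetric).
#' @export
angle_error <- function(pred, ref, symmetric = FALSE) {
  period <- ifelse(symmetric, pi, 2 * pi)
  abs(torus_log(ref, pred, period)) * 180 / pi
}

#' Fraction of angle errors below a threshold
#'
#' @param errors numeric vector of errors (degrees); `NA`s are dropped.
#' @param threshold cut-off in degrees (strict `<`, default 20).
#' @return fraction in `[0, 1]`, or `NA` if no errors remain.
#' @export
angle_accuracy <- function(errors, threshold = 20) {
  stopifnot(threshold > 0)
  errors <- errors[!is.na(errors)]
  if (!length(errors)) return(NA_real_)
  mean(errors < threshold)
}

# symmetric terminal-pair slot permutations (atom14 indices); ring flips swap
# both pairs jointly
.symmetric_swaps <- function(aa, include_amide_flips = FALSE) {
  sw <- switch(aa,
               ASP = list(c(7L, 8L)),
               GLU = list(c(8L, 9L)),
               PHE = list(c(7L, 8L), c(9L, 10L)),
               TYR = list(c(7L, 8L), c(9L, 10L)),
               NULL)
  if (include_amide_flips) {
    sw <- switch(aa,
                 ASN = list(c(7L, 8L)),
                 GLN = list(c(8L, 9L)),
                 HIS = list(c(7L, 8L), c(9L, 10L)),
                 ARG = list(c(10L, 11L)),
                 sw)
  }
  if (is.null(sw)) return(NULL)
  perm <- seq_len(14)
  for (p in sw) {
    perm[p] <- rev(perm[p])
  }
  perm
}

#' Per-residue side-chain RMSD
#'
#' RMSD over side-chain heavy atoms (C-beta onward) in the shared backbone
#' frame, with symmetric terminal pairs (ASP OD1/OD2, GLU OE1/OE2, PHE/TYR
#' ring carbons; optionally ASN/GLN/HIS/ARG flips) matched to minimise the
#' value.
#'
#' @param pred_atoms,ref_atoms `14 x 3` atom14 coordinate matrices.
#' @param aa residue code.
#' @param include_amide_flips also match amide/imidazole/guanidinium flips
#'   (default `FALSE`).
#' @return RMSD in Angstrom, or `NA` for residues without atoms beyond
#'   C-beta (ALA, GLY, UNK).
#' @export
residue_rmsd <- function(pred_atoms, ref_atoms, aa,
                         include_amide_flips = FALSE) {
  tp <- residue_templates()[[aa_three(aa)]]
  if (is.null(tp)) return(NA_real_)
  slots <- which(tp$mask)
  slots <- slots[slots >= 5]
  if (length(slots) < 2) return(NA_real_)  # ALA: CB only
  rms <- function(ref) {
    sqrt(mean(rowSums((pred_atoms[slots, , drop = FALSE] -
                         ref[slots, , drop = FALSE])^2)))
  }
  best <- rms(ref_atoms)
  perm <- .symmetric_swaps(aa_three(aa), include_amide_flips)
  if (!is.null(perm)) best <- min(best, rms(ref_atoms[perm, , drop = FALSE]))
  best
}

#' Per-residue side-chain RMSDs for a whole structure
#'
#' @param pred,ref [chi_structure()] objects with identical sequences.
#' @inheritParams residue_rmsd
#' @return numeric length-R vector (`NA` where undefined).
#' @export
structure_rmsd <- function(pred, ref, include_amide_flips = FALSE) {
  stopifnot(identical(pred$aa, ref$aa))
  vapply(seq_len(n_residues(pred)), function(i) {
    residue_rmsd(pred$atom14[i, , ], ref$atom14[i, , ], pred$aa[i],
                 include_amide_flips)
  }, numeric(1))
}

#' Classify residues as core / surface / other by C-beta burial
#'
#' Counts the other residues whose idealized C-beta lies within `radius`;
#' at least `core_min` neighbours makes a residue core, at most
#' `surface_max` makes it surface. Labels depend only on backbone geometry.
#'
#' @param structure a [chi_structure()].
#' @param radius neighbour radius (Angstrom, default 10).
#' @param core_min,surface_max burial thresholds (defaults 20 and 15).
#' @return character vector of labels `"core"`, `"surface"`, `"other"`.
#' @export
classify_core_surface <- function(structure, radius = 10, core_min = 20,
                                  surface_max = 15) {
  cb <- structure_cbeta(structure)
  d <- as.matrix(stats::dist(cb))
  counts <- unname(rowSums(d <= radius)) - 1L
  ifelse(counts >= core_min, "core",
         ifelse(counts <= surface_max, "surface", "other"))
}

# flatten masked atoms of a structure into a table used by the clash counter
.atom_table <- function(structure) {
  tmpl <- residue_templates()
  R <- n_residues(structure)
  res <- c(); slot <- c(); elem <- c()
  for (i in seq_len(R)) {
    sl <- which(structure$atom_mask[i, ])
    tp <- tmpl[[structure$aa[i]]]
    el <- if (is.null(tp)) rep("C", length(sl)) else tp$elements[sl]
    res <- c(res, rep(i, length(sl)))
    slot <- c(slot, sl)
    elem <- c(elem, el)
  }
  xyz <- cbind(structure$atom14[cbind(res, slot, 1)],
               structure$atom14[cbind(res, slot, 2)],
               structure$atom14[cbind(res, slot, 3)])
  keep <- apply(is.finite(xyz), 1, all)
  list(res = res[keep], slot = slot[keep], elem = elem[keep],
       xyz = xyz[keep, , drop = FALSE])
}

# is the atom pair (residue i slot a) -- (residue j slot b), j = i + 1 on the
# same chain, within `max_span` bonds through the peptide bond C(i)-N(j)?
.peptide_excluded <- function(aa_i, aa_j, a, b, max_span = 3) {
  tmpl <- residue_templates()
  ti <- tmpl[[aa_i]]; tj <- tmpl[[aa_j]]
  if (is.null(ti) || is.null(tj)) return(FALSE)
  ti$dist_to_C[a] + 1 + tj$dist_to_N[b] <= max_span
}

#' Count steric clashes in a structure
#'
#' Spatial-grid (cell list) implementation of the van der Waals overlap
#' criterion; heavy atoms only.
#'
#' @param structure a [chi_structure()].
#' @param overlap_tol allowed overlap before a contact counts as a clash
#'   (Angstrom, default 0.4).
#' @param max_bond_span exclude atom pairs connected by at most this many
#'   bonds across the peptide link (default 3, i.e. 1-2/1-3/1-4; ideal
#'   trans-peptide geometry already places 1-4 pairs such as O(i)-CA(i+1)
#'   inside the overlap threshold, so excluding them keeps ideal backbones
#'   clash-free; set 2 for a strict 1-2/1-3 rule).
#' @return integer clash count.
#' @export
count_clashes <- function(structure, overlap_tol = 0.4, max_bond_span = 3) {
  at <- .atom_table(structure)
  n <- length(at$res)
  if (n < 2) return(0L)
  radii <- vdw_radii()[at$elem]
  radii[is.na(radii)] <- 1.7
  cutoff <- 2 * max(vdw_radii()) - overlap_tol
  cell <- floor(sweep(at$xyz, 2, apply(at$xyz, 2, min)) / cutoff)
  key <- cell[, 1] * 1e6 + cell[, 2] * 1e3 + cell[, 3]
  cells <- split(seq_len(n), key)
  cell_of <- match(key, names(cells))
  # map each occupied cell to its (up to 27) occupied neighbours
  cell_coord <- do.call(rbind, lapply(cells, function(ix) cell[ix[1], ]))
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  count <- 0L
  chain <- structure$chain
  for (ci in seq_along(cells)) {
    ix <- cells[[ci]]
    nb_keys <- (cell_coord[ci, 1] + offsets[, 1]) * 1e6 +
      (cell_coord[ci, 2] + offsets[, 2]) * 1e3 +
      (cell_coord[ci, 3] + offsets[, 3])
    cand <- unlist(cells[as.character(nb_keys)], use.names = FALSE)
    for (p in ix) {
      q <- cand[cand > p]
      if (!length(q)) next
      ri <- at$res[p]; rj <- at$res[q]
      same <- rj == ri
      q <- q[!same]; rj <- rj[!same]
      if (!length(q)) next
      d <- sqrt(colSums((t(at$xyz[q, , drop = FALSE]) - at$xyz[p, ])^2))
      thr <- radii[p] + radii[q] - overlap_tol
      hit <- d < thr
      if (any(hit)) {
        for (w in which(hit)) {
          i1 <- min(ri, rj[w]); i2 <- max(ri, rj[w])
          if (i2 == i1 + 1 && chain[i1] == chain[i2]) {
            a <- if (ri < rj[w]) at$slot[p] else at$slot[q[w]]
            b <- if (ri < rj[w]) at$slot[q[w]] else at$slot[p]
            if (.peptide_excluded(structure$aa[i1], structure$aa[i2], a, b,
                                  max_bond_span)) next
          }
          count <- count + 1L
        }
      }
    }
  }
  count
}

#' Full packing evaluation report
#'
#' Compares a predicted structure (or chi set) against a reference and
#' aggregates the metric suite. Chi errors are micro-averaged over all
#' evaluated residues.
#'
#' @param pred a [chi_structure()] with predicted side chains.
#' @param ref the reference [chi_structure()] (same sequence/backbone).
#' @param residue_subset optional integer indices restricting the chi/RMSD
#'   aggregation (e.g. inpainted residues); burial classes and clash counts
#'   always use the full structure.
#' @inheritParams residue_rmsd
#' @return object of class `"packing_report"`: list with `mae_per_chi`
#'   (degrees), `accuracy_per_chi`, `accuracy_all`, `rmsd_all`, `rmsd_core`,
#'   `rmsd_surface`, `clash_count`, and `per_residue` (data.frame).
#' @export
pack_report <- function(pred, ref, residue_subset = NULL,
                        include_amide_flips = FALSE) {
  stopifnot(identical(pred$aa, ref$aa))
  chi_p <- measure_chi_all(pred)
  chi_r <- measure_chi_all(ref)
  R <- n_residues(pred)
  sub <- if (is.null(residue_subset)) seq_len(R) else residue_subset
  err <- matrix(NA_real_, R, 4)
  both <- chi_p$exists & chi_r$exists
  err[both] <- angle_error(chi_p$angles[both], chi_r$angles[both],
                           chi_r$symmetric[both])
  rmsd <- structure_rmsd(pred, ref, include_amide_flips)
  burial <- classify_core_surface(ref)
  err_sub <- err[sub, , drop = FALSE]
  rmsd_sub <- rmsd[sub]
  burial_sub <- burial[sub]
  mae <- colMeans(err_sub, na.rm = TRUE)
  acc <- apply(err_sub, 2, angle_accuracy)
  mean_or_na <- function(x) if (any(!is.na(x))) mean(x, na.rm = TRUE) else NA_real_
  report <- list(
    mae_per_chi = mae,
    accuracy_per_chi = acc,
    accuracy_all = angle_accuracy(as.vector(err_sub)),
    rmsd_all = mean_or_na(rmsd_sub),
    rmsd_core = mean_or_na(rmsd_sub[burial_sub == "core"]),
    rmsd_surface = mean_or_na(rmsd_sub[burial_sub == "surface"]),
    clash_count = count_clashes(pred),
    per_residue = data.frame(index = seq_len(R), aa = pred$aa,
                             chain = pred$chain,
                             chi1_err = err[, 1], chi2_err = err[, 2],
                             chi3_err = err[, 3], chi4_err = err[, 4],
                             rmsd = rmsd, burial = burial,
                             evaluated = seq_len(R) %in% sub))
  structure(report, class = "packing_report")
}

#' @export
print.packing_report <- function(x, ...) {
  cat("<packing_report>\n")
  cat("  chi MAE (deg):   ",
      paste(sprintf("%.2f", x$mae_per_chi), collapse = "  "), "\n")
  cat("  chi acc (<20deg):",
      paste(sprintf("%.3f", x$accuracy_per_chi), collapse = "  "), "\n")
  cat(sprintf("  RMSD all/core/surface: %.3f / %.3f / %.3f A\n",
              x$rmsd_all, x$rmsd_core, x$rmsd_surface))
  cat(sprintf("  clashes: %d\n", x$clash_count))
  invisible(x)
}
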