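#' Side-chain kinematics: dihedrals, chi measurement, atom14 reconstruction
#'
#' Under idealized covalent geometry the chi dihedrals are the only side-chain
#' degrees of freedom. This file measures chi angles from coordinates and
#' rebuilds full heavy-atom residues from backbone + chi by rigidly aligning
#' the idealized template onto the observed N/CA/C frame and then applying the
#' chi rotations in order chi1 -> chi4 about the current bond axes, which makes
#' the measure/build roundtrip exact by construction.
#'
#' @name kinematics
#' @keywords internal
NULL

.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.as_rows <- function(p) if (is.matrix(p)) p else matrix(p, 1, 3)

#' Signed torsion angle of four points
#'
#' IUPAC convention: cis = 0, trans = pi; result in `(-pi, pi]`. Vectorised
#' over rows when the arguments are `n x 3` matrices.
#'
#' @param p1,p2,p3,p4 points (length-3 vectors or `n x 3` matrices, Angstrom).
#' @return numeric vector of torsions (radians).
#' @export
dihedral <- function(p1, p2, p3, p4) {
  p1 <- .as_rows(p1); p2 <- .as_rows(p2); p3 <- .as_rows(p3); p4 <- .as_rows(p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  nb2 <- sqrt(rowSums(b2^2))
  if (any(nb2 < 1e-8) ||
      any(rowSums(n1^2) < 1e-14) || any(rowSums(n2^2) < 1e-14)) {
    stop("degenerate geometry: coincident or collinear points in dihedral()")
  }
  # y = (n1 x n2) . b2_hat gives the IUPAC sign (cis = 0, phi < 0 in
  # right-handed helices)
  m1 <- .cross3(n1, n2)
  ang <- atan2(rowSums(m1 * (b2 / nb2)), rowSums(n1 * n2))
  ang[ang <= -pi + 1e-15] <- pi
  ang
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Returns the point `d` with bond length `|d - c| = r`, bond angle
#' `angle(b, c, d) = theta` and torsion `dihedral(a, b, c, d) = tau`.
#'
#' @param a,b,c reference points (length-3 numeric).
#' @param r bond length (Angstrom).
#' @param theta bond angle (radians).
#' @param tau torsion (radians).
#' @return length-3 numeric coordinates.
#' @export
nerf_place <- function(a, b, c, r, theta, tau) {
  out <- .nerf_rows(.as_rows(a), .as_rows(b), .as_rows(c), r, theta, tau)
  if (nrow(out) == 1) as.vector(out) else out
}

# vectorised NeRF over rows
.nerf_rows <- function(a, b, c, r, theta, tau) {
  bc <- c - b
  bc <- bc / sqrt(rowSums(bc^2))
  ab <- b - a
  n <- .cross3(ab, bc)
  n <- n / sqrt(rowSums(n^2))
  m <- .cross3(n, bc)
  c + (-r * cos(theta)) * bc + (r * sin(theta) * cos(tau)) * m +
    (r * sin(theta) * sin(tau)) * n
}

# rigid transform (rotation + translation) mapping template points P (n x 3)
# onto target points Q (n x 3) in the least-squares sense (Kabsch)
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  Rm <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = Rm, t = cq - as.vector(Rm %*% cp))
}

.apply_rigid <- function(P, tr) {
  sweep(P %*% t(tr$R), 2, tr$t, "+")
}

# Rodrigues rotation of points P (n x 3) about the axis through `origin` with
# unit direction `u`, by angle `delta`
.rotate_about <- function(P, origin, u, delta) {
  v <- sweep(P, 2, origin)
  cd <- cos(delta); sd <- sin(delta)
  ux <- .cross3(matrix(u, nrow(v), 3, byrow = TRUE), v)
  dot <- as.vector(v %*% u)
  out <- v * cd + ux * sd + outer(dot * (1 - cd), u)
  sweep(out, 2, origin, "+")
}

#' Idealized (virtual) C-beta position from a backbone frame
#'
#' Deterministic tetrahedral construction from N, CA, C with the internal
#' coordinates of the vendored idealized alanine (CA-CB 1.529 Angstrom,
#' N-CA-CB 109.5 degrees, C-N-CA-CB torsion 120 degrees); used for the
#' residue-graph node positions and core/surface burial counts, including a
#' virtual C-beta for glycine. The construction is rigid-motion equivariant.
#'
#' @param N,CA,C backbone coordinates (length-3 vectors or `n x 3` matrices).
#' @return C-beta coordinates, same shape as the inputs.
#' @export
idealize_cbeta <- function(N, CA, C) {
  N <- .as_rows(N); CA <- .as_rows(CA); C <- .as_rows(C)
  if (any(rowSums(.cross3(CA - N, C - CA)^2) < 1e-12)) {
    stop("collinear backbone atoms in idealize_cbeta()")
  }
  ic <- .cbeta_internal()
  out <- .nerf_rows(C, N, CA, ic$r, ic$theta, ic$tau)
  if (nrow(out) == 1) as.vector(out) else out
}

# CA-CB internal coordinates measured once from the idealized ALA template
.cbeta_internal <- function() {
  if (is.null(.chiflow_env$cbeta_ic)) {
    co <- residue_templates()[["ALA"]]$coords
    v1 <- co[1, ] - co[2, ]; v2 <- co[5, ] - co[2, ]
    .chiflow_env$cbeta_ic <- list(
      r = sqrt(sum(v2^2)),
      theta = acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))),
      tau = dihedral(co[3, ], co[1, ], co[2, ], co[5, ]))
  }
  .chiflow_env$cbeta_ic
}

#' Idealized C-beta positions for every residue of a structure
#' @param structure a [chi_structure()].
#' @return `R x 3` matrix (virtual C-beta for GLY/UNK).
#' @export
structure_cbeta <- function(structure) {
  bb <- structure$atom14
  idealize_cbeta(bb[, 1, , drop = TRUE], bb[, 2, , drop = TRUE],
                 bb[, 3, , drop = TRUE])
}

#' Measure the chi angles of one residue
#'
#' @param structure a [chi_structure()].
#' @param residue_index residue position (1-based).
#' @return list with `angles` (length 4, radians, unreduced), `exists`
#'   (length-4 logical; `FALSE` where the residue has no such chi or a
#'   defining atom is missing) and `symmetric` (length-4 logical).
#' @export
measure_chi <- function(structure, residue_index) {
  stopifnot(residue_index >= 1, residue_index <= n_residues(structure))
  aa <- structure$aa[residue_index]
  tmpl <- residue_templates()[[aa]]
  angles <- numeric(4)
  exists <- logical(4)
  symmetric <- logical(4)
  if (is.null(tmpl)) {
    if (aa != "UNK") stop("unknown residue type: ", aa)
    return(list(angles = angles, exists = exists, symmetric = symmetric))
  }
  xyz <- structure$atom14[residue_index, , ]
  msk <- structure$atom_mask[residue_index, ]
  if (tmpl$n_chi > 0) {
    for (k in seq_len(tmpl$n_chi)) {
      sl <- tmpl$chi_atoms[k, ]
      if (all(msk[sl])) {
        angles[k] <- dihedral(xyz[sl[1], ], xyz[sl[2], ], xyz[sl[3], ],
                              xyz[sl[4], ])
        exists[k] <- TRUE
      }
      symmetric[k] <- tmpl$chi_symmetric[k]
    }
  }
  list(angles = angles, exists = exists, symmetric = symmetric)
}

#' Measure all chi angles of a structure
#'
#' @param structure a [chi_structure()].
#' @param reduce map pi-symmetric angles into `[0, pi)` (default `TRUE`).
#' @return a [chi_set()].
#' @export
measure_chi_all <- function(structure, reduce = TRUE) {
  R <- n_residues(structure)
  angles <- matrix(0, R, 4)
  exists <- matrix(FALSE, R, 4)
  symmetric <- matrix(FALSE, R, 4)
  # collect every defined chi quadruple and evaluate one vectorised dihedral
  tmpl <- residue_templates()
  qi <- list(); qk <- list(); qs <- list()
  for (i in seq_len(R)) {
    tp <- tmpl[[structure$aa[i]]]
    if (is.null(tp) || tp$n_chi == 0) next
    msk <- structure$atom_mask[i, ]
    for (k in seq_len(tp$n_chi)) {
      symmetric[i, k] <- tp$chi_symmetric[k]
      sl <- tp$chi_atoms[k, ]
      if (all(msk[sl])) {
        qi[[length(qi) + 1L]] <- i
        qk[[length(qk) + 1L]] <- k
        qs[[length(qs) + 1L]] <- sl
      }
    }
  }
  if (length(qi)) {
    ii <- unlist(qi); kk <- unlist(qk)
    sl <- do.call(rbind, qs)
    xyz <- structure$atom14
    p <- function(col) {
      cbind(xyz[cbind(ii, sl[, col], 1)], xyz[cbind(ii, sl[, col], 2)],
            xyz[cbind(ii, sl[, col], 3)])
    }
    ang <- dihedral(p(1), p(2), p(3), p(4))
    angles[cbind(ii, kk)] <- ang
    exists[cbind(ii, kk)] <- TRUE
  }
  out <- chi_set(angles, exists, symmetric)
  if (reduce) reduce_symmetry(out) else out
}

# Per-residue template coordinates rigidly aligned to the observed backbone,
# before any chi rotation. Backbone N/CA/C/O slots are taken from the input
# structure; alignment is least-squares on (N, CA, C). Cached by callers that
# rebuild atoms repeatedly while the backbone stays fixed.
.sidechain_base <- function(structure) {
  tmpl <- residue_templates()
  R <- n_residues(structure)
  out <- vector("list", R)
  for (i in seq_len(R)) {
    aa <- structure$aa[i]
    tp <- tmpl[[aa]]
    if (is.null(tp)) { out[[i]] <- NULL; next }
    bb <- structure$atom14[i, 1:3, ]
    if (!all(is.finite(bb))) stop("non-finite backbone at residue ", i)
    tr <- .kabsch(tp$coords[1:3, ], bb)
    coords <- matrix(NA_real_, 14, 3)
    coords[tp$mask, ] <- .apply_rigid(tp$coords[tp$mask, , drop = FALSE], tr)
    coords[1:3, ] <- bb
    if (structure$atom_mask[i, 4]) coords[4, ] <- structure$atom14[i, 4, ]
    out[[i]] <- coords
  }
  out
}

# apply chi rotations (in order) to one residue's aligned base coordinates
.apply_chi <- function(base, tp, chi, n_chi_use = tp$n_chi) {
  coords <- base
  if (tp$n_chi == 0 || n_chi_use == 0) return(coords)
  for (k in seq_len(min(n_chi_use, tp$n_chi))) {
    sl <- tp$chi_atoms[k, ]
    cur <- dihedral(coords[sl[1], ], coords[sl[2], ], coords[sl[3], ],
                    coords[sl[4], ])
    delta <- torus_log(cur, chi[k])
    axis <- coords[sl[3], ] - coords[sl[2], ]
    axis <- axis / sqrt(sum(axis^2))
    rot <- tp$chi_rotating[[k]]
    # rotating by +delta about unit(a3 - a2) increases the torsion by delta
    coords[rot, ] <- .rotate_about(coords[rot, , drop = FALSE],
                                  coords[sl[3], ], axis, delta)
  }
  coords
}

#' Rebuild one residue's atom14 coordinates from backbone + chi
#'
#' Rigidly aligns the idealized template onto the residue's N/CA/C, keeps the
#' observed backbone atoms, then applies the requested chi rotations in order
#' about the current bond axes. Bond lengths and angles are template-ideal.
#'
#' @param structure a [chi_structure()] providing the backbone.
#' @param residue_index residue position.
#' @param chi numeric length-4 chi angles (radians; extra entries ignored for
#'   residues with fewer chi angles).
#' @return `14 x 3` coordinate matrix (`NA` rows for unused slots).
#' @export
build_atoms <- function(structure, residue_index, chi) {
  aa <- structure$aa[residue_index]
  tp <- residue_templates()[[aa]]
  if (is.null(tp)) stop("unknown residue type: ", aa)
  base <- .sidechain_base(subset_structure(structure, residue_index))[[1]]
  .apply_chi(base, tp, chi)
}

# Precomputed kinematic context for repeated rebuilds on a fixed backbone:
# the aligned-template base coordinates as an R x 14 x 3 array, the output
# atom mask, and, per chi index, the residues that have it, their atom
# quadruples and per-residue rotating masks.
.kin_context <- function(structure) {
  tmpl <- residue_templates()
  base_list <- .sidechain_base(structure)
  R <- n_residues(structure)
  base <- array(NA_real_, c(R, 14, 3))
  mask <- matrix(FALSE, R, 14)
  quad <- vector("list", 4)
  rotm <- vector("list", 4)
  has <- vector("list", 4)
  for (k in 1:4) {
    quad[[k]] <- matrix(NA_integer_, R, 4)
    rotm[[k]] <- matrix(FALSE, R, 14)
  }
  passthrough <- logical(R)
  for (i in seq_len(R)) {
    tp <- tmpl[[structure$aa[i]]]
    if (is.null(tp)) {
      base[i, , ] <- structure$atom14[i, , ]
      mask[i, ] <- structure$atom_mask[i, ]
      passthrough[i] <- TRUE
      next
    }
    base[i, , ] <- base_list[[i]]
    mask[i, ] <- tp$mask
    if (!structure$atom_mask[i, 4]) mask[i, 4] <- FALSE
    if (tp$n_chi > 0) {
      for (k in seq_len(tp$n_chi)) {
        quad[[k]][i, ] <- tp$chi_atoms[k, ]
        rotm[[k]][i, tp$chi_rotating[[k]]] <- TRUE
      }
    }
  }
  for (k in 1:4) has[[k]] <- which(!is.na(quad[[k]][, 1]))
  list(structure = structure, base = base, mask = mask, quad = quad,
       rotm = rotm, has = has, passthrough = passthrough)
}

# vectorised rebuild: apply chi rotations to all residues at once, one chi
# index at a time (later chi axes depend on earlier rotations)
.rebuild_atoms <- function(kin, angles) {
  P <- kin$base
  for (k in 1:4) {
    idx <- kin$has[[k]]
    if (!length(idx)) next
    q <- kin$quad[[k]][idx, , drop = FALSE]
    n <- length(idx)
    gx <- function(col) cbind(P[cbind(idx, q[, col], 1)],
                              P[cbind(idx, q[, col], 2)],
                              P[cbind(idx, q[, col], 3)])
    cur <- dihedral(gx(1), gx(2), gx(3), gx(4))
    delta <- torus_log(cur, angles[idx, k])
    p2 <- gx(2); p3 <- gx(3)
    ax <- p3 - p2
    ax <- ax / sqrt(rowSums(ax^2))
    cd <- cos(delta); sd <- sin(delta)
    Vx <- P[idx, , 1] - p3[, 1]
    Vy <- P[idx, , 2] - p3[, 2]
    Vz <- P[idx, , 3] - p3[, 3]
    if (n == 1) { Vx <- matrix(Vx, 1); Vy <- matrix(Vy, 1); Vz <- matrix(Vz, 1) }
    Cx <- ax[, 2] * Vz - ax[, 3] * Vy
    Cy <- ax[, 3] * Vx - ax[, 1] * Vz
    Cz <- ax[, 1] * Vy - ax[, 2] * Vx
    dot <- ax[, 1] * Vx + ax[, 2] * Vy + ax[, 3] * Vz
    Rx <- Vx * cd + Cx * sd + ax[, 1] * (dot * (1 - cd)) + p3[, 1]
    Ry <- Vy * cd + Cy * sd + ax[, 2] * (dot * (1 - cd)) + p3[, 2]
    Rz <- Vz * cd + Cz * sd + ax[, 3] * (dot * (1 - cd)) + p3[, 3]
    m <- kin$rotm[[k]][idx, , drop = FALSE]
    sub <- P[idx, , , drop = FALSE]
    sel <- which(m)
    nidx <- length(idx)
    sub[sel] <- Rx[sel]
    sub[sel + nidx * 14] <- Ry[sel]
    sub[sel + 2 * nidx * 14] <- Rz[sel]
    P[idx, , ] <- sub
  }
  P
}

#' Rebuild all side chains of a structure from a chi set
#'
#' Backbone atoms (N, CA, C, O) are kept from the input; every side-chain slot
#' is reconstructed from the idealized template and `chi`. Used both to build
#' noised coordinates during training and to realize samples.
#'
#' @param structure a [chi_structure()].
#' @param chi a [chi_set()] (angles at non-existing slots ignored).
#' @param base optional precomputed kinematic context (internal) for repeated
#'   calls with a fixed backbone.
#' @return a [chi_structure()] with rebuilt atom14 and the template atom mask
#'   (backbone O mask preserved from the input).
#' @export
build_structure_atoms <- function(structure, chi, base = NULL) {
  kin <- if (is.null(base)) .kin_context(structure) else base
  atom14 <- .rebuild_atoms(kin, chi$angles)
  chi_structure(structure$aa, atom14, kin$mask, chain = structure$chain,
                resno = structure$resno)
}
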