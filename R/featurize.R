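#' Residue-graph featurization
#'
#' The denoiser operates on a residue-level k-nearest-neighbour graph: one
#' node per residue positioned at its idealized C-beta, directed edges from
#' each residue to its `k` nearest neighbours (k = 30 by default). Node
#' features are the one-hot amino-acid identity (20 canonical + unknown),
#' sin/cos of the backbone torsions phi/psi/omega with per-torsion validity
#' bits (chain termini), and a sinusoidal embedding of the flow time t. Edge
#' features are a 65-bin one-hot of the relative sequence position clamped to
#' `[-32, 32]` (edges between different chains are pinned to the +32 bin) and
#' the 14 x 14 = 196 pairwise atom14 distances between the two residues at the
#' current (noised) coordinates, with per-pair availability bits. All features
#' are invariant under rigid motions of the coordinates.
#'
#' @name featurize
#' @keywords internal
NULL

#' Backbone torsion angles of a structure
#'
#' phi/psi/omega per residue; a torsion is invalid at chain termini (phi and
#' omega for the first residue of a chain, psi for the last). Residues are
#' consecutive when adjacent in the record and on the same chain.
#'
#' @param structure a [chi_structure()].
#' @return list with `angles` (R x 3 radians, 0 where invalid) and `valid`
#'   (R x 3 logical); columns phi, psi, omega.
#' @export
backbone_torsions <- function(structure) {
  R <- n_residues(structure)
  xyz <- structure$atom14
  N <- xyz[, 1, , drop = TRUE]; CA <- xyz[, 2, , drop = TRUE]
  C <- xyz[, 3, , drop = TRUE]
  if (R == 1) { N <- matrix(N, 1); CA <- matrix(CA, 1); C <- matrix(C, 1) }
  angles <- matrix(0, R, 3, dimnames = list(NULL, c("phi", "psi", "omega")))
  valid <- matrix(FALSE, R, 3)
  linked <- if (R > 1) {
    structure$chain[-R] == structure$chain[-1]
  } else logical(0)
  prev_ok <- c(FALSE, linked)
  next_ok <- c(linked, FALSE)
  ip <- which(prev_ok)
  if (length(ip)) {
    angles[ip, 1] <- dihedral(C[ip - 1, , drop = FALSE],
                              N[ip, , drop = FALSE], CA[ip, , drop = FALSE],
                              C[ip, , drop = FALSE])
    angles[ip, 3] <- dihedral(CA[ip - 1, , drop = FALSE],
                              C[ip - 1, , drop = FALSE],
                              N[ip, , drop = FALSE], CA[ip, , drop = FALSE])
    valid[ip, c(1, 3)] <- TRUE
  }
  inx <- which(next_ok)
  if (length(inx)) {
    angles[inx, 2] <- dihedral(N[inx, , drop = FALSE],
                               CA[inx, , drop = FALSE],
                               C[inx, , drop = FALSE],
                               N[inx + 1, , drop = FALSE])
    valid[inx, 2] <- TRUE
  }
  list(angles = angles, valid = valid)
}

#' Directed k-nearest-neighbour edges over C-beta positions
#'
#' Each residue gets edges to its `min(k, R - 1)` nearest other residues by
#' Euclidean C-beta distance; distance ties break deterministically toward the
#' lower residue index. Edges are returned grouped by centre residue.
#'
#' @param cbeta `R x 3` matrix of (idealized) C-beta coordinates.
#' @param k neighbour count (default 30).
#' @return integer `E x 2` matrix with columns `i` (centre) and `j`
#'   (neighbour); no self-edges.
#' @export
knn_edges <- function(cbeta, k = 30) {
  R <- nrow(cbeta)
  if (R < 2) stop("k-NN graph needs at least 2 residues")
  if (any(!is.finite(cbeta))) stop("non-finite C-beta coordinates")
  kk <- min(k, R - 1)
  d2 <- as.matrix(stats::dist(cbeta))^2
  diag(d2) <- Inf
  js <- apply(d2, 1, function(row) order(row)[seq_len(kk)])
  cbind(i = rep(seq_len(R), each = kk), j = as.integer(js))
}

#' Sinusoidal embedding of the flow time
#'
#' @param t numeric vector of times in `[0, 1]`.
#' @param dim embedding dimension (even, default 32).
#' @return `length(t) x dim` matrix of `sin`/`cos` pairs at geometrically
#'   spaced frequencies.
#' @export
timestep_embedding <- function(t, dim = 32) {
  stopifnot(dim %% 2 == 0)
  half <- dim / 2
  freq <- exp(seq(log(1), log(1000), length.out = half))
  ang <- outer(t, freq)
  cbind(sin(ang), cos(ang))
}

#' Node feature matrix
#'
#' @param structure a [chi_structure()].
#' @param t flow time, scalar or length-R vector.
#' @param t_dim timestep embedding dimension.
#' @return `R x (21 + 9 + t_dim)` feature matrix: amino-acid one-hot
#'   (20 canonical + unknown), sin/cos of phi/psi/omega zeroed where invalid,
#'   three validity bits, timestep embedding.
#' @export
node_features <- function(structure, t, t_dim = 32) {
  R <- n_residues(structure)
  aa_idx <- match(structure$aa, AA3)
  aa_idx[is.na(aa_idx)] <- 21L
  onehot <- matrix(0, R, 21)
  onehot[cbind(seq_len(R), aa_idx)] <- 1
  bt <- backbone_torsions(structure)
  sc <- cbind(sin(bt$angles), cos(bt$angles))[, c(1, 4, 2, 5, 3, 6)]
  sc <- sc * bt$valid[, c(1, 1, 2, 2, 3, 3)]
  temb <- timestep_embedding(rep_len(t, R), t_dim)
  cbind(onehot, sc, bt$valid * 1, temb)
}

#' Relative-position bin for an edge
#'
#' Same-chain edges use the sequence offset `j - i` clamped to `[-32, 32]`;
#' edges between residues of different chains are fixed to the +32 bin. Bin 1
#' corresponds to offset -32, bin 65 to offset +32.
#'
#' @param chain_ids per-residue chain labels.
#' @param i,j residue indices (vectors of equal length).
#' @return integer bin indices in `1:65`.
#' @export
multimer_relpos <- function(chain_ids, i, j) {
  off <- pmax(-32, pmin(32, j - i))
  off[chain_ids[i] != chain_ids[j]] <- 32L
  as.integer(off + 33L)
}

#' Edge feature matrix
#'
#' @param structure a [chi_structure()] (provides chain labels).
#' @param atoms14 `R x 14 x 3` current (possibly noised) coordinates used for
#'   the pairwise distances; defaults to the structure's own atoms.
#' @param atom_mask `R x 14` availability mask for `atoms14`.
#' @param edge_index `E x 2` matrix from [knn_edges()].
#' @return `E x 457` matrix: 65 relpos one-hot columns, 196 pairwise atom14
#'   distances (Angstrom, 0 where either atom is missing), 196 availability
#'   bits. Distance column `65 + (a-1)*14 + b` is the distance from atom slot
#'   `a` of residue `i` to slot `b` of residue `j`.
#' @export
edge_features <- function(structure, edge_index, atoms14 = structure$atom14,
                          atom_mask = structure$atom_mask) {
  E <- nrow(edge_index)
  ii <- edge_index[, 1]; jj <- edge_index[, 2]
  rel <- matrix(0, E, 65)
  rel[cbind(seq_len(E), multimer_relpos(structure$chain, ii, jj))] <- 1
  Ai <- atoms14[ii, , , drop = FALSE]
  Aj <- atoms14[jj, , , drop = FALSE]
  Mi <- atom_mask[ii, , drop = FALSE]
  Mj <- atom_mask[jj, , drop = FALSE]
  dist <- matrix(0, E, 196)
  dmask <- matrix(0, E, 196)
  for (b in seq_len(14)) {
    dx <- Ai[, , 1] - Aj[, b, 1]
    dy <- Ai[, , 2] - Aj[, b, 2]
    dz <- Ai[, , 3] - Aj[, b, 3]
    cols <- (seq_len(14) - 1) * 14 + b
    m <- Mi * Mj[, b]
    d <- sqrt(dx * dx + dy * dy + dz * dz)
    d[m == 0] <- 0
    dist[, cols] <- d
    dmask[, cols] <- m
  }
  cbind(rel, dist, dmask)
}

#' Gaussian radial basis expansion of distances
#'
#' @param d numeric matrix of distances (Angstrom).
#' @param centers number of basis centres (default 16).
#' @param d_min,d_max range spanned by the centres (default 0-20 Angstrom).
#' @return matrix with `ncol(d) * centers` columns (centre-major blocks).
#' @export
rbf_expand <- function(d, centers = 16, d_min = 0, d_max = 20) {
  mu <- seq(d_min, d_max, length.out = centers)
  sigma <- (d_max - d_min) / (centers - 1)
  out <- matrix(0, nrow(d), ncol(d) * centers)
  for (c_ in seq_len(centers)) {
    out[, ((c_ - 1) * ncol(d) + 1):(c_ * ncol(d))] <-
      exp(-((d - mu[c_])^2) / (2 * sigma^2))
  }
  out
}

#' Build the static part of a packing graph
#'
#' Everything that does not depend on the flow state: k-NN edges over
#' idealized C-beta positions, relative-position one-hots, and the
#' time-independent node columns. The time embedding and the noised-atom
#' distance block are filled in per step.
#'
#' @param structure a [chi_structure()].
#' @param k neighbour count (default 30, the model's operating value).
#' @return list of class `"packing_graph"` with `edge_index`, `cbeta`,
#'   `node_static` (R x 30), `relpos` (E x 65), `knn_k`.
#' @export
pack_graph <- function(structure, k = 30) {
  cb <- structure_cbeta(structure)
  edges <- knn_edges(cb, k)
  nf <- node_features(structure, 0, t_dim = 2)
  node_static <- nf[, 1:30, drop = FALSE]
  E <- nrow(edges)
  rel <- matrix(0, E, 65)
  rel[cbind(seq_len(E),
            multimer_relpos(structure$chain, edges[, 1], edges[, 2]))] <- 1
  structure(list(edge_index = edges, cbeta = cb, node_static = node_static,
                 relpos = rel, knn_k = k),
            class = "packing_graph")
}

#' @export
print.packing_graph <- function(x, ...) {
  cat(sprintf("<packing_graph> %d nodes, %d edges (k = %d)\n",
              nrow(x$node_static), nrow(x$edge_index), x$knn_k))
  invisible(x)
}
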