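# Shared small fixtures, computed once per test run.

trio_fixtures <- fixture_trio(seed = 7)

# a single mid-size fixture reused by several files
fx_helix <- trio_fixtures[[1]]

random_rigid_transform <- function(seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3)
  qr_ <- qr(A)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = rnorm(3, 0, 10))
}

apply_rigid_structure <- function(structure, tr) {
  out <- structure
  for (s in 1:14) {
    xyz <- structure$atom14[, s, ]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    out$atom14[, s, ] <- sweep(xyz %*% t(tr$R), 2, tr$t, "+")
  }
  out
}

# independent torsion implementation (projection form) used as an oracle
dihedral_oracle <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(c(b1[2] * v[3] - b1[3] * v[2],
             b1[3] * v[1] - b1[1] * v[3],
             b1[1] * v[2] - b1[2] * v[1]) * w)
  atan2(y, x)
}

# brute-force shortest signed arc via integer shifts (oracle for torus_log)
shortest_arc_oracle <- function(x0, x1, period = 2 * pi) {
  ks <- -3:3
  cand <- x1 - x0 + ks * period
  cand[which.min(abs(cand))]
}
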