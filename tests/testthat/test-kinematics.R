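# backbone-only single-residue structure on the template's own frame
ideal_residue_structure <- function(aa) {
  tp <- residue_templates()[[aa]]
  bb <- array(NA_real_, c(1, 14, 3))
  msk <- matrix(FALSE, 1, 14)
  bb[1, 1:4, ] <- tp$coords[1:4, ]
  msk[1, 1:4] <- TRUE
  chi_structure(aa, bb, msk)
}

test_that("dihedral follows the IUPAC convention and matches an independent oracle", {
  p1 <- c(1, 1, 0); p2 <- c(0, 1, 0); p3 <- c(0, 0, 0)
  expect_equal(dihedral(p1, p2, p3, c(1, 0, 0)), 0)        # cis
  expect_equal(dihedral(p1, p2, p3, c(-1, 0, 0)), pi)      # trans
  set.seed(21)
  for (i in 1:50) {
    p <- matrix(rnorm(12, sd = 2), 4)
    expect_lt(abs(torus_log(dihedral_oracle(p[1, ], p[2, ], p[3, ], p[4, ]),
                            dihedral(p[1, ], p[2, ], p[3, ], p[4, ]))),
              1e-9)
  }
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear|degenerate")
})

test_that("chi measurement handles missing angles and atoms", {
  st <- ideal_residue_structure("ALA")
  m <- measure_chi(st, 1)
  expect_false(any(m$exists))
  # SER with OG removed: chi1 masked
  tp <- residue_templates()[["SER"]]
  full <- array(tp$coords, c(1, 14, 3))
  msk <- matrix(tp$mask, 1, 14)
  msk[1, 6] <- FALSE  # OG
  st2 <- chi_structure("SER", full, msk)
  expect_false(measure_chi(st2, 1)$exists[1])
  expect_error(measure_chi(st2, 5), "residue_index")
})

test_that("build then measure recovers chi for all chi-bearing residues", {
  set.seed(31)
  for (aa in names(residue_templates())) {
    tp <- residue_templates()[[aa]]
    if (tp$n_chi == 0) next
    st <- ideal_residue_structure(aa)
    for (rep in 1:10) {
      chi <- runif(4, -pi, pi)
      xyz <- build_atoms(st, 1, chi)
      st2 <- chi_structure(aa, array(xyz, c(1, 14, 3)),
                           matrix(tp$mask, 1, 14))
      m <- measure_chi(st2, 1)
      expect_true(all(m$exists[seq_len(tp$n_chi)]))
      err <- abs(torus_log(m$angles[m$exists],
                           chi[seq_len(4)][m$exists]))
      expect_lt(max(err), 1e-6)
    }
  }
})

test_that("glycine builds only backbone atoms", {
  st <- ideal_residue_structure("GLY")
  xyz <- build_atoms(st, 1, rep(0, 4))
  expect_true(all(is.finite(xyz[1:4, ])))
  expect_true(all(is.na(xyz[5:14, ])))
})

test_that("chi rotations move exactly their rotating set", {
  tp <- residue_templates()[["LYS"]]
  st <- ideal_residue_structure("LYS")
  chi <- c(1, -2, 0.5, 2.5)
  a <- build_atoms(st, 1, chi)
  for (k in 1:4) {
    chi2 <- chi
    chi2[k] <- chi[k] + 0.7
    b <- build_atoms(st, 1, chi2)
    moved <- sqrt(rowSums((b - a)^2)) > 1e-9
    moved[is.na(moved)] <- FALSE
    expect_setequal(which(moved), tp$chi_rotating[[k]])
    # the axis-defining atoms of chi_1..chi_k never move under chi_k
    expect_false(any(tp$chi_atoms[seq_len(k), 1:3] %in% which(moved)))
  }
})

test_that("rebuilt residues keep template-ideal bonded geometry", {
  set.seed(12)
  for (aa in c("ARG", "TRP", "ILE", "MET")) {
    tp <- residue_templates()[[aa]]
    st <- ideal_residue_structure(aa)
    xyz <- build_atoms(st, 1, runif(4, -pi, pi))
    for (r in seq_len(nrow(tp$bonds))) {
      b <- tp$bonds[r, ]
      want <- sqrt(sum((tp$coords[b[1], ] - tp$coords[b[2], ])^2))
      got <- sqrt(sum((xyz[b[1], ] - xyz[b[2], ])^2))
      expect_lt(abs(got - want), 0.01)
    }
  }
})

test_that("building commutes with rigid transforms of the backbone", {
  fx <- make_full_structure(20, seed = 14)
  tr <- random_rigid_transform(2)
  moved <- apply_rigid_structure(fx$structure, tr)
  a <- build_structure_atoms(fx$structure, fx$chi)
  b <- build_structure_atoms(moved, fx$chi)
  for (i in seq_len(20)) {
    sl <- which(a$atom_mask[i, ])
    want <- sweep(a$atom14[i, sl, , drop = FALSE][1, , ] %*% t(tr$R), 2,
                  tr$t, "+")
    expect_lt(max(abs(b$atom14[i, sl, ] - want)), 1e-6)
  }
})

test_that("idealized C-beta has fixed geometry and is frame-equivariant", {
  fx <- make_full_structure(15, seed = 4)
  bb <- fx$structure$atom14
  cb <- idealize_cbeta(bb[, 1, ], bb[, 2, ], bb[, 3, ])
  len <- sqrt(rowSums((cb - bb[, 2, ])^2))
  expect_true(all(len > 1.52 & len < 1.54))
  tr <- random_rigid_transform(6)
  moved <- apply_rigid_structure(fx$structure, tr)
  cb2 <- idealize_cbeta(moved$atom14[, 1, ], moved$atom14[, 2, ],
                        moved$atom14[, 3, ])
  expect_lt(max(abs(cb2 - sweep(cb %*% t(tr$R), 2, tr$t, "+"))), 1e-9)
  expect_error(idealize_cbeta(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "collinear")
})

test_that("pi-symmetry reduction maps flagged angles to [0, pi)", {
  meta <- chi_metadata(c("ASP", "LEU", "GLU", "PHE", "TYR"))
  ang <- matrix(0, 5, 4)
  ang[1, 2] <- 190 * pi / 180   # ASP chi2
  ang[2, 2] <- 190 * pi / 180   # LEU chi2 (not flagged)
  chi <- chi_set(ang, meta$exists, meta$symmetric)
  red <- reduce_symmetry(chi)
  expect_equal(red$angles[1, 2], 10 * pi / 180, tolerance = 1e-12)
  expect_equal(red$angles[2, 2], torus_wrap(190 * pi / 180), tolerance = 1e-12)
  expect_true(meta$symmetric[1, 2])   # ASP chi2
  expect_true(meta$symmetric[3, 3])   # GLU chi3
  expect_true(meta$symmetric[4, 2] && meta$symmetric[5, 2])  # PHE/TYR chi2
  expect_false(any(meta$symmetric[2, ]))
})

test_that("pi-flipped chi angles give the same heavy-atom set up to a name swap", {
  set.seed(44)
  for (aa in c("ASP", "GLU", "PHE", "TYR")) {
    tp <- residue_templates()[[aa]]
    st <- ideal_residue_structure(aa)
    kflip <- which(tp$chi_symmetric)
    chi <- runif(4, -pi, pi)
    chi2 <- chi
    chi2[kflip] <- chi[kflip] + pi
    a <- build_atoms(st, 1, chi)
    b <- build_atoms(st, 1, chi2)
    sl <- which(tp$mask)
    # greedy assignment: every atom of one set has a near-exact partner of
    # the same element in the other
    for (s in sl) {
      partners <- sl[tp$elements[sl] == tp$elements[s]]
      dmin <- min(sqrt(rowSums((b[partners, , drop = FALSE] -
                                  matrix(a[s, ], length(partners), 3,
                                         byrow = TRUE))^2)))
      expect_lt(dmin, 1e-6)
    }
  }
})
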