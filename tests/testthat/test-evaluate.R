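test_that("angle errors use the minimum arc with the right period", {
  expect_equal(angle_error(350 * pi / 180, 10 * pi / 180), 20)
  expect_equal(angle_error(1.2, 1.2), 0)
  # ASP chi2 is pi-symmetric: 175 vs 355 degrees is a perfect match
  expect_equal(angle_error(175 * pi / 180, 355 * pi / 180, symmetric = TRUE),
               0, tolerance = 1e-9)
  set.seed(2)
  a <- runif(300, -10, 10); b <- runif(300, -10, 10)
  expect_equal(angle_error(a, b), angle_error(b, a), tolerance = 1e-9)
  expect_true(all(angle_error(a, b) <= 180))
  expect_true(all(angle_error(a, b, symmetric = TRUE) <= 90))
})

test_that("angle accuracy counts strict sub-threshold errors", {
  expect_equal(angle_accuracy(c(0, 0, 0)), 1)
  expect_equal(angle_accuracy(c(10, 30)), 0.5)
  expect_true(is.na(angle_accuracy(numeric(0))))
  set.seed(3)
  for (rep in 1:5) {
    errs <- runif(100, 0, 90)
    thr <- runif(1, 5, 45)
    expect_equal(angle_accuracy(errs, thr), sum(errs < thr) / 100)
  }
})

test_that("per-residue RMSD follows the formula and matches symmetric swaps", {
  tp <- residue_templates()[["LEU"]]
  a <- tp$coords
  b <- a
  n_side <- sum(tp$mask) - 4
  b[6, ] <- b[6, ] + c(1, 0, 0)  # displace one side-chain atom by 1 A
  expect_equal(residue_rmsd(a, a, "LEU"), 0)
  expect_equal(residue_rmsd(b, a, "LEU"), 1 / sqrt(n_side))
  expect_true(is.na(residue_rmsd(a, a, "ALA")))
  expect_true(is.na(residue_rmsd(a, a, "GLY")))
  # exchanging OD1/OD2 in the reference leaves ASP RMSD unchanged
  tpd <- residue_templates()[["ASP"]]
  st <- chi_structure("ASP", array(tpd$coords, c(1, 14, 3)),
                      matrix(tpd$mask, 1, 14))
  pred <- build_atoms(st, 1, c(0.7, 0.4, 0, 0))
  ref <- build_atoms(st, 1, c(0.9, 1.1, 0, 0))
  ref_sw <- ref
  ref_sw[c(7, 8), ] <- ref[c(8, 7), ]
  expect_equal(residue_rmsd(pred, ref, "ASP"), residue_rmsd(pred, ref_sw, "ASP"),
               tolerance = 1e-9)
  # a pi-flip of ASP chi2 is RMSD-neutral
  pred_flip <- build_atoms(st, 1, c(0.7, 0.4 + pi, 0, 0))
  expect_lt(abs(residue_rmsd(pred_flip, ref, "ASP") -
                  residue_rmsd(pred, ref, "ASP")), 1e-6)
})

test_that("core/surface labels match a brute-force neighbour count", {
  fx <- make_full_structure(50, secondary_structure = "mixed", seed = 23)
  labels <- classify_core_surface(fx$structure)
  cb <- structure_cbeta(fx$structure)
  for (i in seq_len(50)) {
    cnt <- sum(sqrt(colSums((t(cb) - cb[i, ])^2)) <= 10) - 1
    want <- if (cnt >= 20) "core" else if (cnt <= 15) "surface" else "other"
    expect_equal(labels[i], want)
  }
  # an isolated 2-residue structure is all surface
  two <- subset_structure(fx$structure, 1:2)
  expect_equal(classify_core_surface(two), c("surface", "surface"))
  # labels ignore side-chain conformation
  meta <- chi_metadata(fx$structure$aa)
  other <- build_structure_atoms(fx$structure,
                                 chi_set(matrix(1, 50, 4), meta$exists,
                                         meta$symmetric))
  expect_equal(classify_core_surface(other), labels)
})

test_that("a dense backbone cluster is classified as core", {
  set.seed(31)
  R <- 25
  atom14 <- array(NA_real_, c(R, 14, 3))
  mask <- matrix(FALSE, R, 14)
  for (i in seq_len(R)) {
    centre <- rnorm(3, sd = 1.5)
    frame <- residue_templates()[["GLY"]]$coords[1:4, ]
    atom14[i, 1:4, ] <- sweep(frame, 2, centre, "+")
    mask[i, 1:4] <- TRUE
  }
  st <- chi_structure(rep("GLY", R), atom14, mask)
  expect_true(all(classify_core_surface(st) == "core"))
})

test_that("clash counting applies the vdW overlap criterion", {
  # two lone CA carbons: 10 A apart no clash; 2.0 A apart (vdW sum 3.4,
  # threshold 3.0) exactly one clash
  mk <- function(sep) {
    atom14 <- array(NA_real_, c(2, 14, 3))
    atom14[1, 2, ] <- c(0, 0, 0)
    atom14[2, 2, ] <- c(sep, 0, 0)
    mask <- matrix(FALSE, 2, 14)
    mask[, 2] <- TRUE
    chi_structure(c("GLY", "GLY"), atom14, mask, chain = c("A", "B"))
  }
  expect_equal(count_clashes(mk(10)), 0L)
  expect_equal(count_clashes(mk(2.0)), 1L)
  expect_equal(count_clashes(mk(3.1)), 0L)
})

test_that("grid clash counting equals a brute-force pair scan", {
  brute_clashes <- function(st, max_span = 3) {
    at <- chiflow:::.atom_table(st)
    n <- length(at$res)
    radii <- vdw_radii()[at$elem]
    cnt <- 0L
    for (p in seq_len(n - 1)) {
      for (q in (p + 1):n) {
        ri <- at$res[p]; rj <- at$res[q]
        if (ri == rj) next
        d <- sqrt(sum((at$xyz[p, ] - at$xyz[q, ])^2))
        if (d >= radii[p] + radii[q] - 0.4) next
        i1 <- min(ri, rj); i2 <- max(ri, rj)
        if (i2 == i1 + 1 && st$chain[i1] == st$chain[i2]) {
          a <- if (ri < rj) at$slot[p] else at$slot[q]
          b <- if (ri < rj) at$slot[q] else at$slot[p]
          if (chiflow:::.peptide_excluded(st$aa[i1], st$aa[i2], a, b,
                                          max_span)) next
        }
        cnt <- cnt + 1L
      }
    }
    cnt
  }
  for (s in 1:6) {
    fx <- make_full_structure(30, secondary_structure =
                                c("helix", "strand", "mixed")[1 + s %% 3],
                              seed = 40 + s)
    expect_identical(count_clashes(fx$structure),
                     brute_clashes(fx$structure))
  }
})

test_that("ideal peptide geometry sits inside the overlap threshold only via 1-4 pairs", {
  # O(i) and CA(i+1) are 1-4 across the peptide bond yet ~2.7-2.8 A apart in
  # ideal trans geometry, below the O/C overlap threshold of
  # 1.52 + 1.70 - 0.4 = 2.82 A; this is why the default exclusion spans 3
  # bonds
  bb <- make_backbone(10, secondary_structure = "strand", seed = 4)
  d <- sqrt(sum((bb$atom14[5, 4, ] - bb$atom14[6, 2, ])^2))
  expect_lt(d, vdw_radii()["O"] + vdw_radii()["C"] - 0.4)
  expect_gt(d, 2.6)
  # with 1-4 pairs excluded the ideal backbone is clash-free; with the
  # strict 1-2/1-3 rule every peptide link would count
  expect_equal(count_clashes(bb), 0L)
  expect_gt(count_clashes(bb, max_bond_span = 2), 0L)
})

test_that("an ideal sparse strand of small residues is clash-free", {
  bb <- make_backbone(30, secondary_structure = "strand",
                      sequence = rep(c("SER", "ALA", "GLY"), 10), seed = 2)
  meta <- chi_metadata(bb$aa)
  ang <- matrix(pi, 30, 4)
  ang[!meta$exists] <- 0
  built <- build_structure_atoms(bb, chi_set(ang, meta$exists,
                                             meta$symmetric))
  expect_equal(count_clashes(built), 0L)
})

test_that("evaluating a structure against itself is a perfect report", {
  fx <- trio_fixtures[[2]]
  ref <- build_structure_atoms(fx$structure, fx$chi)
  rep <- pack_report(ref, ref)
  expect_equal(unname(rep$mae_per_chi), rep(0, 4))
  expect_equal(unname(rep$accuracy_per_chi), rep(1, 4))
  expect_equal(rep$accuracy_all, 1)
  expect_equal(rep$rmsd_all, 0)
  expect_s3_class(rep$per_residue, "data.frame")
})

test_that("metrics are invariant under a joint rigid transform", {
  fx <- trio_fixtures[[2]]
  ref <- build_structure_atoms(fx$structure, fx$chi)
  meta <- chi_metadata(fx$structure$aa)
  other <- build_structure_atoms(fx$structure,
                                 chi_set(matrix(0.5, nrow(meta$exists), 4),
                                         meta$exists, meta$symmetric))
  r1 <- pack_report(other, ref)
  tr <- random_rigid_transform(12)
  r2 <- pack_report(apply_rigid_structure(other, tr),
                    apply_rigid_structure(ref, tr))
  expect_equal(r1$mae_per_chi, r2$mae_per_chi, tolerance = 1e-6)
  expect_equal(r1$rmsd_all, r2$rmsd_all, tolerance = 1e-6)
  expect_equal(r1$clash_count, r2$clash_count)
})
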