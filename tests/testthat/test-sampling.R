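oracle_field <- function(chi1) {
  per <- chi_periods(chi1)
  function(chi_t, t) {
    torus_log(chi_t$angles, chi1$angles, per) / (1 - t) * chi1$exists
  }
}

initial_prior_distance <- function(structure, chi1, seed) {
  meta <- chi_metadata(structure$aa)
  per <- ifelse(meta$symmetric, pi, 2 * pi)
  a <- chiflow:::with_local_seed(seed, {
    x <- matrix(sample_torus_uniform(n_residues(structure) * 4, 2 * pi),
                ncol = 4)
    x[meta$symmetric] <- x[meta$symmetric] %% pi
    x
  })
  abs(torus_log(a, chi1$angles, per))[chi1$exists]
}

test_that("the scheduled field reconstructs the endpoint from the exact field", {
  fx <- make_full_structure(20, seed = 81)
  chi1 <- fx$chi
  per <- chi_periods(chi1)
  set.seed(9)
  pair <- make_training_pair(chi1, t = 0.35)
  v <- oracle_field(chi1)(pair$chi_t, 0.35)
  f <- scheduled_field(v, pair$chi_t, 0.35, schedule_c = 5)
  x1hat <- torus_exp(pair$chi_t$angles, (1 - 0.35) * v, per)
  expect_lt(max(abs(torus_log(x1hat, chi1$angles, per))[chi1$exists]), 1e-9)
  expect_equal(f, 5 * torus_log(pair$chi_t$angles, chi1$angles, per) *
                 chi1$exists, tolerance = 1e-9)
  # zero field at the (estimated) endpoint, and the log-map bound
  f0 <- scheduled_field(matrix(0, 20, 4), pair$chi_t, 0.35)
  expect_true(all(f0 == 0))
  expect_true(all(abs(f) <= 5 * per / 2 + 1e-12))
})

test_that("oracle-field Euler sampling contracts geometrically to the target", {
  fx <- trio_fixtures[[2]]
  chi1 <- fx$chi
  per <- chi_periods(chi1)
  cfg <- sampler_config(num_steps = 10, schedule_c = 5, seed = 11)
  out <- euler_sample(fx$structure, NULL, cfg, field_fn = oracle_field(chi1))
  d0 <- initial_prior_distance(fx$structure, chi1, 11)
  d1 <- abs(torus_log(out$chi$angles, chi1$angles, per))[chi1$exists]
  expect_lt(sum(d1) / sum(d0), 0.01)
  # single step with c = 1 lands exactly on the target
  out1 <- euler_sample(fx$structure, NULL,
                       sampler_config(num_steps = 1, schedule_c = 1,
                                      seed = 11),
                       field_fn = oracle_field(chi1))
  expect_lt(max(abs(torus_log(out1$chi$angles, chi1$angles,
                              per))[chi1$exists]), 1e-9)
  # determinism and chart containment
  out2 <- euler_sample(fx$structure, NULL, cfg, field_fn = oracle_field(chi1))
  expect_identical(out$chi$angles, out2$chi$angles)
  symm <- chi1$symmetric & chi1$exists
  expect_true(all(out$chi$angles[symm] >= 0 & out$chi$angles[symm] < pi))
  reg <- !chi1$symmetric & chi1$exists
  expect_true(all(out$chi$angles[reg] >= -pi & out$chi$angles[reg] < pi))
})

test_that("each oracle Euler step contracts the wrapped distance", {
  fx <- make_full_structure(15, seed = 91)
  chi1 <- fx$chi
  per <- chi_periods(chi1)
  f <- oracle_field(chi1)
  meta <- chi_metadata(fx$structure$aa)
  set.seed(3)
  ang <- matrix(sample_torus_uniform(15 * 4), 15, 4)
  ang[meta$symmetric] <- ang[meta$symmetric] %% pi
  ang[!meta$exists] <- 0
  chi <- chi_set(ang, meta$exists, meta$symmetric)
  dt <- 0.1
  prev <- sum(abs(torus_log(chi$angles, chi1$angles, per))[chi1$exists])
  for (s in 1:10) {
    t <- (s - 1) * dt
    fld <- scheduled_field(f(chi, t), chi, t, 5)
    chi$angles <- torus_exp(chi$angles, dt * fld, per)
    cur <- sum(abs(torus_log(chi$angles, chi1$angles, per))[chi1$exists])
    expect_lte(cur, prev + 1e-9)
    prev <- cur
  }
})

test_that("sampling with a network is seed-deterministic and rigid-invariant", {
  fx <- make_full_structure(20, seed = 85)
  net <- chi_net_init(chi_net_config(hidden = 16, blocks = 1), seed = 3)
  cfg <- sampler_config(num_steps = 4, seed = 5)
  a <- euler_sample(fx$structure, net, cfg)
  b <- euler_sample(fx$structure, net, cfg)
  expect_identical(a$chi$angles, b$chi$angles)
  tr <- random_rigid_transform(31)
  c_ <- euler_sample(apply_rigid_structure(fx$structure, tr), net, cfg)
  expect_lt(max(abs(torus_log(a$chi$angles, c_$chi$angles,
                              chi_periods(a$chi)))[a$chi$exists]), 1e-6)
})

test_that("multimer sampling needs no special casing beyond the relpos rule", {
  mm <- make_full_structure(22, chains = 2, seed = 87)
  net <- chi_net_init(chi_net_config(hidden = 16, blocks = 1), seed = 8)
  cfg <- sampler_config(num_steps = 3, seed = 6)
  a <- euler_sample(mm$structure, net, cfg)
  b <- euler_sample(mm$structure, net, cfg)
  expect_identical(a$chi$angles, b$chi$angles)
  expect_true(all(is.finite(a$chi$angles)))
  expect_true(all(a$structure$atom_mask[, 1:4]))
})

test_that("inpainting pins known residues bit-exactly", {
  fx <- make_full_structure(30, seed = 83)
  chi1 <- fx$chi
  net <- chi_net_init(chi_net_config(hidden = 16, blocks = 1), seed = 4)
  cfg <- sampler_config(num_steps = 5, seed = 17)
  for (frac in c(0.25, 0.5, 1)) {
    set.seed(frac * 100)
    mask <- rep(FALSE, 30)
    mask[sample(30, round(frac * 30))] <- TRUE
    out <- inpaint(fx$structure, chi1, mask, net, cfg)
    if (any(!mask)) {
      expect_identical(out$chi$angles[!mask, ], chi1$angles[!mask, ])
    }
  }
  # mask covering everything behaves exactly like unconditional sampling
  all_mask <- rep(TRUE, 30)
  o1 <- inpaint(fx$structure, chi1, all_mask, net, cfg)
  o2 <- euler_sample(fx$structure, net, cfg)
  expect_identical(o1$chi$angles, o2$chi$angles)
  # empty mask returns the known angles untouched
  o3 <- inpaint(fx$structure, chi1, !all_mask, net, cfg)
  expect_identical(o3$chi$angles, chi1$angles)
})

test_that("confidence selection returns the argmin of the mean score", {
  fx <- make_full_structure(20, seed = 95)
  net <- chi_net_init(chi_net_config(hidden = 16, blocks = 1), seed = 6)
  samples <- sample_sidechains(fx$structure, net,
                               sampler_config(num_steps = 3,
                                              num_samples = 4, seed = 2))
  expect_length(samples, 4)
  # mocked constant scores
  fake <- c(3, 1, 2, 5)
  sel <- select_by_confidence(samples, fx$structure,
                              score_fn = function(s) {
                                fake[[vapply(samples, identical, logical(1),
                                             s) |> which()]]
                              })
  expect_equal(sel$index, 2)
  # true-RMSD oracle picks the sample with minimal true mean RMSD
  ref <- build_structure_atoms(fx$structure, fx$chi)
  sel2 <- select_by_confidence(samples, fx$structure,
                               score_fn = function(s)
                                 structure_rmsd(s$structure, ref))
  true_means <- vapply(samples, function(s)
    mean(structure_rmsd(s$structure, ref), na.rm = TRUE), numeric(1))
  expect_equal(sel2$index, which.min(true_means))
  # single sample comes back unchanged
  sel3 <- select_by_confidence(samples[1], fx$structure,
                               score_fn = function(s) 1)
  expect_identical(sel3$sample, samples[[1]])
  expect_error(select_by_confidence(list(), fx$structure, score_fn = sum),
               "no samples")
})
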