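test_that("training pairs follow the geodesic noising scheme", {
  fx <- make_full_structure(20, seed = 11)
  chi1 <- fx$chi
  per <- chi_periods(chi1)
  set.seed(1)
  p0 <- make_training_pair(chi1, t = 0)
  expect_equal(p0$chi_t$angles[chi1$exists],
               torus_wrap(p0$chi0, per)[chi1$exists], tolerance = 1e-12)
  p1 <- make_training_pair(chi1, t = 1 - 1e-9)
  expect_lt(max(abs(torus_log(p1$chi_t$angles, chi1$angles,
                              per))[chi1$exists]), 1e-6)
  # the target is the constant log map, independent of t
  set.seed(4)
  pa <- make_training_pair(chi1, t = 0.2)
  expect_equal(pa$target[chi1$exists],
               (torus_log(pa$chi0, chi1$angles, per) * chi1$exists)[chi1$exists])
  # symmetric angles stay in the reduced chart with bounded targets
  symm <- chi1$symmetric & chi1$exists
  if (any(symm)) {
    expect_true(all(pa$chi_t$angles[symm] >= 0 & pa$chi_t$angles[symm] < pi))
    expect_true(all(abs(pa$target[symm]) <= pi / 2 + 1e-12))
  }
  expect_true(all(pa$target[!chi1$exists] == 0))
})

test_that("the CFM loss implements the 1/(1-t)^2 weighting", {
  pred <- matrix(0.1, 1, 4)
  target <- matrix(0, 1, 4)
  mask <- matrix(c(TRUE, FALSE, FALSE, FALSE), 1, 4)
  expect_equal(cfm_loss(target, target, 0.3, mask)$loss, 0)
  expect_equal(cfm_loss(pred, target, 0, mask)$loss, 0.01)
  expect_equal(cfm_loss(pred, target, 0.5, mask)$loss, 0.04)
  expect_warning(out <- cfm_loss(pred, target, 0, mask & FALSE),
                 "masked")
  expect_equal(out$loss, 0)
  # gradient consistency
  ls <- cfm_loss(pred, target, 0.5, mask)
  expect_equal(ls$dpred[1, 1], 2 * 4 * 0.1 / 1)
  expect_true(all(ls$dpred[!mask] == 0))
})

test_that("EMA updates follow the exact convex combination", {
  shadow <- list(a = matrix(1, 2, 2), b = rep(0, 3))
  current <- list(a = matrix(3, 2, 2), b = rep(1, 3))
  out <- ema_update(shadow, current, 0.9)
  expect_equal(out$a, matrix(0.9 * 1 + 0.1 * 3, 2, 2))
  expect_equal(out$b, rep(0.1, 3))
})

test_that("cropping is contiguous and a no-op below the crop length", {
  fx <- make_full_structure(40, seed = 3)
  out <- chiflow:::.crop_structure(fx$structure, fx$chi, 512)
  expect_identical(out$structure$atom14, fx$structure$atom14)
  set.seed(2)
  cr <- chiflow:::.crop_structure(fx$structure, fx$chi, 16)
  expect_lte(n_residues(cr$structure), 16)
  idx <- match(apply(cr$structure$atom14[, 2, ], 1, paste, collapse = ","),
               apply(fx$structure$atom14[, 2, ], 1, paste, collapse = ","))
  expect_false(any(is.na(idx)))
  expect_equal(idx, seq(idx[1], length.out = length(idx)))
})

test_that("short training runs are deterministic under a fixed seed", {
  fixtures <- list(make_full_structure(20, seed = 51))
  net <- chi_net_init(chi_net_config(hidden = 8, blocks = 1, t_dim = 4),
                      seed = 2)
  cfg <- train_config(iterations = 5, batch_size = 1, seed = 77)
  a <- train_pack_model(fixtures, net, cfg, knn_k = 5)
  b <- train_pack_model(fixtures, net, cfg, knn_k = 5)
  expect_identical(a$net$W, b$net$W)
  expect_identical(a$log, b$log)
})

test_that("the loss decreases markedly while overfitting a small fixture", {
  fixtures <- list(make_full_structure(16, seed = 61))
  net <- chi_net_init(chi_net_config(hidden = 32, blocks = 2), seed = 5)
  cfg <- train_config(learning_rate = 1e-2, iterations = 800,
                      batch_size = 1, t_epsilon = 0.09, seed = 13)
  out <- train_pack_model(fixtures, net, cfg, knn_k = 8)
  expect_true(all(is.finite(out$log$loss)))
  # the running loss is heavy-tailed in t, so measure progress on a fixed
  # evaluation set of noised pairs instead of the raw trace
  eval_loss <- function(model) {
    total <- 0
    for (fx in fixtures) {
      ctx <- chiflow:::.flow_context(model, fx$structure, 8)
      for (r in 1:10) {
        pair <- chiflow:::with_local_seed(300 + r,
                                          make_training_pair(fx$chi, t = 0.5))
        inp <- chiflow:::.fill_inputs(model, ctx, pair$chi_t, pair$t)
        V <- chiflow:::.net_forward(model, inp$Xn, inp$Xe, ctx$ei,
                                    ctx$ej)$V
        total <- total + cfm_loss(V, pair$target, pair$t,
                                  fx$chi$exists)$loss
      }
    }
    total
  }
  expect_lt(eval_loss(out$net), 0.5 * eval_loss(net))
})

test_that("confidence training drives its regression loss down", {
  fixtures <- list(make_full_structure(24, seed = 71))
  main <- chi_net_init(chi_net_config(hidden = 16, blocks = 1), seed = 6)
  conf <- chi_net_init(chi_net_config(hidden = 16, blocks = 1),
                       out_dim = 1, seed = 7)
  cfg <- train_config(learning_rate = 3e-3, iterations = 200, seed = 21)
  out <- train_confidence(fixtures, main, conf, cfg,
                          sampler = sampler_config(num_samples = 1, seed = 1),
                          resample_every = 40, knn_k = 15)
  expect_true(all(out$log$loss >= 0))
  expect_lt(median(out$log$loss[181:200]), median(out$log$loss[1:20]))
  # on a fresh sample, predicted and true per-residue RMSD correlate
  fx <- fixtures[[1]]
  samp <- euler_sample(fx$structure, main,
                       sampler_config(num_steps = 10, seed = 99))
  ref <- build_structure_atoms(fx$structure, fx$chi)
  truth <- structure_rmsd(samp$structure, ref)
  pred <- predict_confidence(out$net, fx$structure, samp$chi,
                             atoms = samp$structure)
  ok <- !is.na(truth)
  expect_gt(suppressWarnings(cor(pred[ok], truth[ok], method = "spearman")),
            0)
})
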