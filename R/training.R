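#' Conditional flow matching training
#'
#' Each iteration draws, per structure, a flow time `t ~ U(0, 1 - t_epsilon)`
#' and a prior sample chi0 uniform on each angle's circle (period-aware, so
#' pi-symmetric angles are noised on their reduced chart), forms the noised
#' state `chi_t = exp_chi0(t * log_chi0(chi1))` along the geodesic to the
#' ground truth chi1, rebuilds the noised atom coordinates, and regresses the
#' network output on the conditional vector field `log_chi0(chi1)` under the
#' weight `1 / (1 - t)^2`. The weight diverges at `t = 1`, so the time draw
#' is clipped at `1 - t_epsilon` to keep the loss finite. Optimisation is
#' AdamW-style Adam with global gradient-norm clipping and an exponential
#' moving average (EMA) of the weights updated every iteration; the EMA
#' shadow is what sampling uses. Structures longer than `crop_length` are
#' cropped to a random sequence-contiguous window per chain, preserving local
#' graph context.
#'
#' @name training
#' @keywords internal
NULL

#' Training configuration
#'
#' @param learning_rate Adam step size (default 1e-4, the model's operating
#'   value; the overfit tests use a larger rate).
#' @param grad_clip_norm global gradient-norm clip (default 1.0).
#' @param ema_decay EMA decay per iteration (default 0.999).
#' @param crop_length maximum residues per training example (default 512).
#' @param batch_size structures per iteration (default 16).
#' @param t_epsilon upper clip on the flow time draw (default 1e-3).
#' @param iterations number of optimiser steps.
#' @param seed integer seed controlling all randomness of the run.
#' @return list of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 1e-4, grad_clip_norm = 1.0,
                         ema_decay = 0.999, crop_length = 512,
                         batch_size = 16, t_epsilon = 1e-3,
                         iterations = 1000, seed = 1) {
  stopifnot(crop_length > 0, ema_decay > 0, ema_decay < 1,
            t_epsilon > 0, t_epsilon < 0.1)
  structure(list(learning_rate = learning_rate,
                 grad_clip_norm = grad_clip_norm, ema_decay = ema_decay,
                 crop_length = crop_length, batch_size = batch_size,
                 t_epsilon = t_epsilon, iterations = iterations, seed = seed),
            class = "train_config")
}

#' Draw one noised training pair for a structure
#'
#' @param chi1 ground-truth [chi_set()] (reduced chart).
#' @param t_epsilon upper clip on the time draw.
#' @param t optional fixed flow time (drawn uniformly when `NULL`).
#' @return list with `chi_t` (a [chi_set()]), `t`, `chi0`, and `target`
#'   (R x 4 tangent matrix, the conditional vector field; 0 where masked).
#' @export
make_training_pair <- function(chi1, t_epsilon = 1e-3, t = NULL) {
  per <- chi_periods(chi1)
  R <- nrow(chi1$angles)
  if (is.null(t)) t <- stats::runif(1, 0, 1 - t_epsilon)
  chi0 <- matrix(sample_torus_uniform(R * 4, 2 * pi), R, 4)
  chi0[chi1$symmetric] <- chi0[chi1$symmetric] %% pi
  chi0[!chi1$exists] <- 0
  target <- torus_log(chi0, chi1$angles, per) * chi1$exists
  xt <- geodesic_point(chi0, chi1$angles, t, per)
  xt[!chi1$exists] <- 0
  list(chi_t = chi_set(xt, chi1$exists, chi1$symmetric), t = t,
       chi0 = chi0, target = target)
}

#' Conditional flow matching loss
#'
#' Mean over unmasked chi entries of `(pred - target)^2 / (1 - t)^2`.
#'
#' @param pred R x 4 predicted tangent matrix.
#' @param target R x 4 conditional vector field.
#' @param t flow time (scalar or per-residue vector).
#' @param exists R x 4 logical mask.
#' @return list with `loss` (nonnegative scalar) and `dpred` (gradient wrt
#'   `pred`).
#' @export
cfm_loss <- function(pred, target, t, exists) {
  stopifnot(identical(dim(pred), dim(target)))
  n <- sum(exists)
  if (n == 0) {
    warning("all chi entries masked; loss defined as 0")
    return(list(loss = 0, dpred = pred * 0))
  }
  w <- 1 / (1 - t)^2
  diff <- (pred - target) * exists
  loss <- sum(w * diff^2) / n
  list(loss = loss, dpred = 2 * w * diff / n)
}

# Adam update; returns list(W, m, v). AdamW-style decoupled weight decay = 0
# by default (none of the tests need it).
.adam_step <- function(W, g, m, v, lr, step, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  for (nm in names(g)) {
    m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
    v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- m[[nm]] / (1 - beta1^step)
    vhat <- v[[nm]] / (1 - beta2^step)
    W[[nm]] <- W[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(W = W, m = m, v = v)
}

.grad_norm <- function(g) sqrt(sum(vapply(g, function(x) sum(x^2), numeric(1))))

.clip_grads <- function(g, max_norm) {
  nrm <- .grad_norm(g)
  if (is.finite(nrm) && nrm > max_norm) {
    g <- lapply(g, function(x) x * (max_norm / nrm))
  }
  g
}

#' Update an EMA shadow of the weights
#'
#' `shadow <- decay * shadow + (1 - decay) * current`, element-wise.
#' @param shadow,current weight lists of identical shape.
#' @param decay EMA decay in (0, 1).
#' @return updated shadow list.
#' @export
ema_update <- function(shadow, current, decay) {
  for (nm in names(current)) {
    shadow[[nm]] <- decay * shadow[[nm]] + (1 - decay) * current[[nm]]
  }
  shadow
}

# random sequence-contiguous crop (per chain) to at most crop_length residues
.crop_structure <- function(structure, chi, crop_length) {
  R <- n_residues(structure)
  if (R <= crop_length) return(list(structure = structure, chi = chi))
  # crop within a single randomly chosen chain window
  start <- sample.int(R - crop_length + 1, 1)
  idx <- start:(start + crop_length - 1)
  idx <- idx[structure$chain[idx] == structure$chain[idx[1]]]
  list(structure = subset_structure(structure, idx),
       chi = chi_set(chi$angles[idx, , drop = FALSE],
                     chi$exists[idx, , drop = FALSE],
                     chi$symmetric[idx, , drop = FALSE]))
}

# precompute the static per-structure pieces used every iteration
.prep_example <- function(net, structure, chi, k) {
  ctx <- .flow_context(net, structure, k)
  ctx$chi <- chi
  ctx
}

#' Train the vector-field network
#'
#' @param dataset list of `list(structure=, chi=)` pairs (e.g. from
#'   [make_full_structure()] or [read_structure()] + [measure_chi_all()]).
#' @param net a [chi_net_init()] network (`out_dim = 4`).
#' @param config a [train_config()].
#' @param knn_k graph neighbour count (default 30).
#' @param verbose print progress every 100 iterations.
#' @return list with `net` (final weights), `ema` (EMA shadow network, used
#'   for sampling), and `log` (data.frame iteration/loss).
#' @export
train_pack_model <- function(dataset, net, config = train_config(),
                             knn_k = 30, verbose = FALSE) {
  stopifnot(length(dataset) > 0)
  with_local_seed(config$seed, {
    cropped <- lapply(dataset, function(d) {
      .crop_structure(d$structure, d$chi, config$crop_length)
    })
    prep <- lapply(cropped, function(d) .prep_example(net, d$structure,
                                                      d$chi, knn_k))
    W <- net$W
    m <- lapply(W, function(x) x * 0)
    v <- lapply(W, function(x) x * 0)
    # EMA accumulated from zero and debiased by 1/(1 - decay^step), so short
    # runs are not dominated by the random initialisation
    ema <- lapply(W, function(x) x * 0)
    log_it <- integer(config$iterations)
    log_loss <- numeric(config$iterations)
    for (it in seq_len(config$iterations)) {
      take <- if (length(prep) <= config$batch_size) seq_along(prep)
      else sample(length(prep), config$batch_size)
      total_loss <- 0
      gsum <- NULL
      for (b in take) {
        ex <- prep[[b]]
        pair <- make_training_pair(ex$chi, config$t_epsilon)
        net$W <- W
        inp <- .fill_inputs(net, ex, pair$chi_t, pair$t)
        fw <- .net_forward(net, inp$Xn, inp$Xe, ex$ei, ex$ej, cache = TRUE)
        ls <- cfm_loss(fw$V, pair$target, pair$t, ex$chi$exists)
        if (!is.finite(ls$loss)) {
          stop(sprintf("non-finite loss at iteration %d (t = %.4f)", it,
                       pair$t))
        }
        g <- .net_backward(net, fw$cache, ls$dpred)
        total_loss <- total_loss + ls$loss
        gsum <- if (is.null(gsum)) g else mapply(`+`, gsum, g,
                                                 SIMPLIFY = FALSE)
      }
      nb <- length(take)
      gsum <- lapply(gsum, function(x) x / nb)
      gsum <- .clip_grads(gsum, config$grad_clip_norm)
      upd <- .adam_step(W, gsum, m, v, config$learning_rate, it)
      W <- upd$W; m <- upd$m; v <- upd$v
      ema <- ema_update(ema, W, config$ema_decay)
      log_it[it] <- it
      log_loss[it] <- total_loss / nb
      if (verbose && it %% 100 == 0) {
        message(sprintf("iter %d  loss %.4f", it,
                        mean(log_loss[max(1, it - 99):it])))
      }
    }
    net$W <- W
    ema_net <- net
    debias <- 1 - config$ema_decay^config$iterations
    ema_net$W <- lapply(ema, function(x) x / debias)
    list(net = net, ema = ema_net,
         log = data.frame(iteration = log_it, loss = log_loss))
  })
}

#' Train the confidence model
#'
#' For each iteration a structure is drawn, side chains are sampled with the
#' (EMA) main model, the true per-residue side-chain RMSD against the ground
#' truth is computed, and the confidence head is regressed on it with squared
#' error. Samples are refreshed every `resample_every` iterations per
#' structure to amortise the sampling cost.
#'
#' @param dataset list of `list(structure=, chi=)` pairs.
#' @param main_net trained vector-field network (typically the EMA shadow).
#' @param conf_net a [chi_net_init()] network with `out_dim = 1`.
#' @param config a [train_config()].
#' @param sampler a [sampler_config()] for the generation step.
#' @param resample_every refresh cached samples every this many iterations
#'   (default 25).
#' @param knn_k graph neighbour count.
#' @return list with `net` (trained confidence network) and `log`
#'   (data.frame iteration/loss).
#' @export
train_confidence <- function(dataset, main_net, conf_net,
                             config = train_config(),
                             sampler = sampler_config(num_samples = 1),
                             resample_every = 25, knn_k = 30) {
  stopifnot(length(dataset) > 0)
  with_local_seed(config$seed, {
    prep <- lapply(dataset, function(d) .prep_example(conf_net, d$structure,
                                                      d$chi, knn_k))
    cachep <- vector("list", length(prep))
    W <- conf_net$W
    m <- lapply(W, function(x) x * 0)
    v <- lapply(W, function(x) x * 0)
    log_loss <- numeric(config$iterations)
    for (it in seq_len(config$iterations)) {
      b <- ((it - 1) %% length(prep)) + 1
      ex <- prep[[b]]
      if (is.null(cachep[[b]]) || it %% resample_every == 1) {
        sc <- sampler
        sc$seed <- sample.int(2^30, 1)
        samp <- euler_sample(ex$structure, main_net, sc, graph = ex$graph,
                             base = ex$kin)
        ref <- build_structure_atoms(ex$structure, ex$chi, base = ex$kin)
        true_rmsd <- structure_rmsd(samp$structure, ref)
        cachep[[b]] <- list(chi = samp$chi, atoms = samp$structure,
                            rmsd = true_rmsd)
      }
      cp <- cachep[[b]]
      ok <- which(!is.na(cp$rmsd))
      conf_net$W <- W
      inp <- .fill_inputs(conf_net, ex, cp$chi, 1,
                          atoms14 = cp$atoms$atom14)
      fw <- .net_forward(conf_net, inp$Xn, inp$Xe, ex$ei, ex$ej,
                         cache = TRUE)
      vraw <- as.vector(fw$V)
      pred <- ifelse(vraw > 30, vraw, log1p(exp(pmin(vraw, 30))))
      diff <- numeric(length(pred))
      diff[ok] <- pred[ok] - cp$rmsd[ok]
      loss <- sum(diff^2) / max(1, length(ok))
      if (!is.finite(loss)) stop("non-finite confidence loss at iter ", it)
      dpred <- 2 * diff / max(1, length(ok))
      dv <- dpred * stats::plogis(vraw)  # softplus derivative
      g <- .net_backward(conf_net, fw$cache, matrix(dv, ncol = 1))
      g <- .clip_grads(g, config$grad_clip_norm)
      upd <- .adam_step(W, g, m, v, config$learning_rate, it)
      W <- upd$W; m <- upd$m; v <- upd$v
      log_loss[it] <- loss
    }
    conf_net$W <- W
    list(net = conf_net,
         log = data.frame(iteration = seq_len(config$iterations),
                          loss = log_loss))
  })
}
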