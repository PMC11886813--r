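#' Sampling side chains by integrating the learned field
#'
#' Sampling starts from the uniform torus prior and integrates the learned
#' vector field with a 10-step Euler solver. The network is trained to
#' predict the constant conditional field of the linear schedule, so at state
#' `(chi_t, t)` its prediction `v` implies the endpoint estimate
#' `chi1_hat = exp_chi_t((1 - t) * v)`; the integration then follows the
#' exponential schedule `c * log_chi_t(chi1_hat)` (c = 5 by default), which
#' contracts the remaining distance geometrically -- with the exact
#' conditional field each Euler step shrinks the wrapped distance to the
#' target by the factor `|1 - c * dt|`. Edge features are recomputed from
#' atoms rebuilt at the current chi after every step; node backbone features
#' are static. Inpainting pins known residues to their reference angles at
#' every step so they only contribute context.
#'
#' @name sampling
#' @keywords internal
NULL

#' Sampler configuration
#'
#' @param num_steps Euler steps (default 10).
#' @param schedule_c exponential schedule gain (default 5).
#' @param num_samples samples to draw per call of [sample_sidechains()]
#'   (default 4).
#' @param seed integer seed.
#' @param fixed_mask optional length-R logical: `TRUE` residues are pinned to
#'   the supplied reference chi (inpainting).
#' @return list of class `"sampler_config"`.
#' @export
sampler_config <- function(num_steps = 10, schedule_c = 5, num_samples = 4,
                           seed = 1, fixed_mask = NULL) {
  stopifnot(num_steps >= 1, schedule_c > 0, num_samples >= 1)
  structure(list(num_steps = num_steps, schedule_c = schedule_c,
                 num_samples = num_samples, seed = seed,
                 fixed_mask = fixed_mask),
            class = "sampler_config")
}

#' Convert a predicted field to the exponential-schedule field
#'
#' @param predicted R x 4 network output (tangent, linear-schedule
#'   parameterisation).
#' @param chi_t current [chi_set()].
#' @param t current flow time in `[0, 1)`.
#' @param schedule_c schedule gain.
#' @return R x 4 tangent matrix `c * log_chi_t(chi1_hat)`; its magnitude is
#'   bounded by `c * period / 2`.
#' @export
scheduled_field <- function(predicted, chi_t, t, schedule_c = 5) {
  stopifnot(t >= 0, t < 1)
  per <- chi_periods(chi_t)
  chi1_hat <- torus_exp(chi_t$angles, (1 - t) * predicted, per)
  schedule_c * torus_log(chi_t$angles, chi1_hat, per) * chi_t$exists
}

#' Draw one side-chain sample with the Euler solver
#'
#' @param structure a [chi_structure()] (backbone used; side chains ignored).
#' @param net trained vector-field network (or a field oracle, see
#'   `field_fn`).
#' @param config a [sampler_config()] (`num_samples` ignored here).
#' @param known_chi reference [chi_set()] required when `config$fixed_mask`
#'   pins residues.
#' @param field_fn optional `function(chi_t, t)` returning an R x 4 tangent
#'   matrix, replacing the network (used for oracle-field tests).
#' @param graph,base optional precomputed [pack_graph()] / aligned-template
#'   cache.
#' @return list with `chi` (a [chi_set()]) and `structure` (atoms rebuilt
#'   from the final chi).
#' @export
euler_sample <- function(structure, net, config = sampler_config(),
                         known_chi = NULL, field_fn = NULL,
                         graph = NULL, base = NULL) {
  meta <- chi_metadata(structure$aa)
  R <- n_residues(structure)
  per <- ifelse(meta$symmetric, pi, 2 * pi)
  pinned <- config$fixed_mask
  if (!is.null(pinned)) {
    stopifnot(length(pinned) == R)
    if (is.null(known_chi)) stop("fixed_mask requires known_chi")
  }
  ctx <- NULL
  if (is.null(field_fn)) {
    ctx <- .flow_context(net, structure, graph = graph)
    base <- ctx$kin
  } else if (is.null(base)) {
    base <- .kin_context(structure)
  }
  with_local_seed(config$seed, {
    ang <- matrix(sample_torus_uniform(R * 4, 2 * pi), R, 4)
    ang[meta$symmetric] <- ang[meta$symmetric] %% pi
    ang[!meta$exists] <- 0
    if (!is.null(pinned) && any(pinned)) {
      ang[pinned, ] <- known_chi$angles[pinned, ]
    }
    chi <- chi_set(ang, meta$exists, meta$symmetric)
    if (!is.null(pinned) && any(pinned)) {
      chi$angles[pinned, ] <- known_chi$angles[pinned, ]
    }
    dt <- 1 / config$num_steps
    for (step in seq_len(config$num_steps)) {
      t <- (step - 1) * dt
      v <- if (is.null(field_fn)) {
        inp <- .fill_inputs(net, ctx, chi, t)
        fw <- .net_forward(net, inp$Xn, inp$Xe, ctx$ei, ctx$ej)
        fw$V * meta$exists
      } else {
        field_fn(chi, t)
      }
      if (any(!is.finite(v[meta$exists]))) {
        stop("non-finite field during sampling at t = ", t)
      }
      field <- scheduled_field(v, chi, t, config$schedule_c)
      newang <- torus_exp(chi$angles, dt * field, per)
      newang[!meta$exists] <- 0
      chi$angles <- newang
      if (!is.null(pinned) && any(pinned)) {
        chi$angles[pinned, ] <- known_chi$angles[pinned, ]
      }
    }
    list(chi = chi, structure = build_structure_atoms(structure, chi, base))
  })
}

#' Inpaint side chains for a subset of residues
#'
#' Residues where `mask` is `FALSE` keep their known chi angles bit-exactly
#' (they are pinned at every integration step and contribute context through
#' the rebuilt atoms); residues where `mask` is `TRUE` are generated.
#'
#' @param structure a [chi_structure()].
#' @param known_chi reference [chi_set()] providing the pinned angles.
#' @param mask length-R logical: `TRUE` = generate, `FALSE` = keep.
#' @param net trained vector-field network.
#' @param config a [sampler_config()] (its `fixed_mask` is overridden).
#' @param ... passed to [euler_sample()].
#' @return as [euler_sample()].
#' @export
inpaint <- function(structure, known_chi, mask, net,
                    config = sampler_config(), ...) {
  stopifnot(length(mask) == n_residues(structure))
  config$fixed_mask <- !mask
  euler_sample(structure, net, config, known_chi = known_chi, ...)
}

#' Draw several samples and keep them all
#'
#' @param structure a [chi_structure()].
#' @param net trained vector-field network.
#' @param config a [sampler_config()]; `num_samples` draws with seeds
#'   `seed + 0:(num_samples-1)`.
#' @param ... passed to [euler_sample()].
#' @return list of [euler_sample()] results.
#' @export
sample_sidechains <- function(structure, net, config = sampler_config(),
                              ...) {
  lapply(seq_len(config$num_samples), function(s) {
    cfg <- config
    cfg$seed <- config$seed + s - 1
    euler_sample(structure, net, cfg, ...)
  })
}

#' Select the best of several samples by predicted RMSD
#'
#' Scores each sample by the mean per-residue predicted side-chain RMSD and
#' returns the argmin; ties break toward the earlier sample.
#'
#' @param samples list of [euler_sample()] results.
#' @param structure the packed [chi_structure()].
#' @param conf_net confidence network, or `NULL` when `score_fn` is given.
#' @param score_fn optional `function(sample)` returning a per-residue score
#'   vector (lower is better), replacing the confidence model (e.g. a
#'   true-RMSD oracle).
#' @param graph optional precomputed [pack_graph()].
#' @return list with `sample` (the selected element), `index`, and `scores`
#'   (mean score per sample).
#' @export
select_by_confidence <- function(samples, structure, conf_net = NULL,
                                 score_fn = NULL, graph = NULL) {
  if (!length(samples)) stop("no samples to select from")
  if (is.null(score_fn) && is.null(conf_net)) {
    stop("either conf_net or score_fn is required")
  }
  if (is.null(graph) && is.null(score_fn)) graph <- pack_graph(structure)
  scores <- vapply(samples, function(s) {
    per_res <- if (is.null(score_fn)) {
      predict_confidence(conf_net, structure, s$chi, graph = graph,
                         atoms = s$structure)
    } else {
      score_fn(s)
    }
    mean(per_res, na.rm = TRUE)
  }, numeric(1))
  idx <- which.min(scores)
  list(sample = samples[[idx]], index = idx, scores = scores)
}
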