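#' Riemannian geometry on the circle and flat torus
#'
#' Side-chain chi angles live on a product of circles: each angle has period
#' \eqn{2\pi}, except pi-symmetric angles (chemically indistinguishable under a
#' 180 degree flip) whose effective period is \eqn{\pi}. All geometry used by
#' the conditional flow -- wrapping into a canonical chart, exponential and
#' logarithmic maps, geodesic interpolation and the conditional vector field --
#' is closed-form on this manifold. Every function here is vectorised and
#' recycles `period` against its angle arguments.
#'
#' The canonical chart is `[-period/2, period/2)` for the full circle
#' (`period = 2*pi`) and `[0, period)` for symmetry-reduced angles
#' (`period = pi` or any other period), one fixed chart per period.
#'
#' @name torus
#' @keywords internal
NULL

.chart_centered <- function(period) abs(period - 2 * pi) < 1e-9

#' Wrap angles into their canonical chart
#'
#' @param value numeric vector of angles (radians).
#' @param period numeric vector of periods (radians), recycled; must be > 0.
#' @return numeric vector congruent to `value` mod `period`, inside the
#'   canonical chart (`[-pi, pi)` for period `2*pi`, `[0, period)` otherwise).
#' @export
#' @examples
#' torus_wrap(3 * pi, 2 * pi)      # -pi (== +pi on the circle)
#' torus_wrap(2.5 * pi, pi)        # 0.5 * pi
torus_wrap <- function(value, period = 2 * pi) {
  if (any(period <= 0)) stop("'period' must be positive")
  dv <- dim(value)
  n <- max(length(value), length(period))
  value <- rep_len(value, n)
  period <- rep_len(period, n)
  centered <- .chart_centered(period)
  out <- value %% period
  out[centered] <- ((value[centered] + period[centered] / 2) %%
    period[centered]) - period[centered] / 2
  if (!is.null(dv) && prod(dv) == n) dim(out) <- dv
  out
}

#' Exponential map on the circle
#'
#' Moves from base point `x0` along tangent vector `v` and wraps back into the
#' canonical chart: `exp_x0(v) = wrap(x0 + v)`.
#'
#' @param x0 numeric vector of base angles (radians).
#' @param v numeric vector of tangent values (radians, unbounded).
#' @inheritParams torus_wrap
#' @return wrapped angles, same length as the recycled inputs.
#' @export
torus_exp <- function(x0, v, period = 2 * pi) {
  torus_wrap(x0 + v, period)
}

#' Logarithmic map on the circle
#'
#' Signed shortest arc from `x0` to `x1`, computed as
#' `atan2(sin(d), cos(d))` on the angle rescaled to its period, so that
#' `|result| <= period / 2` with the antipodal tie resolved to `+period/2`
#' (the `atan2(0, -1) = pi` convention).
#'
#' @param x0,x1 numeric vectors of angles (radians).
#' @inheritParams torus_wrap
#' @return numeric tangent vector with `torus_exp(x0, result)` equal to
#'   `torus_wrap(x1)`.
#' @export
torus_log <- function(x0, x1, period = 2 * pi) {
  if (any(period <= 0)) stop("'period' must be positive")
  s <- 2 * pi / period
  d <- (x1 - x0) * s
  out <- atan2(sin(d), cos(d)) / s
  dv <- if (!is.null(dim(x0))) dim(x0) else dim(x1)
  if (!is.null(dv) && prod(dv) == length(out)) dim(out) <- dv
  out
}

#' Point along the geodesic from x0 to x1
#'
#' The conditional flow interpolant: `exp_x0(t * log_x0(x1))`. At `t = 0` this
#' is `x0`, at `t = 1` it is `x1` (up to wrapping).
#'
#' @inheritParams torus_log
#' @param t interpolation time(s) in `[0, 1]`, recycled.
#' @export
geodesic_point <- function(x0, x1, t, period = 2 * pi) {
  if (any(t < 0 | t > 1)) stop("'t' must lie in [0, 1]")
  torus_exp(x0, t * torus_log(x0, x1, period), period)
}

#' Conditional vector field of the linear-schedule geodesic flow
#'
#' For the linear schedule the time derivative of [geodesic_point()] is the
#' constant `log_x0(x1)` (the `"exact"` variant). The `"endpoint"` variant is
#' the equivalent reformulation `log_xt(x1) / (1 - t)` evaluated at
#' `xt = geodesic_point(x0, x1, t)`; the two agree along exact geodesics. The
#' endpoint variant guards `t >= 1 - 1e-5` by returning the exact field, since
#' the division degenerates at the data endpoint.
#'
#' @inheritParams geodesic_point
#' @param variant `"exact"` (constant field) or `"endpoint"`
#'   (`log_xt(x1)/(1-t)`).
#' @export
conditional_vector_field <- function(x0, x1, t, period = 2 * pi,
                                     variant = c("exact", "endpoint")) {
  variant <- match.arg(variant)
  if (any(t < 0 | t >= 1)) stop("'t' must lie in [0, 1)")
  exact <- torus_log(x0, x1, period)
  if (variant == "exact") {
    return(exact)
  }
  n <- max(length(x0), length(x1), length(t), length(period))
  x0 <- rep_len(x0, n); x1 <- rep_len(x1, n)
  t <- rep_len(t, n); period <- rep_len(period, n)
  exact <- rep_len(exact, n)
  out <- exact
  ok <- t < 1 - 1e-5
  xt <- geodesic_point(x0[ok], x1[ok], t[ok], period[ok])
  out[ok] <- torus_log(xt, x1[ok], period[ok]) / (1 - t[ok])
  out
}

#' Draw angles uniformly on the circle
#'
#' The base (prior) distribution of the flow: uniform on the canonical chart of
#' the given period. Uses the current RNG state unless `seed` is given, in
#' which case the global RNG is left untouched.
#'
#' @param n number of draws (>= 0).
#' @param period period of the target circle (radians).
#' @param seed optional integer seed for reproducible draws.
#' @return numeric vector of length `n` in the canonical chart.
#' @export
sample_torus_uniform <- function(n, period = 2 * pi, seed = NULL) {
  stopifnot(n >= 0)
  draw <- function() {
    u <- stats::runif(n, 0, 1)
    if (length(period) == 1 && .chart_centered(period)) {
      u * period - period / 2
    } else {
      torus_wrap(u * rep_len(period, n), rep_len(period, n))
    }
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded helpers do not perturb
#' the global random stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
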