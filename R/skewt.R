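#' Jones-Faddy skew-t parameter set
#'
#' Bundles the four parameters of the Jones-Faddy skew-t distribution used
#' throughout the package: a location and scale (in the units of the modelled
#' variable, here log ng/mL of AMH) and two positive shape parameters `a` and
#' `b`. The standard variate `T` satisfies
#' `U = (1 + T / sqrt(a + b + T^2)) / 2 ~ Beta(a, b)`, so the density,
#' distribution function and quantile function are all incomplete-beta
#' transforms. `a = b` recovers a Student-t with `2a` degrees of freedom;
#' `a < b` gives left (negative) skew, `a > b` right skew. The mean exists for
#' `a, b > 1/2` and the variance for `a, b > 1`.
#'
#' Shapes within `5e-4` of the boundary `1/2` are rejected rather than
#' silently computed: so close to the boundary the mean is numerically
#' unstable and the mean-zero constraint used by the regression machinery
#' becomes meaningless.
#'
#' @param location Real location parameter.
#' @param scale Positive scale parameter.
#' @param a,b Positive shape parameters.
#' @return An object of class `skt_params`.
#' @examples
#' p <- skt_params(0, 1, a = 2, b = 6)
#' dskt(0, p)
#' qskt(0.5, p)
#' @export
skt_params <- function(location = 0, scale = 1, a, b) {
  stopifnot(is.numeric(location), is.numeric(scale), is.numeric(a), is.numeric(b))
  if (!is.finite(location)) stop("`location` must be finite")
  if (!is.finite(scale) || scale <= 0) stop("`scale` must be a positive real")
  if (!is.finite(a) || a < 0.5001) {
    stop("shape `a` must be finite and >= 0.5001 (got ", format(a), ")")
  }
  if (!is.finite(b) || b < 0.5001) {
    stop("shape `b` must be finite and >= 0.5001 (got ", format(b), ")")
  }
  structure(list(location = location, scale = scale, a = a, b = b),
            class = "skt_params")
}

#' @export
print.skt_params <- function(x, ...) {
  cat(sprintf("Jones-Faddy skew-t: location %.4g, scale %.4g, a %.4g, b %.4g\n",
              x$location, x$scale, x$a, x$b))
  mom <- skt_moments(x)
  if (is.finite(mom$mean)) cat(sprintf("  mean %.4g", mom$mean))
  if (is.finite(mom$variance)) cat(sprintf(", variance %.4g", mom$variance))
  cat("\n")
  invisible(x)
}

check_skt <- function(p) {
  if (!inherits(p, "skt_params")) {
    stop("expected an `skt_params` object; see skt_params()")
  }
  p
}

# mean of the standard (location 0, scale 1) variate; finite for a,b > 1/2
skt_std_mean <- function(a, b) {
  (a - b) * sqrt(a + b) *
    exp(lgamma(a - 0.5) + lgamma(b - 0.5) - lgamma(a) - lgamma(b)) / 2
}

# E[T^2] of the standard variate; finite for a,b > 1
skt_std_m2 <- function(a, b) {
  (a + b) * ((a - b)^2 + a + b - 2) / (4 * (a - 1) * (b - 1))
}

# the bounded transform r = t / sqrt(a + b + t^2), guarded against t^2
# overflowing to Inf (which would silently collapse r to 0)
skt_std_r <- function(t, a, b) {
  r <- t / sqrt(a + b + t * t)
  big <- abs(t) > 1e150
  big[is.na(big)] <- FALSE
  if (any(big)) r[big] <- sign(t[big])
  r
}

# log density of the standard variate, vectorized over t
skt_std_logpdf <- function(t, a, b) {
  r <- skt_std_r(t, a, b)
  (a + 0.5) * log1p(r) + (b + 0.5) * log1p(-r) -
    ((a + b - 1) * log(2) + lbeta(a, b) + 0.5 * log(a + b))
}

skt_std_cdf <- function(t, a, b) {
  stats::pbeta(0.5 * (1 + skt_std_r(t, a, b)), a, b)
}

skt_std_quantile <- function(prob, a, b) {
  u <- stats::qbeta(prob, a, b)
  (2 * u - 1) * sqrt(a + b) / (2 * sqrt(u * (1 - u)))
}

#' Skew-t density, distribution function, quantile and sampling
#'
#' Density (`dskt`), distribution function (`pskt`), quantile function
#' (`qskt`) and random generation (`rskt`) for the Jones-Faddy skew-t
#' distribution. The quantile function inverts the beta quantile directly
#' (no root-finding): with `u* = qbeta(prob, a, b)`,
#' `t = (2 u* - 1) sqrt(a + b) / (2 sqrt(u* (1 - u*)))`.
#'
#' @param x,q Vector of quantiles (finite reals).
#' @param prob Vector of probabilities, strictly inside (0, 1).
#' @param n Number of draws, a positive integer.
#' @param p An [skt_params()] object.
#' @param log Logical; if `TRUE`, `dskt` returns the log density.
#' @param seed Optional integer seed. When supplied, draws are reproducible
#'   and the caller's RNG state is left untouched.
#' @return `dskt`: densities; `pskt`: probabilities; `qskt`: quantiles;
#'   `rskt`: a numeric vector of `n` draws.
#' @examples
#' p <- skt_params(0, 1, a = 2, b = 6)
#' pskt(qskt(0.9, p), p)
#' @export
dskt <- function(x, p, log = FALSE) {
  check_skt(p)
  if (any(!is.finite(x))) stop("`x` must be finite")
  z <- (x - p$location) / p$scale
  ld <- skt_std_logpdf(z, p$a, p$b) - base::log(p$scale)
  if (log) ld else exp(ld)
}

#' @rdname dskt
#' @export
pskt <- function(q, p) {
  check_skt(p)
  out <- rep(NA_real_, length(q))
  out[q == -Inf] <- 0
  out[q == Inf] <- 1
  fin <- is.finite(q)
  out[fin] <- skt_std_cdf((q[fin] - p$location) / p$scale, p$a, p$b)
  if (anyNA(out)) stop("`q` contains NA/NaN")
  out
}

#' @rdname dskt
#' @export
qskt <- function(prob, p) {
  check_skt(p)
  if (any(!is.finite(prob)) || any(prob <= 0) || any(prob >= 1)) {
    stop("`prob` must lie strictly inside (0, 1)")
  }
  p$location + p$scale * skt_std_quantile(prob, p$a, p$b)
}

#' @rdname dskt
#' @export
rskt <- function(n, p, seed = NULL) {
  check_skt(p)
  if (length(n) != 1 || !is.finite(n) || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer")
  }
  draw <- function() {
    u <- stats::rbeta(n, p$a, p$b)
    t <- (2 * u - 1) * sqrt(p$a + p$b) / (2 * sqrt(u * (1 - u)))
    p$location + p$scale * t
  }
  if (is.null(seed)) draw() else with_preserved_seed(seed, draw())
}

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Mean and variance of a skew-t distribution
#'
#' Closed-form first two moments via the beta moments of the incomplete-beta
#' transform. The mean exists only for `a, b > 1/2` and the variance only for
#' `a, b > 1`; non-existent moments are returned as `NA` with a warning, never
#' as silent finite numbers.
#'
#' @param p An [skt_params()] object.
#' @return A list with elements `mean` and `variance` (each `NA_real_` when
#'   undefined).
#' @export
skt_moments <- function(p) {
  check_skt(p)
  m <- if (p$a > 0.5 && p$b > 0.5) {
    p$location + p$scale * skt_std_mean(p$a, p$b)
  } else NA_real_
  v <- if (p$a > 1 && p$b > 1) {
    p$scale^2 * (skt_std_m2(p$a, p$b) - skt_std_mean(p$a, p$b)^2)
  } else {
    warning("variance undefined: requires a > 1 and b > 1")
    NA_real_
  }
  list(mean = m, variance = v)
}

#' Shift a skew-t distribution to mean zero
#'
#' Returns the same distribution re-located so that its mean is exactly zero;
#' scale and shapes are unchanged. Used to identify the residual law of the
#' AMH regression: residuals are deviations from the estimated mean, so their
#' distribution must itself have mean zero.
#'
#' @param p An [skt_params()] object with `a, b > 1/2`.
#' @return An [skt_params()] object with mean zero.
#' @export
skt_mean_zero <- function(p) {
  check_skt(p)
  if (p$a <= 0.5 || p$b <= 0.5) stop("mean undefined: requires a, b > 1/2")
  skt_params(location = -p$scale * skt_std_mean(p$a, p$b),
             scale = p$scale, a = p$a, b = p$b)
}
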