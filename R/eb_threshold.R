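#' Point-mass + Laplace mixture prior
#'
#' Constructs the spike-and-slab prior used throughout the package: a
#' coefficient is zero with probability `1 - w` and otherwise drawn from a
#' Laplace (double-exponential) density `(a/2) * exp(-a * |u|)`. Observations
#' are modelled as the coefficient plus standard normal noise, so all
#' thresholding quantities below live on the unit-noise scale.
#'
#' @param w Prior probability that a coefficient is nonzero, in `[0, 1]`.
#' @param a Laplace scale parameter of the nonzero component, `> 0`.
#' @return An object of class `"mixture_prior"` with elements `w` and `a`.
#' @examples
#' pr <- mixture_prior(w = 0.1, a = 0.5)
#' posterior_median(3, pr)
#' @export
mixture_prior <- function(w, a) {
  stopifnot(is.numeric(w), length(w) == 1L, is.finite(w),
            is.numeric(a), length(a) == 1L, is.finite(a))
  if (w < 0 || w > 1)
    stop("mixture weight `w` must lie in [0, 1], got ", w)
  if (a <= 0)
    stop("Laplace scale `a` must be > 0, got ", a)
  structure(list(w = w, a = a), class = "mixture_prior")
}

#' @export
print.mixture_prior <- function(x, ...) {
  cat(sprintf("mixture_prior: P(nonzero) w = %.6g, Laplace scale a = %.6g\n",
              x$w, x$a))
  invisible(x)
}

stop_if_not_prior <- function(prior) {
  if (!inherits(prior, "mixture_prior"))
    stop("`prior` must be a mixture_prior object")
  invisible(prior)
}

## log of the Laplace * Normal(0,1) convolution, stable for |z| up to ~1e4.
## g(z) = (a/2) e^{a^2/2} [ e^{-a|z|} Phi(|z|-a) + e^{a|z|} Phi(-|z|-a) ];
## both branches are kept in log space (the naive second factor overflows
## already around |z| = 40 for moderate a).
log_marginal_laplace <- function(z, a) {
  az <- abs(z)
  base <- log(a / 2) + a * a / 2
  lneg <- base + a * az + stats::pnorm(-(az + a), log.p = TRUE)
  lpos <- base - a * az + stats::pnorm(az - a, log.p = TRUE)
  hi <- pmax(lneg, lpos)
  hi + log1p(exp(pmin(lneg, lpos) - hi))
}

#' Marginal density of an observation under the Laplace signal component
#'
#' Density of `z = u + e` where `u` has Laplace density `(a/2) exp(-a|u|)`
#' and `e` is standard normal, evaluated in log space so that the extreme
#' tails (|z| of 40 and far beyond) do not overflow.
#'
#' @param z Numeric vector of observations on the unit-noise scale.
#' @param a Laplace scale, `> 0`.
#' @return Numeric vector of densities.
#' @export
laplace_marginal_density <- function(z, a) {
  stopifnot(is.numeric(z), is.numeric(a), length(a) == 1L)
  if (!is.finite(a) || a <= 0)
    stop("Laplace scale `a` must be a finite value > 0, got ", a)
  exp(log_marginal_laplace(z, a))
}

#' Posterior probability that the underlying mean is nonzero
#'
#' Given `z ~ Normal(mu, 1)` and the mixture prior on `mu`, returns
#' `w g(z) / (w g(z) + (1 - w) phi(z))`, where `g` is the Laplace-convolved
#' marginal. Monotone nondecreasing in `|z|`.
#'
#' @param z Numeric vector of observations.
#' @param prior A [mixture_prior()].
#' @return Vector of probabilities in `[0, 1]`.
#' @export
posterior_nonzero_prob <- function(z, prior) {
  stop_if_not_prior(prior)
  w <- prior$w
  if (w == 0) return(rep(0, length(z)))
  if (w == 1) return(rep(1, length(z)))
  ## phi(z)/g(z) in log space; ratio -> 0 as |z| grows
  lr <- stats::dnorm(z, log = TRUE) - log_marginal_laplace(z, prior$a)
  1 / (1 + (1 - w) / w * exp(lr))
}

## Weight of the negative-mean branch of the posterior given the signal
## component: for z >= 0 the slab posterior is a two-piece truncated normal,
## N(z + a, 1) on (-Inf, 0] and N(z - a, 1) on [0, Inf).
slab_negative_weight <- function(az, a) {
  lneg <- a * az + stats::pnorm(-(az + a), log.p = TRUE)
  lpos <- -a * az + stats::pnorm(az - a, log.p = TRUE)
  hi <- pmax(lneg, lpos)
  exp(lneg - (hi + log1p(exp(pmin(lneg, lpos) - hi))))
}

#' Posterior median under the mixture prior (the thresholding rule)
#'
#' The posterior median of `mu` given `z ~ Normal(mu, 1)` under the
#' point-mass + Laplace prior. It is exactly zero for `|z|` below a
#' threshold `t(w, a)` (see [selection_threshold()]), antisymmetric and
#' monotone in `z`, and shrinks large observations by a bounded amount
#' (approaching `a` as `|z| -> Inf`). Computed in closed form from the
#' two-piece truncated-normal representation of the slab posterior.
#'
#' @param z Numeric vector of observations on the unit-noise scale.
#' @param prior A [mixture_prior()].
#' @return Numeric vector of posterior medians (same length as `z`).
#' @seealso [eb_shrink()] for the median together with the posterior
#'   nonzero probability.
#' @export
posterior_median <- function(z, prior) {
  stop_if_not_prior(prior)
  w <- prior$w
  a <- prior$a
  if (w == 0) return(numeric(length(z)) * sign(z)) # zeros, keeps NA through
  s <- sign(z)
  az <- abs(z)
  wneg <- slab_negative_weight(az, a)
  pnz <- posterior_nonzero_prob(az, prior)
  med <- numeric(length(z))
  pos <- pnz * (1 - wneg) > 0.5
  if (any(pos)) {
    q <- 1 - 0.5 / pnz[pos]                  # slab CDF level to invert
    wp <- 1 - wneg[pos]
    pr <- stats::pnorm(a - az[pos]) +
      (q - wneg[pos]) / wp * stats::pnorm(az[pos] - a)
    med[pos] <- pmax(az[pos] - a + stats::qnorm(pmin(pmax(pr, 0), 1)), 0)
  }
  s * med
}

#' Posterior median and nonzero probability in one call
#'
#' @param z Numeric vector of observations.
#' @param prior A [mixture_prior()].
#' @return A data frame with columns `estimate` (posterior median) and
#'   `prob_nonzero`.
#' @export
eb_shrink <- function(z, prior) {
  data.frame(estimate = posterior_median(z, prior),
             prob_nonzero = posterior_nonzero_prob(z, prior))
}

#' Selection threshold of the posterior-median rule
#'
#' Smallest `z >= 0` at which the posterior median becomes nonzero,
#' `t(w, a) = inf { z >= 0 : posterior_median(z) > 0 }`, located by
#' bisection. Monotone nonincreasing in `w`. For `w = 0` no observation is
#' ever selected and `+Inf` is returned.
#'
#' @param prior A [mixture_prior()].
#' @param tol Bisection tolerance (default `1e-8`).
#' @return Nonnegative scalar (possibly `Inf`).
#' @export
selection_threshold <- function(prior, tol = 1e-8) {
  stop_if_not_prior(prior)
  if (prior$w == 0) return(Inf)
  is_pos <- function(z) posterior_median(z, prior) > 0
  hi <- 1
  while (!is_pos(hi)) {
    hi <- hi * 2
    if (hi > 1e6) return(Inf)
  }
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (is_pos(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Conditional mode of the mixture weight
#'
#' Mode of the full conditional of the mixture weight `w` given a current
#' coefficient vector: with `k` nonzero entries out of `p`, the conditional
#' is proportional to `w^k (1-w)^(p-k)` times the hyperprior. Under the
#' default flat hyperprior the mode is `k/p`; under a `Beta(s1, s2)`
#' hyperprior it is `(k + s1 - 1) / (p + s1 + s2 - 2)`. The result is
#' clamped to `[w_min, w_max]`.
#'
#' @param beta Numeric coefficient vector (finite).
#' @param w_min,w_max Clamping bounds; `w_min` defaults to
#'   `max(1/length(beta), 1e-6)`.
#' @param hyper `NULL` for the flat hyperprior, or `c(shape1, shape2)` of a
#'   Beta hyperprior.
#' @return Scalar weight in `[w_min, w_max]`.
#' @export
conditional_mode_w <- function(beta, w_min = NULL, w_max = 1 - 1e-6,
                               hyper = NULL) {
  if (length(beta) == 0L) stop("`beta` must be non-empty")
  if (!all(is.finite(beta))) stop("`beta` must be finite")
  p <- length(beta)
  k <- sum(beta != 0)
  if (is.null(w_min)) w_min <- max(1 / p, 1e-6)
  w <- if (is.null(hyper)) {
    k / p
  } else {
    stopifnot(length(hyper) == 2L, all(hyper > 0))
    (k + hyper[1] - 1) / (p + hyper[1] + hyper[2] - 2)
  }
  min(max(w, w_min), w_max)
}

#' Conditional mode of the Laplace scale
#'
#' Mode of the full conditional of the Laplace scale `a` given the nonzero
#' coefficients, which are put on the unit-noise scale by dividing by
#' `sigma`: with `k` nonzero entries and `S = sum(|beta_j| / sigma)`, the
#' flat-hyperprior conditional log-density is `k log(a) - a S`, maximized at
#' `k / S`; a `Gamma(shape, rate)` hyperprior shifts this to
#' `(k + shape - 1) / (S + rate)`. Clamped to `[a_min, a_max]`. When no
#' coefficient is nonzero the previous value `a_prev` is returned unchanged.
#'
#' @param beta Numeric coefficient vector.
#' @param sigma Noise scale used to standardize the coefficients.
#' @param a_prev Value returned when `beta` has no nonzero entry.
#' @param a_min,a_max Clamping bounds (defaults 0.05 and 3).
#' @param hyper `NULL` for flat, or `c(shape, rate)` of a Gamma hyperprior.
#' @return Scalar scale in `[a_min, a_max]` (or `a_prev`).
#' @export
conditional_mode_a <- function(beta, sigma = 1, a_prev = 0.5,
                               a_min = 0.05, a_max = 3, hyper = NULL) {
  if (!all(is.finite(beta))) stop("`beta` must be finite")
  stopifnot(sigma > 0)
  nz <- beta != 0
  k <- sum(nz)
  if (k == 0L) return(a_prev)
  S <- sum(abs(beta[nz])) / sigma
  a <- if (is.null(hyper)) {
    k / S
  } else {
    stopifnot(length(hyper) == 2L, all(hyper >= 0))
    (k + hyper[1] - 1) / (S + hyper[2])
  }
  min(max(a, a_min), a_max)
}
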