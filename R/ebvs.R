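#' Prepare a design matrix for EBVS
#'
#' Centers every column and scales it to unit Euclidean norm, recording the
#' transforms so fitted coefficients can be mapped back to the original
#' predictor scale. With unit-norm columns the partial-residual correlation
#' used in the coordinate sweep is already on the unit-noise scale.
#'
#' @param x Numeric matrix, `n >= 3` rows, finite entries.
#' @param kind Optional character vector tagging each column as
#'   `"covariate"` or `"gene_marker"` (any labels are accepted).
#' @return An object of class `"ebvs_design"`: list with `x` (standardized
#'   matrix), `kind`, `center`, `scale`, `names`.
#' @export
prepare_design <- function(x, kind = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x) || !all(is.finite(x)))
    stop("design matrix must be numeric and finite")
  n <- nrow(x)
  p <- ncol(x)
  if (n < 3L) stop("need at least 3 rows, got ", n)
  if (p < 1L) stop("need at least 1 column")
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))
  if (is.null(kind)) kind <- rep("predictor", p)
  if (length(kind) != p) stop("`kind` must have one tag per column")
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr, `-`)
  scl <- sqrt(colSums(xc^2))
  bad <- scl < 1e-12 * max(1, sqrt(n) * apply(abs(x), 2, max))
  bad <- bad | scl == 0
  if (any(bad))
    stop("constant column(s) not allowed: ", paste(nm[bad], collapse = ", "))
  xs <- sweep(xc, 2L, scl, `/`)
  structure(list(x = xs, kind = kind, center = ctr, scale = scl, names = nm),
            class = "ebvs_design")
}

#' Control parameters for [ebvs_fit()]
#'
#' @param tol Convergence tolerance on the maximum absolute change of the
#'   standardized-scale coefficients, applied relative to `sd(y)` so the fit
#'   is exactly equivariant under rescaling of the response.
#' @param max_iter Maximum number of full coordinate sweeps.
#' @param w_init Initial mixture weight; default `min(max(1/p, 1e-6), 0.5)`.
#' @param a_init Initial Laplace scale.
#' @param a_min,a_max Bounds for the Laplace scale update.
#' @param w_hyper,a_hyper Optional Beta / Gamma hyperprior parameters passed
#'   to [conditional_mode_w()] and [conditional_mode_a()]; `NULL` = flat.
#' @param sigma Fix the noise scale at this value instead of updating it.
#' @param update_w,update_a Logical; freeze the corresponding hyperparameter
#'   at its initial value when `FALSE` (used by diagnostics and tests).
#' @param unpenalized Integer indices of columns exempt from the mixture
#'   prior (updated by plain partial least squares); default none.
#' @return A list of class `"ebvs_control"`.
#' @export
ebvs_control <- function(tol = 1e-6, max_iter = 500L, w_init = NULL,
                         a_init = 0.5, a_min = 0.05, a_max = 3,
                         w_hyper = NULL, a_hyper = NULL, sigma = NULL,
                         update_w = TRUE, update_a = TRUE,
                         unpenalized = integer(0)) {
  stopifnot(tol > 0, max_iter >= 1L, a_init > 0, a_min > 0, a_max >= a_min)
  structure(list(tol = tol, max_iter = as.integer(max_iter), w_init = w_init,
                 a_init = a_init, a_min = a_min, a_max = a_max,
                 w_hyper = w_hyper, a_hyper = a_hyper, sigma = sigma,
                 update_w = update_w, update_a = update_a,
                 unpenalized = as.integer(unpenalized)),
            class = "ebvs_control")
}

#' Empirical Bayes variable selection for the large-p linear model
#'
#' Fits `y = X beta + e` with the point-mass + Laplace mixture prior on each
#' coefficient. The response is centered, coefficients start at zero, and
#' the algorithm alternates (1) a full cyclic coordinate sweep in which each
#' standardized-scale coefficient is replaced by `sigma` times the posterior
#' median of its partial-residual correlation `z_j = x_j'(y - X beta + x_j
#' beta_j) / sigma`, (2) conditional-mode updates of the mixture weight `w`
#' and Laplace scale `a`, and (3) the conditional-mode noise update
#' `sigma^2 = RSS / n`, until the sweep no longer moves any coefficient by
#' more than `tol * sd(y)` or `max_iter` is reached. Output is deterministic
#' for fixed input and control.
#'
#' @param design An [prepare_design()] object (or a raw matrix, which is
#'   passed through `prepare_design`).
#' @param y Numeric response of length `nrow(design$x)`.
#' @param control An [ebvs_control()] list.
#' @return An object of class `"ebvs_fit"`: `beta` (original predictor
#'   scale), `beta_std` (standardized scale), `intercept`, `prior` (final
#'   mixture_prior), `sigma`, `selected` (indices with nonzero beta),
#'   `n_iter`, `converged`, `sigma_floored`, and `trace` (per-iteration
#'   `w`, `a`, `sigma`, `n_nonzero`, `delta`, `rss`).
#' @export
ebvs_fit <- function(design, y, control = ebvs_control()) {
  if (!inherits(design, "ebvs_design")) design <- prepare_design(design)
  X <- design$x
  n <- nrow(X)
  p <- ncol(X)
  y <- as.numeric(y)
  if (length(y) != n) stop("length(y) must equal nrow(design)")
  if (!all(is.finite(y))) stop("`y` must be finite")
  ybar <- mean(y)
  y0 <- y - ybar
  sdy <- stats::sd(y0)
  if (sdy == 0) stop("constant response")

  ## flag near-duplicate predictors: unit-norm centered columns make the
  ## Gram matrix a correlation matrix
  if (p >= 2L && p <= 4000L) {
    G <- crossprod(X)
    diag(G) <- 0
    if (max(abs(G)) > 0.999)
      warning("collinear predictors (|correlation| > 0.999); ",
              "sweep order resolves selection among them")
  }

  pen <- rep(TRUE, p)
  pen[control$unpenalized] <- FALSE
  p_pen <- sum(pen)
  if (p_pen == 0L) stop("all columns unpenalized; use refit_unpenalized()")
  w_min <- max(1 / p_pen, 1e-6)
  w_max <- 1 - 1e-6
  w <- if (is.null(control$w_init)) min(max(1 / p_pen, 1e-6), 0.5)
       else control$w_init
  a <- control$a_init
  sigma_fixed <- !is.null(control$sigma)
  sigma <- if (sigma_fixed) control$sigma else sdy

  beta <- numeric(p)
  r <- y0
  tol <- control$tol * sdy
  trace <- vector("list", control$max_iter)
  converged <- FALSE
  sigma_floored <- FALSE
  it <- 0L
  for (it in seq_len(control$max_iter)) {
    beta_old <- beta
    prior <- mixture_prior(w, a)
    for (j in seq_len(p)) {
      zj <- (sum(X[, j] * r) + beta[j]) / sigma
      bnew <- if (pen[j]) sigma * posterior_median(zj, prior) else sigma * zj
      if (bnew != beta[j]) {
        r <- r + X[, j] * (beta[j] - bnew)
        beta[j] <- bnew
      }
    }
    if (control$update_w)
      w <- conditional_mode_w(beta[pen], w_min = w_min, w_max = w_max,
                              hyper = control$w_hyper)
    if (control$update_a)
      a <- conditional_mode_a(beta[pen], sigma = sigma, a_prev = a,
                              a_min = control$a_min, a_max = control$a_max,
                              hyper = control$a_hyper)
    rss <- sum(r^2)
    if (!sigma_fixed) {
      sigma <- sqrt(rss / n)
      if (sigma < 1e-8 * sdy) {
        sigma <- 1e-8 * sdy
        sigma_floored <- TRUE
      }
    }
    delta <- max(abs(beta - beta_old))
    trace[[it]] <- c(iter = it, w = w, a = a, sigma = sigma,
                     n_nonzero = sum(beta != 0), delta = delta, rss = rss)
    if (delta <= tol) {
      converged <- TRUE
      break
    }
  }
  trace <- as.data.frame(do.call(rbind, trace[seq_len(it)]))

  beta_orig <- beta / design$scale
  structure(list(
    beta = stats::setNames(beta_orig, design$names),
    beta_std = stats::setNames(beta, design$names),
    intercept = ybar - sum(design$center * beta_orig),
    prior = mixture_prior(w, a),
    sigma = sigma,
    selected = which(beta != 0),
    kind = design$kind,
    n_iter = it,
    converged = converged,
    sigma_floored = sigma_floored,
    trace = trace), class = "ebvs_fit")
}

#' @export
print.ebvs_fit <- function(x, ...) {
  cat(sprintf(
    "ebvs_fit: %d of %d predictors selected | w = %.4g, a = %.4g, sigma = %.4g\n",
    length(x$selected), length(x$beta), x$prior$w, x$prior$a, x$sigma))
  cat(sprintf("  %d sweep(s), converged = %s\n", x$n_iter, x$converged))
  if (length(x$selected))
    print(x$beta[x$selected])
  invisible(x)
}

#' Unpenalized refit on the selected predictors
#'
#' Ordinary least squares of `y` on the selected columns only, reported on
#' the original predictor scale; used for the per-replicate effect-size
#' summaries. Rank-deficient selections drop the dependent columns with a
#' warning.
#'
#' @param x Original-scale predictor matrix.
#' @param y Response vector.
#' @param selected Integer indices of the selected columns.
#' @return A data frame `(predictor, estimate)`; zero rows when nothing is
#'   selected (intercept-only model).
#' @export
refit_unpenalized <- function(x, y, selected) {
  x <- as.matrix(x)
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("x", seq_len(ncol(x)))
  selected <- as.integer(selected)
  if (length(selected) == 0L)
    return(data.frame(predictor = character(0), estimate = numeric(0)))
  if (length(selected) >= nrow(x))
    stop("more selected predictors than observations")
  xs <- x[, selected, drop = FALSE]
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, xs), y)
  coefs <- fit$coefficients[-1]
  if (anyNA(coefs)) {
    warning("rank-deficient selection; dropping: ",
            paste(nm[selected][is.na(coefs)], collapse = ", "))
    keep <- !is.na(coefs)
    coefs <- coefs[keep]
    selected <- selected[keep]
  }
  data.frame(predictor = nm[selected], estimate = unname(coefs))
}
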