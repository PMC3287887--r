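#' One gene's block of SNP genotypes
#'
#' @param gene_id Gene identifier.
#' @param snp_ids Character vector of unique SNP identifiers.
#' @param x `n x l_k` matrix of minor-allele counts (entries 0/1/2), one
#'   column per SNP in `snp_ids` order.
#' @return An object of class `"gene_block"`.
#' @export
gene_block <- function(gene_id, snp_ids, x) {
  x <- as.matrix(x)
  if (ncol(x) < 1L) stop("gene block must contain at least one SNP")
  if (length(snp_ids) != ncol(x)) stop("one snp_id per column required")
  if (anyDuplicated(snp_ids)) stop("snp_ids must be unique")
  if (!all(x %in% c(0, 1, 2)))
    stop("genotype entries must be minor-allele counts in {0, 1, 2}")
  colnames(x) <- snp_ids
  structure(list(gene_id = gene_id, snp_ids = as.character(snp_ids), x = x),
            class = "gene_block")
}

#' Control parameters for [pocre_fit()]
#'
#' @param a Laplace scale used inside the thresholding penalty; fixed (not
#'   estimated) because gene blocks are small.
#' @param alpha_entry Familywise error rate under a null gene that
#'   calibrates the entry threshold: the initial mixture weight is chosen so
#'   the selection threshold equals `qnorm(1 - alpha_entry / (2 l_k))`.
#' @param max_components Maximum number of orthogonal components per gene.
#' @param rel_tol Stop when a component reduces the residual sum of squares
#'   by less than this relative amount.
#' @return A list of class `"pocre_control"`.
#' @export
pocre_control <- function(a = 0.5, alpha_entry = 0.05, max_components = 5L,
                          rel_tol = 1e-8) {
  stopifnot(a > 0, alpha_entry > 0, alpha_entry < 1, max_components >= 1L,
            rel_tol > 0)
  structure(list(a = a, alpha_entry = alpha_entry,
                 max_components = as.integer(max_components),
                 rel_tol = rel_tol), class = "pocre_control")
}

## cache for entry weights: solving t(w, a) = t_target is a double
## root-find, and the same (l, a, alpha) triple recurs across genes
.entry_weight_cache <- new.env(parent = emptyenv())

## mixture weight whose selection threshold equals the two-sided Bonferroni
## point for l coefficients at level alpha
entry_weight <- function(l, a, alpha) {
  key <- sprintf("%d_%.10g_%.10g", l, a, alpha)
  hit <- .entry_weight_cache[[key]]
  if (!is.null(hit)) return(hit)
  target <- stats::qnorm(1 - alpha / (2 * l))
  f <- function(lw) selection_threshold(mixture_prior(exp(lw), a)) - target
  lo <- log(1e-12)
  hi <- log(1 - 1e-9)
  if (f(lo) <= 0) {
    w <- 1e-12          # even the sparsest prior thresholds below target
  } else if (f(hi) >= 0) {
    w <- 1 - 1e-9
  } else {
    w <- exp(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
  }
  .entry_weight_cache[[key]] <- w
  w
}

#' Penalized orthogonal-components regression on one gene block
#'
#' Sequentially builds mutually orthogonal components whose sparse loadings
#' are obtained by empirical Bayes thresholding of the (robustly scaled)
#' predictor-residual correlations, then collapses them into a single
#' coefficient vector `b_k` in the original SNP space. Each step: (1)
#' `s = E'r` for the deflated working matrix `E` and working residual `r`;
#' (2) `z = s / (MAD(s)/0.6745)` (population sd of `s` when the MAD
#' degenerates to zero; stop when both do); (3) a first thresholding pass at
#' the entry weight (see [pocre_control()]), one conditional-mode update of
#' the weight from the resulting nonzero pattern, and a second pass giving
#' the sparse `gamma`; (4) stop if `gamma = 0`; (5) unit-norm loading,
#' component scores, regression coefficient, deflation of `r` and `E`.
#' Components are tracked as linear maps of the original columns, so
#' `X_k b_k` equals the sum of fitted component contributions exactly.
#'
#' @param block A [gene_block()] (centered internally; column means are
#'   recorded).
#' @param y Training phenotype vector (centered internally).
#' @param control A [pocre_control()] list.
#' @return An object of class `"pocre_model"`: `gene_id`, `snp_ids`,
#'   `components` (list with `loading`, `scores`, `coef` per component),
#'   `snp_coefficients` (`b_k`, original SNP space), `n_components`,
#'   `centers` (training column means).
#' @export
pocre_fit <- function(block, y, control = pocre_control()) {
  if (!inherits(block, "gene_block")) stop("`block` must be a gene_block")
  n <- nrow(block$x)
  l <- ncol(block$x)
  y <- as.numeric(y)
  if (length(y) != n) stop("length(y) must match block rows")
  if (!all(is.finite(y))) stop("`y` must be finite")

  centers <- colMeans(block$x)
  E <- sweep(block$x, 2L, centers, `-`)
  r <- y - mean(y)
  C <- diag(l)                      # E = X_centered %*% C throughout
  w_entry <- entry_weight(l, control$a, control$alpha_entry)
  prior_entry <- mixture_prior(w_entry, control$a)

  comps <- list()
  b <- numeric(l)
  max_m <- min(n - 1L, l, control$max_components)
  m <- 0L
  while (m < max_m) {
    s <- as.numeric(crossprod(E, r))
    ## exact null sd of each correlation, ||e_j|| * sd(r): the robust
    ## cross-SNP scale is floored here, otherwise the sampling noise of a
    ## MAD over a handful of values inflates z and breaks the familywise
    ## calibration of the entry threshold
    null_sd <- sqrt(colSums(E^2) * mean(r^2))
    if (l >= 3L) {
      scl <- stats::mad(s)          # MAD(s)/0.6745
      if (scl == 0) scl <- sqrt(mean((s - mean(s))^2))
      denom <- pmax(scl, null_sd)
    } else {
      ## 1-2 SNPs: a cross-SNP scale statistic is degenerate
      denom <- null_sd
    }
    if (all(denom == 0)) break
    z <- as.numeric(ifelse(denom > 0, s / denom, 0))
    g0 <- posterior_median(z, prior_entry)
    if (all(g0 == 0)) break
    w1 <- conditional_mode_w(g0, w_min = max(1 / l, 1e-6))
    gam <- posterior_median(z, mixture_prior(w1, control$a))
    if (all(gam == 0)) break
    loading <- gam / sqrt(sum(gam^2))
    v <- as.numeric(C %*% loading)  # loading mapped to original columns
    Z <- as.numeric(E %*% loading)
    zz <- sum(Z^2)
    if (zz < 1e-12) break
    cm <- sum(Z * r) / zz
    if (cm^2 * zz < control$rel_tol * sum(r^2)) break
    q <- as.numeric(crossprod(E, Z)) / zz
    r <- r - cm * Z
    E <- E - tcrossprod(Z, q)
    C <- C - tcrossprod(v, q)
    b <- b + cm * v
    m <- m + 1L
    comps[[m]] <- list(loading = loading, scores = Z, coef = cm)
  }

  structure(list(gene_id = block$gene_id, snp_ids = block$snp_ids,
                 components = comps,
                 snp_coefficients = stats::setNames(b, block$snp_ids),
                 n_components = m, centers = centers),
            class = "pocre_model")
}

#' @export
print.pocre_model <- function(x, ...) {
  cat(sprintf("pocre_model for gene %s: %d SNP(s), %d component(s), %d nonzero coefficient(s)\n",
              x$gene_id, length(x$snp_ids), x$n_components,
              sum(x$snp_coefficients != 0)))
  invisible(x)
}

#' Gene-level marker from a fitted POCRE model
#'
#' Applies the collapsed coefficient vector to (new) genotypes of the same
#' SNPs: `marker = centered(X_new) %*% b_k`. Linear in `X_new`; a model with
#' no components yields the zero vector.
#'
#' @param model A [pocre_fit()] result.
#' @param x_new `n x l_k` genotype matrix; column names must equal the
#'   model's `snp_ids` in order.
#' @return Numeric marker vector of length `nrow(x_new)`.
#' @export
gene_marker <- function(model, x_new) {
  if (!inherits(model, "pocre_model")) stop("`model` must be a pocre_model")
  x_new <- as.matrix(x_new)
  ids <- colnames(x_new)
  if (is.null(ids) || !identical(as.character(ids), model$snp_ids)) {
    missing_ids <- setdiff(model$snp_ids, ids)
    extra <- setdiff(ids, model$snp_ids)
    stop("SNP mismatch for gene ", model$gene_id,
         if (length(missing_ids)) paste0("; missing: ",
                                         paste(missing_ids, collapse = ",")),
         if (length(extra)) paste0("; extra/misordered: ",
                                   paste(extra, collapse = ",")))
  }
  if (model$n_components == 0L) return(numeric(nrow(x_new)))
  xc <- sweep(x_new, 2L, colMeans(x_new), `-`)
  as.numeric(xc %*% model$snp_coefficients)
}

#' Coalesce every gene of a study into a POCRE model
#'
#' Runs [pocre_fit()] independently on each gene's SNP block (results do
#' not depend on execution order). SNPs with no gene assignment are dropped
#' with a message. A failing gene does not abort the run unless
#' `strict = TRUE`; its error is re-raised with the gene id attached
#' (strict) or downgraded to a warning and an empty model (default).
#'
#' @param study A [genotype_study()] object.
#' @param y Training phenotype vector.
#' @param control A [pocre_control()] list.
#' @param strict Abort on the first per-gene error?
#' @return Named list of `pocre_model`, one entry per mapped gene.
#' @export
coalesce_all <- function(study, y, control = pocre_control(),
                         strict = FALSE) {
  stopifnot(inherits(study, "genotype_study"))
  st <- study$snp_table
  mapped <- !is.na(st$gene_id) & st$gene_id != ""
  n_drop <- sum(!mapped)
  if (n_drop > 0)
    message(n_drop, " SNP(s) without gene assignment dropped from coalescing")
  st <- st[mapped, , drop = FALSE]
  genes <- unique(st$gene_id)
  models <- vector("list", length(genes))
  names(models) <- genes
  for (g in genes) {
    ids <- st$snp_id[st$gene_id == g]
    blk <- gene_block(g, ids, study$genotypes[, ids, drop = FALSE])
    models[[g]] <- tryCatch(pocre_fit(blk, y, control), error = function(e) {
      if (strict) stop("gene ", g, ": ", conditionMessage(e), call. = FALSE)
      warning("gene ", g, " failed (", conditionMessage(e),
              "); empty model used", call. = FALSE)
      structure(list(gene_id = g, snp_ids = as.character(ids),
                     components = list(),
                     snp_coefficients = stats::setNames(numeric(length(ids)), ids),
                     n_components = 0L,
                     centers = colMeans(study$genotypes[, ids, drop = FALSE])),
                class = "pocre_model")
    })
  }
  models
}
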