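# Brute-force quadrature oracles for the mixture-prior machinery.
# These integrate the Laplace-convolution posterior directly and stay
# independent of the closed-form path they certify.

laplace_density <- function(u, a) (a / 2) * exp(-a * abs(u))

oracle_marginal <- function(z, a) {
  stats::integrate(function(u) stats::dnorm(z - u) * laplace_density(u, a),
                   -Inf, Inf, rel.tol = 1e-12)$value
}

# posterior CDF of the mean given z under the point-mass + Laplace prior;
# the slab integral is taken from whichever side keeps the integrand's
# spike (near u = z) close to a finite bound
oracle_posterior_cdf <- function(m, z, w, a) {
  g <- oracle_marginal(z, a)
  pnz <- w * g / (w * g + (1 - w) * stats::dnorm(z))
  f <- function(u) stats::dnorm(z - u) * laplace_density(u, a)
  slab <- if (m <= z) {
    stats::integrate(f, -Inf, m, rel.tol = 1e-12)$value / g
  } else {
    1 - stats::integrate(f, m, Inf, rel.tol = 1e-12)$value / g
  }
  pnz * slab + (1 - pnz) * (m >= 0)
}

oracle_posterior_median <- function(z, w, a) {
  if (z < 0) return(-oracle_posterior_median(-z, w, a))
  below0 <- oracle_posterior_cdf(0, z, w, a)       # includes the point mass
  just_below <- below0 - (1 - w * oracle_marginal(z, a) /
    (w * oracle_marginal(z, a) + (1 - w) * stats::dnorm(z)))
  if (below0 >= 0.5 && just_below <= 0.5) return(0)
  stats::uniroot(function(m) oracle_posterior_cdf(m, z, w, a) - 0.5,
                 c(1e-12, z + 10 / max(a, 0.05)), tol = 1e-12)$root
}

# a random polymorphic genotype block (counts in {0,1,2})
random_block <- function(n, l, maf = NULL, gene_id = "g") {
  if (is.null(maf)) maf <- stats::runif(l, 0.02, 0.3)
  x <- sapply(maf, function(f) stats::rbinom(n, 2, f))
  mono <- apply(x, 2, stats::sd) == 0
  while (any(mono)) {
    x[, mono] <- sapply(which(mono), function(j) stats::rbinom(n, 2, 0.2))
    mono <- apply(x, 2, stats::sd) == 0
  }
  gene_block(gene_id, paste0("s", seq_len(l)), x)
}

# a small hand-built study: n individuals, per-gene MAFs given as a list
build_study <- function(n, gene_mafs, n_replicates = 2, seed = 1,
                        phenotype_fun = NULL, truth = NULL) {
  set.seed(seed)
  blocks <- lapply(gene_mafs, function(mafs)
    sapply(mafs, function(f) stats::rbinom(n, 2, f)))
  geno <- do.call(cbind, blocks)
  M <- ncol(geno)
  lk <- vapply(gene_mafs, length, integer(1))
  snp_id <- paste0("snp", seq_len(M))
  colnames(geno) <- snp_id
  f <- colMeans(geno) / 2
  st <- data.frame(snp_id = snp_id, chrom = "1",
                   pos = seq_len(M) * 1000L,
                   gene_id = rep(paste0("g", seq_along(gene_mafs)), lk),
                   maf = pmin(f, 1 - f), stringsAsFactors = FALSE)
  covs <- data.frame(Age = pmin(pmax(round(stats::rnorm(n, 49, 12)), 18), 90),
                     Sex = stats::rbinom(n, 1, 0.5),
                     Smoke = stats::rbinom(n, 1, 0.3))
  phen <- NULL
  if (!is.null(phenotype_fun))
    phen <- sapply(seq_len(n_replicates), function(r) phenotype_fun(geno, covs))
  genotype_study(geno, st, covs, phen, truth)
}
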