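#' Simulation configuration for a GAW17-like study
#'
#' Defaults emulate the structure of the GAW17 unrelated-individuals
#' mini-exome: 697 individuals, 3,205 autosomal genes carrying on average
#' ~7.6 SNPs each (about 24,500 SNPs), a strongly rare-skewed allele
#' frequency spectrum with ~12.8% of SNPs common (MAF >= 0.05), fixed
#' genotypes, and many phenotype replicates that redraw only the
#' environmental noise. See [gaw17_mini()] for the small preset used in
#' tests.
#'
#' @param seed Integer seed; every random draw is reproducible from it.
#' @param n_individuals Number of (unrelated) individuals.
#' @param n_genes Number of genes.
#' @param snps_per_gene `list(mean=, max=)`: block sizes are
#'   `1 + Poisson(mean - 1)` truncated at `max`.
#' @param maf_model `list(fraction_common=, rare_range=, common_range=)`:
#'   each SNP is common with probability `fraction_common`, MAF uniform on
#'   `common_range`; otherwise rare, MAF log-uniform on `rare_range`.
#' @param ld_rho Within-gene latent (haplotype) correlation in `[0, 1)`;
#'   0 = independent SNPs.
#' @param n_replicates Number of phenotype replicates (`>= 2`).
#' @param causal List of causal-gene specs, each
#'   `list(gene=, n_causal=, share=, effect_rule=)` where `gene` is an index
#'   or id, `share` the relative genetic-variance weight and `effect_rule`
#'   `"constant"` or `"log_maf"` (`|log10(MAF)|`-proportional, giving rare
#'   variants larger per-allele effects). Empty list = null study.
#' @param covariate_effects `list(age=, sex=, smoke=)` regression
#'   coefficients in natural units (years, indicator, indicator).
#' @param h2 Target proportion of phenotypic variance explained by the
#'   genetic value, in `[0, 1)`.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_individuals = 697L,
                       n_genes = 3205L,
                       snps_per_gene = list(mean = 7.6, max = 60L),
                       maf_model = list(fraction_common = 0.1279,
                                        rare_range = c(7e-4, 0.05),
                                        common_range = c(0.05, 0.5)),
                       ld_rho = 0,
                       n_replicates = 200L,
                       causal = list(),
                       covariate_effects = list(age = 0, sex = 0, smoke = 0),
                       h2 = 0.4) {
  bad <- function(msg) stop("invalid sim_config: ", msg)
  if (!is.numeric(seed) || length(seed) != 1L) bad("seed must be a scalar")
  if (n_individuals < 3) bad("n_individuals must be >= 3")
  if (n_genes < 1) bad("n_genes must be >= 1")
  if (snps_per_gene$mean < 1) bad("snps_per_gene$mean must be >= 1")
  fc <- maf_model$fraction_common
  if (fc < 0 || fc > 1) bad("fraction_common must be in [0, 1]")
  if (ld_rho < 0 || ld_rho >= 1) bad("ld_rho must be in [0, 1)")
  if (n_replicates < 2) bad("n_replicates must be >= 2")
  if (h2 < 0 || h2 >= 1) bad("h2 must be in [0, 1)")
  structure(list(seed = as.integer(seed),
                 n_individuals = as.integer(n_individuals),
                 n_genes = as.integer(n_genes),
                 snps_per_gene = snps_per_gene, maf_model = maf_model,
                 ld_rho = ld_rho, n_replicates = as.integer(n_replicates),
                 causal = causal, covariate_effects = covariate_effects,
                 h2 = h2), class = "sim_config")
}

#' Genotype-study container
#'
#' @param genotypes `n x M` minor-allele-count matrix (0/1/2), column names
#'   = SNP ids; fixed across phenotype replicates.
#' @param snp_table Data frame `(snp_id, chrom, pos, gene_id, maf)`.
#' @param covariates Data frame with columns `Age`, `Sex`, `Smoke`.
#' @param phenotypes Optional `n x R` matrix, one column per replicate.
#' @param truth Optional list `(causal_genes, causal_snps, covariates,
#'   snp_effects)`.
#' @return An object of class `"genotype_study"`.
#' @export
genotype_study <- function(genotypes, snp_table, covariates,
                           phenotypes = NULL, truth = NULL) {
  genotypes <- as.matrix(genotypes)
  stopifnot(is.data.frame(snp_table),
            all(c("snp_id", "chrom", "pos", "gene_id", "maf") %in%
                  names(snp_table)),
            nrow(snp_table) == ncol(genotypes),
            is.data.frame(covariates),
            all(c("Age", "Sex", "Smoke") %in% names(covariates)),
            nrow(covariates) == nrow(genotypes))
  if (!all(genotypes %in% c(0, 1, 2)))
    stop("genotype entries must be in {0, 1, 2}")
  if (anyDuplicated(snp_table$snp_id)) stop("duplicate snp_id in snp_table")
  colnames(genotypes) <- snp_table$snp_id
  f <- colMeans(genotypes) / 2
  if (max(abs(pmin(f, 1 - f) - snp_table$maf)) > 1e-12)
    stop("snp_table$maf does not match MAF recomputed from genotypes")
  if (!is.null(phenotypes)) {
    phenotypes <- as.matrix(phenotypes)
    stopifnot(nrow(phenotypes) == nrow(genotypes))
  }
  structure(list(genotypes = genotypes, snp_table = snp_table,
                 covariates = covariates, phenotypes = phenotypes,
                 truth = truth), class = "genotype_study")
}

#' @export
print.genotype_study <- function(x, ...) {
  cat(sprintf("genotype_study: %d individuals, %d SNPs in %d genes",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$snp_table$gene_id))), "\n")
  cat(sprintf("  fraction MAF >= 0.05: %.4f\n",
              mean(x$snp_table$maf >= 0.05)))
  if (!is.null(x$phenotypes))
    cat(sprintf("  %d phenotype replicate(s)\n", ncol(x$phenotypes)))
  if (!is.null(x$truth))
    cat(sprintf("  truth: %d causal gene(s), %d causal SNP(s)\n",
                length(x$truth$causal_genes), length(x$truth$causal_snps)))
  invisible(x)
}

#' Simulate genotypes, SNP map and covariates
#'
#' Gene block sizes are drawn from the configured truncated Poisson; each
#' SNP's MAF comes from the common/rare two-part mixture; genotypes are the
#' sum of two Bernoulli(MAF) haplotype draws, optionally correlated within
#' a gene through an equicorrelated latent Gaussian thresholded at the MAF
#' quantile. Genes are laid out round-robin across chromosomes 1-22 with
#' increasing 1-based positions. Covariates: Age ~ round(Normal(49, 12^2))
#' clipped to [18, 90], Sex ~ Bernoulli(0.5), Smoke ~ Bernoulli(0.3).
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_study()] without phenotypes or truth.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  G <- cfg$n_genes
  lk <- pmin(1L + stats::rpois(G, cfg$snps_per_gene$mean - 1),
             as.integer(cfg$snps_per_gene$max))
  M <- sum(lk)
  mm <- cfg$maf_model
  common <- stats::runif(M) < mm$fraction_common
  lr <- log(mm$rare_range)
  maf <- ifelse(common,
                stats::runif(M, mm$common_range[1], mm$common_range[2]),
                exp(stats::runif(M, lr[1], lr[2])))

  geno <- matrix(0L, n, M)
  rho <- cfg$ld_rho
  col0 <- 0L
  for (g in seq_len(G)) {
    l <- lk[g]
    idx <- col0 + seq_len(l)
    thr <- stats::qnorm(maf[idx])
    cnt <- matrix(0L, n, l)
    for (h in 1:2) {                      # two haplotypes per individual
      if (rho > 0 && l > 1) {
        f <- stats::rnorm(n)
        lat <- sqrt(rho) * f + sqrt(1 - rho) * matrix(stats::rnorm(n * l), n, l)
      } else {
        lat <- matrix(stats::rnorm(n * l), n, l)
      }
      cnt <- cnt + (lat < rep(thr, each = n))
    }
    geno[, idx] <- cnt
    col0 <- col0 + l
  }

  gene_id <- rep(sprintf("GENE%04d", seq_len(G)), lk)
  chrom <- rep(as.character(1L + (seq_len(G) - 1L) %% 22L), lk)
  ## positions increase within each chromosome: genes 100kb apart, SNPs ~1kb
  gene_rank <- rep((seq_len(G) - 1L) %/% 22L, lk)
  within <- sequence(lk)
  pos <- 1L + gene_rank * 100000L + (within - 1L) * 1000L
  snp_id <- sprintf("SNP%05d", seq_len(M))
  colnames(geno) <- snp_id
  f <- colMeans(geno) / 2
  ## maf = realized sample MAF (matches the genotype matrix exactly);
  ## maf_pop = generating frequency, whose common fraction is exactly
  ## Binomial(M, fraction_common)
  snp_table <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                          gene_id = gene_id, maf = pmin(f, 1 - f),
                          maf_pop = maf, stringsAsFactors = FALSE)

  covariates <- data.frame(
    Age = pmin(pmax(round(stats::rnorm(n, 49, 12)), 18), 90),
    Sex = stats::rbinom(n, 1, 0.5),
    Smoke = stats::rbinom(n, 1, 0.3))

  genotype_study(geno, snp_table, covariates)
}

## resolve a causal-gene reference (index or id) to a gene id
resolve_gene <- function(g, gene_ids) {
  if (is.numeric(g)) {
    if (g < 1 || g > length(gene_ids)) stop("causal gene index out of range")
    return(gene_ids[g])
  }
  if (!g %in% gene_ids) stop("causal gene not present in study: ", g)
  g
}

#' Simulate phenotype replicates with known truth
#'
#' The genetic value of each causal gene is a linear combination of its
#' causal SNP counts — effect sizes constant or proportional to
#' `|log10(MAF)|` — rescaled so its empirical variance equals the gene's
#' normalized share of a unit total genetic variance. The covariate value
#' adds `age_beta * Age + sex_beta * Sex + smoke_beta * Smoke`. The residual
#' variance is then chosen so `Var(g) / Var(y) = h2` empirically. Each of
#' the `R` replicates redraws only the residual noise; the genetic and
#' covariate parts are fixed.
#'
#' @param study A [genotype_study()] (phenotypes ignored if present).
#' @param cfg The [sim_config()] describing causal structure (`seed + 1` is
#'   used for the phenotype stream so genotypes and phenotypes come from
#'   distinct streams).
#' @return The study with `phenotypes` (`n x R`, columns `rep1..repR`) and
#'   `truth` filled in: `causal_genes`, `causal_snps`, `covariates`
#'   (nonzero-effect names), `snp_effects` data frame, and the realized
#'   `h2`.
#' @export
simulate_phenotypes <- function(study, cfg) {
  stopifnot(inherits(study, "genotype_study"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- nrow(study$genotypes)
  st <- study$snp_table
  gene_ids <- unique(st$gene_id)

  g_val <- numeric(n)
  causal_genes <- character(0)
  eff <- data.frame(snp_id = character(0), gene_id = character(0),
                    effect = numeric(0), stringsAsFactors = FALSE)
  if (length(cfg$causal) > 0 && cfg$h2 > 0) {
    shares <- vapply(cfg$causal, function(cs) cs$share %||% 1, numeric(1))
    shares <- shares / sum(shares)
    for (i in seq_along(cfg$causal)) {
      cs <- cfg$causal[[i]]
      gid <- resolve_gene(cs$gene, gene_ids)
      ids <- st$snp_id[st$gene_id == gid]
      poly <- ids[st$maf[match(ids, st$snp_id)] > 0]
      if (length(poly) == 0L)
        stop("causal gene ", gid, " has no polymorphic SNP")
      k <- min(cs$n_causal %||% length(poly), length(poly))
      picked <- if (k == length(poly)) poly else sample(poly, k)
      rule <- cs$effect_rule %||% "constant"
      maf_p <- st$maf[match(picked, st$snp_id)]
      raw <- switch(rule,
                    constant = rep(1, k),
                    log_maf = abs(log10(maf_p)),
                    stop("unknown effect_rule: ", rule))
      gk <- as.numeric(study$genotypes[, picked, drop = FALSE] %*% raw)
      v <- stats::var(gk)
      if (v == 0) stop("causal gene ", gid, " has zero genetic variance")
      sc <- sqrt(shares[i] / v)
      g_val <- g_val + gk * sc
      causal_genes <- c(causal_genes, gid)
      eff <- rbind(eff, data.frame(snp_id = picked, gene_id = gid,
                                   effect = raw * sc,
                                   stringsAsFactors = FALSE))
    }
  }

  ce <- cfg$covariate_effects
  cov_val <- ce$age * study$covariates$Age + ce$sex * study$covariates$Sex +
    ce$smoke * study$covariates$Smoke
  v_g <- stats::var(g_val)
  if (v_g > 0) {
    sigma2_e <- v_g / cfg$h2 - stats::var(g_val + cov_val)
    if (sigma2_e <= 0)
      stop("covariate variance too large for target heritability h2 = ",
           cfg$h2)
  } else {
    sigma2_e <- 1
  }
  R <- cfg$n_replicates
  Y <- matrix(stats::rnorm(n * R, 0, sqrt(sigma2_e)), n, R) + g_val + cov_val
  colnames(Y) <- paste0("rep", seq_len(R))

  cov_truth <- c("Age", "Sex", "Smoke")[c(ce$age, ce$sex, ce$smoke) != 0]
  study$phenotypes <- Y
  study$truth <- list(causal_genes = causal_genes,
                      causal_snps = eff$snp_id,
                      covariates = cov_truth,
                      snp_effects = eff,
                      h2_realized = if (v_g > 0)
                        v_g / (stats::var(g_val + cov_val) + sigma2_e)
                      else 0)
  study
}

#' Simulate a complete study (genotypes + phenotypes + truth)
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_study()] with phenotypes and truth.
#' @export
simulate_study <- function(cfg) {
  simulate_phenotypes(simulate_genotypes(cfg), cfg)
}

#' The GAW17-mini preset
#'
#' A scaled-down study used throughout the test suite: 300 individuals, 150
#' genes (~1,150 SNPs with the GAW17 block-size and MAF spectrum), 20
#' phenotype replicates, residual heritability ~0.4, and three causal genes
#' with 11, 10 and 2 causal SNPs and descending genetic-variance shares
#' 0.6 / 0.3 / 0.1 — echoing the frequency ordering of the strong, middle
#' and weak causal genes of the motivating Q1 analysis. Age and Smoke carry
#' real effects (about 8% of phenotypic variance each), Sex does not. The
#' three causal genes are the three largest blocks so the causal-SNP counts
#' always fit.
#'
#' @param seed Integer seed.
#' @return A [genotype_study()] with phenotypes and truth; the config used
#'   is attached as attribute `"sim_config"`.
#' @export
gaw17_mini <- function(seed = 1L) {
  cfg <- sim_config(seed = seed, n_individuals = 300L, n_genes = 150L,
                    n_replicates = 20L, h2 = 0.4,
                    covariate_effects = list(age = 0.037, sex = 0,
                                             smoke = 0.98))
  study <- simulate_genotypes(cfg)
  lk <- table(factor(study$snp_table$gene_id,
                     levels = unique(study$snp_table$gene_id)))
  big3 <- names(sort(lk, decreasing = TRUE))[1:3]
  cfg$causal <- list(
    list(gene = big3[1], n_causal = 11L, share = 0.6, effect_rule = "log_maf"),
    list(gene = big3[2], n_causal = 10L, share = 0.3, effect_rule = "log_maf"),
    list(gene = big3[3], n_causal = 2L, share = 0.1, effect_rule = "log_maf"))
  study <- simulate_phenotypes(study, cfg)
  attr(study, "sim_config") <- cfg
  study
}

`%||%` <- function(x, y) if (is.null(x)) y else x
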