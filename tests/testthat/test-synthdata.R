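mini_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_individuals = 120, n_genes = 30,
             n_replicates = 3, ...)
}

test_that("simulate_genotypes: shapes, count values, reproducibility", {
  cfg <- mini_cfg()
  st <- simulate_genotypes(cfg)
  expect_s3_class(st, "genotype_study")
  expect_identical(nrow(st$genotypes), 120L)
  expect_identical(length(unique(st$snp_table$gene_id)), 30L)
  expect_true(all(st$genotypes %in% c(0, 1, 2)))
  expect_true(all(st$snp_table$pos >= 1))
  # block sizes hover around the configured mean
  lk <- table(st$snp_table$gene_id)
  expect_gt(mean(lk), 4)
  expect_lt(mean(lk), 12)
  # reproducible from seed; different seed differs
  st2 <- simulate_genotypes(mini_cfg())
  expect_identical(st, st2)
  st3 <- simulate_genotypes(mini_cfg(seed = 2))
  expect_false(identical(st$genotypes, st3$genotypes))
})

test_that("MAF spectrum: common fraction within 3 SE of its target", {
  # maf_pop is the generating frequency, so the common count is exactly
  # Binomial(M, fraction_common); pool 5 seeds
  p <- 0.1279
  hits <- 0; M <- 0
  for (s in 1:5) {
    st <- simulate_genotypes(mini_cfg(seed = s))
    hits <- hits + sum(st$snp_table$maf_pop >= 0.05)
    M <- M + nrow(st$snp_table)
  }
  se <- sqrt(p * (1 - p) / M)
  expect_lt(abs(hits / M - p), 3 * se)
  # and the realized sample MAF matrix matches the stored maf column
  f <- colMeans(st$genotypes) / 2
  expect_equal(unname(pmin(f, 1 - f)), st$snp_table$maf, tolerance = 1e-14)
})

test_that("ld_rho induces within-gene genotype correlation", {
  st0 <- simulate_genotypes(mini_cfg(seed = 3, ld_rho = 0,
                                     maf_model = list(fraction_common = 1,
                                                      rare_range = c(7e-4, 0.05),
                                                      common_range = c(0.2, 0.4))))
  st1 <- simulate_genotypes(mini_cfg(seed = 3, ld_rho = 0.8,
                                     maf_model = list(fraction_common = 1,
                                                      rare_range = c(7e-4, 0.05),
                                                      common_range = c(0.2, 0.4))))
  within_cor <- function(st) {
    g1 <- st$snp_table$snp_id[st$snp_table$gene_id == st$snp_table$gene_id[1]]
    if (length(g1) < 2) return(0)
    C <- cor(st$genotypes[, g1])
    mean(C[upper.tri(C)])
  }
  expect_gt(within_cor(st1), within_cor(st0) + 0.2)
})

test_that("phenotypes: variance calibration, fixed genetic part, truth round-trip", {
  cfg <- sim_config(seed = 5, n_individuals = 120, n_genes = 30,
                    n_replicates = 30, h2 = 0.35,
                  causal = list(list(gene = 1, n_causal = 3, share = 1,
                                     effect_rule = "constant")),
                  covariate_effects = list(age = 0.02, sex = 0, smoke = 0.5))
  study <- simulate_study(cfg)
  tr <- study$truth
  expect_identical(length(tr$causal_genes), 1L)
  expect_identical(sort(unique(tr$snp_effects$gene_id)), tr$causal_genes)
  expect_identical(tr$covariates, c("Age", "Smoke"))
  # rebuild g from the stored effect table: realized h2 within 0.05 of target
  g <- as.numeric(study$genotypes[, tr$snp_effects$snp_id, drop = FALSE] %*%
                    tr$snp_effects$effect)
  ratio <- var(g) / mean(apply(study$phenotypes, 2, var))
  expect_lt(abs(ratio - 0.35), 0.05)
  # replicates share the genetic+covariate part: between-replicate
  # differences are pure noise, uncorrelated with g
  d <- study$phenotypes[, 2] - study$phenotypes[, 1]
  expect_lt(abs(cor(d, g)), 0.25)
  # truth -> confusion_rates(selected = truth) is a perfect score
  expect_equal(confusion_rates(tr$causal_genes, tr$causal_genes,
                               30, "discovery"),
               c(fpr = 0, fnr = 0))
})

test_that("h2 = 0 yields a phenotype independent of the genotypes", {
  cfg <- mini_cfg(seed = 6, h2 = 0,
                  covariate_effects = list(age = 0, sex = 0, smoke = 0))
  study <- simulate_study(cfg)
  expect_identical(length(study$truth$causal_genes), 0L)
  poly <- which(apply(study$genotypes, 2, sd) > 0)[1:20]
  cors <- abs(cor(study$phenotypes[, 1], study$genotypes[, poly]))
  expect_lt(max(cors), 4.5 / sqrt(120))    # ~ Bonferroni bound for 20 nulls
})

test_that("invalid configurations are rejected by field", {
  expect_error(sim_config(h2 = 1), "h2")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(n_replicates = 1), "n_replicates")
  cfg <- mini_cfg(causal = list(list(gene = "NOPE", n_causal = 2, share = 1)))
  expect_error(simulate_study(cfg), "NOPE")
})

test_that("the GAW17-mini preset has the documented structure", {
  study <- gaw17_mini(seed = 2)
  cfg <- attr(study, "sim_config")
  expect_identical(nrow(study$genotypes), 300L)
  expect_identical(length(unique(study$snp_table$gene_id)), 150L)
  expect_identical(ncol(study$phenotypes), 20L)
  expect_identical(length(study$truth$causal_genes), 3L)
  ncs <- table(factor(study$truth$snp_effects$gene_id,
                      levels = study$truth$causal_genes))
  expect_identical(as.integer(ncs), c(11L, 10L, 2L))
  expect_identical(study$truth$covariates, c("Age", "Smoke"))
  expect_identical(gaw17_mini(seed = 2)$phenotypes, study$phenotypes)
})
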