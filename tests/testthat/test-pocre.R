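test_that("gene_block validates counts and ids", {
  x <- matrix(c(0, 1, 2, 1), 2)
  expect_s3_class(gene_block("g", c("s1", "s2"), x), "gene_block")
  expect_error(gene_block("g", c("s1", "s1"), x), "unique")
  expect_error(gene_block("g", c("s1", "s2"), x + 0.5), "0, 1, 2")
  expect_error(gene_block("g", "s1", matrix(numeric(0), 2, 0)), "at least one")
})

test_that("a single strong SNP is recovered with an OLS-accurate slope", {
  set.seed(4)
  x <- matrix(rbinom(500, 2, 0.3), ncol = 1)
  blk <- gene_block("g1", "s1", x)
  y <- 1.0 * x[, 1] + rnorm(500, 0, 0.2)
  m <- pocre_fit(blk, y)
  expect_identical(m$n_components, 1L)
  expect_equal(abs(unname(m$components[[1]]$loading)), 1)
  expect_equal(unname(m$snp_coefficients), 1.0, tolerance = 0.1)
  # and the marker on training data equals the component contribution
  mk <- gene_marker(m, blk$x)
  expect_equal(mk, m$components[[1]]$coef * m$components[[1]]$scores,
               tolerance = 1e-8)
})

test_that("components are orthogonal with unit loadings and a consistent linear map", {
  set.seed(21)
  for (rep in 1:10) {
    l <- sample(3:15, 1)
    blk <- random_block(250, l)
    beta <- rnorm(l) * rbinom(l, 1, 0.5)
    y <- as.numeric(blk$x %*% beta) + rnorm(250)
    m <- pocre_fit(blk, y)
    if (m$n_components >= 1) {
      for (cm in m$components)
        expect_equal(sum(cm$loading^2), 1, tolerance = 1e-10)
      if (m$n_components >= 2) {
        S <- sapply(m$components, `[[`, "scores")
        G <- crossprod(S)
        nrm <- sqrt(diag(G))
        C <- G / tcrossprod(nrm)
        expect_lt(max(abs(C[upper.tri(C)])), 1e-8)
      }
      fitted1 <- gene_marker(m, blk$x)
      fitted2 <- Reduce(`+`, lapply(m$components,
                                    function(cm) cm$coef * cm$scores))
      expect_equal(fitted1, fitted2, tolerance = 1e-8)
    }
  }
})

test_that("pure-noise blocks yield no components in nearly all seeded runs", {
  empty <- 0L
  for (s in 1:20) {
    set.seed(100 + s)
    blk <- random_block(300, 7, maf = rep(0.1, 7))
    m <- pocre_fit(blk, rnorm(300))
    empty <- empty + (m$n_components == 0L)
  }
  expect_gte(empty, 18L)
})

test_that("gene_marker honours emptiness, linearity and sparsity of the loading", {
  set.seed(22)
  blk <- random_block(200, 4)
  # empty model -> zero marker
  empty_model <- pocre_fit(blk, rnorm(200))
  if (empty_model$n_components == 0L)
    expect_identical(gene_marker(empty_model, blk$x), numeric(200))
  # strong signal on snp 1 only
  y <- 2 * blk$x[, 1] + rnorm(200, 0, 0.3)
  m <- pocre_fit(blk, y)
  expect_gte(m$n_components, 1L)
  zero_cols <- which(m$snp_coefficients == 0)
  nz_cols <- which(m$snp_coefficients != 0)
  base <- gene_marker(m, blk$x)
  if (length(zero_cols) > 0) {
    x2 <- blk$x
    x2[, zero_cols[1]] <- 2 * x2[, zero_cols[1]]
    expect_equal(gene_marker(m, x2), base)
  }
  x3 <- blk$x
  x3[, nz_cols[1]] <- 2 * x3[, nz_cols[1]]
  expect_false(isTRUE(all.equal(gene_marker(m, x3), base)))
  # SNP mismatch is named
  x4 <- blk$x
  colnames(x4) <- paste0("other", 1:4)
  expect_error(gene_marker(m, x4), "mismatch")
})

test_that("markers overfit the training replicate relative to a fresh one", {
  set.seed(23)
  r2 <- function(mk, y) if (sd(mk) == 0) 0 else cor(mk, y)^2
  gain <- replicate(10, {
    blk <- random_block(150, 8)
    beta <- c(0.3, 0.3, rep(0, 6))
    g <- as.numeric(blk$x %*% beta)
    y_train <- g + rnorm(150)
    y_new <- g + rnorm(150)
    m <- pocre_fit(blk, y_train)
    mk <- gene_marker(m, blk$x)
    r2(mk, y_train) - r2(mk, y_new)
  })
  expect_gt(mean(gain), 0)
})

test_that("coalesce_all maps genes independently and deterministically", {
  set.seed(24)
  study <- build_study(250, list(rep(0.2, 5), rep(0.1, 4), 0.3),
                       phenotype_fun = function(g, covs)
                         1.2 * g[, 1] + rnorm(250))
  models <- coalesce_all(study, study$phenotypes[, 1])
  expect_named(models, c("g1", "g2", "g3"))
  expect_gte(models$g1$n_components, 1L)
  expect_true("snp1" %in%
                names(which(models$g1$snp_coefficients != 0)))
  # single-SNP gene handled (select-or-drop)
  expect_identical(length(models$g3$snp_ids), 1L)
  # deterministic
  models2 <- coalesce_all(study, study$phenotypes[, 1])
  expect_identical(models, models2)
  # unmapped SNPs are dropped with a message
  study2 <- study
  study2$snp_table$gene_id[10] <- ""
  expect_message(m3 <- coalesce_all(study2, study2$phenotypes[, 1]),
                 "without gene assignment")
  expect_false("g3" %in% names(m3))   # its only SNP became unmapped
  expect_named(m3, c("g1", "g2"))
})
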