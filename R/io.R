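#' Read a PLINK `.raw`-style additive genotype file
#'
#' Whitespace-delimited text with a header row; the standard PLINK leading
#' columns (FID IID PAT MAT SEX PHENOTYPE), or a minimal id-only dialect
#' (first column named FID/IID/ID), are skipped; every remaining column is
#' a SNP with 0/1/2 minor-allele counts or `NA`.
#'
#' @param path File path.
#' @param missing_policy `"mean"` (default): replace `NA` with the SNP's
#'   mean count rounded to the nearest of 0/1/2; `"fail"`: error on any
#'   missing genotype.
#' @return List with `genotypes` (integer matrix, SNP ids as column names,
#'   the PLINK `_allele` suffix stripped), `snp_ids`, `sample_ids`,
#'   `n_imputed`.
#' @export
read_raw_genotypes <- function(path, missing_policy = c("mean", "fail")) {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty file: ", path)
  split_ws <- function(x) strsplit(trimws(x), "[ \t]+")[[1]]
  header <- split_ws(lines[1])
  lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  n_lead <- 0L
  while (n_lead < length(header) && header[n_lead + 1L] %in% lead)
    n_lead <- n_lead + 1L
  if (n_lead == 0L && header[1] %in% c("ID", "id"))
    n_lead <- 1L
  snp_cols <- header[seq_len(length(header) - n_lead) + n_lead]
  snp_ids <- sub("_[ACGT0-9]+$", "", snp_cols)
  p <- length(snp_ids)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  n <- length(body)
  geno <- matrix(NA_real_, n, p)
  sample_ids <- character(n)
  for (i in seq_len(n)) {
    tok <- split_ws(body[i])
    if (length(tok) != n_lead + p)
      stop("ragged row at line ", i + 1L, ": expected ", n_lead + p,
           " fields, found ", length(tok))
    sample_ids[i] <- if (n_lead > 0) tok[min(n_lead, 2L)] else as.character(i)
    g <- tok[seq_len(p) + n_lead]
    ok <- g %in% c("0", "1", "2", "NA")
    if (!all(ok)) {
      j <- which(!ok)[1]
      stop("invalid genotype token \"", g[j], "\" at line ", i + 1L,
           ", SNP column ", snp_ids[j])
    }
    geno[i, ] <- suppressWarnings(as.numeric(g))
  }
  n_imputed <- sum(is.na(geno))
  if (n_imputed > 0) {
    if (missing_policy == "fail")
      stop(n_imputed, " missing genotype(s) with missing_policy = \"fail\"")
    for (j in which(colSums(is.na(geno)) > 0)) {
      v <- geno[, j]
      fill <- if (all(is.na(v))) 0 else min(max(round(mean(v, na.rm = TRUE)), 0), 2)
      geno[is.na(v), j] <- fill
    }
  }
  storage.mode(geno) <- "integer"
  colnames(geno) <- snp_ids
  list(genotypes = geno, snp_ids = snp_ids, sample_ids = sample_ids,
       n_imputed = n_imputed)
}

#' Write genotypes in PLINK `.raw`-style additive coding
#'
#' @param genotypes 0/1/2 matrix with SNP ids as column names.
#' @param path Output path.
#' @param sample_ids Optional individual ids (default `ind1..indn`).
#' @export
write_raw_genotypes <- function(genotypes, path, sample_ids = NULL) {
  n <- nrow(genotypes)
  if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_len(n))
  header <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
              colnames(genotypes))
  body <- cbind(sample_ids, sample_ids, "0", "0", "0", "-9",
                matrix(as.character(genotypes), n))
  writeLines(c(paste(header, collapse = " "),
               apply(body, 1, paste, collapse = " ")), path)
  invisible(path)
}

#' Read a SNP-to-gene map
#'
#' Tab-separated with columns `snp_id`, `chrom`, `pos`, `gene_id` (and any
#' extras, e.g. `maf`). Positions are 1-based; chromosomes are strings.
#' SNPs with an empty `gene_id` are allowed (they are dropped from
#' coalescing downstream, with a log message).
#'
#' @param path File path.
#' @return Data frame validated for column presence and `snp_id`
#'   uniqueness.
#' @export
read_gene_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  need <- c("snp_id", "chrom", "pos", "gene_id")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("gene map is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$snp_id))
    stop("duplicate snp_id in gene map: ",
         paste(unique(tab$snp_id[duplicated(tab$snp_id)]), collapse = ", "))
  if (any(tab$pos < 1)) stop("positions must be 1-based (>= 1)")
  tab$gene_id[is.na(tab$gene_id)] <- ""
  n_unmapped <- sum(tab$gene_id == "")
  if (n_unmapped > 0)
    message(n_unmapped, " SNP(s) have no gene assignment")
  tab
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated study as plain-text files
#'
#' Files written to `dir`: `genotypes.raw` (PLINK-style additive),
#' `gene_map.tsv`, `phenotypes.tsv` (one column per replicate),
#' `covariates.tsv`, and when truth is present `truth_genes.tsv`,
#' `truth_snps.tsv`, `truth_covariates.tsv`.
#'
#' @param study A [genotype_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "genotype_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_raw_genotypes(study$genotypes, file.path(dir, "genotypes.raw"))
  write_tsv(study$snp_table, file.path(dir, "gene_map.tsv"))
  write_tsv(as.data.frame(study$covariates), file.path(dir, "covariates.tsv"))
  if (!is.null(study$phenotypes))
    write_tsv(as.data.frame(study$phenotypes), file.path(dir, "phenotypes.tsv"))
  if (!is.null(study$truth)) {
    write_tsv(data.frame(gene_id = study$truth$causal_genes),
              file.path(dir, "truth_genes.tsv"))
    write_tsv(study$truth$snp_effects, file.path(dir, "truth_snps.tsv"))
    write_tsv(data.frame(covariate = study$truth$covariates),
              file.path(dir, "truth_covariates.tsv"))
  }
  invisible(dir)
}

#' Read a study written by [write_study()]
#'
#' @param dir Directory containing the study files.
#' @param missing_policy Passed to [read_raw_genotypes()].
#' @return A [genotype_study()].
#' @export
read_study <- function(dir, missing_policy = "mean") {
  raw <- read_raw_genotypes(file.path(dir, "genotypes.raw"), missing_policy)
  map <- read_gene_map(file.path(dir, "gene_map.tsv"))
  if (!identical(map$snp_id, raw$snp_ids))
    stop("gene map SNP ids do not match genotype columns")
  if (is.null(map$maf)) {
    f <- colMeans(raw$genotypes) / 2
    map$maf <- pmin(f, 1 - f)
  }
  covs <- utils::read.delim(file.path(dir, "covariates.tsv"))
  phen_path <- file.path(dir, "phenotypes.tsv")
  phen <- if (file.exists(phen_path))
    as.matrix(utils::read.delim(phen_path)) else NULL
  truth <- NULL
  tg <- file.path(dir, "truth_genes.tsv")
  if (file.exists(tg)) {
    genes <- utils::read.delim(tg, colClasses = "character")
    snps <- utils::read.delim(file.path(dir, "truth_snps.tsv"),
                              stringsAsFactors = FALSE)
    covt <- utils::read.delim(file.path(dir, "truth_covariates.tsv"),
                              colClasses = "character")
    truth <- list(causal_genes = genes$gene_id, causal_snps = snps$snp_id,
                  covariates = covt$covariate, snp_effects = snps)
  }
  genotype_study(raw$genotypes, map, covs, phen, truth)
}

#' Serialize POCRE models as a coefficient table
#'
#' Long format `(gene_id, snp_id, coefficient)` plus a per-gene component
#' count table; [read_pocre_models()] round-trips the collapsed coefficient
#' vectors (component score vectors are training-data artifacts and are not
#' stored).
#'
#' @param models Named list of `pocre_model`.
#' @param path Output TSV path (the component-count table goes to
#'   `<path>.ncomp`).
#' @export
write_pocre_models <- function(models, path) {
  coefs <- do.call(rbind, lapply(models, function(m)
    data.frame(gene_id = m$gene_id, snp_id = m$snp_ids,
               coefficient = unname(m$snp_coefficients),
               center = unname(m$centers))))
  write_tsv(coefs, path)
  ncomp <- data.frame(gene_id = names(models),
                      n_components = vapply(models, `[[`, integer(1),
                                            "n_components"))
  write_tsv(ncomp, paste0(path, ".ncomp"))
  invisible(path)
}

#' @rdname write_pocre_models
#' @param path Path written by `write_pocre_models`.
#' @return Named list of `pocre_model` (without component score vectors).
#' @export
read_pocre_models <- function(path) {
  coefs <- utils::read.delim(path, stringsAsFactors = FALSE)
  ncomp <- utils::read.delim(paste0(path, ".ncomp"), stringsAsFactors = FALSE)
  sp <- split(coefs, factor(coefs$gene_id, levels = unique(coefs$gene_id)))
  models <- lapply(sp, function(d) {
    g <- d$gene_id[1]
    structure(list(gene_id = g, snp_ids = d$snp_id, components = NULL,
                   snp_coefficients = stats::setNames(d$coefficient, d$snp_id),
                   n_components = ncomp$n_components[ncomp$gene_id == g],
                   centers = stats::setNames(d$center, d$snp_id)),
              class = "pocre_model")
  })
  names(models) <- vapply(models, `[[`, character(1), "gene_id")
  models
}

#' Write the aggregated study reports
#'
#' Tab-separated outputs: `selections.tsv` (one row per replicate and
#' selected predictor), `gene_frequency.tsv` (Table-1 shape),
#' `snp_frequency.tsv` (frequency by chromosomal position) and, when truth
#' was available, `rates.tsv` / `rate_summary.tsv`.
#'
#' @param summary A [run_study()] result.
#' @param dir Output directory.
#' @export
write_reports <- function(summary, dir) {
  stopifnot(inherits(summary, "replicate_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sel <- do.call(rbind, lapply(summary$results, function(res) {
    if (nrow(res$coefficients) == 0L) return(NULL)
    cbind(replicate = res$replicate_id, res$coefficients)
  }))
  if (is.null(sel))
    sel <- data.frame(replicate = integer(0), predictor = character(0),
                      estimate = numeric(0), kind = character(0))
  write_tsv(sel, file.path(dir, "selections.tsv"))
  write_tsv(summary$gene_table, file.path(dir, "gene_frequency.tsv"))
  write_tsv(summary$snp_table, file.path(dir, "snp_frequency.tsv"))
  if (!is.null(summary$rates)) {
    write_tsv(summary$rates, file.path(dir, "rates.tsv"))
    write_tsv(summary$rate_summary, file.path(dir, "rate_summary.tsv"))
  }
  invisible(dir)
}
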