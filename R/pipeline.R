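#' False-positive / false-negative rates for a selection
#'
#' Two conventions are provided because published rare-variant analyses
#' rarely print the formula. `"discovery"` (default): the false-positive
#' rate is the false-discovery proportion `|selected \ truth| /
#' max(|selected|, 1)` and the false-negative rate is the number of missed
#' causal items over the whole universe. `"classical"`: false positives
#' over the non-causal universe, false negatives over the causal set.
#'
#' @param selected Character/integer vector of selected item ids.
#' @param truth Vector of causal item ids (subset of the universe).
#' @param universe_size Number of items that could have been selected.
#' @param convention `"discovery"` or `"classical"`.
#' @return Named numeric `c(fpr=, fnr=)`.
#' @export
confusion_rates <- function(selected, truth, universe_size,
                            convention = c("discovery", "classical")) {
  convention <- match.arg(convention)
  if (universe_size < length(unique(truth)))
    stop("universe_size smaller than the truth set")
  selected <- unique(selected)
  truth <- unique(truth)
  fp <- length(setdiff(selected, truth))
  fn <- length(setdiff(truth, selected))
  if (convention == "discovery") {
    c(fpr = fp / max(length(selected), 1), fnr = fn / universe_size)
  } else {
    c(fpr = if (universe_size > length(truth))
        fp / (universe_size - length(truth)) else 0,
      fnr = if (length(truth) > 0) fn / length(truth) else 0)
  }
}

#' Pipeline options
#'
#' @param training_replicate Column of the phenotype matrix used to train
#'   the POCRE gene markers (default 1); all other replicates are evaluated.
#' @param pocre A [pocre_control()].
#' @param ebvs An [ebvs_control()].
#' @param min_frequency Minimum selection frequency for [frequency_table()].
#' @param convention Rate convention for [confusion_rates()].
#' @param allow_same_replicate Permit evaluating the training replicate
#'   (overfitting guard off).
#' @param exempt_covariates Exclude the covariate columns from penalization.
#' @return A list of class `"pipeline_control"`.
#' @export
pipeline_control <- function(training_replicate = 1L,
                             pocre = pocre_control(),
                             ebvs = ebvs_control(),
                             min_frequency = 5L,
                             convention = "discovery",
                             allow_same_replicate = FALSE,
                             exempt_covariates = FALSE) {
  structure(list(training_replicate = as.integer(training_replicate),
                 pocre = pocre, ebvs = ebvs,
                 min_frequency = as.integer(min_frequency),
                 convention = convention,
                 allow_same_replicate = allow_same_replicate,
                 exempt_covariates = exempt_covariates),
            class = "pipeline_control")
}

## gene markers for every nonempty POCRE model, as an n x K matrix
marker_matrix <- function(study, models) {
  nonempty <- vapply(models, function(m) m$n_components > 0L, logical(1))
  keep <- names(models)[nonempty]
  if (length(keep) == 0L)
    return(matrix(numeric(0), nrow(study$genotypes), 0))
  mk <- vapply(keep, function(g) {
    m <- models[[g]]
    gene_marker(m, study$genotypes[, m$snp_ids, drop = FALSE])
  }, numeric(nrow(study$genotypes)))
  colnames(mk) <- keep
  mk
}

#' Select genes and covariates on one evaluation replicate
#'
#' Builds the design `[Age, Sex, Smoke | gene markers]` from POCRE models
#' trained on a *different* replicate, standardizes it, runs [ebvs_fit()] on
#' the replicate's phenotype, back-maps each selected gene to the SNPs with
#' nonzero POCRE coefficients, and refits OLS on the selected predictors
#' for the reported effect sizes.
#'
#' @param study A [genotype_study()] with phenotypes.
#' @param replicate_id Phenotype column to analyse.
#' @param models Named list of POCRE models (from [coalesce_all()]).
#' @param control A [pipeline_control()]; `training_replicate` must differ
#'   from `replicate_id` unless `allow_same_replicate`.
#' @param markers Optional precomputed [marker_matrix] (internal reuse).
#' @return An object of class `"selection_result"`.
#' @export
run_replicate <- function(study, replicate_id, models,
                          control = pipeline_control(), markers = NULL) {
  stopifnot(inherits(study, "genotype_study"), !is.null(study$phenotypes))
  replicate_id <- as.integer(replicate_id)
  if (replicate_id == control$training_replicate &&
      !control$allow_same_replicate)
    stop("evaluation replicate equals the training replicate; ",
         "markers would be overfit (set allow_same_replicate to override)")
  if (is.null(markers)) markers <- marker_matrix(study, models)
  covs <- as.matrix(study$covariates[, c("Age", "Sex", "Smoke")])
  raw <- cbind(covs, markers)
  kind <- c(rep("covariate", ncol(covs)), rep("gene_marker", ncol(markers)))
  ## drop degenerate columns (e.g. zero markers, constant covariate)
  ok <- apply(raw, 2, function(v) stats::sd(v) > 0)
  raw <- raw[, ok, drop = FALSE]
  kind <- kind[ok]
  design <- prepare_design(raw, kind)
  ebc <- control$ebvs
  if (control$exempt_covariates)
    ebc$unpenalized <- which(kind == "covariate")
  y <- study$phenotypes[, replicate_id]
  fit <- ebvs_fit(design, y, ebc)

  sel_names <- design$names[fit$selected]
  sel_genes <- sel_names[design$kind[fit$selected] == "gene_marker"]
  sel_covs <- sel_names[design$kind[fit$selected] == "covariate"]
  sel_snps <- unlist(lapply(sel_genes, function(g) {
    m <- models[[g]]
    m$snp_ids[m$snp_coefficients != 0]
  }), use.names = FALSE)
  coef_tab <- refit_unpenalized(raw, y, fit$selected)
  coef_tab$kind <- design$kind[match(coef_tab$predictor, design$names)]

  structure(list(replicate_id = replicate_id,
                 selected_genes = sel_genes,
                 selected_covariates = sel_covs,
                 selected_snps = as.character(sel_snps %||% character(0)),
                 coefficients = coef_tab,
                 diagnostics = list(n_iter = fit$n_iter,
                                    converged = fit$converged,
                                    w = fit$prior$w, a = fit$prior$a,
                                    sigma = fit$sigma)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result (replicate %d): %d gene(s), %d covariate(s), %d SNP(s)\n",
              x$replicate_id, length(x$selected_genes),
              length(x$selected_covariates), length(x$selected_snps)))
  invisible(x)
}

#' Frequency table of selected predictors across replicates
#'
#' Predictors selected in at least `min_frequency` replicates, with the
#' mean and SD of their (OLS-refit) estimates over the replicates where
#' they were selected, sorted by frequency (descending) then name. SD is
#' `NA` when a predictor was selected only once.
#'
#' @param results List of [run_replicate()] results.
#' @param min_frequency Minimum number of replicates.
#' @return Data frame `(predictor, kind, mean_estimate, sd_estimate,
#'   frequency)`.
#' @export
frequency_table <- function(results, min_frequency = 5L) {
  if (length(results) == 0L) stop("need at least one selection result")
  all_coef <- do.call(rbind, lapply(results, `[[`, "coefficients"))
  if (is.null(all_coef) || nrow(all_coef) == 0L)
    return(data.frame(predictor = character(0), kind = character(0),
                      mean_estimate = numeric(0), sd_estimate = numeric(0),
                      frequency = integer(0)))
  sp <- split(all_coef, all_coef$predictor)
  tab <- do.call(rbind, lapply(sp, function(d) {
    data.frame(predictor = d$predictor[1], kind = d$kind[1],
               mean_estimate = mean(d$estimate),
               sd_estimate = if (nrow(d) > 1) stats::sd(d$estimate) else NA_real_,
               frequency = nrow(d))
  }))
  tab <- tab[tab$frequency >= min_frequency, , drop = FALSE]
  tab <- tab[order(-tab$frequency, tab$predictor), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

## per-SNP selection frequency with chromosomal position (figure data)
snp_frequency_table <- function(results, snp_table, min_frequency = 1L) {
  counts <- table(unlist(lapply(results, `[[`, "selected_snps")))
  if (length(counts) == 0L)
    return(data.frame(snp_id = character(0), chrom = character(0),
                      pos = integer(0), gene_id = character(0),
                      frequency = integer(0)))
  keep <- counts[counts >= min_frequency]
  i <- match(names(keep), snp_table$snp_id)
  out <- data.frame(snp_id = names(keep), chrom = snp_table$chrom[i],
                    pos = snp_table$pos[i], gene_id = snp_table$gene_id[i],
                    frequency = as.integer(keep),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Run the full study: train, evaluate all replicates, aggregate
#'
#' Trains POCRE on the configured training replicate, evaluates every other
#' replicate with [run_replicate()], and aggregates selections into
#' frequency tables and (when truth is available) per-replicate gene- and
#' SNP-level false-positive/false-negative rates with their mean and SD.
#' Deterministic given the study and control.
#'
#' @param study A [genotype_study()] with `R >= 2` phenotype replicates.
#' @param control A [pipeline_control()].
#' @return An object of class `"replicate_summary"`: `results` (list of
#'   selection_result), `models`, `gene_table`, `snp_table` (frequency by
#'   position), `rates` (per-replicate data frame) and `rate_summary`
#'   (mean/sd per level and convention), `convention`, `n_evaluated`.
#' @export
run_study <- function(study, control = pipeline_control()) {
  stopifnot(inherits(study, "genotype_study"), !is.null(study$phenotypes))
  R <- ncol(study$phenotypes)
  tr <- control$training_replicate
  if (R < 2 && !control$allow_same_replicate)
    stop("need at least 2 replicates (one to train, one to evaluate)")
  if (tr < 1 || tr > R) stop("training_replicate out of range")
  models <- coalesce_all(study, study$phenotypes[, tr], control$pocre)
  markers <- marker_matrix(study, models)
  eval_ids <- if (control$allow_same_replicate && R == 1) 1L
              else setdiff(seq_len(R), tr)
  results <- lapply(eval_ids, function(r)
    run_replicate(study, r, models, control, markers = markers))

  gene_tab <- frequency_table(results, control$min_frequency)
  snp_tab <- snp_frequency_table(results, study$snp_table)

  rates <- NULL
  rate_summary <- NULL
  if (!is.null(study$truth)) {
    n_genes <- length(unique(study$snp_table$gene_id))
    n_snps <- nrow(study$snp_table)
    rates <- do.call(rbind, lapply(results, function(res) {
      gr <- confusion_rates(res$selected_genes, study$truth$causal_genes,
                            n_genes, control$convention)
      sr <- confusion_rates(res$selected_snps, study$truth$causal_snps,
                            n_snps, control$convention)
      data.frame(replicate = res$replicate_id,
                 gene_fpr = gr["fpr"], gene_fnr = gr["fnr"],
                 snp_fpr = sr["fpr"], snp_fnr = sr["fnr"],
                 row.names = NULL)
    }))
    rate_summary <- data.frame(
      level = c("gene", "gene", "snp", "snp"),
      rate = c("fpr", "fnr", "fpr", "fnr"),
      mean = c(mean(rates$gene_fpr), mean(rates$gene_fnr),
               mean(rates$snp_fpr), mean(rates$snp_fnr)),
      sd = c(stats::sd(rates$gene_fpr), stats::sd(rates$gene_fnr),
             stats::sd(rates$snp_fpr), stats::sd(rates$snp_fnr)))
  }

  structure(list(results = results, models = models,
                 gene_table = gene_tab, snp_table = snp_tab,
                 rates = rates, rate_summary = rate_summary,
                 convention = control$convention,
                 training_replicate = tr,
                 n_evaluated = length(eval_ids)),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("replicate_summary: %d replicate(s) evaluated (training = %d)\n",
              x$n_evaluated, x$training_replicate))
  cat("Predictors selected at least", min(c(x$gene_table$frequency, Inf)),
      "time(s):\n")
  print(utils::head(x$gene_table, 15))
  if (!is.null(x$rate_summary)) {
    cat(sprintf("Error rates (%s convention):\n", x$convention))
    print(x$rate_summary)
  }
  invisible(x)
}
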