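#' Parameters of the synthetic pharmacogenomic world
#'
#' The generator emulates the structure the screen assumes: expression is
#' driven by latent transcriptional programs shared between cell lines and
#' tumors; drug response is driven by the same programs through per-drug
#' couplings.  One program is the "SOC resistance program": SOC drugs couple
#' to it positively (active program = higher SOC log-IC50 = resistant),
#' planted candidate drugs couple negatively (active program = more
#' sensitive), and all remaining drugs are null (no coupling to any
#' program, pure measurement noise).  Platforms re-observe the same tumors
#' through an affine shift/scale, a random gene subset and extra noise.
#'
#' Gene loadings on their program are half-normal (single-signed), so a
#' program's gene set behaves like a coherently activated pathway.
#'
#' @param n_programs Number of latent programs; genes are split evenly
#'   across programs (program 1 is the resistance program).
#' @param loading_sd Root-mean-square gene loading on its program.
#' @param noise_sd_expression SD of gene-level expression noise.
#' @param noise_sd_response SD of drug response noise (log-IC50 units).
#' @param beta_soc Coupling of SOC drugs to the resistance program.
#' @param beta_candidate Coupling of planted candidate drugs (negative).
#' @param n_candidates Number of planted candidate drugs.
#' @param platform_effects Named list of per-platform effects, each a list
#'   with `shift`, `scale`, `gene_subset_fraction`, `noise_sd`.
#' @param auc_midpoint,auc_range,auc_noise_sd Parameters of the monotone
#'   logistic link mapping true log-IC50 to measured AUC (higher AUC = more
#'   resistant) and of its measurement noise.
#' @return Named list of class `TruthParams`.
#' @export
synthetic_truth_params <- function(n_programs = 10,
                                   loading_sd = 0.2,
                                   noise_sd_expression = 0.5,
                                   noise_sd_response = 0.5,
                                   beta_soc = 1,
                                   beta_candidate = -1,
                                   n_candidates = 5,
                                   platform_effects = default_platform_effects(2),
                                   auc_midpoint = 8,
                                   auc_range = 8,
                                   auc_noise_sd = 0.5) {
  stopifnot(n_programs >= 1, loading_sd > 0, n_candidates >= 1,
            beta_candidate <= 0, beta_soc >= 0)
  structure(list(
    n_programs = as.integer(n_programs),
    loading_sd = loading_sd,
    noise_sd_expression = noise_sd_expression,
    noise_sd_response = noise_sd_response,
    beta_soc = beta_soc,
    beta_candidate = beta_candidate,
    n_candidates = as.integer(n_candidates),
    platform_effects = platform_effects,
    auc_midpoint = auc_midpoint,
    auc_range = auc_range,
    auc_noise_sd = auc_noise_sd
  ), class = "TruthParams")
}

#' Default platform effect sets
#'
#' Affine shift/scale, gene-subset and extra-noise settings emulating two
#' microarray platforms and two RNA-seq pipelines re-profiling one cohort.
#'
#' @param n Number of platforms (1 to 4).
#' @return Named list of per-platform effect lists.
#' @export
default_platform_effects <- function(n = 2) {
  all <- list(
    affymetrix = list(shift = 0.3, scale = 1.1, gene_subset_fraction = 0.7,
                      noise_sd = 1.0),
    agilent = list(shift = -0.2, scale = 0.9, gene_subset_fraction = 0.7,
                   noise_sd = 1.0),
    rnaseq = list(shift = 0.5, scale = 1.2, gene_subset_fraction = 0.8,
                  noise_sd = 1.0),
    rnaseq_v2 = list(shift = 0.1, scale = 1.0, gene_subset_fraction = 0.8,
                     noise_sd = 1.0)
  )
  stopifnot(n >= 1, n <= length(all))
  all[seq_len(n)]
}

.program_of_gene <- function(n_genes, n_programs) {
  rep_len(seq_len(n_programs), n_genes)
}

#' Generate a synthetic cell-line training panel
#'
#' Expression is `loadings %*% t(activity) + noise`; log-IC50 is
#' `activity %*% t(coupling) + noise`.  Drug ids: the two SOC drugs are
#' named `cisplatin` and `docetaxel`, planted candidates `candidate_01` ...,
#' and null drugs `drug_...`.
#'
#' @param n_lines Number of cell lines (>= 20).
#' @param n_genes Number of genes.
#' @param n_drugs Total number of drugs (SOC + candidates + nulls).
#' @param params A [synthetic_truth_params()].
#' @param seed Integer seed; the whole panel is reproducible from
#'   `(params, seed)`.
#' @return List with `expression` (`ExpressionMatrix`, genes x lines),
#'   `response` (`DrugResponseTable`, log-IC50), and `truth`
#'   (`SyntheticTruth`: loadings, activities, couplings, planted drug ids).
#' @export
generate_cell_line_panel <- function(n_lines = 300, n_genes = 1000,
                                     n_drugs = 138,
                                     params = synthetic_truth_params(),
                                     seed = 1) {
  stopifnot(n_lines >= 20)
  k <- params$n_programs
  if (k < 1) stop("degenerate parameters: need at least one program")
  n_cand <- params$n_candidates
  if (n_drugs < 2 + n_cand)
    stop("n_drugs must cover 2 SOC drugs plus the planted candidates")
  soc_drugs <- c("cisplatin", "docetaxel")
  candidates <- sprintf("candidate_%02d", seq_len(n_cand))
  nulls <- sprintf("drug_%03d", seq_len(n_drugs - 2 - n_cand))
  drug_ids <- c(soc_drugs, candidates, nulls)

  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  line_ids <- sprintf("line_%03d", seq_len(n_lines))
  prog <- .program_of_gene(n_genes, k)

  out <- with_seed(seed, {
    loadings <- matrix(0, n_genes, k,
                       dimnames = list(gene_ids, sprintf("program_%d", 1:k)))
    loadings[cbind(seq_len(n_genes), prog)] <-
      abs(stats::rnorm(n_genes, sd = params$loading_sd))
    activity <- matrix(stats::rnorm(n_lines * k), n_lines, k,
                       dimnames = list(line_ids, colnames(loadings)))
    expr <- loadings %*% t(activity) +
      matrix(stats::rnorm(n_genes * n_lines, sd = params$noise_sd_expression),
             n_genes, n_lines)
    coupling <- matrix(0, n_drugs, k,
                       dimnames = list(drug_ids, colnames(loadings)))
    coupling[soc_drugs, 1] <- params$beta_soc
    coupling[candidates, 1] <- params$beta_candidate
    resp <- activity %*% t(coupling) +
      matrix(stats::rnorm(n_lines * n_drugs, sd = params$noise_sd_response),
             n_lines, n_drugs)
    list(loadings = loadings, activity = activity, expr = expr,
         coupling = coupling, resp = resp)
  })
  dimnames(out$expr) <- list(gene_ids, line_ids)
  dimnames(out$resp) <- list(line_ids, drug_ids)
  truth <- structure(list(
    program_loadings = out$loadings,
    program_activity = out$activity,
    drug_coupling = out$coupling,
    gene_program = stats::setNames(prog, gene_ids),
    soc_drugs = soc_drugs,
    planted_candidates = candidates,
    params = params,
    seed = seed
  ), class = "SyntheticTruth")
  list(
    expression = expression_matrix(out$expr, platform = "cell_line_panel"),
    response = drug_response_table(out$resp, measure = "log_ic50"),
    truth = truth
  )
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf(paste0("SyntheticTruth: %d genes, %d programs, %d drugs ",
                     "(%d planted candidates), seed %d\n"),
              nrow(x$program_loadings), ncol(x$program_loadings),
              nrow(x$drug_coupling), length(x$planted_candidates), x$seed))
  invisible(x)
}

#' Generate multi-platform tumor cohorts sharing one underlying biology
#'
#' Draws one set of tumor program activities and re-observes the same
#' tumors once per platform: platform shift/scale applied, a random gene
#' subset retained, platform noise added.  The tumors' true SOC resistance
#' is their activity on the resistance program (higher = more resistant).
#'
#' @param n_tumors Number of tumors.
#' @param platforms Named list of platform effects (see
#'   [default_platform_effects()]); defaults to the truth's parameter set.
#' @param truth A `SyntheticTruth` from [generate_cell_line_panel()] (the
#'   cohorts share its program loadings).
#' @param seed Integer seed.
#' @return List with `cohorts` (named list of `ExpressionMatrix`),
#'   `true_soc_resistance` (named numeric vector) and `activity`.
#' @export
generate_tumor_cohorts <- function(n_tumors = 200, platforms = NULL, truth,
                                   seed = 1) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  params <- truth$params
  if (is.null(platforms)) platforms <- params$platform_effects
  L <- truth$program_loadings
  n_genes <- nrow(L)
  k <- ncol(L)
  tumor_ids <- sprintf("tumor_%04d", seq_len(n_tumors))

  out <- with_seed(seed, {
    activity <- matrix(stats::rnorm(n_tumors * k), n_tumors, k,
                       dimnames = list(tumor_ids, colnames(L)))
    base <- L %*% t(activity) +
      matrix(stats::rnorm(n_genes * n_tumors, sd = params$noise_sd_expression),
             n_genes, n_tumors)
    rownames(base) <- rownames(L)
    cohorts <- lapply(names(platforms), function(pf) {
      eff <- platforms[[pf]]
      n_keep <- floor(eff$gene_subset_fraction * n_genes)
      if (n_keep < 50)
        stop("platform '", pf, "' gene subset leaves fewer than 50 genes")
      keep <- sort(sample.int(n_genes, n_keep))
      vals <- base[keep, , drop = FALSE] * eff$scale + eff$shift
      if (eff$noise_sd > 0)
        vals <- vals + matrix(stats::rnorm(length(vals), sd = eff$noise_sd),
                              nrow(vals), ncol(vals))
      colnames(vals) <- tumor_ids
      expression_matrix(vals, platform = pf)
    })
    names(cohorts) <- names(platforms)
    list(activity = activity, cohorts = cohorts)
  })
  list(
    cohorts = out$cohorts,
    true_soc_resistance = out$activity[, 1],
    activity = out$activity
  )
}

#' Generate measured dose-response AUCs from true drug response
#'
#' Measured AUC is a noisy monotone-increasing (logistic) transform of the
#' log-IC50 table: higher AUC = more resistant, matching screening-portal
#' convention.
#'
#' @param truth A `SyntheticTruth` (supplies the link parameters).
#' @param cell_panel_response A `DrugResponseTable` of log-IC50 values.
#' @param noise_sd AUC measurement noise; defaults to the truth's
#'   `auc_noise_sd`.
#' @param seed Integer seed.
#' @return A `DrugResponseTable` with measure `"auc"`.
#' @export
generate_measured_auc <- function(truth, cell_panel_response, noise_sd = NULL,
                                  seed = 1) {
  stopifnot(inherits(truth, "SyntheticTruth"),
            measure(cell_panel_response) == "log_ic50")
  params <- truth$params
  if (is.null(noise_sd)) noise_sd <- params$auc_noise_sd
  x <- unclass(cell_panel_response)
  auc <- params$auc_midpoint + params$auc_range * stats::plogis(x)
  if (noise_sd > 0) {
    auc <- auc + with_seed(seed, matrix(stats::rnorm(length(auc),
                                                     sd = noise_sd),
                                        nrow(auc), ncol(auc)))
  }
  auc[is.na(x)] <- NA
  drug_response_table(auc, measure = "auc")
}

#' Gene sets derived from the planted programs, plus random decoys
#'
#' One set per latent program (its member genes), named
#' `PROGRAM_1_RESISTANCE`, `PROGRAM_2`, ...; plus `n_decoys` random gene
#' sets.  The resistance-program set is the planted "pathway" that the
#' opposite-sign GSEA filter should recover.
#'
#' @param truth A `SyntheticTruth`.
#' @param n_decoys Number of random decoy sets.
#' @param decoy_size Genes per decoy set.
#' @param seed Integer seed for decoy sampling.
#' @return A `GeneSetCollection`.
#' @export
truth_gene_sets <- function(truth, n_decoys = 20, decoy_size = 50, seed = 1) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  genes <- names(truth$gene_program)
  k <- ncol(truth$program_loadings)
  sets <- lapply(seq_len(k), function(p) genes[truth$gene_program == p])
  names(sets) <- c("PROGRAM_1_RESISTANCE",
                   if (k > 1) sprintf("PROGRAM_%d", 2:k))
  decoys <- with_seed(seed, {
    lapply(seq_len(n_decoys), function(i) sample(genes, decoy_size))
  })
  names(decoys) <- sprintf("DECOY_%02d", seq_len(n_decoys))
  gene_set_collection(c(sets, decoys), source = "synthetic_truth")
}
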