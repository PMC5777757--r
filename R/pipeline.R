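#' Run the full screen end-to-end on synthetic data
#'
#' Orchestrates simulate -> impute -> screen -> intersect -> in vitro
#' validation -> GSEA from a single configuration, writing every stage's
#' table as TSV/CSV plus a JSON run manifest.  All randomness flows from the
#' single root seed in the config, split deterministically per stage, so a
#' rerun with the same config reproduces every output byte-for-byte.
#'
#' @param config A [run_config()] or the path to a YAML config file.  A
#'   `synthetic` section in the YAML (keys `n_lines`, `n_genes`, `n_drugs`,
#'   `n_tumors`, `n_platforms`, `n_validation_lines` plus any
#'   [synthetic_truth_params()] argument) sizes the simulated study.
#' @param out_dir Output directory (created if needed).
#' @param synthetic Optional named list overriding the synthetic section.
#' @return A `RunManifest`: list with the config echo, seed, per-stage
#'   output paths, file digests and the final candidate list.  Written to
#'   `manifest.json` in `out_dir`.
#' @export
run_all <- function(config, out_dir, synthetic = list()) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    synthetic <- utils::modifyList(raw$synthetic %||% list(), synthetic)
    config <- read_run_config(config)
  }
  stopifnot(inherits(config, "RunConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sizes <- utils::modifyList(list(
    n_lines = 100, n_genes = 400, n_drugs = 30, n_tumors = 120,
    n_platforms = 2, n_validation_lines = 41
  ), synthetic)
  param_names <- names(formals(synthetic_truth_params))
  tp_args <- sizes[intersect(names(sizes), param_names)]
  if (!"platform_effects" %in% names(tp_args))
    tp_args$platform_effects <- default_platform_effects(sizes$n_platforms)
  params <- do.call(synthetic_truth_params, tp_args)

  paths <- list()
  add_path <- function(name, p) paths[[name]] <<- p

  # --- simulate ------------------------------------------------------------
  ss_log("stage simulate")
  panel <- generate_cell_line_panel(sizes$n_lines, sizes$n_genes,
                                    sizes$n_drugs, params,
                                    seed = stage_seed(config$seed, "simulate"))
  tumors <- generate_tumor_cohorts(sizes$n_tumors, truth = panel$truth,
                                   seed = stage_seed(config$seed, "tumors"))
  vpanel <- generate_cell_line_panel(sizes$n_validation_lines, sizes$n_genes,
                                     sizes$n_drugs, params,
                                     seed = stage_seed(config$seed, "validate"))
  auc <- generate_measured_auc(panel$truth, vpanel$response,
                               seed = stage_seed(config$seed, "auc"))
  add_path("train_expression",
           write_expression(panel$expression,
                            file.path(out_dir, "train_expression.tsv")))
  add_path("train_response",
           write_drug_response(panel$response,
                               file.path(out_dir, "train_response.csv")))
  add_path("measured_auc",
           write_drug_response(auc, file.path(out_dir, "measured_auc.csv")))

  # --- impute --------------------------------------------------------------
  ss_log("stage impute (%d cohorts)", length(tumors$cohorts))
  preds <- impute_all(panel$expression, panel$response, tumors$cohorts, config)
  for (pf in names(preds)) {
    p <- file.path(out_dir, sprintf("predictions_%s.tsv", pf))
    utils::write.table(
      data.frame(sample_id = rownames(preds[[pf]]), unclass(preds[[pf]]),
                 check.names = FALSE),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    add_path(sprintf("predictions_%s", pf), p)
  }

  # --- screen --------------------------------------------------------------
  ss_log("stage screen")
  screens <- lapply(preds, function(pm) {
    soc <- compute_soc_score(pm, config$soc_drugs)
    strat <- stratify(soc, config$resistant_fraction, rule = "top_quantile")
    differential_screen(pm, strat, alpha = config$alpha,
                        soc_drugs = config$soc_drugs)
  })
  for (pf in names(screens)) {
    p <- file.path(out_dir, sprintf("screen_%s.tsv", pf))
    utils::write.table(screens[[pf]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add_path(sprintf("screen_%s", pf), p)
  }
  candset <- intersect_candidates(screens)
  p <- file.path(out_dir, "candidates.tsv")
  utils::write.table(data.frame(drug_id = candset$final), p, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  add_path("candidates", p)

  # --- in vitro validation -------------------------------------------------
  invitro <- NULL
  if (length(candset$final)) {
    ss_log("stage validate (%d candidates)", length(candset$final))
    vpred <- impute_all(panel$expression, panel$response,
                        list(as_expression_matrix(unclass(vpanel$expression),
                                                  "validation_lines")),
                        config)[[1]]
    invitro <- invitro_validate(vpred, auc, candset$final,
                                alpha = config$alpha,
                                soc_drugs = config$soc_drugs)
    p <- file.path(out_dir, "invitro_validation.tsv")
    utils::write.table(invitro, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add_path("invitro_validation", p)
  }

  # --- GSEA ----------------------------------------------------------------
  gsea_hits <- character()
  if (length(candset$final)) {
    ss_log("stage gsea")
    sets <- truth_gene_sets(panel$truth,
                            seed = stage_seed(config$seed, "gsea"))
    pm <- preds[[1]]
    expr <- tumors$cohorts[[1]]
    soc <- compute_soc_score(pm, config$soc_drugs)
    gseed <- stage_seed(config$seed, "gsea")
    soc_res <- permutation_null(expr, soc, sets,
                                n_permutations = config$n_permutations,
                                seed = gseed,
                                min_size = config$min_set_size,
                                max_size = config$max_set_size)
    cand_res <- lapply(stats::setNames(candset$final, candset$final),
                       function(d) {
      permutation_null(expr, unclass(pm)[, d], sets,
                       n_permutations = config$n_permutations, seed = gseed,
                       min_size = config$min_set_size,
                       max_size = config$max_set_size)
    })
    gsea_hits <- as.character(opposite_sign_filter(soc_res, cand_res,
                                                   config$gsea_fdr_q))
    p <- file.path(out_dir, "gsea_soc.tsv")
    utils::write.table(soc_res, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add_path("gsea_soc", p)
    p <- file.path(out_dir, "gsea_opposition.tsv")
    utils::write.table(data.frame(pathway = gsea_hits), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add_path("gsea_opposition", p)
  }

  manifest <- list(
    tool = "socscreen",
    version = as.character(utils::packageVersion("socscreen")),
    seed = config$seed,
    config = unclass(config),
    synthetic = sizes,
    outputs = lapply(paths, basename),
    digests = stats::setNames(
      as.list(unname(tools::md5sum(unlist(paths, use.names = FALSE)))),
      basename(unlist(paths, use.names = FALSE))),
    final_candidates = candset$final,
    planted_candidates = panel$truth$planted_candidates,
    gsea_opposition = gsea_hits
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  structure(c(manifest, list(manifest_path = manifest_path,
                             predictions = preds, screens = screens,
                             candidate_set = candset, invitro = invitro)),
            class = "RunManifest")
}

#' @export
print.RunManifest <- function(x, ...) {
  cat(sprintf("RunManifest (seed %d): %d outputs, final candidates: %s\n",
              x$seed, length(x$outputs),
              paste(x$final_candidates, collapse = ", ")))
  invisible(x)
}
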