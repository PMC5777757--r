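#' Replicate the drug screen in an independent cohort at several cutoffs
#'
#' Runs SOC scoring, stratification, the differential screen and the
#' SOC correlation analysis at each responder/non-responder cutoff (default
#' 80/20 and 50/50), reporting which drugs are flagged candidates at each.
#' Robustness of a candidate to the stratification cutoff is the replication
#' criterion.
#'
#' @param pred A `PredictionMatrix` for the validation cohort.
#' @param config A [run_config()].
#' @param cutoffs Non-responder fractions to evaluate.
#' @return Named list (one element per cutoff) with components `screen`
#'   (a `DrugScreen`), `correlations` (values + ranks) and `candidates`.
#' @export
replicate_screen <- function(pred, config = run_config(),
                             cutoffs = c(0.20, 0.50)) {
  soc <- compute_soc_score(pred, config$soc_drugs)
  out <- lapply(cutoffs, function(f) {
    strat <- stratify(soc, resistant_fraction = f, rule = "top_quantile")
    scr <- differential_screen(pred, strat, alpha = config$alpha,
                               soc_drugs = config$soc_drugs)
    corr <- rbind(
      correlate_with_soc(pred, soc, method = "pearson", on = "values",
                         soc_drugs = config$soc_drugs),
      correlate_with_soc(pred, soc, method = "pearson", on = "ranks",
                         soc_drugs = config$soc_drugs)
    )
    list(screen = scr, correlations = corr,
         candidates = scr$drug_id[scr$candidate])
  })
  names(out) <- sprintf("cutoff_%g", cutoffs)
  out
}

#' Validate candidate drugs against measured cell-line AUCs
#'
#' Cell lines are stratified by their *predicted* SOC score only (mean
#' split, suited to small panels); measured dose-response AUCs play no role
#' in the stratification, so there is no leakage of the validation readout
#' into the grouping.  For each candidate drug, a one-sided pooled t-test
#' asks whether the SOC-resistant group has lower measured AUC (higher
#' measured sensitivity).  Candidates absent from the measured panel are
#' reported as not testable (`validated = NA`).
#'
#' @param pred_cell_lines `PredictionMatrix` for the cell-line panel.
#' @param measured `DrugResponseTable` with measure `"auc"`.
#' @param candidates Character vector of candidate drug ids.
#' @param alpha Significance threshold.
#' @param soc_drugs Drug ids averaged into the predicted SOC score.
#' @return Data frame with one row per candidate: group mean AUCs, pooled t,
#'   one-sided p and the `validated` flag.
#' @export
invitro_validate <- function(pred_cell_lines, measured, candidates,
                             alpha = 0.05,
                             soc_drugs = c("cisplatin", "docetaxel")) {
  if (measure(measured) != "auc")
    stop("measured response table must carry measure 'auc'")
  soc <- compute_soc_score(pred_cell_lines, soc_drugs)
  strat <- stratify(soc, rule = "mean_split")
  lab <- stats::setNames(strat$label, strat$sample_id)
  rows <- lapply(candidates, function(d) {
    if (!d %in% colnames(measured)) {
      ss_log("candidate '%s' not screened in the measured panel; not testable", d)
      return(data.frame(drug_id = d, mean_auc_sensitive = NA_real_,
                        mean_auc_resistant = NA_real_, t_statistic = NA_real_,
                        p_value = NA_real_, validated = NA,
                        stringsAsFactors = FALSE))
    }
    auc <- unclass(measured)[, d]
    ok <- !is.na(auc) & names(auc) %in% names(lab)
    sens <- auc[ok][lab[names(auc)[ok]] == "responder"]
    res <- auc[ok][lab[names(auc)[ok]] == "non_responder"]
    if (length(sens) < 2 || length(res) < 2)
      stop("fewer than 2 cell lines in a SOC group for drug '", d, "'")
    tt <- pooled_t_test(res, sens, alternative = "less")
    data.frame(drug_id = d, mean_auc_sensitive = tt$mean_y,
               mean_auc_resistant = tt$mean_x, t_statistic = tt$t,
               p_value = tt$p,
               validated = tt$mean_x < tt$mean_y & tt$p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "stratification") <- strat
  out
}

#' Associate predicted drug sensitivity with survival outcome
#'
#' Proof-of-concept check that imputed IC50 carries clinical signal when no
#' measured drug response exists: vital status at last follow-up is used as
#' a surrogate response phenotype.  Predicted log-IC50 for the given drug is
#' compared between alive and dead patients with a pooled t-test and a
#' Wilcoxon rank-sum test; when tumor stage is supplied, a linear probability
#' model `I(alive) ~ predicted IC50 + stage` reports the stage-adjusted p for
#' the IC50 term.
#'
#' @param pred A `PredictionMatrix`.
#' @param drug_id Drug to test.
#' @param vital_status Named character vector (`"alive"`/`"dead"`) per sample.
#' @param stage Optional named categorical covariate per sample.
#' @return List with `drug_id`, `t_p`, `wilcoxon_p`, `adjusted_p` (NA when no
#'   usable stage covariate), `direction` (sign of mean alive - mean dead
#'   predicted IC50) and group sizes.
#' @export
survival_association <- function(pred, drug_id, vital_status, stage = NULL) {
  if (!drug_id %in% colnames(pred))
    stop("drug '", drug_id, "' absent from prediction matrix")
  common <- intersect(rownames(pred), names(vital_status))
  vs <- vital_status[common]
  if (!all(vs %in% c("alive", "dead")))
    stop("vital_status values must be 'alive' or 'dead'")
  x <- unclass(pred)[common, drug_id]
  alive <- x[vs == "alive"]
  dead <- x[vs == "dead"]
  if (length(alive) < 2 || length(dead) < 2)
    stop("need at least 2 samples per vital-status group")
  tt <- pooled_t_test(alive, dead)
  wp <- suppressWarnings(stats::wilcox.test(alive, dead))$p.value
  adjusted_p <- NA_real_
  if (!is.null(stage)) {
    st <- factor(stage[common])
    if (nlevels(droplevels(st[!is.na(st)])) < 2) {
      warning("stage covariate has a single level; dropped from the model")
    } else {
      keep <- !is.na(st)
      fit <- stats::lm(as.numeric(vs[keep] == "alive") ~ x[keep] + droplevels(st[keep]))
      adjusted_p <- summary(fit)$coefficients["x[keep]", "Pr(>|t|)"]
    }
  }
  list(drug_id = drug_id,
       t_p = tt$p,
       wilcoxon_p = wp,
       adjusted_p = adjusted_p,
       direction = sign(tt$mean_x - tt$mean_y),
       n_alive = length(alive),
       n_dead = length(dead))
}
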