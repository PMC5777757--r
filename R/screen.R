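# Pooled-variance two-sample Student's t with explicit conventions for the
# degenerate zero-variance cases the screen can produce on imputed values:
# zero pooled variance with equal means -> t = 0, p = 1; zero pooled
# variance with unequal means -> p = 0 with a warning (the direction still
# decides candidacy).
pooled_t_test <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  nx <- length(x)
  ny <- length(y)
  if (nx < 2 || ny < 2) stop("each group needs at least 2 observations")
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  delta <- mean(x) - mean(y)
  if (sp2 == 0) {
    if (delta == 0) {
      t <- 0
      p <- if (alternative == "two.sided") 1 else 0.5
    } else {
      warning("zero pooled variance with unequal means; reporting p = 0")
      t <- sign(delta) * Inf
      p <- 0
    }
  } else {
    t <- delta / sqrt(sp2 * (1 / nx + 1 / ny))
    p <- switch(alternative,
                two.sided = 2 * stats::pt(-abs(t), df),
                less = stats::pt(t, df),
                greater = stats::pt(t, df, lower.tail = FALSE))
  }
  list(t = t, df = df, p = p, mean_x = mean(x), mean_y = mean(y))
}

#' Compute per-sample standard-of-care (SOC) sensitivity scores
#'
#' The SOC score of a sample is the arithmetic mean of its predicted
#' log-IC50 for the SOC component drugs (default cisplatin + docetaxel,
#' the platinum/taxane doublet).  Higher score = predicted more resistant
#' to SOC.
#'
#' @param pred A `PredictionMatrix` (samples x drugs).
#' @param soc_drugs Drug ids averaged into the score.
#' @return Named numeric vector, one score per sample.
#' @export
compute_soc_score <- function(pred, soc_drugs = c("cisplatin", "docetaxel")) {
  missing <- setdiff(soc_drugs, colnames(pred))
  if (length(missing))
    stop("SOC drug(s) absent from prediction matrix: ",
         paste(missing, collapse = ", "))
  rowMeans(unclass(pred)[, soc_drugs, drop = FALSE])
}

#' Stratify samples into SOC responders and non-responders
#'
#' Two rules are supported.  `top_quantile` labels the `round(fraction * n)`
#' samples with the highest SOC scores as non-responders (the published 80/20
#' split mirrors the documented ~80% clinical response rate to SOC);
#' `mean_split` labels samples scoring above the mean as non-responders (used
#' for small cell-line panels).  Ties at the quantile cut are broken by
#' sample id so the labelling is deterministic.
#'
#' @param soc_score Named numeric vector from [compute_soc_score()].
#' @param resistant_fraction Fraction labelled non-responder under
#'   `top_quantile`.
#' @param rule `"top_quantile"` or `"mean_split"`.
#' @return An object of class `SOCStratification`: data frame with columns
#'   `sample_id`, `soc_score`, `label` plus attributes recording the rule.
#' @export
stratify <- function(soc_score, resistant_fraction = 0.20,
                     rule = c("top_quantile", "mean_split")) {
  rule <- match.arg(rule)
  n <- length(soc_score)
  if (is.null(names(soc_score)))
    stop("soc_score must be named by sample id")
  if (rule == "top_quantile") {
    stopifnot(n >= 5, resistant_fraction > 0, resistant_fraction < 1)
    if (stats::var(soc_score) == 0)
      stop("all SOC scores identical: top-quantile stratification undefined")
    k <- floor(resistant_fraction * n + 0.5)  # round half up
    ord <- order(-soc_score, names(soc_score))
    label <- rep("responder", n)
    label[ord[seq_len(k)]] <- "non_responder"
  } else {
    label <- ifelse(soc_score > mean(soc_score), "non_responder", "responder")
  }
  structure(
    data.frame(sample_id = names(soc_score), soc_score = as.numeric(soc_score),
               label = label, stringsAsFactors = FALSE),
    resistant_fraction = if (rule == "top_quantile") resistant_fraction else NA,
    rule = rule,
    class = c("SOCStratification", "data.frame")
  )
}

#' Screen drugs for higher predicted sensitivity in SOC non-responders
#'
#' For every screened drug, predicted log-IC50 is compared between SOC
#' responders and non-responders with a pooled-variance Student's t-test.
#' A drug is a candidate when its mean predicted log-IC50 is lower in
#' non-responders (predicted more effective exactly where SOC fails) and the
#' test is significant.  SOC component drugs are excluded from the screen.
#' An FDR (Benjamini-Hochberg) column is reported for information only; the
#' candidate call uses the raw p-value.
#'
#' @param pred A `PredictionMatrix`.
#' @param strat An `SOCStratification` covering the prediction samples.
#' @param alpha Significance threshold.
#' @param tail `"two_sided"` (default: two-tailed test plus direction
#'   filter) or `"one_sided"` (directional alternative).
#' @param soc_drugs Drug ids excluded from the screened set.
#' @return Data frame of class `DrugScreen` with one row per screened drug:
#'   `drug_id`, `mean_responder`, `mean_non_responder`, `t_statistic`,
#'   `p_value`, `fdr`, `tail`, `candidate`.
#' @export
differential_screen <- function(pred, strat, alpha = 0.05,
                                tail = c("two_sided", "one_sided"),
                                soc_drugs = c("cisplatin", "docetaxel")) {
  tail <- match.arg(tail)
  stopifnot(inherits(strat, "SOCStratification"))
  common <- intersect(rownames(pred), strat$sample_id)
  if (length(common) < 4) stop("too few samples shared with stratification")
  lab <- stats::setNames(strat$label, strat$sample_id)[common]
  resp <- common[lab == "responder"]
  nonresp <- common[lab == "non_responder"]
  if (length(resp) < 2 || length(nonresp) < 2)
    stop("need at least 2 samples per SOC group")
  drugs <- setdiff(colnames(pred), soc_drugs)
  alt <- if (tail == "one_sided") "less" else "two.sided"
  rows <- lapply(drugs, function(d) {
    tt <- pooled_t_test(unclass(pred)[nonresp, d], unclass(pred)[resp, d],
                        alternative = alt)
    data.frame(drug_id = d,
               mean_responder = tt$mean_y,
               mean_non_responder = tt$mean_x,
               t_statistic = tt$t,
               p_value = tt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$tail <- tail
  out$candidate <- out$mean_non_responder < out$mean_responder &
    out$p_value < alpha
  structure(out, alpha = alpha, platform = platform(pred),
            class = c("DrugScreen", "data.frame"))
}

#' Intersect per-platform candidate drug lists
#'
#' Each expression platform is treated as a technical replication of the
#' same cohort; only drugs flagged as candidates on every platform survive.
#'
#' @param per_platform Named list mapping platform label to a character
#'   vector of candidate drug ids (or a list of `DrugScreen` data frames,
#'   from which candidates are extracted).
#' @return An object of class `CandidateSet`: list with `per_platform`
#'   (the input lists) and `final` (their intersection, sorted).
#' @export
intersect_candidates <- function(per_platform) {
  if (!length(per_platform)) stop("need at least one platform candidate list")
  lists <- lapply(per_platform, function(x) {
    if (inherits(x, "DrugScreen")) x$drug_id[x$candidate] else as.character(x)
  })
  final <- Reduce(intersect, lists)
  structure(list(per_platform = lists, final = sort(final)),
            class = "CandidateSet")
}

#' @export
print.CandidateSet <- function(x, ...) {
  sizes <- paste(sprintf("%s=%d", names(x$per_platform),
                         lengths(x$per_platform)), collapse = ", ")
  cat(sprintf("CandidateSet: per-platform [%s]; final %d: %s\n", sizes,
              length(x$final), paste(x$final, collapse = ", ")))
  invisible(x)
}

#' Correlate per-drug predicted IC50 with the SOC score
#'
#' Robustness companion to the group-wise screen: candidate drugs should
#' show negative correlation between their predicted log-IC50 and the SOC
#' score (more effective exactly in the more SOC-resistant tumors).  With
#' `on = "ranks"` both variables are rank-transformed (average ranks for
#' ties) before the Pearson correlation, which equals the Spearman
#' correlation on values.
#'
#' @param pred A `PredictionMatrix`.
#' @param soc_score Named numeric vector aligned with the samples.
#' @param method `"pearson"` or `"spearman"`.
#' @param on `"values"` or `"ranks"`.
#' @param soc_drugs Drug ids excluded from the correlation set.
#' @return Data frame with `drug_id`, `method`, `on`, `r`, `p_value`,
#'   `usable` (FALSE for constant drug columns, whose correlation is
#'   undefined).
#' @export
correlate_with_soc <- function(pred, soc_score,
                               method = c("pearson", "spearman"),
                               on = c("values", "ranks"),
                               soc_drugs = c("cisplatin", "docetaxel")) {
  method <- match.arg(method)
  on <- match.arg(on)
  common <- intersect(rownames(pred), names(soc_score))
  if (length(common) < 3) stop("need at least 3 samples for correlation")
  s <- soc_score[common]
  drugs <- setdiff(colnames(pred), soc_drugs)
  rows <- lapply(drugs, function(d) {
    v <- unclass(pred)[common, d]
    if (stats::var(v) == 0)
      return(data.frame(drug_id = d, method = method, on = on,
                        r = NA_real_, p_value = NA_real_, usable = FALSE,
                        stringsAsFactors = FALSE))
    a <- v
    b <- s
    if (on == "ranks") {
      a <- rank(a)
      b <- rank(b)
    }
    ct <- if (method == "spearman") {
      suppressWarnings(stats::cor.test(a, b, method = "spearman"))
    } else {
      stats::cor.test(a, b, method = "pearson")
    }
    data.frame(drug_id = d, method = method, on = on,
               r = unname(ct$estimate), p_value = ct$p.value, usable = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
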