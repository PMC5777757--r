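#' Rank genes by correlation with a continuous phenotype
#'
#' The continuous-phenotype GSEA metric: per-gene Pearson correlation of
#' expression with the phenotype (here typically a predicted IC50 vector).
#' Genes with constant expression get metric 0; ties in the metric are
#' broken by gene id for a deterministic ranking.
#'
#' @param expr An `ExpressionMatrix` (genes x samples).
#' @param phenotype Named numeric vector over the samples.
#' @return An object of class `RankedGeneList`: data frame with `gene_id`
#'   and `metric`, sorted by metric descending.
#' @export
gene_phenotype_metric <- function(expr, phenotype) {
  common <- intersect(colnames(expr), names(phenotype))
  if (length(common) < 3) stop("need at least 3 samples")
  y <- phenotype[common]
  if (stats::var(y) == 0) stop("phenotype is constant")
  X <- unclass(expr)[, common, drop = FALSE]
  n <- length(y)
  xc <- X - rowMeans(X)
  yc <- y - mean(y)
  sx <- sqrt(rowSums(xc^2))
  r <- as.numeric(xc %*% yc) / (sx * sqrt(sum(yc^2)))
  r[sx == 0] <- 0
  ord <- order(-r, rownames(X))
  structure(data.frame(gene_id = rownames(X)[ord], metric = r[ord],
                       stringsAsFactors = FALSE),
            class = c("RankedGeneList", "data.frame"))
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The classic GSEA statistic: walking down the ranked gene list, the
#' running sum increases by `|metric|^p / NR` at genes in the set (NR
#' normalising the hit weights to sum 1) and decreases by `1 / (N - Nh)` at
#' genes outside it; the enrichment score is the signed maximum deviation of
#' this running sum from zero.  The sum terminates at exactly 0 by
#' construction.
#'
#' @param ranked A `RankedGeneList`.
#' @param gene_set Character vector of gene ids.
#' @param weight_exponent Exponent `p` on the metric weights (1 = the
#'   standard "weighted" scheme).
#' @return Enrichment score in `[-1, 1]`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  hit <- ranked$gene_id %in% gene_set
  nh <- sum(hit)
  if (nh == 0) stop("gene set has no overlap with the ranked list")
  n <- nrow(ranked)
  if (nh == n) return(1)
  w <- abs(ranked$metric)^weight_exponent
  nr <- sum(w[hit])
  steps <- numeric(n)
  if (nr == 0) {
    # all hit metrics zero: fall back to equal hit weights
    steps[hit] <- 1 / nh
  } else {
    steps[hit] <- w[hit] / nr
  }
  steps[!hit] <- -1 / (n - nh)
  running <- cumsum(steps)
  i <- which.max(abs(running))
  running[i]
}

# Enrichment scores for many sets sharing one ranking; sets are given as
# integer index vectors into the ranked list (precomputed by the caller).
.es_many <- function(metric_sorted, set_idx_list, weight_exponent = 1) {
  n <- length(metric_sorted)
  w <- abs(metric_sorted)^weight_exponent
  vapply(set_idx_list, function(idx) {
    nh <- length(idx)
    if (nh == n) return(1)
    nr <- sum(w[idx])
    steps <- rep(-1 / (n - nh), n)
    steps[idx] <- if (nr == 0) 1 / nh else w[idx] / nr
    running <- cumsum(steps)
    running[which.max(abs(running))]
  }, 0)
}

#' Continuous-phenotype GSEA with phenotype permutation
#'
#' For each gene set: the observed enrichment score on the correlation-ranked
#' list, a phenotype-permutation null (the sample-level phenotype vector is
#' re-randomized, the per-gene metric and enrichment score recomputed each
#' time), the normalized enrichment score (ES divided by the mean |null ES|
#' of matching sign for that set), a sign-matched nominal p, and an FDR q
#' over the observed NES distribution following the standard permutation
#' scheme (ratio of the null to the observed tail fraction at each NES,
#' capped at 1).
#'
#' @param expr An `ExpressionMatrix`.
#' @param phenotype Named numeric vector over the samples.
#' @param sets A `GeneSetCollection`.
#' @param n_permutations Number of phenotype permutations.
#' @param seed Seed for the permutation stream.
#' @param weight_exponent Hit-weight exponent (1 = weighted scheme).
#' @param min_size,max_size Sets outside these overlap sizes are skipped.
#' @return An `EnrichmentTable`: data frame with one row per retained set
#'   (`set_name`, `size`, `es`, `nes`, `nominal_p`, `fdr_q`, `direction`).
#' @export
permutation_null <- function(expr, phenotype, sets, n_permutations = 1000,
                             seed = 1, weight_exponent = 1,
                             min_size = 5, max_size = 500) {
  stopifnot(n_permutations >= 1)
  ranked <- gene_phenotype_metric(expr, phenotype)
  universe <- ranked$gene_id
  kept <- list()
  for (nm in names(sets)) {
    ov <- intersect(sets[[nm]], universe)
    if (length(ov) < min_size || length(ov) > max_size) {
      ss_log("skipping set '%s' (overlap %d outside [%d, %d])",
             nm, length(ov), min_size, max_size)
      next
    }
    kept[[nm]] <- ov
  }
  if (!length(kept)) stop("no gene set within the size limits")

  common <- intersect(colnames(expr), names(phenotype))
  X <- unclass(expr)[, common, drop = FALSE]
  y <- phenotype[common]
  n <- length(y)
  xc <- X - rowMeans(X)
  sx <- sqrt(rowSums(xc^2))

  metric_for <- function(yy) {
    yc <- yy - mean(yy)
    r <- as.numeric(xc %*% yc) / (sx * sqrt(sum(yc^2)))
    r[sx == 0] <- 0
    r
  }
  es_for <- function(r) {
    ord <- order(-r, rownames(X))
    genes_sorted <- rownames(X)[ord]
    pos <- stats::setNames(seq_len(length(genes_sorted)), genes_sorted)
    idx <- lapply(kept, function(g) sort(unname(pos[g])))
    .es_many(r[ord], idx, weight_exponent)
  }

  es_obs <- es_for(metric_for(y))
  null_es <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      es_for(metric_for(y[sample.int(n)]))
    }, numeric(length(kept)))
  })
  if (is.null(dim(null_es))) null_es <- matrix(null_es, nrow = length(kept))

  m <- length(kept)
  nes <- nominal_p <- numeric(m)
  null_nes <- matrix(NA_real_, m, n_permutations)
  for (i in seq_len(m)) {
    nulls <- null_es[i, ]
    pos <- nulls[nulls >= 0]
    neg <- nulls[nulls < 0]
    mean_pos <- if (length(pos)) mean(pos) else NA_real_
    mean_neg <- if (length(neg)) mean(abs(neg)) else NA_real_
    if (es_obs[i] >= 0) {
      nes[i] <- if (is.na(mean_pos) || mean_pos == 0) NA_real_ else
        es_obs[i] / mean_pos
      nominal_p <- replace(nominal_p, i,
                           (sum(pos >= es_obs[i]) + 1) / (length(pos) + 1))
    } else {
      nes[i] <- if (is.na(mean_neg) || mean_neg == 0) NA_real_ else
        -abs(es_obs[i]) / mean_neg
      nominal_p <- replace(nominal_p, i,
                           (sum(abs(neg) >= abs(es_obs[i])) + 1) / (length(neg) + 1))
    }
    null_nes[i, nulls >= 0] <- if (!is.na(mean_pos) && mean_pos > 0)
      pos / mean_pos else NA_real_
    null_nes[i, nulls < 0] <- if (!is.na(mean_neg) && mean_neg > 0)
      neg / mean_neg else NA_real_
  }

  all_null <- as.numeric(null_nes)
  all_null <- all_null[!is.na(all_null)]
  fdr_q <- vapply(seq_len(m), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      null_frac <- mean(all_null[all_null >= 0] >= nes[i])
      obs_frac <- mean(nes[!is.na(nes) & nes >= 0] >= nes[i])
    } else {
      null_frac <- mean(all_null[all_null < 0] <= nes[i])
      obs_frac <- mean(nes[!is.na(nes) & nes < 0] <= nes[i])
    }
    if (is.nan(null_frac)) null_frac <- 0
    min(1, null_frac / max(obs_frac, .Machine$double.eps))
  }, 0)

  structure(
    data.frame(set_name = names(kept), size = lengths(kept),
               es = es_obs, nes = nes, nominal_p = nominal_p, fdr_q = fdr_q,
               direction = sign(es_obs), row.names = NULL,
               stringsAsFactors = FALSE),
    n_permutations = n_permutations, seed = seed,
    class = c("EnrichmentTable", "data.frame")
  )
}

#' Opposite-sign pathway filter
#'
#' Retains pathways that are significantly positively enriched for the SOC
#' phenotype (their activity tracks predicted SOC resistance) and
#' significantly negatively enriched for *every* candidate drug phenotype
#' (their activity tracks candidate-drug sensitivity) at the given FDR
#' threshold.  These are the pathways whose activation is predicted to
#' desensitize tumors to SOC while sensitizing them to the candidates.
#'
#' @param soc_results `EnrichmentTable` for the SOC phenotype.
#' @param candidate_results Named list of `EnrichmentTable`s, one per
#'   candidate drug.
#' @param q_threshold FDR q threshold (default 0.25).
#' @return Character vector of pathway names satisfying all sign and
#'   significance conditions, with a `detail` attribute holding the ES of
#'   each retained pathway per phenotype.
#' @export
opposite_sign_filter <- function(soc_results, candidate_results,
                                 q_threshold = 0.25) {
  if (!length(candidate_results) || is.null(names(candidate_results)))
    stop("candidate_results must be a named list of enrichment tables")
  keep <- soc_results$set_name[soc_results$es > 0 &
                                 !is.na(soc_results$fdr_q) &
                                 soc_results$fdr_q < q_threshold]
  for (drug in names(candidate_results)) {
    res <- candidate_results[[drug]]
    if (is.null(res)) stop("missing enrichment results for drug '", drug, "'")
    ok <- res$set_name[res$es < 0 & !is.na(res$fdr_q) &
                         res$fdr_q < q_threshold]
    keep <- intersect(keep, ok)
  }
  keep <- sort(keep)
  detail <- cbind(
    SOC = soc_results$es[match(keep, soc_results$set_name)],
    do.call(cbind, lapply(candidate_results, function(res)
      res$es[match(keep, res$set_name)]))
  )
  rownames(detail) <- keep
  structure(keep, detail = detail, class = c("PathwayOpposition", "character"))
}
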