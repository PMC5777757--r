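test_that("gene-phenotype metric is the per-gene Pearson correlation", {
  ph <- setNames(c(1, 2, 3), c("s1", "s2", "s3"))
  x <- make_expr(rbind(up = c(1, 2, 3), down = c(3, 2, 1),
                       curved = c(1, 2, 4), flat = c(5, 5, 5)),
                 samples = names(ph))
  rk <- gene_phenotype_metric(x, ph)
  expect_equal(rk$gene_id[1], "up")
  expect_equal(rk$metric[1], 1)
  expect_equal(rk$gene_id[nrow(rk)], "down")
  expect_equal(rk$metric[nrow(rk)], -1)
  expect_equal(rk$metric[rk$gene_id == "curved"],
               cor(c(1, 2, 4), c(1, 2, 3)), tolerance = 1e-12)
  expect_equal(rk$metric[rk$gene_id == "curved"], 0.98198, tolerance = 1e-5)
  expect_equal(rk$metric[rk$gene_id == "flat"], 0)
  expect_true(all(diff(rk$metric) <= 0))
  expect_error(gene_phenotype_metric(x, ph * 0), "constant")
})

ranked_fixture <- function() {
  structure(data.frame(gene_id = paste0("g", 1:5),
                       metric = c(0.9, 0.5, 0.4, -0.3, -0.8),
                       stringsAsFactors = FALSE),
            class = c("RankedGeneList", "data.frame"))
}

test_that("enrichment score matches worked examples and brute-force oracle", {
  rk <- ranked_fixture()
  expect_equal(enrichment_score(rk, c("g1", "g5")), 0.9 / 1.7,
               tolerance = 1e-12)
  expect_equal(enrichment_score(rk, paste0("g", 1:5)), 1)
  # sole hit at the bottom: running sum reaches -1 just before the hit
  expect_equal(enrichment_score(rk, "g5"),
               oracle_es(rk$metric, 5))
  expect_error(enrichment_score(rk, "absent"), "no overlap")
  skip_if_not_installed("fgsea")
  expect_equal(enrichment_score(rk, c("g1", "g5")),
               fgsea::calcGseaStat(rk$metric, c(1L, 5L), gseaParam = 1),
               tolerance = 1e-12)
})

test_that("ES equals exhaustive enumeration for all small sets of 6 genes", {
  set.seed(42)
  metric <- sort(rnorm(6), decreasing = TRUE)
  rk <- structure(data.frame(gene_id = paste0("g", 1:6), metric = metric,
                             stringsAsFactors = FALSE),
                  class = c("RankedGeneList", "data.frame"))
  for (k in 1:3) {
    for (pos in utils::combn(6, k, simplify = FALSE)) {
      expect_equal(enrichment_score(rk, paste0("g", pos)),
                   oracle_es(metric, pos), tolerance = 1e-12,
                   info = paste(pos, collapse = ","))
    }
  }
})

test_that("running sum conservation: terminal value is exactly zero", {
  set.seed(8)
  metric <- sort(rnorm(50), decreasing = TRUE)
  for (k in c(3, 10, 25)) {
    hits <- sort(sample(50, k))
    w <- abs(metric)^1
    steps <- rep(-1 / (50 - k), 50)
    steps[hits] <- w[hits] / sum(w[hits])
    expect_equal(sum(steps), 0, tolerance = 1e-12)
  }
})

test_that("negating the phenotype negates the enrichment score", {
  set.seed(13)
  x <- random_expr(40, 12, seed = 13)
  ph <- setNames(rnorm(12), colnames(x))
  gs <- paste0("g", sprintf("%02d", sample(40, 8)))
  rk_pos <- gene_phenotype_metric(x, ph)
  rk_neg <- gene_phenotype_metric(x, -ph)
  expect_equal(enrichment_score(rk_pos, gs), -enrichment_score(rk_neg, gs),
               tolerance = 1e-10)
})

test_that("permutation GSEA is seed-deterministic with bounded p-values", {
  x <- random_expr(60, 15, seed = 3)
  ph <- setNames(rnorm(15), colnames(x))
  sets <- gene_set_collection(list(
    S1 = rownames(x)[1:10], S2 = rownames(x)[11:25], tiny = rownames(x)[1:2]))
  r1 <- suppressMessages(permutation_null(x, ph, sets, n_permutations = 50,
                                          seed = 9))
  r2 <- suppressMessages(permutation_null(x, ph, sets, n_permutations = 50,
                                          seed = 9))
  expect_identical(r1, r2)
  expect_false("tiny" %in% r1$set_name)  # below min_size, skipped
  expect_true(all(r1$nominal_p >= 1 / 51))
  expect_true(all(r1$fdr_q >= 0 & r1$fdr_q <= 1))
  expect_true(all(abs(r1$es) <= 1))
  expect_equal(r1$direction, sign(r1$es))
})

test_that("planted pathway survives the opposite-sign filter, decoys do not", {
  panel <- generate_cell_line_panel(100, 200, 8, seed = 23)
  tum <- generate_tumor_cohorts(
    120, platforms = list(p1 = list(shift = 0, scale = 1,
                                    gene_subset_fraction = 1, noise_sd = 0.2)),
    truth = panel$truth, seed = 24)
  cfg <- run_config(seed = 23, cv_folds = 5)
  pred <- suppressMessages(impute_all(panel$expression, panel$response,
                                      tum$cohorts, cfg))[[1]]
  soc <- compute_soc_score(pred)
  sets <- truth_gene_sets(panel$truth, n_decoys = 10, decoy_size = 20,
                          seed = 25)
  expr <- tum$cohorts[[1]]
  soc_res <- suppressMessages(
    permutation_null(expr, soc, sets, n_permutations = 200, seed = 26))
  cand <- panel$truth$planted_candidates[1:2]
  cand_res <- lapply(setNames(cand, cand), function(d)
    suppressMessages(permutation_null(expr, unclass(pred)[, d], sets,
                                      n_permutations = 200, seed = 26)))
  hits <- opposite_sign_filter(soc_res, cand_res, q_threshold = 0.25)
  expect_true("PROGRAM_1_RESISTANCE" %in% hits)
  # decoys share genes with the resistance program by chance (20 random of
  # 200 genes), so allow at most one partially-true decoy through
  expect_lte(sum(grepl("^DECOY", hits)), 1)
})

test_that("opposite-sign filter applies the AND rule over phenotypes", {
  mk <- function(es, q) {
    structure(data.frame(set_name = c("A", "B", "C"), size = 10,
                         es = es, nes = es, nominal_p = 0.01, fdr_q = q,
                         direction = sign(es), stringsAsFactors = FALSE),
              class = c("EnrichmentTable", "data.frame"))
  }
  soc <- mk(c(0.8, 0.7, -0.5), c(0.01, 0.01, 0.01))
  # B is positive for one candidate -> excluded; C fails the SOC sign
  cands <- list(d1 = mk(c(-0.9, 0.6, -0.2), c(0.01, 0.01, 0.01)),
                d2 = mk(c(-0.8, -0.6, -0.2), c(0.01, 0.01, 0.01)))
  keep <- opposite_sign_filter(soc, cands, q_threshold = 0.25)
  expect_equal(as.character(keep), "A")
  expect_error(opposite_sign_filter(soc, list(mk(c(-1, -1, -1), rep(0.1, 3)))),
               "named")
})
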