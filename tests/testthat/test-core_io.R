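test_that("expression TSV/CSV round-trips are identity and validation fires", {
  x <- make_expr(matrix(c(1.25, -2.5, 3.125, 0.5, 7.75, -0.125), 3, 2),
                 genes = c("TP53", "BRCA1", "EGFR"), samples = c("sA", "sB"),
                 platform = "affymetrix")
  for (fmt in c("tsv", "csv")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_expression(x, f, format = fmt)
    y <- read_expression(f, format = fmt, platform = "affymetrix")
    expect_identical(unclass(y), unclass(x))
    expect_equal(platform(y), "affymetrix")
  }
  expect_error(expression_matrix(matrix(1:4, 2, 2)), "names")
  bad <- matrix(c(1, NA, 2, 3), 2, 2,
                dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(expression_matrix(bad), "non-finite.*gene 'b', sample 's1'")
})

test_that("GCT 1.2 files are accepted and dimension mismatches rejected", {
  f <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "2\t3",
               "Name\tDescription\ts1\ts2\ts3",
               "gA\tna\t1\t2\t3",
               "gB\tna\t4\t5\t6"), f)
  x <- read_expression(f, format = "gct", platform = "agilent")
  expect_equal(dim(x), c(2L, 3L))
  expect_equal(unclass(x)["gB", "s2"], 5)

  g <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "3\t3",
               "Name\tDescription\ts1\ts2\ts3",
               "gA\tna\t1\t2\t3"), g)
  expect_error(read_expression(g, format = "gct"), "dimension")
  h <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("nope", "2\t3"), h)
  expect_error(read_expression(h, format = "gct"), "#1.2")
})

test_that("duplicate gene rows collapse by mean with a log message", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "TP53\t1\t5", "KRAS\t2\t2", "TP53\t3\t7"), f)
  expect_message(x <- read_expression(f, format = "tsv"), "collapsing")
  expect_equal(nrow(x), 2)
  # hand collapse: TP53 = mean of (1,3) and (5,7)
  expect_equal(unname(unclass(x)["TP53", ]), c(2, 6))
  # non-numeric body cells are named by location
  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "TP53\t1\toops"), g)
  expect_error(read_expression(g, format = "tsv"), "row 'TP53'.*column 's2'")
  # duplicated sample ids are an error
  h <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts1", "TP53\t1\t2"), h)
  expect_error(read_expression(h, format = "tsv"), "duplicate sample")
})

test_that("GMT parsing de-duplicates genes and reports bad lines", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB\tA", "S2\tdesc\tC"), f)
  gs <- read_gmt(f)
  expect_equal(length(gs), 2L)
  expect_equal(gs$S1, c("A", "B"))
  expect_equal(gs$S2, "C")

  empty <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(), empty)
  expect_length(read_gmt(empty), 0)

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA", "S2\tonlydesc"), bad)
  expect_error(read_gmt(bad), "line 2")

  # round trip
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, out)
  rt <- read_gmt(out)
  expect_equal(names(rt), names(gs))
  expect_equal(rt$S1, gs$S1)
  expect_equal(rt$S2, gs$S2)
})

test_that("drug response tables keep blanks as missing and round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,cisplatin,gefitinib", "c1,1.5,", "c2,2.5,3.5"), f)
  x <- read_drug_response(f, measure = "log_ic50")
  expect_equal(sum(is.na(x)), 1L)
  expect_true(is.na(unclass(x)["c1", "gefitinib"]))
  expect_equal(measure(x), "log_ic50")

  out <- withr::local_tempfile(fileext = ".csv")
  write_drug_response(x, out)
  y <- read_drug_response(out, measure = "log_ic50")
  expect_identical(unclass(y), unclass(x))

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,d1", "c1,-0.5"), g)
  expect_warning(z <- read_drug_response(g, measure = "auc"), "negative AUC")
  expect_equal(unclass(z)["c1", "d1"], -0.5)
  expect_error(read_drug_response(g, measure = "ec50"))
})

test_that("run_config validates thresholds and reads YAML with defaults", {
  cfg <- run_config()
  expect_equal(cfg$soc_drugs, c("cisplatin", "docetaxel"))
  expect_equal(cfg$resistant_fraction, 0.20)
  expect_equal(cfg$alpha, 0.05)
  expect_equal(cfg$gsea_fdr_q, 0.25)
  expect_error(run_config(resistant_fraction = 1.2))
  expect_error(run_config(cv_folds = 1))

  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 7", "alpha: 0.01", "soc_drugs: [cisplatin, docetaxel]"), f)
  cfg2 <- read_run_config(f)
  expect_equal(cfg2$seed, 7L)
  expect_equal(cfg2$alpha, 0.01)
  expect_equal(cfg2$gsea_fdr_q, 0.25)
  g <- withr::local_tempfile(fileext = ".yaml")
  writeLines("alhpa: 0.01", g)
  expect_error(read_run_config(g), "unknown config key")
})
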