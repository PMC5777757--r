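#' Construct an expression matrix
#'
#' The unit of data shuttled between all pipeline stages: a genes x samples
#' matrix of log-scale expression values together with a free-text platform
#' label (e.g. `"affymetrix"`, `"agilent"`, `"rnaseq"`).
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names.
#' @param platform Character scalar platform label.
#' @return An object of class `ExpressionMatrix` (a named numeric matrix with
#'   a `platform` attribute).
#' @export
expression_matrix <- function(values, platform = "unknown") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene row names and sample column names")
  dup_g <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_g))
    stop("duplicate gene ids: ", paste(unique(dup_g), collapse = ", "))
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(unique(dup_s), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  structure(values, platform = as.character(platform)[1],
            class = c("ExpressionMatrix", "matrix", "array"))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (platform: %s)\n",
              nrow(x), ncol(x), attr(x, "platform")))
  invisible(x)
}

#' Platform label of an expression or prediction matrix
#' @param x An `ExpressionMatrix` or `PredictionMatrix`.
#' @return Character scalar.
#' @export
platform <- function(x) attr(x, "platform")

# Rebuild the class/platform attributes after subsetting a plain matrix.
as_expression_matrix <- function(values, platform) {
  expression_matrix(unclass(values), platform = platform)
}

#' Construct a drug response table
#'
#' Samples x drugs matrix of measured drug response.  Training tables carry
#' log-IC50 values (lower = more sensitive); in vitro validation tables carry
#' dose-response AUCs (higher = more resistant).  Missing entries are allowed
#' (screening panels are incomplete); non-missing entries must be finite.
#'
#' @param values Numeric matrix, samples in rows, drugs in columns.
#' @param measure Either `"log_ic50"` or `"auc"`.
#' @return An object of class `DrugResponseTable`.
#' @export
drug_response_table <- function(values, measure = c("log_ic50", "auc")) {
  measure <- match.arg(measure)
  if (!is.matrix(values) || !is.numeric(values))
    stop("drug response values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("drug response table needs sample row names and drug column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids in drug response table")
  if (anyDuplicated(colnames(values)))
    stop("duplicate drug ids in drug response table")
  if (any(is.infinite(values) | is.nan(values)))
    stop("drug response values must be finite or NA")
  structure(values, measure = measure,
            class = c("DrugResponseTable", "matrix", "array"))
}

#' Measurement type of a drug response table
#' @param x A `DrugResponseTable`.
#' @return `"log_ic50"` or `"auc"`.
#' @export
measure <- function(x) attr(x, "measure")

#' @export
print.DrugResponseTable <- function(x, ...) {
  cat(sprintf("DrugResponseTable: %d samples x %d drugs (%s, %d missing)\n",
              nrow(x), ncol(x), attr(x, "measure"), sum(is.na(x))))
  invisible(x)
}

#' Construct a gene set collection
#'
#' @param sets Named list of character vectors of gene ids.
#' @param source Free-text provenance label.
#' @return An object of class `GeneSetCollection` (named list).
#' @export
gene_set_collection <- function(sets, source = "unknown") {
  if (length(sets)) {
    if (is.null(names(sets)) || any(names(sets) == ""))
      stop("every gene set needs a name")
    if (anyDuplicated(names(sets)))
      stop("duplicate gene set names")
    sets <- lapply(sets, function(g) unique(as.character(g)))
    if (any(lengths(sets) == 0))
      stop("empty gene set after de-duplication")
  }
  structure(as.list(sets), source = source, class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets (source: %s)\n",
              length(x), attr(x, "source")))
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles every tunable threshold of the screen.  Defaults reproduce the
#' published analysis settings: SOC operationalised as the cisplatin +
#' docetaxel mean, top 20% of SOC scores called non-responders, candidate
#' threshold P < 0.05, GSEA FDR q < 0.25.
#'
#' @param soc_drugs Drug ids averaged into the SOC score.
#' @param resistant_fraction Fraction of samples labelled SOC non-responders
#'   under the top-quantile rule, in (0, 1).
#' @param alpha Significance threshold for the drug screen t-tests.
#' @param gsea_fdr_q FDR q threshold for the pathway opposition filter.
#' @param n_permutations Phenotype permutations for GSEA.
#' @param seed Root random seed; recorded in every output artifact.
#' @param variance_filter_fraction Fraction of highest-variance genes kept
#'   before model fitting, in (0, 1].
#' @param ridge_penalty_grid Non-negative ridge penalties searched by
#'   cross-validation.
#' @param cv_folds Number of cross-validation folds.
#' @param min_set_size,max_set_size Gene set size limits for GSEA.
#' @return An object of class `RunConfig` (a named list).
#' @export
run_config <- function(soc_drugs = c("cisplatin", "docetaxel"),
                       resistant_fraction = 0.20,
                       alpha = 0.05,
                       gsea_fdr_q = 0.25,
                       n_permutations = 1000L,
                       seed = 1L,
                       variance_filter_fraction = 1.0,
                       ridge_penalty_grid = 10^seq(-2, 1, length.out = 5),
                       cv_folds = 10L,
                       min_set_size = 5L,
                       max_set_size = 500L) {
  stopifnot(
    length(soc_drugs) >= 1,
    resistant_fraction > 0, resistant_fraction < 1,
    alpha > 0, alpha < 1,
    gsea_fdr_q > 0, gsea_fdr_q <= 1,
    n_permutations >= 1,
    variance_filter_fraction > 0, variance_filter_fraction <= 1,
    all(ridge_penalty_grid >= 0),
    cv_folds >= 2
  )
  structure(list(
    soc_drugs = as.character(soc_drugs),
    resistant_fraction = resistant_fraction,
    alpha = alpha,
    gsea_fdr_q = gsea_fdr_q,
    n_permutations = as.integer(n_permutations),
    seed = as.integer(seed),
    variance_filter_fraction = variance_filter_fraction,
    ridge_penalty_grid = sort(as.numeric(ridge_penalty_grid)),
    cv_folds = as.integer(cv_folds),
    min_set_size = as.integer(min_set_size),
    max_set_size = as.integer(max_set_size)
  ), class = "RunConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; absent keys take the
#' defaults.  Unknown keys are an error so that typos do not silently fall
#' back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  extra <- setdiff(names(vals), c(known, "synthetic", "pipeline"))
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  do.call(run_config, vals[intersect(names(vals), known)])
}

# ---------------------------------------------------------------------------
# Readers / writers

.read_delim_matrix <- function(path, sep) {
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2) stop("expected an id column plus at least one data column")
  ids <- as.character(df[[1]])
  header <- colnames(df)[-1]          # before [.data.frame uniquifies them
  body <- df[, -1, drop = FALSE]
  colnames(body) <- header
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      suppressWarnings(num <- as.numeric(body[[j]]))
      bad <- which(is.na(num) & !is.na(body[[j]]) & body[[j]] != "")
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                     body[[j]][bad[1]], ids[bad[1]], colnames(body)[j]))
      body[[j]] <- num
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  m
}

#' Read an expression matrix from TSV, CSV or GCT
#'
#' TSV/CSV files carry gene ids in the first column and sample ids in the
#' header.  GCT files follow the standard 1.2 layout (`#1.2` header, a
#' dimensions line, then `Name`/`Description` columns).  Duplicate gene rows
#' are collapsed by their mean (a symmetric, order-independent rule) and the
#' collapse is logged.
#'
#' @param path Input file.
#' @param format One of `"tsv"`, `"csv"`, `"gct"`.
#' @param platform Platform label attached to the result.
#' @return An `ExpressionMatrix`.
#' @export
read_expression <- function(path, format = c("tsv", "csv", "gct"),
                            platform = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3 || !startsWith(lines[1], "#1.2"))
      stop("not a GCT 1.2 file (missing '#1.2' header): ", path)
    dims <- as.integer(strsplit(lines[2], "\t", fixed = TRUE)[[1]][1:2])
    df <- utils::read.table(text = lines[-(1:2)], sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "\"", comment.char = "")
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -(1:2), drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    if (nrow(m) != dims[1] || ncol(m) != dims[2])
      stop(sprintf("GCT dimension line says %d x %d but body is %d x %d",
                   dims[1], dims[2], nrow(m), ncol(m)))
  } else {
    m <- .read_delim_matrix(path, sep = if (format == "csv") "," else "\t")
  }
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (anyDuplicated(rownames(m))) {
    dups <- unique(rownames(m)[duplicated(rownames(m))])
    ss_log("collapsing %d duplicated gene id(s) by mean: %s",
           length(dups), paste(utils::head(dups, 5), collapse = ", "))
    m <- rowsum(m, group = rownames(m), reorder = FALSE) /
      as.vector(table(rownames(m))[unique(rownames(m))])
  }
  expression_matrix(m, platform = platform)
}

#' Write an expression matrix to TSV or CSV
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output file.
#' @param format `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  df <- data.frame(gene_id = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line is `name <tab> description <tab> gene [<tab> gene ...]`.  The
#' description is discarded; duplicate genes within a set are removed.
#'
#' @param path Input GMT file.
#' @return A `GeneSetCollection`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(gene_set_collection(list(), source = path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short))
    stop(sprintf("GMT line %d has fewer than 3 tab-separated fields", short[1]))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  gene_set_collection(sets, source = path)
}

#' Write gene sets to a GMT file
#' @param x A `GeneSetCollection`.
#' @param path Output file.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path, description = "na") {
  lines <- vapply(names(x), function(nm) {
    paste(c(nm, description, x[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a drug response table from CSV
#'
#' Sample ids in the first column, drug ids in the header; blank cells become
#' missing values.  Negative AUC values are physically implausible but are
#' kept with a warning (they occur in noisy screens).
#'
#' @param path Input CSV.
#' @param measure `"log_ic50"` or `"auc"`.
#' @return A `DrugResponseTable`.
#' @export
read_drug_response <- function(path, measure = c("log_ic50", "auc")) {
  measure <- match.arg(measure)
  if (!file.exists(path)) stop("drug response file not found: ", path)
  m <- .read_delim_matrix(path, sep = ",")
  if (measure == "auc" && any(m < 0, na.rm = TRUE)) {
    warning(sprintf("%d negative AUC value(s) in %s kept as-is",
                    sum(m < 0, na.rm = TRUE), path))
  }
  drug_response_table(m, measure = measure)
}

#' Write a drug response table to CSV
#' @param x A `DrugResponseTable`.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_drug_response <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
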