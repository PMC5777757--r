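#' Restrict two expression matrices to their shared genes
#'
#' Training panel and target cohort must be on an identical gene universe
#' (in identical order) before joint homogenization; genes private to either
#' matrix are dropped.
#'
#' @param train,test `ExpressionMatrix` objects.
#' @return List with elements `train` and `test`, both restricted to the
#'   shared genes in the same (training) order.
#' @export
intersect_genes <- function(train, test) {
  shared <- intersect(rownames(train), rownames(test))
  if (length(shared) < 2)
    stop("fewer than 2 shared genes between training and test matrices")
  list(
    train = as_expression_matrix(train[shared, , drop = FALSE], platform(train)),
    test = as_expression_matrix(test[shared, , drop = FALSE], platform(test))
  )
}

#' Homogenize training and target expression by pooled quantile normalization
#'
#' Cross-platform transfer of a cell-line-trained model requires the target
#' cohort to share the training data's expression distribution.  Training
#' and target samples are pooled and quantile-normalized together: after the
#' call, every sample's sorted value vector equals the common reference
#' quantile vector (the mean of the pooled per-sample sorted vectors).  Ties
#' within a sample receive the mean of the reference quantiles they span.
#'
#' @param train,test `ExpressionMatrix` objects on identical genes in
#'   identical order (see [intersect_genes()]).
#' @return List with homogenized `train` and `test`.
#' @export
homogenize <- function(train, test) {
  if (!identical(rownames(train), rownames(test)))
    stop("train and test must share identical gene ids in identical order; ",
         "run intersect_genes() first")
  pooled <- cbind(unclass(train), unclass(test))
  sds <- apply(pooled, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(pooled)[sds == 0], collapse = ", "))
  norm <- limma::normalizeQuantiles(pooled, ties = TRUE)
  dimnames(norm) <- dimnames(pooled)
  list(
    train = as_expression_matrix(norm[, seq_len(ncol(train)), drop = FALSE],
                                 platform(train)),
    test = as_expression_matrix(norm[, ncol(train) + seq_len(ncol(test)),
                                     drop = FALSE], platform(test))
  )
}

#' Keep the highest-variance genes of an expression matrix
#'
#' Variance is computed on the training portion only (the matrix given
#' here); downstream cohorts must be subset to the same genes.  Ties in
#' variance are broken by gene id so the kept set is deterministic.
#'
#' @param expr An `ExpressionMatrix`.
#' @param keep_fraction Fraction of genes kept, in (0, 1].
#' @return An `ExpressionMatrix` with `ceiling(keep_fraction * n_genes)`
#'   rows, original order preserved.
#' @export
filter_low_variance <- function(expr, keep_fraction) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  if (keep_fraction == 1) return(expr)
  v <- apply(unclass(expr), 1, stats::var)
  k <- ceiling(keep_fraction * nrow(expr))
  ord <- order(-v, rownames(expr))
  keep <- sort(ord[seq_len(k)])
  as_expression_matrix(expr[keep, , drop = FALSE], platform(expr))
}

# ---------------------------------------------------------------------------
# Ridge engine.  Features (genes) are standardized to mean 0 / sd 1 on the
# training samples; the intercept is unpenalized (it equals the response
# mean on standardized features).  Coefficients solve
#   (X'X + lambda I) beta = X'y
# via the SVD of X, which handles p > n and a whole grid of penalties (and
# many response vectors) at marginal extra cost.

.standardize <- function(X) {
  ctr <- colMeans(X)
  sc <- apply(X, 2, stats::sd)
  ok <- sc > 0
  Xs <- sweep(sweep(X[, ok, drop = FALSE], 2, ctr[ok]), 2, sc[ok], "/")
  list(X = Xs, center = ctr[ok], scale = sc[ok], kept = colnames(X)[ok])
}

# Coefficients for every lambda: list over lambdas of p x q matrices.
.ridge_coefs <- function(sv, Y, lambdas) {
  G <- crossprod(sv$u, Y)                      # r x q
  lapply(lambdas, function(lam) {
    d <- sv$d
    w <- if (lam == 0) ifelse(d > d[1] * 1e-10, 1 / d, 0) else d / (d^2 + lam)
    sv$v %*% (w * G)
  })
}

# K-fold CV over a penalty grid for a matrix of responses sharing one
# design.  Returns per-drug chosen lambda (ties -> smallest), the held-out
# predictions at the chosen lambda, and the CV mean squared errors.
.ridge_cv <- function(X, Y, lambdas, folds) {
  n <- nrow(X)
  q <- ncol(Y)
  L <- length(lambdas)
  cvpred <- array(NA_real_, dim = c(n, q, L))
  for (f in sort(unique(folds))) {
    hold <- folds == f
    st <- .standardize(X[!hold, , drop = FALSE])
    sv <- svd(st$X)
    coefs <- .ridge_coefs(sv, Y[!hold, , drop = FALSE], lambdas)
    ybar <- colMeans(Y[!hold, , drop = FALSE])
    Xh <- sweep(sweep(X[hold, st$kept, drop = FALSE], 2, st$center),
                2, st$scale, "/")
    for (l in seq_len(L))
      cvpred[hold, , l] <- sweep(Xh %*% coefs[[l]], 2, ybar, "+")
  }
  mse <- matrix(NA_real_, q, L)
  for (l in seq_len(L)) mse[, l] <- colMeans((cvpred[, , l] - Y)^2)
  best <- apply(mse, 1, which.min)             # ties -> first = smallest lambda
  cvp <- matrix(NA_real_, n, q)
  for (j in seq_len(q)) cvp[, j] <- cvpred[, j, best[j]]
  list(lambda_index = best, cv_pred = cvp, mse = mse)
}

.make_folds <- function(n, k, seed) {
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Fit a ridge model linking expression to drug response
#'
#' Trains one penalized linear model per drug on a cell-line panel: genes are
#' standardized, the penalty is selected from `config$ridge_penalty_grid` by
#' k-fold cross-validated mean squared error (ties broken towards the
#' smallest penalty, i.e. least shrinkage), and the model's expected
#' predictive value is summarised as the Pearson correlation between held-out
#' predictions and the observed response.  With a single-element penalty grid
#' the penalty is taken as fixed and no cross-validation is run.
#'
#' @param train_expr `ExpressionMatrix` (genes x cell lines).
#' @param response Numeric vector of log-IC50 values, one per training
#'   sample (aligned with the columns of `train_expr`); missing entries are
#'   dropped.
#' @param config A [run_config()].
#' @param drug_id Drug label stored in the model.
#' @return An object of class `RidgeModel`: coefficients on the standardized
#'   feature scale, per-gene centers/scales, unpenalized intercept, chosen
#'   penalty and a training summary (`n_train`, `cv_correlation`,
#'   `penalty_grid`).
#' @export
fit_ridge <- function(train_expr, response, config = run_config(),
                      drug_id = "drug") {
  if (length(response) != ncol(train_expr))
    stop("response length must match the number of training samples")
  ok <- !is.na(response)
  y <- response[ok]
  X <- t(unclass(train_expr)[, ok, drop = FALSE])
  n <- length(y)
  grid <- config$ridge_penalty_grid
  if (stats::var(y) == 0) {
    warning("constant response for drug '", drug_id,
            "': returning intercept-only model")
    return(.ridge_model(drug_id, character(), numeric(), numeric(), numeric(),
                        intercept = y[1], penalty = NA_real_,
                        n_train = n, cv_correlation = NA_real_, grid = grid))
  }
  if (length(grid) > 1 && n < config$cv_folds)
    stop(sprintf("only %d non-missing samples but %d CV folds requested",
                 n, config$cv_folds))
  if (length(grid) > 1) {
    folds <- .make_folds(n, config$cv_folds, stage_seed(config$seed, "folds"))
    cv <- .ridge_cv(X, matrix(y, ncol = 1), grid, folds)
    lam <- grid[cv$lambda_index[1]]
    cv_cor <- stats::cor(cv$cv_pred[, 1], y)
  } else {
    lam <- grid[1]
    cv_cor <- NA_real_
  }
  st <- .standardize(X)
  sv <- svd(st$X)
  beta <- .ridge_coefs(sv, matrix(y, ncol = 1), lam)[[1]][, 1]
  .ridge_model(drug_id, st$kept, beta, st$center, st$scale,
               intercept = mean(y), penalty = lam,
               n_train = n, cv_correlation = cv_cor, grid = grid)
}

.ridge_model <- function(drug_id, gene_ids, coefficients, center, scale,
                         intercept, penalty, n_train, cv_correlation, grid) {
  structure(list(
    drug_id = drug_id,
    gene_ids = gene_ids,
    coefficients = stats::setNames(as.numeric(coefficients), gene_ids),
    center = stats::setNames(as.numeric(center), gene_ids),
    scale = stats::setNames(as.numeric(scale), gene_ids),
    intercept = intercept,
    penalty = penalty,
    training_summary = list(n_train = n_train, cv_correlation = cv_correlation,
                            penalty_grid = grid)
  ), class = "RidgeModel")
}

#' @export
print.RidgeModel <- function(x, ...) {
  cat(sprintf("RidgeModel '%s': %d genes, lambda = %s, cv r = %s\n",
              x$drug_id, length(x$gene_ids), format(x$penalty),
              format(x$training_summary$cv_correlation, digits = 3)))
  invisible(x)
}

#' Predict log-IC50 for a cohort from a fitted ridge model
#'
#' @param model A `RidgeModel`.
#' @param cohort_expr `ExpressionMatrix` homogenized with the model's
#'   training data; all model genes must be present.
#' @return Named numeric vector of predicted log-IC50, one per sample.
#' @export
predict_ic50 <- function(model, cohort_expr) {
  if (length(model$gene_ids) == 0)
    return(stats::setNames(rep(model$intercept, ncol(cohort_expr)),
                           colnames(cohort_expr)))
  missing <- setdiff(model$gene_ids, rownames(cohort_expr))
  if (length(missing))
    stop("cohort is missing model genes: ",
         paste(utils::head(missing, 10), collapse = ", "))
  X <- t(unclass(cohort_expr)[model$gene_ids, , drop = FALSE])
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  stats::setNames(as.numeric(model$intercept + Xs %*% model$coefficients),
                  rownames(X))
}

#' Impute drug response for one or more cohorts
#'
#' The pipeline's engine: for every cohort, the training panel and the
#' cohort are restricted to shared genes, homogenized together by pooled
#' quantile normalization, filtered to the most variable genes (variance
#' measured on the training portion), and one ridge model per drug is
#' fitted and applied.  Each cohort is homogenized with the training panel
#' independently, so per-drug models are refit per cohort pairing.  Drugs
#' whose models cannot be fit (e.g. too few non-missing responses) are
#' skipped with a log message, not an error.
#'
#' @param train_expr Training `ExpressionMatrix` (genes x cell lines).
#' @param train_response `DrugResponseTable` with measure `"log_ic50"`
#'   (cell lines x drugs); rows must cover the training samples.
#' @param cohorts A single `ExpressionMatrix` or a list of them.
#' @param config A [run_config()].
#' @return A list of `PredictionMatrix` objects (samples x drugs matrices of
#'   predicted log-IC50 with a `platform` attribute and a `model_info`
#'   attribute holding per-drug penalty and CV correlation), one per cohort,
#'   named by platform.
#' @export
impute_all <- function(train_expr, train_response, cohorts,
                       config = run_config()) {
  if (measure(train_response) != "log_ic50")
    stop("training response must carry measure 'log_ic50'")
  if (inherits(cohorts, "ExpressionMatrix")) cohorts <- list(cohorts)
  missing_lines <- setdiff(colnames(train_expr), rownames(train_response))
  if (length(missing_lines))
    stop("training lines absent from response table: ",
         paste(utils::head(missing_lines, 5), collapse = ", "))
  Yfull <- unclass(train_response)[colnames(train_expr), , drop = FALSE]
  out <- lapply(cohorts, function(cohort) {
    .impute_one_cohort(train_expr, Yfull, cohort, config)
  })
  names(out) <- vapply(out, platform, "")
  out
}

.impute_one_cohort <- function(train_expr, Yfull, cohort, config) {
  pair <- intersect_genes(train_expr, cohort)
  pair <- homogenize(pair$train, pair$test)
  train <- filter_low_variance(pair$train, config$variance_filter_fraction)
  test <- as_expression_matrix(pair$test[rownames(train), , drop = FALSE],
                               platform(pair$test))
  Xall <- t(unclass(train))
  grid <- config$ridge_penalty_grid
  n_samp <- ncol(test)
  drugs <- colnames(Yfull)
  pred <- matrix(NA_real_, n_samp, length(drugs),
                 dimnames = list(colnames(test), drugs))
  info <- data.frame(drug_id = drugs, penalty = NA_real_,
                     cv_correlation = NA_real_, n_train = NA_integer_,
                     stringsAsFactors = FALSE)
  usable <- rep(TRUE, length(drugs))

  # Group drugs by missingness pattern so that drugs screened on the same
  # lines share fold splits, standardization and SVDs.
  pattern <- apply(is.na(Yfull), 2, function(z) paste(which(z), collapse = ","))
  for (pat in unique(pattern)) {
    idx <- which(pattern == pat)
    keep_rows <- !is.na(Yfull[, idx[1]])
    n <- sum(keep_rows)
    if (n < max(config$cv_folds, 3)) {
      ss_log("skipping %d drug(s) with only %d responses (pattern '%s')",
             length(idx), n, pat)
      usable[idx] <- FALSE
      next
    }
    X <- Xall[keep_rows, , drop = FALSE]
    Y <- Yfull[keep_rows, idx, drop = FALSE]
    const <- apply(Y, 2, stats::var) == 0
    if (any(const)) {
      for (j in idx[const]) {
        pred[, j] <- mean(Yfull[keep_rows, j])
        info$penalty[j] <- NA_real_
        info$n_train[j] <- n
      }
      idx <- idx[!const]
      Y <- Y[, !const, drop = FALSE]
      if (!length(idx)) next
    }
    if (length(grid) > 1) {
      folds <- .make_folds(n, config$cv_folds, stage_seed(config$seed, "folds"))
      cv <- .ridge_cv(X, Y, grid, folds)
      lam_idx <- cv$lambda_index
      cv_cor <- vapply(seq_along(idx),
                       function(j) stats::cor(cv$cv_pred[, j], Y[, j]), 0)
    } else {
      lam_idx <- rep(1L, length(idx))
      cv_cor <- rep(NA_real_, length(idx))
    }
    st <- .standardize(X)
    sv <- svd(st$X)
    coefs <- .ridge_coefs(sv, Y, grid)
    Xt <- sweep(sweep(t(unclass(test))[, st$kept, drop = FALSE], 2, st$center),
                2, st$scale, "/")
    ybar <- colMeans(Y)
    for (l in unique(lam_idx)) {
      cols <- which(lam_idx == l)
      pred[, idx[cols]] <- sweep(Xt %*% coefs[[l]][, cols, drop = FALSE],
                                 2, ybar[cols], "+")
    }
    info$penalty[idx] <- grid[lam_idx]
    info$cv_correlation[idx] <- cv_cor
    info$n_train[idx] <- n
  }
  pred <- pred[, usable, drop = FALSE]
  prediction_matrix(pred, platform = platform(test),
                    model_info = info[usable, , drop = FALSE])
}

#' Construct a prediction matrix
#'
#' @param values Numeric samples x drugs matrix of predicted log-IC50.
#' @param platform Platform label of the cohort the predictions belong to.
#' @param model_info Optional per-drug data frame (penalty, CV correlation).
#' @return An object of class `PredictionMatrix`.
#' @export
prediction_matrix <- function(values, platform = "unknown",
                              model_info = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("prediction values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("prediction matrix needs sample row names and drug column names")
  if (!all(is.finite(values)))
    stop("prediction matrix contains non-finite values")
  structure(values, platform = as.character(platform)[1],
            model_info = model_info,
            class = c("PredictionMatrix", "matrix", "array"))
}

#' @export
print.PredictionMatrix <- function(x, ...) {
  cat(sprintf("PredictionMatrix: %d samples x %d drugs (platform: %s)\n",
              nrow(x), ncol(x), attr(x, "platform")))
  invisible(x)
}
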