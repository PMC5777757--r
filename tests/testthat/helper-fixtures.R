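# Small builders and independent oracles shared across test files.

make_expr <- function(values, genes = NULL, samples = NULL,
                      platform = "test") {
  if (is.null(genes))
    genes <- rownames(values) %||% sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples))
    samples <- colnames(values) %||% sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, platform = platform)
}

make_pred <- function(values, samples = NULL, drugs = NULL,
                      platform = "test") {
  if (is.null(samples))
    samples <- rownames(values) %||% sprintf("s%02d", seq_len(nrow(values)))
  if (is.null(drugs))
    drugs <- colnames(values) %||% sprintf("d%02d", seq_len(ncol(values)))
  dimnames(values) <- list(samples, drugs)
  prediction_matrix(values, platform = platform)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bare numeric matrix: drop socscreen attributes for value comparisons.
bare <- function(m) {
  m <- unclass(m)
  attr(m, "platform") <- NULL
  attr(m, "model_info") <- NULL
  m
}

random_expr <- function(n_genes, n_samples, seed, platform = "test") {
  set.seed(seed)
  make_expr(matrix(rnorm(n_genes * n_samples), n_genes, n_samples),
            platform = platform)
}

# Textbook pooled-variance two-sample t (independent of the package path).
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = nx + ny - 2, p_two = 2 * pt(-abs(t), nx + ny - 2),
       p_less = pt(t, nx + ny - 2))
}

# Direct standardized ridge solve: (X'X + lambda I) beta = X'y.
oracle_ridge <- function(X, y, lambda) {
  Xs <- scale(X)
  keep <- attr(Xs, "scaled:scale") > 0
  Xs <- Xs[, keep, drop = FALSE]
  p <- ncol(Xs)
  beta <- solve(crossprod(Xs) + lambda * diag(p), crossprod(Xs, y))
  list(beta = as.numeric(beta), intercept = mean(y),
       fitted = mean(y) + as.numeric(Xs %*% beta))
}

# Brute-force weighted-KS enrichment score over every list position.
oracle_es <- function(metric_sorted, hit_positions, p = 1) {
  n <- length(metric_sorted)
  nh <- length(hit_positions)
  if (nh == n) return(1)
  w <- abs(metric_sorted)^p
  running <- 0
  best <- 0
  for (i in seq_len(n)) {
    running <- running +
      if (i %in% hit_positions) w[i] / sum(w[hit_positions]) else -1 / (n - nh)
    if (abs(running) > abs(best)) best <- running
  }
  best
}
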