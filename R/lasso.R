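# Joint analysis: all genes enter one L1-penalised logistic regression of
# disease status; the selected genes are those with nonzero coefficients at
# a cross-validated penalty. Fitting is delegated to glmnet; this module
# owns fold construction, the penalty rule, and the selection contract.

#' Configure the lasso gene selection
#'
#' @param n_folds Cross-validation folds (default 10). When the smaller
#'   class has fewer members than `n_folds`, leave-one-out folds are used
#'   instead (e.g. a 5-case/5-control cohort).
#' @param lambda_rule `"min_deviance"` (penalty minimising cross-validated
#'   binomial deviance; default) or `"one_se"` (largest penalty within one
#'   standard error of the minimum).
#' @param lambda_grid_size Length of the log-spaced penalty grid descending
#'   from the smallest all-zero penalty (default 100).
#' @param standardize Standardise gene columns to unit variance before
#'   penalising (default TRUE), so selection does not depend on per-gene
#'   scale or column order.
#' @param seed Seed for the fold assignment.
#' @param max_iter,tol Solver budget and convergence threshold.
#' @return A `lasso_config` list.
#' @export
lasso_config <- function(n_folds = 10L,
                         lambda_rule = c("min_deviance", "one_se"),
                         lambda_grid_size = 100L, standardize = TRUE,
                         seed = 1L, max_iter = 1e5, tol = 1e-7) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(n_folds >= 2L, lambda_grid_size >= 2L, tol > 0)
  structure(list(n_folds = as.integer(n_folds), lambda_rule = lambda_rule,
                 lambda_grid_size = as.integer(lambda_grid_size),
                 standardize = standardize, seed = as.integer(seed),
                 max_iter = max_iter, tol = tol),
            class = "lasso_config")
}

# Stratified fold ids: each class is shuffled and dealt round-robin, so every
# fold contains both classes whenever class sizes allow it.
stratified_folds <- function(labels, n_folds, seed) {
  n <- length(labels)
  min_class <- min(table(labels))
  if (min_class < n_folds) return(seq_len(n))  # leave-one-out fallback
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  foldid <- integer(n)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  foldid
}

#' Select genes by L1-penalised logistic regression
#'
#' Fits case/control status on all gene columns jointly over a log-spaced
#' penalty grid descending from the smallest penalty at which every gene
#' coefficient is zero, picks the penalty by stratified cross-validated
#' binomial deviance (per `cfg$lambda_rule`), and returns the genes with
#' nonzero coefficients there. Deterministic given `cfg$seed`.
#'
#' @param gm A [gene_matrix()] on the log2 scale.
#' @param cfg A [lasso_config()].
#' @param lambda Optional override: a numeric penalty, or `"max"` to force
#'   the smallest all-zero penalty (yields an empty, intercept-only
#'   selection). Skips cross-validation.
#' @return A [selection_set()] with method `"lasso"`; `params` records the
#'   chosen penalty, the rule, and the nonzero coefficients.
#' @export
lasso_select <- function(gm, cfg = lasso_config(), lambda = NULL) {
  stopifnot(inherits(gm, "gene_matrix"), inherits(cfg, "lasso_config"))
  x <- t(gm$values)
  y <- as.integer(gm$labels == "case")
  n <- nrow(x)
  if (n < cfg$n_folds && is.null(lambda))
    stop("reduce folds: only ", n, " samples for ", cfg$n_folds, "-fold CV")

  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(x, y, family = "binomial",
                          nlambda = cfg$lambda_grid_size,
                          standardize = cfg$standardize,
                          maxit = cfg$max_iter, thresh = cfg$tol)
    if (identical(lambda, "max")) {
      lam <- fit$lambda[1]
    } else {
      lam <- as.numeric(lambda)
      if (!lam %in% fit$lambda)  # refit with lam on the grid: exact solution
        fit <- glmnet::glmnet(x, y, family = "binomial",
                              lambda = sort(unique(c(fit$lambda, lam)),
                                            decreasing = TRUE),
                              standardize = cfg$standardize,
                              maxit = cfg$max_iter, thresh = cfg$tol)
    }
    cf <- as.matrix(stats::coef(fit, s = lam))[, 1]
  } else {
    foldid <- stratified_folds(gm$labels, cfg$n_folds, cfg$seed)
    loo <- length(unique(foldid)) == n
    # leave-one-out folds on tiny cohorts trip glmnet's small-fold warnings;
    # they are expected there, not actionable
    cv <- withCallingHandlers(
      glmnet::cv.glmnet(x, y, family = "binomial",
                        type.measure = "deviance",
                        nlambda = cfg$lambda_grid_size,
                        standardize = cfg$standardize, foldid = foldid,
                        grouped = !loo,
                        maxit = cfg$max_iter, thresh = cfg$tol),
      warning = function(w) {
        if (grepl("fewer than|grouped=FALSE|too small", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    lam <- if (cfg$lambda_rule == "min_deviance") cv$lambda.min else cv$lambda.1se
    cf <- as.matrix(stats::coef(cv, s = lam))[, 1]
  }
  nz <- cf[-1][cf[-1] != 0]
  selection_set(gm$dataset_id, "lasso", names(nz),
                params = list(lambda = lam, lambda_rule = cfg$lambda_rule,
                              n_folds = cfg$n_folds,
                              intercept = unname(cf[1]),
                              coefficients = nz))
}

#' Full lasso path selection sizes
#'
#' Diagnostic helper exposing the number of nonzero coefficients at each
#' grid penalty (descending), used to check that the selection size is
#' non-increasing in the penalty and empty at the grid top.
#'
#' @param gm A [gene_matrix()].
#' @param cfg A [lasso_config()].
#' @return Data frame with columns `lambda`, `n_selected`.
#' @export
lasso_path_sizes <- function(gm, cfg = lasso_config()) {
  x <- t(gm$values)
  y <- as.integer(gm$labels == "case")
  fit <- glmnet::glmnet(x, y, family = "binomial",
                        nlambda = cfg$lambda_grid_size,
                        standardize = cfg$standardize,
                        maxit = cfg$max_iter, thresh = cfg$tol)
  data.frame(lambda = fit$lambda, n_selected = fit$df)
}
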