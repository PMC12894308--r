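#' PCA composite index for a predictor group
#'
#' Variables are z-scored, the first principal component of their
#' covariance (= correlation) matrix is extracted, and its sign is
#' oriented so the scores correlate non-negatively with the mean of the
#' standardized variables (eigenvectors are sign-ambiguous; the rule makes
#' the composite direction reproducible). Constant variables are dropped
#' with a warning.
#'
#' @param vars data.frame / matrix, samples in rows, >= 2 non-constant
#'   variables, >= 3 samples.
#' @param name composite label.
#' @return List of class `composite_index`: `name`, `scores` (zero-mean,
#'   per sample), `variance_explained`, `loadings`, `orientation_sign`.
#' @export
composite_index <- function(vars, name = "composite") {
  m <- as.matrix(vars)
  if (nrow(m) < 3)
    stop_n2onet("need >= 3 samples", "n2onet_insufficient_data_error")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    if (all(sds == 0))
      stop_n2onet("all variables constant", "n2onet_input_error")
    warning(sprintf("dropping %d constant variable(s): %s", sum(sds == 0),
                    paste(colnames(m)[sds == 0], collapse = ", ")))
    m <- m[, sds > 0, drop = FALSE]
  }
  if (ncol(m) < 2)
    stop_n2onet("need >= 2 non-constant variables", "n2onet_input_error")
  z <- scale(m)
  ev <- eigen(cov(z), symmetric = TRUE)
  v1 <- ev$vectors[, 1]
  scores <- as.numeric(z %*% v1)
  s <- if (sd(rowMeans(z)) > 0 && sd(scores) > 0)
    sign(cor(scores, rowMeans(z))) else sign(sum(v1))
  if (s == 0) s <- 1
  structure(list(name = name, scores = s * scores,
                 variance_explained = ev$values[1] / sum(ev$values),
                 loadings = setNames(s * v1, colnames(m)),
                 orientation_sign = s),
            class = "composite_index")
}

#' Random-forest driver importance
#'
#' Regression random forest (bootstrap per tree, `mtry = max(1,
#' floor(p/3))` candidate predictors per split, CART variance-reduction
#' splits, terminal nodes of at most `nodesize` observations) implemented
#' in compiled code against R's RNG, so a seed makes it fully
#' reproducible. Importance is the increase in node purity: the total
#' decrease in node sum of squares attributable to splits on each
#' predictor, averaged over trees. Explained variance is out-of-bag:
#' R2 = 1 - MSE_OOB / var(response).
#'
#' @param predictors data.frame / matrix of per-sample predictors
#'   (n >= 5 rows).
#' @param response numeric N2O rates.
#' @param n_trees number of trees.
#' @param mtry candidate predictors per split (default `max(1,
#'   floor(p/3))`).
#' @param nodesize minimal node size below which splitting stops.
#' @param seed RNG seed (`set.seed` is called when non-NULL).
#' @return List of class `driver_importance`: `importance` (named,
#'   inc-node-purity), `model_r2`, `oob_pred`, `n_trees`, `mtry`, `seed`.
#' @export
rf_importance <- function(predictors, response, n_trees = 500, mtry = NULL,
                          nodesize = 5, seed = 1L) {
  x <- as.matrix(predictors)
  storage.mode(x) <- "double"
  y <- as.numeric(response)
  if (nrow(x) != length(y))
    stop_n2onet("predictors and response differ in length", "n2onet_input_error")
  if (nrow(x) < 5)
    stop_n2onet("need >= 5 samples", "n2onet_insufficient_data_error")
  if (ncol(x) < 1)
    stop_n2onet("need >= 1 predictor", "n2onet_input_error")
  if (sd(y) == 0)
    stop_n2onet("constant response", "n2onet_degenerate_error")
  mtry <- mtry %||% max(1L, floor(ncol(x) / 3))
  if (!is.null(seed)) set.seed(as.integer(seed))
  fit <- forest_cpp(x, y, as.integer(n_trees), as.integer(mtry),
                    as.integer(nodesize))
  oob <- fit$oob_pred
  seen <- fit$oob_count > 0
  mse_oob <- mean((y[seen] - oob[seen])^2)
  structure(list(importance = setNames(fit$importance, colnames(x)),
                 model_r2 = 1 - mse_oob / var(y),
                 oob_pred = ifelse(seen, oob, NA_real_),
                 n_trees = n_trees, mtry = mtry, nodesize = nodesize,
                 seed = seed),
            class = "driver_importance")
}

#' Permutation significance of forest importances and model fit
#'
#' The response is permuted `n_perm` times; the forest is refitted on each
#' permutation with identical settings. Per-predictor
#' p = (1 + #\{null importance >= observed\}) / (1 + n_perm), and the model
#' p-value is computed the same way on the out-of-bag R2, so p-values are
#' never 0.
#'
#' @inheritParams rf_importance
#' @param n_perm number of response permutations (a warning is issued
#'   below 99: resolution too coarse).
#' @return List of class `driver_significance`: `observed` (the
#'   [rf_importance()] fit), `perm_p` (named per predictor), `model_p`,
#'   `stars`, `n_perm`, `seed`.
#' @export
permutation_significance <- function(predictors, response, n_trees = 500,
                                     mtry = NULL, nodesize = 5,
                                     n_perm = 1000, seed = 1L) {
  if (n_perm < 99)
    warning("n_perm < 99: permutation p-value resolution is too coarse")
  x <- as.matrix(predictors)
  obs <- rf_importance(x, response, n_trees = n_trees, mtry = mtry,
                       nodesize = nodesize, seed = seed)
  exceed <- setNames(numeric(ncol(x)), names(obs$importance))
  exceed_r2 <- 0
  for (b in seq_len(n_perm)) {
    yb <- sample(response)
    fb <- rf_importance(x, yb, n_trees = n_trees, mtry = mtry,
                        nodesize = nodesize, seed = NULL)
    exceed <- exceed + (fb$importance >= obs$importance)
    exceed_r2 <- exceed_r2 + (fb$model_r2 >= obs$model_r2)
  }
  perm_p <- (1 + exceed) / (1 + n_perm)
  structure(list(observed = obs, perm_p = perm_p,
                 model_p = (1 + exceed_r2) / (1 + n_perm),
                 stars = vapply(perm_p, stars_for, character(1)),
                 n_perm = n_perm, seed = seed),
            class = "driver_significance")
}
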