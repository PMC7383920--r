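#' Build a line-similarity kernel from a feature matrix
#'
#' Columns are standardized (mean 0, SD 1; zero-variance features
#' dropped with a warning) and K = Z Z' / m, the usual
#' relationship-kernel construction for BLUP with m features, so the
#' diagonal mean is ~1 and K is positive semidefinite.
#'
#' @param feature_matrix Lines x features numeric matrix (e.g.
#'   replicate-averaged log2 metabolite abundances).
#' @return Symmetric PSD kernel matrix with line ids as dimnames and
#'   the standardized matrix in `attr(, "Z")`.
#' @export
build_kernel <- function(feature_matrix) {
  X <- as.matrix(feature_matrix)
  sds <- apply(X, 2, stats::sd)
  zero <- !is.finite(sds) | sds == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance feature(s) dropped")
    X <- X[, !zero, drop = FALSE]
    sds <- sds[!zero]
  }
  if (!ncol(X)) stop("no informative features left")
  Z <- scale(X)
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(rownames(X), rownames(X))
  attr(K, "Z") <- Z
  K
}

# REML fit of y = 1*mu + u + e, u ~ N(0, su2 K), on one training set.
# delta = su2/se2 is profiled by 1-d optimization of the REML
# log-likelihood over log(delta) unless supplied.
blup_fit <- function(K, y, delta = NULL, jitter = 1e-8) {
  n <- length(y)
  ed <- eigen(K + diag(jitter, n), symmetric = TRUE)
  U <- ed$vectors; d <- pmax(ed$values, 0)
  yt <- crossprod(U, y); xt <- crossprod(U, rep(1, n))
  reml_nll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- delta * d + 1
    xwx <- sum(xt^2 / w)
    beta <- sum(xt * yt / w) / xwx
    r <- yt - xt * beta
    s2 <- sum(r^2 / w) / (n - 1)
    0.5 * ((n - 1) * log(s2) + sum(log(w)) + log(xwx) + (n - 1))
  }
  if (is.null(delta)) {
    opt <- stats::optimize(reml_nll, c(-12, 12))
    delta <- exp(opt$minimum)
  }
  w <- delta * d + 1
  beta <- sum(xt * yt / w) / sum(xt^2 / w)
  resid <- y - beta
  # (delta K + I)^{-1} residual, for predicting held-out u
  vinv_r <- U %*% (crossprod(U, resid) / w)
  list(beta = beta, delta = delta, vinv_resid = vinv_r)
}

make_folds <- function(ids, k_folds, seed) {
  n <- length(ids)
  stopifnot(k_folds >= 2, k_folds <= n)
  set.seed(seed)
  stats::setNames(sample(rep(seq_len(k_folds), length.out = n)), ids)
}

#' Cross-validated BLUP predictability
#'
#' Per fold, the mixed model y = mu + u + e with u ~ N(0, su2 K) is fit
#' by REML on the training lines (eigen-decomposition, 1-d variance
#' ratio optimization) and the held-out lines are predicted by the
#' conditional expectation u_test = delta K_test,train
#' (delta K_train + I)^{-1} (y_train - mu). Predictability is the
#' Pearson correlation between observations and out-of-fold
#' predictions, averaged over folds by default (see `pooling`).
#'
#' @param K Kernel from [build_kernel()].
#' @param y Named numeric trait vector (names = line ids; lines with NA
#'   dropped).
#' @param k_folds Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param trait_id Label stored in the result.
#' @param pooling `"fold_mean"` (default; mean of within-fold
#'   correlations, calibrated to 0 for signal-free traits) or
#'   `"pooled"` (one correlation over the concatenated out-of-fold
#'   predictions, which is biased negative under the null because each
#'   prediction embeds its training-fold mean). Leave-one-out always
#'   uses pooled.
#' @return A `prediction_result`: list with `trait_id`, `model`,
#'   `predictability`, `predictions`, `observed`, `fold_assignments`.
#' @export
blup_cv <- function(K, y, k_folds = 10, seed = 1, trait_id = "trait",
                    pooling = c("fold_mean", "pooled")) {
  pooling <- match.arg(pooling)
  ids <- intersect(rownames(K), names(y)[!is.na(y)])
  y <- y[ids]; K <- K[ids, ids]
  folds <- make_folds(ids, k_folds, seed)
  pred <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (f in sort(unique(folds))) {
    tr <- ids[folds != f]; te <- ids[folds == f]
    fit <- blup_fit(K[tr, tr], y[tr])
    u_te <- fit$delta * K[te, tr, drop = FALSE] %*% fit$vinv_resid
    pred[te] <- fit$beta + drop(u_te)
  }
  structure(list(trait_id = trait_id, model = "BLUP",
                 predictability = cv_predictability(y, pred, folds, pooling),
                 predictions = pred, observed = y,
                 fold_assignments = folds),
            class = "prediction_result")
}

# Cross-validated predictability: Pearson r between observed values
# and out-of-fold predictions. The default averages the correlation
# over folds, which is calibrated to 0 for traits with no signal; the
# naive correlation over the pooled prediction vector is biased
# negative under the null (the per-fold training mean embedded in the
# predictions anti-correlates with the held-out values) and is kept as
# an option, and as the automatic fallback when folds are too small to
# correlate within (e.g. leave-one-out). Constant predictions are
# flagged undefined and reported as 0.
cv_predictability <- function(y, pred, folds,
                              pooling = c("fold_mean", "pooled")) {
  pooling <- match.arg(pooling)
  sizes <- table(folds)
  if (pooling == "fold_mean" && min(sizes) >= 3) {
    rs <- vapply(names(sizes), function(f) {
      j <- folds == f
      if (stats::sd(pred[j]) < 1e-12 || stats::sd(y[j]) == 0) 0
      else stats::cor(y[j], pred[j])
    }, numeric(1))
    if (all(rs == 0))
      warning("constant predictions: predictability undefined, reported as 0")
    mean(rs)
  } else {
    if (stats::sd(pred) < 1e-12 || stats::sd(y) == 0) {
      warning("constant predictions: predictability undefined, reported as 0")
      return(0)
    }
    stats::cor(y, pred)
  }
}

#' Cross-validated LASSO predictability and feature selection
#'
#' Per outer fold, the penalty is chosen by inner cross-validation on
#' the training lines only (lambda-min rule; no information from the
#' held-out lines is used) and the held-out lines are predicted at that
#' penalty. Out-of-fold predictions are pooled into one Pearson
#' predictability. The reported feature set comes from a final inner-CV
#' fit on all lines at the same rule.
#'
#' @param X Lines x features matrix (row names = line ids).
#' @param y Named numeric trait vector.
#' @param k_folds Outer folds (default 10).
#' @param seed Seed for fold assignments (outer and inner).
#' @param inner_folds Inner CV folds for the penalty (default 5).
#' @param lambda_rule `"min"` (default) or `"1se"`.
#' @param trait_id Label stored in the result.
#' @inheritParams blup_cv
#' @return A `prediction_result` with `selected_features` (data frame
#'   feature / effect) in addition to the fields of [blup_cv()].
#' @export
lasso_cv <- function(X, y, k_folds = 10, seed = 1, inner_folds = 5,
                     lambda_rule = c("min", "1se"), trait_id = "trait",
                     pooling = c("fold_mean", "pooled")) {
  pooling <- match.arg(pooling)
  lambda_rule <- match.arg(lambda_rule)
  s_rule <- if (lambda_rule == "min") "lambda.min" else "lambda.1se"
  ids <- intersect(rownames(X), names(y)[!is.na(y)])
  X <- as.matrix(X[ids, , drop = FALSE]); y <- y[ids]
  folds <- make_folds(ids, k_folds, seed)
  pred <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    set.seed(seed + 1000L * f)
    foldid <- sample(rep(seq_len(inner_folds), length.out = sum(tr)))
    cvfit <- glmnet::cv.glmnet(X[tr, , drop = FALSE], y[tr],
                               foldid = foldid, standardize = TRUE)
    pred[!tr] <- drop(stats::predict(cvfit, X[!tr, , drop = FALSE],
                                     s = s_rule))
  }
  set.seed(seed + 99991L)
  foldid_all <- sample(rep(seq_len(inner_folds), length.out = length(y)))
  cv_all <- glmnet::cv.glmnet(X, y, foldid = foldid_all, standardize = TRUE)
  cf <- stats::coef(cv_all, s = s_rule)
  nz <- which(cf[-1] != 0)
  selected <- data.frame(feature = colnames(X)[nz],
                         effect = as.numeric(cf[-1][nz]),
                         stringsAsFactors = FALSE)
  structure(list(trait_id = trait_id, model = "LASSO",
                 predictability = cv_predictability(y, pred, folds, pooling),
                 predictions = pred, observed = y,
                 fold_assignments = folds,
                 selected_features = selected),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("%s prediction of %s: predictability r = %.3f (%d lines, %d folds)\n",
              x$model, x$trait_id, x$predictability,
              length(x$predictions), length(unique(x$fold_assignments))))
  if (!is.null(x$selected_features))
    cat(sprintf("  %d feature(s) with nonzero effect\n",
                nrow(x$selected_features)))
  invisible(x)
}

#' Nominal significance of selected features by OLS refit
#'
#' The selected features are refit jointly by ordinary least squares
#' and per-feature two-sided t-test P-values reported. These are
#' post-selection (nominal) P-values: the same data chose the features,
#' so they are labelled with `post_selection = TRUE` and should be read
#' as descriptive.
#'
#' @param X Lines x features matrix.
#' @param y Named numeric trait vector.
#' @param selected_features Data frame with a `feature` column (from
#'   [lasso_cv()]), or a character vector of feature names.
#' @return Data frame: `feature`, `effect` (OLS), `p_value`,
#'   `post_selection`.
#' @export
feature_significance <- function(X, y, selected_features) {
  feats <- if (is.data.frame(selected_features)) {
    sf <- selected_features
    as.character(sf$feature)
  } else as.character(selected_features)
  if (!length(feats))
    return(data.frame(feature = character(), effect = numeric(),
                      p_value = numeric(), post_selection = logical()))
  ids <- intersect(rownames(X), names(y)[!is.na(y)])
  X <- as.matrix(X[ids, feats, drop = FALSE]); y <- y[ids]
  max_k <- length(y) - 3L
  if (length(feats) > max_k) {
    warning("selected set larger than n - 3: truncated by |effect|")
    ord <- order(-abs(if (is.data.frame(selected_features))
      selected_features$effect else rep(0, length(feats))))
    feats <- feats[ord][seq_len(max_k)]
    X <- X[, feats, drop = FALSE]
  }
  fit <- stats::lm(y ~ ., data = as.data.frame(X, check.names = FALSE))
  sm <- summary(fit)$coefficients
  rows <- match(make.names(feats), rownames(sm))
  data.frame(feature = feats,
             effect = sm[rows, "Estimate"],
             p_value = sm[rows, "Pr(>|t|)"],
             post_selection = TRUE, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Compare metabolome- and genotype-based predictability
#'
#' Both results must come from identical fold assignments (shared
#' seed); reports the pooled predictabilities and their difference,
#' plus per-fold paired correlations.
#'
#' @param metabolome_result,genotype_result `prediction_result`s for
#'   the same trait and model.
#' @return List with `trait_id`, `model`, `predictability_metabolome`,
#'   `predictability_genotype`, `delta`, and a per-fold data frame.
#' @export
compare_predictors <- function(metabolome_result, genotype_result) {
  m <- metabolome_result; g <- genotype_result
  if (!identical(m$fold_assignments, g$fold_assignments))
    stop("fold assignments differ: rerun both with a shared seed")
  folds <- m$fold_assignments
  per_fold <- do.call(rbind, lapply(sort(unique(folds)), function(f) {
    ids <- names(folds)[folds == f]
    data.frame(fold = f,
               r_metabolome = stats::cor(m$observed[ids],
                                         m$predictions[ids]),
               r_genotype = stats::cor(g$observed[ids],
                                       g$predictions[ids]),
               stringsAsFactors = FALSE)
  }))
  list(trait_id = m$trait_id, model = m$model,
       predictability_metabolome = m$predictability,
       predictability_genotype = g$predictability,
       delta = m$predictability - g$predictability,
       per_fold = per_fold)
}
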