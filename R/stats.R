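#' Log2-transform a trait table
#'
#' Metabolite abundances are log2-transformed before statistical
#' analysis to improve normality. Zeros are handled per policy;
#' negative values are rejected.
#'
#' @param table A `trait_table` with non-negative values.
#' @param zero_policy `"offset"` (log2(x + offset)), `"half_min"`
#'   (zeros replaced by half the trait's minimum positive value) or
#'   `"error"`.
#' @param offset Offset used by the `"offset"` policy (default 1).
#' @return The table with transformed values; monotone within trait.
#' @export
log2_transform <- function(table, zero_policy = c("half_min", "offset",
                                                  "error"), offset = 1) {
  zero_policy <- match.arg(zero_policy)
  v <- table$value
  if (any(v < 0, na.rm = TRUE)) stop("negative value in abundance table")
  zero <- !is.na(v) & v == 0
  if (any(zero)) {
    if (zero_policy == "error") stop("zero value with zero_policy = 'error'")
    if (zero_policy == "half_min") {
      minpos <- tapply(ifelse(v > 0, v, NA), table$trait_id, min,
                       na.rm = TRUE)
      repl <- minpos[table$trait_id] / 2
      if (any(zero & !is.finite(repl)))
        stop("trait with all-zero values cannot use half_min policy")
      v[zero] <- repl[zero]
      message(sum(zero), " zero value(s) replaced by half the trait minimum")
    }
  }
  table$value <- if (zero_policy == "offset") log2(v + offset) else log2(v)
  table
}

#' Coefficient of variation across lines (percent)
#'
#' CV = 100 * S / A with S the sample standard deviation (n-1
#' denominator) and A the mean, computed over per-line values —
#' conventionally the replicate means of untransformed abundances.
#'
#' @param x A `trait_table` (replicates averaged per line first) or a
#'   numeric vector of line means for one trait.
#' @return Named numeric vector of CV percentages (single value for a
#'   vector input). A zero mean yields NA with a warning.
#' @export
coefficient_of_variation <- function(x) {
  cv_one <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) stop("CV needs >= 2 line values")
    if (mean(v) == 0) {
      warning("zero mean: CV undefined")
      return(NA_real_)
    }
    100 * stats::sd(v) / mean(v)
  }
  if (inherits(x, "trait_table")) {
    m <- trait_matrix(x, replicate = "mean")
    apply(m, 2, cv_one)
  } else cv_one(as.numeric(x))
}

#' Broad-sense heritability from replicate-structured one-way ANOVA
#'
#' Lines are the groups, biological replicates the within-group
#' observations. With MSB and MSW the between/within mean squares and r
#' the (mean) replicate count, the genetic variance is
#' sigma2_g = max(0, (MSB - MSW) / r) and
#' H2 = sigma2_g / (sigma2_g + MSW) on the per-observation ("plot")
#' basis, the default: replicate-to-replicate variation is taken as the
#' environmental phenotypic variance. `basis = "line-mean"` divides the
#' environmental term by r instead.
#'
#' @param x A `trait_table` with replicated values (typically already
#'   log2-transformed) or a lines x replicates numeric matrix for one
#'   trait.
#' @param basis `"plot"` (default) or `"line-mean"`.
#' @return Named numeric vector of H2 in [0, 1], one per trait.
#' @export
broad_sense_heritability <- function(x, basis = c("plot", "line-mean")) {
  basis <- match.arg(basis)
  h2_one <- function(value, line) {
    ok <- !is.na(value)
    value <- value[ok]; line <- line[ok]
    ni <- table(line)
    keep <- names(ni)[ni >= 2]
    if (length(keep) < 2)
      stop("heritability needs >= 2 lines with >= 2 replicates")
    sel <- line %in% keep
    value <- value[sel]; line <- factor(line[sel])
    k <- nlevels(line); N <- length(value)
    gm <- tapply(value, line, mean)
    n_i <- tabulate(line)
    MSB <- sum(n_i * (gm - mean(value))^2) / (k - 1)
    MSW <- sum((value - gm[line])^2) / (N - k)
    r <- mean(n_i)
    sg2 <- max(0, (MSB - MSW) / r)
    env <- if (basis == "plot") MSW else MSW / r
    if (sg2 + env <= 0) return(0)
    min(1, max(0, sg2 / (sg2 + env)))
  }
  if (inherits(x, "trait_table")) {
    out <- vapply(split(seq_len(nrow(x)), x$trait_id), function(i)
      h2_one(x$value[i], x$line_id[i]), numeric(1))
    out[unique(x$trait_id)]
  } else {
    m <- as.matrix(x)
    h2_one(as.vector(m), rep(seq_len(nrow(m)), ncol(m)))
  }
}

#' All pairwise trait correlations with t-approximation P-values
#'
#' Correlations are computed on per-line values (replicate means) over
#' pairwise-complete observations; significance from
#' t = r * sqrt((n-2) / (1-r^2)) on n-2 degrees of freedom (ranks first
#' for Spearman). Pairs with fewer than 4 complete observations are
#' skipped with a warning.
#'
#' @param table_a A `trait_table` or lines x traits matrix.
#' @param table_b Optional second table; when omitted all within-`table_a`
#'   unordered pairs are returned, otherwise all cross pairs.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Data frame of correlation edges: `trait_a`, `trait_b`, `r`,
#'   `p_value`, `method`, `n`.
#' @export
pairwise_correlation <- function(table_a, table_b = NULL,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  to_mat <- function(x) if (inherits(x, "trait_table"))
    trait_matrix(x, replicate = "mean") else as.matrix(x)
  A <- to_mat(table_a)
  within <- is.null(table_b)
  B <- if (within) A else to_mat(table_b)
  shared <- intersect(rownames(A), rownames(B))
  A <- A[shared, , drop = FALSE]; B <- B[shared, , drop = FALSE]
  if (method == "spearman") {
    A <- apply(A, 2, rank, na.last = "keep")
    B <- apply(B, 2, rank, na.last = "keep")
  }
  r <- suppressWarnings(stats::cor(A, B, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(A), !is.na(B))
  tstat <- r * sqrt(pmax(n - 2, 0) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = pmax(n - 2, 1))
  p[!is.finite(r)] <- NA
  idx <- if (within) which(upper.tri(r), arr.ind = TRUE)
         else as.matrix(expand.grid(seq_len(ncol(A)), seq_len(ncol(B))))
  edges <- data.frame(trait_a = colnames(A)[idx[, 1]],
                      trait_b = colnames(B)[idx[, 2]],
                      r = r[idx], p_value = p[idx],
                      method = method, n = as.integer(n[idx]),
                      stringsAsFactors = FALSE)
  few <- edges$n < 4 | is.na(edges$r)
  if (any(few)) {
    warning(sum(few), " pair(s) skipped: fewer than 4 complete observations")
    edges <- edges[!few, , drop = FALSE]
    rownames(edges) <- NULL
  }
  edges
}

#' Threshold a correlation edge list into a network
#'
#' Keeps edges with p below the threshold (raw P, no multiple-testing
#' correction by default, matching the conventional P < 0.01 network
#' cut; set `fdr = TRUE` for Benjamini-Hochberg adjustment first).
#'
#' @param edges Edge data frame from [pairwise_correlation()].
#' @param p_threshold Retention threshold (default 0.01).
#' @param fdr Apply BH adjustment before thresholding (default FALSE).
#' @return A `corr_network` list: `edges` (kept), `nodes`, `degree`
#'   (named vector over connected nodes), `n_positive`, `n_negative`.
#' @export
build_network <- function(edges, p_threshold = 0.01, fdr = FALSE) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  p <- if (fdr) stats::p.adjust(edges$p_value, "BH") else edges$p_value
  kept <- edges[!is.na(p) & p < p_threshold, , drop = FALSE]
  rownames(kept) <- NULL
  nodes <- unique(c(edges$trait_a, edges$trait_b))
  deg <- table(factor(c(kept$trait_a, kept$trait_b), levels = nodes))
  structure(list(edges = kept, nodes = nodes,
                 degree = stats::setNames(as.integer(deg), nodes),
                 n_positive = sum(kept$r > 0), n_negative = sum(kept$r < 0),
                 p_threshold = p_threshold),
            class = "corr_network")
}

#' @export
print.corr_network <- function(x, ...) {
  cat(sprintf(paste0("Correlation network: %d nodes, %d edges at P < %g ",
                     "(%d positive / %d negative)\n"),
              length(x$nodes), nrow(x$edges), x$p_threshold,
              x$n_positive, x$n_negative))
  invisible(x)
}

#' Leaf ordering from correlation-based hierarchical clustering
#'
#' Average-linkage clustering on distance 1 - r; the returned
#' permutation orders heatmap rows/columns so correlated traits sit
#' together. Deterministic: ties are resolved by hclust's fixed
#' agglomeration order.
#'
#' @param correlation_matrix Square symmetric correlation matrix.
#' @return Integer leaf permutation.
#' @export
cluster_order <- function(correlation_matrix) {
  m <- as.matrix(correlation_matrix)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop("correlation matrix must be square and symmetric")
  if (nrow(m) < 3) return(seq_len(nrow(m)))
  stats::hclust(stats::as.dist(1 - m), method = "average")$order
}
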