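#' Stepwise cofactor selection for composite interval mapping
#'
#' Forward-backward stepwise linear regression of the trait on marker
#' indicators. A marker enters when its partial-F P-value is at most
#' `pin` and is removed when, in the joint model, its P-value exceeds
#' `pout`. Ties break on lowest P, then map order. Selection stops with
#' a warning if more than n/2 markers would be retained (overfitting
#' guard).
#'
#' @param genotypes Lines x markers matrix (+1/-1/NA; missing calls are
#'   mean-imputed for the regression).
#' @param trait Named numeric vector of trait values (names = line ids)
#'   or unnamed vector aligned to the genotype rows.
#' @param pin Entry P-value (default 0.001, the conventional PIN for
#'   stepwise cofactor selection).
#' @param pout Removal P-value (default 2 * pin); must satisfy
#'   pin <= pout.
#' @return Character vector of selected marker names (map order of
#'   selection preserved).
#' @export
select_cofactors <- function(genotypes, trait, pin = 0.001, pout = 2 * pin) {
  stopifnot(pin <= pout, pin > 0)
  y <- align_trait(trait, genotypes)
  ok <- !is.na(y)
  y <- y[ok]
  X <- genotypes[ok, , drop = FALSE]
  X <- impute_marker_means(X)
  n <- length(y)
  sel <- integer(0)
  max_k <- floor(n / 2)
  repeat {
    k <- length(sel)
    Q <- qr.Q(qr(cbind(1, X[, sel, drop = FALSE])))
    ey <- y - drop(Q %*% crossprod(Q, y))
    cand <- setdiff(seq_len(ncol(X)), sel)
    if (!length(cand) || n - k - 3 < 1) break
    Xc <- X[, cand, drop = FALSE]
    Exc <- Xc - Q %*% crossprod(Q, Xc)
    den <- colSums(Exc^2)
    sy2 <- sum(ey^2)
    r2 <- ifelse(den > 1e-10 & sy2 > 0,
                 (colSums(Exc * ey))^2 / (den * sy2), 0)
    df2 <- n - k - 2
    Fv <- r2 * df2 / pmax(1 - r2, 1e-300)
    p <- stats::pf(Fv, 1, df2, lower.tail = FALSE)
    best <- which.min(p)   # lowest p; ties resolved by map order
    if (p[best] > pin) break
    sel <- c(sel, cand[best])
    if (length(sel) > max_k) {
      warning("cofactor selection stopped: more than n/2 markers entered")
      sel <- sel[seq_len(max_k)]
      break
    }
    # backward sweep at pout
    repeat {
      if (length(sel) < 2) break
      pj <- marginal_p(y, X[, sel, drop = FALSE])
      worst <- which.max(pj)
      if (pj[worst] > pout) sel <- sel[-worst] else break
    }
  }
  colnames(X)[sel]
}

align_trait <- function(trait, genotypes) {
  if (!is.null(names(trait))) {
    y <- trait[rownames(genotypes)]
    names(y) <- rownames(genotypes)
    y
  } else {
    stopifnot(length(trait) == nrow(genotypes))
    stats::setNames(as.numeric(trait), rownames(genotypes))
  }
}

impute_marker_means <- function(X) {
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) {
    cm <- colMeans(X, na.rm = TRUE)
    X[nas] <- cm[nas[, 2]]
  }
  X
}

# two-sided t-test p-values for each column's coefficient in the joint
# OLS fit (with intercept)
marginal_p <- function(y, X) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  k <- fit$rank
  df <- length(y) - k
  if (df <= 0) return(rep(0, ncol(X)))
  s2 <- sum(fit$residuals^2) / df
  R <- qr.R(fit$qr)
  XtXinv <- chol2inv(R)
  se <- sqrt(pmax(diag(XtXinv) * s2, 1e-300))
  tval <- fit$coefficients / se
  2 * stats::pt(-abs(tval[-1]), df)
}

#' Composite interval scan of one trait (ICIM-style)
#'
#' At each grid position the phenotype, adjusted for the selected
#' cofactors, is regressed on the conditional expectation of the locus
#' genotype given the flanking markers (Haley-Knott regression);
#' LOD = (n/2) log10(RSS0 / RSS1). For background control, cofactors
#' lying within `window_cM` of the scanned position (same chromosome)
#' are dropped from the adjustment at that position so the scanned
#' locus is not absorbed by its own proxy marker.
#'
#' @inheritParams select_cofactors
#' @param map A `genetic_map` matching the genotype columns.
#' @param cofactors Character vector of cofactor marker names (possibly
#'   empty, giving plain interval mapping).
#' @param step Scan step in cM (default 1).
#' @param window_cM Cofactor exclusion window around the scanned
#'   position (default 10).
#' @param genoprob Optional precomputed [scan_genoprob()] (must match
#'   `step`); computing it once and passing it in makes multi-trait
#'   scans much faster.
#' @return A `scan_profile`: list with `positions` (chromosome,
#'   pos_cM), `lod`, `additive_effect`, `cofactors`, `n` (lines used).
#'   Monomorphic positions get LOD 0 and are flagged in `monomorphic`.
#' @export
icim_scan <- function(genotypes, map, trait, cofactors = character(),
                      step = 1, window_cM = 10, genoprob = NULL) {
  if (is.null(genoprob)) genoprob <- scan_genoprob(genotypes, map, step)
  stopifnot(inherits(genoprob, "scan_genoprob"))
  y <- align_trait(trait, genotypes)
  ok <- !is.na(y)
  y <- y[ok]
  n <- length(y)
  Ex <- genoprob$Ex[ok, , drop = FALSE]
  pos <- genoprob$positions
  C <- if (length(cofactors)) {
    stopifnot(all(cofactors %in% map$marker))
    impute_marker_means(genotypes[ok, cofactors, drop = FALSE])
  } else NULL
  cof_chr <- map$chromosome[match(cofactors, map$marker)]
  cof_pos <- map$pos_cM[match(cofactors, map$marker)]
  # positions sharing the same active-cofactor set form one group
  excl <- matrix(FALSE, nrow(pos), length(cofactors))
  if (length(cofactors))
    for (j in seq_along(cofactors))
      excl[, j] <- pos$chromosome == cof_chr[j] &
        abs(pos$pos_cM - cof_pos[j]) <= window_cM
  sig <- if (length(cofactors))
    do.call(paste0, lapply(seq_len(ncol(excl)),
                           function(j) as.integer(excl[, j])))
  else rep("", nrow(pos))
  lod <- eff <- numeric(nrow(pos))
  mono <- logical(nrow(pos))
  for (s in unique(sig)) {
    pidx <- which(sig == s)
    active <- if (length(cofactors)) which(!excl[pidx[1], ]) else integer(0)
    Q <- qr.Q(qr(cbind(rep(1, n), if (length(active))
      C[, active, drop = FALSE] else NULL)))
    y_adj <- y - Q %*% crossprod(Q, y)
    rss0 <- sum(y_adj^2)
    Eg <- Ex[, pidx, drop = FALSE]
    Eg <- Eg - Q %*% crossprod(Q, Eg)
    den <- .colSums(Eg * Eg, n, length(pidx))
    num <- drop(crossprod(Eg, y_adj))
    poly <- den > 1e-8 * n
    b <- ifelse(poly, num / pmax(den, 1e-300), 0)
    rss1 <- pmax(rss0 - ifelse(poly, num^2 / pmax(den, 1e-300), 0), 1e-300)
    l <- ifelse(poly & rss0 > 0, (n / 2) * log10(rss0 / rss1), 0)
    lod[pidx] <- pmax(l, 0)
    eff[pidx] <- b
    mono[pidx] <- !poly
  }
  structure(list(positions = pos, lod = lod, additive_effect = eff,
                 cofactors = cofactors, n = n, monomorphic = mono,
                 step = genoprob$step),
            class = "scan_profile")
}

#' Genome-wide permutation LOD threshold
#'
#' Trait values are shuffled across lines; for each permutation the
#' cofactors are reselected and the genome rescanned, and the
#' (1 - alpha) empirical quantile (type-1, i.e. an order statistic) of
#' the genome-wide maximum LOD is returned.
#'
#' @inheritParams icim_scan
#' @param n_perm Number of permutations (>= 100; 1000 conventional).
#' @param alpha Genome-wide type-I error (default 0.05).
#' @param seed Integer seed for the permutation stream.
#' @param pin Entry P-value for per-permutation cofactor selection.
#' @return The LOD threshold, with the permutation maxima in
#'   `attr(, "max_lods")`.
#' @export
permutation_threshold <- function(genotypes, map, trait, n_perm = 1000,
                                  alpha = 0.05, seed = 1, step = 1,
                                  pin = 0.001, window_cM = 10,
                                  genoprob = NULL) {
  stopifnot(n_perm >= 100, alpha > 0, alpha <= 1)
  if (is.null(genoprob)) genoprob <- scan_genoprob(genotypes, map, step)
  y <- align_trait(trait, genotypes)
  set.seed(seed)
  maxima <- vapply(seq_len(n_perm), function(i) {
    yp <- stats::setNames(sample(y), names(y))
    cof <- select_cofactors(genotypes, yp, pin = pin)
    max(icim_scan(genotypes, map, yp, cofactors = cof, step = step,
                  window_cM = window_cM, genoprob = genoprob)$lod)
  }, numeric(1))
  thr <- stats::quantile(maxima, probs = 1 - alpha, type = 1, names = FALSE)
  attr(thr, "max_lods") <- maxima
  thr
}

#' Call QTL from a scan profile
#'
#' One record per contiguous supra-threshold segment per chromosome:
#' the peak is the (leftmost, on plateaus) maximum-LOD grid position;
#' the support interval spans the outermost grid positions within 1.5
#' LOD of the peak, then is widened to the nearest mapped marker at or
#' beyond each end. PVE is recovered from the peak likelihood ratio,
#' PVE = 100 (1 - 10^(-2 LOD / n)), i.e. against the cofactor-adjusted
#' null; a locus with PVE > 15 is flagged major.
#'
#' @param profile A `scan_profile` from [icim_scan()].
#' @param map The `genetic_map` used for the scan (for marker
#'   extension).
#' @param lod_threshold Minimum peak LOD (default 2.5).
#' @param trait_id Trait label stored in the records.
#' @return A `qtl_table` (possibly empty).
#' @export
call_qtl <- function(profile, map, lod_threshold = 2.5, trait_id = "trait") {
  stopifnot(inherits(profile, "scan_profile"))
  if (!nrow(profile$positions)) stop("empty scan profile")
  pos <- profile$positions
  out <- list()
  for (ch in unique(pos$chromosome)) {
    ci <- which(pos$chromosome == ch)
    lod <- profile$lod[ci]
    above <- lod >= lod_threshold
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    mpos <- map$pos_cM[map$chromosome == ch]
    mname <- map$marker[map$chromosome == ch]
    for (rn in which(runs$values)) {
      seg <- starts[rn]:ends[rn]
      pk <- seg[which.max(lod[seg])]   # leftmost on plateaus
      peak_lod <- lod[pk]
      drop_lvl <- peak_lod - 1.5
      lo <- pk; while (lo > 1L && lod[lo - 1L] >= drop_lvl) lo <- lo - 1L
      hi <- pk; while (hi < length(ci) && lod[hi + 1L] >= drop_lvl)
        hi <- hi + 1L
      lo_cM <- pos$pos_cM[ci[lo]]; hi_cM <- pos$pos_cM[ci[hi]]
      lo_m <- max(which(mpos <= lo_cM + 1e-9), 1L)
      hi_m <- min(which(mpos >= hi_cM - 1e-9), length(mpos))
      if (!length(hi_m) || !is.finite(hi_m)) hi_m <- length(mpos)
      pve <- 100 * (1 - 10^(-2 * peak_lod / profile$n))
      out[[length(out) + 1L]] <- data.frame(
        trait_id = trait_id, chromosome = ch,
        peak_cM = pos$pos_cM[ci[pk]], LOD = peak_lod,
        additive_effect = profile$additive_effect[ci[pk]],
        PVE = pve, ci_lo_cM = mpos[lo_m], ci_hi_cM = mpos[hi_m],
        ci_lo_marker = mname[lo_m], ci_hi_marker = mname[hi_m],
        stringsAsFactors = FALSE)
    }
  }
  qtl_table(if (length(out)) do.call(rbind, out) else NULL)
}
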