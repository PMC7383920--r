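#' Conditional genotype probabilities between flanking markers
#'
#' For a putative locus between two flanking markers of a RIL line, the
#' probability of each parental state follows from the Markov property
#' of the recombination process: with switch probabilities
#' R_left, R_right (Haldane distance converted to a per-meiosis
#' fraction, then RIL-corrected via R = 2r/(1+2r)),
#' P(Q = P1 | flanks) is proportional to the product of the two
#' transition probabilities. A missing flank is marginalized at the 1/2
#' prior; with both flanks missing the result is (1/2, 1/2).
#'
#' @param flank_left,flank_right Flanking genotypes: `"P1"`, `"P2"`,
#'   `NA` (missing), or numeric +1/-1/NA. Vectorized.
#' @param d_left,d_right Distances (cM, >= 0) from the locus to each
#'   flank. A zero distance makes the observed flank certain.
#' @return Data frame with columns `p_P1`, `p_P2` (rows sum to 1).
#' @export
conditional_genotype_probs <- function(flank_left, flank_right,
                                       d_left, d_right) {
  code <- function(g) {
    if (is.character(g) || is.factor(g)) {
      g <- as.character(g)
      out <- rep(0, length(g))
      out[!is.na(g) & g == "P1"] <- 1
      out[!is.na(g) & g == "P2"] <- -1
      bad <- !is.na(g) & !(g %in% c("P1", "P2"))
      if (any(bad)) stop("unknown flank genotype: ", g[bad][1])
      out
    } else {
      g <- as.numeric(g)
      g[is.na(g)] <- 0
      g
    }
  }
  if (any(c(d_left, d_right) < 0)) stop("distances must be >= 0")
  GL <- code(flank_left); GR <- code(flank_right)
  cL <- 0.5 - ril_recomb(haldane_r(d_left))
  cR <- 0.5 - ril_recomb(haldane_r(d_right))
  ex <- .flank_expectation(GL, GR, cL, cR)
  data.frame(p_P1 = (ex + 1) / 2, p_P2 = (1 - ex) / 2)
}

#' Expected genotypes on a genome-wide scan grid
#'
#' Builds the scan grid (every chromosome covered end to end at the
#' given step, terminal position included) and the conditional
#' expectation E[x] of the +1/-1 genotype at each grid position for
#' every line, given its nearest flanking marker calls. This matrix
#' depends only on the genotypes and map, so it is computed once and
#' shared across all traits, replicates and permutations.
#'
#' @param genotypes Lines x markers matrix (+1/-1/NA).
#' @param map Matching `genetic_map`.
#' @param step Grid step in cM (default 1).
#' @return A `scan_genoprob` list: `positions` (data frame
#'   chromosome / pos_cM), `Ex` (lines x positions), `map`, `step`.
#' @export
scan_genoprob <- function(genotypes, map, step = 1) {
  stopifnot(is_genetic_map(map), step > 0,
            all(colnames(genotypes) == map$marker))
  chroms <- unique(map$chromosome)
  G <- genotypes
  G[is.na(G)] <- 0   # marginalize missing flanks at the 1/2 prior
  pos_list <- list(); ex_list <- list()
  for (ch in chroms) {
    idx <- which(map$chromosome == ch)
    pm <- map$pos_cM[idx]
    L <- max(pm)
    sp <- seq(min(pm), L, by = step)
    if (sp[length(sp)] < L - 1e-9) sp <- c(sp, L)
    li <- pmin(pmax(findInterval(sp, pm), 1L), length(pm))
    at_marker <- pm[li] >= sp - 1e-9
    ri <- ifelse(at_marker, li, pmin(li + 1L, length(pm)))
    dL <- pmax(sp - pm[li], 0)
    dR <- pmax(pm[ri] - sp, 0)
    cL <- 0.5 - ril_recomb(haldane_r(dL))
    cR <- 0.5 - ril_recomb(haldane_r(dR))
    GL <- G[, idx[li], drop = FALSE]
    GR <- G[, idx[ri], drop = FALSE]
    ex <- .flank_expectation(GL,
                             GR,
                             matrix(cL, nrow(G), length(sp), byrow = TRUE),
                             matrix(cR, nrow(G), length(sp), byrow = TRUE))
    pos_list[[ch]] <- data.frame(chromosome = ch, pos_cM = sp,
                                 stringsAsFactors = FALSE)
    ex_list[[ch]] <- ex
  }
  positions <- do.call(rbind, pos_list)
  rownames(positions) <- NULL
  Ex <- do.call(cbind, ex_list)
  dimnames(Ex) <- list(rownames(genotypes), NULL)
  structure(list(positions = positions, Ex = Ex, map = map, step = step),
            class = "scan_genoprob")
}
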