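#' Construct a genetic map
#'
#' A genetic map is a data frame of markers ordered by chromosome and
#' genetic position (centiMorgan, 0-based at each chromosome start).
#' Physical positions in Mb, when present, are carried as annotation only;
#' all computation in the package is on the genetic (cM) scale.
#'
#' @param marker Character vector of unique marker identifiers.
#' @param chromosome Character (or coercible) vector of chromosome names.
#' @param pos_cM Numeric vector of non-negative genetic positions in cM.
#' @param pos_Mb Optional numeric vector of physical positions in Mb.
#' @return A `genetic_map` object: a data frame with columns `marker`,
#'   `chromosome`, `pos_cM` and optionally `pos_Mb`, sorted by
#'   (chromosome, pos_cM).
#' @export
genetic_map <- function(marker, chromosome, pos_cM, pos_Mb = NULL) {
  marker <- as.character(marker)
  chromosome <- as.character(chromosome)
  pos_cM <- as.numeric(pos_cM)
  if (length(marker) != length(chromosome) || length(marker) != length(pos_cM))
    stop("marker, chromosome and pos_cM must have equal length")
  if (anyDuplicated(marker))
    stop("duplicate marker id: ", marker[duplicated(marker)][1L])
  if (any(!is.finite(pos_cM)) || any(pos_cM < 0))
    stop("pos_cM must be finite and >= 0")
  map <- data.frame(marker = marker, chromosome = chromosome,
                    pos_cM = pos_cM, stringsAsFactors = FALSE)
  if (!is.null(pos_Mb)) {
    pos_Mb <- as.numeric(pos_Mb)
    if (any(!is.na(pos_Mb) & pos_Mb < 0)) stop("pos_Mb must be >= 0")
    map$pos_Mb <- pos_Mb
  }
  ord <- order(factor(map$chromosome, levels = unique(map$chromosome)),
               map$pos_cM)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("Genetic map: %d markers on %d chromosome(s), %.1f cM total\n",
              nrow(x), length(unique(x$chromosome)), sum(chrom_lengths(x))))
  NextMethod()
}

is_genetic_map <- function(x) inherits(x, "genetic_map")

#' Chromosome genetic lengths
#'
#' @param map A `genetic_map`.
#' @return Named numeric vector: maximum cM position per chromosome.
#' @export
chrom_lengths <- function(map) {
  stopifnot(is_genetic_map(map))
  vapply(split(map$pos_cM, factor(map$chromosome,
                                  levels = unique(map$chromosome))),
         max, numeric(1))
}

#' Haldane map function
#'
#' Converts a genetic distance in cM to a per-meiosis recombination
#' fraction under the Haldane (no interference) model:
#' r = (1 - exp(-2 d / 100)) / 2.
#'
#' @param d_cM Genetic distance(s) in cM, >= 0.
#' @return Recombination fraction(s) in [0, 0.5).
#' @export
haldane_r <- function(d_cM) {
  if (any(d_cM < 0)) stop("distance must be >= 0")
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' RIL recombination correction (Haldane-Waddington)
#'
#' In a recombinant inbred line produced by repeated selfing, the
#' observed fraction of lines switching parental state between two loci
#' exceeds the per-meiosis recombination fraction r because
#' recombination accumulates over generations: R = 2r / (1 + 2r).
#'
#' @param r Per-meiosis recombination fraction(s) in [0, 0.5].
#' @return Equilibrium RIL switch probability R in [0, 0.5]; monotone in r.
#' @export
ril_recomb <- function(r) {
  if (any(r < 0 | r > 0.5)) stop("r must lie in [0, 0.5]")
  2 * r / (1 + 2 * r)
}

#' Simulate an evenly spaced genetic map
#'
#' @param n_chrom Number of chromosomes.
#' @param length_cM Chromosome length(s) in cM (recycled to `n_chrom`).
#' @param spacing_cM Marker spacing in cM.
#' @param chrom_names Optional chromosome names (default "chr1", ...).
#' @return A `genetic_map` with markers at 0, spacing, 2*spacing, ...
#'   up to the chromosome end (the terminal marker sits at the end even
#'   when the length is not a multiple of the spacing).
#' @export
simulate_map <- function(n_chrom, length_cM, spacing_cM, chrom_names = NULL) {
  stopifnot(n_chrom >= 1, all(length_cM > 0), spacing_cM > 0)
  length_cM <- rep_len(length_cM, n_chrom)
  if (any(spacing_cM > length_cM))
    stop("spacing_cM exceeds a chromosome length")
  if (is.null(chrom_names)) chrom_names <- paste0("chr", seq_len(n_chrom))
  pieces <- lapply(seq_len(n_chrom), function(i) {
    pos <- seq(0, length_cM[i], by = spacing_cM)
    if (pos[length(pos)] < length_cM[i]) pos <- c(pos, length_cM[i])
    data.frame(marker = sprintf("%s_m%03d", chrom_names[i], seq_along(pos)),
               chromosome = chrom_names[i], pos_cM = pos,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, pieces)
  genetic_map(all$marker, all$chromosome, all$pos_cM)
}
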