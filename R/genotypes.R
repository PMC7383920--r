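#' @name genotype-coding
#' @title Genotype coding for RIL populations
#' @description Genotype calls are stored as a numeric matrix of
#'   lines x markers with +1 for the first parental allele (P1), -1 for
#'   the second (P2) and NA for missing. A RIL population carries no
#'   heterozygous class. Three file dialects are supported: `"AB"`
#'   (codes A/B), `"num"` (1/-1) and `"02"` (0/2, with 0 = P1).
#'   Missing is written as NA and read from any of NA, "-", ".", "".
NULL

.geno_dialects <- list(
  "AB"  = c(P1 = "A", P2 = "B"),
  "num" = c(P1 = "1", P2 = "-1"),
  "02"  = c(P1 = "0", P2 = "2")
)
.missing_codes <- c("NA", "-", ".", "")

decode_geno_calls <- function(x, dialect = "AB") {
  codes <- .geno_dialects[[match.arg(dialect, names(.geno_dialects))]]
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  out[x == codes[["P1"]]] <- 1
  out[x == codes[["P2"]]] <- -1
  bad <- !(x %in% c(codes, .missing_codes)) & !is.na(x)
  if (any(bad)) {
    b <- unique(x[bad])
    if (any(toupper(b) == "H"))
      stop("heterozygote not allowed in RIL genotype matrix (code 'H')")
    stop("unknown genotype code(s): ", paste(b, collapse = ", "))
  }
  out
}

encode_geno_calls <- function(x, dialect = "AB") {
  codes <- .geno_dialects[[match.arg(dialect, names(.geno_dialects))]]
  out <- rep("NA", length(x))
  out[!is.na(x) & x > 0] <- codes[["P1"]]
  out[!is.na(x) & x < 0] <- codes[["P2"]]
  out
}

#' Read a RIL genotype matrix and genetic map
#'
#' The expected layout is one row per marker with columns `marker`,
#' `chromosome`, `pos_cM` (optionally `pos_Mb`) followed by one column
#' per line, tab- or comma-delimited with a header. Alternatively, pass
#' a pre-built map and a file holding only `marker` plus line columns.
#'
#' @param path Path to the delimited genotype file.
#' @param dialect One of `"AB"`, `"num"`, `"02"` (see [genotype-coding]).
#' @param map Optional `genetic_map`; when supplied the file needs no
#'   position columns and every marker must be present in the map.
#' @param sep Field separator; tab (default) or comma.
#' @param max_missing Markers or lines with a missing fraction above
#'   this are dropped with a warning (default 0.1).
#' @return A list with elements `map` (a `genetic_map`) and `genotypes`
#'   (numeric lines x markers matrix coded +1/-1/NA), sharing marker order.
#' @export
read_genotypes <- function(path, dialect = "AB", map = NULL, sep = "\t",
                           max_missing = 0.1) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (nrow(df) == 0L) stop("empty genotype matrix: ", path)
  if (!"marker" %in% names(df)) stop("genotype file needs a 'marker' column")
  meta_cols <- intersect(c("marker", "chromosome", "pos_cM", "pos_Mb"),
                         names(df))
  if (is.null(map)) {
    if (!all(c("chromosome", "pos_cM") %in% names(df)))
      stop("genotype file needs 'chromosome' and 'pos_cM' columns ",
           "(or pass a map)")
    map <- genetic_map(df$marker, df$chromosome, as.numeric(df$pos_cM),
                       if ("pos_Mb" %in% names(df)) as.numeric(df$pos_Mb))
  } else {
    stopifnot(is_genetic_map(map))
    absent <- setdiff(df$marker, map$marker)
    if (length(absent))
      stop("marker(s) in genotype file absent from map: ",
           paste(utils::head(absent, 5), collapse = ", "))
  }
  if (anyDuplicated(df$marker))
    stop("duplicate marker id: ", df$marker[duplicated(df$marker)][1L])
  line_cols <- setdiff(names(df), meta_cols)
  if (length(line_cols) == 0L) stop("empty genotype matrix: no line columns")
  calls <- vapply(line_cols,
                  function(l) decode_geno_calls(df[[l]], dialect),
                  numeric(nrow(df)))
  # calls is markers x lines here; store lines x markers
  geno <- t(matrix(calls, nrow = nrow(df), ncol = length(line_cols),
                   dimnames = list(df$marker, line_cols)))
  # align to map order, restricted to markers present in the file
  map <- map[map$marker %in% colnames(geno), , drop = FALSE]
  class(map) <- c("genetic_map", "data.frame")
  geno <- geno[, map$marker, drop = FALSE]
  filtered <- filter_missing(geno, max_missing)
  map <- map[map$marker %in% colnames(filtered), , drop = FALSE]
  class(map) <- c("genetic_map", "data.frame")
  list(map = map, genotypes = filtered)
}

filter_missing <- function(geno, max_missing = 0.1) {
  miss_m <- colMeans(is.na(geno))
  if (any(miss_m > max_missing)) {
    warning(sprintf("dropping %d marker(s) with > %.0f%% missing calls",
                    sum(miss_m > max_missing), 100 * max_missing))
    geno <- geno[, miss_m <= max_missing, drop = FALSE]
  }
  miss_l <- rowMeans(is.na(geno))
  if (any(miss_l > max_missing)) {
    warning(sprintf("dropping %d line(s) with > %.0f%% missing calls",
                    sum(miss_l > max_missing), 100 * max_missing))
    geno <- geno[miss_l <= max_missing, , drop = FALSE]
  }
  geno
}

#' Write a genotype matrix with its map
#'
#' Inverse of [read_genotypes()]: one row per marker with map columns
#' followed by line columns.
#'
#' @inheritParams read_genotypes
#' @param genotypes Numeric lines x markers matrix coded +1/-1/NA.
#' @export
write_genotypes <- function(genotypes, map, path, dialect = "AB", sep = "\t") {
  stopifnot(is_genetic_map(map), all(colnames(genotypes) == map$marker))
  coded <- apply(genotypes, 1L, encode_geno_calls, dialect = dialect)
  df <- data.frame(marker = map$marker, chromosome = map$chromosome,
                   pos_cM = map$pos_cM, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!is.null(map$pos_Mb)) df$pos_Mb <- map$pos_Mb
  df <- cbind(df, as.data.frame(coded, check.names = FALSE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
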