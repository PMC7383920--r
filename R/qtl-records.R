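#' Construct a QTL record table
#'
#' One row per mapped locus, mirroring the usual supplementary-table
#' layout: trait, chromosome, peak position, LOD, additive effect,
#' percentage of variance explained (PVE), and the marker-extended
#' 1.5-LOD support interval. A locus is flagged major when its PVE
#' exceeds 15%.
#'
#' @param df A data frame with columns `trait_id`, `chromosome`,
#'   `peak_cM`, `LOD`, `additive_effect`, `PVE`, `ci_lo_cM`, `ci_hi_cM`,
#'   `ci_lo_marker`, `ci_hi_marker` and optionally
#'   `n_replicates_detected`. `is_major` is (re)derived as PVE > 15.
#' @return A `qtl_table` data frame sorted by (trait, chromosome, peak).
#' @export
qtl_table <- function(df = NULL) {
  cols <- c("trait_id", "chromosome", "peak_cM", "LOD", "additive_effect",
            "PVE", "ci_lo_cM", "ci_hi_cM", "ci_lo_marker", "ci_hi_marker",
            "n_replicates_detected", "is_major")
  if (is.null(df) || nrow(df) == 0L) {
    df <- data.frame(trait_id = character(), chromosome = character(),
                     peak_cM = numeric(), LOD = numeric(),
                     additive_effect = numeric(), PVE = numeric(),
                     ci_lo_cM = numeric(), ci_hi_cM = numeric(),
                     ci_lo_marker = character(), ci_hi_marker = character(),
                     n_replicates_detected = integer(),
                     is_major = logical(), stringsAsFactors = FALSE)
  } else {
    if (is.null(df$n_replicates_detected))
      df$n_replicates_detected <- NA_integer_
    df$is_major <- df$PVE > 15
    missing_cols <- setdiff(cols, names(df))
    if (length(missing_cols))
      stop("missing QTL record column(s): ",
           paste(missing_cols, collapse = ", "))
    df <- df[cols]
    if (any(df$LOD < 0)) stop("LOD must be >= 0")
    if (any(df$PVE < 0 | df$PVE > 100)) stop("PVE must lie in [0, 100]")
    if (any(df$ci_lo_cM > df$peak_cM | df$peak_cM > df$ci_hi_cM))
      stop("support interval must contain the peak")
    df <- df[order(df$trait_id, df$chromosome, df$peak_cM), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("qtl_table", "data.frame")
  df
}

#' Write / read a QTL table (TSV)
#'
#' Round-trip stable: `read_qtl_table(write_qtl_table(x))` equals `x`
#' field for field.
#'
#' @param records A `qtl_table`.
#' @param path Output path.
#' @export
write_qtl_table <- function(records, path) {
  records <- qtl_table(as.data.frame(records))
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_qtl_table
#' @export
read_qtl_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = c(trait_id = "character",
                                         chromosome = "character",
                                         ci_lo_marker = "character",
                                         ci_hi_marker = "character",
                                         n_replicates_detected = "integer"))
  qtl_table(df)
}
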