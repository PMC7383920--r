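#' Construct a long-format trait table
#'
#' One row per measurement. Metabolite tables typically carry three
#' biological replicates per line; agronomic tables one (multi-year
#' mean) value per line.
#'
#' @param line_id,trait_id Character vectors.
#' @param value Numeric measurements (abundances or trait values).
#' @param replicate_id Optional replicate labels; defaults to 1.
#' @param trait_class Optional per-row trait class label
#'   (e.g. "flavonoid", "agronomic").
#' @return A `trait_table` data frame with columns `line_id`, `trait_id`,
#'   `replicate_id`, `value` and optionally `trait_class`;
#'   (line, trait, replicate) combinations are unique.
#' @export
trait_table <- function(line_id, trait_id, value, replicate_id = NULL,
                        trait_class = NULL) {
  n <- length(value)
  tt <- data.frame(line_id = as.character(line_id),
                   trait_id = as.character(trait_id),
                   replicate_id = if (is.null(replicate_id)) rep("1", n)
                                  else as.character(replicate_id),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  if (!is.null(trait_class)) tt$trait_class <- as.character(trait_class)
  key <- paste(tt$line_id, tt$trait_id, tt$replicate_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (line, trait, replicate) combination")
  if (any(is.infinite(tt$value)))
    stop("trait values must be finite or NA")
  class(tt) <- c("trait_table", "data.frame")
  tt
}

as_trait_table <- function(df) {
  trait_table(df$line_id, df$trait_id, df$value,
              replicate_id = df$replicate_id, trait_class = df$trait_class)
}

#' Read / write trait tables (long TSV)
#'
#' @param path File path; tab-delimited with header, columns `line_id`,
#'   `trait_id`, `replicate_id` (optional), `value`,
#'   `trait_class` (optional).
#' @return `read_traits`: a `trait_table`.
#' @export
read_traits <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(df$replicate_id)) df$replicate_id <- "1"
  as_trait_table(df)
}

#' @rdname read_traits
#' @param table A `trait_table`.
#' @export
write_traits <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Reshape a trait table to a lines x traits matrix
#'
#' @param table A `trait_table`.
#' @param replicate Either `"mean"` (default; average over replicates)
#'   or a single replicate id to extract.
#' @return Numeric matrix, rows = lines, columns = traits, NA where a
#'   (line, trait) combination is absent.
#' @export
trait_matrix <- function(table, replicate = "mean") {
  if (!identical(replicate, "mean")) {
    table <- table[table$replicate_id == as.character(replicate), ,
                   drop = FALSE]
    if (nrow(table) == 0L) stop("no rows for replicate ", replicate)
  }
  lines <- unique(table$line_id)
  traits <- unique(table$trait_id)
  m <- matrix(NA_real_, length(lines), length(traits),
              dimnames = list(lines, traits))
  li <- match(table$line_id, lines)
  ti <- match(table$trait_id, traits)
  if (identical(replicate, "mean")) {
    ok <- !is.na(table$value)
    cell <- (ti - 1L) * length(lines) + li   # 1-d index into m
    sums <- rowsum(table$value[ok], cell[ok])
    cnts <- rowsum(rep(1, sum(ok)), cell[ok])
    m[as.integer(rownames(sums))] <- sums / cnts
  } else {
    m[cbind(li, ti)] <- table$value
  }
  m
}

trait_classes <- function(table) {
  if (is.null(table$trait_class)) return(NULL)
  cls <- table$trait_class[!duplicated(table$trait_id)]
  names(cls) <- table$trait_id[!duplicated(table$trait_id)]
  cls
}
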