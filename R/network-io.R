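#' Export a correlation network for Cytoscape
#'
#' Writes either a SIF file (`a corr b`, one line per edge; isolated
#' nodes as single-token lines) together with a tab-delimited
#' edge-attribute file `<path>.edges.tsv` carrying the correlation r and
#' P-value, or a GraphML file carrying the same as edge attributes.
#'
#' @param edges Data frame with columns `trait_a`, `trait_b`, `r`,
#'   `p_value` (as produced by [pairwise_correlation()] /
#'   [build_network()]). Self-edges are rejected.
#' @param path Output path.
#' @param format `"sif"` (default) or `"graphml"`.
#' @param nodes Optional character vector of node ids to include even
#'   when isolated; defaults to the nodes appearing in `edges`.
#' @return `path`, invisibly. For SIF the attribute file is written
#'   alongside.
#' @export
write_network_sif <- function(edges, path, format = c("sif", "graphml"),
                              nodes = NULL) {
  format <- match.arg(format)
  if (is.null(edges) || nrow(edges) == 0L)
    edges <- data.frame(trait_a = character(), trait_b = character(),
                        r = numeric(), p_value = numeric())
  if (any(edges$trait_a == edges$trait_b))
    stop("self-edges are not allowed in the correlation network")
  if (is.null(nodes)) nodes <- unique(c(edges$trait_a, edges$trait_b))
  if (format == "sif") {
    lines <- character(0)
    if (nrow(edges))
      lines <- paste(edges$trait_a, "corr", edges$trait_b)
    isolated <- setdiff(nodes, c(edges$trait_a, edges$trait_b))
    writeLines(c(lines, isolated), path)
    attr_df <- data.frame(edge = sprintf("%s (corr) %s",
                                         edges$trait_a, edges$trait_b),
                          r = edges$r, p_value = edges$p_value)
    utils::write.table(attr_df, paste0(path, ".edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      edges[, c("trait_a", "trait_b", "r", "p_value")],
      directed = FALSE,
      vertices = data.frame(name = nodes))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
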