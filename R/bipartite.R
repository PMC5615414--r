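# The miRNA-disease bipartite association network. The container is an
# igraph graph: miRNA and disease nodes carry a `role` attribute, edges carry
# the Fisher p-value as weight, the supporting-paper count, and -log10(p) as
# a numeric "strength" attribute for viewers that render edge thickness.

#' Build the bipartite miRNA-disease network
#'
#' One node per distinct miRNA and disease group, one edge per association
#' record, weighted by the pair's p-value. Strict bipartiteness holds by
#' construction and is re-verified structurally.
#'
#' @param records A `mirna_associations` data frame (or any data frame with
#'   `mirna`, `disease`, `p_value`, `paper_count` columns). Duplicate
#'   (miRNA, group) rows are an error.
#' @return An igraph graph with vertex attributes `role` and `type` (logical
#'   bipartite mapping) and edge attributes `p_value`, `paper_count`,
#'   `neg_log10_p` and `weight`.
#' @export
build_bipartite <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("mirna", "disease", "p_value", "paper_count") %in%
                  names(records)))
  if (anyDuplicated(paste0(records$mirna, "\r", records$disease))) {
    stop("duplicate (miRNA, disease) association records", call. = FALSE)
  }
  mirnas <- unique(records$mirna)
  diseases <- unique(records$disease)
  clash <- intersect(mirnas, diseases)
  if (length(clash)) {
    stop("name used as both miRNA and disease: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  vertices <- data.frame(
    name = c(mirnas, diseases),
    role = c(rep("mirna", length(mirnas)), rep("disease", length(diseases))),
    stringsAsFactors = FALSE)
  vertices$type <- vertices$role == "disease"
  edges <- data.frame(from = records$mirna, to = records$disease,
                      p_value = records$p_value,
                      paper_count = records$paper_count,
                      neg_log10_p = -log10(records$p_value),
                      weight = records$p_value,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  assert_bipartite(g)
  g
}

# structural re-check: every edge must join a mirna to a disease
assert_bipartite <- function(g) {
  if (igraph::ecount(g) == 0) return(invisible(g))
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  role <- igraph::vertex_attr(g, "role")
  ok <- role[ends[, 1]] != role[ends[, 2]]
  if (!all(ok)) stop("network is not bipartite", call. = FALSE)
  invisible(g)
}

igraph_to_tables <- function(g) {
  vat <- igraph::vertex_attr_names(g)
  nodes <- data.frame(id = igraph::vertex_attr(g, "name"),
                      stringsAsFactors = FALSE)
  for (a in setdiff(vat, c("name", "type"))) {
    nodes[[a]] <- igraph::vertex_attr(g, a)
  }
  eat <- igraph::edge_attr_names(g)
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  edges <- data.frame(source = ends[, 1], target = ends[, 2],
                      stringsAsFactors = FALSE)
  for (a in eat) edges[[a]] <- igraph::edge_attr(g, a)
  list(nodes = nodes, edges = edges)
}

#' Export a network to a standard graph format
#'
#' `graphml` and `xgmml` are lossless (re-import reproduces node/edge sets
#' and attributes); `sif` and `edge_tsv` carry topology plus edge weight
#' only.
#'
#' @param net An igraph graph (from [build_bipartite()] or
#'   [extended_to_igraph()]).
#' @param format One of `"graphml"`, `"sif"`, `"xgmml"`, `"edge_tsv"`.
#' @param path Output file path.
#' @param label Graph label used in XGMML output.
#' @return The path, invisibly.
#' @export
export_network <- function(net, format = c("graphml", "sif", "xgmml",
                                           "edge_tsv"),
                           path, label = "network") {
  format <- match.arg(format)
  tabs <- igraph_to_tables(net)
  switch(format,
         graphml = igraph::write_graph(net, path, format = "graphml"),
         sif = {
           rel <- if ("support_count" %in% names(tabs$edges)) "targets" else
             "associates"
           lines <- if (nrow(tabs$edges)) {
             paste(tabs$edges$source, rel, tabs$edges$target, sep = "\t")
           } else character(0)
           writeLines(lines, path, useBytes = TRUE)
         },
         xgmml = write_xgmml_graph(path, label, tabs$nodes, tabs$edges,
                                   directed = igraph::is_directed(net)),
         edge_tsv = write_tsv_file(tabs$edges, path))
  invisible(path)
}

#' Import a network written by [export_network()]
#'
#' @param path File path.
#' @param format `"graphml"` or `"xgmml"` (the lossless dialects).
#' @return An igraph graph.
#' @export
import_network <- function(path, format = c("graphml", "xgmml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  gr <- read_xgmml_graph(path)
  nodes <- gr$nodes
  names(nodes)[names(nodes) == "id"] <- "name"
  igraph::graph_from_data_frame(gr$edges, directed = gr$directed,
                                vertices = nodes)
}
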