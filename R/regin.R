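# Regulatory interaction networks (RegINs) and seed-set extension with
# source-overlap filtering: the network-extension semantics of
# CyTargetLinker-style tools, re-implemented as pure functions. Each loaded
# RegIN is a directed regulator -> target edge list from one source
# database; extension annotates each edge with the set of sources that
# support it, and the overlap threshold retains edges supported by >= k
# distinct sources.

#' Construct a RegIN
#'
#' @param source_name Label of the source database.
#' @param edges Data frame with `regulator` and `target` columns; duplicate
#'   edges are collapsed.
#' @return An object of class `regin`.
#' @export
regin <- function(source_name, edges) {
  stopifnot(is.character(source_name), length(source_name) == 1L,
            nzchar(source_name), is.data.frame(edges),
            all(c("regulator", "target") %in% names(edges)))
  edges <- unique(edges[, c("regulator", "target")])
  if (nrow(edges) && (any(!nzchar(edges$regulator)) ||
                      any(!nzchar(edges$target)))) {
    stop("empty regulator or target identifier", call. = FALSE)
  }
  rownames(edges) <- NULL
  structure(list(source_name = source_name, edges = edges),
            class = "regin")
}

#' @export
print.regin <- function(x, ...) {
  cat("RegIN '", x$source_name, "': ", nrow(x$edges),
      " regulator->target edges, ", length(unique(x$edges$regulator)),
      " regulators, ", length(unique(x$edges$target)), " targets\n",
      sep = "")
  invisible(x)
}

#' Load a RegIN from file
#'
#' @param path File path.
#' @param dialect `"tsv"` (3 columns: regulator, target, source; the third
#'   may be absent) or `"xgmml"`.
#' @param source_name Override for the source label; defaults to the file's
#'   metadata (XGMML graph label / TSV source column) or the file name.
#' @return A `regin` object with deduplicated edges.
#' @export
load_regin <- function(path, dialect = c("tsv", "xgmml"),
                       source_name = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    if (file.size(path) == 0) {
      return(regin(source_name %||%
                     tools::file_path_sans_ext(basename(path)),
                   data.frame(regulator = character(0),
                              target = character(0),
                              stringsAsFactors = FALSE)))
    }
    df <- tryCatch(read_tsv_file(path), error = function(e) {
      stop("cannot parse RegIN TSV ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
    if (!all(c("regulator", "target") %in% names(df))) {
      stop("RegIN TSV ", path, " lacks regulator/target columns ",
           "(found: ", paste(names(df), collapse = ", "), ")",
           call. = FALSE)
    }
    sn <- source_name %||%
      (if ("source" %in% names(df) && nrow(df)) df$source[1] else
        tools::file_path_sans_ext(basename(path)))
    return(regin(sn, df))
  }
  gr <- read_xgmml_graph(path)
  sn <- source_name %||% gr$label %||%
    tools::file_path_sans_ext(basename(path))
  regin(sn, data.frame(regulator = gr$edges$source,
                       target = gr$edges$target,
                       stringsAsFactors = FALSE))
}

#' Write a RegIN to file
#'
#' @param x A `regin`.
#' @param path Output path.
#' @param dialect `"tsv"` or `"xgmml"`.
#' @return The path, invisibly.
#' @export
write_regin <- function(x, path, dialect = c("tsv", "xgmml")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "regin"))
  if (dialect == "tsv") {
    df <- x$edges
    df$source <- rep(x$source_name, nrow(df))
    return(write_tsv_file(df, path))
  }
  ids <- unique(c(x$edges$regulator, x$edges$target))
  write_xgmml_graph(path, x$source_name,
                    nodes = data.frame(id = ids, stringsAsFactors = FALSE),
                    edges = data.frame(source = x$edges$regulator,
                                       target = x$edges$target,
                                       source_db = rep(x$source_name,
                                                       nrow(x$edges)),
                                       stringsAsFactors = FALSE))
}

#' Extend a seed miRNA set with RegIN interactions
#'
#' For `direction = "targets"` adds every gene `g` with an edge `(s, g)` in
#' any RegIN for a seed `s`; `"regulators"` adds every regulator `r` with an
#' edge `(r, s)`; `"both"` adds both. Each retained edge is annotated with
#' the set of source databases supporting it.
#'
#' @param seeds Non-empty character vector of seed identifiers (miRBase-style
#'   accessions).
#' @param regins List of `regin` objects (at least one).
#' @param direction `"targets"`, `"regulators"` or `"both"`.
#' @return An object of class `extended_network`: fields `seeds`,
#'   `direction`, `sources`, `edges` (data frame `regulator`, `target`,
#'   `support_sources` pipe-separated, `support_count`) and `hidden`
#'   (currently hidden sources, initially none). Seeds absent from every
#'   RegIN yield a seeds-only network.
#' @export
extend_network <- function(seeds, regins,
                           direction = c("targets", "regulators", "both")) {
  direction <- match.arg(direction)
  stopifnot(length(seeds) >= 1L, length(regins) >= 1L,
            all(vapply(regins, inherits, logical(1), "regin")))
  sources <- vapply(regins, `[[`, "", "source_name")
  if (anyDuplicated(sources)) {
    stop("duplicate RegIN source names", call. = FALSE)
  }
  rows <- lapply(regins, function(rg) {
    e <- rg$edges
    keep <- switch(direction,
                   targets = e$regulator %in% seeds,
                   regulators = e$target %in% seeds,
                   both = e$regulator %in% seeds | e$target %in% seeds)
    if (!any(keep)) return(NULL)
    cbind(e[keep, , drop = FALSE], src = rg$source_name)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L) {
    edges <- data.frame(regulator = character(0), target = character(0),
                        support_sources = character(0),
                        support_count = integer(0), stringsAsFactors = FALSE)
  } else {
    key <- paste0(rows$regulator, "\r", rows$target)
    supp <- lapply(split(rows$src, key), function(s) sort(unique(s)))
    keys <- names(supp)
    parts <- strsplit(keys, "\r", fixed = TRUE)
    edges <- data.frame(
      regulator = vapply(parts, `[`, "", 1L),
      target = vapply(parts, `[`, "", 2L),
      support_sources = vapply(supp, paste, "", collapse = "|"),
      support_count = lengths(supp),
      stringsAsFactors = FALSE)
    edges <- edges[order_c(edges$regulator, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(seeds = unique(seeds), direction = direction,
                 sources = unname(sources), edges = edges,
                 hidden = character(0)),
            class = "extended_network")
}

# support sets restricted to visible (non-hidden) sources; edges whose
# visible support is empty are dropped
visible_edges <- function(extnet) {
  ed <- extnet$edges
  if (!nrow(ed) || !length(extnet$hidden)) {
    ed$visible_sources <- ed$support_sources
    ed$visible_count <- ed$support_count
    return(ed)
  }
  vis <- lapply(strsplit(ed$support_sources, "|", fixed = TRUE),
                setdiff, y = extnet$hidden)
  ed$visible_sources <- vapply(vis, paste, "", collapse = "|")
  ed$visible_count <- lengths(vis)
  ed[ed$visible_count > 0L, , drop = FALSE]
}

added_nodes <- function(extnet) {
  ed <- visible_edges(extnet)
  setdiff(unique(c(ed$regulator, ed$target)), extnet$seeds)
}

#' @export
print.extended_network <- function(x, ...) {
  ed <- visible_edges(x)
  cat("Extended network: ", length(x$seeds), " seeds, direction '",
      x$direction, "'\n", sep = "")
  cat("  sources: ", paste(x$sources, collapse = ", "),
      if (length(x$hidden)) paste0(" (hidden: ",
                                   paste(x$hidden, collapse = ", "), ")"),
      "\n", sep = "")
  cat("  visible edges: ", nrow(ed), ", added nodes: ",
      length(added_nodes(x)), "\n", sep = "")
  invisible(x)
}

#' Retain only edges supported by at least k sources
#'
#' The overlap-threshold filter: keeps exactly the edges whose (visible)
#' support set has size `>= k`, then drops added nodes left without any
#' incident edge; seeds are always retained. With `s` loaded sources,
#' `k = s` is equivalent to the per-seed intersection of the source target
#' sets.
#'
#' @param extnet An `extended_network`.
#' @param k Minimum number of distinct supporting sources (`>= 1`).
#' @return The filtered `extended_network`.
#' @export
overlap_threshold <- function(extnet, k) {
  stopifnot(inherits(extnet, "extended_network"))
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("`k` must be an integer >= 1", call. = FALSE)
  }
  ed <- visible_edges(extnet)
  keep <- ed$visible_count >= k
  extnet$edges <- ed[keep, c("regulator", "target", "support_sources",
                             "support_count"), drop = FALSE]
  rownames(extnet$edges) <- NULL
  extnet
}

#' Temporarily hide RegIN sources
#'
#' Support sets are recomputed over the visible sources and edges with empty
#' visible support disappear from accessors, but the operation is
#' non-destructive: `hide_sources(net, character(0))` restores the original
#' network exactly.
#'
#' @param extnet An `extended_network`.
#' @param hidden Character vector of source names to hide (must be loaded
#'   sources).
#' @return The network with its hidden set replaced.
#' @export
hide_sources <- function(extnet, hidden) {
  stopifnot(inherits(extnet, "extended_network"))
  unknown <- setdiff(hidden, extnet$sources)
  if (length(unknown)) {
    stop("unknown source name: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  extnet$hidden <- unique(hidden)
  extnet
}

#' Summarize an extended network
#'
#' Reports total (visible) nodes and edges, per-source edge counts, and the
#' number of defined targets per seed set — the shape of published
#' network-extension accounting tables, whose grand total row is the sum of
#' the per-set rows.
#'
#' @param extnet An `extended_network`.
#' @param seed_sets Optional named list partitioning (a subset of) the seeds
#'   into sets; defaults to one set holding all seeds.
#' @return A list with `totals` (nodes, edges), `per_source` (source, edges),
#'   `per_set` (set, seeds, defined_targets) and `total_defined`.
#' @export
mti_accounting <- function(extnet, seed_sets = NULL) {
  stopifnot(inherits(extnet, "extended_network"))
  ed <- visible_edges(extnet)
  if (is.null(seed_sets)) seed_sets <- list(all = extnet$seeds)
  if (is.null(names(seed_sets))) {
    names(seed_sets) <- sprintf("set-%d", seq_along(seed_sets))
  }
  visible_sources <- setdiff(extnet$sources, extnet$hidden)
  per_source <- data.frame(
    source = visible_sources,
    edges = vapply(visible_sources, function(s) {
      sum(vapply(strsplit(ed$visible_sources, "|", fixed = TRUE),
                 function(x) s %in% x, logical(1)))
    }, 0L), stringsAsFactors = FALSE, row.names = NULL)
  defined_for <- function(seeds) {
    sub <- switch(extnet$direction,
                  targets = ed[ed$regulator %in% seeds, , drop = FALSE],
                  regulators = ed[ed$target %in% seeds, , drop = FALSE],
                  both = ed[ed$regulator %in% seeds |
                              ed$target %in% seeds, , drop = FALSE])
    length(setdiff(unique(c(sub$regulator, sub$target)), extnet$seeds))
  }
  per_set <- data.frame(
    set = names(seed_sets),
    seeds = vapply(seed_sets, length, 0L),
    defined_targets = vapply(seed_sets, defined_for, 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  nodes <- length(extnet$seeds) + length(added_nodes(extnet))
  list(totals = data.frame(nodes = nodes, edges = nrow(ed)),
       per_source = per_source, per_set = per_set,
       total_defined = length(added_nodes(extnet)))
}

#' Convert an extended network to igraph
#'
#' Visible edges become directed regulator -> target igraph edges carrying
#' `support_sources` and `support_count`; node attribute `role` is `seed` or
#' `added`.
#'
#' @param extnet An `extended_network`.
#' @return An igraph graph.
#' @export
extended_to_igraph <- function(extnet) {
  ed <- visible_edges(extnet)
  nodes <- data.frame(
    name = unique(c(extnet$seeds, ed$regulator, ed$target)),
    stringsAsFactors = FALSE)
  nodes$role <- ifelse(nodes$name %in% extnet$seeds, "seed", "added")
  igraph::graph_from_data_frame(
    data.frame(from = ed$regulator, to = ed$target,
               support_sources = ed$visible_sources,
               support_count = ed$visible_count, stringsAsFactors = FALSE),
    directed = TRUE, vertices = nodes)
}
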