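# Gene Ontology overrepresentation: minimal OBO parsing, true-path
# annotation propagation, the right-sided hypergeometric term test, and
# Benjamini-Hochberg step-up adjustment.

#' Construct a GO DAG object
#'
#' @param terms Data frame with columns `id`, `name`, `namespace`.
#' @param parents Named list: term id -> character vector of `is_a` parents
#'   (empty or `NULL` for roots).
#' @return A validated object of class `go_dag`.
#' @export
go_dag <- function(terms, parents) {
  stopifnot(is.data.frame(terms),
            all(c("id", "name", "namespace") %in% names(terms)))
  if (anyDuplicated(terms$id)) stop("duplicate term ids", call. = FALSE)
  parents <- parents[terms$id]
  names(parents) <- terms$id
  parents <- lapply(parents, function(p) as.character(p %||% character(0)))
  missing <- setdiff(unlist(parents, use.names = FALSE), terms$id)
  if (length(missing)) {
    stop("is_a parent not defined in the ontology: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dag <- structure(list(terms = terms, parents = parents), class = "go_dag")
  assert_acyclic(dag)
  dag
}

# Depth-first cycle check; names the cycle it finds.
assert_acyclic <- function(dag) {
  state <- new.env(parent = emptyenv())  # 1 = in progress, 2 = done
  visit <- function(id, path) {
    s <- if (exists(id, envir = state, inherits = FALSE))
      get(id, envir = state) else 0L
    if (s == 2L) return(invisible())
    if (s == 1L) {
      cyc <- c(path[which(path == id)[1]:length(path)], id)
      stop("cycle in is_a hierarchy: ", paste(cyc, collapse = " -> "),
           call. = FALSE)
    }
    assign(id, 1L, envir = state)
    for (p in dag$parents[[id]]) visit(p, c(path, id))
    assign(id, 2L, envir = state)
  }
  for (id in dag$terms$id) visit(id, character(0))
  invisible(dag)
}

#' @export
print.go_dag <- function(x, ...) {
  roots <- sum(lengths(x$parents) == 0)
  cat("GO DAG: ", nrow(x$terms), " terms (", roots, " root",
      if (roots != 1) "s", "), ",
      sum(lengths(x$parents)), " is_a edges\n", sep = "")
  invisible(x)
}

#' Parse a minimal OBO ontology file
#'
#' Supports the `[Term]` stanza subset: `id`, `name`, `namespace`, `is_a`
#' (with optional `! comment` suffixes). The resulting hierarchy is
#' validated: unknown parents are a reference error, cycles a structural
#' error naming the cycle.
#'
#' @param path Path to the OBO file.
#' @return A `go_dag`.
#' @export
parse_obo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  ids <- character(0); nms <- character(0); nss <- character(0)
  parents <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur) || is.null(cur$id)) return()
    ids <<- c(ids, cur$id)
    nms <<- c(nms, cur$name %||% cur$id)
    nss <<- c(nss, cur$namespace %||% "biological_process")
    parents[[cur$id]] <<- cur$is_a
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush(); cur <- list(is_a = character(0)); in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      flush(); cur <- NULL; in_term <- FALSE
    } else if (in_term && grepl("^id:", ln)) {
      cur$id <- trimws(sub("^id:", "", ln))
    } else if (in_term && grepl("^name:", ln)) {
      cur$name <- trimws(sub("^name:", "", ln))
    } else if (in_term && grepl("^namespace:", ln)) {
      cur$namespace <- trimws(sub("^namespace:", "", ln))
    } else if (in_term && grepl("^is_a:", ln)) {
      p <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$is_a <- c(cur$is_a, p)
    }
  }
  flush()
  go_dag(terms = data.frame(id = ids, name = nms, namespace = nss,
                            stringsAsFactors = FALSE),
         parents = parents)
}

#' Write a GO DAG as minimal OBO
#'
#' @param dag A `go_dag`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    writeLines(c("", "[Term]",
                 paste0("id: ", id),
                 paste0("name: ", dag$terms$name[i]),
                 paste0("namespace: ", dag$terms$namespace[i]),
                 if (length(dag$parents[[id]]))
                   paste0("is_a: ", dag$parents[[id]])), con)
  }
  invisible(path)
}

#' Read a gene-to-term annotation TSV
#'
#' @param path TSV with columns `gene` and `term` (direct annotations).
#' @return A data frame with those columns.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_file(path)
  stopifnot(all(c("gene", "term") %in% names(df)))
  df[, c("gene", "term")]
}

#' Write a gene-to-term annotation TSV
#'
#' @param annotations Data frame with `gene`, `term` columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  write_tsv_file(annotations[, c("gene", "term")], path)
}

# memoized ancestor closure (excluding the term itself)
term_ancestors <- function(dag) {
  memo <- new.env(parent = emptyenv())
  anc <- function(id) {
    if (exists(id, envir = memo, inherits = FALSE))
      return(get(id, envir = memo))
    ps <- dag$parents[[id]]
    out <- unique(c(ps, unlist(lapply(ps, anc), use.names = FALSE)))
    assign(id, out, envir = memo)
    out
  }
  stats::setNames(lapply(dag$terms$id, anc), dag$terms$id)
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Closes every gene's term set under `is_a` ancestry: a gene annotated to a
#' term is implicitly annotated to all its ancestors. Idempotent.
#'
#' @param annotations Data frame with `gene`, `term` columns.
#' @param dag A `go_dag`; all annotated terms must exist in it.
#' @return The propagated annotation data frame (unique gene/term rows).
#' @export
propagate <- function(annotations, dag) {
  stopifnot(inherits(dag, "go_dag"))
  bad <- setdiff(annotations$term, dag$terms$id)
  if (length(bad)) {
    stop("annotation references unknown terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  anc <- term_ancestors(dag)
  ext <- lapply(seq_len(nrow(annotations)), function(i) {
    terms <- c(annotations$term[i], anc[[annotations$term[i]]])
    data.frame(gene = annotations$gene[i], term = terms,
               stringsAsFactors = FALSE)
  })
  out <- unique(do.call(rbind, c(list(annotations[0, c("gene", "term")]),
                                 ext)))
  out <- out[order_c(out$gene, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Right tail P(X >= k) for X ~ Hypergeometric(N, K, n), via the same
# log-space point-probability machinery as the Fisher test.
hyper_right_tail <- function(k, N, K, n) {
  if (k <= max(0, n + K - N)) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  j <- k:hi
  lp <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  m <- max(lp)
  min(1, exp(m) * sum(exp(lp - m)))
}

#' Right-sided hypergeometric p-value for one GO term
#'
#' With `N` background genes of which `K` are annotated to the term
#' (after propagation), and a query of `n` genes of which `k` are annotated:
#' the probability of drawing `k` or more annotated genes in a sample of `n`
#' without replacement.
#'
#' @param term Term id.
#' @param query_genes Character vector of query genes (must lie in the
#'   universe).
#' @param annotations Propagated annotation data frame (`gene`, `term`).
#' @param universe Background gene universe; defaults to all annotated genes.
#' @return The tail probability.
#' @export
hypergeom_term_p <- function(term, query_genes, annotations,
                             universe = unique(annotations$gene)) {
  if (!all(query_genes %in% universe)) {
    stop("query genes outside the background universe: ",
         paste(setdiff(query_genes, universe), collapse = ", "),
         call. = FALSE)
  }
  ann_genes <- unique(annotations$gene[annotations$term == term])
  ann_genes <- intersect(ann_genes, universe)
  N <- length(unique(universe))
  K <- length(ann_genes)
  n <- length(unique(query_genes))
  k <- length(intersect(unique(query_genes), ann_genes))
  hyper_right_tail(k, N, K, n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj_(i) = min_{j >= i} ( m * p_(j) / j )`, capped at 1 and mapped back to
#' the input order; controls the false discovery rate over the family of
#' tested hypotheses.
#'
#' @param pvals Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvals)
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * pvals[o]))[ro]
}

#' GO term overrepresentation in a query gene set
#'
#' Tests every term annotating at least one query gene (after true-path
#' propagation unless disabled) with the right-sided hypergeometric test,
#' then applies Benjamini-Hochberg correction over exactly that tested
#' family. Terms with no query gene are not tested and do not enter the BH
#' family (this changes `m`, and is why the adjusted values depend on the
#' query).
#'
#' @param query_genes Non-empty character vector of query genes.
#' @param annotations Direct annotation data frame (`gene`, `term`).
#' @param dag A `go_dag`.
#' @param alpha Significance level on the adjusted p-value (or the raw one
#'   when `correct = "raw"`).
#' @param propagate_annotations Apply the true-path rule before counting
#'   (default); set `FALSE` to count raw annotations.
#' @param universe Background universe; defaults to every gene in the
#'   annotation table.
#' @param correct `"bh"` (default) flags significance on the adjusted
#'   p-value; `"raw"` on the raw p-value.
#' @return A data frame of class `go_enrichment`, sorted by ascending raw
#'   p-value, with columns `term_id`, `description`, `total_genes` (universe
#'   genes annotated), `partner_genes` (query genes annotated), `p_value`,
#'   `adj_p_value` and `significant`.
#' @export
enrich <- function(query_genes, annotations, dag, alpha = 0.05,
                   propagate_annotations = TRUE,
                   universe = NULL, correct = c("bh", "raw")) {
  correct <- match.arg(correct)
  stopifnot(inherits(dag, "go_dag"))
  query_genes <- unique(query_genes)
  if (!length(query_genes)) stop("empty query gene set", call. = FALSE)
  ann <- if (propagate_annotations) propagate(annotations, dag) else
    unique(annotations[, c("gene", "term")])
  universe <- unique(universe %||% ann$gene)
  if (!all(query_genes %in% universe)) {
    stop("query genes outside the background universe: ",
         paste(setdiff(query_genes, universe), collapse = ", "),
         call. = FALSE)
  }
  ann <- ann[ann$gene %in% universe, , drop = FALSE]
  N <- length(universe)
  n <- length(query_genes)
  by_term <- split(ann$gene, ann$term)
  K_all <- lengths(lapply(by_term, unique))
  k_all <- vapply(by_term, function(g)
    length(intersect(unique(g), query_genes)), 0L)
  tested <- names(by_term)[k_all >= 1L]
  if (!length(tested)) {
    res <- data.frame(term_id = character(0), description = character(0),
                      total_genes = integer(0), partner_genes = integer(0),
                      p_value = numeric(0), adj_p_value = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  } else {
    p <- vapply(tested, function(tm)
      hyper_right_tail(k_all[[tm]], N, K_all[[tm]], n), numeric(1))
    adj <- bh_adjust(p)
    res <- data.frame(
      term_id = tested,
      description = dag$terms$name[match(tested, dag$terms$id)],
      total_genes = unname(K_all[tested]),
      partner_genes = unname(k_all[tested]),
      p_value = unname(p), adj_p_value = unname(adj),
      stringsAsFactors = FALSE)
    res$significant <- if (correct == "bh") res$adj_p_value <= alpha else
      res$p_value <= alpha
    res <- res[order_c(res$p_value, res$term_id), , drop = FALSE]
    rownames(res) <- NULL
  }
  structure(res, universe_size = N, query_size = n, alpha = alpha,
            correct = correct,
            class = c("go_enrichment", "data.frame"))
}

#' @export
print.go_enrichment <- function(x, ...) {
  cat("GO overrepresentation (right-sided hypergeometric, ",
      if (attr(x, "correct") == "bh") "BH-adjusted" else "raw",
      " alpha = ", attr(x, "alpha"), ")\n", sep = "")
  cat("  universe ", attr(x, "universe_size"), " genes, query ",
      attr(x, "query_size"), " genes, ", nrow(x), " terms tested, ",
      sum(x$significant), " significant\n\n", sep = "")
  df <- as.data.frame(x)
  df$p_value <- format_sci(df$p_value)
  df$adj_p_value <- format_sci(df$adj_p_value)
  print(utils::head(df, 15), row.names = FALSE)
  if (nrow(df) > 15) cat("  ... and", nrow(df) - 15, "more rows\n")
  invisible(x)
}

#' Write enrichment rows as TSV
#'
#' Columns mirror published BiNGO result tables: GO ID, description, total
#' (background) genes, partner (query) genes, raw and adjusted p-values in
#' `1.83E-06`-style notation.
#'
#' @param enrichment A `go_enrichment` data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_enrichment <- function(enrichment, path) {
  df <- as.data.frame(enrichment)
  out <- data.frame(go_id = df$term_id, description = df$description,
                    total_genes = df$total_genes,
                    partner_genes = df$partner_genes,
                    p_value = format_sci(df$p_value),
                    adj_p_value = format_sci(df$adj_p_value),
                    significant = df$significant, stringsAsFactors = FALSE)
  write_tsv_file(out, path)
}
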