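#' Build a 2x2 abstract contingency table
#'
#' The unit of counting is the abstract: `a` abstracts mention both the miRNA
#' and the disease term (true positives under the co-occurrence assumption),
#' `b` only the miRNA, `c` only the disease, and `d` neither; `n = a+b+c+d` is
#' the corpus size.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return An object of class `contingency_table` with fields `a`, `b`, `c`,
#'   `d` and `n`.
#' @examples
#' contingency_table(3, 2, 2, 13)
#' @export
contingency_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d), n = as.integer(a + b + c + d)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("miRNA+", "miRNA-"),
                              c("disease+", "disease-")))
  cat("2x2 abstract contingency table (n = ", x$n, ")\n", sep = "")
  print(m)
  invisible(x)
}

# log point probability of the table under the hypergeometric null with all
# marginals fixed:  log[ (a+b)! (c+d)! (a+c)! (b+d)! / (a! b! c! d! n!) ].
# Vectorized over cells; computed with lgamma so n up to ~1e5 is safe.
log_point_hyper <- function(a, b, c, d) {
  n <- a + b + c + d
  lgamma(a + b + 1) + lgamma(c + d + 1) + lgamma(a + c + 1) +
    lgamma(b + d + 1) -
    (lgamma(a + 1) + lgamma(b + 1) + lgamma(c + 1) + lgamma(d + 1) +
       lgamma(n + 1))
}

#' Point hypergeometric probability of a 2x2 table
#'
#' Probability of observing exactly this table under the hypergeometric null
#' with both margins fixed: `(a+b)!(c+d)!(a+c)!(b+d)! / (a!b!c!d!n!)`.
#' Computed in log space so it remains stable for corpora up to ~1e5
#' abstracts.
#'
#' @param table A [contingency_table()].
#' @return A probability in `[0, 1]`.
#' @examples
#' point_hypergeometric(contingency_table(1, 1, 1, 1))  # 2/3
#' @export
point_hypergeometric <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  if (table$n < 1L) stop("undefined for an empty corpus (n = 0)", call. = FALSE)
  exp(log_point_hyper(table$a, table$b, table$c, table$d))
}

# Right-tail Fisher probability from raw cells; vectorized building block.
fisher_one_sided_counts <- function(a, b, c, d) {
  stopifnot(length(a) == length(b), length(b) == length(c),
            length(c) == length(d))
  out <- numeric(length(a))
  for (i in seq_along(a)) {
    imax <- min(b[i], c[i])          # shifts a -> a + j, j = 0..imax
    j <- 0:imax
    lp <- log_point_hyper(a[i] + j, b[i] - j, c[i] - j, d[i] + j)
    m <- max(lp)
    out[i] <- min(1, exp(m) * sum(exp(lp - m)))
  }
  out
}

#' One-sided Fisher's exact test (enrichment tail)
#'
#' Right-tail probability of observing `a` or more co-occurrences given the
#' table's margins: the sum of [point_hypergeometric()] over every table with
#' the same margins and a co-occurrence cell `>= a`. This is the enrichment
#' direction, appropriate when asking whether a miRNA and a disease are
#' mentioned together more often than independence predicts.
#'
#' @param table A [contingency_table()].
#' @return A p-value in `[0, 1]`.
#' @examples
#' fisher_one_sided(contingency_table(3, 2, 2, 13))  # 1126/15504
#' @export
fisher_one_sided <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  if (table$n < 1L) stop("undefined for an empty corpus (n = 0)", call. = FALSE)
  fisher_one_sided_counts(table$a, table$b, table$c, table$d)
}

#' Build the contingency table for one miRNA-disease pair
#'
#' Counts, over an annotated corpus, the abstracts falling in each cell for
#' the given pair. Every abstract contributes to exactly one cell and
#' `n` equals the corpus size.
#'
#' @param annotated An `annotated_corpus` from [annotate_corpus()].
#' @param mirna_id Canonical miRNA id (or compound pair key) known to the
#'   corpus annotation.
#' @param disease_group A disease/identifier group name.
#' @return A [contingency_table()].
#' @export
build_contingency <- function(annotated, mirna_id, disease_group) {
  stopifnot(inherits(annotated, "annotated_corpus"))
  if (!(mirna_id %in% annotated$known_mirnas)) {
    stop("unknown miRNA id: ", mirna_id, call. = FALSE)
  }
  if (!(disease_group %in% annotated$known_groups)) {
    stop("unknown disease group: ", disease_group, call. = FALSE)
  }
  has_m <- vapply(annotated$mirnas, function(s) mirna_id %in% s, logical(1))
  has_d <- vapply(annotated$diseases, function(s) disease_group %in% s,
                  logical(1))
  contingency_table(sum(has_m & has_d), sum(has_m & !has_d),
                    sum(!has_m & has_d), sum(!has_m & !has_d))
}

#' Score every co-occurring miRNA-disease pair
#'
#' Builds the 2x2 table for each pair that co-occurs in at least one abstract
#' (pairs with `a = 0` are not scored: under the co-occurrence assumption
#' there is no evidence to test) and computes the one-sided Fisher p-value.
#'
#' @param annotated An `annotated_corpus` from [annotate_corpus()].
#' @param alpha Significance threshold on the (raw) p-value; default 0.05.
#' @param bh If `TRUE`, add a Benjamini-Hochberg adjusted p-value column and
#'   flag significance on it instead. Off by default: the association stage
#'   applies a raw `p <= alpha` cutoff, multiple-testing correction only
#'   enters the GO stage.
#' @param n_total Total number of abstracts `n`; defaults to the corpus size.
#' @return A data frame of class `mirna_associations` with columns `mirna`,
#'   `disease`, `paper_count` (the `a` cell), `p_value` and `significant`
#'   (plus `adj_p_value` when `bh = TRUE`), and attributes `n` and `alpha`.
#' @export
score_all_pairs <- function(annotated, alpha = 0.05, bh = FALSE,
                            n_total = NULL) {
  stopifnot(inherits(annotated, "annotated_corpus"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single number in (0, 1)", call. = FALSE)
  }
  n <- n_total %||% annotated$n
  # pair co-occurrence and margin counts in one pass over abstracts
  pair_a <- new.env(parent = emptyenv())
  mir_n <- new.env(parent = emptyenv())
  dis_n <- new.env(parent = emptyenv())
  bump <- function(env, key) {
    assign(key, (if (exists(key, envir = env, inherits = FALSE))
      get(key, envir = env) else 0L) + 1L, envir = env)
  }
  for (i in seq_len(annotated$n)) {
    ms <- annotated$mirnas[[i]]
    ds <- annotated$diseases[[i]]
    for (m in ms) bump(mir_n, m)
    for (d in ds) bump(dis_n, d)
    for (m in ms) for (d in ds) bump(pair_a, paste0(m, "\r", d))
  }
  keys <- ls(pair_a)
  if (length(keys) == 0L) {
    res <- data.frame(mirna = character(0), disease = character(0),
                      paper_count = integer(0), p_value = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    mirna <- vapply(parts, `[`, "", 1L)
    disease <- vapply(parts, `[`, "", 2L)
    a <- vapply(keys, get, 0L, envir = pair_a, USE.NAMES = FALSE)
    b <- vapply(mirna, get, 0L, envir = mir_n, USE.NAMES = FALSE) - a
    cc <- vapply(disease, get, 0L, envir = dis_n, USE.NAMES = FALSE) - a
    d <- n - a - b - cc
    if (any(d < 0)) stop("`n_total` smaller than observed margins",
                         call. = FALSE)
    p <- fisher_one_sided_counts(a, b, cc, d)
    res <- data.frame(mirna = mirna, disease = disease, paper_count = a,
                      p_value = p, significant = p <= alpha,
                      stringsAsFactors = FALSE)
    if (bh) {
      res$adj_p_value <- bh_adjust(res$p_value)
      res$significant <- res$adj_p_value <= alpha
    }
    res <- res[order_c(res$p_value, -res$paper_count, res$mirna), ,
               drop = FALSE]
    rownames(res) <- NULL
  }
  structure(res, n = n, alpha = alpha, class = c("mirna_associations",
                                                 "data.frame"))
}

#' Rank associations and keep the top k
#'
#' Orders association records by ascending p-value, breaking ties by
#' descending supporting-paper count and then lexicographic miRNA name
#' (C locale), and truncates to `k` rows. This tie-break reproduces the
#' conventional ordering of published top-20 tables where several pairs share
#' one p-value.
#'
#' @param records A `mirna_associations` data frame (or any data frame with
#'   `mirna`, `paper_count`, `p_value` columns).
#' @param k Number of rows to keep; must be positive.
#' @return The reordered, truncated data frame with a `rank` column.
#' @export
top_k <- function(records, k = 20) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  stopifnot(is.data.frame(records),
            all(c("mirna", "paper_count", "p_value") %in% names(records)))
  out <- records[order_c(records$p_value, -records$paper_count,
                         records$mirna), , drop = FALSE]
  out <- utils::head(out, n = k)
  rownames(out) <- NULL
  out <- cbind(rank = seq_len(nrow(out)), out)
  attr(out, "n") <- attr(records, "n", exact = TRUE)
  attr(out, "alpha") <- attr(records, "alpha", exact = TRUE)
  class(out) <- unique(c(class(records), "data.frame"))
  out
}

#' @export
print.mirna_associations <- function(x, ...) {
  cat("miRNA-disease association scores (one-sided Fisher's exact test)\n")
  cat("  corpus size n = ", attr(x, "n", exact = TRUE) %||% NA,
      ", alpha = ", attr(x, "alpha", exact = TRUE) %||% NA, "\n", sep = "")
  cat("  ", nrow(x), " co-occurring pairs, ", sum(x$significant),
      " significant\n\n", sep = "")
  df <- as.data.frame(x)
  df$p_value <- format_sci(df$p_value)
  if ("adj_p_value" %in% names(df)) df$adj_p_value <- format_sci(df$adj_p_value)
  print(utils::head(df, 20), row.names = FALSE)
  if (nrow(df) > 20) cat("  ... and", nrow(df) - 20, "more rows\n")
  invisible(x)
}

#' @export
summary.mirna_associations <- function(object, ...) {
  cat("Corpus abstracts (n):      ", attr(object, "n", exact = TRUE), "\n")
  cat("Co-occurring pairs scored: ", nrow(object), "\n")
  cat("Distinct miRNAs:           ", length(unique(object$mirna)), "\n")
  cat("Distinct disease groups:   ", length(unique(object$disease)), "\n")
  cat("Significant at alpha =", attr(object, "alpha", exact = TRUE), ":",
      sum(object$significant), "\n")
  invisible(object)
}

#' Write association records as a ranked TSV
#'
#' Columns mirror published top-association tables: rank, miRNA, disease
#' group, number of supporting papers, p-value in `3.40E-05`-style scientific
#' notation.
#'
#' @param records A `mirna_associations` data frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_associations <- function(records, path) {
  df <- as.data.frame(records)
  if (!("rank" %in% names(df))) df <- cbind(rank = seq_len(nrow(df)), df)
  out <- data.frame(rank = df$rank, miRNA = df$mirna,
                    disease_group = df$disease,
                    paper_count = df$paper_count,
                    p_value = format_sci(df$p_value),
                    significant = df$significant,
                    stringsAsFactors = FALSE)
  write_tsv_file(out, path)
}
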