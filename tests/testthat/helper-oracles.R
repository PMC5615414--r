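# Independent oracles used to freeze expected values. These deliberately use
# direct combinatorial formulas (exact double arithmetic via choose()) and
# never touch the package's log-space implementations.

# Right-tail Fisher probability by exhaustive enumeration of all tables with
# the observed margins and co-occurrence cell >= a.
fisher_enum_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b   # miRNA margin
  c1 <- a + c   # disease margin
  aa <- a:min(r1, c1)
  sum(choose(r1, aa) * choose(n - r1, c1 - aa)) / choose(n, c1)
}

# Point probability of one table, same route.
point_enum_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  choose(a + b, a) * choose(c + d, c) / choose(n, a + c)
}

# P(X >= k), X ~ Hypergeometric(N, K, n), by term-wise enumeration.
hyper_enum_oracle <- function(k, N, K, n) {
  lo <- max(0, n + K - N)
  hi <- min(K, n)
  if (k > hi) return(0)
  j <- max(k, lo):hi
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Literal Benjamini-Hochberg step-up evaluation.
bh_direct_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[o[i]] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  adj
}

# Small corpus configuration reused across NER / association tests.
small_config <- function(seed, n_abstracts = 60,
                         planted = list(c("miR-33a", "HDL-Cholesterol")),
                         p_comention = 0.8, bg = 0.05, ...) {
  corpus_config(
    n_abstracts = n_abstracts,
    mirna_ids = c("miR-33a", "miR-33b", "miR-122", "miR-15", "miR-16",
                  "miR-221", "miR-222", "lin-4", "let-7", "miR-1a-1"),
    disease_groups = c("Dyslipidemia", "HDL-Cholesterol", "Triglyceride"),
    planted_pairs = planted, p_comention = p_comention,
    p_background_mirna = bg, p_background_disease = bg, seed = seed, ...)
}

# Pair-level co-mention counts computed from ground-truth intent lists,
# bypassing text rendering entirely.
truth_pair_counts <- function(truth) {
  counts <- list()
  for (i in seq_along(truth$mirnas)) {
    for (m in truth$mirnas[[i]]) {
      for (d in truth$diseases[[i]]) {
        key <- paste(m, d, sep = "\r")
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
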