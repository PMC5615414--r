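# Contingency tables, the point hypergeometric probability, the one-sided
# Fisher tail, pair scoring and top-k ranking.

test_that("point hypergeometric matches direct enumeration", {
  # frozen from the enumeration oracle: 2!2!2!2!/(1!1!1!1!4!) = 16/24
  expect_equal(point_hypergeometric(contingency_table(1, 1, 1, 1)), 2 / 3,
               tolerance = 1e-12)
  # degenerate margins admitting a single table force probability one
  expect_equal(point_hypergeometric(contingency_table(4, 0, 0, 0)), 1,
               tolerance = 1e-12)
  expect_equal(point_hypergeometric(contingency_table(0, 0, 0, 6)), 1,
               tolerance = 1e-12)
  set.seed(42)
  for (rep in 1:25) {
    cells <- as.integer(rmultinom(1, sample(4:60, 1), rep(0.25, 4)))
    expect_equal(point_hypergeometric(do.call(contingency_table,
                                              as.list(cells))),
                 point_enum_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
  }
})

test_that("point probabilities over the admissible range sum to one", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(2:200, 1)
    r1 <- sample.int(n, 1)
    c1 <- sample.int(n, 1)
    a_range <- max(0, r1 + c1 - n):min(r1, c1)
    tot <- sum(vapply(a_range, function(a) {
      point_hypergeometric(contingency_table(a, r1 - a, c1 - a,
                                             n - r1 - c1 + a))
    }, numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("one-sided Fisher tail matches enumeration and fisher.test", {
  # frozen from the enumeration oracle over margins (5,15) x (5,15)
  expect_equal(fisher_one_sided(contingency_table(3, 2, 2, 13)),
               1126 / 15504, tolerance = 1e-10)
  # whole tail at the minimum admissible a
  expect_equal(fisher_one_sided(contingency_table(0, 5, 5, 10)), 1,
               tolerance = 1e-12)
  # single admissible table
  expect_equal(fisher_one_sided(contingency_table(0, 0, 0, 10)), 1)
  set.seed(11)
  for (rep in 1:40) {
    cells <- as.integer(rmultinom(1, sample(4:80, 1), rep(0.25, 4)))
    tab <- do.call(contingency_table, as.list(cells))
    p <- fisher_one_sided(tab)
    expect_equal(p, fisher_enum_oracle(cells[1], cells[2], cells[3],
                                       cells[4]), tolerance = 1e-10)
    # independent library route
    ft <- stats::fisher.test(matrix(c(cells[1], cells[2], cells[3],
                                      cells[4]), 2, byrow = TRUE),
                             alternative = "greater")
    expect_equal(p, ft$p.value, tolerance = 1e-8)
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("empty tables are rejected", {
  expect_error(point_hypergeometric(contingency_table(0, 0, 0, 0)), "n = 0")
  expect_error(fisher_one_sided(contingency_table(0, 0, 0, 0)), "n = 0")
  expect_error(contingency_table(-1, 0, 0, 2), "non-negative")
})

test_that("tail probability strictly decreases in a with margins fixed", {
  set.seed(5)
  for (rep in 1:30) {
    n <- sample(4:100, 1)
    r1 <- sample.int(n - 1, 1)
    c1 <- sample.int(n - 1, 1)
    a_range <- max(0, r1 + c1 - n):min(r1, c1)
    if (length(a_range) < 2) next
    p <- vapply(a_range, function(a)
      fisher_one_sided(contingency_table(a, r1 - a, c1 - a,
                                         n - r1 - c1 + a)), numeric(1))
    # strict wherever the removed point probability is resolvable above
    # the tail's accumulated rounding
    point <- exp(mirlipidnet:::log_point_hyper(a_range, r1 - a_range,
                                               c1 - a_range,
                                               n - r1 - c1 + a_range))
    len <- length(p)
    expect_true(all(diff(p) < 0 | point[-len] < 1e-12 * p[-len]))
  }
})

test_that("build_contingency counts abstracts into the four cells", {
  corpus <- data.frame(
    id = paste0("a", 1:5), source = "synthetic", year = 2010,
    title = c("t1", "t2", "t3", "t4", "t5"),
    text = c("miR-33a is linked to dyslipidemia here",
             "miR-33a acts alone",
             "dyslipidemia discussed alone",
             "nothing relevant", "plain filler"),
    stringsAsFactors = FALSE)
  ann <- annotate_corpus(corpus)
  tab <- build_contingency(ann, "miR-33a", "Dyslipidemia")
  expect_identical(unclass(tab)[c("a", "b", "c", "d", "n")],
                   list(a = 1L, b = 1L, c = 1L, d = 2L, n = 5L))
  expect_error(build_contingency(ann, "miR-9999x", "Dyslipidemia"),
               "unknown miRNA")
  expect_error(build_contingency(ann, "miR-33a", "NotAGroup"),
               "unknown disease")
})

test_that("contingency from text equals counts from ground-truth intent", {
  cfg <- small_config(seed = 21, n_abstracts = 120)
  gen <- generate_corpus(cfg)
  ann <- annotate_corpus(gen$corpus, expand_compounds = TRUE)
  counts <- truth_pair_counts(gen$truth)
  n_m <- sum(vapply(gen$truth$mirnas, function(s) "miR-33a" %in% s,
                    logical(1)))
  n_d <- sum(vapply(gen$truth$diseases, function(s)
    "HDL-Cholesterol" %in% s, logical(1)))
  a <- counts[["miR-33a\rHDL-Cholesterol"]] %||% 0L
  tab <- build_contingency(ann, "miR-33a", "HDL-Cholesterol")
  expect_identical(tab$a, a)
  expect_identical(tab$b, n_m - a)
  expect_identical(tab$c, n_d - a)
  expect_identical(tab$n, 120L)
})

test_that("score_all_pairs flags enriched pairs and skips a = 0 pairs", {
  # 100 abstracts: pair co-occurs in 8, each entity alone in 2 more
  mk <- function(m, d) data.frame(m = m, d = d, stringsAsFactors = FALSE)
  ann <- structure(list(
    abstract_ids = paste0("a", 1:100), n = 100L,
    mirnas = c(rep(list("miR-122"), 10), rep(list(character(0)), 90)),
    diseases = c(rep(list("Triglyceride"), 8), rep(list(character(0)), 2),
                 rep(list("Triglyceride"), 2), rep(list(character(0)), 88)),
    spans = NULL, known_mirnas = "miR-122", known_groups = "Triglyceride",
    expand_compounds = FALSE), class = "annotated_corpus")
  recs <- score_all_pairs(ann)
  expect_identical(nrow(recs), 1L)
  expect_identical(recs$paper_count, 8L)
  expect_equal(recs$p_value, fisher_enum_oracle(8, 2, 2, 88),
               tolerance = 1e-10)
  expect_true(recs$significant)
  # a pair that never co-occurs is not reported
  ann$diseases <- c(rep(list(character(0)), 10),
                    rep(list("Triglyceride"), 5),
                    rep(list(character(0)), 85))
  recs2 <- score_all_pairs(ann)
  expect_identical(nrow(recs2), 0L)
})

test_that("top_k sorts by p, then paper count, then name, and truncates", {
  recs <- data.frame(
    mirna = c("miR-5", "miR-1", "miR-3", "miR-2", "miR-4"),
    disease = "LDL",
    paper_count = c(1L, 2L, 5L, 5L, 9L),
    p_value = c(0.04, 0.01, 0.02, 0.02, 0.02),
    stringsAsFactors = FALSE)
  out <- top_k(recs, k = 4)
  expect_identical(out$mirna, c("miR-1", "miR-4", "miR-2", "miR-3"))
  expect_identical(out$rank, 1:4)
  out_all <- top_k(recs, k = 99)
  expect_identical(nrow(out_all), 5L)
  # all-distinct p-values: pure ascending sort
  recs2 <- data.frame(mirna = paste0("miR-", 1:4), disease = "LDL",
                      paper_count = 1L, p_value = c(0.4, 0.1, 0.3, 0.2),
                      stringsAsFactors = FALSE)
  expect_identical(top_k(recs2, 4)$p_value, sort(recs2$p_value))
  expect_error(top_k(recs, k = 0), "positive")
})

test_that("association TSV uses ranked table schema and notation", {
  recs <- data.frame(mirna = "miR-33a", disease = "HDL-Cholesterol",
                     paper_count = 7L, p_value = 3.4e-5, significant = TRUE,
                     stringsAsFactors = FALSE)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_associations(recs, tf)
  got <- read.delim(tf, stringsAsFactors = FALSE,
                    colClasses = "character")
  expect_identical(names(got), c("rank", "miRNA", "disease_group",
                                 "paper_count", "p_value", "significant"))
  expect_identical(got$p_value, "3.40E-05")
})
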