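# The synthetic corpus / RegIN / GO generators: planted structure, edge
# cases and determinism.

test_that("configuration is validated", {
  expect_error(corpus_config(10, "miR-33a", "LDL", p_comention = 1.5),
               "probabilities")
  expect_error(corpus_config(10, "miR-33a", "LDL", p_background_mirna = -1),
               "probabilities")
  expect_error(corpus_config(10, "not-a-mirna", "LDL"), "absent")
  expect_error(corpus_config(10, "miR-33a", "LDL",
                             planted_pairs = list(c("miR-1", "LDL"))),
               "planted pair")
})

test_that("empty corpus case", {
  cfg <- corpus_config(0, "miR-33a", "LDL", seed = 1)
  gen <- generate_corpus(cfg)
  expect_identical(nrow(gen$corpus), 0L)
  expect_identical(length(gen$truth$mirnas), 0L)
})

test_that("forced probabilities give complete co-mention and nothing else", {
  cfg <- corpus_config(10, c("miR-33a", "miR-122"),
                       c("HDL-Cholesterol", "Triglyceride"),
                       planted_pairs = list(c("miR-33a", "HDL-Cholesterol")),
                       p_comention = 1, p_background_mirna = 0,
                       p_background_disease = 0, seed = 4)
  gen <- generate_corpus(cfg)
  ann <- annotate_corpus(gen$corpus, expand_compounds = TRUE)
  for (i in 1:10) {
    expect_identical(ann$mirnas[[i]], "miR-33a")
    expect_identical(ann$diseases[[i]], "HDL-Cholesterol")
  }
})

test_that("planted pairs co-mention above all non-planted pairs", {
  cfg <- corpus_config(
    500, c("miR-33a", "miR-122", "miR-15", "miR-16", "miR-221"),
    c("HDL-Cholesterol", "Triglyceride", "Dyslipidemia"),
    planted_pairs = list(c("miR-33a", "HDL-Cholesterol"),
                         c("miR-122", "Triglyceride")),
    p_comention = 0.8, p_background_mirna = 0.05,
    p_background_disease = 0.05, seed = 1)
  gen <- generate_corpus(cfg)
  counts <- truth_pair_counts(gen$truth)
  planted_keys <- c("miR-33a\rHDL-Cholesterol", "miR-122\rTriglyceride")
  planted_min <- min(unlist(counts[planted_keys]))
  others <- unlist(counts[setdiff(names(counts), planted_keys)])
  expect_gt(planted_min, max(c(others, 0)))
})

test_that("every planted pair appears at least once", {
  for (seed in 1:5) {
    cfg <- small_config(seed, n_abstracts = 20, p_comention = 0.3)
    gen <- generate_corpus(cfg)
    counts <- truth_pair_counts(gen$truth)
    expect_gte(counts[["miR-33a\rHDL-Cholesterol"]] %||% 0L, 1L)
  }
})

test_that("generation is deterministic and seed-sensitive", {
  cfg <- small_config(seed = 13, n_abstracts = 30)
  expect_identical(generate_corpus(cfg), generate_corpus(cfg))
  cfg2 <- small_config(seed = 14, n_abstracts = 30)
  expect_false(identical(generate_corpus(cfg)$corpus$text,
                         generate_corpus(cfg2)$corpus$text))
})

test_that("corpus JSONL round-trips", {
  gen <- generate_corpus(small_config(seed = 6, n_abstracts = 15))
  tf <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(gen$corpus, tf)
  expect_identical(read_corpus(tf), gen$corpus)
  # empty corpus writes a valid empty file
  tf2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(gen$corpus[0, ], tf2)
  expect_identical(nrow(read_corpus(tf2)), 0L)
})

test_that("RegIN generation follows the overlap specification exactly", {
  regs <- generate_regins(3, c("M1", "M2"),
                          overlap_spec = list(g1 = c("A", "B", "C")),
                          seed = 1)
  expect_true(all(vapply(regs, function(r) "g1" %in% r$edges$target,
                         logical(1))))
  empty <- generate_regins(3, "M1", overlap_spec = stats::setNames(
    list(), character(0)), seed = 1)
  expect_identical(vapply(empty, function(r) nrow(r$edges), 0L),
                   c(0L, 0L, 0L))
  regs2 <- generate_regins(3, c("M1", "M2"),
                           overlap_spec = list(g1 = c("A", "B", "C"),
                                               g2 = c("A", "B"),
                                               g3 = "C"), seed = 2)
  expect_identical(vapply(regs2, function(r) nrow(r$edges), 0L),
                   c(2L, 2L, 2L))
  expect_error(generate_regins(3, "M1",
                               overlap_spec = list(g1 = character(0)),
                               seed = 1), "empty source set")
  # determinism
  expect_identical(generate_regins(3, c("M1", "M2"), n_targets = 8,
                                   seed = 9),
                   generate_regins(3, c("M1", "M2"), n_targets = 8,
                                   seed = 9))
})

test_that("GO fixture: root-only DAG annotates every gene after propagation", {
  fx <- generate_go_fixture(6, 1, seed = 2)
  pann <- propagate(fx$annotations, fx$dag)
  expect_setequal(unique(pann$gene), fx$genes)
  expect_identical(unique(pann$term), "GO:0000001")
})

test_that("GO fixture: designated term annotates exactly the planted genes", {
  fx <- generate_go_fixture(12, 8, enriched_term = 8,
                            enriched_genes = sprintf("G%03d", 1:5), seed = 3)
  direct <- fx$annotations$gene[fx$annotations$term == fx$enriched_term]
  expect_setequal(direct, sprintf("G%03d", 1:5))
  # enriched term = all genes makes every query completely unsurprising
  fx2 <- generate_go_fixture(8, 3, enriched_term = 3,
                             enriched_genes = sprintf("G%03d", 1:8),
                             seed = 4)
  pann2 <- propagate(fx2$annotations, fx2$dag)
  p <- hypergeom_term_p(fx2$enriched_term, sprintf("G%03d", c(2, 5, 7)),
                        pann2, universe = fx2$genes)
  expect_equal(p, 1)
})

test_that("GO fixture enrichment matches exhaustive enumeration", {
  # 10 genes, term annotating 4, query of 5 containing all 4: 6/252
  fx <- generate_go_fixture(10, 5, enriched_term = 5,
                            enriched_genes = sprintf("G%03d", 1:4), seed = 5)
  pann <- propagate(fx$annotations, fx$dag)
  p <- hypergeom_term_p(fx$enriched_term, sprintf("G%03d", c(1:4, 8)), pann,
                        universe = fx$genes)
  expect_equal(p, 6 / 252, tolerance = 1e-12)
  expect_equal(p, hyper_enum_oracle(4, 10, 4, 5), tolerance = 1e-12)
})
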