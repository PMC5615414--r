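# RegIN loading, seed extension, overlap thresholding, hide/show and
# accounting.

toy_regins <- function() {
  list(regin("A", data.frame(regulator = c("m1", "m1"),
                             target = c("g1", "g2"))),
       regin("B", data.frame(regulator = "m1", target = "g1")),
       regin("C", data.frame(regulator = c("m1", "m2"),
                             target = c("g1", "g3"))))
}

test_that("RegIN TSV loading deduplicates and handles empty files", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  file.create(tf)
  expect_identical(nrow(load_regin(tf, "tsv")$edges), 0L)
  writeLines(c("regulator\ttarget\tsource",
               "m1\tg1\tA", "m1\tg1\tA", "m1\tg2\tA"), tf)
  rg <- load_regin(tf, "tsv")
  expect_identical(nrow(rg$edges), 2L)
  expect_identical(rg$source_name, "A")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("x\ty", "1\t2"), bad)
  expect_error(load_regin(bad, "tsv"), "regulator/target")
})

test_that("XGMML round-trips reproduce the generator's edge set", {
  regs <- generate_regins(3, c("M1", "M2", "M3"), n_targets = 10, seed = 5)
  for (rg in regs) {
    tf <- withr::local_tempfile(fileext = ".xgmml")
    write_regin(rg, tf, "xgmml")
    back <- load_regin(tf, "xgmml")
    expect_identical(back$source_name, rg$source_name)
    o1 <- rg$edges[order(rg$edges$regulator, rg$edges$target), ]
    o2 <- back$edges[order(back$edges$regulator, back$edges$target), ]
    rownames(o1) <- rownames(o2) <- NULL
    expect_identical(o2, o1)
  }
  expect_error(load_regin(withr::local_tempfile(fileext = ".xgmml"),
                          "xgmml"), "malformed|cannot|error")
})

test_that("extension annotates edges with their supporting sources", {
  ext <- extend_network(c("m1", "m2"), toy_regins())
  expect_setequal(setdiff(unique(c(ext$edges$regulator, ext$edges$target)),
                          ext$seeds), c("g1", "g2", "g3"))
  e <- ext$edges
  expect_identical(e$support_sources[e$target == "g1"], "A|B|C")
  expect_identical(e$support_count[e$target == "g1"], 3L)
  expect_identical(e$support_sources[e$target == "g2"], "A")
  expect_identical(e$support_sources[e$target == "g3"], "C")
  # seeds absent from every RegIN: unchanged network
  ext2 <- extend_network("m999", toy_regins())
  expect_identical(nrow(ext2$edges), 0L)
  expect_identical(ext2$seeds, "m999")
})

test_that("support sets equal the generator's overlap specification", {
  spec <- list(g1 = c("A", "B", "C"), g2 = c("A", "C"), g3 = "B",
               g4 = c("B", "C"))
  regs <- generate_regins(3, c("M1", "M2"), overlap_spec = spec, seed = 3)
  ext <- extend_network(c("M1", "M2"), regs)
  for (g in names(spec)) {
    got <- strsplit(ext$edges$support_sources[ext$edges$target == g],
                    "|", fixed = TRUE)[[1]]
    expect_setequal(got, spec[[g]])
  }
})

test_that("overlap threshold filters by support size", {
  ext <- extend_network(c("m1", "m2"), toy_regins())
  expect_identical(overlap_threshold(ext, 1)$edges, ext$edges)
  th <- overlap_threshold(ext, 3)
  expect_identical(th$edges$target, "g1")
  expect_error(overlap_threshold(ext, 0), ">= 1")
})

test_that("threshold composition and monotonicity laws hold", {
  set.seed(17)
  for (rep in 1:20) {
    spec <- stats::setNames(lapply(1:12, function(i)
      sample(c("A", "B", "C"), sample.int(3, 1))),
      sprintf("g%02d", 1:12))
    regs <- generate_regins(3, c("M1", "M2", "M3"), overlap_spec = spec,
                            seed = rep)
    ext <- extend_network(c("M1", "M2", "M3"), regs)
    for (k1 in 1:3) for (k2 in 1:3) {
      expect_identical(overlap_threshold(overlap_threshold(ext, k1), k2),
                       overlap_threshold(ext, max(k1, k2)))
    }
    sizes <- vapply(1:3, function(k) nrow(overlap_threshold(ext, k)$edges),
                    0L)
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("threshold at k = |sources| equals per-seed intersection", {
  set.seed(23)
  spec <- stats::setNames(lapply(1:15, function(i)
    sample(c("A", "B", "C"), sample.int(3, 1))), sprintf("g%02d", 1:15))
  regs <- generate_regins(3, c("M1", "M2"), overlap_spec = spec, seed = 2)
  ext <- extend_network(c("M1", "M2"), regs)
  th <- overlap_threshold(ext, 3)
  for (s in c("M1", "M2")) {
    per_source <- lapply(regs, function(rg)
      rg$edges$target[rg$edges$regulator == s])
    expect_setequal(th$edges$target[th$edges$regulator == s],
                    Reduce(intersect, per_source))
  }
})

test_that("hide/show is non-destructive and recomputes support", {
  ext <- extend_network(c("m1", "m2"), toy_regins())
  expect_identical(hide_sources(ext, character(0)), ext)
  h <- hide_sources(ext, "B")
  ve <- mirlipidnet:::visible_edges(h)
  expect_identical(ve$visible_sources[ve$target == "g1"], "A|C")
  all_hidden <- hide_sources(ext, c("A", "B", "C"))
  expect_identical(nrow(mirlipidnet:::visible_edges(all_hidden)), 0L)
  expect_identical(mirlipidnet:::added_nodes(all_hidden), character(0))
  expect_identical(hide_sources(h, character(0)), ext)
  expect_error(hide_sources(ext, "Z"), "unknown source")
})

test_that("accounting reports nodes, per-source edges and defined targets", {
  ext <- extend_network(c("m1", "m2"), toy_regins())
  acc <- mti_accounting(ext)
  expect_identical(acc$totals$nodes, 5L)  # 2 seeds + g1 g2 g3
  expect_identical(acc$totals$edges, 3L)
  expect_identical(acc$per_source$edges[acc$per_source$source == "A"], 2L)
  expect_identical(acc$per_source$edges[acc$per_source$source == "B"], 1L)
  expect_identical(acc$per_source$edges[acc$per_source$source == "C"], 2L)
  th <- overlap_threshold(ext, 3)
  expect_identical(mti_accounting(th)$total_defined, 1L)
  # per-set rows sum to the grand total when the sets' targets are disjoint
  acc2 <- mti_accounting(ext, list(s1 = "m1", s2 = "m2"))
  expect_identical(acc2$per_set$defined_targets, c(2L, 1L))
  expect_identical(sum(acc2$per_set$defined_targets), acc2$total_defined)
})
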