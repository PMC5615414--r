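# End-to-end orchestration: simulate a fixture directory, then run the five
# mining stages over files, writing one artifact per stage plus a manifest
# of content hashes. Reruns with the same inputs and seed are
# byte-identical.

#' Pipeline configuration
#'
#' @param corpus Path to a line-delimited JSON corpus.
#' @param mirna_lexicon,disease_groups Paths to the lexicon TSVs.
#' @param regins Character vector of RegIN file paths.
#' @param regin_dialect `"tsv"` or `"xgmml"`.
#' @param obo,annotations Paths to the GO ontology and gene-to-term TSV.
#' @param out_dir Output directory (created if missing).
#' @param alpha Significance level for association scoring.
#' @param top_k Number of top associations carried into network extension.
#' @param overlap_k Overlap threshold (minimum supporting sources).
#' @param seed_sets Number of sets the top miRNAs are partitioned into for
#'   the accounting table.
#' @param expand_compounds Passed to [annotate_corpus()].
#' @param seed Integer seed (the pipeline stages themselves are
#'   deterministic; the seed is recorded in the manifest for provenance).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(corpus, mirna_lexicon = NULL,
                            disease_groups = NULL, regins = character(0),
                            regin_dialect = c("tsv", "xgmml"),
                            obo = NULL, annotations = NULL,
                            out_dir = tempfile("mirlipidnet_run_"),
                            alpha = 0.05, top_k = 20, overlap_k = 3,
                            seed_sets = 4, expand_compounds = FALSE,
                            seed = 1L) {
  regin_dialect <- match.arg(regin_dialect)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("configuration error: alpha must lie in (0, 1)", call. = FALSE)
  }
  if (overlap_k < 1) {
    stop("configuration error: overlap_k must be >= 1", call. = FALSE)
  }
  for (p in c(corpus, mirna_lexicon, disease_groups, regins, obo,
              annotations)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("configuration error: missing input file ", p, call. = FALSE)
    }
  }
  structure(list(corpus = corpus, mirna_lexicon = mirna_lexicon,
                 disease_groups = disease_groups, regins = regins,
                 regin_dialect = regin_dialect, obo = obo,
                 annotations = annotations, out_dir = out_dir,
                 alpha = alpha, top_k = top_k, overlap_k = overlap_k,
                 seed_sets = seed_sets, expand_compounds = expand_compounds,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a key = value text file
#'
#' Lines of the form `key = value` (or `key: value`); `regins` may be a
#' comma-separated list. Relative paths are resolved against the file's
#' directory.
#'
#' @param path Path to the configuration file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*[:=]\\s*(.*?)\\s*$",
                                  lines))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  cfg <- stats::setNames(as.list(vals), keys)
  base <- dirname(path)
  rel <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  pipeline_config(
    corpus = rel(cfg$corpus),
    mirna_lexicon = rel(cfg$mirna_lexicon),
    disease_groups = rel(cfg$disease_groups),
    regins = if (is.null(cfg$regins)) character(0) else
      rel(trimws(strsplit(cfg$regins, ",")[[1]])),
    regin_dialect = cfg$regin_dialect %||% "tsv",
    obo = rel(cfg$obo), annotations = rel(cfg$annotations),
    out_dir = cfg$out_dir %||% tempfile("mirlipidnet_run_"),
    alpha = num(cfg$alpha, 0.05), top_k = num(cfg$top_k, 20),
    overlap_k = num(cfg$overlap_k, 3),
    seed_sets = num(cfg$seed_sets, 4),
    expand_compounds = isTRUE(as.logical(cfg$expand_compounds %||% "FALSE")),
    seed = num(cfg$seed, 1))
}

default_fixture_config <- function(seed = 1L) {
  lex <- default_mirna_lexicon()
  corpus_config(
    n_abstracts = 300,
    mirna_ids = c("miR-33a", "miR-33b", "miR-122", "miR-144", "miR-223",
                  "miR-155", "miR-103", "miR-375", "miR-126", "miR-30c",
                  "miR-15", "miR-16"),
    disease_groups = c("Dyslipidemia", "Hyperlipidemia", "HDL-Cholesterol",
                       "LDL", "Triglyceride"),
    planted_pairs = list(c("miR-33a", "HDL-Cholesterol"),
                         c("miR-122", "Triglyceride"),
                         c("miR-155", "Hyperlipidemia")),
    p_comention = 0.6, p_background_mirna = 0.05,
    p_background_disease = 0.05, seed = seed, lexicon = lex)
}

#' Write the default synthetic fixture directory
#'
#' Generates and writes, under `dir`: the corpus (`corpus.jsonl`), the two
#' lexicon TSVs, three RegINs (both XGMML and TSV dialects), the GO ontology
#' (`go.obo`) and annotation TSV, and a `ground_truth.json` record of the
#' planted structure. Regulators in the RegINs are the accessions of the
#' configured miRNAs; a block of targets is supported by all three sources
#' so overlap thresholding at 3 keeps them, and the designated enriched GO
#' term annotates a subset of that block.
#'
#' @param dir Output directory.
#' @param config A [corpus_config()]; default emulates the stated study
#'   world (300 abstracts, planted pairs at co-mention 0.6, backgrounds
#'   0.05).
#' @param seed Integer seed used for every random component.
#' @return Invisibly, a manifest data frame (`file`, `md5`).
#' @export
simulate_fixture <- function(dir, config = NULL, seed = 1L) {
  if (is.null(config)) config <- default_fixture_config(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_corpus(config)
  write_corpus(gen$corpus, file.path(dir, "corpus.jsonl"))
  write_tsv_file(config$lexicon, file.path(dir, "mirna_lexicon.tsv"))
  write_tsv_file(config$groups, file.path(dir, "disease_groups.tsv"))

  accs <- mirna_to_accession(config$mirna_ids, config$lexicon)
  n_targets <- 40L
  targets <- sprintf("TG%03d", seq_len(n_targets))
  srcs <- c("miRTarBaseSyn", "MicroCosmSyn", "TargetScanSyn")
  overlap <- with_seed(seed + 1L, {
    spec <- lapply(seq_len(n_targets), function(i) {
      if (i <= 12L) srcs else sample(srcs, sample.int(2L, 1L))
    })
    stats::setNames(spec, targets)
  })
  regs <- generate_regins(3, accs, overlap_spec = overlap, seed = seed + 2L,
                          source_names = srcs)
  for (rg in regs) {
    write_regin(rg, file.path(dir, paste0("regin_", rg$source_name, ".tsv")),
                "tsv")
    write_regin(rg, file.path(dir, paste0("regin_", rg$source_name,
                                          ".xgmml")), "xgmml")
  }
  go <- generate_go_fixture(n_genes = n_targets, n_terms = 15,
                            enriched_term = 15, genes = targets,
                            enriched_genes = targets[1:8], seed = seed + 3L,
                            p_annot = 0.2)
  write_obo(go$dag, file.path(dir, "go.obo"))
  write_annotations(go$annotations, file.path(dir, "annotations.tsv"))
  truth <- list(planted_pairs = lapply(gen$truth$planted_pairs, as.list),
                forced_pairs = lapply(gen$truth$forced_pairs, as.list),
                enriched_term = go$enriched_term,
                enriched_genes = targets[1:8],
                all_source_targets = targets[1:12],
                seed = seed)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "ground_truth.json"), useBytes = TRUE)
  files <- sort(list.files(dir), method = "radix")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))),
                         stringsAsFactors = FALSE)
  write_tsv_file(manifest, file.path(dir, "fixture_manifest.tsv"))
  invisible(manifest)
}

stage_fail <- function(stage, e) {
  stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
       call. = FALSE)
}

#' Run the full mining pipeline
#'
#' Executes, in order: entity recognition (mentions TSV), association
#' scoring (ranked associations TSV), bipartite network construction
#' (GraphML/SIF/XGMML/edge TSV), RegIN extension with overlap thresholding
#' (extended network + accounting TSVs), and GO overrepresentation of the
#' post-threshold target genes (enrichment TSV). A manifest listing every
#' artifact with its MD5 content hash is written last; a rerun with the same
#' inputs and seed is byte-identical.
#'
#' @param config A [pipeline_config()] or path to a key = value config file.
#' @return Invisibly, a list with the manifest data frame, the association
#'   records, the extended network and the enrichment table.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- function(...) message("[mirlipidnet] ", ...)

  corpus <- tryCatch(read_corpus(config$corpus),
                     error = function(e) stage_fail("read_corpus", e))
  lexicon <- if (is.null(config$mirna_lexicon)) default_mirna_lexicon() else
    tryCatch(load_mirna_lexicon(config$mirna_lexicon),
             error = function(e) stage_fail("load_lexicon", e))
  groups <- if (is.null(config$disease_groups)) default_disease_groups() else
    tryCatch(load_disease_groups(config$disease_groups),
             error = function(e) stage_fail("load_lexicon", e))

  # stage 1: entity recognition
  annotated <- tryCatch(
    annotate_corpus(corpus, lexicon, groups,
                    expand_compounds = config$expand_compounds),
    error = function(e) stage_fail("mine", e))
  write_mentions(annotated, file.path(out, "mentions.tsv"))
  log("mine: ", annotated$n, " abstracts, ", nrow(annotated$spans),
      " miRNA mention spans")

  # stage 2: association scoring
  if (annotated$n == 0L) {
    stop("pipeline stage 'score' failed: empty corpus", call. = FALSE)
  }
  records <- tryCatch(score_all_pairs(annotated, alpha = config$alpha),
                      error = function(e) stage_fail("score", e))
  ranked <- top_k(records, k = max(config$top_k, nrow(records)))
  write_associations(ranked, file.path(out, "associations.tsv"))
  log("score: ", nrow(records), " pairs, ", sum(records$significant),
      " significant at alpha = ", config$alpha)

  # stage 3: bipartite network
  net <- tryCatch(build_bipartite(records),
                  error = function(e) stage_fail("network", e))
  export_network(net, "graphml", file.path(out, "network.graphml"))
  export_network(net, "sif", file.path(out, "network.sif"))
  export_network(net, "xgmml", file.path(out, "network.xgmml"),
                 label = "mirna-disease-bipartite")
  export_network(net, "edge_tsv", file.path(out, "network_edges.tsv"))
  log("network: ", igraph::vcount(net), " nodes, ", igraph::ecount(net),
      " edges")

  extnet <- NULL
  enr <- NULL
  if (length(config$regins)) {
    # stage 4: RegIN extension + overlap threshold
    regins <- tryCatch(
      lapply(config$regins, load_regin, dialect = config$regin_dialect),
      error = function(e) stage_fail("extend", e))
    top <- top_k(records, k = min(config$top_k, nrow(records)))
    seeds <- mirna_to_accession(top$mirna, lexicon)
    extnet <- tryCatch(extend_network(seeds, regins, "targets"),
                       error = function(e) stage_fail("extend", e))
    thresholded <- overlap_threshold(extnet, config$overlap_k)
    n_sets <- max(1L, min(config$seed_sets, length(seeds)))
    sets <- split(seeds, rep(seq_len(n_sets), length.out = length(seeds)))
    names(sets) <- sprintf("set-%d", seq_len(n_sets))
    acc_pre <- mti_accounting(extnet, sets)
    acc_post <- mti_accounting(thresholded, sets)
    export_network(extended_to_igraph(thresholded), "graphml",
                   file.path(out, "extended.graphml"))
    export_network(extended_to_igraph(thresholded), "xgmml",
                   file.path(out, "extended.xgmml"), label = "extended")
    write_tsv_file(acc_pre$per_source,
                   file.path(out, "extension_per_source.tsv"))
    per_set <- acc_post$per_set
    per_set <- rbind(per_set,
                     data.frame(set = "Total", seeds = sum(per_set$seeds),
                                defined_targets = sum(per_set$defined_targets),
                                stringsAsFactors = FALSE))
    write_tsv_file(per_set, file.path(out, "defined_targets.tsv"))
    log("extend: ", nrow(extnet$edges), " edges pre-threshold, ",
        nrow(thresholded$edges), " at k >= ", config$overlap_k)

    # stage 5: GO enrichment of the post-threshold targets
    if (!is.null(config$obo) && !is.null(config$annotations)) {
      dag <- tryCatch(parse_obo(config$obo),
                      error = function(e) stage_fail("enrich", e))
      ann <- tryCatch(read_annotations(config$annotations),
                      error = function(e) stage_fail("enrich", e))
      query <- added_nodes(thresholded)
      query <- intersect(query, unique(ann$gene))
      if (length(query)) {
        enr <- tryCatch(enrich(query, ann, dag, alpha = config$alpha),
                        error = function(e) stage_fail("enrich", e))
        write_enrichment(enr, file.path(out, "enrichment.tsv"))
        log("enrich: ", nrow(enr), " terms tested, ", sum(enr$significant),
            " significant")
      } else {
        log("enrich: no annotated post-threshold targets; stage skipped")
      }
    }
  }

  files <- sort(setdiff(list.files(out), "manifest.tsv"), method = "radix")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out, files))),
                         seed = config$seed, stringsAsFactors = FALSE)
  write_tsv_file(manifest, file.path(out, "manifest.tsv"))
  log("done: ", nrow(manifest), " artifacts in ", out)
  invisible(list(manifest = manifest, associations = records,
                 extended = extnet, enrichment = enr, out_dir = out))
}

#' Configuration for the packaged default fixture
#'
#' Convenience wrapper building a [pipeline_config()] pointing at a fixture
#' directory written by [simulate_fixture()].
#'
#' @param dir Fixture directory.
#' @param out_dir Output directory for [run_pipeline()].
#' @param ... Overrides passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
fixture_pipeline_config <- function(dir, out_dir = tempfile("run_"), ...) {
  regins <- sort(list.files(dir, pattern = "^regin_.*\\.xgmml$",
                            full.names = TRUE), method = "radix")
  pipeline_config(corpus = file.path(dir, "corpus.jsonl"),
                  mirna_lexicon = file.path(dir, "mirna_lexicon.tsv"),
                  disease_groups = file.path(dir, "disease_groups.tsv"),
                  regins = regins, regin_dialect = "xgmml",
                  obo = file.path(dir, "go.obo"),
                  annotations = file.path(dir, "annotations.tsv"),
                  out_dir = out_dir, ...)
}
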