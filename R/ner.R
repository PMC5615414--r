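# Dictionary + pattern recognition of miRNA and disease mentions.
#
# The recognizer is deterministic: a generic pattern covers the nomenclature
# variant families (stem spellings MicroRNA/MiRNA/miR, species prefix
# "hsa-", precursor prefix "pre-", loci/variant suffix "miR-1a-1", the
# lin-4/let-7 names, and slash/ampersand compounds "miR-221/222",
# "miR-15 & -16"), and lexicon aliases are added as literal alternatives.

mirna_pattern <- function(lexicon = NULL) {
  pre <- "(?:pre-)?"
  sp <- "(?:[a-z]{3}-)?"
  stem <- "(?:micro-?rna|mirna|mir)"
  unit <- "\\d+[a-z]{0,3}(?:-\\d+)*"
  comp <- "(?:\\s*[/&]\\s*-?(?:\\d+[a-z]{0,3}(?:-\\d+)*|[a-z]{1,3}))*"
  mir <- paste0(pre, sp, pre, stem, "-?", unit, comp)
  letlin <- paste0(pre, sp, "(?:let-7[a-z]?(?:-\\d+)*|lin-4)")
  alts <- c(mir, letlin)
  if (!is.null(lexicon) && nrow(lexicon)) {
    lits <- unlist(strsplit(lexicon$aliases, "|", fixed = TRUE))
    lits <- unique(c(lexicon$canonical_id, lits))
    lits <- lits[nzchar(lits)]
    lits <- lits[order(-nchar(lits))]
    alts <- c(alts, gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", lits))
  }
  paste0("(?<![\\w-])(?:", paste(alts, collapse = "|"), ")(?![\\w-])")
}

#' Normalize a raw miRNA mention to canonical ids
#'
#' Strips species ("hsa-") and precursor ("pre-") prefixes, case-folds the
#' stem spelling (MicroRNA/MiRNA/miRNA/miR) to the canonical "miR-" (or
#' "let-"/"lin-"), expands slash and ampersand compounds into their member
#' ids, and preserves loci/variant suffixes ("miR-1a-1").
#'
#' @param matched_text A raw mention as matched in text.
#' @return Character vector of canonical ids with attributes `precursor`
#'   (logical) and `compound` (the canonical compound key such as
#'   `"miR-33a/b"`, or `NA` for simple mentions).
#' @examples
#' normalize_mirna_mention("hsa-miR-1")      # "miR-1"
#' normalize_mirna_mention("miR-221/222")    # "miR-221" "miR-222"
#' normalize_mirna_mention("miR-15 & -16")   # "miR-15" "miR-16"
#' @export
normalize_mirna_mention <- function(matched_text) {
  x <- tolower(ascii_dashes(trimws(matched_text)))
  precursor <- FALSE
  repeat {
    if (startsWith(x, "pre-")) {
      x <- substring(x, 5L)
      precursor <- TRUE
    } else if (grepl("^[a-z]{3}-(?=(micro-?rna|mirna|mir|let|lin)[-0-9])",
                     x, perl = TRUE) &&
               !grepl("^(mir|let|lin)[-0-9]", x)) {
      x <- sub("^[a-z]{3}-", "", x)
    } else break
  }
  parts <- strsplit(x, "\\s*[/&]\\s*-?\\s*", perl = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  m <- regmatches(parts[1],
                  regexec("^(micro-?rna|mirna|mir|let|lin)-?(.+)$", parts[1],
                          perl = TRUE))[[1]]
  if (length(m) == 0L) {
    out <- character(0)
    attr(out, "precursor") <- precursor
    attr(out, "compound") <- NA_character_
    return(out)
  }
  cstem <- if (m[2] %in% c("let", "lin")) m[2] else "miR"
  ids <- paste0(cstem, "-", m[3])
  vary <- character(0)
  for (p in parts[-1]) {
    if (grepl("^\\d", p)) {
      ids <- c(ids, paste0(cstem, "-", p))
    } else {
      # letter suffix swap: miR-33a / b -> miR-33b
      prev <- ids[length(ids)]
      ids <- c(ids, sub("^(.*?\\d)([a-z]*)([-0-9]*)$", paste0("\\1", p, "\\3"),
                        prev, perl = TRUE))
    }
    vary <- c(vary, p)
  }
  compound <- if (length(ids) > 1L) {
    paste0(ids[1], "/", paste(vary, collapse = "/"))
  } else NA_character_
  attr(ids, "precursor") <- precursor
  attr(ids, "compound") <- compound
  ids
}

# Vectorized recognition over full texts; returns a span data frame.
# Offsets are 0-based half-open into the supplied text.
recognize_mirnas_text <- function(texts, ids, lexicon) {
  pat <- mirna_pattern(lexicon)
  amap <- mirna_alias_map(lexicon)
  canon_lc <- tolower(lexicon$canonical_id)
  clean <- ascii_dashes(texts)
  hits <- gregexpr(pat, clean, perl = TRUE, ignore.case = TRUE)
  rows <- vector("list", length(texts))
  for (i in seq_along(texts)) {
    st <- hits[[i]]
    if (st[1] == -1L) next
    len <- attr(st, "match.length")
    matched <- substring(texts[i], st, st + len - 1L)
    norm <- character(length(st))
    comp <- character(length(st))
    prec <- logical(length(st))
    unnorm <- logical(length(st))
    for (j in seq_along(st)) {
      raw <- matched[j]
      hit <- amap[tolower(ascii_dashes(raw))]
      if (!is.na(hit)) {
        members <- unname(hit)
        comp[j] <- NA_character_
      } else {
        nm <- normalize_mirna_mention(raw)
        prec[j] <- attr(nm, "precursor")
        comp[j] <- attr(nm, "compound")
        mapped <- amap[tolower(nm)]
        miss <- is.na(mapped)
        mapped[miss] <- nm[miss]
        members <- unname(mapped)
        unnorm[j] <- any(!(tolower(members) %in% canon_lc))
      }
      norm[j] <- paste(members, collapse = "|")
    }
    rows[[i]] <- data.frame(
      start = st - 1L, end = st - 1L + len, matched_text = matched,
      normalized = norm, compound = comp, precursor = prec,
      unnormalized = unnorm, stringsAsFactors = FALSE)
  }
  idx <- which(!vapply(rows, is.null, logical(1)))
  if (!length(idx)) {
    return(data.frame(abstract_id = character(0), start = integer(0),
                      end = integer(0), matched_text = character(0),
                      normalized = character(0), compound = character(0),
                      precursor = logical(0), unnormalized = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows[idx])
  out <- cbind(abstract_id = rep(ids[idx],
                                 vapply(rows[idx], nrow, 0L)), out)
  rownames(out) <- NULL
  out
}

abstract_text <- function(record) {
  body <- record$text %||% record$body
  paste(record$title, body, sep = "\n")
}

#' Recognize miRNA mentions in one abstract
#'
#' Finds all maximal, non-overlapping matches of lexicon aliases and the
#' nomenclature pattern families in `title + "\n" + body`, case-insensitive
#' and word-boundary anchored, with en-dashes treated as hyphens. Matches
#' whose normalized ids are absent from the lexicon are flagged
#' `unnormalized` rather than dropped.
#'
#' @param record A list or one-row data frame with fields `id`, `title` and
#'   `text` (or `body`).
#' @param lexicon A miRNA lexicon data frame.
#' @return A data frame of mention spans: `abstract_id`, `start`, `end`
#'   (0-based, half-open), `matched_text`, `normalized` (pipe-separated
#'   canonical ids), `compound` key, `precursor` and `unnormalized` flags.
#' @export
recognize_mirnas <- function(record, lexicon = default_mirna_lexicon()) {
  recognize_mirnas_text(abstract_text(record), record$id %||% "abstract",
                        lexicon)
}

disease_pattern <- function(groups) {
  syn <- unlist(strsplit(groups$synonyms, "|", fixed = TRUE))
  syn <- syn[order(-nchar(syn))]
  lits <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", ascii_dashes(syn))
  paste0("(?<![\\w-])(?:", paste(lits, collapse = "|"), ")(?![\\w-])")
}

disease_synonym_map <- function(groups) {
  syn_lists <- strsplit(groups$synonyms, "|", fixed = TRUE)
  stats::setNames(rep(groups$name, lengths(syn_lists)),
                  tolower(ascii_dashes(unlist(syn_lists))))
}

recognize_diseases_text <- function(texts, groups, spans = FALSE) {
  pat <- disease_pattern(groups)
  smap <- disease_synonym_map(groups)
  clean <- ascii_dashes(texts)
  hits <- gregexpr(pat, clean, perl = TRUE, ignore.case = TRUE)
  lapply(seq_along(texts), function(i) {
    st <- hits[[i]]
    if (st[1] == -1L) {
      if (spans) return(data.frame(start = integer(0), end = integer(0),
                                   matched_text = character(0),
                                   group = character(0),
                                   stringsAsFactors = FALSE))
      return(character(0))
    }
    len <- attr(st, "match.length")
    matched <- substring(texts[i], st, st + len - 1L)
    grp <- unname(smap[tolower(ascii_dashes(matched))])
    if (spans) {
      return(data.frame(start = st - 1L, end = st - 1L + len,
                        matched_text = matched, group = grp,
                        stringsAsFactors = FALSE))
    }
    unique(grp)  # a group counts at most once per abstract
  })
}

#' Recognize disease/identifier groups in one abstract
#'
#' Longest-match-wins across overlapping synonyms (so "HDL-Cholesterol" does
#' not additionally fire "HDL"), case-insensitive, word-boundary anchored;
#' each group is reported at most once per abstract regardless of mention
#' count.
#'
#' @param record A list or one-row data frame with `title` and `text`/`body`.
#' @param groups A disease group table.
#' @return Character vector of group names mentioned in the abstract.
#' @export
recognize_diseases <- function(record, groups = default_disease_groups()) {
  recognize_diseases_text(abstract_text(record), groups)[[1]]
}

#' Annotate a corpus with miRNA and disease mentions
#'
#' Runs both recognizers over every abstract and collects, per abstract, the
#' set of miRNA pair keys and disease groups mentioned. Compound mentions
#' ("miR-33a/b") are kept as their own pair key by default, mirroring
#' published tables that list compound rows alongside their members; set
#' `expand_compounds = TRUE` to credit the member ids instead.
#'
#' @param corpus A data frame with columns `id`, `title`, `text`.
#' @param lexicon miRNA lexicon data frame.
#' @param groups Disease group table.
#' @param expand_compounds Credit compound mentions to their member ids.
#' @return An object of class `annotated_corpus`.
#' @export
annotate_corpus <- function(corpus, lexicon = default_mirna_lexicon(),
                            groups = default_disease_groups(),
                            expand_compounds = FALSE) {
  stopifnot(is.data.frame(corpus),
            all(c("id", "title", "text") %in% names(corpus)))
  if (anyDuplicated(corpus$id)) stop("duplicate abstract ids", call. = FALSE)
  texts <- paste(corpus$title, corpus$text, sep = "\n")
  spans <- recognize_mirnas_text(texts, corpus$id, lexicon)
  dis <- recognize_diseases_text(texts, groups)
  per_abs <- split(spans, factor(spans$abstract_id, levels = corpus$id))
  mirnas <- lapply(per_abs, function(df) {
    if (nrow(df) == 0L) return(character(0))
    keys <- character(0)
    for (j in seq_len(nrow(df))) {
      if (!is.na(df$compound[j]) && !expand_compounds) {
        keys <- c(keys, df$compound[j])
      } else {
        keys <- c(keys, strsplit(df$normalized[j], "|", fixed = TRUE)[[1]])
      }
    }
    unique(keys)
  })
  structure(list(
    abstract_ids = corpus$id,
    n = nrow(corpus),
    mirnas = unname(mirnas),
    diseases = unname(dis),
    spans = spans,
    known_mirnas = unique(c(lexicon$canonical_id,
                            unlist(mirnas, use.names = FALSE))),
    known_groups = groups$name,
    expand_compounds = expand_compounds
  ), class = "annotated_corpus")
}

#' @export
print.annotated_corpus <- function(x, ...) {
  cat("Annotated corpus: ", x$n, " abstracts\n", sep = "")
  cat("  miRNA mention spans: ", nrow(x$spans), "\n", sep = "")
  cat("  abstracts with a miRNA:  ", sum(lengths(x$mirnas) > 0), "\n", sep = "")
  cat("  abstracts with a disease:", sum(lengths(x$diseases) > 0), "\n",
      sep = "")
  invisible(x)
}

#' Write mention spans as TSV
#'
#' @param annotated An `annotated_corpus`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mentions <- function(annotated, path) {
  write_tsv_file(annotated$spans, path)
}
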