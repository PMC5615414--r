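#' Default miRNA lexicon (synthetic stand-in)
#'
#' The original study worked from a curated list of 148 miRNAs that was never
#' deposited, so this packaged default is a synthetic stand-in: it contains
#' every miRNA named in the study's published tables (the miR-33 family,
#' miR-122/122a, miR-17-92, miR-155, lin-4, let-7, ...) topped up with
#' programmatically generated miRBase-style names and accessions to reach the
#' documented lexicon size of at least 148 entries. Accessions are synthetic
#' MIMAT-style strings, not real miRBase records.
#'
#' @return A data frame with columns `canonical_id`, `accession` and
#'   `aliases` (pipe-separated; possibly empty).
#' @export
default_mirna_lexicon <- function() {
  named <- c(
    "miR-33", "miR-33a", "miR-33b", "miR-144", "miR-223", "miR-185",
    "miR-96", "miR-103", "miR-122", "miR-122a", "miR-17-92", "miR-375",
    "miR-200c", "miR-126", "miR-30c", "miR-145", "miR-29b", "miR-155",
    "miR-146a", "miR-27b", "miR-1", "miR-1a-1", "miR-15", "miR-16",
    "miR-221", "miR-222", "lin-4", "let-7", "let-7a", "let-7b"
  )
  used_nums <- unique(sub("^miR-(\\d+).*$", "\\1",
                          grep("^miR-", named, value = TRUE)))
  extra_nums <- setdiff(as.character(1:135), used_nums)
  extras <- paste0("miR-", extra_nums)
  ids <- c(named, extras)
  data.frame(
    canonical_id = ids,
    accession = sprintf("MIMAT%07d", 9000000 + seq_along(ids)),
    aliases = "",
    stringsAsFactors = FALSE
  )
}

#' Default lipid disease and identifier groups
#'
#' The four common lipid diseases (Dyslipidemia, Hyperlipidemia,
#' Hypercholesterolemia, Hypertriglyceridemia) and the seven identifier
#' groups (HDL-Cholesterol, HDL, LDL-Cholesterol, LDL, Triglyceride,
#' Low HDL-C, High LDL-C) used as co-occurrence targets. Synonym overlap
#' between e.g. "HDL" and "HDL-Cholesterol" is resolved downstream by the
#' longest-match-wins rule.
#'
#' @return A data frame with columns `name`, `kind` (`disease` or
#'   `identifier`) and `synonyms` (pipe-separated).
#' @export
default_disease_groups <- function() {
  data.frame(
    name = c("Dyslipidemia", "Hyperlipidemia", "Hypercholesterolemia",
             "Hypertriglyceridemia", "HDL-Cholesterol", "HDL",
             "LDL-Cholesterol", "LDL", "Triglyceride", "Low HDL-C",
             "High LDL-C"),
    kind = c(rep("disease", 4), rep("identifier", 7)),
    synonyms = c(
      "Dyslipidemia|Dyslipidaemia",
      "Hyperlipidemia|Hyperlipidaemia",
      "Hypercholesterolemia|Hypercholesterolaemia",
      "Hypertriglyceridemia|Hypertriglyceridaemia",
      "HDL-Cholesterol|HDL cholesterol|HDL-C",
      "HDL|high-density lipoprotein",
      "LDL-Cholesterol|LDL cholesterol|LDL-C",
      "LDL|low-density lipoprotein",
      "Triglyceride|Triglycerides|TG",
      "Low HDL-C",
      "High LDL-C"
    ),
    stringsAsFactors = FALSE
  )
}

validate_mirna_lexicon <- function(lex) {
  stopifnot(is.data.frame(lex),
            all(c("canonical_id", "accession", "aliases") %in% names(lex)))
  dup <- lex$canonical_id[duplicated(lex$canonical_id)]
  if (length(dup)) {
    stop("duplicate canonical_id in miRNA lexicon: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  alias_lists <- strsplit(lex$aliases, "|", fixed = TRUE)
  all_names <- c(lex$canonical_id, unlist(alias_lists, use.names = FALSE))
  all_names <- all_names[nzchar(all_names)]
  folded <- tolower(all_names)
  dup2 <- unique(all_names[folded %in% folded[duplicated(folded)]])
  if (length(dup2)) {
    stop("alias collision across miRNA lexicon entries: ",
         paste(dup2, collapse = ", "), call. = FALSE)
  }
  lex
}

#' Load a miRNA lexicon from TSV
#'
#' Expects columns `canonical_id`, `accession` and `aliases`
#' (pipe-separated). Duplicate canonical ids or alias strings shared by two
#' entries (after case-folding) are rejected, naming the colliding strings.
#'
#' @param path Path to the TSV file.
#' @return A validated lexicon data frame.
#' @export
load_mirna_lexicon <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(canonical_id = character(0), accession = character(0),
                      aliases = character(0), stringsAsFactors = FALSE))
  }
  lex <- read_tsv_file(path)
  lex$aliases[is.na(lex$aliases)] <- ""
  validate_mirna_lexicon(lex)
}

validate_disease_groups <- function(groups) {
  stopifnot(is.data.frame(groups),
            all(c("name", "kind", "synonyms") %in% names(groups)))
  if (anyDuplicated(groups$name)) {
    stop("duplicate disease group names", call. = FALSE)
  }
  syn <- tolower(unlist(strsplit(groups$synonyms, "|", fixed = TRUE)))
  dup <- unique(syn[duplicated(syn)])
  if (length(dup)) {
    stop("synonym shared across disease groups: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  groups
}

#' Load disease/identifier groups from TSV
#'
#' @param path Path to a TSV with columns `name`, `kind`, `synonyms`
#'   (pipe-separated).
#' @return A validated group table.
#' @export
load_disease_groups <- function(path) {
  validate_disease_groups(read_tsv_file(path))
}

# case-folded alias -> canonical id map (canonical ids map to themselves)
mirna_alias_map <- function(lex) {
  alias_lists <- strsplit(lex$aliases, "|", fixed = TRUE)
  keys <- c(tolower(lex$canonical_id),
            tolower(unlist(alias_lists, use.names = FALSE)))
  vals <- c(lex$canonical_id,
            rep(lex$canonical_id, lengths(alias_lists)))
  keep <- nzchar(keys)
  stats::setNames(vals[keep], keys[keep])
}

#' Map canonical miRNA names to accessions
#'
#' Compound pair keys such as `"miR-33a/b"` are expanded into their member
#' ids before lookup, mirroring the conversion of a top-association list to
#' accessions ahead of regulatory-network extension.
#'
#' @param names Canonical ids or compound keys.
#' @param lexicon A miRNA lexicon data frame.
#' @return Character vector of unique accessions (names absent from the
#'   lexicon are dropped with a warning).
#' @export
mirna_to_accession <- function(names, lexicon) {
  members <- unique(unlist(lapply(names, function(nm) {
    if (grepl("/", nm, fixed = TRUE)) normalize_mirna_mention(nm) else nm
  }), use.names = FALSE))
  idx <- match(tolower(members), tolower(lexicon$canonical_id))
  if (anyNA(idx)) {
    warning("no accession for: ", paste(members[is.na(idx)], collapse = ", "),
            call. = FALSE)
  }
  unique(lexicon$accession[idx[!is.na(idx)]])
}
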