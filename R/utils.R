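# shared internal helpers

# Canonicalize unicode dashes (en/em/minus/figure) to ASCII hyphen before any
# matching; the literature itself mixes them (e.g. "miR-15 & –16").
ascii_dashes <- function(x) {
  gsub("[\u2010\u2011\u2012\u2013\u2014\u2212]", "-", x)
}

# Scientific notation in the style of published tables: "3.40E-05".
format_sci <- function(p) {
  out <- toupper(sprintf("%.2E", p))
  out[is.na(p)] <- NA_character_
  out
}

# C-locale (radix) ordering so tie-breaks are platform independent.
order_c <- function(...) order(..., method = "radix")

read_tsv_file <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "", ...)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

# Run code under a private RNG stream without disturbing the caller's state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
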