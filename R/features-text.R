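#' Load a keyword vocabulary
#'
#' Plain-text format: one keyword (or space-separated phrase) per line;
#' blank lines and `#` comments are ignored; entries are lowercased and
#' deduplicated, and the file order fixes the histogram dimension
#' assignment.
#'
#' @param path vocabulary file path, or `NULL` for the vocabulary bundled
#'   with the package (90 modality-indicative terms; a synthetic
#'   reconstruction, not a published list).
#' @return Character vector of class `vocabulary`.
#' @export
load_vocabulary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vocabulary_synthetic.txt",
                        package = "modfuse", mustWork = TRUE)
  }
  if (!file.exists(path)) {
    stop(sprintf("vocabulary file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(tolower(lines))
  lines <- lines[nzchar(lines)]
  vocab <- lines[!duplicated(lines)]
  if (length(vocab) < 1) stop("vocabulary is empty", call. = FALSE)
  structure(vocab, class = "vocabulary")
}

#' Tokenize a caption
#'
#' Lowercased maximal runs of alphanumeric characters, in order of
#' appearance; punctuation and whitespace split tokens ("T1-weighted" gives
#' "t1", "weighted").
#'
#' @param caption a character string (may be empty or `NA`).
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize_caption <- function(caption) {
  if (length(caption) != 1) stop("caption must be a single string", call. = FALSE)
  if (is.na(caption) || !nzchar(caption)) return(character(0))
  toks <- regmatches(tolower(caption),
                     gregexpr("[[:alnum:]]+", tolower(caption)))[[1]]
  toks
}

#' Binary keyword histogram of a caption
#'
#' Entry v is 1 if vocabulary keyword v occurs at least once among the
#' caption's tokens (whole-token, case-insensitive; multi-word entries match
#' as consecutive token runs), else 0. The vector is intentionally not
#' renormalized: it is a presence indicator, not a frequency histogram, and
#' the kernel-level gamma normalization absorbs its scale.
#'
#' @param caption a character string.
#' @param vocab a [load_vocabulary()] result (or character vector of
#'   lowercase keywords).
#' @return Binary (0/1) numeric vector of length `length(vocab)`.
#' @export
binary_keyword_histogram <- function(caption, vocab) {
  if (length(vocab) < 1) stop("vocabulary must be non-empty", call. = FALSE)
  toks <- tokenize_caption(caption)
  vapply(as.character(vocab), function(kw) {
    kw_toks <- strsplit(kw, " ", fixed = TRUE)[[1]]
    as.numeric(contains_run(toks, kw_toks))
  }, numeric(1), USE.NAMES = FALSE)
}

# TRUE if `needle` occurs as a consecutive run inside `haystack`.
contains_run <- function(haystack, needle) {
  n <- length(needle)
  h <- length(haystack)
  if (n == 0 || h < n) return(FALSE)
  if (n == 1) return(needle %in% haystack)
  starts <- which(haystack == needle[1])
  for (s in starts) {
    if (s + n - 1 <= h && all(haystack[s:(s + n - 1)] == needle)) return(TRUE)
  }
  FALSE
}
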