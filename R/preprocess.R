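#' Default German stopword list
#'
#' Reads the configurable function-word list shipped with the package
#' (articles, prepositions, conjunctions), one token per line, UTF-8,
#' `#` comments allowed.
#'
#' @param path optional path to an alternative stopword file.
#' @return character vector of lowercase stopword tokens.
#' @export
default_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords_de.txt", package = "problistr")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Normalization chain configuration
#'
#' Parameters of the minimal language-dependent normalization chain applied
#' to each 50-character problem-list entry before vectorization:
#' tokenization, lowercasing, stopword removal, Snowball German stemming,
#' and removal of character spans matching `strip_pattern` (by default
#' digits, dots, commas, underscores and colons, which erases dates, code
#' fragments and enumeration noise).
#'
#' @param stopwords character vector of lowercase tokens to remove.
#' @param stemmer_language currently only `"german"` (the Snowball German
#'   stemmer); `"none"` disables stemming.
#' @param strip_pattern Perl-compatible regular expression; matching spans
#'   are stripped from the normalized tokens, and tokens fully consumed by
#'   it are dropped.
#' @param ngram_size character n-gram window size (>= 1, default 3).
#' @return an object of class `normalization_config`.
#' @export
normalization_config <- function(stopwords = default_stopwords(),
                                 stemmer_language = c("german", "none"),
                                 strip_pattern = "[\\d\\.\\,\\_\\:]+",
                                 ngram_size = 3L) {
  stemmer_language <- match.arg(stemmer_language)
  ngram_size <- as.integer(ngram_size)
  if (is.na(ngram_size) || ngram_size < 1L) {
    stop("ngram_size must be an integer >= 1", call. = FALSE)
  }
  ok <- tryCatch({grepl(strip_pattern, "x", perl = TRUE); TRUE},
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("strip_pattern is not a valid regular expression", call. = FALSE)
  structure(list(stopwords = tolower(stopwords),
                 stemmer_language = stemmer_language,
                 strip_pattern = strip_pattern,
                 ngram_size = ngram_size),
            class = "normalization_config")
}

#' Normalize problem-list text into a token sequence
#'
#' Applies, in order: tokenization at non-alphanumeric boundaries,
#' lowercasing, stopword removal, Snowball German stemming, and stripping of
#' spans matching the configured pattern (tokens fully matched are
#' dropped). Empty input yields an empty token sequence.
#'
#' @param x character vector of descriptions.
#' @param config a [normalization_config()].
#' @return list of character vectors, one token sequence per input string.
#' @examples
#' normalize_text("Chronische Niereninsuffizienz 12.03.2004")
#' @export
normalize_text <- function(x, config = normalization_config()) {
  stopifnot(inherits(config, "normalization_config"))
  if (length(x) == 0L) return(list())
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character(0))
    tokens <- strsplit(s, "[^\\p{L}\\p{N}]+", perl = TRUE)[[1]]
    tokens <- tokens[nzchar(tokens)]
    tokens <- tolower(tokens)
    tokens <- tokens[!(tokens %in% config$stopwords)]
    if (length(tokens) > 0L && config$stemmer_language == "german") {
      tokens <- stem_german(tokens)
    }
    if (length(tokens) > 0L && nzchar(config$strip_pattern)) {
      tokens <- gsub(config$strip_pattern, "", tokens, perl = TRUE)
      tokens <- tokens[nzchar(tokens)]
    }
    tokens
  })
}

#' Character n-grams of a token sequence
#'
#' Slides a window of length `n` over each token; windows never cross token
#' boundaries and no padding characters are used. Tokens shorter than `n`
#' are kept whole as a single gram (preserving clinically salient short
#' abbreviations). Counts accumulate across tokens.
#'
#' @param tokens character vector of tokens.
#' @param n window size (>= 1).
#' @return named integer vector of gram counts (names sorted).
#' @examples
#' char_ngrams(c("nephritis"), 3)
#' @export
char_ngrams <- function(tokens, n = 3L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be an integer >= 1", call. = FALSE)
  if (length(tokens) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  grams <- unlist(lapply(tokens, function(tok) {
    L <- nchar(tok, type = "chars")
    if (L <= n) return(tok)
    substring(tok, 1:(L - n + 1L), n:L)
  }), use.names = FALSE)
  tab <- table(grams)
  counts <- stats::setNames(as.integer(tab), names(tab))
  counts[order(names(counts), method = "radix")]
}

#' Turn a corpus (or raw texts) into bag-of-n-gram documents
#'
#' Runs the full normalization chain and n-gram extraction on every item
#' description, producing the bag-of-grams documents the vector space model
#' is built from.
#'
#' @param x a `problem_corpus`, or a character vector of texts (optionally
#'   named with document ids).
#' @param config a [normalization_config()].
#' @return named list of n-gram count vectors (names = item ids).
#' @export
ngram_documents <- function(x, config = normalization_config()) {
  if (inherits(x, "problem_corpus")) {
    texts <- stats::setNames(x$items$description, x$items$item_id)
  } else {
    texts <- stats::setNames(as.character(x), names(x))
    if (is.null(names(texts))) names(texts) <- paste0("d", seq_along(texts))
  }
  toks <- normalize_text(texts, config)
  docs <- lapply(toks, char_ngrams, n = config$ngram_size)
  names(docs) <- names(texts)
  docs
}
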