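# Snowball stemming algorithm for German, implemented directly from the
# published algorithm description. Operates on lowercase UTF-8 words.
#
# Outline: replace "ß" by "ss"; mark u/y between vowels as consonants;
# compute the standard R1/R2 regions (R1 additionally starts no earlier than
# the fourth character); strip inflectional suffixes in three steps; finally
# unmark u/y and remove umlauts.

.de_vowels <- c("a", "e", "i", "o", "u", "y", "ä", "ö", "ü")
.de_s_ending <- c("b", "d", "f", "g", "h", "k", "l", "m", "n", "r", "t")
.de_st_ending <- setdiff(.de_s_ending, "r")

.de_regions <- function(chars) {
  n <- length(chars)
  vow <- chars %in% .de_vowels
  region_from <- function(from) {
    i <- from
    while (i <= n && !vow[i]) i <- i + 1L
    j <- i + 1L
    while (j <= n && vow[j]) j <- j + 1L
    if (j <= n) j + 1L else n + 1L
  }
  p1 <- region_from(1L)
  p2 <- region_from(p1)
  p1 <- max(p1, 4L)  # at least three letters before R1
  c(p1 = p1, p2 = p2)
}

.ends_with <- function(chars, suffix) {
  ns <- nchar(suffix)
  n <- length(chars)
  n >= ns && identical(paste(chars[(n - ns + 1L):n], collapse = ""), suffix)
}

.longest_suffix <- function(chars, candidates) {
  hits <- candidates[vapply(candidates, function(s) .ends_with(chars, s), logical(1))]
  if (length(hits) == 0L) return(NULL)
  hits[[which.max(nchar(hits))]]
}

.stem_german_word <- function(word) {
  word <- gsub("ß", "ss", word)
  chars <- strsplit(word, "", fixed = FALSE)[[1]]
  n <- length(chars)
  if (n < 2L) {
    return(chartr("äöü", "aou", paste(chars, collapse = "")))
  }
  # mark u and y between vowels as consonants
  if (n >= 3L) {
    for (i in 2L:(n - 1L)) {
      if (chars[i] %in% c("u", "y") &&
          chars[i - 1L] %in% .de_vowels && chars[i + 1L] %in% .de_vowels) {
        chars[i] <- toupper(chars[i])
      }
    }
  }
  reg <- .de_regions(chars)
  p1 <- reg[["p1"]]; p2 <- reg[["p2"]]
  in_r1 <- function(start) start >= p1
  in_r2 <- function(start) start >= p2
  drop_tail <- function(k) chars[seq_len(length(chars) - k)]

  # Step 1
  suf <- .longest_suffix(chars, c("ern", "em", "er", "en", "es", "e", "s"))
  if (!is.null(suf)) {
    start <- length(chars) - nchar(suf) + 1L
    if (suf == "s") {
      prev <- if (start > 1L) chars[start - 1L] else ""
      if (in_r1(start) && prev %in% .de_s_ending) chars <- drop_tail(1L)
    } else if (suf %in% c("en", "es", "e")) {
      if (in_r1(start)) {
        chars <- drop_tail(nchar(suf))
        if (.ends_with(chars, "niss")) chars <- drop_tail(1L)
      }
    } else if (in_r1(start)) {
      chars <- drop_tail(nchar(suf))
    }
  }

  # Step 2
  suf <- .longest_suffix(chars, c("est", "en", "er", "st"))
  if (!is.null(suf)) {
    start <- length(chars) - nchar(suf) + 1L
    if (suf == "st") {
      prev_i <- start - 1L
      if (in_r2(start) && prev_i >= 4L && chars[prev_i] %in% .de_st_ending) {
        chars <- drop_tail(2L)
      }
    } else if (in_r2(start)) {
      chars <- drop_tail(nchar(suf))
    }
  }

  # Step 3 (derivational suffixes)
  suf <- .longest_suffix(chars, c("end", "ung", "isch", "ik", "ig",
                                  "lich", "heit", "keit"))
  if (!is.null(suf)) {
    start <- length(chars) - nchar(suf) + 1L
    prev <- function() if (length(chars) > 0L) chars[length(chars)] else ""
    if (suf %in% c("end", "ung")) {
      if (in_r2(start)) {
        chars <- drop_tail(nchar(suf))
        if (.ends_with(chars, "ig")) {
          s2 <- length(chars) - 1L
          before <- if (s2 > 1L) chars[s2 - 1L] else ""
          if (in_r2(s2) && before != "e") chars <- drop_tail(2L)
        }
      }
    } else if (suf %in% c("isch", "ik", "ig")) {
      before <- if (start > 1L) chars[start - 1L] else ""
      if (in_r2(start) && before != "e") chars <- drop_tail(nchar(suf))
    } else if (suf %in% c("lich", "heit")) {
      if (in_r2(start)) {
        chars <- drop_tail(nchar(suf))
        s2 <- .longest_suffix(chars, c("er", "en"))
        if (!is.null(s2) && in_r1(length(chars) - 1L)) chars <- drop_tail(2L)
      }
    } else if (suf == "keit") {
      if (in_r2(start)) {
        chars <- drop_tail(4L)
        s2 <- .longest_suffix(chars, c("lich", "ig"))
        if (!is.null(s2) && in_r2(length(chars) - nchar(s2) + 1L)) {
          chars <- drop_tail(nchar(s2))
        }
      }
    }
  }

  out <- paste(chars, collapse = "")
  out <- chartr("UY", "uy", out)
  chartr("äöü", "aou", out)
}

#' Stem German words with the Snowball algorithm
#'
#' Suffix-stripping stemmer for German following the Snowball algorithm:
#' inflectional endings (-e, -en, -es, -er, -em, -ern, plural -s after a
#' valid consonant), superlative/verbal endings (-st, -est) and derivational
#' suffixes (-end, -ung, -ig, -ik, -isch, -lich, -heit, -keit) are removed
#' subject to the standard R1/R2 region conditions; umlauts are removed at
#' the end. Input is expected lowercase (the normalization chain lowercases
#' before stemming).
#'
#' @param words character vector of lowercase words.
#' @return character vector of stems.
#' @examples
#' stem_german(c("chronische", "akutes", "nephrotisches"))
#' @export
stem_german <- function(words) {
  if (length(words) == 0L) return(character(0))
  stopifnot(is.character(words))
  vapply(words, .stem_german_word, character(1), USE.NAMES = FALSE)
}
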