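#' Normalize an ICD-10 code and extract its 3-character category
#'
#' Codes are uppercased and stripped of surrounding whitespace; the
#' 3-character category (one letter followed by two digits, e.g. `"N17"`)
#' is the prefix of the normalized code. Codes may be given with or without
#' the dot and with up to two subcategory characters; only the category is
#' used anywhere downstream, because topic-level evaluation operates at the
#' 3-digit ICD-10 level.
#'
#' @param code_text character vector of raw ICD-10 codes.
#' @return character vector of 3-character categories, with the normalized
#'   raw codes in attribute `"raw"`.
#' @examples
#' icd10_category(c("N17.0", " e87.5 "))
#' @export
icd10_category <- function(code_text) {
  if (length(code_text) == 0L) {
    return(structure(character(0), raw = character(0)))
  }
  stopifnot(is.character(code_text))
  raw <- toupper(gsub("\\s+", "", code_text))
  if (any(!nzchar(raw) & !is.na(raw))) {
    stop("empty ICD-10 code", call. = FALSE)
  }
  cat3 <- substr(raw, 1L, 3L)
  bad <- !is.na(cat3) & !grepl("^[A-Z][0-9]{2}$", cat3)
  if (any(bad)) {
    stop(
      "invalid ICD-10 code(s): ",
      paste(unique(code_text[bad]), collapse = ", "),
      " (expected letter + two digits, e.g. 'N17' or 'N17.0')",
      call. = FALSE
    )
  }
  structure(cat3, raw = raw)
}

#' Construct a validated problem-list corpus
#'
#' A corpus is an ordered collection of problem-list items: one row per item
#' with a patient identifier, a unique item identifier, a free-text
#' description of at most 50 characters, and an optional ICD-10 code.
#' Synthetic corpora may additionally carry a `true_code` column (the hidden
#' generating topic) and a `masked` flag.
#'
#' @param items data.frame with columns `patient_id`, `item_id`,
#'   `description` and optionally `code`, `true_code`, `masked`.
#' @param permissive if `TRUE`, over-long descriptions are truncated to 50
#'   characters with a warning and malformed rows are dropped with a warning
#'   instead of raising an error.
#' @return an object of class `problem_corpus`: a list with element `items`
#'   (the validated data.frame, with `code` holding the 3-character category
#'   and `code_raw` the normalized full code).
#' @export
problem_corpus <- function(items, permissive = FALSE) {
  stopifnot(is.data.frame(items))
  required <- c("patient_id", "item_id", "description")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  for (col in intersect(c(required, "code", "true_code"), names(items))) {
    items[[col]] <- as.character(items[[col]])
  }
  if (is.null(items$code)) items$code <- NA_character_
  items$code[!is.na(items$code) & !nzchar(trimws(items$code))] <- NA_character_
  items$description <- trimws(items$description)

  drop <- rep(FALSE, nrow(items))

  empty_desc <- !nzchar(items$description) | is.na(items$description)
  if (any(empty_desc)) {
    msg <- paste0("empty description in row(s): ",
                  paste(which(empty_desc), collapse = ", "))
    if (permissive) {
      warning(msg, "; dropped", call. = FALSE)
      drop <- drop | empty_desc
    } else {
      stop(msg, call. = FALSE)
    }
  }

  too_long <- !drop & nchar(items$description, type = "chars") > 50L
  if (any(too_long)) {
    if (permissive) {
      warning("description(s) longer than 50 characters truncated in row(s): ",
              paste(which(too_long), collapse = ", "), call. = FALSE)
      items$description[too_long] <-
        substr(items$description[too_long], 1L, 50L)
    } else {
      stop("description longer than 50 characters in row(s): ",
           paste(which(too_long), collapse = ", "),
           " (use permissive = TRUE to truncate)", call. = FALSE)
    }
  }

  coded <- !drop & !is.na(items$code)
  items$code_raw <- NA_character_
  if (any(coded)) {
    parsed <- tryCatch(icd10_category(items$code[coded]), error = function(e) e)
    if (inherits(parsed, "error")) {
      if (permissive) {
        ok <- vapply(items$code[coded], function(x) {
          !inherits(tryCatch(icd10_category(x), error = function(e) e), "error")
        }, logical(1))
        bad_rows <- which(coded)[!ok]
        warning("unparseable ICD-10 code in row(s): ",
                paste(bad_rows, collapse = ", "), "; code dropped",
                call. = FALSE)
        items$code[bad_rows] <- NA_character_
        coded <- !drop & !is.na(items$code)
        parsed <- icd10_category(items$code[coded])
      } else {
        bad <- which(coded)[vapply(items$code[coded], function(x) {
          inherits(tryCatch(icd10_category(x), error = function(e) e), "error")
        }, logical(1))]
        stop("unparseable ICD-10 code in row(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
    items$code_raw[coded] <- attr(parsed, "raw")
    items$code[coded] <- as.character(parsed)
  }

  items <- items[!drop, , drop = FALSE]
  rownames(items) <- NULL

  if (anyDuplicated(items$item_id)) {
    stop("duplicate item_id(s): ",
         paste(unique(items$item_id[duplicated(items$item_id)]), collapse = ", "),
         call. = FALSE)
  }

  structure(list(items = items), class = "problem_corpus")
}

#' @export
print.problem_corpus <- function(x, ...) {
  it <- x$items
  sp <- split_coded(x)
  cat("Problem-list corpus\n")
  cat(sprintf("  items:    %d (%d coded, %d uncoded)\n",
              nrow(it), length(sp$coded), length(sp$uncoded)))
  cat(sprintf("  patients: %d\n", length(unique(it$patient_id))))
  if (!is.null(it$true_code)) {
    cat(sprintf("  synthetic truth: %d topics, %d masked\n",
                length(unique(it$true_code)), sum(it$masked %in% TRUE)))
  }
  invisible(x)
}

#' Read a problem-list corpus from CSV or JSON lines
#'
#' CSV files must have a header with columns
#' `patient_id,item_id,description,code` (`code` may be empty); JSONL files
#' carry the same keys, one item object per line. The format is inferred
#' from the file extension when `format = "auto"`.
#'
#' @param path file path.
#' @param format `"auto"`, `"csv"` or `"jsonl"`.
#' @param permissive passed to [problem_corpus()].
#' @return a `problem_corpus`.
#' @export
read_problem_list <- function(path, format = c("auto", "csv", "jsonl"),
                              permissive = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character",
                          na.strings = "", fileEncoding = "UTF-8")
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty JSONL file: ", path, call. = FALSE)
    rows <- lapply(lines, function(l) {
      x <- jsonlite::fromJSON(l)
      x[vapply(x, is.null, logical(1))] <- NA_character_
      as.data.frame(x, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, lapply(rows, function(r) {
      for (col in c("patient_id", "item_id", "description", "code",
                    "true_code", "masked")) {
        if (is.null(r[[col]]) &&
            col %in% unique(unlist(lapply(rows, names)))) {
          r[[col]] <- NA
        }
      }
      r
    }))
  }
  if (nrow(df) == 0L) stop("no rows in ", path, call. = FALSE)
  if (!is.null(df$masked)) df$masked <- as.logical(df$masked)
  problem_corpus(df, permissive = permissive)
}

#' Write a problem-list corpus to CSV or JSON lines
#'
#' Writes the corpus in the same dialect [read_problem_list()] reads, so a
#' write/read round trip reproduces the items field by field. Any extra
#' columns present (e.g. `cluster_id`, `assigned_code` after a pipeline run,
#' or synthetic `true_code`/`masked`) are preserved.
#'
#' @param corpus a `problem_corpus`.
#' @param path output file path.
#' @param format `"auto"`, `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_problem_list <- function(corpus, path, format = c("auto", "csv", "jsonl")) {
  stopifnot(inherits(corpus, "problem_corpus"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  df <- corpus$items
  df$code_raw <- NULL
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      row <- as.list(df[i, , drop = FALSE])
      row <- row[!vapply(row, function(v) is.na(v[[1]]), logical(1))]
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, null = "null"), con)
    }
  }
  invisible(path)
}

#' Split a corpus into coded and uncoded item ids
#'
#' The split is disjoint and exhaustive: every item is either coded (an
#' ICD-10 code is present) or uncoded.
#'
#' @param corpus a `problem_corpus`.
#' @return list with character vectors `coded` and `uncoded` of item ids.
#' @export
split_coded <- function(corpus) {
  stopifnot(inherits(corpus, "problem_corpus"))
  has_code <- !is.na(corpus$items$code)
  list(coded = corpus$items$item_id[has_code],
       uncoded = corpus$items$item_id[!has_code])
}

#' Map item ids to their 3-digit ICD-10 category
#'
#' @param corpus a `problem_corpus`.
#' @param truth if `TRUE`, return the hidden generating codes (`true_code`)
#'   of a synthetic corpus instead of the visible ones.
#' @return named character vector (names = item ids) for items that carry a
#'   code; items without one are omitted.
#' @export
coded_labels <- function(corpus, truth = FALSE) {
  stopifnot(inherits(corpus, "problem_corpus"))
  it <- corpus$items
  col <- if (truth) "true_code" else "code"
  if (is.null(it[[col]])) {
    if (truth) stop("corpus carries no true_code column", call. = FALSE)
    return(stats::setNames(character(0), character(0)))
  }
  keep <- !is.na(it[[col]])
  stats::setNames(it[[col]][keep], it$item_id[keep])
}
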