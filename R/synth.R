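#' Bundled synthetic topic templates
#'
#' German-like clinical diagnosis topics (3-digit ICD-10 category, a
#' canonical description, and surface-variant templates) used by the
#' synthetic corpus generator. The phrases are template-written for this
#' package — no real patient vocabulary is involved.
#'
#' @param codes optional character vector of topic codes to keep (in the
#'   given order).
#' @return data.frame with columns `code`, `canonical` and `variants`
#'   (`|`-separated).
#' @export
default_topics <- function(codes = NULL) {
  df <- utils::read.csv(
    system.file("extdata", "topics_de.csv", package = "problistr"),
    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!is.null(codes)) {
    missing <- setdiff(codes, df$code)
    if (length(missing) > 0L) {
      stop("unknown topic code(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    df <- df[match(codes, df$code), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Noise operator configuration for the synthetic generator
#'
#' Emulates how clinicians overwrite standardized diagnosis text: random
#' per-character typos (substitution or deletion), drastic word
#' abbreviation, and appended context (date-like tokens, drug-like tokens,
#' markers such as "Z.n." or "beidseits"); the result is truncated to the
#' 50-character field width.
#'
#' @param typo_rate per-character substitution/deletion probability.
#' @param abbreviation_prob probability of truncating one long word to an
#'   abbreviated form.
#' @param context_prob probability of appending one context token.
#' @param truncate_at field width (characters).
#' @return an object of class `noise_config`.
#' @export
noise_config <- function(typo_rate = 0.02, abbreviation_prob = 0.10,
                         context_prob = 0.20, truncate_at = 50L) {
  probs <- c(typo_rate, abbreviation_prob, context_prob)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("noise probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(typo_rate = typo_rate,
                 abbreviation_prob = abbreviation_prob,
                 context_prob = context_prob,
                 truncate_at = as.integer(truncate_at)),
            class = "noise_config")
}

#' Synthetic corpus configuration
#'
#' Defaults mirror the study conditions the package targets: five patients
#' with between 250 and 861 problem-list entries each, drawn from the
#' bundled topic templates, with 60% of items visibly coded and moderate
#' noise.
#'
#' @param n_patients number of patients.
#' @param topics data.frame as returned by [default_topics()].
#' @param items_per_patient integer range `c(min, max)`.
#' @param coded_fraction probability that an item's code is visible (the
#'   complement is masked).
#' @param noise a [noise_config()].
#' @param wrong_code_rate probability that a *visible* code is deliberately
#'   replaced by another topic's code, emulating occasional plainly wrong
#'   routine codes; default 0 (generator never mislabels).
#' @param seed integer seed; the generator is fully deterministic given it.
#'   Per-patient substreams are derived from it, so adding patients never
#'   perturbs earlier ones.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_patients = 5L,
                         topics = default_topics(),
                         items_per_patient = c(250L, 861L),
                         coded_fraction = 0.6,
                         noise = noise_config(),
                         wrong_code_rate = 0,
                         seed = 1L) {
  stopifnot(is.data.frame(topics),
            all(c("code", "canonical", "variants") %in% names(topics)))
  if (nrow(topics) < 2L) stop("need at least 2 topics", call. = FALSE)
  if (anyDuplicated(topics$code)) stop("topic codes must be unique", call. = FALSE)
  if (coded_fraction < 0 || coded_fraction > 1) {
    stop("coded_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (wrong_code_rate < 0 || wrong_code_rate > 1) {
    stop("wrong_code_rate must lie in [0, 1]", call. = FALSE)
  }
  items_per_patient <- as.integer(items_per_patient)
  if (length(items_per_patient) == 1L) {
    items_per_patient <- rep(items_per_patient, 2L)
  }
  stopifnot(length(items_per_patient) == 2L,
            items_per_patient[1] >= 1L,
            items_per_patient[1] <= items_per_patient[2])
  stopifnot(inherits(noise, "noise_config"))
  structure(list(n_patients = as.integer(n_patients), topics = topics,
                 items_per_patient = items_per_patient,
                 coded_fraction = coded_fraction, noise = noise,
                 wrong_code_rate = wrong_code_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

.synth_context_tokens <- function() {
  c("Z.n.", "V.a.", "beidseits", "links", "rechts",
    "ASS", "Metoprolol", "Torasemid", "Pantoprazol", "Insulin")
}

.apply_noise <- function(text, noise) {
  # abbreviation: truncate one long word to its first four letters + "."
  if (stats::runif(1) < noise$abbreviation_prob) {
    words <- strsplit(text, " ", fixed = TRUE)[[1]]
    long <- which(nchar(words) > 5L)
    if (length(long) > 0L) {
      w <- long[[sample.int(length(long), 1L)]]
      words[w] <- paste0(substr(words[w], 1L, 4L), ".")
      text <- paste(words, collapse = " ")
    }
  }
  # per-character typos: substitution or deletion
  if (noise$typo_rate > 0) {
    chars <- strsplit(text, "")[[1]]
    hit <- stats::runif(length(chars)) < noise$typo_rate
    hit <- hit & chars %in% c(letters, LETTERS)
    if (any(hit)) {
      for (i in which(hit)) {
        if (stats::runif(1) < 0.5) {
          chars[i] <- sample(letters, 1L)
        } else {
          chars[i] <- ""
        }
      }
      text <- paste(chars, collapse = "")
    }
  }
  # appended context: date-like, drug-like or marker token
  if (stats::runif(1) < noise$context_prob) {
    if (stats::runif(1) < 0.5) {
      tok <- sprintf("%02d.%02d.%04d", sample.int(28, 1L),
                     sample.int(12, 1L), sample(1995:2018, 1L))
    } else {
      pool <- .synth_context_tokens()
      tok <- pool[[sample.int(length(pool), 1L)]]
    }
    text <- paste(text, tok)
  }
  substr(text, 1L, noise$truncate_at)
}

#' Generate a synthetic problem-list corpus with hidden topic truth
#'
#' Draws, per patient, a number of items in the configured range; each item
#' samples a topic and one of its surface variants, passes through the
#' noise operators, and is truncated to 50 characters. The visible ICD-10
#' code is kept with probability `coded_fraction` and masked otherwise
#' (uniformly at random); the generating topic is always retained in
#' `true_code`, with `masked` flagging hidden codes. Fully deterministic
#' given the seed.
#'
#' @param config a [synth_config()].
#' @return a `problem_corpus` whose `items` carry `true_code` and `masked`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  topics <- config$topics
  variant_sets <- lapply(seq_len(nrow(topics)), function(i) {
    v <- topics$variants[i]
    extra <- if (is.na(v) || !nzchar(v)) character(0)
             else strsplit(v, "|", fixed = TRUE)[[1]]
    c(topics$canonical[i], extra)
  })
  base_seed <- (abs(config$seed) %% 1000000L)
  rows <- vector("list", config$n_patients)
  for (p in seq_len(config$n_patients)) {
    set.seed(base_seed * 541L + p * 7919L)
    rng <- config$items_per_patient
    n_p <- if (rng[1] == rng[2]) rng[1] else
      rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
    topic_idx <- sample.int(nrow(topics), n_p, replace = TRUE)
    desc <- character(n_p); visible <- logical(n_p); code <- character(n_p)
    for (i in seq_len(n_p)) {
      vs <- variant_sets[[topic_idx[i]]]
      text <- vs[[sample.int(length(vs), 1L)]]
      desc[i] <- .apply_noise(text, config$noise)
      visible[i] <- stats::runif(1) < config$coded_fraction
      code[i] <- topics$code[topic_idx[i]]
      if (visible[i] && config$wrong_code_rate > 0 &&
          stats::runif(1) < config$wrong_code_rate) {
        others <- setdiff(seq_len(nrow(topics)), topic_idx[i])
        code[i] <- topics$code[others[[sample.int(length(others), 1L)]]]
      }
    }
    rows[[p]] <- data.frame(
      patient_id = sprintf("P%d", p),
      item_id = sprintf("P%d_i%04d", p, seq_len(n_p)),
      description = desc,
      code = ifelse(visible, code, NA_character_),
      true_code = topics$code[topic_idx],
      masked = !visible,
      stringsAsFactors = FALSE)
  }
  corpus <- problem_corpus(do.call(rbind, rows), permissive = TRUE)
  corpus
}

#' Write the truth table of a synthetic corpus
#'
#' @param corpus a synthetic `problem_corpus` (with `true_code`/`masked`).
#' @param path output CSV path (`item_id`, `true_code`, `was_masked`).
#' @return `path`, invisibly.
#' @export
write_truth <- function(corpus, path) {
  stopifnot(inherits(corpus, "problem_corpus"),
            !is.null(corpus$items$true_code))
  utils::write.csv(
    data.frame(item_id = corpus$items$item_id,
               true_code = corpus$items$true_code,
               was_masked = corpus$items$masked),
    path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Topic separability of a vector space
#'
#' Exact extrema over all labeled document pairs: the largest within-topic
#' cosine distance and the smallest between-topic cosine distance. A
#' positive gap (`min_between - max_within > 0`) means a single cut height
#' separates every topic perfectly.
#'
#' @param corpus a `problem_corpus` with `true_code` (or visible codes).
#' @param space a `tfidf_matrix` or `lsa_space` over (a subset of) the
#'   corpus items.
#' @return list with `max_within` and `min_between`.
#' @export
separability <- function(corpus, space) {
  stopifnot(inherits(corpus, "problem_corpus"))
  it <- corpus$items
  lab_col <- if (!is.null(it$true_code)) "true_code" else "code"
  labs <- stats::setNames(it[[lab_col]], it$item_id)
  ids <- intersect(doc_ids(space), names(labs)[!is.na(labs)])
  if (length(unique(labs[ids])) < 2L) {
    stop("need at least 2 topics present in the space", call. = FALSE)
  }
  d <- distance_matrix(space)[ids, ids]
  same <- outer(labs[ids], labs[ids], "==")
  ut <- upper.tri(d)
  list(max_within = max(d[ut & same]),
       min_between = min(d[ut & !same]))
}
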