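#' Fit the semantic grouping model to a problem-list corpus
#'
#' The core fit runs the full chain on one (pooled) corpus: normalization
#' and character n-gram extraction on the unique description strings,
#' tf-idf vectorization, optional LSA reduction, cosine distances, UPGMA
#' clustering, supervised cut-off inference against the visible 3-digit
#' ICD-10 codes, dendrogram cutting, and nearest-neighbour post-coding of
#' uncoded items. Duplicate descriptions are deduplicated before
#' clustering and re-expanded afterwards, so an uncoded duplicate of a
#' coded string inherits that code directly (cosine similarity 1).
#'
#' @param corpus a `problem_corpus`.
#' @param config a [normalization_config()].
#' @param lsa_fraction if non-`NULL`, fraction of LSA dimensions to retain
#'   (in `(0, 1]`); similarity and post-coding then operate in the reduced
#'   space, never mixed with the full space.
#' @param grid candidate cut heights for [infer_cutoff()].
#' @return an object of class `problist_fit` with components `corpus`,
#'   `dedup`, `tfidf`, `space`, `dendrogram`, `cutoff`, `partition`
#'   (over unique strings), and `items` (per-item data.frame with
#'   `cluster_id`, `assigned_code`, `source_item`, `similarity`). Methods:
#'   [print()], [summary()], [plot()], [predict()].
#' @examples
#' cfg <- synth_config(n_patients = 2, items_per_patient = c(40, 40),
#'                     topics = default_topics(c("N17", "I10", "E11")),
#'                     noise = noise_config(0, 0, 0), seed = 7)
#' fit <- problist_fit(generate_corpus(cfg))
#' summary(fit)
#' @export
problist_fit <- function(corpus, config = normalization_config(),
                         lsa_fraction = NULL, grid = seq(0, 1, by = 0.01)) {
  stopifnot(inherits(corpus, "problem_corpus"))
  dedup <- deduplicate_corpus(corpus)
  reps <- dedup$representatives
  if (length(reps) < 2L) {
    stop("need at least 2 unique descriptions to cluster", call. = FALSE)
  }
  it <- corpus$items
  rep_rows <- match(reps, it$item_id)
  docs <- ngram_documents(
    stats::setNames(it$description[rep_rows], reps), config)
  tfidf <- build_tfidf(docs)
  space <- if (is.null(lsa_fraction)) tfidf else lsa_reduce(tfidf, lsa_fraction)
  sims <- similarity_matrix(space)
  dend <- upgma(distance_matrix(sims))
  rep_codes <- stats::setNames(it$code[rep_rows], reps)
  rep_codes <- rep_codes[!is.na(rep_codes)]
  cutoff <- infer_cutoff(dend, rep_codes, grid = grid)
  partition <- cut_partition(dend, cutoff$best_height)
  rep_assign <- post_assign(partition, rep_codes, sims)

  # re-expand unique-string clusters and assignments to all items
  rep_of <- dedup$map[it$item_id]
  cluster_id <- unname(partition$clusters[rep_of])
  assigned_code <- rep(NA_character_, nrow(it))
  source_item <- rep(NA_character_, nrow(it))
  similarity <- rep(NA_real_, nrow(it))
  uncoded <- is.na(it$code)
  rep_coded <- rep_of %in% names(rep_codes)
  # uncoded duplicate of a coded string: inherit that code directly
  idx <- which(uncoded & rep_coded)
  assigned_code[idx] <- unname(rep_codes[rep_of[idx]])
  source_item[idx] <- rep_of[idx]
  similarity[idx] <- 1
  # otherwise: the representative's post-assignment
  ra <- rep_assign[match(rep_of, rep_assign$item_id), ]
  idx <- which(uncoded & !rep_coded)
  assigned_code[idx] <- ra$assigned_code[idx]
  source_item[idx] <- ra$source_item[idx]
  similarity[idx] <- ra$similarity[idx]

  items <- data.frame(it[, c("patient_id", "item_id", "description", "code")],
                      cluster_id = cluster_id,
                      assigned_code = assigned_code,
                      source_item = source_item,
                      similarity = similarity,
                      stringsAsFactors = FALSE)
  if (!is.null(it$true_code)) {
    items$true_code <- it$true_code
    items$masked <- it$masked
  }
  structure(list(corpus = corpus, dedup = dedup, config = config,
                 lsa_fraction = lsa_fraction, tfidf = tfidf, space = space,
                 similarities = sims, dendrogram = dend, cutoff = cutoff,
                 partition = partition, rep_assignments = rep_assign,
                 items = items, call = match.call()),
            class = "problist_fit")
}

#' @export
print.problist_fit <- function(x, ...) {
  cat("Problem-list semantic grouping fit\n")
  cat(sprintf("  space:     %s\n",
              if (is.null(x$lsa_fraction)) "tf-idf character n-grams"
              else sprintf("LSA (fraction %.2f, k = %d)", x$lsa_fraction,
                           x$space$k)))
  cat(sprintf("  items:     %d (%d unique strings)\n",
              nrow(x$items), length(x$dedup$representatives)))
  cat(sprintf("  cut-off:   %.4g (pairwise F = %.4f on coded items)\n",
              x$cutoff$best_height, x$cutoff$best_f))
  cat(sprintf("  topics:    %d\n", x$partition$n_topics))
  n_unc <- sum(is.na(x$items$code))
  cat(sprintf("  post-coded: %d of %d uncoded items\n",
              sum(!is.na(x$items$assigned_code)), n_unc))
  invisible(x)
}

#' Summarize a fitted grouping model
#'
#' Computes the per-corpus summary mirroring the reference table layout:
#' item/unique/topic counts, compression rate, the fraction of uncoded
#' items that received a post-assigned code, and — when the corpus carries
#' synthetic truth — precision/recall/F of post-coding (masked-code
#' recovery) and of the residual string clusters (pair counting over the
#' unassigned items), plus their coded-fraction-weighted combination.
#'
#' @param object a `problist_fit`.
#' @param truth optional named character vector item id -> true 3-digit
#'   code, overriding the corpus' own `true_code` column.
#' @param ... unused.
#' @return an object of class `summary.problist_fit` (a one-row list of
#'   named statistics).
#' @export
summary.problist_fit <- function(object, truth = NULL, ...) {
  items <- object$items
  n_items <- nrow(items)
  n_unique <- length(object$dedup$representatives)
  n_topics <- object$partition$n_topics
  uncoded <- is.na(items$code)
  assigned <- !is.na(items$assigned_code)
  out <- list(
    n_items = n_items, n_unique = n_unique, n_topics = n_topics,
    compression_rate = compression_rate(n_items, n_topics),
    best_height = object$cutoff$best_height,
    best_f = object$cutoff$best_f,
    assigned_fraction = if (sum(uncoded) > 0) mean(assigned[uncoded]) else NA_real_,
    coded_precision = NA_real_, coded_recall = NA_real_, coded_f = NA_real_,
    clustered_precision = NA_real_, clustered_recall = NA_real_,
    clustered_f = NA_real_, combined_f = NA_real_)
  if (is.null(truth) && !is.null(items$true_code)) {
    truth <- stats::setNames(items$true_code, items$item_id)
  }
  if (!is.null(truth)) {
    ev <- items[uncoded, , drop = FALSE]
    if (nrow(ev) > 0L) {
      prf <- prf_from_counts(evaluate_postcoding(ev, truth))
      out$coded_precision <- prf$precision
      out$coded_recall <- prf$recall
      out$coded_f <- prf$f_measure
    }
    resid <- items[uncoded & !assigned, , drop = FALSE]
    resid_labs <- truth[resid$item_id]
    resid_labs <- resid_labs[!is.na(resid_labs)]
    if (length(resid_labs) >= 2L) {
      cl <- stats::setNames(items$cluster_id, items$item_id)
      prf <- prf_from_counts(
        evaluate_pairwise_clustering(cl[names(resid_labs)], resid_labs))
      out$clustered_precision <- prf$precision
      out$clustered_recall <- prf$recall
      out$clustered_f <- prf$f_measure
    }
    w <- out$assigned_fraction
    if (is.finite(w) && !is.na(out$coded_f)) {
      out$combined_f <- if (is.na(out$clustered_f)) out$coded_f else
        w * out$coded_f + (1 - w) * out$clustered_f
    }
  }
  structure(out, class = "summary.problist_fit")
}

#' @export
print.summary.problist_fit <- function(x, ...) {
  cat("Problem-list grouping summary\n")
  cat(sprintf("  list items        %d\n", x$n_items))
  cat(sprintf("  unique list items %d\n", x$n_unique))
  cat(sprintf("  topics            %d\n", x$n_topics))
  cat(sprintf("  compression rate  %.2f\n", x$compression_rate))
  cat(sprintf("  inferred cut-off  %.4g (pairwise F %.2f)\n",
              x$best_height, x$best_f))
  if (is.finite(x$assigned_fraction)) {
    cat(sprintf("  post-coded        %.2f of uncoded items\n",
                x$assigned_fraction))
  }
  if (!is.na(x$coded_f)) {
    cat(sprintf("  post-coding P/R/F %.2f / %.2f / %.2f\n",
                x$coded_precision, x$coded_recall, x$coded_f))
  }
  if (!is.na(x$clustered_f)) {
    cat(sprintf("  residual clusters P/R/F %.2f / %.2f / %.2f\n",
                x$clustered_precision, x$clustered_recall, x$clustered_f))
  }
  if (!is.na(x$combined_f)) {
    cat(sprintf("  weighted combination F  %.2f\n", x$combined_f))
  }
  invisible(x)
}

#' Plot the fitted dendrogram with its inferred cut-off
#'
#' @param x a `problist_fit`.
#' @param ... passed to [plot.hclust()].
#' @export
plot.problist_fit <- function(x, ...) {
  plot(stats::as.dendrogram(x$dendrogram), leaflab = "none",
       ylab = "cosine distance", ...)
  graphics::abline(h = x$cutoff$best_height, col = 2, lty = 2)
  invisible(x)
}

#' Post-coding assignments of a fitted model
#'
#' @param object a `problist_fit`.
#' @param ... unused.
#' @return data.frame of the uncoded items with their cluster, assigned
#'   code, donor item and similarity (`NA` where no coded item shared the
#'   cluster).
#' @export
predict.problist_fit <- function(object, ...) {
  items <- object$items
  items[is.na(items$code),
        c("item_id", "cluster_id", "assigned_code", "source_item",
          "similarity")]
}

.subset_corpus <- function(corpus, keep) {
  items <- corpus$items[keep, , drop = FALSE]
  rownames(items) <- NULL
  structure(list(items = items), class = "problem_corpus")
}

.mask_codes <- function(corpus, mask_fraction, seed = NULL) {
  it <- corpus$items
  if (!is.null(it$true_code)) return(corpus)  # already carries truth
  if (!is.null(seed)) set.seed(seed)
  coded <- which(!is.na(it$code))
  k <- floor(mask_fraction * length(coded))
  hide <- if (k > 0) sample(coded, k) else integer(0)
  it$true_code <- it$code
  it$masked <- FALSE
  it$masked[hide] <- TRUE
  it$code[hide] <- NA_character_
  it$code_raw[hide] <- NA_character_
  structure(list(items = it), class = "problem_corpus")
}

#' Run the full grouping pipeline, per patient or pooled
#'
#' Orchestrates [problist_fit()] in the two study scenarios: `"intra"`
#' fits every patient's list in isolation (codes can only be learned from
#' the same patient), `"inter"` pools all patients so codes are learned
#' across patients. Optionally writes the partition, assignment table,
#' Newick dendrogram and a JSON report to `output_dir`.
#'
#' @param corpus a `problem_corpus` or a file path readable by
#'   [read_problem_list()].
#' @param mode `"inter"` (pooled) or `"intra"` (per patient).
#' @param config a [normalization_config()].
#' @param lsa_fraction optional LSA fraction in `(0, 1]`.
#' @param grid candidate cut heights.
#' @param mask_fraction if given and the corpus has no synthetic truth,
#'   this fraction of the visibly coded items is masked at random and used
#'   as held-out truth for the post-coding evaluation.
#' @param seed seed for the masking draw.
#' @param output_dir optional directory for output files.
#' @return an object of class `problist_report`: list with `mode`, `fits`,
#'   `per_patient` (one summary row per fitted unit) and `aggregate`
#'   (unweighted column means, via [summarize_patients()]).
#' @export
run_pipeline <- function(corpus, mode = c("inter", "intra"),
                         config = normalization_config(),
                         lsa_fraction = NULL, grid = seq(0, 1, by = 0.01),
                         mask_fraction = NULL, seed = NULL,
                         output_dir = NULL) {
  mode <- match.arg(mode)
  if (is.character(corpus)) corpus <- read_problem_list(corpus)
  stopifnot(inherits(corpus, "problem_corpus"))
  if (nrow(corpus$items) == 0L) stop("empty corpus", call. = FALSE)
  if (!is.null(mask_fraction)) {
    corpus <- .mask_codes(corpus, mask_fraction, seed)
  }
  units <- if (mode == "inter") list(pooled = corpus) else {
    pats <- unique(corpus$items$patient_id)
    stats::setNames(
      lapply(pats, function(p) .subset_corpus(corpus, corpus$items$patient_id == p)),
      pats)
  }
  fits <- list(); rows <- list()
  for (nm in names(units)) {
    fit <- tryCatch(
      problist_fit(units[[nm]], config = config,
                   lsa_fraction = lsa_fraction, grid = grid),
      error = function(e) {
        warning("unit '", nm, "' skipped: ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(fit)) next
    fits[[nm]] <- fit
    s <- summary(fit)
    rows[[nm]] <- data.frame(patient = nm, as.data.frame(unclass(s)),
                             stringsAsFactors = FALSE)
  }
  if (length(fits) == 0L) stop("no unit could be fitted", call. = FALSE)
  per_patient <- do.call(rbind, rows)
  rownames(per_patient) <- NULL
  aggregate <- summarize_patients(per_patient)
  report <- structure(list(mode = mode, fits = fits,
                           per_patient = per_patient, aggregate = aggregate),
                      class = "problist_report")
  if (!is.null(output_dir)) .write_report_files(report, output_dir)
  report
}

#' @export
print.problist_report <- function(x, ...) {
  cat(sprintf("Problem-list grouping report (%s-patient mode, %d unit(s))\n",
              x$mode, length(x$fits)))
  print(x$per_patient[, c("patient", "n_items", "n_unique", "n_topics",
                          "compression_rate", "best_height", "best_f")],
        row.names = FALSE)
  invisible(x)
}

.write_report_files <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$fits)) {
    fit <- report$fits[[nm]]
    prefix <- file.path(output_dir, nm)
    utils::write.csv(fit$items[, c("item_id", "cluster_id")],
                     paste0(prefix, "_partition.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(fit$items[, c("item_id", "cluster_id")],
                 original_code = fit$items$code,
                 assigned_code = fit$items$assigned_code,
                 source_item = fit$items$source_item,
                 similarity = fit$items$similarity),
      paste0(prefix, "_assignments.csv"), row.names = FALSE, na = "")
    if (length(fit$dedup$representatives) >= 3L) {
      export_newick(fit$dendrogram, paste0(prefix, "_dendrogram.nwk"))
    }
  }
  jsonlite::write_json(
    list(mode = report$mode,
         per_patient = report$per_patient,
         aggregate = as.list(report$aggregate)),
    file.path(output_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(output_dir)
}

#' Sweep LSA dimension-reduction levels
#'
#' Reruns the pooled pipeline at each retained-dimension fraction and
#' tabulates the inferred cut-off and its pairwise F, mirroring a
#' reduction-level versus F curve. Duplicate fractions produce duplicate
#' rows, order preserved.
#'
#' @param corpus a `problem_corpus`.
#' @param fractions numeric vector of fractions in `(0, 1]`.
#' @param ... passed to [problist_fit()] (e.g. `config`, `grid`).
#' @return data.frame with columns `fraction`, `k`, `best_height`,
#'   `best_f`.
#' @export
sweep_lsa <- function(corpus, fractions, ...) {
  stopifnot(is.numeric(fractions), length(fractions) > 0L)
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  rows <- lapply(fractions, function(fr) {
    fit <- problist_fit(corpus, lsa_fraction = fr, ...)
    data.frame(fraction = fr, k = fit$space$k,
               best_height = fit$cutoff$best_height,
               best_f = fit$cutoff$best_f)
  })
  do.call(rbind, rows)
}
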