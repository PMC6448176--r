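#' TP/FP/FN/TN counts
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return an object of class `eval_counts`.
#' @export
eval_counts <- function(tp = 0L, fp = 0L, fn = 0L, tn = 0L) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(v)) || any(v < 0) || any(abs(v - round(v)) > 1e-9)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(list(tp = as.integer(round(v[["tp"]])),
                 fp = as.integer(round(v[["fp"]])),
                 fn = as.integer(round(v[["fn"]])),
                 tn = as.integer(round(v[["tn"]]))),
            class = "eval_counts")
}

#' @export
print.eval_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

# Pair-counting contingency over labeled items: clusters and labels are
# parallel vectors over the same items. O(cells), not O(pairs).
pair_counts <- function(clusters, labels) {
  stopifnot(length(clusters) == length(labels))
  if (length(labels) < 2L) stop("need at least 2 labeled items", call. = FALSE)
  tab <- table(clusters, labels)
  pairs2 <- function(x) sum(x * (x - 1) / 2)
  tp <- pairs2(tab)
  same_cluster <- pairs2(table(clusters))
  same_label <- pairs2(table(labels))
  total <- choose(length(labels), 2)
  eval_counts(tp = tp, fp = same_cluster - tp, fn = same_label - tp,
              tn = total - same_cluster - same_label + tp)
}

#' Precision, recall and F-measure from counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)` (each 0 when its
#' denominator is 0) and `F = 2 P R / (P + R)` (0 when `P + R = 0`).
#'
#' @param counts an [eval_counts()] object.
#' @return an object of class `prf_scores`: list with `precision`, `recall`,
#'   `f_measure`.
#' @export
prf_from_counts <- function(counts) {
  stopifnot(inherits(counts, "eval_counts"))
  p <- if (counts$tp + counts$fp > 0) counts$tp / (counts$tp + counts$fp) else 0
  r <- if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn) else 0
  structure(list(precision = p, recall = r, f_measure = f_from_pr(p, r)),
            class = "prf_scores")
}

#' @export
print.prf_scores <- function(x, ...) {
  cat(sprintf("P %.4f  R %.4f  F %.4f\n", x$precision, x$recall, x$f_measure))
  invisible(x)
}

#' F-measure (harmonic mean) from precision and recall
#'
#' @param precision,recall values in `[0, 1]`.
#' @return `2 P R / (P + R)`, or 0 when both are 0.
#' @examples
#' f_from_pr(0.91, 0.87)
#' @export
f_from_pr <- function(precision, recall) {
  if (any(!is.finite(c(precision, recall))) ||
      any(c(precision, recall) < 0) || any(c(precision, recall) > 1)) {
    stop("precision and recall must lie in [0, 1]", call. = FALSE)
  }
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Score post-coding against held-out truth
#'
#' Per evaluated (uncoded) item: assigned the true code -> TP; assigned a
#' different code -> FP; not assigned although a true code exists -> FN;
#' not assigned and genuinely codeless -> TN.
#'
#' @param assignments data.frame as returned by [post_assign()] (columns
#'   `item_id`, `assigned_code`).
#' @param truth named character vector, item id -> true 3-digit code
#'   (`NA` for genuinely codeless items).
#' @return an `eval_counts` object over the items in `assignments`.
#' @export
evaluate_postcoding <- function(assignments, truth) {
  stopifnot(is.data.frame(assignments),
            all(c("item_id", "assigned_code") %in% names(assignments)))
  ids <- assignments$item_id
  got <- assignments$assigned_code
  tr <- truth[ids]
  has_truth <- !is.na(tr)
  assigned <- !is.na(got)
  eval_counts(tp = sum(assigned & has_truth & got == tr, na.rm = TRUE),
              fp = sum(assigned & (!has_truth | got != tr), na.rm = TRUE),
              fn = sum(!assigned & has_truth),
              tn = sum(!assigned & !has_truth))
}

#' Pair-counting evaluation of a flat clustering
#'
#' Over all pairs of labeled items: same code and same cluster -> TP;
#' different code, same cluster -> FP; same code, different cluster -> FN;
#' different code and cluster -> TN.
#'
#' @param partition a `topic_partition` (or named cluster vector).
#' @param labels named character vector, item id -> 3-digit code.
#' @return an `eval_counts` object.
#' @export
evaluate_pairwise_clustering <- function(partition, labels) {
  cl <- if (inherits(partition, "topic_partition")) partition$clusters else partition
  common <- intersect(names(cl), names(labels))
  if (length(common) < 2L) stop("need at least 2 labeled items", call. = FALSE)
  pair_counts(cl[common], labels[common])
}

#' Semantic compression rate
#'
#' The fraction of list entries absorbed into shared topic groups:
#' `1 - n_topics / n_items`.
#'
#' @param n_items number of list items (>= 1).
#' @param n_topics number of topic groups (1..n_items).
#' @return compression rate in `[0, 1)`.
#' @examples
#' compression_rate(302, 60)
#' @export
compression_rate <- function(n_items, n_topics) {
  if (any(n_topics < 1) || any(n_items < 1) || any(n_topics > n_items)) {
    stop("need 1 <= n_topics <= n_items", call. = FALSE)
  }
  1 - n_topics / n_items
}

#' Aggregate per-patient summaries
#'
#' Unweighted arithmetic means of the per-patient columns. Following the
#' presentation convention of the reference tables, means are taken over
#' values rounded to two decimals (configurable via `digits`); integer
#' columns (item, topic counts) are averaged as is.
#'
#' @param per_patient data.frame with one row per patient; numeric columns
#'   are averaged.
#' @param digits rounding applied to non-count columns before averaging
#'   (`NULL` to average unrounded values).
#' @return named numeric vector of column means.
#' @export
summarize_patients <- function(per_patient, digits = 2L) {
  stopifnot(is.data.frame(per_patient))
  if (nrow(per_patient) == 0L) stop("empty summary list", call. = FALSE)
  num <- vapply(per_patient, is.numeric, logical(1))
  out <- vapply(names(per_patient)[num], function(col) {
    v <- per_patient[[col]]
    count_col <- all(is.na(v) | v == round(v))
    if (!is.null(digits) && !count_col) v <- round(v, digits)
    mean(v, na.rm = TRUE)
  }, numeric(1))
  out
}

#' Chernoff-bound sample size estimate
#'
#' Minimum sample size `n >= (3 / epsilon^2) * ln(2 / delta)` guaranteeing,
#' with probability `1 - delta`, that sampled proportions lie within
#' `epsilon` of the population values, independent of the pool size.
#'
#' @param epsilon accuracy, in `(0, 1)`.
#' @param delta one minus the confidence, in `(0, 1)`.
#' @return the integer ceiling of the bound.
#' @examples
#' estimate_sample_size(0.05, 0.05)  # 4427
#' @export
estimate_sample_size <- function(epsilon, delta) {
  if (!is.numeric(epsilon) || !is.numeric(delta) ||
      any(epsilon <= 0 | epsilon >= 1) || any(delta <= 0 | delta >= 1)) {
    stop("epsilon and delta must lie in (0, 1)", call. = FALSE)
  }
  as.integer(ceiling(3 / epsilon^2 * log(2 / delta)))
}

#' Bundled reference evaluation summaries
#'
#' Per-patient reference summaries of a five-patient nephrology problem-list
#' evaluation, shipped as plain-text tables: post-coding and string-cluster
#' precision/recall for the intra-patient setting, post-coding
#' precision/recall for the inter-patient setting, and item/unique/topic
#' counts for both settings. They serve as worked examples and as
#' regression anchors for the scoring arithmetic: compression rates and
#' column averages are always recomputed from these inputs, never stored.
#'
#' @return named list of data.frames: `intra_coded`, `intra_clustered`,
#'   `inter_coded`, `intra_topics`, `inter_topics`.
#' @export
reference_summaries <- function() {
  rd <- function(f) utils::read.csv(
    system.file("extdata", f, package = "problistr"),
    stringsAsFactors = FALSE)
  list(intra_coded = rd("reference_intra_coded.csv"),
       intra_clustered = rd("reference_intra_clustered.csv"),
       inter_coded = rd("reference_inter_coded.csv"),
       intra_topics = rd("reference_intra_topics.csv"),
       inter_topics = rd("reference_inter_topics.csv"))
}
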