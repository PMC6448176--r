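#' Post-assign ICD-10 codes to uncoded items by cluster co-membership
#'
#' An uncoded item receives a code if and only if it shares a cluster with
#' at least one coded item; it then inherits the 3-digit code of the most
#' similar (highest cosine) coded member of its cluster. When a cluster
#' mixes several codes, each uncoded member is resolved individually by its
#' own nearest coded neighbour (per-item arg-max, not cluster majority).
#' Exact similarity ties are broken deterministically by the
#' lexicographically smallest donor item id, with a warning. Existing codes
#' are never modified.
#'
#' @param partition a `topic_partition` over all items.
#' @param coded_labels named character vector, item id -> 3-digit code, for
#'   the coded items.
#' @param similarities symmetric similarity matrix with item ids as
#'   dimnames, from the same space (VSM or LSA) used for clustering.
#' @return data.frame with one row per uncoded item: `item_id`,
#'   `cluster_id`, `assigned_code`, `source_item`, `similarity`
#'   (`NA` columns when the cluster holds no coded member).
#' @export
post_assign <- function(partition, coded_labels, similarities) {
  stopifnot(inherits(partition, "topic_partition"))
  cl <- partition$clusters
  ids <- names(cl)
  stopifnot(!is.null(ids),
            !is.null(rownames(similarities)),
            all(ids %in% rownames(similarities)))
  coded_ids <- intersect(names(coded_labels), ids)
  uncoded_ids <- setdiff(ids, coded_ids)
  n_u <- length(uncoded_ids)
  out <- data.frame(item_id = uncoded_ids,
                    cluster_id = unname(cl[uncoded_ids]),
                    assigned_code = rep(NA_character_, n_u),
                    source_item = rep(NA_character_, n_u),
                    similarity = rep(NA_real_, n_u),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) return(out)
  ties <- character(0)
  coded_by_cluster <- split(coded_ids, cl[coded_ids])
  for (r in seq_len(nrow(out))) {
    donors <- coded_by_cluster[[as.character(out$cluster_id[r])]]
    if (is.null(donors) || length(donors) == 0L) next
    sims <- similarities[out$item_id[r], donors]
    best <- max(sims)
    cand <- donors[sims == best]
    if (length(cand) > 1L) {
      cand <- sort(cand, method = "radix")
      ties <- c(ties, out$item_id[r])
    }
    donor <- cand[[1L]]
    out$assigned_code[r] <- coded_labels[[donor]]
    out$source_item[r] <- donor
    out$similarity[r] <- best
  }
  if (length(ties) > 0L) {
    warning("similarity tie(s) broken by smallest donor id for item(s): ",
            paste(utils::head(ties, 5L), collapse = ", "), call. = FALSE)
  }
  out
}
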