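#' UPGMA (average-linkage) agglomerative clustering
#'
#' Builds the merge tree whose inter-cluster distance is the unweighted
#' average of all pairwise document distances between two clusters.
#' Computation is delegated to `stats::hclust(method = "average")`, which
#' implements exactly this linkage; the input is validated against the
#' contract (square, symmetric, non-negative, zero diagonal).
#'
#' @param distances symmetric n x n distance matrix (or a `dist` object)
#'   with document ids as dimnames.
#' @return an `hclust` object (subclass `upgma`) with `labels` set to the
#'   document ids. Merge heights are non-decreasing for metric inputs; a
#'   violation (possible for non-metric dissimilarities) is reported via a
#'   warning, not an error.
#' @export
upgma <- function(distances) {
  if (inherits(distances, "dist")) distances <- as.matrix(distances)
  if (!is.matrix(distances) || nrow(distances) != ncol(distances)) {
    stop("distances must be a square matrix", call. = FALSE)
  }
  n <- nrow(distances)
  if (n < 2L) stop("need at least 2 documents to cluster", call. = FALSE)
  if (any(is.na(distances))) stop("distances contain NA", call. = FALSE)
  if (max(abs(distances - t(distances))) > 1e-8) {
    stop("distances must be symmetric", call. = FALSE)
  }
  if (any(distances < 0)) stop("distances must be non-negative", call. = FALSE)
  if (any(abs(diag(distances)) > 1e-12)) {
    stop("distance diagonal must be zero", call. = FALSE)
  }
  if (is.null(rownames(distances))) {
    rownames(distances) <- colnames(distances) <- paste0("d", seq_len(n))
  }
  hc <- stats::hclust(stats::as.dist(distances), method = "average")
  if (is.unsorted(hc$height)) {
    warning("non-monotone merge heights (non-metric input)", call. = FALSE)
  }
  class(hc) <- c("upgma", "hclust")
  hc
}

#' Cut a dendrogram at a height into a flat topic partition
#'
#' Clusters are the connected components after severing all merges strictly
#' above the cut height: a merge at height exactly equal to the cut height
#' still joins (closed boundary). Raising the height never splits an
#' existing cluster, so partitions along a grid of heights are nested.
#'
#' @param dendrogram an `hclust`/`upgma` tree.
#' @param height cut height (>= 0).
#' @return an object of class `topic_partition`: list with `cut_height`,
#'   `clusters` (named integer vector, item id -> cluster id) and
#'   `n_topics`.
#' @export
cut_partition <- function(dendrogram, height) {
  stopifnot(inherits(dendrogram, "hclust"))
  if (!is.numeric(height) || length(height) != 1L || is.na(height) || height < 0) {
    stop("height must be a single non-negative number", call. = FALSE)
  }
  cl <- stats::cutree(dendrogram, h = height)
  structure(list(cut_height = height,
                 clusters = cl,
                 n_topics = length(unique(cl))),
            class = "topic_partition")
}

#' @export
print.topic_partition <- function(x, ...) {
  cat(sprintf("Topic partition: %d clusters over %d items (cut height %.4g)\n",
              x$n_topics, length(x$clusters), x$cut_height))
  invisible(x)
}

#' Infer the dendrogram cut-off from partially coded items
#'
#' Iterates over a grid of candidate cut heights and scores every resulting
#' flat partition against the available 3-digit ICD-10 codes with the
#' pairwise (pair-counting) F-measure: a pair of coded items is a true
#' positive when it shares both code and cluster, a false positive when it
#' shares the cluster but not the code, a false negative when it shares the
#' code but not the cluster. The returned cut-off is the smallest height
#' attaining the maximum F (ties favour more, purer clusters).
#'
#' @param dendrogram an `hclust`/`upgma` tree whose labels are item ids.
#' @param coded_labels named character vector, item id -> 3-digit code, for
#'   the coded items (at least two, with at least one same-code pair).
#' @param grid numeric vector of candidate heights (default 0 to 1 in steps
#'   of 0.01).
#' @return an object of class `cutoff_search`: list with `best_height`,
#'   `best_f` and `trace` (data.frame of height, precision, recall,
#'   f_measure, n_topics).
#' @export
infer_cutoff <- function(dendrogram, coded_labels,
                         grid = seq(0, 1, by = 0.01)) {
  stopifnot(inherits(dendrogram, "hclust"))
  if (length(grid) == 0L || any(is.na(grid))) {
    stop("grid must be a non-empty numeric vector", call. = FALSE)
  }
  grid <- sort(unique(as.numeric(grid)))
  labs <- dendrogram$labels
  coded_labels <- coded_labels[names(coded_labels) %in% labs]
  if (length(coded_labels) < 2L) {
    stop("need at least two coded items on the tree", call. = FALSE)
  }
  code_sizes <- table(coded_labels)
  if (sum(choose(code_sizes, 2)) == 0) {
    stop("no pair of items shares a code; recall is undefined", call. = FALSE)
  }
  cuts <- stats::cutree(dendrogram, h = grid)
  if (is.null(dim(cuts))) cuts <- matrix(cuts, ncol = 1L,
                                         dimnames = list(labs, NULL))
  cuts <- cuts[names(coded_labels), , drop = FALSE]
  trace <- data.frame(height = grid, precision = NA_real_, recall = NA_real_,
                      f_measure = NA_real_, n_topics = NA_integer_)
  for (g in seq_along(grid)) {
    counts <- pair_counts(cuts[, g], coded_labels)
    prf <- prf_from_counts(counts)
    trace$precision[g] <- prf$precision
    trace$recall[g] <- prf$recall
    trace$f_measure[g] <- prf$f_measure
    trace$n_topics[g] <- length(unique(cuts[, g]))
  }
  best_f <- max(trace$f_measure)
  best_height <- trace$height[which(trace$f_measure == best_f)[1L]]
  structure(list(best_height = best_height, best_f = best_f, trace = trace),
            class = "cutoff_search")
}

#' @export
print.cutoff_search <- function(x, ...) {
  cat(sprintf("Cut-off search over %d heights: best F = %.4f at height %.4g\n",
              nrow(x$trace), x$best_f, x$best_height))
  invisible(x)
}

#' Deduplicate a corpus to unique description strings
#'
#' Clustering operates on unique (whitespace-trimmed) description strings;
#' the multiplicity map re-expands cluster membership to all original items
#' afterwards. The representative of a duplicate group is its first item in
#' corpus order, preferring a coded item so the group's code survives
#' deduplication; identical strings trivially co-cluster.
#'
#' @param corpus a `problem_corpus`.
#' @return list with `representatives` (character vector of representative
#'   item ids, one per unique string), `map` (named character vector, item
#'   id -> representative id) and `multiplicity` (named integer vector per
#'   representative).
#' @export
deduplicate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "problem_corpus"))
  it <- corpus$items
  key <- it$description
  coded_first <- order(match(key, unique(key)), is.na(it$code))
  first_idx <- coded_first[!duplicated(key[coded_first])]
  reps <- stats::setNames(it$item_id[first_idx], key[first_idx])
  map <- stats::setNames(unname(reps[key]), it$item_id)
  mult <- table(unname(map))
  list(representatives = unname(reps),
       map = map,
       multiplicity = stats::setNames(as.integer(mult), names(mult)))
}

#' Export a dendrogram as a Newick tree
#'
#' Leaves are item ids and branch lengths derive from merge heights, for
#' external dendrogram viewers.
#'
#' @param dendrogram an `hclust`/`upgma` tree.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_newick <- function(dendrogram, path) {
  stopifnot(inherits(dendrogram, "hclust"))
  phy <- ape::as.phylo(dendrogram)
  ape::write.tree(phy, file = path)
  invisible(path)
}
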