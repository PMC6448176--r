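#' Build a tf-idf weighted term-document matrix
#'
#' Rows are the unique character n-gram types of the collection, columns the
#' documents. Weights are raw term frequency times smoothed inverse document
#' frequency, `idf(t) = ln((1 + n) / (1 + df(t))) + 1`, and every nonzero
#' column is scaled to unit Euclidean norm so that cosine similarity is a
#' plain dot product. Documents whose normalization produced no grams are
#' kept as zero columns (and reported via a message), so document indexing
#' stays aligned with the corpus.
#'
#' @param docs named list of n-gram count vectors, as produced by
#'   [ngram_documents()].
#' @return an object of class `tfidf_matrix`: list with `matrix` (sparse
#'   `dgCMatrix`, m x n, unit columns), `vocabulary` (row names) and
#'   `doc_ids` (column names).
#' @export
build_tfidf <- function(docs) {
  stopifnot(is.list(docs))
  if (length(docs) == 0L) stop("empty document collection", call. = FALSE)
  if (all(vapply(docs, length, integer(1)) == 0L)) {
    stop("no document contains any gram", call. = FALSE)
  }
  if (is.null(names(docs)) || anyDuplicated(names(docs))) {
    stop("documents must carry unique ids", call. = FALSE)
  }
  vocab <- sort(unique(unlist(lapply(docs, names), use.names = FALSE)),
                method = "radix")
  n <- length(docs)
  i <- unlist(lapply(docs, function(d) match(names(d), vocab)),
              use.names = FALSE)
  j <- rep(seq_len(n), times = vapply(docs, length, integer(1)))
  x <- as.numeric(unlist(docs, use.names = FALSE))
  tf <- Matrix::sparseMatrix(i = i, j = j, x = x,
                             dims = c(length(vocab), n),
                             dimnames = list(vocab, names(docs)))
  df <- Matrix::rowSums(tf > 0)
  idf <- log((1 + n) / (1 + df)) + 1
  w <- Matrix::Diagonal(x = idf) %*% tf
  norms <- sqrt(Matrix::colSums(w^2))
  empty <- norms == 0
  if (any(empty)) {
    message(sum(empty), " document(s) with no grams kept as zero columns: ",
            paste(utils::head(names(docs)[empty], 5L), collapse = ", "))
    norms[empty] <- 1
  }
  w <- w %*% Matrix::Diagonal(x = 1 / norms)
  dimnames(w) <- list(vocab, names(docs))
  structure(list(matrix = methods::as(w, "CsparseMatrix"),
                 vocabulary = vocab, doc_ids = names(docs)),
            class = "tfidf_matrix")
}

#' @export
print.tfidf_matrix <- function(x, ...) {
  cat(sprintf("tf-idf term-document matrix: %d gram types x %d documents (%.1f%% nonzero)\n",
              length(x$vocabulary), length(x$doc_ids),
              100 * Matrix::nnzero(x$matrix) /
                (length(x$vocabulary) * length(x$doc_ids))))
  invisible(x)
}

# Unit-norm document representations of a vector space (columns = documents).
.doc_vectors <- function(space) {
  if (inherits(space, "tfidf_matrix")) {
    return(space$matrix)  # columns already unit norm (or zero)
  }
  if (inherits(space, "lsa_space")) {
    y <- space$doc_space  # k x n, rows weighted by singular values
    norms <- sqrt(colSums(y^2))
    norms[norms == 0] <- 1
    return(Matrix::Matrix(sweep(y, 2L, norms, "/"), sparse = FALSE))
  }
  stop("unsupported space: ", paste(class(space), collapse = "/"), call. = FALSE)
}

#' Pairwise cosine similarity matrix of a vector space
#'
#' @param space a `tfidf_matrix` or an `lsa_space`.
#' @return dense symmetric n x n matrix of cosine similarities with unit
#'   diagonal for nonzero documents; similarities involving a zero column
#'   are 0 by convention. In a reduced LSA space raw cosines may leave
#'   `[0, 1]`; they are clipped to that range so distances keep the same
#'   contract in both spaces.
#' @export
similarity_matrix <- function(space) {
  v <- .doc_vectors(space)
  s <- as.matrix(Matrix::crossprod(v))
  s <- pmin(pmax(s, 0), 1)
  zero <- Matrix::colSums(v^2) == 0
  s[zero, ] <- 0
  s[, zero] <- 0
  diag(s) <- as.numeric(!zero)
  dimnames(s) <- list(doc_ids(space), doc_ids(space))
  s
}

#' Cosine similarity between two documents
#'
#' @param space a `tfidf_matrix` or `lsa_space`.
#' @param i,j document indices (integer position or document id).
#' @return cosine similarity in `[0, 1]`; 0 if either document has a zero
#'   vector.
#' @export
cosine_similarity <- function(space, i, j) {
  v <- .doc_vectors(space)
  ids <- doc_ids(space)
  idx <- function(k) {
    if (is.character(k)) k <- match(k, ids)
    k <- as.integer(k)
    if (is.na(k) || k < 1L || k > length(ids)) {
      stop("document index out of range", call. = FALSE)
    }
    k
  }
  i <- idx(i); j <- idx(j)
  a <- v[, i]; b <- v[, j]
  if (sum(a^2) == 0 || sum(b^2) == 0) return(0)
  min(max(sum(a * b), 0), 1)
}

#' Document ids of a vector space
#' @param space a `tfidf_matrix` or `lsa_space`.
#' @return character vector of document ids in column order.
#' @export
doc_ids <- function(space) {
  if (!is.null(space$doc_ids)) return(space$doc_ids)
  stop("object carries no document ids", call. = FALSE)
}

#' Latent semantic analysis: truncated SVD of the term-document matrix
#'
#' Decomposes the tf-idf matrix `X = T S D'` and retains the top
#' `k = max(1, round(fraction * min(m, n)))` dimensions (the attainable
#' rank is `min(m, n)`). Document representations for similarity are the
#' columns of `S_k D_k'`. Singular-vector signs are fixed so that the
#' largest-magnitude entry of each term-space column is positive, making
#' results deterministic across runs.
#'
#' @param x a `tfidf_matrix`.
#' @param fraction fraction of dimensions to retain, in `(0, 1]`.
#' @return an object of class `lsa_space`: list with `term_space` (m x k,
#'   orthonormal columns), `singular_values` (length k, non-increasing),
#'   `doc_space` (k x n, equal to `S_k D_k'`), `k` and `doc_ids`.
#' @export
lsa_reduce <- function(x, fraction) {
  stopifnot(inherits(x, "tfidf_matrix"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      is.na(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be a single number in (0, 1]", call. = FALSE)
  }
  m <- length(x$vocabulary); n <- length(x$doc_ids)
  k <- max(1L, as.integer(round(fraction * min(m, n))))
  sv <- svd(as.matrix(x$matrix), nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  u <- sv$u; v <- sv$v
  # deterministic sign convention
  for (jj in seq_len(k)) {
    s <- sign(u[which.max(abs(u[, jj])), jj])
    if (s < 0) { u[, jj] <- -u[, jj]; v[, jj] <- -v[, jj] }
  }
  doc_space <- d * t(v)  # k x n
  rownames(u) <- x$vocabulary
  colnames(doc_space) <- x$doc_ids
  structure(list(term_space = u, singular_values = d,
                 doc_space = doc_space, k = k, doc_ids = x$doc_ids),
            class = "lsa_space")
}

#' @export
print.lsa_space <- function(x, ...) {
  cat(sprintf("LSA document space: k = %d dimensions, %d documents\n",
              x$k, length(x$doc_ids)))
  invisible(x)
}

#' Cosine distance matrix of a vector space
#'
#' `d(i, j) = 1 - cos(i, j)`, clipped to `[0, 1]`, with a zero diagonal.
#' This is the distance UPGMA averages over.
#'
#' @param space a `tfidf_matrix` or `lsa_space` (a precomputed similarity
#'   matrix is also accepted).
#' @return symmetric n x n distance matrix.
#' @export
distance_matrix <- function(space) {
  s <- if (is.matrix(space)) space else similarity_matrix(space)
  if (nrow(s) < 2L) stop("need at least 2 documents", call. = FALSE)
  d <- 1 - s
  d <- pmin(pmax(d, 0), 1)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Dump a tf-idf matrix in MatrixMarket format
#'
#' Writes the sparse matrix as `<stem>.mtx` plus `<stem>_vocabulary.txt`
#' and `<stem>_docs.txt` (one entry per line) for external inspection.
#'
#' @param x a `tfidf_matrix`.
#' @param stem output path stem.
#' @return the `.mtx` path, invisibly.
#' @export
write_tfidf_mtx <- function(x, stem) {
  stopifnot(inherits(x, "tfidf_matrix"))
  mtx <- paste0(stem, ".mtx")
  Matrix::writeMM(x$matrix, mtx)
  writeLines(x$vocabulary, paste0(stem, "_vocabulary.txt"), useBytes = TRUE)
  writeLines(x$doc_ids, paste0(stem, "_docs.txt"), useBytes = TRUE)
  invisible(mtx)
}
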