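test_that("tf-idf weights match a hand computation on a 3-document corpus", {
  docs <- list(A = c(ab = 2L, bc = 1L), B = c(ab = 1L), C = c(cd = 1L))
  tf <- build_tfidf(docs)
  # independent spreadsheet-style computation: idf = ln((1+n)/(1+df)) + 1
  idf_ab <- log(4 / 3) + 1
  idf_bc <- log(4 / 2) + 1
  idf_cd <- log(4 / 2) + 1
  a <- c(ab = 2 * idf_ab, bc = 1 * idf_bc, cd = 0)
  a <- a / sqrt(sum(a^2))
  m <- as.matrix(tf$matrix)
  expect_equal(m[c("ab", "bc", "cd"), "A"], a, tolerance = 1e-12)
  expect_equal(unname(m["ab", "B"]), 1)            # single nonzero, unit norm
  expect_equal(unname(m["cd", "C"]), 1)
  expect_equal(unname(Matrix::colSums(tf$matrix^2)), rep(1, 3), tolerance = 1e-12)
})

test_that("idf decreases with document frequency", {
  docs <- c(list(one = c(rare = 1L)),
            lapply(stats::setNames(1:9, paste0("d", 1:9)),
                   function(i) c(everywhere = 1L)))
  docs$one <- c(docs$one, everywhere = 1L)  # df(everywhere) = 10, df(rare) = 1
  tf <- build_tfidf(docs)
  m <- as.matrix(tf$matrix)
  # in doc "one" both grams have tf 1; the ubiquitous gram gets less weight
  expect_lt(m["everywhere", "one"], m["rare", "one"])
})

test_that("cosine similarity follows the unit-column dot product", {
  # df(x) = df(y) = 2 over 3 docs, so idf cancels: cos(A, B) = 1/sqrt(2)
  docs <- list(A = c(x = 1L, y = 1L), B = c(x = 1L), C = c(y = 1L))
  tf <- build_tfidf(docs)
  expect_equal(cosine_similarity(tf, "A", "B"), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(cosine_similarity(tf, "A", "A"), 1, tolerance = 1e-12)
  expect_equal(cosine_similarity(tf, "B", "C"), 0)
  expect_error(cosine_similarity(tf, "A", "nope"), "out of range")
  d <- distance_matrix(tf)
  expect_equal(d["A", "B"], 1 - 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(d["B", "C"], 1)
  expect_equal(diag(d), c(A = 0, B = 0, C = 0))
})

test_that("zero-gram documents become zero columns with similarity 0", {
  docs <- list(A = c(ab = 1L), B = stats::setNames(integer(0), character(0)))
  expect_message(tf <- build_tfidf(docs), "zero column")
  expect_equal(cosine_similarity(tf, "A", "B"), 0)
  s <- similarity_matrix(tf)
  expect_equal(s["B", "B"], 0)
  expect_error(build_tfidf(list(A = stats::setNames(integer(0), character(0)))),
               "no document")
})

test_that("distance matrices are symmetric, clipped and zero-diagonal", {
  set.seed(21)
  for (rep in 1:5) {
    docs <- lapply(stats::setNames(1:8, paste0("d", 1:8)), function(i) {
      grams <- sample(c("aa", "bb", "cc", "dd", "ee"), sample(2:4, 1))
      stats::setNames(sample.int(3, length(grams), replace = TRUE), grams)
    })
    d <- distance_matrix(build_tfidf(docs))
    expect_equal(d, t(d))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(unname(diag(d)), rep(0, 8))
  }
})

test_that("full-rank LSA reproduces vector-space similarities", {
  set.seed(33)
  for (rep in 1:5) {
    docs <- lapply(stats::setNames(1:10, paste0("d", 1:10)), function(i) {
      grams <- sample(paste0("g", 1:12), sample(3:6, 1))
      stats::setNames(sample.int(4, length(grams), replace = TRUE), grams)
    })
    tf <- build_tfidf(docs)
    lsa <- lsa_reduce(tf, 1.0)
    expect_equal(similarity_matrix(lsa), similarity_matrix(tf),
                 tolerance = 1e-8)
  }
})

test_that("LSA factors satisfy the SVD contract and Eckart-Young error", {
  set.seed(17)
  docs <- lapply(stats::setNames(1:15, paste0("d", 1:15)), function(i) {
    grams <- sample(paste0("g", 1:20), sample(4:8, 1))
    stats::setNames(sample.int(4, length(grams), replace = TRUE), grams)
  })
  tf <- build_tfidf(docs)
  lsa <- lsa_reduce(tf, 0.5)
  k <- lsa$k
  expect_equal(k, round(0.5 * min(dim(tf$matrix))))
  # non-increasing positive singular values, orthonormal term space
  expect_true(all(diff(lsa$singular_values) <= 1e-12))
  expect_true(all(lsa$singular_values > 0))
  expect_equal(crossprod(lsa$term_space), diag(k), tolerance = 1e-8,
               ignore_attr = TRUE)
  # reconstruction error equals the Frobenius tail of discarded singular values
  full <- svd(as.matrix(tf$matrix))
  recon <- lsa$term_space %*% lsa$doc_space
  tail_sq <- sum(full$d[(k + 1):length(full$d)]^2)
  expect_equal(sum((as.matrix(tf$matrix) - recon)^2), tail_sq,
               tolerance = 1e-8)
})

test_that("rank-1 matrices collapse to |cosine| 1 in any reduced space", {
  docs <- list(A = c(g = 1L), B = c(g = 3L), C = c(g = 7L))
  tf <- build_tfidf(docs)
  lsa <- lsa_reduce(tf, 0.5)
  s <- similarity_matrix(lsa)
  expect_equal(unname(s[upper.tri(s)]), rep(1, 3), tolerance = 1e-8)
})

test_that("lsa_reduce and distance_matrix validate parameters", {
  docs <- list(A = c(ab = 1L), B = c(cd = 1L))
  tf <- build_tfidf(docs)
  expect_error(lsa_reduce(tf, 0), "fraction")
  expect_error(lsa_reduce(tf, 1.2), "fraction")
  one <- build_tfidf(list(A = c(ab = 1L)))
  expect_error(distance_matrix(one), "at least 2")
})

test_that("MatrixMarket dump writes matrix plus vocabulary and doc ids", {
  docs <- list(A = c(ab = 2L, bc = 1L), B = c(ab = 1L))
  tf <- build_tfidf(docs)
  stem <- tempfile()
  write_tfidf_mtx(tf, stem)
  back <- Matrix::readMM(paste0(stem, ".mtx"))
  expect_equal(as.matrix(back), unname(as.matrix(tf$matrix)), tolerance = 1e-12)
  expect_equal(readLines(paste0(stem, "_vocabulary.txt")), tf$vocabulary)
  unlink(paste0(stem, c(".mtx", "_vocabulary.txt", "_docs.txt")))
})
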