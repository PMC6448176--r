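test_that("generation is fully deterministic given the seed", {
  cfg <- synth_config(n_patients = 3, items_per_patient = c(20, 40), seed = 99)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1$items, c2$items)
  c3 <- generate_corpus(synth_config(n_patients = 3,
                                     items_per_patient = c(20, 40), seed = 100))
  expect_false(identical(c1$items$description, c3$items$description))
})

test_that("per-patient substreams are stable when patients are added", {
  c2 <- generate_corpus(synth_config(n_patients = 2,
                                     items_per_patient = c(15, 25), seed = 5))
  c4 <- generate_corpus(synth_config(n_patients = 4,
                                     items_per_patient = c(15, 25), seed = 5))
  first_two <- c4$items[c4$items$patient_id %in% c("P1", "P2"), ]
  rownames(first_two) <- NULL
  expect_identical(c2$items, first_two)
})

test_that("zero noise and single variants reproduce canonical descriptions", {
  topics <- default_topics(c("N17", "I10"))
  topics$variants <- ""
  cfg <- synth_config(n_patients = 1, topics = topics,
                      items_per_patient = c(30, 30),
                      noise = noise_config(0, 0, 0), seed = 3)
  corp <- generate_corpus(cfg)
  expect_true(all(corp$items$description %in% topics$canonical))
  expect_equal(unname(stats::setNames(topics$canonical, topics$code)[
    corp$items$true_code]), corp$items$description)
})

test_that("descriptions respect the 50-character field width under noise", {
  cfg <- synth_config(n_patients = 3, items_per_patient = c(50, 80),
                      noise = noise_config(0.05, 0.3, 0.9), seed = 17)
  corp <- generate_corpus(cfg)
  expect_true(all(nchar(corp$items$description, type = "chars") <= 50L))
})

test_that("masking follows the coded fraction and never mislabels", {
  cfg <- synth_config(n_patients = 4, items_per_patient = c(200, 200),
                      coded_fraction = 0.7, seed = 23)
  corp <- generate_corpus(cfg)
  n <- nrow(corp$items)
  frac_coded <- mean(!is.na(corp$items$code))
  # within ~4 binomial standard errors of 0.7
  expect_lt(abs(frac_coded - 0.7), 4 * sqrt(0.7 * 0.3 / n))
  vis <- !is.na(corp$items$code)
  expect_equal(corp$items$code[vis], corp$items$true_code[vis])
  expect_equal(corp$items$masked, !vis)

  all_coded <- generate_corpus(synth_config(n_patients = 1,
                                            items_per_patient = c(40, 40),
                                            coded_fraction = 1, seed = 2))
  expect_false(any(is.na(all_coded$items$code)))
})

test_that("wrong-code injection mislabels only visible codes at the set rate", {
  cfg <- synth_config(n_patients = 2, items_per_patient = c(300, 300),
                      coded_fraction = 1, wrong_code_rate = 0.2, seed = 31)
  corp <- generate_corpus(cfg)
  wrong <- corp$items$code != corp$items$true_code
  expect_gt(mean(wrong), 0.1)
  expect_lt(mean(wrong), 0.3)
})

test_that("separability extrema equal a brute-force pair scan", {
  corp <- separable_fixture(n_patients = 1, items = 40, seed = 41)
  docs <- ngram_documents(corp)
  tf <- build_tfidf(docs)
  sep <- separability(corp, tf)
  d <- distance_matrix(tf)
  labs <- stats::setNames(corp$items$true_code, corp$items$item_id)
  w <- b <- c()
  ids <- corp$items$item_id
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i < j) {
      if (labs[[ids[i]]] == labs[[ids[j]]]) w <- c(w, d[ids[i], ids[j]])
      else b <- c(b, d[ids[i], ids[j]])
    }
  }
  expect_equal(sep$max_within, max(w))
  expect_equal(sep$min_between, min(b))
  # zero noise, distinct canonical strings: identical strings at distance 0
  topics <- default_topics(c("N17", "I10")); topics$variants <- ""
  c0 <- generate_corpus(synth_config(n_patients = 1, topics = topics,
                                     items_per_patient = c(20, 20),
                                     noise = noise_config(0, 0, 0), seed = 1))
  tf0 <- build_tfidf(ngram_documents(c0))
  expect_equal(separability(c0, tf0)$max_within, 0, tolerance = 1e-12)
})

test_that("separability requires at least two topics", {
  topics <- default_topics(c("N17", "I10"))
  cfg <- synth_config(n_patients = 1, topics = topics,
                      items_per_patient = c(10, 10), seed = 7)
  corp <- generate_corpus(cfg)
  one <- structure(list(items = corp$items[corp$items$true_code == "N17", ]),
                   class = "problem_corpus")
  tf <- build_tfidf(ngram_documents(one))
  expect_error(separability(one, tf), "2 topics")
})

test_that("generator configuration validates probabilities and topics", {
  expect_error(noise_config(typo_rate = 1.5), "\\[0, 1\\]")
  expect_error(synth_config(coded_fraction = 2), "coded_fraction")
  expect_error(synth_config(topics = default_topics("N17")), "at least 2")
  dup <- default_topics(c("N17", "I10")); dup$code <- "N17"
  expect_error(synth_config(topics = dup), "unique")
})

test_that("truth tables round-trip through CSV", {
  corp <- separable_fixture(n_patients = 1, items = 15, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_truth(corp, path)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$item_id, corp$items$item_id)
  expect_equal(back$true_code, corp$items$true_code)
  expect_equal(back$was_masked, corp$items$masked)
  unlink(path)
})
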