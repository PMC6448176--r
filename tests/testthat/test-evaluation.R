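test_that("precision/recall/F follow their defining formulas", {
  prf <- prf_from_counts(eval_counts(tp = 3))
  expect_equal(c(prf$precision, prf$recall, prf$f_measure), c(1, 1, 1))
  prf0 <- prf_from_counts(eval_counts(tp = 0, fp = 4, fn = 2))
  expect_equal(prf0$f_measure, 0)
  prf2 <- prf_from_counts(eval_counts(tp = 1, fp = 2, fn = 1))
  expect_equal(prf2$precision, 1 / 3)
  expect_equal(prf2$recall, 1 / 2)
  expect_equal(prf2$f_measure, 0.4)
  expect_error(eval_counts(tp = -1), "non-negative")
})

test_that("harmonic-mean F agrees with prf_from_counts wherever both apply", {
  expect_equal(f_from_pr(1, 1), 1)
  expect_equal(f_from_pr(0, 0), 0)
  expect_error(f_from_pr(1.2, 0.5), "\\[0, 1\\]")
  set.seed(9)
  for (rep in 1:50) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    prf <- prf_from_counts(eval_counts(tp = tp, fp = fp, fn = fn))
    expect_equal(prf$f_measure, f_from_pr(prf$precision, prf$recall),
                 tolerance = 1e-12)
  }
})

test_that("post-coding evaluation classifies each masked item", {
  assign_df <- function(ids, codes) {
    data.frame(item_id = ids, assigned_code = codes, stringsAsFactors = FALSE)
  }
  truth <- stats::setNames(rep("N17", 10), paste0("i", 1:10))
  all_right <- assign_df(paste0("i", 1:10), rep("N17", 10))
  ev <- evaluate_postcoding(all_right, truth)
  expect_equal(c(ev$tp, ev$fp, ev$fn, ev$tn), c(10, 0, 0, 0))

  mixed <- assign_df(paste0("i", 1:10),
                     c(rep("N17", 7), "E87", "I10", NA))
  ev2 <- evaluate_postcoding(mixed, truth)
  expect_equal(c(ev2$tp, ev2$fp, ev2$fn, ev2$tn), c(7, 2, 1, 0))

  # genuinely codeless unassigned items are true negatives
  truth3 <- c(i1 = "N17", i2 = NA)
  ev3 <- evaluate_postcoding(assign_df(c("i1", "i2"), c("N17", NA)), truth3)
  expect_equal(c(ev3$tp, ev3$tn), c(1, 1))
})

test_that("random post-coding scenarios match an item-by-item recount", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    ids <- paste0("i", seq_len(n))
    truth <- stats::setNames(
      sample(c("N17", "E87", NA), n, replace = TRUE), ids)
    got <- sample(c("N17", "E87", NA), n, replace = TRUE)
    ev <- evaluate_postcoding(
      data.frame(item_id = ids, assigned_code = got), truth)
    tp <- fp <- fn <- tn <- 0L
    for (i in seq_len(n)) {
      if (!is.na(got[i])) {
        if (!is.na(truth[i]) && got[i] == truth[i]) tp <- tp + 1L else fp <- fp + 1L
      } else {
        if (!is.na(truth[i])) fn <- fn + 1L else tn <- tn + 1L
      }
    }
    expect_equal(c(ev$tp, ev$fp, ev$fn, ev$tn), c(tp, fp, fn, tn))
    expect_equal(ev$tp + ev$fp + ev$fn + ev$tn, n)
  }
})

test_that("pairwise clustering evaluation matches the worked 4-item example", {
  labels <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  partition <- c(a1 = 1L, a2 = 1L, b1 = 1L, b2 = 2L)
  ev <- evaluate_pairwise_clustering(partition, labels)
  expect_equal(c(ev$tp, ev$fp, ev$fn, ev$tn), c(1, 2, 1, 2))
  expect_equal(prf_from_counts(ev)$f_measure, 0.4)
  # perfect partition by code
  perfect <- c(a1 = 1L, a2 = 1L, b1 = 2L, b2 = 2L)
  expect_equal(prf_from_counts(evaluate_pairwise_clustering(perfect, labels))$f_measure, 1)
  # singletons: recall 0
  singles <- c(a1 = 1L, a2 = 2L, b1 = 3L, b2 = 4L)
  expect_equal(prf_from_counts(evaluate_pairwise_clustering(singles, labels))$f_measure, 0)
  expect_error(evaluate_pairwise_clustering(c(a1 = 1L), labels["a1"]),
               "at least 2")
})

test_that("pair counts cover every labeled pair exactly once", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(4:30, 1)
    ids <- paste0("i", seq_len(n))
    clusters <- stats::setNames(sample.int(5, n, replace = TRUE), ids)
    labels <- stats::setNames(sample(LETTERS[1:4], n, replace = TRUE), ids)
    ev <- evaluate_pairwise_clustering(clusters, labels)
    expect_equal(ev$tp + ev$fp + ev$fn + ev$tn, choose(n, 2))
    orc <- oracle_pair_counts(clusters, labels)
    expect_equal(list(ev$tp, ev$fp, ev$fn, ev$tn),
                 list(orc$tp, orc$fp, orc$fn, orc$tn))
  }
})

test_that("compression rate reproduces the reference table arithmetic", {
  expect_equal(round(compression_rate(302, 60), 2), 0.80)
  expect_equal(round(compression_rate(861, 95), 2), 0.89)
  expect_equal(compression_rate(10, 10), 0)
  expect_error(compression_rate(5, 6), "n_topics")
})

test_that("patient summaries average column-wise, rounded as presented", {
  df <- data.frame(topics = c(60, 70, 95, 77, 90),
                   f = c(0.833, 0.733, 0.713, 0.888, 0.70))
  out <- summarize_patients(df)
  expect_equal(unname(out["topics"]), 78.4)
  # averages run over 2 d.p.-rounded values
  expect_equal(unname(out["f"]), mean(c(0.83, 0.73, 0.71, 0.89, 0.70)))
  expect_equal(unname(summarize_patients(df[1, ])["topics"]), 60)
  expect_error(summarize_patients(df[0, ]), "empty")
})

test_that("Chernoff sample-size bound matches the closed form", {
  expect_equal(estimate_sample_size(0.05, 0.05), 4427L)
  expect_equal(estimate_sample_size(0.1, 0.05), 1107L)
  expect_equal(estimate_sample_size(0.5, 0.5), 17L)
  # monotone: tighter accuracy or confidence demands more samples
  eps <- c(0.3, 0.2, 0.1, 0.05); del <- c(0.3, 0.2, 0.1, 0.05)
  expect_true(all(diff(vapply(eps, estimate_sample_size, integer(1),
                              delta = 0.05)) > 0))
  expect_true(all(diff(vapply(del, estimate_sample_size, integer(1),
                              epsilon = 0.05)) > 0))
  expect_error(estimate_sample_size(0, 0.05), "\\(0, 1\\)")
  expect_error(estimate_sample_size(0.05, 1), "\\(0, 1\\)")
})

test_that("bundled reference summaries load with the expected shape", {
  ref <- reference_summaries()
  expect_named(ref, c("intra_coded", "intra_clustered", "inter_coded",
                      "intra_topics", "inter_topics"))
  expect_equal(nrow(ref$intra_coded), 5L)
  expect_equal(ref$intra_topics$list_items, ref$inter_topics$list_items)
})
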