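test_that("confusion counts align on keys and partition the universe", {
  p <- tibble::tibble(doc_id = c("a", "b"), label = c("positive", "negative"))
  g <- tibble::tibble(doc_id = c("a", "b"), label = c("positive", "positive"))
  cc <- confusion(p, g, level = "document")
  expect_equal(as.integer(cc[c("tp", "fp", "fn", "tn")]), c(1L, 0L, 1L, 0L))

  # identical label sets: no errors of either kind
  cc <- confusion(g, g, level = "document")
  expect_equal(cc$fp + cc$fn, 0L)

  # all predicted positive vs all gold negative
  p5 <- tibble::tibble(doc_id = letters[1:5], label = "positive")
  g5 <- tibble::tibble(doc_id = letters[1:5], label = "negative")
  expect_equal(confusion(p5, g5, level = "document")$fp, 5L)

  # unmatched predicted positives are fp; unmatched gold positives are fn
  p <- tibble::tibble(doc_id = "x", instance_id = "x#001", label = "positive")
  g <- tibble::tibble(doc_id = "y", instance_id = "y#001", label = "positive")
  cc <- confusion(p, g, level = "instance")
  expect_equal(c(cc$fp, cc$fn), c(1L, 1L))

  expect_error(
    confusion(dplyr::bind_rows(p, p), g, level = "instance"),
    "duplicate")
})

test_that("precision/recall point estimates, F1 and undefined flags", {
  ev <- precision_recall(tibble::tibble(tp = 54, fp = 16, fn = 27))
  expect_equal(ev$precision, 54 / 70)
  expect_equal(ev$recall, 54 / 81)
  expect_equal(ev$f1, 2 * ev$precision * ev$recall /
                 (ev$precision + ev$recall))
  expect_true(ev$ci_precision[["lower"]] <= ev$precision)
  expect_true(ev$ci_precision[["upper"]] >= ev$precision)

  expect_equal(precision_recall(tibble::tibble(tp = 9, fp = 0,
                                               fn = 3))$precision, 1)

  ev <- precision_recall(tibble::tibble(tp = 0, fp = 0, fn = 0))
  expect_true(is.na(ev$precision))
  expect_true(is.na(ev$recall))
  expect_true(is.na(ev$f1))

  td <- tidy(precision_recall(tibble::tibble(tp = 8, fp = 2, fn = 2)))
  expect_equal(td$metric, c("precision", "recall", "f1"))
  expect_equal(td$estimate[1], 0.8)
})

test_that("precision/recall agree with an independent implementation", {
  skip_if_not_installed("caret")
  set.seed(11)
  for (i in 1:20) {
    n <- 60
    pred <- factor(sample(c("positive", "negative"), n, replace = TRUE),
                   levels = c("positive", "negative"))
    gold <- factor(sample(c("positive", "negative"), n, replace = TRUE),
                   levels = c("positive", "negative"))
    keys <- tibble::tibble(doc_id = sprintf("d%02d", seq_len(n)))
    ev <- evaluate_detection(
      dplyr::mutate(keys, label = as.character(pred)),
      dplyr::mutate(keys, label = as.character(gold)),
      level = "document")
    expect_equal(ev$precision,
                 unname(caret::posPredValue(pred, gold,
                                            positive = "positive")))
    expect_equal(ev$recall,
                 unname(caret::sensitivity(pred, gold,
                                           positive = "positive")))
  }
})

test_that("Clopper-Pearson boundaries are exact and match binom.test", {
  expect_equal(clopper_pearson(0, 10)[["lower"]], 0)
  expect_equal(clopper_pearson(10, 10)[["upper"]], 1)
  ci <- clopper_pearson(8, 10)
  bt <- stats::binom.test(8, 10)$conf.int
  expect_equal(unname(ci), as.numeric(bt), tolerance = 1e-12)
  # interval contains the point estimate; width shrinks with n at fixed k/n
  expect_true(ci[["lower"]] <= 0.8 && ci[["upper"]] >= 0.8)
  w10 <- diff(clopper_pearson(8, 10))
  w100 <- diff(clopper_pearson(80, 100))
  expect_lt(w100, w10)
  expect_error(clopper_pearson(5, 4), "k must")
  expect_error(clopper_pearson(0, 0), "n must")
})

test_that("Clopper-Pearson matches the tail-sum root-finding oracle", {
  for (n in c(1, 5, 12, 30)) {
    for (k in 0:n) {
      got <- clopper_pearson(k, n)
      want <- oracle_clopper_pearson(k, n)
      expect_equal(unname(got), unname(want), tolerance = 1e-6,
                   info = sprintf("k=%d n=%d", k, n))
    }
  }
})

test_that("Cohen's kappa follows the chance-corrected formula", {
  expect_equal(cohens_kappa(matrix(c(50, 0, 0, 50), 2))$kappa, 1)

  k <- cohens_kappa(matrix(c(40, 5, 10, 45), 2))
  expect_equal(k$observed_agreement, 0.85)
  expect_equal(k$expected_agreement, 0.50)
  expect_equal(k$kappa, 0.70)

  # degenerate: all mass in one cell -> undefined
  k <- cohens_kappa(matrix(c(100, 0, 0, 0), 2))
  expect_true(is.na(k$kappa))
  expect_equal(k$observed_agreement, 1)

  expect_error(cohens_kappa(matrix(1:6, 2)), "square")

  # invariant under simultaneous relabelling of categories
  tab <- matrix(c(30, 7, 4, 59), 2)
  perm <- tab[2:1, 2:1]
  expect_equal(cohens_kappa(tab)$kappa, cohens_kappa(perm)$kappa)

  # from paired label vectors
  a <- c("positive", "positive", "negative", "negative")
  b <- c("positive", "negative", "negative", "negative")
  expect_equal(cohens_kappa(a, b)$observed_agreement, 0.75)
})

test_that("kappa relates to observed agreement as the formula demands", {
  set.seed(21)
  for (i in 1:30) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    k <- cohens_kappa(tab)
    po <- k$observed_agreement; pe <- k$expected_agreement
    expect_equal(k$kappa, (po - pe) / (1 - pe))
    if (po < 1 && pe > 0) expect_lt(k$kappa, po)
  }
})

test_that("span-overlap alignment is greedy and leftmost-first", {
  gold <- tibble::tibble(doc_id = "d", instance_id = c("g1", "g2"),
                         char_start = c(10L, 40L), char_end = c(20L, 50L))
  pred <- tibble::tibble(doc_id = "d",
                         char_start = c(12L, 15L, 60L),
                         char_end = c(18L, 22L, 70L),
                         label = "positive")
  out <- align_instances(pred, gold)
  expect_equal(out$instance_id[1], "g1")
  # second overlapping prediction cannot reuse the consumed gold span
  expect_match(out$instance_id[2], "unmatched")
  expect_match(out$instance_id[3], "unmatched")
})
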