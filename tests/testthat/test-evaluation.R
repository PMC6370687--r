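test_that("cohort rates use the conventional denominators", {
  r <- cohort_rates(c("recognized", "inconclusive", "unrecognized",
                      "unrecognized"),
                    c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$inconclusive_rate, 25)
  expect_equal(r$hit_rate, 100)
  expect_equal(r$correct_rejection_rate, 100)

  # all judged recognized, all truly recognizing: CR undefined, not 0/100
  r2 <- cohort_rates(rep("recognized", 3), rep(TRUE, 3))
  expect_equal(r2$inconclusive_rate, 0)
  expect_equal(r2$hit_rate, 100)
  expect_true(is.na(r2$correct_rejection_rate))

  r3 <- cohort_rates(rep("inconclusive", 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r3$inconclusive_rate, 100)
  expect_true(is.na(r3$hit_rate))
  expect_true(is.na(r3$correct_rejection_rate))

  # conclusive + inconclusive = total
  expect_equal(sum(r$counts), 4)
  expect_error(cohort_rates("recognized", c(TRUE, FALSE)), "equal length")
})

test_that("trapezoidal AUC matches hand-enumerated and degenerate cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(5, 6, 7, 1, 2, 3), rep(c(TRUE, FALSE), each = 3)),
               1)
  expect_equal(roc_auc(rep(2, 8), rep(c(TRUE, FALSE), 4)), 0.5)
  # p-type scores: smaller means more recognizing
  expect_equal(roc_auc(c(0.01, 0.6, 0.02, 0.9), c(1, 0, 1, 0),
                       direction = "less"), 1)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC equals Mann-Whitney pair counting on random score sets", {
  withr::with_seed(61, {
    for (k in 1:100) {
      n1 <- sample(2:12, 1); n0 <- sample(2:12, 1)
      scores <- round(c(rnorm(n1, 0.5), rnorm(n0)), sample(0:2, 1))
      truth <- rep(c(TRUE, FALSE), c(n1, n0))
      expect_equal(roc_auc(scores, truth), brute_force_auc(scores, truth),
                   tolerance = 1e-12)
    }
    # and against the U statistic of wilcox.test as a second oracle
    for (k in 1:10) {
      scores <- rnorm(30)
      truth <- rep(c(TRUE, FALSE), 15)
      w <- stats::wilcox.test(scores[truth], scores[!truth],
                              exact = FALSE)$statistic
      expect_equal(roc_auc(scores, truth), unname(w) / (15 * 15),
                   tolerance = 1e-12)
    }
  })
})

test_that("binned ratios follow the published edges and sum to 100", {
  d_scores <- c(-0.5, -0.1, 0.1, 0.3, 0.5, 0.9, 0.45, 0.41)
  truth <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE)
  tab <- binned_recognition_ratios(d_scores, truth, type = "d")
  expect_equal(nrow(tab), 6)
  expect_equal(sum(tab$share_of_all), 100)
  expect_equal(sum(tab$n), length(d_scores))
  # the [0.4, 0.6) bin holds 2 recognizing and 1 unrecognizing
  b <- tab[tab$bin == "[0.4, 0.6)", ]
  expect_equal(b$n, 3)
  expect_equal(b$share_recognizing, 200 / 3)
  expect_equal(b$share_unrecognizing, 100 / 3)

  p_tab <- binned_recognition_ratios(c(0.01, 0.5, 1), c(T, F, F),
                                     type = "p")
  expect_equal(nrow(p_tab), 8)
  expect_equal(sum(p_tab$n), 3)
  expect_equal(p_tab$n[p_tab$bin == "[0.8, 1)"], 1)  # 1 sits in the last bin
  expect_error(binned_recognition_ratios(c(-1, 2), c(T, F), type = "p"),
               "outside")

  # all scores in one bin; the empty bins report conditional shares as NA
  one <- binned_recognition_ratios(rep(0.5, 4), rep(TRUE, 4), type = "d")
  expect_equal(one$share_of_all[one$bin == "[0.4, 0.6)"], 100)
  expect_true(all(is.na(one$share_recognizing[one$n == 0])))
})

test_that("left-closed right-open bin convention at the boundaries", {
  tab <- binned_recognition_ratios(c(0, 0.2, 0.4, 0.6), rep(TRUE, 4),
                                   type = "d")
  expect_equal(tab$n, c(0, 0, 1, 1, 1, 1))
})

test_that("searching decomposition separates the two false-positive types", {
  jud <- data.frame(
    label = c("recognized", "recognized", "unrecognized", "inconclusive",
              "recognized", "unrecognized", "inconclusive"),
    identified_item = c(3L, 2L, NA, NA, 4L, NA, NA))
  truth <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  true_items <- c(3L, 3L, 3L, 3L, NA, NA, NA)
  dec <- searching_error_decomposition(jud, truth, true_items)
  expect_equal(unname(dec$counts[c("hit", "false_positive_wrong_item",
                                   "false_negative",
                                   "correct_rejection",
                                   "false_positive_unrecognizing")]),
               c(1L, 1L, 1L, 1L, 1L))
  expect_equal(sum(dec$counts), length(truth))
  expect_equal(dec$rates[["hit_rate"]], 100 / 3)
  expect_equal(dec$rates[["wrong_item_rate"]], 100 / 3)
  expect_equal(dec$rates[["correct_rejection_rate"]], 50)
  expect_equal(dec$rates[["false_alarm_rate"]], 50)
  expect_equal(dec$rates[["inconclusive_rate"]], 100 * 2 / 7)
})

test_that("cohort AUC never decreases as the simulated effect grows", {
  aucs <- vapply(c(0, 0.5, 1.5), function(dl) {
    cfg <- cit_synthetic_config(
      n_recognizing = 150, n_unrecognizing = 150,
      delta = c(SCR = dl, HR = dl, RLL = dl, NPV = dl),
      nonresponder_prob = 0, seed = 62)
    coh <- simulate_cit_cohort(cfg)
    d <- vapply(coh$sessions, function(s) cit_d(s)$integrated_d, numeric(1))
    roc_auc(d, coh$truth$recognizing)
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})
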