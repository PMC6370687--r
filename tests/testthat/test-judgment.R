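test_that("every published preset partitions the score axis as printed", {
  check_bands <- function(preset, rec_vals, inc_vals, unrec_vals,
                          judge = function(v, cfg) judge_known(v, cfg)$label) {
    cfg <- cit_preset(preset)
    for (v in rec_vals) expect_equal(judge(v, cfg), "recognized")
    for (v in inc_vals) expect_equal(judge(v, cfg), "inconclusive")
    for (v in unrec_vals) expect_equal(judge(v, cfg), "unrecognized")
  }
  # known-solution d: recognized > 0.4, unrecognized < 0
  check_bands("known_d", c(0.401, 0.5, 2), c(0, 0.2, 0.4, 0.399),
              c(-0.001, -1))
  # lenient d: 0.3 / 0.1
  check_bands("known_d_lenient", c(0.301, 1), c(0.1, 0.2, 0.3),
              c(0.099, -0.5))
  # known-solution p: recognized < 0.025, unrecognized > 0.6
  check_bands("known_p", c(0.001, 0.024), c(0.025, 0.1, 0.6), c(0.601, 0.7))
  # lenient p: 0.05 / 0.4
  check_bands("known_p_lenient", c(0.049), c(0.05, 0.2, 0.4), c(0.401, 1))
  # boundary values are always inconclusive
  expect_equal(judge_known(0.4, cit_preset("known_d"))$label, "inconclusive")
  expect_equal(judge_known(0, cit_preset("known_d"))$label, "inconclusive")
  expect_equal(judge_known(0.025, cit_preset("known_p"))$label,
               "inconclusive")
  expect_equal(judge_known(0.6, cit_preset("known_p"))$label, "inconclusive")
})

test_that("judgment is monotone in the statistic", {
  ord <- c(recognized = 3, inconclusive = 2, unrecognized = 1)
  grid <- seq(-1, 1.5, by = 0.01)
  lab_d <- ord[vapply(grid, function(v)
    judge_known(v, cit_preset("known_d"))$label, character(1))]
  expect_true(all(diff(lab_d) >= 0))
  pgrid <- seq(0.001, 1, by = 0.001)
  lab_p <- ord[vapply(pgrid, function(v)
    judge_known(v, cit_preset("known_p"))$label, character(1))]
  expect_true(all(diff(lab_p) <= 0))
})

test_that("known-solution judging rejects searching configs and vice versa", {
  expect_error(judge_known(0.5, cit_preset("searching_d")),
               "known-solution")
  sc <- data.frame(item = 1:2, label = c("a", "b"),
                   integrated_d = c(0.7, 0), integrated_p = c(0.01, 0.5))
  expect_error(judge_searching(sc, cit_preset("known_d")), "searching")
  expect_error(cit_judgment_config("known_solution", "d", 0.1, 0.4),
               ">=")
})

test_that("conjunctive d-and-p judgment requires agreement", {
  expect_equal(judge_both(0.5, 0.01)$label, "recognized")
  expect_equal(judge_both(-0.2, 0.9)$label, "unrecognized")
  expect_equal(judge_both(0.5, 0.9)$label, "inconclusive")
  expect_equal(judge_both(-0.2, 0.01)$label, "inconclusive")
  expect_equal(judge_both(0.2, 0.3)$label, "inconclusive")
})

test_that("searching judgment uses the extremal item with attribution", {
  sc <- data.frame(item = 1:5, label = paste0("it", 1:5),
                   integrated_d = c(0.1, 0.7, 0.3, -0.2, 0.5),
                   integrated_p = c(0.5, 0.004, 0.2, 0.9, 0.05))
  jd <- judge_searching(sc, cit_preset("searching_d"))
  expect_equal(jd$label, "recognized")
  expect_equal(jd$identified_item, 2L)
  jp <- judge_searching(sc, cit_preset("searching_p"))
  expect_equal(jp$label, "recognized")
  expect_equal(jp$identified_item, 2L)
  # middle band: no item is identified
  sc$integrated_d <- c(0.1, 0.4, 0.3, -0.2, 0.35)
  jmid <- judge_searching(sc, cit_preset("searching_d"))
  expect_equal(jmid$label, "inconclusive")
  expect_true(is.na(jmid$identified_item))
  # low band (all items tied, which also triggers the tie warning)
  sc$integrated_d <- rep(0.1, 5)
  expect_warning(jlow <- judge_searching(sc, cit_preset("searching_d")),
                 "tie")
  expect_equal(jlow$label, "unrecognized")
  # boundary of the searching bands is inconclusive
  sc$integrated_d <- c(0.6, 0, 0, 0, 0)
  expect_equal(judge_searching(sc, cit_preset("searching_d"))$label,
               "inconclusive")
  # exact tie for the extremum: lowest index wins, with a warning
  sc$integrated_d <- c(0.1, 0.8, 0.8, 0.1, 0.1)
  expect_warning(jt <- judge_searching(sc, cit_preset("searching_d")),
                 "tie")
  expect_equal(jt$identified_item, 2L)
})

test_that("searching scores identify an injected effect", {
  withr::with_seed(41, {
    hits <- 0L
    for (k in 1:8) {
      s <- random_session(relevant = 3, shift = 3)
      s$relevant <- NA_integer_
      sc <- searching_scores(s, B = 300, seed = 500 + k)
      if (which.max(sc$integrated_d) == 3) hits <- hits + 1L
      expect_equal(which.min(sc$integrated_p), which.max(sc$integrated_d))
    }
    expect_gte(hits, 7L)  # shift = 3 SD: identification nearly certain
  })
})

test_that("under an exchangeable null the argmax item is uniform", {
  withr::with_seed(42, {
    n_sim <- 400
    argmax <- integer(n_sim)
    for (k in 1:n_sim) {
      m <- matrix(rnorm(25), 5, 5)
      s <- cit_session(list(SCR = m))
      d_i <- vapply(1:5, function(i) effect_size_d(s, "SCR", i), numeric(1))
      argmax[k] <- which.max(d_i)
    }
    tab <- tabulate(argmax, 5)
    expect_gt(stats::chisq.test(tab)$p.value, 0.001)
  })
})

test_that("searching d and p share one relabeling draw across items", {
  s <- random_session(seed = 43, shift = 1)
  s$relevant <- NA_integer_
  a <- searching_scores(s, B = 200, seed = 7)
  b <- searching_scores(s, B = 200, seed = 7)
  expect_identical(a, b)
})
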