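test_that("relabelings are uniform subsets, reproducible, and enumerable", {
  r <- cit_relabelings(5, 5, B = 100, seed = 1, exhaustive = FALSE)
  expect_equal(dim(r$idx), c(100, 5))
  expect_true(all(r$idx >= 1 & r$idx <= 25))
  expect_true(all(apply(r$idx, 1, anyDuplicated) == 0))
  expect_false(r$exhaustive)
  # reproducibility from seed; a single draw is deterministic
  r2 <- cit_relabelings(5, 5, B = 100, seed = 1, exhaustive = FALSE)
  expect_identical(r$idx, r2$idx)
  expect_identical(cit_relabelings(5, 5, B = 1, seed = 9,
                                   exhaustive = FALSE)$idx,
                   cit_relabelings(5, 5, B = 1, seed = 9,
                                   exhaustive = FALSE)$idx)
  # exhaustive 3 items x 2 reps: all C(6, 2) = 15 subsets, auto-selected
  re <- cit_relabelings(3, 2)
  expect_true(re$exhaustive)
  expect_equal(re$B, 15)
  expect_equal(nrow(unique(re$idx)), 15)
  # the 5x5 space exceeds the default cap, so Monte-Carlo is selected
  expect_false(cit_relabelings(5, 5, B = 10, seed = 2)$exhaustive)
  expect_error(cit_relabelings(5, 5, exhaustive = TRUE), "cap")
})

test_that("the rank rule maps a 50th-largest difference to p = 0.05", {
  gen <- (1:1000) / 1000
  # real sits between the 49th and 50th largest generated difference:
  # 49 generated are strictly larger, so the real is the 50th largest
  r <- rank_to_p(0.9515, gen, direction = 1)
  expect_identical(r$x, 50L)
  expect_equal(r$p, 0.05)
  # direction -1: 49 strictly smaller -> 50th smallest
  r2 <- rank_to_p(0.0495, gen, direction = -1)
  expect_equal(r2$p, 0.05)
  # beating every generated difference floors at p = 1/B, never 0
  expect_equal(rank_to_p(2, gen, direction = 1)$p, 1 / 1000)
  # fully tied differences are maximally conservative
  expect_equal(rank_to_p(0, rep(0, 1000), direction = 1)$p, 1)
})

test_that("per-measure p agrees with the recorded rank and the tie rule", {
  s <- random_session(seed = 21, shift = 1.2)
  relab <- cit_relabelings(5, 5, B = 500, seed = 4, exhaustive = FALSE)
  for (ms in names(s$responses)) {
    res <- randomization_p(s$responses[[ms]], s$relevant, relab,
                           s$directions[ms])
    expect_equal(res$p, res$x / 500)
    # independent recount from the returned generated differences
    dir <- s$directions[[ms]]
    recount <- 1 + sum(dir * res$generated_differences >=
                         dir * res$real_difference)
    expect_equal(res$x, min(recount, 500))
  }
  # constant data: every generated difference ties the real one
  const <- matrix(3, 5, 5)
  expect_equal(randomization_p(const, 1, relab, 1)$p, 1)
})

test_that("exhaustive p matches an independent brute-force enumeration", {
  withr::with_seed(22, {
    for (k in 1:25) {
      n_items <- sample(c(3, 4), 1)
      n_reps <- if (n_items == 3) 2 else 3
      dir <- sample(c(-1, 1), 1)
      m <- matrix(rnorm(n_items * n_reps), n_items, n_reps)
      rel <- sample(n_items, 1)
      relab <- cit_relabelings(n_items, n_reps, exhaustive = TRUE)
      got <- randomization_p(m, rel, relab, dir)$p
      expect_equal(got, brute_force_exhaustive_p(m, rel, dir))
    }
  })
})

test_that("Monte-Carlo p converges to the exhaustive p", {
  withr::with_seed(23, {
    for (k in 1:10) {
      m <- matrix(rnorm(12), 4, 3)
      relab_ex <- cit_relabelings(4, 3, exhaustive = TRUE)
      p_ex <- randomization_p(m, 1, relab_ex, 1)$p
      B <- 4000
      relab_mc <- cit_relabelings(4, 3, B = B, seed = 100 + k,
                                  exhaustive = FALSE)
      p_mc <- randomization_p(m, 1, relab_mc, 1)$p
      se <- sqrt(p_ex * (1 - p_ex) / B)
      expect_lt(abs(p_mc - p_ex), 3 * se + 2 / B)
    }
  })
})

test_that("integrated p reduces to the per-measure p for one measure", {
  withr::with_seed(24, {
    for (k in 1:10) {
      s <- random_session(measures = c(SCR = 1), shift = runif(1, 0, 1.5))
      res <- cit_p(s, B = 1000, seed = 200 + k)
      # continuous data: the rank-calibrated product of a single p is the
      # p itself up to the 1/B granularity of self-inclusive ranking
      expect_lt(abs(res$integrated_p - res$per_measure_p[["SCR"]]),
                2 / res$B + 1e-12)
    }
  })
})

test_that("integrated p is deterministic given (session, B, seed)", {
  s <- random_session(seed = 25, shift = 0.8)
  r1 <- cit_p(s, B = 300, seed = 77)
  r2 <- cit_p(s, B = 300, seed = 77)
  expect_identical(r1[c("per_measure_p", "per_measure_x", "integrated_p",
                        "integrated_x", "original_multiplied_p")],
                   r2[c("per_measure_p", "per_measure_x", "integrated_p",
                        "integrated_x", "original_multiplied_p")])
  expect_equal(r1$integrated_p, r1$integrated_x / r1$B)
  expect_gte(r1$integrated_p, 1 / r1$B)
  expect_lte(r1$integrated_p, 1)
})

test_that("all-constant measures give integrated p = 1", {
  s <- cit_session(list(SCR = matrix(1, 5, 5), HR = matrix(2, 5, 5)),
                   relevant = 1)
  res <- cit_p(s, B = 200, seed = 1)
  expect_equal(unname(res$per_measure_p), c(1, 1))
  expect_equal(res$integrated_p, 1)
})

test_that("raising relevant responses never increases p (fixed relabelings)", {
  withr::with_seed(26, {
    relab <- cit_relabelings(5, 5, B = 400, seed = 5, exhaustive = FALSE)
    for (k in 1:10) {
      m <- matrix(rnorm(25), 5, 5)
      p_prev <- Inf
      for (bump in c(0, 0.5, 1, 2, 4)) {
        m2 <- m
        m2[2, ] <- m2[2, ] + bump
        p <- randomization_p(m2, 2, relab, 1)$p
        expect_lte(p, p_prev)
        p_prev <- p
      }
    }
  })
})

test_that("missing measures are skipped in the integration", {
  s4 <- random_session(seed = 27, shift = 1)
  s3 <- cit_session(s4$responses[c("HR", "RLL", "NPV")], items = s4$items,
                    relevant = s4$relevant)
  relab <- cit_relabelings(5, 5, B = 300, seed = 6, exhaustive = FALSE)
  r4 <- cit_p(s4, relabelings = relab)
  r3 <- cit_p(s3, relabelings = relab)
  expect_named(r3$per_measure_p, c("HR", "RLL", "NPV"))
  expect_equal(r3$per_measure_p, r4$per_measure_p[c("HR", "RLL", "NPV")])
  expect_equal(r3$original_multiplied_p,
               prod(r4$per_measure_p[c("HR", "RLL", "NPV")]))
})
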