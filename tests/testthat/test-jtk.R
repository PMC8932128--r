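test_that("templates evaluate the cosine at true sample times with mid-ranks, deduplicated", {
  d <- sampling_design(c(0, 6, 12, 18), period = 24, unit = "h")
  tp <- build_templates(d, phase_step = 6)
  # cos at 0,6,12,18 h is (1, 0, -1, 0): mid-ranks 4, 2.5, 1, 2.5
  expect_equal(tp$patterns[[1]], c(4, 2.5, 1, 2.5))
  expect_lte(tp$group_count, 4L)
  # no two retained patterns identical
  keys <- vapply(tp$patterns, paste, character(1), collapse = ",")
  expect_false(anyDuplicated(keys) > 0)

  # phase_step = period -> exactly one template
  one <- build_templates(d, phase_step = 24)
  expect_equal(one$group_count, 1L)

  # offsets differing by a whole period yield the same pattern (dedup check
  # via a step that wraps the period exactly)
  fine <- build_templates(d, phase_step = 1)
  expect_equal(fine$group_count, length(unique(vapply(fine$patterns, paste,
                                                      character(1), collapse = ","))))
  expect_true(all(fine$offsets < 24))

  expect_error(build_templates(sampling_design(c(0, 1), period = 2)), "at least 3")
  expect_error(build_templates(d, phase_step = 0), "phase_step")
})

test_that("tau-b matches hand computation, perfect concordance cases and stats::cor", {
  expect_equal(kendall_tau_b(c(1, 2, 3, 4), c(10, 20, 30, 40)), 1)
  expect_equal(kendall_tau_b(c(1, 2, 3, 4), c(40, 30, 20, 10)), -1)
  expect_equal(kendall_tau_b(c(3, 1, 2), c(1, 2, 3)), -1 / 3)
  expect_true(is.na(kendall_tau_b(c(2, 2, 2), c(1, 2, 3))))

  withr::with_seed(14, {
    for (i in 1:30) {
      n <- sample(4:15, 1)
      x <- sample(1:5, n, replace = TRUE) + 0 # ties likely
      y <- sample(1:4, n, replace = TRUE) + 0
      if (length(unique(x)) == 1L || length(unique(y)) == 1L) next
      expect_equal(kendall_tau_b(x, y),
                   suppressWarnings(stats::cor(x, y, method = "kendall")),
                   tolerance = 1e-12)
    }
  })
})

test_that("exact JTK p-values equal the exhaustive permutation oracle for small n", {
  withr::with_seed(20, {
    for (n in 5:7) {
      d <- sampling_design(seq(0, by = 4, length.out = n), period = 24, unit = "h")
      tp <- build_templates(d)
      for (i in 1:8) {
        x <- rnorm(n)
        expect_equal(jtk_pvalue(x, tp), jtk_brute_oracle(x, tp), tolerance = 1e-12)
      }
    }
  })
})

test_that("exact mode matches the 720-permutation oracle for tied profiles at n = 6", {
  d <- sampling_design(seq(0, 20, by = 4), period = 24, unit = "h")
  tp <- build_templates(d)
  withr::with_seed(21, {
    for (i in 1:10) {
      x <- sample(1:3, 6, replace = TRUE) + 0
      if (length(unique(x)) == 1L) next
      expect_equal(jtk_pvalue(x, tp), jtk_brute_oracle(x, tp), tolerance = 1e-12)
    }
  })
})

test_that("a noiseless template-matching profile attains the Bonferroni-adjusted minimum p", {
  d <- sampling_design(seq(0, 20, by = 4), period = 24, unit = "h")
  tp <- build_templates(d)
  x <- cos(2 * pi * d$times / 24) + seq(0, 1e-6, length.out = 6) # break exact ties
  p <- jtk_pvalue(x, tp)
  # oracle: the minimal attainable tail at the best template, Bonferroni-scaled
  p_min <- min(vapply(tp$patterns, function(r) {
    perms <- gtools_perms(6)
    s_all <- apply(perms, 1L, function(pm) kendall_s_oracle(x[pm], r))
    s_obs <- kendall_s_oracle(x, r)
    mean(s_all >= s_obs - 1e-9)
  }, numeric(1)))
  expect_equal(p, min(1, p_min * tp$group_count), tolerance = 1e-12)
})

test_that("degenerate and invariance properties of the JTK p-value hold", {
  d <- yeast_ma_design()
  tp <- build_templates(d)
  expect_equal(jtk_pvalue(rep(2, 16), tp), 1)
  withr::with_seed(22, {
    for (i in 1:10) {
      x <- rnorm(16)
      p <- jtk_pvalue(x, tp)
      expect_equal(jtk_pvalue(x + 100, tp), p, tolerance = 1e-12)
      expect_equal(jtk_pvalue(3 * x, tp), p, tolerance = 1e-12)
    }
  })
})

test_that("time reversal preserves the minimal p over a phase-symmetric template grid", {
  # 96 h period sampled every 16 h: offsets {0,16,...,80} form a mirror-
  # symmetric phase grid, so reversing a profile in time maps template hits
  # to mirrored phases without changing the minimum
  d <- sampling_design(seq(0, 240, by = 16), period = 96, unit = "min")
  tp <- build_templates(d)
  withr::with_seed(23, {
    for (i in 1:10) {
      x <- rnorm(16)
      expect_equal(jtk_pvalue(rev(x), tp), jtk_pvalue(x, tp), tolerance = 1e-9)
    }
  })
})

test_that("one-template null p-values are uniform or super-uniform", {
  d <- yeast_ma_design()
  tp1 <- build_templates(d, phase_step = d$period) # single template
  ps <- withr::with_seed(24, replicate(4000, jtk_pvalue(rnorm(16), tp1)))
  for (alpha in c(0.01, 0.05, 0.1, 0.25)) {
    mc_se <- sqrt(alpha * (1 - alpha) / 4000)
    expect_lte(mean(ps <= alpha), alpha + 3 * mc_se)
  }
})

test_that("exact and approximate modes agree closely at n = 20", {
  d <- sampling_design(seq(0, 76, by = 4), period = 24, unit = "h")
  tp <- build_templates(d)
  diffs <- withr::with_seed(25, replicate(1000, {
    x <- rnorm(20)
    jtk_pvalue(x, tp, n_exact = 25) - jtk_pvalue(x, tp, n_exact = 0)
  }))
  expect_lt(max(abs(diffs)), 0.005)
})
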