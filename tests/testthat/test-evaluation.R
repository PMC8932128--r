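make_ranked <- function(ids, scores, direction = "ascending") {
  rank_genes(tibble::tibble(gene_id = ids, m = scores), "m", direction)
}

test_that("AP of a perfect ranking is exactly 1 and of small cases matches hand computation", {
  ids <- sprintf("g%03d", 1:307)
  labels <- label_set(ids, ids[1:17])
  perfect <- make_ranked(ids, 1:307)
  res <- average_precision(perfect, labels)
  expect_identical(res$average_precision, 1)
  expect_equal(res$baseline, 17 / 307)

  # labels (+, -, +) in ranked order: AP = (1/2)(1 + 2/3) = 5/6
  lab3 <- label_set(c("a", "b", "c"), c("a", "c"))
  expect_equal(average_precision(make_ranked(c("a", "b", "c"), 1:3), lab3)$average_precision,
               5 / 6)
})

test_that("tie policies bracket AP and the expected policy matches a Monte-Carlo oracle", {
  withr::with_seed(41, {
    for (trial in 1:6) {
      n <- 60
      ids <- sprintf("g%02d", 1:n)
      ranked <- make_ranked(ids, sample(1:6, n, replace = TRUE))
      labels <- label_set(ids, sample(ids, 8))
      res <- average_precision(ranked, labels)
      expect_lte(res$ap_pessimistic, res$ap_expected + 1e-12)
      expect_lte(res$ap_expected, res$ap_optimistic + 1e-12)
      mc <- ap_shuffle_oracle(ranked, labels$positives, 5000, seed = trial)
      expect_lt(abs(res$ap_expected - mc), 0.005)
    }
  })
})

test_that("AP is invariant under strictly monotone transforms of the scores", {
  withr::with_seed(42, {
    ids <- sprintf("g%03d", 1:100)
    sc <- sample(c(0.01, 0.1, 0.5, 1), 100, replace = TRUE)
    labels <- label_set(ids, sample(ids, 10))
  })
  a1 <- average_precision(make_ranked(ids, sc), labels)$average_precision
  a2 <- average_precision(make_ranked(ids, log(sc)), labels)$average_precision
  a3 <- average_precision(make_ranked(ids, 1 / sc, "descending"), labels)$average_precision
  expect_equal(a1, a2)
  expect_equal(a1, a3)
})

test_that("PR curves behave correctly at the extremes of tie structure", {
  ids <- sprintf("g%03d", 1:307)
  labels <- label_set(ids, ids[1:17])

  perfect <- make_ranked(ids, 1:307)
  pc <- pr_curve(perfect, labels)
  expect_true(all(pc$precision[pc$recall <= 1 & seq_len(nrow(pc)) <= 17] == 1))
  expect_equal(max(pc$recall), 1)
  expect_true(all(diff(pc$recall) >= 0))

  # a single global tie block: every expected precision equals C/N
  tied <- make_ranked(ids, rep(1, 307))
  pc_tied <- pr_curve(tied, labels)
  expect_true(all(abs(pc_tied$precision - 17 / 307) < 1e-12))

  # pessimistic policy on the tied ranking: first positive after all negatives
  pc_pess <- pr_curve(tied, labels, "pessimistic")
  expect_equal(pc_pess$precision[1], 1 / (307 - 17 + 1))
})

test_that("the expected PR height of a random classifier is the base rate C/N", {
  # exact statement behind the random baseline: at any fixed prefix depth the
  # expected precision is C/N; verified by averaging precision at depth k
  # over label shuffles
  withr::with_seed(43, {
    ids <- sprintf("g%03d", 1:100)
    ranked <- make_ranked(ids, 1:100)
    prec_at_20 <- replicate(4000, {
      labels <- sample(ids, 9)
      mean(ranked$gene_id[1:20] %in% labels)
    })
  })
  expect_lt(abs(mean(prec_at_20) - 9 / 100), 3 * stats::sd(prec_at_20) / sqrt(4000))
})

test_that("recall@k counts positives in the prefix with tie-aware sharing", {
  # 13 of 17 positives in the top 25 -> recall 76.5%
  ids <- sprintf("g%03d", 1:307)
  pos <- c(ids[1:13], ids[100:103])
  labels <- label_set(ids, pos)
  ranked <- make_ranked(ids, 1:307)
  rec <- recall_at_k(ranked, labels, k = 25)
  expect_equal(rec$n_found, 13)
  expect_equal(round(100 * rec$recall, 1), 76.5)

  expect_equal(recall_at_k(ranked, labels, k = 307)$recall, 1)
  expect_equal(recall_at_k(ranked, labels, k = 400)$recall, 1)
  none <- label_set(ids, ids[300:305])
  expect_equal(recall_at_k(ranked, none, k = 25)$n_found, 0)

  # straddling tie block shares hypergeometrically under the expected policy
  tied <- make_ranked(ids, rep(1, 307))
  expect_equal(recall_at_k(tied, labels, k = 25)$n_found, 17 * 25 / 307)
  expect_equal(recall_at_k(tied, labels, k = 25, "optimistic")$n_found, 17)
  expect_equal(recall_at_k(tied, labels, k = 25, "pessimistic")$n_found, 0)
})

test_that("evaluation rejects degenerate or inconsistent inputs", {
  ids <- c("a", "b", "c")
  ranked <- make_ranked(ids, 1:3)
  expect_error(average_precision(ranked, label_set(ids, character(0))), "C = 0")
  expect_error(
    average_precision(ranked, label_set(c(ids, "zz"), "a")),
    "ZZ"
  )
  dup <- rank_genes(tibble::tibble(gene_id = c("a", "a", "b"), m = 1:3), "m", "ascending")
  expect_error(average_precision(dup, label_set(ids, "a")), "duplicate")
})

test_that("run_task resolves universes per task and warns on unmatched labels", {
  cfg <- sim_config(n_genes = 400, n_core = 8, n_output = 60, n_tf_extra = 52,
                    gamma = 0.4, seed = 44)
  sim <- simulate_dataset(cfg)
  sc <- score_profiles(sim$expression, n_null = 500, seed = 45)

  tf_task <- run_task(sc, core = sim$core$positives, tfs = sim$tfs$positives,
                      task = "core_in_tfs")
  all_task <- run_task(sc, core = sim$core$positives, task = "core_in_all")
  expect_equal(nrow(tf_task), 8L)
  expect_equal(unique(tf_task$n_universe), 60L)
  expect_equal(unique(all_task$n_universe), 400L)
  expect_equal(unique(all_task$baseline), 8 / 400)

  # smaller universe at equal positive count cannot lower ranking quality here
  for (metric in c("per_reg", "dl_jtk")) {
    expect_gte(tf_task$average_precision[tf_task$metric == metric],
               all_task$average_precision[all_task$metric == metric] - 1e-9)
  }

  expect_error(run_task(sc, core = sim$core$positives, tfs = character(0),
                        task = "core_in_tfs"), "non-empty TF list")
  expect_warning(
    run_task(sc, core = c(sim$core$positives, "NOSUCHGENE"), task = "core_in_all"),
    "NOSUCHGENE"
  )
})

test_that("tidy, glance and autoplot expose PR results", {
  ids <- sprintf("g%02d", 1:50)
  labels <- label_set(ids, ids[1:5])
  res <- average_precision(make_ranked(ids, 1:50), labels)
  expect_s3_class(tidy(res), "tbl_df")
  expect_named(tidy(res), c("recall", "precision"))
  g <- glance(res)
  expect_equal(g$average_precision, 1)
  expect_equal(g$n_positives, 5)
  expect_s3_class(autoplot(res), "ggplot")
})
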