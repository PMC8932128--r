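test_that("well-formed tables parse, preserving row order and duplicates", {
  d <- sampling_design(c(0, 16, 32), period = 94)
  path <- write_fixture_table(c(
    "gene\t0\t16\t32",
    "GA\t1.5\t2.5\t3.5",
    "GB\t0.1\t0.2\t0.3"
  ))
  m <- read_expression_table(path, d)
  expect_s3_class(m, "expr_mat")
  expect_equal(nrow(m), 2L)
  expect_equal(m$gene_id, c("GA", "GB"))
  expect_equal(unname(expr_values(m)[1, ]), c(1.5, 2.5, 3.5))

  # duplicate IDs are retained as distinct profiles pending collapse
  path2 <- write_fixture_table(c(
    "gene,0,16,32",
    "GA,1,1,1",
    "GA,2,2,2"
  ), ext = "csv")
  m2 <- read_expression_table(path2, d)
  expect_equal(m2$gene_id, c("GA", "GA"))
})

test_that("malformed tables raise informative parse/format errors", {
  d <- sampling_design(c(0, 16, 32), period = 94)
  bad_cell <- write_fixture_table(c("g\t0\t16\t32", "GA\t1\tNA\t3"))
  expect_error(read_expression_table(bad_cell, d), "parse error.*GA.*16")

  wrong_cols <- write_fixture_table(c("g\t0\t16", "GA\t1\t2"))
  expect_error(read_expression_table(wrong_cols, d), "format error")

  expect_error(
    expression_matrix(matrix(c(1, NA, 3, 4, 5, 6), 2), c("A", "B"), d),
    "non-finite"
  )
})

test_that("expression tables round-trip through write/read", {
  d <- yeast_ma_design()
  sim <- simulate_dataset(sim_config(n_genes = 30, n_core = 3, n_output = 5,
                                     n_tf_extra = 5, design = d, seed = 4))
  path <- tempfile(fileext = ".tsv")
  write_expression_table(sim$expression, path)
  back <- read_expression_table(path, d)
  expect_equal(back$gene_id, sim$expression$gene_id)
  expect_equal(expr_values(back), expr_values(sim$expression), tolerance = 1e-12)
})

test_that("low-expression filter removes profiles below floor in strictly more than half of timepoints", {
  d <- sampling_design(seq(0, 44, by = 4), period = 24, unit = "h") # 12 tp
  v <- rbind(
    c(rep(0.5, 7), rep(5, 5)),  # 7 of 12 below 1 -> removed
    c(rep(0.5, 6), rep(5, 6)),  # exactly half -> kept
    rep(2, 12)                  # all above -> kept
  )
  m <- expression_matrix(v, c("LOW", "EDGE", "HIGH"), d, modality = "rnaseq")
  f <- filter_low_expression(m)
  expect_equal(f$gene_id, c("EDGE", "HIGH"))
  expect_equal(attr(f, "removed")$gene_id, "LOW")
  expect_equal(attr(f, "removed")$n_below, 7L)

  # idempotent
  f2 <- filter_low_expression(f)
  expect_equal(expr_values(f2), expr_values(f))
  expect_equal(nrow(attr(f2, "removed")), 0L)

  # no-op with warning on microarray data
  ma <- expression_matrix(v, c("A", "B", "C"), d, modality = "microarray")
  expect_warning(fm <- filter_low_expression(ma), "RNA-seq")
  expect_equal(nrow(fm), 3L)
})

test_that("leading-timepoint removal truncates design and composes additively", {
  d <- sampling_design(seq(0, 150, by = 10), period = 75, unit = "min") # 16 tp
  m <- expression_matrix(matrix(rnorm(3 * 16), 3), c("A", "B", "C"), d)

  t2 <- drop_leading_timepoints(m, 2)
  expect_equal(length(expr_design(t2)$times), 14L)
  expect_equal(expr_design(t2)$times[1], d$times[3])
  expect_equal(expr_design(t2)$duration, d$times[16] - d$times[3])

  expect_equal(drop_leading_timepoints(m, 0), m)
  expect_error(drop_leading_timepoints(m, 16), "cannot drop")

  # composition: dropping a then b equals dropping a + b
  ab <- drop_leading_timepoints(drop_leading_timepoints(m, 3), 2)
  expect_equal(expr_values(ab), expr_values(drop_leading_timepoints(m, 5)))
  expect_equal(expr_design(ab)$times, expr_design(drop_leading_timepoints(m, 5))$times)
})

test_that("duplicate-probe collapse keeps the highest-mean profile, first on ties", {
  d <- sampling_design(c(0, 16, 32), period = 94)
  v <- rbind(
    c(3, 3, 3.6),   # GA mean 3.2
    c(5, 5, 5.3),   # GA mean 5.1 -> kept
    c(1, 2, 3),     # GB single -> unchanged
    c(2, 2, 2),     # GC mean 2 (first) -> kept on tie
    c(1, 2, 3)      # GC mean 2
  )
  m <- expression_matrix(v, c("GA", "GA", "GB", "GC", "GC"), d)
  cc <- collapse_duplicate_profiles(m)
  expect_equal(cc$gene_id, c("GA", "GB", "GC"))
  expect_equal(unname(expr_values(cc)["GA", ]), c(5, 5, 5.3))
  expect_equal(unname(expr_values(cc)["GC", ]), c(2, 2, 2))
  expect_false(anyDuplicated(cc$gene_id) > 0)
  expect_lte(nrow(cc), nrow(m))
  expect_equal(sum(attr(cc, "collapsed")$n_removed), 2L)
})

test_that("timepoints per cycle reproduces the benchmark design ratios exactly", {
  designs <- list(
    list(period = 75, interval = 5, tpc = 15),
    list(period = 94, interval = 16, tpc = 5.875),
    list(period = 24, interval = 2, tpc = 12),
    list(period = 24, interval = 6, tpc = 4),
    list(period = 24, interval = 4, tpc = 6)
  )
  for (ds in designs) {
    d <- sampling_design(seq(0, by = ds$interval, length.out = 8),
                         period = ds$period)
    expect_identical(timepoints_per_cycle(d), ds$tpc)
    # invariant to simultaneous unit rescaling (minutes -> hours)
    d_h <- sampling_design(seq(0, by = ds$interval / 60, length.out = 8),
                           period = ds$period / 60, unit = "h")
    expect_equal(timepoints_per_cycle(d_h), ds$tpc, tolerance = 1e-12)
  }
})

test_that("gene lists parse with comments and label sets validate", {
  path <- write_fixture_table(c("# core genes", "swi5 ", "", "ACE2  # G1/S", "yox1"))
  ids <- read_gene_list(path)
  expect_equal(ids, c("SWI5", "ACE2", "YOX1"))

  expect_error(label_set(c("A", "B"), c("A", "C")), "not contained")
  ls <- label_set(c("a", "b", "c"), "B")
  expect_equal(ls$positives, "B")
  expect_warning(match_gene_ids(c("A", "ZZZ"), c("a", "b")), "not present")
})

test_that("preprocessing pipeline reports row counts per stage", {
  cfg <- sim_config(n_genes = 200, n_core = 5, n_output = 20, n_tf_extra = 10,
                    modality = "rnaseq", duplicate_probe_fraction = 0.05,
                    low_expression_fraction = 0.1, seed = 21)
  sim <- simulate_dataset(cfg)
  pp <- preprocess_expression(sim$expression)
  rep <- attr(pp, "report")
  expect_equal(rep$rows_read, nrow(sim$expression))
  expect_equal(rep$rows_read - rep$removed_low_expression - rep$removed_duplicate_probes,
               rep$rows_out)
  expect_false(anyDuplicated(pp$gene_id) > 0)
  # log2(FPKM + 1) applied after filtering
  expect_true(all(expr_values(pp) >= 0))
})
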