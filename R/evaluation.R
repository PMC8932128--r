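#' @importFrom rlang .data
NULL

# Per-tie-block bookkeeping for a ranking restricted to a label universe.
# Returns a tibble with one row per block: size b, positives c, items before s,
# positives before r_before.
block_summary <- function(ranked, labels) {
  stopifnot(is.data.frame(ranked), inherits(labels, "label_set"))
  ids <- toupper(ranked$gene_id)
  if (anyDuplicated(ids) > 0L) {
    stop("ranking contains duplicate gene IDs; collapse duplicates before evaluation.",
         call. = FALSE)
  }
  missing <- setdiff(labels$universe, ids)
  if (length(missing) > 0L) {
    stop(sprintf(
      "universe/ranking mismatch: %d universe gene(s) missing a score (e.g. %s).",
      length(missing), paste(utils::head(missing, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  keep <- ids %in% labels$universe
  score <- ranked$score[keep]
  pos <- ids[keep] %in% labels$positives
  if (!any(pos)) stop("undefined AP: the label set has no positives (C = 0).", call. = FALSE)
  # re-derive maximal equal-score runs after restriction to the universe
  new_block <- c(TRUE, score[-1L] != score[-length(score)])
  block <- cumsum(new_block)
  b <- tabulate(block)
  c_pos <- as.vector(rowsum(as.numeric(pos), block))
  tibble::tibble(
    block = seq_along(b),
    b = b,
    c = c_pos,
    s = c(0, cumsum(b)[-length(b)]),
    r_before = c(0, cumsum(c_pos)[-length(c_pos)])
  )
}

# AP under a tie policy, vectorized over one position-expanded pass.
ap_from_blocks <- function(blocks, policy) {
  total_pos <- sum(blocks$c)
  nz <- blocks[blocks$c > 0, , drop = FALSE]
  b <- rep(nz$b, nz$b)
  c <- rep(nz$c, nz$b)
  s <- rep(nz$s, nz$b)
  r0 <- rep(nz$r_before, nz$b)
  i <- sequence(nz$b)
  contrib <- switch(policy,
    expected = {
      interleave <- ifelse(b == 1L, 0, (c - 1) * (i - 1) / (b - 1))
      (c / b) * (r0 + 1 + interleave) / (s + i)
    },
    pessimistic = {
      j <- i - (b - c) # index among block positives when > 0
      ifelse(j > 0, (r0 + j) / (s + i), 0)
    },
    optimistic = ifelse(i <= c, (r0 + i) / (s + i), 0)
  )
  sum(contrib) / total_pos
}

curve_from_blocks <- function(blocks, policy) {
  total_pos <- sum(blocks$c)
  nz <- blocks[blocks$c > 0, , drop = FALSE]
  if (policy == "expected") {
    b <- rep(nz$b, nz$b)
    c <- rep(nz$c, nz$b)
    s <- rep(nz$s, nz$b)
    r0 <- rep(nz$r_before, nz$b)
    i <- sequence(nz$b)
    cum <- r0 + c * i / b
    tibble::tibble(recall = cum / total_pos, precision = cum / (s + i))
  } else {
    # materialized within-block order: negatives first (pessimistic) or
    # positives first (optimistic)
    nc <- as.integer(nz$c)
    b <- rep(nz$b, nc)
    c <- rep(nz$c, nc)
    s <- rep(nz$s, nc)
    r0 <- rep(nz$r_before, nc)
    j <- sequence(nc)
    pos_at <- if (policy == "pessimistic") s + b - c + j else s + j
    tibble::tibble(recall = (r0 + j) / total_pos, precision = (r0 + j) / pos_at)
  }
}

#' Average precision of a tie-aware ranking
#'
#' Non-interpolated average precision: the mean, over positives, of the
#' precision at each positive's rank. A perfect ranking (all positives above
#' all negatives) has AP exactly 1; a uniformly random ranking has expected
#' AP equal to the base rate `C/N`, which is reported as `baseline`.
#'
#' Tie blocks — typically produced by repeated empirical p-values — are
#' handled by `tie_policy`:
#' * `"expected"` (default): the closed-form expectation of AP over uniformly
#'   random orderings within each block, so ambiguous rankings can neither
#'   overstate nor understate the metric;
#' * `"pessimistic"`: every negative in a block precedes every positive
#'   (lower bound);
#' * `"optimistic"`: the reverse (upper bound).
#'
#' All three values are always computed and returned; `tie_policy` selects
#' which one is the headline `average_precision` and which curve is stored.
#'
#' @param ranked A ranking from [rank_genes()] (needs `gene_id` and `score`
#'   columns, ordered best-first). Genes outside the label universe are
#'   ignored; universe genes missing from the ranking are an error.
#' @param labels A [label_set()].
#' @param tie_policy `"expected"`, `"pessimistic"` or `"optimistic"`.
#' @return An object of class `pr_result`; see [tidy.pr_result()] and
#'   [glance.pr_result()].
#' @export
average_precision <- function(ranked, labels,
                              tie_policy = c("expected", "pessimistic", "optimistic")) {
  tie_policy <- match.arg(tie_policy)
  blocks <- block_summary(ranked, labels)
  aps <- vapply(c("pessimistic", "expected", "optimistic"),
                function(p) ap_from_blocks(blocks, p), numeric(1))
  n_pos <- sum(blocks$c)
  n_universe <- sum(blocks$b)
  structure(
    list(
      curve = curve_from_blocks(blocks, tie_policy),
      average_precision = aps[[tie_policy]],
      ap_pessimistic = aps[["pessimistic"]],
      ap_expected = aps[["expected"]],
      ap_optimistic = aps[["optimistic"]],
      baseline = n_pos / n_universe,
      n_positives = n_pos,
      n_universe = n_universe,
      tie_policy = tie_policy,
      metric = attr(ranked, "metric"),
      label_name = labels$name
    ),
    class = "pr_result"
  )
}

#' Precision-recall curve of a tie-aware ranking
#'
#' One `(recall, precision)` point per ranking prefix ending on a positive;
#' inside tie blocks the expected-value analogue is emitted under the
#' `"expected"` policy (for a ranking that is a single tie block every
#' precision equals the base rate `C/N`), or the block is materialized
#' worst-first / best-first under `"pessimistic"` / `"optimistic"`.
#'
#' @inheritParams average_precision
#' @return A tibble with columns `recall` and `precision`.
#' @export
pr_curve <- function(ranked, labels,
                     tie_policy = c("expected", "pessimistic", "optimistic")) {
  tie_policy <- match.arg(tie_policy)
  curve_from_blocks(block_summary(ranked, labels), tie_policy)
}

#' Recall among the top k candidates
#'
#' The fraction (and count) of all positives found in the first `k` ranked
#' candidates. A tie block straddling position `k` contributes its expected
#' (hypergeometric) share of positives under the `"expected"` policy, or its
#' worst/best case under `"pessimistic"` / `"optimistic"`.
#'
#' @inheritParams average_precision
#' @param k Prefix size (e.g. 25 for a top-25 shortlist).
#' @return A one-row tibble with columns `k`, `n_found`, `recall`.
#' @export
recall_at_k <- function(ranked, labels, k = 25L,
                        tie_policy = c("expected", "pessimistic", "optimistic")) {
  tie_policy <- match.arg(tie_policy)
  if (k < 1L) stop("`k` must be at least 1.", call. = FALSE)
  blocks <- block_summary(ranked, labels)
  n_pos <- sum(blocks$c)
  n_universe <- sum(blocks$b)
  if (k >= n_universe) {
    return(tibble::tibble(k = as.integer(k), n_found = as.numeric(n_pos), recall = 1))
  }
  ends <- cumsum(blocks$b)
  idx <- which(ends >= k)[1L]
  full <- if (idx > 1L) sum(blocks$c[seq_len(idx - 1L)]) else 0L
  b <- blocks$b[idx]; c <- blocks$c[idx]; s <- blocks$s[idx]
  m <- k - s
  part <- switch(tie_policy,
    expected = c * m / b,
    pessimistic = max(0, m - (b - c)),
    optimistic = min(c, m)
  )
  n_found <- full + part
  tibble::tibble(k = as.integer(k), n_found = n_found, recall = n_found / n_pos)
}

#' @export
print.pr_result <- function(x, ...) {
  cat(sprintf(
    "<pr_result%s> AP (%s) = %.4f [pessimistic %.4f, optimistic %.4f]; baseline C/N = %d/%d = %.4f\n",
    if (is.null(x$metric)) "" else paste0(" ", x$metric),
    x$tie_policy, x$average_precision, x$ap_pessimistic, x$ap_optimistic,
    x$n_positives, x$n_universe, x$baseline
  ))
  invisible(x)
}

#' Tidy a precision-recall result
#'
#' @param x A `pr_result` from [average_precision()].
#' @param ... Unused.
#' @return `tidy()`: the PR curve as a tibble with `recall` and `precision`.
#' @method tidy pr_result
#' @export
tidy.pr_result <- function(x, ...) x$curve

#' @rdname tidy.pr_result
#' @return `glance()`: a one-row tibble with the AP (all three tie policies),
#'   baseline and problem sizes.
#' @method glance pr_result
#' @export
glance.pr_result <- function(x, ...) {
  tibble::tibble(
    metric = x$metric %||% NA_character_,
    average_precision = x$average_precision,
    ap_pessimistic = x$ap_pessimistic,
    ap_expected = x$ap_expected,
    ap_optimistic = x$ap_optimistic,
    baseline = x$baseline,
    n_positives = x$n_positives,
    n_universe = x$n_universe,
    tie_policy = x$tie_policy
  )
}

#' Evaluate every ranking metric on a labelling task
#'
#' The three tasks mirror the pipeline's standard benchmarks:
#' `"core_in_tfs"` ranks core regulators among annotated transcription
#' factors, `"core_in_all"` among all scored genes, and `"tf_in_all"` ranks
#' TFs among all genes — the negative control on which periodicity/amplitude
#' metrics are expected to sit at the random baseline.
#'
#' @param scores A score table (from [score_profiles()]) containing `gene_id`
#'   and the eight metric columns of [ranking_metrics()].
#' @param core Character vector of core gene IDs.
#' @param tfs Character vector of TF gene IDs (required for `core_in_tfs`
#'   and `tf_in_all`).
#' @param task One of `"core_in_tfs"`, `"core_in_all"`, `"tf_in_all"`.
#' @param tie_policy Tie policy for the headline AP and for recall@k.
#' @param k Shortlist size for recall@k (default 25).
#' @return A tibble with one row per metric: AP under all three tie policies,
#'   the `C/N` baseline, recall@k, and the problem sizes.
#' @export
run_task <- function(scores, core, tfs = NULL,
                     task = c("core_in_tfs", "core_in_all", "tf_in_all"),
                     tie_policy = c("expected", "pessimistic", "optimistic"),
                     k = 25L) {
  task <- match.arg(task)
  tie_policy <- match.arg(tie_policy)
  stopifnot(is.data.frame(scores), "gene_id" %in% names(scores))
  scored_ids <- toupper(scores$gene_id)
  if (task %in% c("core_in_tfs", "tf_in_all")) {
    if (is.null(tfs) || length(tfs) == 0L) {
      stop(sprintf("task '%s' requires a non-empty TF list.", task), call. = FALSE)
    }
    tf_ids <- match_gene_ids(tfs, scored_ids, what = "TF")
  }
  labels <- switch(task,
    core_in_tfs = {
      core_ids <- match_gene_ids(core, tf_ids, what = "core")
      label_set(tf_ids, core_ids, name = "core")
    },
    core_in_all = {
      core_ids <- match_gene_ids(core, scored_ids, what = "core")
      label_set(scored_ids, core_ids, name = "core")
    },
    tf_in_all = label_set(scored_ids, tf_ids, name = "tf")
  )
  if (length(labels$positives) == 0L) {
    stop(sprintf("task '%s' has no resolvable positives.", task), call. = FALSE)
  }
  purrr::pmap_dfr(ranking_metrics(), function(metric, direction) {
    ranked <- rank_genes(scores, metric, direction)
    res <- average_precision(ranked, labels, tie_policy)
    rec <- recall_at_k(ranked, labels, k = k, tie_policy = tie_policy)
    tibble::tibble(
      task = task,
      metric = metric,
      direction = direction,
      average_precision = res$average_precision,
      ap_pessimistic = res$ap_pessimistic,
      ap_optimistic = res$ap_optimistic,
      baseline = res$baseline,
      recall_at_k = rec$recall,
      n_topk = rec$n_found,
      k = rec$k,
      n_positives = res$n_positives,
      n_universe = res$n_universe
    )
  })
}

#' Top-ranked candidates by a metric
#'
#' The shortlist an experimentalist would take to the bench: the first `k`
#' genes of a metric's ranking, flagged by core membership.
#'
#' @inheritParams run_task
#' @param metric Metric column to rank by.
#' @return A tibble with `rank`, `gene_id`, `score`, `is_core`.
#' @export
top_candidates <- function(scores, core, metric = "dl_jtk", k = 25L) {
  ranked <- rank_genes(scores, metric)
  core <- toupper(core)
  utils::head(ranked, k) |>
    dplyr::mutate(is_core = toupper(.data$gene_id) %in% core) |>
    dplyr::select("rank", "gene_id", "score", "is_core")
}
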