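#' Combined ranking metrics
#'
#' The three combined metrics rank candidate core regulators by joining a
#' periodicity signal with a regulation-strength (amplitude) signal:
#'
#' * `dl_combined(p_per, p_reg)` — the DL metric: the product of the two
#'   empirical p-values (smaller = stronger candidate);
#' * `dl_x_jtk(p_jtk, p_reg)` — the same product with the JTK rhythmicity
#'   p-value in place of the empirical periodicity p-value;
#' * `per_reg(per_score, reg_score)` — the product of the two naive scores
#'   (larger = stronger candidate); needs no resampling at all.
#'
#' All are vectorized.
#'
#' @param p_per,p_reg,p_jtk P-values in `(0, 1]`.
#' @param per_score,reg_score Nonnegative scores.
#' @return Numeric vector of combined scores.
#' @examples
#' dl_combined(0.001, 0.01) # 1e-5
#' per_reg(6, 1) # 6
#' @export
dl_combined <- function(p_per, p_reg) {
  check_pvals(p_per, "p_per")
  check_pvals(p_reg, "p_reg")
  p_per * p_reg
}

#' @rdname dl_combined
#' @export
dl_x_jtk <- function(p_jtk, p_reg) {
  check_pvals(p_jtk, "p_jtk")
  check_pvals(p_reg, "p_reg")
  p_jtk * p_reg
}

#' @rdname dl_combined
#' @export
per_reg <- function(per_score, reg_score) {
  if (any(!is.finite(per_score)) || any(per_score < 0) ||
      any(!is.finite(reg_score)) || any(reg_score < 0)) {
    stop("scores must be finite and nonnegative.", call. = FALSE)
  }
  per_score * reg_score
}

check_pvals <- function(p, name) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop(sprintf("`%s` must lie in (0, 1].", name), call. = FALSE)
  }
  invisible(p)
}

# The eight ranking metrics and whether smaller or larger values are stronger.
metric_directions <- c(
  per_score = "descending",
  p_per = "ascending",
  p_jtk = "ascending",
  reg_score = "descending",
  p_reg = "ascending",
  per_reg = "descending",
  dl = "ascending",
  dl_jtk = "ascending"
)

#' Names and sort directions of the ranking metrics
#'
#' @return A tibble with columns `metric` and `direction` (`"ascending"`
#'   means smaller-is-better, the convention for p-value products;
#'   `"descending"` means larger-is-better, for the naive scores).
#' @export
ranking_metrics <- function() {
  tibble::tibble(metric = names(metric_directions),
                 direction = unname(metric_directions))
}

#' Add the combined metrics to a score table
#'
#' @param scores A tibble with columns `per_score`, `reg_score`, `p_per`,
#'   `p_reg`, `p_jtk`.
#' @return The tibble with `per_reg`, `dl` and `dl_jtk` columns appended.
#' @export
add_combined_metrics <- function(scores) {
  dplyr::mutate(
    scores,
    per_reg = per_reg(.data$per_score, .data$reg_score),
    dl = dl_combined(.data$p_per, .data$p_reg),
    dl_jtk = dl_x_jtk(.data$p_jtk, .data$p_reg)
  )
}

#' Rank genes by a metric, grouping ties
#'
#' Produces a deterministic, tie-aware ranking: a stable sort by the metric in
#' its direction, with maximal runs of equal scores grouped into tie blocks.
#' Within a block the input order is kept for reproducibility, but that order
#' is arbitrary — downstream evaluation treats blocks as exchangeable, which
#' is exactly why tie blocks are exported. Repeated empirical p-values are the
#' main source of large blocks; enlarging the null ensemble disambiguates
#' them.
#'
#' @param data A data frame with a `gene_id` column and the metric column.
#' @param metric Name of the score column to rank by.
#' @param direction `"ascending"` (smaller-is-better) or `"descending"`;
#'   defaults to the standard direction for the known metrics
#'   (see [ranking_metrics()]).
#' @return A tibble with columns `gene_id`, `score`, `rank` (1-based min-rank
#'   within each tie block) and `tie_block` (1-based block index), ordered
#'   best-first. The metric and direction are carried as attributes.
#' @export
rank_genes <- function(data, metric, direction = NULL) {
  stopifnot(is.data.frame(data), metric %in% names(data), "gene_id" %in% names(data))
  if (is.null(direction)) {
    if (!metric %in% names(metric_directions)) {
      stop(sprintf("no default direction for metric '%s'; supply `direction`.", metric),
           call. = FALSE)
    }
    direction <- metric_directions[[metric]]
  }
  direction <- match.arg(direction, c("ascending", "descending"))
  score <- data[[metric]]
  if (any(!is.finite(score))) {
    stop(sprintf(
      "non-finite %s score for gene(s): %s",
      metric, paste(utils::head(data$gene_id[!is.finite(score)], 5L), collapse = ", ")
    ), call. = FALSE)
  }
  key <- if (direction == "ascending") score else -score
  ord <- order(key, method = "radix") # stable
  score_sorted <- score[ord]
  new_block <- c(TRUE, score_sorted[-1L] != score_sorted[-length(score_sorted)])
  block <- cumsum(new_block)
  out <- tibble::tibble(
    gene_id = data$gene_id[ord],
    score = score_sorted,
    rank = which(new_block)[block],
    tie_block = block
  )
  attr(out, "metric") <- metric
  attr(out, "direction") <- direction
  out
}
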