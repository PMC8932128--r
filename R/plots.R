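#' Plot a precision-recall curve
#'
#' Draws the PR curve of a [average_precision()] result with the random
#' baseline `C/N` as a horizontal reference line.
#'
#' @param object A `pr_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pr_result
#' @export
autoplot.pr_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_hline(yintercept = object$baseline, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("AP = %.3f (baseline %.3f)%s", object$average_precision,
                      object$baseline,
                      if (is.null(object$metric)) "" else paste0(" - ", object$metric)),
      x = "recall", y = "precision"
    ) +
    ggplot2::theme_minimal()
}

#' Plot average precision per metric against the random baseline
#'
#' Bar chart of the evaluation summary of [evaluate_rankings()]: one bar per
#' metric, with pessimistic/optimistic tie bounds as error bars and the
#' random-classifier baseline as a dashed line, faceted by task.
#'
#' @param summary Tibble from [evaluate_rankings()] or [run_task()].
#' @return A ggplot.
#' @export
plot_evaluation <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$metric, y = .data$average_precision)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ap_pessimistic, ymax = .data$ap_optimistic),
      width = 0.25
    ) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$baseline),
                        linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$task)) +
    ggplot2::labs(x = NULL, y = "average precision") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot expression profiles over time
#'
#' Time-series lines for a selection of genes, useful for eyeballing core
#' versus output versus background dynamics.
#'
#' @param x An `expr_mat`.
#' @param genes Character vector of gene IDs to plot (default: first 6).
#' @return A ggplot.
#' @export
plot_profiles <- function(x, genes = utils::head(unique(x$gene_id), 6L)) {
  stopifnot(inherits(x, "expr_mat"))
  d <- expr_design(x)
  v <- expr_values(x)
  sel <- which(x$gene_id %in% genes)
  long <- tibble::tibble(
    gene_id = rep(x$gene_id[sel], each = length(d$times)),
    time = rep(d$times, length(sel)),
    abundance = as.vector(t(v[sel, , drop = FALSE]))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$abundance,
                                     colour = .data$gene_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = sprintf("time (%s)", d$unit), y = "abundance",
                  colour = "gene") +
    ggplot2::theme_minimal()
}
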