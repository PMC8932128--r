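#' Construct an expression matrix tibble
#'
#' An expression matrix is a wide tibble with a `gene_id` character column and
#' one numeric column per timepoint (named `t<time>`), plus a
#' [sampling_design()] and a modality tag (`"microarray"` for signed
#' log-ratios, `"rnaseq"` for nonnegative FPKM) carried as attributes.
#' Duplicate gene IDs are permitted (multi-probe genes) until
#' [collapse_duplicate_profiles()] is applied.
#'
#' @param values Numeric matrix, genes in rows, one column per design time.
#' @param gene_ids Character vector of row identifiers.
#' @param design A [sampling_design()] whose `times` match `ncol(values)`.
#' @param modality `"microarray"` or `"rnaseq"`.
#' @return A tibble of class `expr_mat`.
#' @examples
#' d <- sampling_design(c(0, 16, 32), period = 94)
#' expression_matrix(matrix(rnorm(6), 2), c("A", "B"), d)
#' @export
expression_matrix <- function(values, gene_ids, design,
                              modality = c("microarray", "rnaseq")) {
  modality <- match.arg(modality)
  stopifnot(inherits(design, "sampling_design"))
  values <- as.matrix(values)
  if (ncol(values) != length(design$times)) {
    stop(sprintf(
      "profiles have %d entries but the design has %d timepoints.",
      ncol(values), length(design$times)
    ), call. = FALSE)
  }
  if (length(gene_ids) != nrow(values)) {
    stop("`gene_ids` must have one entry per row of `values`.", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-finite abundance for gene '%s' at timepoint column %d; missing values are rejected at ingestion.",
      gene_ids[bad[1L]], bad[2L]
    ), call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(values, optional = TRUE),
                           .name_repair = "minimal")
  names(out) <- paste0("t", format(design$times, trim = TRUE, scientific = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(gene_id = as.character(gene_ids)), out)
  new_expr_mat(out, design, modality)
}

new_expr_mat <- function(tbl, design, modality) {
  structure(
    tbl,
    design = design,
    modality = modality,
    class = c("expr_mat", class(tibble::tibble()))
  )
}

#' @rdname expression_matrix
#' @param x An `expr_mat`.
#' @export
expr_design <- function(x) attr(x, "design", exact = TRUE)

#' @rdname expression_matrix
#' @export
expr_modality <- function(x) attr(x, "modality", exact = TRUE)

#' @rdname expression_matrix
#' @export
expr_values <- function(x) {
  v <- as.matrix(x[, -1L, drop = FALSE])
  rownames(v) <- x$gene_id
  v
}

#' @export
print.expr_mat <- function(x, ...) {
  d <- expr_design(x)
  cat(sprintf(
    "<expr_mat> %d profiles x %d timepoints (%s; period %g %s)\n",
    nrow(x), length(d$times), expr_modality(x), d$period, d$unit
  ))
  NextMethod()
}

#' Read a delimited gene-by-timepoint expression table
#'
#' Parses a tab- or comma-delimited text table with one header row of time
#' labels, a first column of gene identifiers and one numeric column per
#' timepoint of `design`. Row order and duplicate gene IDs are preserved
#' (duplicates are collapsed later by [collapse_duplicate_profiles()]).
#' Any non-numeric value cell — including literal `NA` — is a parse error
#' naming the offending row and column; missing data are rejected rather
#' than imputed.
#'
#' @param path Path to the delimited text file.
#' @param design The [sampling_design()] the columns must match.
#' @param modality `"microarray"` or `"rnaseq"`.
#' @param delim Field delimiter; by default inferred from the header line
#'   (tab if present, else comma).
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, design,
                                  modality = c("microarray", "rnaseq"),
                                  delim = NULL) {
  modality <- match.arg(modality)
  stopifnot(inherits(design, "sampling_design"))
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE,
    name_repair = "minimal"
  )
  n_tp <- length(design$times)
  if (ncol(raw) != n_tp + 1L) {
    stop(sprintf(
      "format error: table has %d value columns but the design has %d timepoints.",
      ncol(raw) - 1L, n_tp
    ), call. = FALSE)
  }
  gene_ids <- as.character(raw[[1L]])
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "parse error: non-numeric value '%s' for gene '%s' (row %d, column '%s').",
      cells[bad[1L, 1L], bad[1L, 2L]], gene_ids[bad[1L, 1L]],
      bad[1L, 1L], names(raw)[bad[1L, 2L] + 1L]
    ), call. = FALSE)
  }
  expression_matrix(values, gene_ids, design, modality)
}

#' Write an expression matrix back to delimited text
#'
#' @param x An `expr_mat`.
#' @param path Output file path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, delim = "\t") {
  tbl <- tibble::as_tibble(as.data.frame(x))
  names(tbl) <- c("gene_id", format(expr_design(x)$times, trim = TRUE, scientific = FALSE))
  readr::write_delim(tbl, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Remove consistently low-expressed RNA-seq profiles
#'
#' Drops every profile whose abundance falls below `floor` (1 FPKM by
#' default) in strictly more than `fraction` of the measured timepoints —
#' "more than half" is a strict inequality, so a 12-timepoint profile below
#' the floor at exactly 6 timepoints is kept. A no-op (with a warning) for
#' microarray matrices, whose log-ratio scale has no meaningful floor.
#' The filter is applied to raw abundances, before any log transform.
#'
#' @param x An `expr_mat`.
#' @param floor Abundance threshold (FPKM units).
#' @param fraction Proportion of timepoints that must be below `floor`
#'   (strictly more than) for removal.
#' @return The filtered `expr_mat`. The removed genes are reported in the
#'   `removed` attribute as a tibble with `gene_id` and `n_below` columns.
#' @export
filter_low_expression <- function(x, floor = 1, fraction = 0.5) {
  stopifnot(inherits(x, "expr_mat"))
  if (!identical(expr_modality(x), "rnaseq")) {
    warning("low-expression filter applies to RNA-seq matrices only; returning input unchanged.",
            call. = FALSE)
    attr(x, "removed") <- tibble::tibble(gene_id = character(), n_below = integer())
    return(x)
  }
  v <- expr_values(x)
  n_below <- rowSums(v < floor)
  drop <- n_below > fraction * ncol(v)
  out <- new_expr_mat(x[!drop, , drop = FALSE], expr_design(x), expr_modality(x))
  attr(out, "removed") <- tibble::tibble(
    gene_id = x$gene_id[drop],
    n_below = as.integer(n_below[drop])
  )
  out
}

#' Drop the first timepoints of a series
#'
#' Removes the leading `k` timepoints from every profile and from the design
#' (used e.g. to discard samples taken during recovery from synchronization,
#' whose dynamics are unrelated to the periodic program). The design duration
#' is recomputed from the truncated grid.
#'
#' @param x An `expr_mat`.
#' @param k Number of leading timepoints to drop; must be smaller than the
#'   number of timepoints.
#' @return The truncated `expr_mat`.
#' @export
drop_leading_timepoints <- function(x, k = 2L) {
  stopifnot(inherits(x, "expr_mat"))
  k <- as.integer(k)
  d <- expr_design(x)
  n_tp <- length(d$times)
  if (is.na(k) || k < 0L) stop("`k` must be a nonnegative integer.", call. = FALSE)
  if (k >= n_tp) {
    stop(sprintf("cannot drop %d leading timepoints from a %d-timepoint series.", k, n_tp),
         call. = FALSE)
  }
  if (k == 0L) return(x)
  new_design <- sampling_design(d$times[-seq_len(k)], d$period, d$interval, d$unit)
  expression_matrix(
    expr_values(x)[, -seq_len(k), drop = FALSE],
    x$gene_id, new_design, expr_modality(x)
  )
}

#' Collapse multi-probe genes to one profile each
#'
#' For every gene ID represented by several profiles (multiple microarray
#' probes), keeps the profile with the highest average abundance; exact
#' mean ties keep the first profile in input order. Row order of the kept
#' profiles is preserved.
#'
#' @param x An `expr_mat`.
#' @return The collapsed `expr_mat` with unique gene IDs. The `collapsed`
#'   attribute reports, per affected gene, how many profiles were eliminated.
#' @export
collapse_duplicate_profiles <- function(x) {
  stopifnot(inherits(x, "expr_mat"))
  means <- rowMeans(expr_values(x))
  keep <- logical(nrow(x))
  for (idx in split(seq_len(nrow(x)), factor(x$gene_id, levels = unique(x$gene_id)))) {
    keep[idx[which.max(means[idx])]] <- TRUE
  }
  dropped <- x$gene_id[!keep]
  out <- new_expr_mat(x[keep, , drop = FALSE], expr_design(x), expr_modality(x))
  attr(out, "collapsed") <- tibble::tibble(gene_id = unique(dropped)) |>
    dplyr::mutate(n_removed = as.integer(table(dropped)[.data$gene_id]))
  out
}

#' Log-transform an abundance matrix
#'
#' RNA-seq FPKM values span orders of magnitude, and variance-based scores on
#' the raw scale are dominated by the most abundant genes; the default
#' pipeline therefore scores `log2(FPKM + 1)` after low-expression filtering.
#' Microarray log-ratios are used as provided (`method = "none"`).
#'
#' @param x An `expr_mat`.
#' @param method `"log2p1"` for `log2(v + 1)` or `"none"`.
#' @return The transformed `expr_mat`.
#' @export
transform_expression <- function(x, method = c("log2p1", "none")) {
  method <- match.arg(method)
  if (method == "none") return(x)
  v <- expr_values(x)
  if (any(v < 0)) {
    stop("log2(v + 1) transform requires nonnegative abundances.", call. = FALSE)
  }
  expression_matrix(log2(v + 1), x$gene_id, expr_design(x), expr_modality(x))
}

#' Preprocess an expression matrix for scoring
#'
#' Applies, in order: leading-timepoint removal (microarray series recovering
#' from synchronization), the low-expression FPKM filter (RNA-seq), multi-probe
#' collapse, and the optional log transform (RNA-seq). Every step's row counts
#' are collected into a report suitable for JSON serialization.
#'
#' @param x An `expr_mat`.
#' @param drop_first Leading timepoints to remove (0 = keep all).
#' @param floor,fraction Passed to [filter_low_expression()] for RNA-seq input.
#' @param transform Passed to [transform_expression()] for RNA-seq input.
#' @return The preprocessed `expr_mat`; the `report` attribute holds a named
#'   list of row counts (`rows_read`, `removed_low_expression`,
#'   `removed_duplicate_probes`, `rows_out`).
#' @export
preprocess_expression <- function(x, drop_first = 0L, floor = 1, fraction = 0.5,
                                  transform = c("log2p1", "none")) {
  stopifnot(inherits(x, "expr_mat"))
  transform <- match.arg(transform)
  rows_read <- nrow(x)
  if (drop_first > 0L) x <- drop_leading_timepoints(x, drop_first)
  removed_low <- 0L
  if (identical(expr_modality(x), "rnaseq")) {
    x <- filter_low_expression(x, floor = floor, fraction = fraction)
    removed_low <- nrow(attr(x, "removed"))
  }
  n_before <- nrow(x)
  x <- collapse_duplicate_profiles(x)
  removed_dup <- n_before - nrow(x)
  if (identical(expr_modality(x), "rnaseq")) {
    x <- transform_expression(x, transform)
  }
  attr(x, "report") <- list(
    rows_read = rows_read,
    removed_low_expression = removed_low,
    removed_duplicate_probes = removed_dup,
    rows_out = nrow(x)
  )
  x
}
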