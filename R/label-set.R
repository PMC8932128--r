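#' Binary gene label sets
#'
#' A label set fixes the candidate universe of a ranking task (size `N`) and
#' the positive class within it (size `C`): core transcription factors among
#' all TFs, core genes among all genes, or TFs among all genes. Gene IDs are
#' matched by exact string comparison after upper-casing.
#'
#' @param universe Character vector of candidate gene IDs (the `N` genes).
#' @param positives Character vector of positive gene IDs; must be a subset
#'   of `universe`.
#' @param name Task label, e.g. `"core"` or `"tf"`.
#' @return An object of class `label_set` with elements `universe`,
#'   `positives` and `name`.
#' @export
label_set <- function(universe, positives, name = "core") {
  universe <- unique(toupper(as.character(universe)))
  positives <- unique(toupper(as.character(positives)))
  missing <- setdiff(positives, universe)
  if (length(missing) > 0L) {
    stop(sprintf(
      "positives not contained in the universe: %s",
      paste(utils::head(missing, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  structure(
    list(universe = universe, positives = positives, name = name),
    class = "label_set"
  )
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf(
    "<label_set '%s'> %d positives among %d candidates (baseline C/N = %.4g)\n",
    x$name, length(x$positives), length(x$universe),
    length(x$positives) / length(x$universe)
  ))
  invisible(x)
}

#' Read a plain-text gene list
#'
#' One gene ID per line; blank lines and `#` comments (whole-line or
#' trailing) are ignored. IDs are upper-cased so that matching against
#' expression tables is case-insensitive.
#'
#' @param path Path to the list file.
#' @return Character vector of gene IDs.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  toupper(lines[nzchar(lines)])
}

#' Resolve a gene list against scored gene IDs
#'
#' Matches label IDs to a vector of gene IDs (case-insensitively) and reports
#' rather than silently drops any that are absent.
#'
#' @param ids Character vector of label gene IDs.
#' @param gene_ids Character vector of available gene IDs.
#' @param what Label description used in the warning.
#' @return The matched IDs (upper-cased). Unmatched IDs trigger a warning and
#'   are returned in the `unmatched` attribute.
#' @export
match_gene_ids <- function(ids, gene_ids, what = "label") {
  ids <- unique(toupper(as.character(ids)))
  pool <- toupper(as.character(gene_ids))
  hit <- ids %in% pool
  if (any(!hit)) {
    warning(sprintf(
      "%d %s gene ID(s) not present in the score table (e.g. %s); excluded from evaluation.",
      sum(!hit), what, paste(utils::head(ids[!hit], 3L), collapse = ", ")
    ), call. = FALSE)
  }
  structure(ids[hit], unmatched = ids[!hit])
}
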