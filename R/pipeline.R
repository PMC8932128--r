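#' Score every profile with all eight ranking metrics
#'
#' The scoring stage of the pipeline: builds the shared resampled null
#' ensemble, computes the periodicity and regulation scores with their
#' empirical p-values, the JTK rhythmicity p-value, and the three combined
#' metrics. Input is assumed preprocessed (see [preprocess_expression()]).
#'
#' @param x An `expr_mat`.
#' @param n_null Null ensemble size (default 10000).
#' @param seed Integer seed for the null resampling; required.
#' @param null_mode Null sampling mode, see [sample_null_profiles()].
#' @param phase_step JTK phase offset increment; defaults to the design's
#'   sampling interval.
#' @param n_exact Passed to [jtk_pvalue()].
#' @param sd_type Regulation score flavour, see [reg_score()].
#' @return A tibble with one row per gene and columns `gene_id`, `per_score`,
#'   `reg_score`, `p_per`, `p_reg`, `p_jtk`, `best_phase`, `tau_best`,
#'   `per_reg`, `dl`, `dl_jtk`. Null-ensemble provenance (`n_null`, `seed`,
#'   `mode`) is attached as the `null_info` attribute.
#' @export
score_profiles <- function(x, n_null = 10000L, seed,
                           null_mode = "pooled",
                           phase_step = expr_design(x)$interval,
                           n_exact = 25L,
                           sd_type = "population") {
  stopifnot(inherits(x, "expr_mat"))
  if (missing(seed)) stop("configuration error: `seed` is required when n_null > 0.", call. = FALSE)
  null <- sample_null_profiles(x, n_null = n_null, seed = seed, mode = null_mode,
                               sd_type = sd_type)
  dl <- dl_score_table(x, null, sd_type = sd_type)
  templates <- build_templates(expr_design(x), phase_step = phase_step)
  jtk <- jtk_score_table(x, templates, n_exact = n_exact)
  scores <- dl |>
    dplyr::left_join(jtk, by = "gene_id") |>
    add_combined_metrics()
  attr(scores, "null_info") <- list(n_null = null$n_null, seed = null$seed,
                                    mode = null$mode)
  scores
}

#' Evaluate score rankings on the standard tasks
#'
#' Runs [run_task()] for each requested task and binds the per-metric results.
#'
#' @inheritParams run_task
#' @param tasks Character vector of tasks to evaluate.
#' @return A tibble, one row per task x metric.
#' @export
evaluate_rankings <- function(scores, core, tfs = NULL,
                              tasks = c("core_in_tfs", "core_in_all", "tf_in_all"),
                              tie_policy = "expected", k = 25L) {
  purrr::map_dfr(tasks, function(task) {
    run_task(scores, core = core, tfs = tfs, task = task,
             tie_policy = tie_policy, k = k)
  })
}

#' Pipeline run configuration
#'
#' Collects every knob of a full simulate/read - preprocess - score - evaluate
#' run into one provenance object that is written alongside the outputs.
#'
#' @param sim A [sim_config()] to simulate input data, or `NULL` when reading
#'   from files.
#' @param expression_path,core_path,tf_path Input files (used when `sim` is
#'   `NULL`): expression table and label lists.
#' @param design [sampling_design()] for file input (ignored when simulating).
#' @param modality `"microarray"` or `"rnaseq"` for file input.
#' @param drop_first,floor,fraction,transform Preprocessing settings, see
#'   [preprocess_expression()].
#' @param n_null,null_mode,phase_step,n_exact,sd_type Scoring settings, see
#'   [score_profiles()].
#' @param tasks,tie_policy,k Evaluation settings, see [evaluate_rankings()].
#' @param seed Integer seed used for null resampling (and simulation when
#'   `sim` carries no seed of its own). Required.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = NULL,
                       expression_path = NULL, core_path = NULL, tf_path = NULL,
                       design = NULL, modality = "microarray",
                       drop_first = 0L, floor = 1, fraction = 0.5,
                       transform = "log2p1",
                       n_null = 10000L, null_mode = "pooled",
                       phase_step = NULL, n_exact = 25L, sd_type = "population",
                       tasks = c("core_in_tfs", "core_in_all", "tf_in_all"),
                       tie_policy = "expected", k = 25L,
                       seed, out_dir = NULL) {
  if (missing(seed) || !is.finite(seed)) {
    stop("configuration error: `seed` is required.", call. = FALSE)
  }
  if (is.null(sim) && is.null(expression_path)) {
    stop("configuration error: supply either `sim` or `expression_path`.", call. = FALSE)
  }
  if (!is.null(expression_path) && is.null(design)) {
    stop("configuration error: file input requires a `design`.", call. = FALSE)
  }
  structure(
    list(
      sim = sim, expression_path = expression_path, core_path = core_path,
      tf_path = tf_path, design = design, modality = modality,
      drop_first = drop_first, floor = floor, fraction = fraction,
      transform = transform, n_null = n_null, null_mode = null_mode,
      phase_step = phase_step, n_exact = n_exact, sd_type = sd_type,
      tasks = tasks, tie_policy = tie_policy, k = k,
      seed = as.integer(seed), out_dir = out_dir
    ),
    class = "run_config"
  )
}

log_stage <- function(verbose, stage, n_in, n_out, t0) {
  if (verbose) {
    message(sprintf("[%s] rows in: %d, rows out: %d, elapsed: %.2fs",
                    stage, n_in, n_out, as.numeric(Sys.time()) - t0))
  }
}

#' Run the full ranking pipeline
#'
#' Orchestrates simulate/read, preprocess, score, rank and evaluate, with
#' per-stage row-count logging, and (when `out_dir` is set) writes the score
#' table, per-metric rankings, PR curves, an evaluation summary JSON and the
#' run configuration for provenance.
#'
#' @param config A [run_config()].
#' @param verbose Emit per-stage log messages (default `TRUE`).
#' @return A list with elements `scores` (tibble), `summary` (tibble),
#'   `rankings` (tibble: metric, rank, score, gene_id), `report`
#'   (preprocessing counts), and `paths` (written files, if any).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- as.numeric(Sys.time())
  if (!is.null(config$sim)) {
    sim <- simulate_dataset(config$sim)
    x <- sim$expression
    core <- if (!is.null(sim$core)) sim$core$positives else character(0)
    tfs <- sim$tfs$positives
  } else {
    x <- read_expression_table(config$expression_path, config$design,
                               modality = config$modality)
    core <- if (!is.null(config$core_path)) read_gene_list(config$core_path) else character(0)
    tfs <- if (!is.null(config$tf_path)) read_gene_list(config$tf_path) else character(0)
  }
  log_stage(verbose, "ingest", nrow(x), nrow(x), t0)

  n_in <- nrow(x)
  x <- preprocess_expression(x, drop_first = config$drop_first,
                             floor = config$floor, fraction = config$fraction,
                             transform = config$transform)
  report <- attr(x, "report")
  log_stage(verbose, "preprocess", n_in, nrow(x), t0)

  scores <- score_profiles(
    x, n_null = config$n_null, seed = config$seed,
    null_mode = config$null_mode,
    phase_step = config$phase_step %||% expr_design(x)$interval,
    n_exact = config$n_exact, sd_type = config$sd_type
  )
  log_stage(verbose, "score", nrow(x), nrow(scores), t0)

  rankings <- purrr::pmap_dfr(ranking_metrics(), function(metric, direction) {
    rank_genes(scores, metric, direction) |>
      dplyr::mutate(metric = metric, .before = 1L) |>
      dplyr::select("metric", "rank", "score", "gene_id")
  })

  summary <- NULL
  if (length(core) > 0L || length(tfs) > 0L) {
    tasks <- config$tasks
    if (length(core) == 0L) tasks <- intersect(tasks, "tf_in_all")
    if (length(tfs) == 0L) tasks <- setdiff(tasks, c("core_in_tfs", "tf_in_all"))
    if (length(tasks) > 0L) {
      summary <- evaluate_rankings(scores, core = core, tfs = tfs, tasks = tasks,
                                   tie_policy = config$tie_policy, k = config$k)
      log_stage(verbose, "evaluate", nrow(scores), nrow(summary), t0)
    }
  }

  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      scores = file.path(config$out_dir, "scores.tsv"),
      rankings = file.path(config$out_dir, "rankings.tsv"),
      report = file.path(config$out_dir, "preprocessing_report.json"),
      config = file.path(config$out_dir, "run_config.json")
    )
    readr::write_tsv(scores, paths[["scores"]], progress = FALSE)
    readr::write_tsv(rankings, paths[["rankings"]], progress = FALSE)
    jsonlite::write_json(report, paths[["report"]], auto_unbox = TRUE, pretty = TRUE)
    cfg_out <- config[!vapply(config, is.null, logical(1))]
    cfg_out$sim <- if (!is.null(config$sim)) unclass(config$sim) else NULL
    jsonlite::write_json(
      cfg_out[!vapply(cfg_out, is.null, logical(1))],
      paths[["config"]], auto_unbox = TRUE, pretty = TRUE, force = TRUE
    )
    if (!is.null(summary)) {
      paths[["summary"]] <- file.path(config$out_dir, "summary.json")
      jsonlite::write_json(summary, paths[["summary"]], dataframe = "rows",
                           auto_unbox = TRUE, pretty = TRUE)
    }
  }

  list(scores = scores, summary = summary, rankings = rankings,
       report = report, paths = paths)
}
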