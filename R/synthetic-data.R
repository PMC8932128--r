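#' Configuration for the synthetic periodic transcriptome generator
#'
#' The generator embodies the conceptual picture behind core-gene ranking: a
#' small set of *core* regulators oscillates precisely at the specified period
#' with large amplitude; *output* genes receive the periodic signal at some
#' regulatory distance from the core and show it degraded — geometrically
#' damped amplitude, jittered period, decaying envelope; the *background*
#' majority is aperiodic noise. TF labels are the core set plus a random draw
#' of non-core genes, so TF-vs-all classification by dynamics alone is a
#' negative control sitting at the random baseline.
#'
#' @param n_genes Total gene count.
#' @param n_core Core oscillator genes (period exactly `design$period`).
#' @param n_output Periodic non-core genes with degraded oscillation.
#' @param n_tf_extra Non-core genes labelled TF at random (TF set = core +
#'   these).
#' @param design [sampling_design()] of the experiment. The default is a
#'   16-timepoint, 16-minute-interval, 94-minute-period cell-cycle-style
#'   design, deliberately exercising a non-integer 5.875 timepoints/cycle.
#' @param amp_meanlog,amp_sdlog Log-normal location/scale of core (and
#'   pre-decay output) oscillation amplitudes. Defaults give median amplitude
#'   4 against unit background noise.
#' @param gamma Amplitude decay per regulatory distance step, in (0, 1):
#'   an output gene at distance d oscillates with amplitude `A * gamma^d`.
#' @param max_distance Largest regulatory distance; output distances are
#'   drawn uniformly from `1:max_distance`.
#' @param period_jitter_sd Relative SD of output-gene period: each output
#'   gene oscillates at `T * (1 + delta)`, `delta ~ N(0, period_jitter_sd)`.
#' @param damping_rate Exponential envelope rate `lambda >= 0` applied to
#'   output genes (`exp(-lambda * t)`), per time unit.
#' @param background_sd SD of the aperiodic background genes' white noise.
#' @param measurement_sd SD of measurement noise added to every gene.
#' @param modality `"microarray"` (signed values, used as-is) or `"rnaseq"`
#'   (values exponentiated to an FPKM-like nonnegative scale).
#' @param baseline_log2 RNA-seq mode only: log2 baseline abundance added
#'   before exponentiation, keeping ordinary genes above the 1-FPKM floor.
#' @param duplicate_probe_fraction Fraction of genes that receive a second,
#'   lower-abundance duplicate probe row (exercises probe collapse).
#' @param low_expression_fraction RNA-seq mode only: fraction of genes whose
#'   profiles are replaced by sub-threshold (< 1 FPKM everywhere) values
#'   (exercises the low-expression filter).
#' @param diurnal_fraction,diurnal_amplitude,diurnal_period Optional shared
#'   forcing: this fraction of background genes receives a common-phase
#'   periodic component of this amplitude and period (default the design
#'   period), emulating light/temperature-driven output rhythms.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_core = 17L, n_output = 300L,
                       n_tf_extra = 290L,
                       design = sampling_design(seq(0, 240, by = 16), period = 94,
                                                unit = "min"),
                       amp_meanlog = log(4), amp_sdlog = 0.25,
                       gamma = 0.6, max_distance = 3L,
                       period_jitter_sd = 0.05, damping_rate = 0.001,
                       background_sd = 1, measurement_sd = 0.25,
                       modality = c("microarray", "rnaseq"),
                       baseline_log2 = 5,
                       duplicate_probe_fraction = 0,
                       low_expression_fraction = 0,
                       diurnal_fraction = 0, diurnal_amplitude = 0,
                       diurnal_period = NULL,
                       seed = 1L) {
  modality <- match.arg(modality)
  stopifnot(inherits(design, "sampling_design"))
  n_genes <- as.integer(n_genes); n_core <- as.integer(n_core)
  n_output <- as.integer(n_output); n_tf_extra <- as.integer(n_tf_extra)
  if (n_core < 0L || n_output < 0L || n_core + n_output > n_genes) {
    stop("invalid counts: need n_core + n_output <= n_genes, both nonnegative.", call. = FALSE)
  }
  if (n_tf_extra < 0L || n_core + n_tf_extra > n_genes) {
    stop("invalid counts: need n_core + n_tf_extra <= n_genes.", call. = FALSE)
  }
  if (!is.finite(gamma) || gamma <= 0 || gamma >= 1) {
    stop("`gamma` must lie strictly in (0, 1).", call. = FALSE)
  }
  if (max_distance < 1L) stop("`max_distance` must be at least 1.", call. = FALSE)
  sds <- c(period_jitter_sd, background_sd, measurement_sd)
  if (any(!is.finite(sds)) || any(sds < 0) || damping_rate < 0) {
    stop("noise SDs and the damping rate must be nonnegative.", call. = FALSE)
  }
  fr <- c(duplicate_probe_fraction, low_expression_fraction, diurnal_fraction)
  if (any(fr < 0) || any(fr > 1)) stop("fractions must lie in [0, 1].", call. = FALSE)
  structure(
    list(
      n_genes = n_genes, n_core = n_core, n_output = n_output,
      n_tf_extra = n_tf_extra, design = design,
      amp_meanlog = amp_meanlog, amp_sdlog = amp_sdlog,
      gamma = gamma, max_distance = as.integer(max_distance),
      period_jitter_sd = period_jitter_sd, damping_rate = damping_rate,
      background_sd = background_sd, measurement_sd = measurement_sd,
      modality = modality, baseline_log2 = baseline_log2,
      duplicate_probe_fraction = duplicate_probe_fraction,
      low_expression_fraction = low_expression_fraction,
      diurnal_fraction = diurnal_fraction,
      diurnal_amplitude = diurnal_amplitude,
      diurnal_period = diurnal_period %||% design$period,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a labelled periodic transcriptome
#'
#' Generates an expression matrix plus ground-truth labels according to a
#' [sim_config()]. Core gene profiles are
#' `A * cos(2*pi*(t - phi)/T) + noise` with log-normal amplitude `A`, uniform
#' phase and period exactly `T`; output genes at regulatory distance `d` carry
#' amplitude `A * gamma^d`, a jittered period and an exponential damping
#' envelope; background genes are white noise. Measurement noise is added to
#' every profile. In RNA-seq mode the signal is exponentiated to an FPKM-like
#' scale and, if requested, sub-threshold profiles and duplicate probe rows
#' are planted to exercise the preprocessing filters. Fully deterministic
#' given the config (including its seed).
#'
#' @param config A [sim_config()].
#' @return A list with elements `expression` (an `expr_mat`), `core` and `tfs`
#'   ([label_set()]s over the simulated genes), and `truth` (a tibble with
#'   `gene_id`, `class`, `is_tf`, `amplitude`, `period`, `phase`, `distance`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  d <- cfg$design
  t <- d$times
  n_tp <- length(t)
  n <- cfg$n_genes
  gene_ids <- sprintf("G%05d", seq_len(n))
  class <- rep("background", n)
  if (cfg$n_core > 0L) class[seq_len(cfg$n_core)] <- "core"
  if (cfg$n_output > 0L) class[cfg$n_core + seq_len(cfg$n_output)] <- "output"

  amplitude <- rep(NA_real_, n)
  period <- rep(NA_real_, n)
  phase <- rep(NA_real_, n)
  distance <- rep(NA_integer_, n)
  signal <- matrix(0, n, n_tp)

  periodic <- which(class != "background")
  if (length(periodic) > 0L) {
    base_amp <- stats::rlnorm(length(periodic), cfg$amp_meanlog, cfg$amp_sdlog)
    phi <- stats::runif(length(periodic), 0, d$period)
    for (k in seq_along(periodic)) {
      i <- periodic[k]
      if (class[i] == "core") {
        amp_i <- base_amp[k]
        per_i <- d$period
        env <- 1
        distance[i] <- 0L
      } else {
        distance[i] <- sample.int(cfg$max_distance, 1L)
        amp_i <- base_amp[k] * cfg$gamma^distance[i]
        per_i <- d$period * (1 + stats::rnorm(1L, 0, cfg$period_jitter_sd))
        env <- exp(-cfg$damping_rate * t)
      }
      amplitude[i] <- amp_i
      period[i] <- per_i
      phase[i] <- phi[k]
      signal[i, ] <- amp_i * env * cos(2 * pi * (t - phi[k]) / per_i)
    }
  }
  bg <- which(class == "background")
  if (length(bg) > 0L && cfg$background_sd > 0) {
    signal[bg, ] <- matrix(stats::rnorm(length(bg) * n_tp, 0, cfg$background_sd),
                           length(bg), n_tp)
  }
  if (cfg$diurnal_fraction > 0 && cfg$diurnal_amplitude > 0 && length(bg) > 0L) {
    n_forced <- round(cfg$diurnal_fraction * length(bg))
    forced <- sample(bg, n_forced)
    shared_phase <- stats::runif(1L, 0, cfg$diurnal_period)
    forcing <- cfg$diurnal_amplitude *
      cos(2 * pi * (t - shared_phase) / cfg$diurnal_period)
    signal[forced, ] <- signal[forced, , drop = FALSE] +
      matrix(forcing, n_forced, n_tp, byrow = TRUE)
  }
  if (cfg$measurement_sd > 0) {
    signal <- signal + matrix(stats::rnorm(n * n_tp, 0, cfg$measurement_sd), n, n_tp)
  }

  if (cfg$modality == "rnaseq") {
    values <- 2^(signal + cfg$baseline_log2)
    if (cfg$low_expression_fraction > 0) {
      n_low <- round(cfg$low_expression_fraction * n)
      low <- sample(bg, min(n_low, length(bg)))
      values[low, ] <- matrix(stats::runif(length(low) * n_tp, 0.01, 0.5),
                              length(low), n_tp)
      class[low] <- "low_expression"
    }
  } else {
    values <- signal
  }

  if (cfg$duplicate_probe_fraction > 0) {
    n_dup <- round(cfg$duplicate_probe_fraction * n)
    # duplicates are drawn from genes that pass the abundance floor, so the
    # low-expression filter and the probe collapse exercise disjoint rows
    dup_pool <- which(class != "low_expression")
    dup <- sort(sample(dup_pool, min(n_dup, length(dup_pool))))
    dup_values <- values[dup, , drop = FALSE] * stats::runif(n_dup, 0.3, 0.8)
    values <- rbind(values, dup_values)
    gene_ids <- c(gene_ids, gene_ids[dup])
  }

  tf_pool <- setdiff(which(class %in% c("output", "background")), integer(0))
  tf_idx <- c(which(class == "core"),
              if (cfg$n_tf_extra > 0L) sample(tf_pool, cfg$n_tf_extra) else integer(0))
  core_ids <- sprintf("G%05d", which(class == "core"))
  tf_ids <- sprintf("G%05d", sort(tf_idx))

  truth <- tibble::tibble(
    gene_id = sprintf("G%05d", seq_len(n)),
    class = class,
    is_tf = seq_len(n) %in% tf_idx,
    amplitude = amplitude,
    period = period,
    phase = phase,
    distance = distance
  )
  universe <- sprintf("G%05d", seq_len(n))
  list(
    expression = expression_matrix(values, gene_ids, d, cfg$modality),
    core = if (cfg$n_core > 0L) label_set(universe, core_ids, "core") else NULL,
    tfs = label_set(universe, tf_ids, "tf"),
    truth = truth
  )
}

#' Simulate a fully aperiodic (null) transcriptome
#'
#' Every gene is background white noise plus measurement noise: the
#' calibration harness for p-value uniformity and for AP-at-baseline checks.
#'
#' @param config A [sim_config()]; its core/output counts are ignored.
#' @return An `expr_mat`.
#' @export
simulate_null_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  cfg$n_core <- 0L
  cfg$n_output <- 0L
  cfg$diurnal_fraction <- 0
  cfg$duplicate_probe_fraction <- 0
  cfg$low_expression_fraction <- 0
  withr::with_seed(cfg$seed, simulate_dataset_impl(cfg))$expression
}

#' Write a simulated dataset to plain-text files
#'
#' Emits the same formats the pipeline reads: a TSV expression table, one
#' gene ID per line label files for the core and TF sets, and a TSV truth
#' table.
#'
#' @param sim A list from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    core = file.path(dir, "core_genes.txt"),
    tfs = file.path(dir, "tf_genes.txt"),
    truth = file.path(dir, "truth.tsv")
  )
  write_expression_table(sim$expression, paths[["expression"]])
  writeLines(sim$core$positives, paths[["core"]])
  writeLines(sim$tfs$positives, paths[["tfs"]])
  readr::write_tsv(sim$truth, paths[["truth"]], progress = FALSE)
  invisible(paths)
}
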