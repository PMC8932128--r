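#' Regulation-strength score
#'
#' The variability of a transcript abundance profile about its mean level —
#' a proxy for oscillation amplitude ("strength of regulation"). Realized as
#' the population standard deviation by default (`sd_type = "population"`,
#' the 1/n form), with the sample (1/(n-1)) form available. Zero exactly for
#' constant profiles; equivariant under positive rescaling and invariant
#' under additive shifts.
#'
#' @param x Numeric profile of length at least 2.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return A nonnegative number.
#' @examples
#' reg_score(c(1, -1, 1, -1)) # exactly 1
#' @export
reg_score <- function(x, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(x) < 2L) stop("profile must have at least 2 timepoints.", call. = FALSE)
  denom <- if (sd_type == "population") length(x) else length(x) - 1L
  sqrt(sum((x - mean(x))^2) / denom)
}

#' Periodicity score at a specified period
#'
#' The Fourier magnitude of the mean-centered profile at the single specified
#' period, evaluated at the actual sample times (which need not divide the
#' period evenly):
#' \deqn{Per(G) = \sqrt{\Big(\sum_i \tilde x_i \cos\frac{2\pi t_i}{T}\Big)^2 +
#'   \Big(\sum_i \tilde x_i \sin\frac{2\pi t_i}{T}\Big)^2}}
#' where \eqn{\tilde x} is the centered profile. For a pure cosine of
#' amplitude A sampled evenly over whole cycles the score is `n/2 * A`,
#' independent of phase.
#'
#' @param x Numeric profile of length at least 3.
#' @param design A [sampling_design()] supplying the sample times.
#' @param period Period at which to evaluate; defaults to the design's.
#' @return A nonnegative number.
#' @examples
#' d <- sampling_design(seq(0, 22, 2), period = 24, unit = "h")
#' per_score(cos(2 * pi * d$times / 24), d) # n/2 = 6
#' @export
per_score <- function(x, design, period = design$period) {
  stopifnot(inherits(design, "sampling_design"))
  if (length(x) < 3L) stop("profile must have at least 3 timepoints.", call. = FALSE)
  if (length(x) != length(design$times)) {
    stop("profile length does not match the design's timepoints.", call. = FALSE)
  }
  ang <- 2 * pi * design$times / period
  xc <- x - mean(x)
  sqrt(sum(xc * cos(ang))^2 + sum(xc * sin(ang))^2)
}

# Vectorized scores over the rows of a genes x timepoints matrix.
per_score_matrix <- function(v, times, period) {
  ang <- 2 * pi * times / period
  xc <- v - rowMeans(v)
  sqrt((xc %*% cos(ang))^2 + (xc %*% sin(ang))^2)[, 1L]
}

reg_score_matrix <- function(v, sd_type = "population") {
  xc <- v - rowMeans(v)
  denom <- if (sd_type == "population") ncol(v) else ncol(v) - 1L
  sqrt(rowSums(xc^2) / denom)
}

#' Null ensemble of resampled profiles
#'
#' Generates `n_null` synthetic profiles by resampling the observed data and
#' scores each with both the periodicity and the regulation statistic, giving
#' the shared empirical null distributions from which per-gene empirical
#' p-values are read. One ensemble serves both statistics so the two nulls
#' come from the same synthetic universe.
#'
#' Sampling modes:
#' * `"pooled"` (default): each entry drawn uniformly with replacement from
#'   the pooled multiset of all observed values;
#' * `"per_timepoint"`: entry j drawn from the observed values at timepoint j
#'   (preserves column-wise location/scale);
#' * `"within_gene_permutation"`: a randomly chosen observed profile with its
#'   timepoints randomly permuted (preserves per-gene value sets, destroys
#'   temporal order).
#'
#' @param x An `expr_mat` (normally the post-filter matrix being scored).
#' @param n_null Ensemble size (default 10000).
#' @param seed Integer seed; mandatory, so ensembles are reproducible.
#' @param mode Sampling mode, see above.
#' @param sd_type Passed to the regulation score.
#' @return An object of class `null_ensemble`: sorted score vectors `per` and
#'   `reg`, plus `n_null`, `seed`, `mode` and the scoring `period`.
#' @export
sample_null_profiles <- function(x, n_null = 10000L, seed,
                                 mode = c("pooled", "per_timepoint",
                                          "within_gene_permutation"),
                                 sd_type = "population") {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "expr_mat"))
  if (missing(seed)) stop("`seed` is required for null sampling.", call. = FALSE)
  n_null <- as.integer(n_null)
  if (is.na(n_null) || n_null < 1L) stop("`n_null` must be at least 1.", call. = FALSE)
  if (nrow(x) < 1L) stop("cannot resample from an empty matrix.", call. = FALSE)
  v <- expr_values(x)
  n_tp <- ncol(v)
  d <- expr_design(x)
  null_mat <- withr::with_seed(seed, switch(
    mode,
    pooled = matrix(sample(as.vector(v), n_null * n_tp, replace = TRUE), nrow = n_null),
    per_timepoint = vapply(
      seq_len(n_tp),
      function(j) sample(v[, j], n_null, replace = TRUE),
      numeric(n_null)
    ),
    within_gene_permutation = {
      rows <- sample.int(nrow(v), n_null, replace = TRUE)
      t(vapply(rows, function(r) v[r, sample.int(n_tp)], numeric(n_tp)))
    }
  ))
  if (n_null == 1L) null_mat <- matrix(null_mat, nrow = 1L)
  structure(
    list(
      per = sort(per_score_matrix(null_mat, d$times, d$period)),
      reg = sort(reg_score_matrix(null_mat, sd_type)),
      n_null = n_null, seed = as.integer(seed), mode = mode, period = d$period
    ),
    class = "null_ensemble"
  )
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf(
    "<null_ensemble> %d resampled profiles (mode '%s', seed %d, period %g)\n",
    x$n_null, x$mode, x$seed, x$period
  ))
  invisible(x)
}

#' Empirical tail p-value against a null score ensemble
#'
#' The add-one estimator `(1 + #{null >= observed}) / (1 + n_null)`: the
#' probability that a resampled profile scores at least as high as the gene.
#' The add-one form guarantees p > 0 (minimum `1/(n_null + 1)`), so products
#' of p-values used by the combined metrics stay positive. With `n_null`
#' resamples at most `n_null + 1` distinct p-values are attainable, which is
#' why larger ensembles disambiguate otherwise tied rankings.
#'
#' @param observed Numeric vector of observed scores.
#' @param null_scores Numeric vector of null scores (sorted or not).
#' @return Numeric vector of p-values in `(0, 1]`, one per observed score.
#' @examples
#' empirical_pvalue(10, 1:999) # 1/1000
#' @export
empirical_pvalue <- function(observed, null_scores) {
  if (length(null_scores) < 1L) stop("`null_scores` must be non-empty.", call. = FALSE)
  if (is.unsorted(null_scores)) null_scores <- sort(null_scores)
  n <- length(null_scores)
  n_ge <- n - findInterval(observed, null_scores, left.open = TRUE)
  (1 + n_ge) / (1 + n)
}

#' Periodicity and regulation scores with empirical p-values
#'
#' Scores every profile of a matrix with the periodicity and regulation
#' statistics and attaches empirical p-values read from a shared null
#' ensemble.
#'
#' @param x An `expr_mat`.
#' @param null A `null_ensemble` from [sample_null_profiles()].
#' @param sd_type Passed to the regulation score.
#' @return A tibble with columns `gene_id`, `per_score`, `reg_score`,
#'   `p_per`, `p_reg`.
#' @export
dl_score_table <- function(x, null, sd_type = "population") {
  stopifnot(inherits(x, "expr_mat"), inherits(null, "null_ensemble"))
  v <- expr_values(x)
  d <- expr_design(x)
  per <- per_score_matrix(v, d$times, d$period)
  reg <- reg_score_matrix(v, sd_type)
  tibble::tibble(
    gene_id = x$gene_id,
    per_score = per,
    reg_score = reg,
    p_per = empirical_pvalue(per, null$per),
    p_reg = empirical_pvalue(reg, null$reg)
  )
}
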