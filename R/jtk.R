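#' Phase-shifted cosine rank templates
#'
#' JTK-CYCLE correlates a profile's up-down rank pattern with cosine reference
#' curves at the specified period, one per phase offset. Templates are
#' evaluated at the *actual* sample times (never forced onto an integer grid,
#' so non-integer timepoints-per-cycle designs are handled exactly), rounded
#' to 9 decimals to stabilize numerical ties (e.g. cos at quarter-period is
#' exactly 0), converted to mid-ranks, and deduplicated: offsets a whole
#' period apart, or any offsets yielding identical rank patterns, count once.
#' The number of distinct patterns is the Bonferroni factor applied across
#' phases.
#'
#' @param design A [sampling_design()].
#' @param period Template period; defaults to the design's specified period.
#' @param phase_step Offset increment in time units; defaults to the design's
#'   sampling interval (phase resolution at the sampling resolution). Must be
#'   positive and at most `period`; `phase_step = period` gives one template.
#' @return An object of class `jtk_templates`.
#' @export
build_templates <- function(design, period = design$period,
                            phase_step = design$interval) {
  stopifnot(inherits(design, "sampling_design"))
  times <- design$times
  n <- length(times)
  if (n < 3L) stop("JTK templates require at least 3 timepoints.", call. = FALSE)
  if (!is.finite(phase_step) || phase_step <= 0 || phase_step > period) {
    stop("`phase_step` must be positive and no larger than the period.", call. = FALSE)
  }
  offsets <- seq(0, period * (1 - 1e-12), by = phase_step)
  patterns <- list()
  kept_offsets <- numeric(0)
  seen <- character(0)
  for (phi in offsets) {
    y <- round(cos(2 * pi * (times - phi) / period), 9L)
    r <- rank(y, ties.method = "average")
    key <- paste(r, collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      patterns[[length(patterns) + 1L]] <- r
      kept_offsets <- c(kept_offsets, phi)
    }
  }
  ut <- upper.tri(matrix(0, n, n))
  prep <- lapply(patterns, function(r) {
    sign_r <- sign(outer(r, r, "-"))[ut]
    sizes <- as.integer(table(r))
    list(
      ranks = r,
      sign_upper = sign_r,
      group_sizes = sizes,
      max_s = sum(abs(sign_r)),
      tie_counts = sizes
    )
  })
  structure(
    list(
      period = period, phase_step = phase_step, n = n, times = times,
      offsets = kept_offsets, patterns = patterns, prep = prep,
      group_count = length(patterns), upper = ut, cache = new.env(parent = emptyenv())
    ),
    class = "jtk_templates"
  )
}

#' @export
print.jtk_templates <- function(x, ...) {
  cat(sprintf(
    "<jtk_templates> %d distinct phase patterns (period %g, phase step %g, %d timepoints)\n",
    x$group_count, x$period, x$phase_step, x$n
  ))
  invisible(x)
}

# Kendall S statistic between x and y (sum of sign products over pairs).
kendall_s <- function(x, y) {
  ut <- upper.tri(matrix(0, length(x), length(x)))
  sum(sign(outer(x, x, "-"))[ut] * sign(outer(y, y, "-"))[ut])
}

#' Tie-corrected Kendall correlation (tau-b)
#'
#' Kendall's tau with the tau-b tie correction in both variables:
#' `S / sqrt((n0 - t_x)(n0 - t_y))` where `n0 = n(n-1)/2` and `t` counts tied
#' pairs. A profile with all values tied has no defined correlation and
#' returns `NA` (callers treat such profiles as evidence-free, p = 1).
#'
#' @param x Numeric profile.
#' @param template_ranks Numeric vector of equal length (typically a
#'   template's mid-ranks, but any numeric works).
#' @return A correlation in `[-1, 1]`, or `NA` if either input is fully tied.
#' @examples
#' kendall_tau_b(c(3, 1, 2), c(1, 2, 3)) # -1/3
#' @export
kendall_tau_b <- function(x, template_ranks) {
  n <- length(x)
  if (n != length(template_ranks) || n < 3L) {
    stop("inputs must have equal length of at least 3.", call. = FALSE)
  }
  tie_pairs <- function(v) sum(vapply(table(v), function(t) t * (t - 1) / 2, numeric(1)))
  n0 <- n * (n - 1) / 2
  tx <- tie_pairs(x)
  ty <- tie_pairs(template_ranks)
  if (tx >= n0 || ty >= n0) return(NA_real_)
  kendall_s(x, template_ranks) / sqrt((n0 - tx) * (n0 - ty))
}

# ---- exact null of Kendall S against a tied template (untied profile) ------
#
# With an untied profile, pairs inside a template tie group contribute 0 and
# every cross-group pair contributes +/-1, so S = 2*JT - M where JT is the
# Jonckheere-Terpstra concordance count and M the number of cross-group pairs.
# The permutation distribution of JT is the convolution of Mann-Whitney U
# distributions, i.e. a product of Gaussian binomial coefficients; coefficient
# arithmetic is done in doubles (relative error ~1e-16).

poly_mult <- function(a, b) {
  res <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    res[idx] <- res[idx] + a[i] * b
  }
  res
}

# Coefficients of the Gaussian binomial [m + k choose k]_q (degree m*k):
# the Mann-Whitney U count distribution for group sizes m and k.
gaussian_binomial <- function(m, k) {
  poly <- 1
  for (i in seq_len(k)) {
    # multiply by (1 - q^(m + i))
    a <- m + i
    poly <- c(poly, numeric(a)) - c(numeric(a), poly)
    # divide by (1 - q^i): s_j = p_j + s_(j - i)
    len <- length(poly) - i
    s <- poly[seq_len(len)]
    if (len > i) for (j in (i + 1L):len) s[j] <- s[j] + s[j - i]
    poly <- s
  }
  poly
}

# Exact upper-tail probabilities of JT for template tie-group sizes `sizes`:
# returns list(M, tail) with tail[j + 1] = P(JT >= j), j = 0..M.
jt_null_tail <- function(sizes, cache = NULL) {
  sizes <- sort(as.integer(sizes))
  key <- paste(sizes, collapse = ",")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  n <- sum(sizes)
  m_cross <- (n^2 - sum(sizes^2)) / 2
  poly <- 1
  m_before <- sizes[1L]
  for (k in seq_along(sizes)[-1L]) {
    poly <- poly_mult(poly, gaussian_binomial(m_before, sizes[k]))
    m_before <- m_before + sizes[k]
  }
  probs <- poly / sum(poly)
  out <- list(M = m_cross, tail = rev(cumsum(rev(probs))))
  if (!is.null(cache)) cache[[key]] <- out
  out
}

# Moments of the JT null for template tie-group sizes: because the JT
# generating function factors into Gaussian binomials, JT is distributed as a
# sum of independent Mann-Whitney U components and cumulants add. Used by the
# Edgeworth-corrected approximation for untied profiles.
jt_null_moments <- function(sizes, cache = NULL) {
  sizes <- sort(as.integer(sizes))
  key <- paste("mom", paste(sizes, collapse = ","))
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  n <- sum(sizes)
  var_jt <- 0
  k4_jt <- 0
  m_before <- sizes[1L]
  for (k in seq_along(sizes)[-1L]) {
    p <- gaussian_binomial(m_before, sizes[k])
    p <- p / sum(p)
    u <- seq_along(p) - 1
    mu <- sum(p * u)
    v <- sum(p * (u - mu)^2)
    m4 <- sum(p * (u - mu)^4)
    var_jt <- var_jt + v
    k4_jt <- k4_jt + (m4 - 3 * v^2)
    m_before <- m_before + sizes[k]
  }
  m_cross <- (n^2 - sum(sizes^2)) / 2
  out <- list(M = m_cross, mean = m_cross / 2, var = var_jt,
              gamma2 = if (var_jt > 0) k4_jt / var_jt^2 else 0)
  if (!is.null(cache)) cache[[key]] <- out
  out
}

# Edgeworth tail (symmetric distribution: skew 0, kurtosis-only term) with
# continuity correction, for untied profiles beyond the exact-mode limit.
edgeworth_tail_prob <- function(s_obs, sizes, cache) {
  mom <- jt_null_moments(sizes, cache)
  if (mom$var <= 0) return(1)
  jt_obs <- (s_obs + mom$M) / 2
  z <- (jt_obs - 0.5 - mom$mean) / sqrt(mom$var)
  p <- stats::pnorm(z, lower.tail = FALSE) +
    stats::dnorm(z) * (mom$gamma2 / 24) * (z^3 - 3 * z)
  min(1, max(p, .Machine$double.xmin))
}

# ---- exhaustive permutation null (profiles with ties, small n) -------------

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

perm_cache <- new.env(parent = emptyenv())

get_permutations <- function(n) {
  key <- as.character(n)
  if (is.null(perm_cache[[key]])) perm_cache[[key]] <- all_permutations(n)
  perm_cache[[key]]
}

# P(S_perm >= s_obs) by enumerating all n! permutations of x against sign_r
# (the template's upper-triangle sign vector).
enum_tail_prob <- function(x, sign_upper, s_obs) {
  n <- length(x)
  perms <- get_permutations(n)
  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  s_all <- numeric(nrow(perms))
  for (k in seq_len(nrow(pair_idx))) {
    i <- pair_idx[k, 1L]; j <- pair_idx[k, 2L]
    if (sign_upper[k] == 0) next
    s_all <- s_all + sign(x[perms[, j]] - x[perms[, i]]) * sign_upper[k]
  }
  mean(s_all >= s_obs - 1e-9)
}

# Tie-corrected normal approximation with continuity correction:
# P(S >= s) ~ 1 - Phi((s - 1) / sd(S)).
normal_tail_prob <- function(s_obs, n, ties_x, ties_r) {
  t3 <- function(t) sum(t * (t - 1) * (2 * t + 5))
  t2 <- function(t) sum(t * (t - 1))
  tc <- function(t) sum(t * (t - 1) * (t - 2))
  v0 <- n * (n - 1) * (2 * n + 5)
  var_s <- (v0 - t3(ties_x) - t3(ties_r)) / 18 +
    tc(ties_x) * tc(ties_r) / (9 * n * (n - 1) * (n - 2)) +
    t2(ties_x) * t2(ties_r) / (2 * n * (n - 1))
  if (var_s <= 0) return(1)
  stats::pnorm((s_obs - 1) / sqrt(var_s), lower.tail = FALSE)
}

# One-sided p for one template; dispatches exact / enumeration / approximate.
jtk_template_pvalue <- function(x, prep, n, cache, n_exact) {
  ut <- upper.tri(matrix(0, n, n))
  sign_x <- sign(outer(x, x, "-"))[ut]
  s_obs <- sum(sign_x * prep$sign_upper)
  if (prep$max_s == 0) return(1)
  has_ties <- anyDuplicated(x) > 0L
  if (!has_ties) {
    if (n <= n_exact) {
      null <- jt_null_tail(prep$group_sizes, cache)
      jt_obs <- (s_obs + null$M) / 2
      return(null$tail[jt_obs + 1L])
    }
    return(edgeworth_tail_prob(s_obs, prep$group_sizes, cache))
  }
  if (n <= 8L) {
    return(enum_tail_prob(x, prep$sign_upper, s_obs))
  }
  normal_tail_prob(s_obs, n,
                   ties_x = as.integer(table(x)),
                   ties_r = prep$tie_counts)
}

jtk_details <- function(x, templates, n_exact = 25L) {
  n <- templates$n
  if (length(x) != n) stop("profile length does not match the template design.", call. = FALSE)
  if (length(unique(x)) == 1L) {
    return(list(p = 1, best_phase = NA_real_, tau = NA_real_))
  }
  p_each <- vapply(
    templates$prep,
    function(prep) jtk_template_pvalue(x, prep, n, templates$cache, n_exact),
    numeric(1)
  )
  best <- which.min(p_each)
  list(
    p = min(1, p_each[best] * templates$group_count),
    best_phase = templates$offsets[best],
    tau = kendall_tau_b(x, templates$patterns[[best]])
  )
}

#' JTK-CYCLE rhythmicity p-value
#'
#' For each distinct phase template, computes the one-sided null probability
#' that a random permutation of the profile attains a Kendall S score against
#' the template at least as large as observed; the reported p-value is the
#' minimum over templates times the number of distinct templates (Bonferroni),
#' capped at 1. Because the phase grid spans the full period, anti-phase
#' templates cover negative correlation, making the per-template one-sided
#' test directionally complete.
#'
#' The per-template null is exact for untied profiles up to `n_exact`
#' timepoints (tie-aware convolution of the Kendall S distribution over the
#' template's tie groups); profiles that themselves contain ties use full
#' permutation enumeration up to 8 timepoints; beyond these limits a
#' tie-corrected normal approximation with continuity correction is used.
#' A profile with all values tied carries no rhythmicity evidence and gets
#' p = 1. The p-value is a rank statistic: invariant to adding a constant to,
#' or positively rescaling, the profile.
#'
#' @param profile Numeric profile matching the template design's timepoints.
#' @param templates A [build_templates()] object.
#' @param n_exact Largest profile length for which the exact (convolution)
#'   null is used; set to 0 to force the normal approximation.
#' @return A p-value in `(0, 1]`.
#' @export
jtk_pvalue <- function(profile, templates, n_exact = 25L) {
  stopifnot(inherits(templates, "jtk_templates"))
  jtk_details(profile, templates, n_exact)$p
}

#' JTK p-values for every profile of a matrix
#'
#' @param x An `expr_mat`.
#' @param templates A [build_templates()] object; defaults to templates built
#'   from the matrix's own design.
#' @param n_exact Passed to [jtk_pvalue()].
#' @return A tibble with `gene_id`, `p_jtk`, `best_phase` (offset of the
#'   best-fitting template) and `tau_best` (tau-b at that template).
#' @export
jtk_score_table <- function(x, templates = build_templates(expr_design(x)),
                            n_exact = 25L) {
  stopifnot(inherits(x, "expr_mat"))
  v <- expr_values(x)
  n <- templates$n
  if (ncol(v) != n) stop("matrix timepoints do not match the template design.", call. = FALSE)
  n_genes <- nrow(v)
  p <- best <- tau <- rep(NA_real_, n_genes)

  tied <- apply(v, 1L, anyDuplicated) > 0L
  fast <- which(!tied)
  if (length(fast) > 0L && n <= n_exact) {
    # all pairwise sign differences at once: genes x pairs, then one matrix
    # product against the pairs x templates sign matrix gives every S
    pair_idx <- which(templates$upper, arr.ind = TRUE)
    # orientation matches the stored template sign vectors (value at the pair's
    # first index minus value at its second)
    sx <- sign(v[fast, pair_idx[, 1L], drop = FALSE] -
                 v[fast, pair_idx[, 2L], drop = FALSE])
    w <- vapply(templates$prep, `[[`, numeric(nrow(pair_idx)), "sign_upper")
    s_mat <- sx %*% w
    p_mat <- matrix(1, nrow(s_mat), ncol(s_mat))
    for (k in seq_along(templates$prep)) {
      prep <- templates$prep[[k]]
      if (prep$max_s == 0) next
      null <- jt_null_tail(prep$group_sizes, templates$cache)
      jt <- (s_mat[, k] + null$M) / 2
      p_mat[, k] <- null$tail[jt + 1L]
    }
    kbest <- max.col(-p_mat, ties.method = "first")
    sel <- cbind(seq_along(fast), kbest)
    p[fast] <- pmin(1, p_mat[sel] * templates$group_count)
    best[fast] <- templates$offsets[kbest]
    n0 <- n * (n - 1) / 2
    t_r <- vapply(templates$prep, function(pr) sum(pr$tie_counts * (pr$tie_counts - 1) / 2),
                  numeric(1))
    tau[fast] <- s_mat[sel] / sqrt(n0 * (n0 - t_r[kbest]))
    slow <- which(tied)
  } else {
    slow <- seq_len(n_genes)
  }
  for (i in slow) {
    det <- jtk_details(v[i, ], templates, n_exact)
    p[i] <- det$p
    best[i] <- det$best_phase
    tau[i] <- det$tau
  }
  tibble::tibble(gene_id = x$gene_id, p_jtk = p, best_phase = best, tau_best = tau)
}
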