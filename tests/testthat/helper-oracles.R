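# Independent oracles and small fixture builders shared across tests.

# Plain (untied) average precision of a materialized 0/1 label sequence.
ap_plain <- function(pos) {
  hits <- which(pos)
  mean(seq_along(hits) / hits)
}

# Mean AP over explicit random shuffles within tie blocks of a ranking.
ap_shuffle_oracle <- function(ranked, positives, n_shuffles, seed = 1) {
  positives <- toupper(positives)
  withr::with_seed(seed, {
    mean(replicate(n_shuffles, {
      ord <- order(ranked$score, stats::runif(nrow(ranked)))
      ap_plain(toupper(ranked$gene_id[ord]) %in% positives)
    }))
  })
}

# Exhaustive n!-permutation JTK oracle: per-template one-sided tail
# probability of Kendall's S, then min across templates with a Bonferroni
# factor, mirroring the published combination rule but computed by brute
# force enumeration.
jtk_brute_oracle <- function(x, templates) {
  n <- length(x)
  perms <- gtools_perms(n)
  p_each <- vapply(templates$patterns, function(r) {
    s_obs <- kendall_s_oracle(x, r)
    s_all <- apply(perms, 1L, function(p) kendall_s_oracle(x[p], r))
    mean(s_all >= s_obs - 1e-9)
  }, numeric(1))
  min(1, min(p_each) * templates$group_count)
}

kendall_s_oracle <- function(x, y) {
  s <- 0
  n <- length(x)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
    }
  }
  s
}

gtools_perms_env <- new.env()
gtools_perms <- function(n) {
  key <- as.character(n)
  if (is.null(gtools_perms_env[[key]])) {
    rec <- function(n) {
      if (n == 1L) return(matrix(1L, 1L, 1L))
      sub <- rec(n - 1L)
      do.call(rbind, lapply(seq_len(n), function(k) cbind(k, sub + (sub >= k))))
    }
    gtools_perms_env[[key]] <- rec(n)
  }
  gtools_perms_env[[key]]
}

# Standard benchmark designs.
yeast_ma_design <- function() sampling_design(seq(0, 240, by = 16), period = 94, unit = "min")
circadian_design <- function(n = 12L, interval = 2) {
  sampling_design(seq(0, by = interval, length.out = n), period = 24, unit = "h")
}

# Write a small delimited expression table and return its path.
write_fixture_table <- function(lines, ext = "tsv") {
  path <- tempfile(fileext = paste0(".", ext))
  writeLines(lines, path)
  path
}
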