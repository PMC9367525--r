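#' Per-group summary statistics container
#'
#' @param label group labels.
#' @param mean,sd,n per-group mean, standard deviation and sample size.
#' @return a data frame of class `vascam_summary`.
#' @export
summary_stats <- function(label, mean, sd, n) {
  if (any(sd < 0)) stopf("sd must be >= 0")
  if (any(n < 2)) stopf("every group needs n >= 2")
  structure(data.frame(label = as.character(label), mean = mean,
                       sd = sd, n = as.integer(n)),
            class = c("vascam_summary", "data.frame"))
}

# shared core: fixed-effects one-way ANOVA + Tukey-Kramer HSD from
# per-group (mean, variance, n)
anova_tukey_core <- function(labels, mi, vi, ni, alpha = 0.05) {
  k <- length(mi)
  N <- sum(ni)
  grand <- sum(ni * mi) / N
  ssb <- sum(ni * (mi - grand)^2)
  ssw <- sum((ni - 1) * vi)
  df1 <- k - 1
  df2 <- N - k
  msb <- ssb / df1
  msw <- ssw / df2
  if (msw == 0) {
    # zero within-group variance: take the limit
    f <- if (msb == 0) 0 else Inf
  } else {
    f <- msb / msw
  }
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  pairs <- utils::combn(k, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    diff <- mi[i1] - mi[i2]
    se <- sqrt(msw / 2 * (1 / ni[i1] + 1 / ni[i2]))
    q <- if (se == 0) (if (diff == 0) 0 else Inf) else abs(diff) / se
    p_adj <- stats::ptukey(q, k, df2, lower.tail = FALSE)
    data.frame(group1 = labels[i1], group2 = labels[i2], diff = diff,
               se = se, q = q, p_adj = p_adj,
               stars = if (p_adj < 0.01) "**"
                       else if (p_adj < alpha) "*" else "")
  }))
  structure(list(F = f, df = c(df1, df2), p = p, ms_within = msw,
                 pairwise = pw, alpha = alpha),
            class = "vascam_anova")
}

#' One-way ANOVA with Tukey's multiple-comparisons test
#'
#' Classical fixed-effects one-way ANOVA (pooled within-group variance)
#' followed by all-pairs Tukey HSD based on the studentized range
#' distribution with the pooled error degrees of freedom (Tukey-Kramer
#' standard errors for unequal group sizes).  Groups with zero pooled
#' within-group variance are handled as the limiting case (F and q go to
#' infinity when means differ).
#'
#' @param groups named list of numeric vectors, one per group; at least
#'   two groups with at least two values each.
#' @param alpha significance level for the star flags (default 0.05; two
#'   tiers, 0.05 and 0.01, are reported).
#' @return an object of class `vascam_anova`: list with `F`, `df`, `p`
#'   and a `pairwise` data frame (diff, se, q, Tukey-adjusted p, stars).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2)
    stopf("need a list of >= 2 groups")
  ni <- vapply(groups, length, integer(1))
  if (any(ni < 2)) stopf("every group needs n >= 2")
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("g", seq_along(groups))
  mi <- vapply(groups, mean, numeric(1))
  vi <- vapply(groups, stats::var, numeric(1))
  anova_tukey_core(labels, mi, vi, ni, alpha)
}

#' One-way ANOVA with Tukey HSD from printed summary statistics
#'
#' Reconstructs the identical ANOVA/Tukey result that [anova_tukey()]
#' would give on any raw data matching the per-group mean, SD and n:
#' the between-group sum of squares comes from the means, the
#' within-group sum of squares from `(n - 1) * sd^2`.  This is the only
#' route available when a study's data survives solely as
#' "mean +/- SD (n)" values.
#'
#' @param stats a `vascam_summary` or data frame with columns `label`,
#'   `mean`, `sd`, `n`.
#' @param alpha significance level for the star flags.
#' @return a `vascam_anova`, see [anova_tukey()].
#' @export
anova_tukey_from_summary <- function(stats, alpha = 0.05) {
  need <- c("label", "mean", "sd", "n")
  if (!is.data.frame(stats) || !all(need %in% names(stats)))
    stopf("stats must have columns label, mean, sd, n")
  if (nrow(stats) < 2) stopf("need >= 2 groups")
  if (any(stats$n < 2)) stopf("every group needs n >= 2")
  if (any(stats$sd < 0)) stopf("sd must be >= 0")
  anova_tukey_core(as.character(stats$label), stats$mean, stats$sd^2,
                   as.integer(stats$n), alpha)
}

#' @export
print.vascam_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  cat("Tukey multiple comparisons:\n")
  pw <- x$pairwise
  for (i in seq_len(nrow(pw)))
    cat(sprintf("  %s vs %s: diff = %.4g, p.adj = %.4g %s\n",
                pw$group1[i], pw$group2[i], pw$diff[i], pw$p_adj[i],
                pw$stars[i]))
  invisible(x)
}
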