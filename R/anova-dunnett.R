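#' One-way ANOVA with Dunnett many-to-one comparisons from summary statistics
#'
#' Reconstructs a one-way ANOVA from per-group means, standard errors and a
#' common replicate count, then tests every treatment group against the
#' control with Dunnett-style familywise adjustment. The Dunnett reference
#' distribution (the maximum absolute many-to-one t statistic under the
#' joint null) has no closed form; it is sampled by seeded Monte Carlo, so
#' identical seeds give identical adjusted p values.
#'
#' Mono-factor screening results reported as mean +/- SE of triplicates are
#' the intended input; the `+/-` values are interpreted as standard errors
#' with `n_per_group = 3` replicates.
#'
#' @param means numeric vector of group means (ug/L).
#' @param se numeric vector of group standard errors, same length.
#' @param n_per_group replicates per group (>= 2).
#' @param labels optional group labels.
#' @param control index of the control group.
#' @param n_draws Monte-Carlo draws for the Dunnett null distribution.
#' @param seed integer seed for the Monte-Carlo sampling.
#' @return an object of class `ep_dunnett`: a list with the overall `f`
#'   statistic, its degrees of freedom `df`, overall `p`, and `comparisons`,
#'   a data frame of per-contrast mean difference, t statistic, unadjusted
#'   and Dunnett-adjusted p values.
#' @export
#' @examples
#' # inorganic-salt screening style input: control first
#' anova_dunnett(means = c(28.12, 32.21, 38.85, 62.23),
#'               se = c(2.03, 2.41, 0.75, 1.60), n_per_group = 3,
#'               labels = c("control", "KH2PO4", "MgSO4", "ZnSO4"),
#'               n_draws = 2e4)
anova_dunnett <- function(means, se, n_per_group, labels = NULL,
                          control = 1L, n_draws = 1e5, seed = 0L) {
  k <- length(means)
  ep_assert(k >= 2L, "epferm_insufficient_groups_error",
            "at least two groups (control plus one treatment) are required")
  ep_assert(length(se) == k && all(se >= 0), "epferm_usage_error",
            "'se' must be nonnegative and match 'means'")
  ep_assert(n_per_group >= 2L, "epferm_usage_error",
            "'n_per_group' must be at least 2")
  ep_assert(control >= 1L && control <= k, "epferm_usage_error",
            "'control' index out of range")
  if (is.null(labels)) labels <- paste0("group", seq_len(k))

  n <- rep(n_per_group, k)
  # group sample variance back from the SE of the mean
  s2 <- n * se^2
  df_w <- sum(n - 1L)
  msw <- sum((n - 1L) * s2) / df_w
  grand <- sum(n * means) / sum(n)
  ssb <- sum(n * (means - grand)^2)
  msb <- ssb / (k - 1L)
  if (msw == 0) {
    if (ssb > 0) {
      ep_stop("epferm_degenerate_variance_error",
              "zero pooled variance with unequal group means")
    }
    f <- 0
  } else {
    f <- msb / msw
  }
  p_overall <- pf(f, k - 1L, df_w, lower.tail = FALSE)

  idx <- setdiff(seq_len(k), control)
  diff <- means[idx] - means[control]
  scale <- sqrt(1 / n[idx] + 1 / n[control])
  tstat <- if (msw == 0) rep(0, length(idx)) else diff / (sqrt(msw) * scale)
  p_unadj <- 2 * pt(-abs(tstat), df_w)

  # joint null of the many-to-one comparisons: shared control draw,
  # studentized by a common pooled-variance chi-square
  maxabs <- with_seed(seed, {
    z0 <- rnorm(n_draws, sd = 1 / sqrt(n[control]))
    w <- sqrt(rchisq(n_draws, df_w) / df_w)
    mx <- rep(0, n_draws)
    for (j in seq_along(idx)) {
      zj <- rnorm(n_draws, sd = 1 / sqrt(n[idx[j]]))
      mx <- pmax(mx, abs(zj - z0) / (scale[j] * w))
    }
    mx
  })
  p_adj <- vapply(abs(tstat), function(t0) mean(maxabs >= t0), 1)
  # the familywise adjustment can never be anti-conservative; guard the
  # Monte-Carlo estimate against sampling error at small t
  p_adj <- pmax(p_adj, p_unadj)

  structure(
    list(
      f = f, df = c(k - 1L, df_w), p = p_overall,
      msw = msw, n_per_group = n_per_group, seed = seed, n_draws = n_draws,
      comparisons = data.frame(
        group = labels[idx], control = labels[control],
        diff = diff, t = tstat, p_unadj = p_unadj, p_adj = p_adj,
        row.names = NULL
      )
    ),
    class = "ep_dunnett"
  )
}

#' @export
print.ep_dunnett <- function(x, ...) {
  cat(sprintf("<ep_dunnett> one-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$f, x$p))
  tab <- x$comparisons
  tab$diff <- round(tab$diff, 3)
  tab$t <- round(tab$t, 3)
  tab$p_unadj <- signif(tab$p_unadj, 3)
  tab$p_adj <- signif(tab$p_adj, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
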