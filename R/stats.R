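#' Paired comparison between conditions
#'
#' Paired t-test preceded by a Kolmogorov-Smirnov normality screen of the
#' pair differences (against a normal with estimated mean and SD; a
#' Lilliefors-corrected variant is available when the `nortest` package is
#' installed). The effect size follows the r = |z|/sqrt(N) convention, with
#' z obtained by inverse-normal transform of the two-sided p-value, signed by
#' the test statistic, and N the total number of observations (2n for n
#' pairs).
#'
#' @param x,y equal-length paired samples (e.g. three-back vs zero-back).
#' @param normality `"ks"` (default) or `"lilliefors"`.
#' @return A `cog_test` result: `method`, `statistic`, `p_value`,
#'   `effect_size_r`, `n` (pairs), `normality_p`, `normal` (screen verdict at
#'   0.05).
#' @export
paired_test <- function(x, y, normality = c("ks", "lilliefors")) {
  normality <- match.arg(normality)
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  d <- x - y
  if (sd(d) < .Machine$double.eps) {
    if (max(abs(d)) < .Machine$double.eps) {
      # identical pairs: no evidence of any difference
      return(structure(list(method = "paired t-test", statistic = 0,
                            p_value = 1, effect_size_r = 0, n = n,
                            normality_p = NA_real_, normal = NA),
                       class = "cog_test"))
    }
    stop("zero-variance non-zero differences; the paired t-test is undefined")
  }
  norm_p <- if (normality == "lilliefors" &&
                requireNamespace("nortest", quietly = TRUE)) {
    nortest::lillie.test(d)$p.value
  } else {
    suppressWarnings(ks.test(d, "pnorm", mean(d), sd(d))$p.value)
  }
  tt <- t.test(x, y, paired = TRUE)
  r <- effect_size_r(p_to_z(tt$p.value, sign(unname(tt$statistic))), 2L * n)
  structure(list(method = "paired t-test",
                 statistic = unname(tt$statistic), p_value = tt$p.value,
                 effect_size_r = r, n = n,
                 normality_p = norm_p, normal = norm_p > 0.05),
            class = "cog_test")
}

# two-sided p-value -> signed standard-normal-equivalent statistic
p_to_z <- function(p, sign = 1) {
  sign * qnorm(min(max(p, .Machine$double.xmin), 1) / 2, lower.tail = FALSE)
}

#' Effect size r from a standard-normal-equivalent statistic
#'
#' `r = |z| / sqrt(n_total)`, capped at 1 with a warning (the definition can
#' exceed 1 for extreme z at small N).
#'
#' @param z standard-normal-equivalent statistic.
#' @param n_total total number of observations.
#' @return Effect size in `[0, 1]`.
#' @export
effect_size_r <- function(z, n_total) {
  stopifnot(n_total > 0)
  r <- abs(z) / sqrt(n_total)
  if (r > 1) {
    warning("effect size r = ", signif(r, 3), " capped at 1")
    r <- 1
  }
  r
}

#' Correlation between (difference-score) variables
#'
#' Pearson correlation (Spearman available) between two columns of a
#' participant summary table, by default on condition-difference scores
#' (three-back minus zero-back) — the standard guard against wide
#' between-participant level differences. Incomplete pairs are dropped and
#' counted.
#'
#' @param summary_table data.frame with one row per participant x condition,
#'   including columns `participant_id`, `condition`, and the variables.
#' @param var_a,var_b variable names.
#' @param use_diff length-2 logical: take the three_back - zero_back
#'   difference of `var_a` / `var_b`? When `FALSE`, the three-back value is
#'   used.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A `cog_test` result with Pearson/Spearman `statistic` (r),
#'   `p_value`, `effect_size_r` (|r|), `n` (complete pairs), `n_dropped`.
#' @export
diff_correlation <- function(summary_table, var_a, var_b,
                             use_diff = c(TRUE, TRUE),
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  a <- condition_scores(summary_table, var_a, use_diff[1])
  b <- condition_scores(summary_table, var_b, use_diff[2])
  ids <- intersect(names(a), names(b))
  x <- a[ids]; y <- b[ids]
  ok <- stats::complete.cases(x, y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("fewer than 4 complete pairs")
  if (sd(x) < .Machine$double.eps || sd(y) < .Machine$double.eps)
    stop("constant variable; correlation undefined")
  ct <- suppressWarnings(cor.test(x, y, method = method))
  structure(list(method = paste0(method, " correlation",
                                 if (any(use_diff)) " (difference scores)"),
                 statistic = unname(ct$estimate), p_value = ct$p.value,
                 effect_size_r = abs(unname(ct$estimate)),
                 n = length(x), n_dropped = n_dropped,
                 var_a = var_a, var_b = var_b),
            class = "cog_test")
}

# per-participant score: difference (three_back - zero_back) or three-back
condition_scores <- function(tab, var, diff) {
  stopifnot(var %in% names(tab))
  tb <- tab[tab$condition == "three_back", ]
  v <- stats::setNames(tb[[var]], tb$participant_id)
  if (!diff) return(v)
  zb <- tab[tab$condition == "zero_back", ]
  z <- stats::setNames(zb[[var]], zb$participant_id)
  ids <- intersect(names(v), names(z))
  v[ids] - z[ids]
}

#' @export
print.cog_test <- function(x, ...) {
  cat(sprintf("<cog_test> %s%s: statistic = %.4f, p = %.4g, r = %.3f, n = %d\n",
              x$method,
              if (!is.null(x$var_a)) paste0(" [", x$var_a, " ~ ", x$var_b, "]") else "",
              x$statistic, x$p_value, x$effect_size_r, x$n))
  invisible(x)
}

#' Benjamini-Hochberg multiple-testing correction
#'
#' Step-up false-discovery-rate adjustment of a family of p-values, plus the
#' discovery set at level `q`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q FDR level for the discovery set (default 0.05).
#' @return List with `adj_p` (same order as input) and `discoveries`
#'   (indices with `adj_p <= q`).
#' @export
bh_adjust <- function(p_values, q = 0.05) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p_values, method = "BH")
  list(adj_p = adj, discoveries = which(adj <= q))
}
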