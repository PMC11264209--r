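#' Screening statistics
#'
#' The comparison procedures used across variants: SEM aggregation, a
#' one-sided Mann-Whitney U test (mutant larger than reference), the
#' Benjamini-Hochberg FDR procedure at alpha = 0.05, and a two-group gate
#' that dispatches a t-test or Mann-Whitney test after normality
#' (Shapiro-Wilk) and variance-equality (F-test) checks.
#'
#' @name stats_module
NULL

#' Standard error of the mean
#'
#' Sample standard deviation (n - 1 denominator) divided by sqrt(n).
#' @param values Numeric vector with n >= 2.
#' @return The SEM.
#' @export
sem <- function(values) {
  if (length(values) < 2) abort_param("SEM requires n >= 2")
  sd(values) / sqrt(length(values))
}

#' One-sided Mann-Whitney U test
#'
#' Alternative hypothesis: `x` is stochastically larger than `y`. The p
#' value is exact for small untied samples and uses the tie-corrected
#' normal approximation otherwise (via [stats::wilcox.test()]).
#'
#' @param x,y Nonempty numeric samples.
#' @return A one-row tibble: `test`, `statistic` (U), `p_value`,
#'   `alternative`, `n_x`, `n_y`.
#' @export
mann_whitney_one_sided <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort_param("both groups nonempty")
  res <- suppressWarnings(wilcox.test(x, y, alternative = "greater"))
  tibble::tibble(test = "mann_whitney_u", statistic = unname(res$statistic),
                 p_value = res$p.value, alternative = "x greater",
                 n_x = length(x), n_y = length(y))
}

#' Benjamini-Hochberg FDR selection
#'
#' Sorts the p values ascending, finds the largest k with
#' `p_(k) <= k * alpha / m` and rejects hypotheses 1..k of the sorted
#' order (boundary uses `<=`).
#'
#' @param p_values P values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return An `fdr_report`: list with `p_values`, `alpha`, `rejected`
#'   (indices into the input), `thresholds` (per sorted hypothesis) and
#'   `adjusted` (BH-adjusted p values).
#' @export
benjamini_hochberg <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1) || anyNA(p_values))
    abort_param("p values must lie in [0, 1]")
  m <- length(p_values)
  ord <- order(p_values)
  thresholds <- seq_len(m) * alpha / m
  ok <- p_values[ord] <= thresholds
  k <- if (any(ok)) max(which(ok)) else 0L
  rejected <- if (k > 0) sort(ord[seq_len(k)]) else integer(0)
  structure(list(p_values = p_values, alpha = alpha, rejected = rejected,
                 thresholds = thresholds,
                 adjusted = p.adjust(p_values, method = "BH")),
            class = "fdr_report")
}

#' @export
print.fdr_report <- function(x, ...) {
  cat("<fdr_report> alpha = ", x$alpha, ": ", length(x$rejected), "/",
      length(x$p_values), " hypotheses rejected\n", sep = "")
  invisible(x)
}

#' Two-group comparison with assumption gating
#'
#' Runs a Shapiro-Wilk normality test per group and an F-test of variance
#' equality at `pretest_alpha`; normal data with equal variances get an
#' equal-variance t-test, anything else (including degenerate zero-variance
#' samples) a Mann-Whitney test. Reports which path fired.
#'
#' @param x,y Numeric samples with n >= 3 each.
#' @param alternative Test alternative (default two-sided).
#' @param pretest_alpha Level of the pre-tests (default 0.05).
#' @return A list: `chosen` (`"t_test"` or `"mann_whitney"`), `pretests`
#'   tibble, `result` one-row tibble.
#' @export
two_group_gate <- function(x, y, alternative = "two.sided",
                           pretest_alpha = 0.05) {
  if (length(x) < 3 || length(y) < 3)
    abort_param("pre-tests require n >= 3 per group")
  degenerate <- sd(x) == 0 || sd(y) == 0
  if (!degenerate) {
    sw_x <- shapiro.test(x)$p.value
    sw_y <- shapiro.test(y)$p.value
    fv <- var.test(x, y)$p.value
    normal_ok <- sw_x > pretest_alpha && sw_y > pretest_alpha
    var_ok <- fv > pretest_alpha
  } else {
    sw_x <- sw_y <- fv <- NA_real_
    normal_ok <- var_ok <- FALSE
  }
  pretests <- tibble::tibble(test = c("shapiro_x", "shapiro_y", "f_variance"),
                             p_value = c(sw_x, sw_y, fv))
  if (normal_ok && var_ok) {
    res <- t.test(x, y, alternative = alternative, var.equal = TRUE)
    out <- tibble::tibble(test = "t_test", statistic = unname(res$statistic),
                          p_value = res$p.value, alternative = alternative,
                          n_x = length(x), n_y = length(y))
    list(chosen = "t_test", pretests = pretests, result = out)
  } else {
    res <- suppressWarnings(wilcox.test(x, y, alternative = alternative))
    out <- tibble::tibble(test = "mann_whitney_u",
                          statistic = unname(res$statistic),
                          p_value = res$p.value, alternative = alternative,
                          n_x = length(x), n_y = length(y))
    list(chosen = "mann_whitney", pretests = pretests, result = out)
  }
}
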