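#' Coincidence-of-regressions F test
#'
#' Tests whether several groups' straight-line regressions can be replaced
#' by one common line. The four-step procedure: (1) fit the single pooled
#' line and accumulate its residual (error) sum of squares; (2) fit each
#' group's own line and sum their residual sums of squares; (3) take the
#' difference of the two error sums of squares and of their degrees of
#' freedom; (4) form the variance ratio
#' \deqn{F = \frac{(RSS_{pooled} - RSS_{within}) / 2(k-1)}
#'            {RSS_{within} / (n - 2k)}}
#' and compare it to the upper-\eqn{\alpha} F quantile. This equals the
#' textbook extra-sum-of-squares test of the 2-parameter common-line model
#' against the 2k-parameter separate-lines model.
#'
#' For allometric data the comparison is performed on log-transformed
#' values; see [compare_allometric()], which handles the transformation.
#'
#' When the groups lie exactly on distinct lines (\code{rss_within = 0})
#' the statistic is reported as \code{Inf} with \code{poolable = FALSE}
#' rather than raising an error.
#'
#' @param groups A named list; each element is a list or data frame with
#'   numeric components \code{x} and \code{y} (already in the fitting
#'   space), each of length at least 3.
#' @param alpha Significance level (default 0.05).
#' @return An object of class \code{"regression_comparison"}: a list with
#'   \code{k}, \code{n_total}, \code{rss_pooled}, \code{df_pooled},
#'   \code{rss_within}, \code{df_within}, \code{ss_diff}, \code{df_diff},
#'   \code{ms_diff}, \code{ms_within}, \code{f}, \code{f_crit},
#'   \code{alpha}, \code{p_value} and \code{poolable}.
#' @examples
#' set.seed(1)
#' g <- lapply(1:3, function(i) {
#'   x <- runif(15); list(x = x, y = 1 + 2 * x + rnorm(15, 0, 0.1))
#' })
#' compare_regressions(g)
#' @export
compare_regressions <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2)
    stop("'groups' must be a list of at least 2 (x, y) sets", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  k <- length(groups)
  xs <- lapply(groups, function(g) as.numeric(g$x))
  ys <- lapply(groups, function(g) as.numeric(g$y))
  sizes <- vapply(xs, length, 0L)
  if (any(sizes < 3))
    stop("every group needs at least 3 points; group(s) ",
         paste(which(sizes < 3), collapse = ", "), " too small",
         call. = FALSE)
  if (any(!vapply(seq_len(k), function(i)
    all(is.finite(xs[[i]])) && all(is.finite(ys[[i]])) &&
      length(xs[[i]]) == length(ys[[i]]), TRUE)))
    stop("all x and y must be finite and of matching length", call. = FALSE)
  n_total <- sum(sizes)
  df_within <- n_total - 2L * k
  if (df_within <= 0)
    stop("non-positive within-group degrees of freedom (n - 2k = ",
         df_within, ")", call. = FALSE)

  rss_line <- function(x, y) {
    if (diff(range(x)) == 0)
      stop("a group has constant x: its line is not identifiable",
           call. = FALSE)
    f <- stats::lm.fit(cbind(1, x), y)
    sum(f$residuals^2)
  }
  rss_pooled <- rss_line(unlist(xs), unlist(ys))
  rss_within <- sum(vapply(seq_len(k),
                           function(i) rss_line(xs[[i]], ys[[i]]), 0))
  df_pooled <- n_total - 2L
  ss_diff <- rss_pooled - rss_within
  df_diff <- df_pooled - df_within          # = 2(k - 1)
  ms_diff <- ss_diff / df_diff
  ms_within <- rss_within / df_within
  # a within-RSS that is zero to machine precision means the groups lie
  # exactly on their own lines: the ratio is reported as Inf, not an error
  degenerate <- rss_within <= 1e-12 * rss_pooled
  f <- if (degenerate) {
    if (ss_diff <= 1e-12 * max(rss_pooled, 1e-300)) 0 else Inf
  } else ms_diff / ms_within
  fc <- f_critical(alpha, df_diff, df_within)
  structure(
    list(k = k, n_total = n_total,
         rss_pooled = rss_pooled, df_pooled = df_pooled,
         rss_within = rss_within, df_within = df_within,
         ss_diff = ss_diff, df_diff = df_diff,
         ms_diff = ms_diff, ms_within = ms_within,
         f = f, f_crit = fc, alpha = alpha,
         p_value = stats::pf(f, df_diff, df_within, lower.tail = FALSE),
         poolable = f <= fc),
    class = "regression_comparison")
}

#' @export
print.regression_comparison <- function(x, ...) {
  cat("Coincidence-of-regressions F test\n")
  cat(sprintf("  groups: %d, observations: %d\n", x$k, x$n_total))
  cat(sprintf("  RSS pooled line: %.6g on %d df\n", x$rss_pooled, x$df_pooled))
  cat(sprintf("  RSS separate lines: %.6g on %d df\n",
              x$rss_within, x$df_within))
  cat(sprintf("  F = %.4g on (%d, %d) df;  F_crit(%.2g) = %.4g;  p = %.4g\n",
              x$f, x$df_diff, x$df_within, x$alpha, x$f_crit, x$p_value))
  cat(sprintf("  decision: %s\n",
              if (x$poolable) "poolable (one common line is adequate)"
              else "not poolable (lines differ)"))
  invisible(x)
}

#' Upper-tail critical value of the F distribution
#'
#' Returns the upper-\eqn{\alpha} quantile of the F distribution with
#' \code{df1} and \code{df2} degrees of freedom (the inverse regularized
#' incomplete beta function, as implemented by [stats::qf()]).
#'
#' @param alpha Upper-tail probability in (0, 1).
#' @param df1,df2 Degrees of freedom (at least 1).
#' @return The critical value, a single number.
#' @examples
#' f_critical(0.05, 18, 12)  # 2.57, i.e. 2.6 to one decimal
#' @export
f_critical <- function(alpha, df1, df2) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  if (!is.finite(df1) || !is.finite(df2) || df1 < 1 || df2 < 1)
    stop("degrees of freedom must be >= 1", call. = FALSE)
  stats::qf(alpha, df1, df2, lower.tail = FALSE)
}

#' Compare allometric regressions across groups
#'
#' Log-transforms the predictor and response (the space in which the
#' allometric model is a straight line) and runs the coincidence F test
#' across the levels of a grouping column.
#'
#' @param data Data frame of observations.
#' @param y,x Column names of the (strictly positive) response and
#'   predictor.
#' @param group Column name of the grouping factor.
#' @param alpha Significance level.
#' @return A \code{"regression_comparison"} object; the group labels are
#'   attached as attribute \code{"groups"}.
#' @examples
#' trial <- simulate_trial(trial_config(seed = 1))
#' compare_allometric(trial, y = "sdm_t_ha", x = "cc", group = "cultivar")
#' @export
compare_allometric <- function(data, y, x, group, alpha = 0.05) {
  stopifnot(y %in% names(data), x %in% names(data), group %in% names(data))
  if (any(data[[x]] <= 0 | data[[y]] <= 0))
    stop("all x and y must be strictly positive for the log transform",
         call. = FALSE)
  levs <- unique(data[[group]])
  groups <- lapply(levs, function(g) {
    d <- data[data[[group]] == g, ]
    list(x = log(d[[x]]), y = log(d[[y]]))
  })
  names(groups) <- as.character(levs)
  out <- compare_regressions(groups, alpha = alpha)
  attr(out, "groups") <- as.character(levs)
  out
}
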