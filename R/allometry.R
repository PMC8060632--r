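#' Fit an allometric power-law model Y = a X^b
#'
#' Fits the two-parameter allometric model relating a growth index to
#' canopy cover (or any pair of positive quantities). The default fitting
#' space is log-linear: ordinary least squares of \eqn{\ln y} on
#' \eqn{\ln x}, so \eqn{a = \exp(\mathrm{intercept})} and \eqn{b} is the
#' slope, with confidence intervals from t quantiles on the log scale
#' (back-transformed for \eqn{a}, hence asymmetric). The nonlinear space
#' refits \eqn{y = a x^b} by least squares on the original scale,
#' initialized from the log-linear estimates. \eqn{R^2} is reported in the
#' fitting space, which is recorded in the result.
#'
#' @param x,y Strictly positive numeric vectors of equal length (at least 3).
#' @param space \code{"log-linear"} (default) or \code{"nonlinear"}.
#' @param level Confidence level for parameter intervals (default 0.95).
#' @return An object of class \code{"allometric_fit"}: a list with
#'   \code{a}, \code{b}, \code{se_log_a}, \code{se_b}, \code{ci_a},
#'   \code{ci_b}, \code{r2}, \code{n}, \code{space}, \code{sigma_log}
#'   (residual SD in log space, log-linear mode) and the underlying
#'   \code{lm}/\code{nls} fit in \code{$fit}.
#' @examples
#' cc <- seq(0.2, 0.9, length.out = 10)
#' sdm <- 4.87 * cc^1.92
#' fit <- fit_allometric(cc, sdm)
#' coef(fit)                  # a = 4.87, b = 1.92
#' predict(fit, x = 0.5)
#' @seealso [predict.allometric_fit()], [compare_allometric()]
#' @export
fit_allometric <- function(x, y, space = c("log-linear", "nonlinear"),
                           level = 0.95) {
  space <- match.arg(space)
  if (length(x) != length(y))
    stop("'x' and 'y' must have the same length", call. = FALSE)
  if (length(x) < 3)
    stop("at least 3 observations are required", call. = FALSE)
  bad <- which(!is.finite(x) | !is.finite(y) | x <= 0 | y <= 0)
  if (length(bad))
    stop("all x and y must be strictly positive and finite; offending rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  if (diff(range(x)) == 0)
    stop("'x' is constant: the exponent is not identifiable", call. = FALSE)

  lx <- log(x); ly <- log(y)
  lmfit <- stats::lm(ly ~ lx)
  # noiseless (exact power-law) data are a designed use-case; silence the
  # "essentially perfect fit" warning they trigger
  sm <- suppressWarnings(summary(lmfit))
  co <- sm$coefficients
  a_log <- co[1, 1]; b_hat <- co[2, 1]
  ci_log <- suppressWarnings(stats::confint(lmfit, level = level))

  if (space == "log-linear") {
    out <- list(a = exp(a_log), b = b_hat,
                se_log_a = co[1, 2], se_b = co[2, 2],
                ci_a = exp(ci_log[1, ]), ci_b = ci_log[2, ],
                r2 = sm$r.squared, n = length(x),
                sigma_log = sm$sigma,
                space = space, level = level, fit = lmfit,
                x = x, y = y)
  } else {
    nls_fit <- minpack.lm::nlsLM(
      y ~ a * x^b, start = list(a = exp(a_log), b = b_hat),
      lower = c(1e-12, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    est <- stats::coef(nls_fit)
    se <- sqrt(diag(stats::vcov(nls_fit)))
    tq <- stats::qt(1 - (1 - level) / 2, df = length(x) - 2)
    rss <- sum(stats::residuals(nls_fit)^2)
    tss <- sum((y - mean(y))^2)
    out <- list(a = unname(est["a"]), b = unname(est["b"]),
                se_log_a = unname(se["a"] / est["a"]), se_b = unname(se["b"]),
                ci_a = unname(est["a"] + c(-1, 1) * tq * se["a"]),
                ci_b = unname(est["b"] + c(-1, 1) * tq * se["b"]),
                r2 = 1 - rss / tss, n = length(x),
                sigma_log = sm$sigma,
                space = space, level = level, fit = nls_fit,
                x = x, y = y)
  }
  names(out$ci_a) <- names(out$ci_b) <- c("lower", "upper")
  class(out) <- "allometric_fit"
  out
}

#' Formula interface to [fit_allometric()]
#'
#' @param formula A two-sided formula \code{y ~ x} naming columns of
#'   \code{data}.
#' @param data A data frame.
#' @param ... Passed to [fit_allometric()].
#' @return An \code{"allometric_fit"} object.
#' @examples
#' trial <- simulate_trial(trial_config(noise_cv = 0, seed = 1))
#' ak58 <- subset(trial, cultivar == "AK58")
#' fit_allometric_formula(sdm_t_ha ~ cc, ak58)
#' @export
fit_allometric_formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  if (ncol(mf) != 2L)
    stop("formula must be of the form y ~ x", call. = FALSE)
  fit_allometric(x = mf[[2]], y = mf[[1]], ...)
}

#' @export
coef.allometric_fit <- function(object, ...) {
  c(a = object$a, b = object$b)
}

#' Predict from an allometric fit
#'
#' Evaluates \eqn{a x^b} at new (strictly positive) predictor values.
#'
#' @param object An \code{"allometric_fit"}.
#' @param x Positive numeric vector of predictor values; defaults to the
#'   training values.
#' @param ... Unused.
#' @return Numeric vector of fitted responses.
#' @export
predict.allometric_fit <- function(object, x = object$x, ...) {
  if (any(!is.finite(x) | x <= 0))
    stop("predictor values must be strictly positive", call. = FALSE)
  object$a * x^object$b
}

#' @export
residuals.allometric_fit <- function(object, ...) {
  stats::residuals(object$fit)
}

#' @export
confint.allometric_fit <- function(object, parm = c("a", "b"), ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  out <- rbind(a = object$ci_a, b = object$ci_b)[parm, , drop = FALSE]
  colnames(out) <- c("lower", "upper")
  out
}

#' Simulate responses from a fitted allometric model
#'
#' Draws new responses \eqn{a x^b \epsilon} with lognormal multiplicative
#' noise whose log-SD equals the residual SD of the log-linear fit, i.e.
#' new data consistent with the fitted error model.
#'
#' @param object An \code{"allometric_fit"}.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param x Predictor values (defaults to training values).
#' @param ... Unused.
#' @return A data frame with \code{nsim} columns of simulated responses.
#' @export
simulate.allometric_fit <- function(object, nsim = 1, seed = NULL,
                                    x = object$x, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- log(object$a) + object$b * log(x)
  out <- as.data.frame(replicate(
    nsim, exp(stats::rnorm(length(x), mu, object$sigma_log))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.allometric_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Allometric model: Y = %s * X^%s   (space: %s, n = %d)\n",
              format(x$a, digits = digits), format(x$b, digits = digits),
              x$space, x$n))
  cat(sprintf("  R-squared (%s): %.3f\n", x$space, x$r2))
  invisible(x)
}

#' @export
summary.allometric_fit <- function(object, ...) {
  tab <- data.frame(
    estimate = c(object$a, object$b),
    se = c(object$se_log_a, object$se_b),
    ci_lower = c(object$ci_a[1], object$ci_b[1]),
    ci_upper = c(object$ci_a[2], object$ci_b[2]),
    row.names = c("a", "b"))
  structure(list(coefficients = tab, r2 = object$r2, n = object$n,
                 space = object$space, level = object$level),
            class = "summary.allometric_fit")
}

#' @export
print.summary.allometric_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Allometric power-law fit (space: %s, n = %d)\n", x$space, x$n))
  cat(sprintf("Coefficients (SE of a on the log scale; %.0f%% CIs):\n",
              100 * x$level))
  print(round(x$coefficients, digits))
  cat(sprintf("R-squared: %.4f\n", x$r2))
  invisible(x)
}

#' Plot an allometric fit
#'
#' Scatter of the data with the fitted power-law curve overlaid.
#'
#' @param x An \code{"allometric_fit"}.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.allometric_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "X", ylab = "Y", ...)
  xs <- seq(min(x$x), max(x$x), length.out = 200)
  graphics::lines(xs, predict(x, xs), col = "forestgreen", lwd = 2)
  invisible(x)
}

#' Fit allometric models by group
#'
#' Convenience wrapper fitting one allometric model per level of a grouping
#' column, plus the pooled fit, in the style of per-cultivar or per-N-rate
#' parameter tables.
#'
#' @param data Data frame of observations.
#' @param y,x Column names of the response and predictor.
#' @param group Column name of the grouping factor, or \code{NULL} for the
#'   pooled fit only.
#' @param ... Passed to [fit_allometric()].
#' @return A data frame with one row per group (and a \code{"pooled"} row):
#'   group label, a, b, CI bounds, r2, n. The fit objects are attached as
#'   the \code{"fits"} attribute.
#' @export
fit_allometric_by_group <- function(data, y, x, group = NULL, ...) {
  stopifnot(y %in% names(data), x %in% names(data))
  mk_row <- function(label, fit) {
    data.frame(group = label, a = fit$a, b = fit$b,
               a_lower = fit$ci_a[1], a_upper = fit$ci_a[2],
               b_lower = fit$ci_b[1], b_upper = fit$ci_b[2],
               r2 = fit$r2, n = fit$n, stringsAsFactors = FALSE)
  }
  fits <- list(pooled = fit_allometric(data[[x]], data[[y]], ...))
  rows <- list(mk_row("pooled", fits$pooled))
  if (!is.null(group)) {
    stopifnot(group %in% names(data))
    for (g in unique(data[[group]])) {
      d <- data[data[[group]] == g, ]
      fits[[as.character(g)]] <- fit_allometric(d[[x]], d[[y]], ...)
      rows[[length(rows) + 1L]] <- mk_row(as.character(g),
                                          fits[[as.character(g)]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
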