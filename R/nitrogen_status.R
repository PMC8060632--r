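#' Critical nitrogen dilution curve
#'
#' The critical N concentration is the minimum shoot N concentration
#' permitting maximum growth at a given shoot dry matter, modelled as a
#' declining power law \eqn{N_c = A \cdot SDM^{B}} with \eqn{B < 0}
#' (N dilution). The default (4.15, -0.38) is the established winter-wheat
#' curve, with \eqn{N_c} in % of dry matter and SDM in t/ha.
#'
#' @param A Critical SNC at SDM = 1 t/ha, in % of dry matter. Must be > 0.
#' @param B Dimensionless dilution exponent. Must be < 0.
#' @return A list of class \code{"nc_curve"}.
#' @export
nc_curve <- function(A = 4.15, B = -0.38) {
  if (!is.finite(A) || A <= 0) stop("'A' must be > 0", call. = FALSE)
  if (!is.finite(B) || B >= 0) stop("'B' must be < 0", call. = FALSE)
  structure(list(A = A, B = B), class = "nc_curve")
}

#' @export
print.nc_curve <- function(x, ...) {
  cat(sprintf("Critical N dilution curve: Nc = %g * SDM^%g  (%% of DM, SDM in t/ha)\n",
              x$A, x$B))
  invisible(x)
}

#' Critical N concentration at a given shoot dry matter
#'
#' @param sdm Shoot dry matter, t/ha; strictly positive.
#' @param curve An [nc_curve()] (default the winter-wheat curve
#'   \eqn{4.15\,SDM^{-0.38}}).
#' @return Critical N concentration, % of dry matter.
#' @examples
#' critical_n(1)    # 4.15
#' critical_n(2)    # 4.15 * 2^-0.38
#' @export
critical_n <- function(sdm, curve = nc_curve()) {
  stopifnot(inherits(curve, "nc_curve"))
  if (any(!is.finite(sdm) | sdm <= 0))
    stop("'sdm' must be strictly positive", call. = FALSE)
  curve$A * sdm^curve$B
}

#' Nitrogen Nutrition Index
#'
#' NNI is the ratio of the measured shoot N concentration to the critical
#' concentration at the same shoot dry matter: NNI = 1 indicates optimal N
#' nutrition, NNI < 1 deficiency, NNI > 1 surplus (luxury uptake).
#'
#' @param snc Shoot N concentration, % of dry matter; strictly positive.
#' @param sdm Shoot dry matter, t/ha; strictly positive.
#' @param curve An [nc_curve()].
#' @return Dimensionless NNI values.
#' @examples
#' nni(4.15, 1)   # 1: optimal by construction
#' nni(2.075, 1)  # 0.5: deficient
#' @export
nni <- function(snc, sdm, curve = nc_curve()) {
  if (any(!is.finite(snc) | snc <= 0))
    stop("'snc' must be strictly positive", call. = FALSE)
  snc / critical_n(sdm, curve)
}

#' Classify N status from NNI
#'
#' Classifies each NNI value as \code{"deficient"} (below \eqn{1 - tol}),
#' \code{"surplus"} (above \eqn{1 + tol}) or \code{"optimal"}. The strict
#' boundary is at 1; the tolerance band acknowledges measurement noise and
#' defaults to 0.05.
#'
#' @param nni_value Positive NNI values.
#' @param tol Half-width of the optimal band (default 0.05).
#' @return Factor with levels deficient < optimal < surplus.
#' @examples
#' classify_n_status(c(0.52, 1.0, 1.31))
#' @export
classify_n_status <- function(nni_value, tol = 0.05) {
  if (any(!is.finite(nni_value) | nni_value <= 0))
    stop("NNI values must be strictly positive", call. = FALSE)
  out <- ifelse(nni_value < 1 - tol, "deficient",
                ifelse(nni_value > 1 + tol, "surplus", "optimal"))
  factor(out, levels = c("deficient", "optimal", "surplus"), ordered = TRUE)
}

#' Direct CC-to-NNI model
#'
#' Fits the allometric model \eqn{NNI = a \cdot CC^{b}} directly on paired
#' canopy cover and NNI observations (the "direct method").
#'
#' @param cc Canopy cover values in (0, 1].
#' @param nni_values NNI values.
#' @param stage Optional growth-stage label recorded in the model.
#' @param ... Passed to [fit_allometric()].
#' @return An object of class \code{"nni_model"} with elements
#'   \code{a_prime}, \code{b_prime}, \code{method = "direct"},
#'   \code{stage}, and the underlying \code{"allometric_fit"} in
#'   \code{provenance}.
#' @export
fit_nni_direct <- function(cc, nni_values, stage = NULL, ...) {
  fit <- fit_allometric(cc, nni_values, ...)
  structure(list(a_prime = fit$a, b_prime = fit$b, method = "direct",
                 stage = stage, provenance = fit),
            class = "nni_model")
}

#' Indirect CC-to-NNI model by power-law composition
#'
#' Composes a stage's fitted SNC and SDM power laws with the critical
#' dilution curve into a closed-form CC-to-NNI model, with no further
#' fitting. Substituting \eqn{SNC = a_s CC^{b_s}} and
#' \eqn{SDM = a_d CC^{b_d}} into \eqn{NNI = SNC / (A\,SDM^{B})} gives
#' \deqn{NNI = a' CC^{b'},\qquad a' = \frac{a_s\,a_d^{-B}}{A},\qquad
#'       b' = b_s - B\, b_d,}
#' which at the default curve (A = 4.15, B = -0.38) reduces to
#' \eqn{a' = a_s a_d^{0.38}/4.15} and \eqn{b' = b_s + 0.38 b_d}.
#'
#' @param a_s,b_s Coefficient and exponent of the SNC-vs-CC power law.
#' @param a_d,b_d Coefficient and exponent of the SDM-vs-CC power law.
#' @param curve An [nc_curve()].
#' @param stage Optional growth-stage label.
#' @return An object of class \code{"nni_model"} with
#'   \code{method = "indirect"}; \code{provenance} records the inputs.
#' @examples
#' # Feekes 5: SNC = 3.81 CC^0.5, SDM = 6.2 CC^1.74
#' m <- compose_indirect(a_s = 3.81, b_s = 0.5, a_d = 6.2, b_d = 1.74)
#' round(m$a_prime, 2)  # 1.84
#' @export
compose_indirect <- function(a_s, b_s, a_d, b_d, curve = nc_curve(),
                             stage = NULL) {
  stopifnot(inherits(curve, "nc_curve"))
  if (!is.finite(a_s) || a_s <= 0 || !is.finite(a_d) || a_d <= 0)
    stop("'a_s' and 'a_d' must be strictly positive", call. = FALSE)
  structure(
    list(a_prime = a_s * a_d^(-curve$B) / curve$A,
         b_prime = b_s - curve$B * b_d,
         method = "indirect", stage = stage,
         provenance = list(a_s = a_s, b_s = b_s, a_d = a_d, b_d = b_d,
                           curve = curve)),
    class = "nni_model")
}

#' @export
predict.nni_model <- function(object, cc, ...) {
  if (any(!is.finite(cc) | cc <= 0))
    stop("'cc' must be strictly positive", call. = FALSE)
  object$a_prime * cc^object$b_prime
}

#' @export
coef.nni_model <- function(object, ...) {
  c(a = object$a_prime, b = object$b_prime)
}

#' @export
print.nni_model <- function(x, digits = 3, ...) {
  cat(sprintf("CC-to-NNI model (%s method%s):\n", x$method,
              if (!is.null(x$stage)) paste0(", ", x$stage) else ""))
  cat(sprintf("  NNI = %s * CC^%s\n",
              format(x$a_prime, digits = digits),
              format(x$b_prime, digits = digits)))
  invisible(x)
}

#' Shoot N accumulation from dry matter and concentration
#'
#' Centralizes the unit conversion SNA [kg N/ha] = 10 x SDM [t/ha] x
#' SNC [% of DM].
#'
#' @param sdm Shoot dry matter, t/ha.
#' @param snc Shoot N concentration, % of dry matter.
#' @return Shoot N accumulation, kg N/ha.
#' @examples
#' sna_from(1, 4.15)  # 41.5 kg N/ha
#' @export
sna_from <- function(sdm, snc) 10 * sdm * snc

#' Append N-status columns to a trial table
#'
#' Computes the critical concentration, NNI and N-status class for every
#' row of a plot-record table.
#'
#' @param data Data frame with columns \code{sdm_t_ha} and \code{snc_pct}.
#' @param curve An [nc_curve()].
#' @param tol Optimal-band tolerance for [classify_n_status()].
#' @return \code{data} with added columns \code{nc_pct}, \code{nni},
#'   \code{n_status}.
#' @export
add_n_status <- function(data, curve = nc_curve(), tol = 0.05) {
  stopifnot(all(c("sdm_t_ha", "snc_pct") %in% names(data)))
  data$nc_pct <- critical_n(data$sdm_t_ha, curve)
  data$nni <- nni(data$snc_pct, data$sdm_t_ha, curve)
  data$n_status <- classify_n_status(data$nni, tol = tol)
  data
}
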