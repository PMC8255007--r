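#' Variance components of the direct-maternal animal model
#'
#' Container for the five (co)variance components of the multiple-birth
#' animal model: random herd-year variance, direct (calf) additive genetic
#' variance, maternal (dam) additive genetic variance, the direct-maternal
#' additive covariance, and the residual variance. Units are squared units of
#' the 1/2-coded response.
#'
#' @param herd_year variance of the random herd-year effect (`sigma2_h`).
#' @param direct direct additive genetic variance (`sigma2_a`).
#' @param maternal maternal additive genetic variance (`sigma2_m`).
#' @param covariance direct-maternal additive covariance (`sigma_am`); must
#'   satisfy `sigma_am^2 <= sigma2_a * sigma2_m`.
#' @param residual residual variance (`sigma2_e`).
#' @param se optional named numeric vector of standard errors.
#'
#' @return An object of class `variance_components` (a named list).
#' @examples
#' variance_components(
#'   herd_year = 0.992e-4, direct = 0.578e-4,
#'   maternal = 0.130e-2, covariance = -0.158e-3, residual = 0.036
#' )
#' @export
variance_components <- function(herd_year, direct, maternal, covariance = 0,
                                residual, se = NULL) {
  vals <- c(
    herd_year = herd_year, direct = direct, maternal = maternal,
    covariance = covariance, residual = residual
  )
  if (any(!is.finite(vals))) stop_twinqtl("variance components must be finite")
  if (herd_year < 0 || direct < 0 || maternal < 0 || residual < 0) {
    stop_twinqtl("variances must be non-negative")
  }
  if (covariance^2 > direct * maternal * (1 + 1e-12)) {
    stop_twinqtl(
      "direct-maternal covariance exceeds the bound ",
      "sigma_am^2 <= sigma2_a * sigma2_m"
    )
  }
  structure(
    list(
      herd_year = herd_year, direct = direct, maternal = maternal,
      covariance = covariance, residual = residual, se = se
    ),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  comp <- c("Herd-year", "Animal", "Dam", "Correlation animal/dam", "Residual")
  val <- c(x$herd_year, x$direct, x$maternal, x$covariance, x$residual)
  df <- data.frame(Component = comp, Value = signif(val, 4))
  if (!is.null(x$se)) df$SE <- signif(x$se[c(
    "herd_year", "direct", "maternal", "covariance", "residual"
  )], 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Direct and maternal heritability
#'
#' Computes the heritabilities of the direct and maternal genetic effects as
#' ratios of the corresponding genetic variance to the phenotypic variance
#' `sigma2_p = sigma2_h + sigma2_a + sigma2_m + sigma_am + sigma2_e`. The
#' direct-maternal covariance enters the phenotypic variance once: for a
#' record on a non-inbred calf, the calf's direct value and its dam's
#' maternal value have additive relationship 1/2 each way, so the covariance
#' contributes `2 * (1/2) * sigma_am`.
#'
#' @param vc a [variance_components()] object.
#' @return Named numeric vector `c(direct = ..., maternal = ...)`.
#' @examples
#' h2 <- heritabilities(variance_components(
#'   herd_year = 0.992e-4, direct = 0.578e-4,
#'   maternal = 0.130e-2, covariance = -0.158e-3, residual = 0.036
#' ))
#' round(h2, 4)
#' @export
heritabilities <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  s2p <- vc$herd_year + vc$direct + vc$maternal + vc$covariance + vc$residual
  if (s2p <= 0) stop_twinqtl("phenotypic variance is not positive")
  c(direct = vc$direct / s2p, maternal = vc$maternal / s2p)
}

#' Variance components of the study trait
#'
#' Convenience constructor holding the raw variance components estimated for
#' maternal multiple birth in the Swiss Holstein dataset (herd-year
#' 0.992e-4, direct 0.578e-4, maternal 0.130e-2, direct-maternal covariance
#' -0.158e-3, residual 0.036). These are the default simulation truth of
#' [sim_config()].
#'
#' @return A [variance_components()] object.
#' @export
reference_variance_components <- function() {
  variance_components(
    herd_year = 0.992e-4, direct = 0.578e-4, maternal = 0.130e-2,
    covariance = -0.158e-3, residual = 0.036
  )
}
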