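# EBV post-processing: scale-corrected slopes, variance/heritability
# profiles along the EC, and PEV-based accuracies.

#' Scale-corrected slope breeding values
#'
#' Removes the genetic regression of the slope on the intercept,
#' `a1* = a1 - (sigma_a0a1 / sigma2_a0) * a0`, isolating robustness that is
#' independent of overall merit. The PEV of `a1*` is not derived; the `a1`
#' accuracy serves as its approximation.
#'
#' @param x An `rn_blup` or a data.frame with columns `a0` and `a1`.
#' @param varcomp Variance components holding the 2x2 genetic covariance K.
#' @return `x` with an added `a1_star` column (in the `ebv` element for an
#'   `rn_blup`).
#' @export
#' @examples
#' K <- matrix(c(11.35, 0.64 * sqrt(11.35 * 1.98),
#'               0.64 * sqrt(11.35 * 1.98), 1.98), 2, 2)
#' vc <- rn_varcomp(K = K, sigma2_e = 15, breaks = c(-75, 75))
#' scale_correct(data.frame(a0 = 2, a1 = 0.5), vc)$a1_star # -0.0347
scale_correct <- function(x, varcomp) {
  K <- varcomp$K
  if (is.null(K)) stop("varcomp must contain the 2x2 genetic covariance K")
  if (K[1, 1] <= 0) stop("intercept genetic variance must be positive")
  b <- K[1, 2] / K[1, 1]
  if (inherits(x, "rn_blup")) {
    x$ebv$a1_star <- x$ebv$a1 - b * x$ebv$a0
    return(x)
  }
  x$a1_star <- x$a1 - b * x$a0
  x
}

#' Genetic variance and heritability along the EC
#'
#' Genetic variance at EC level `x` is `lambda' K lambda` with
#' `lambda = (1, x)'`, i.e. `sigma2_a0 + 2 x sigma_a0a1 + x^2 sigma2_a1`.
#' Heritability divides it by the sum of genetic, maternal genetic (if
#' fitted), permanent environmental dam, and residual variance at that EC
#' level.
#'
#' @param varcomp An `rn_varcomp` with K and a residual model.
#' @param ec_grid Numeric grid of EC values in standardized units; must lie
#'   within the fitted EC range.
#' @return Data.frame with `x`, `genetic_variance`, `residual_variance`,
#'   `heritability`.
#' @export
variance_profile <- function(varcomp, ec_grid) {
  K <- varcomp$K
  if (is.null(K)) stop("varcomp must contain K")
  rng <- varcomp$ec_range_std
  if (any(ec_grid < rng[1] - 1e-8 | ec_grid > rng[2] + 1e-8))
    stop("EC grid point outside the fitted range [",
         signif(rng[1], 3), ", ", signif(rng[2], 3), "]")
  gv <- K[1, 1] + 2 * ec_grid * K[1, 2] + ec_grid^2 * K[2, 2]
  if (identical(varcomp$residual_type, "continuous")) {
    E <- varcomp$E
    rv <- E[1, 1] + 2 * ec_grid * E[1, 2] + ec_grid^2 * E[2, 2]
  } else {
    s <- varcomp$sigma2_e
    if (is.null(varcomp$breaks)) {
      rv <- rep(s[1], length(ec_grid))
    } else {
      if (!is.finite(varcomp$ec_sd))
        stop("class residual profile needs ec_sd to map the grid to g/day")
      cls <- findInterval(ec_grid * varcomp$ec_sd, varcomp$breaks,
                          rightmost.closed = TRUE)
      if (any(cls < 1 | cls > length(s)))
        stop("EC grid point outside the residual class breakpoints")
      rv <- s[cls]
    }
  }
  denom <- gv + rv + (varcomp$sigma2_c %||% 0) + (varcomp$sigma2_m %||% 0)
  data.frame(x = ec_grid, genetic_variance = gv, residual_variance = rv,
             heritability = gv / denom)
}

#' EBV accuracy from prediction error variance
#'
#' `r = sqrt(1 - PEV / sigma2)`. PEV marginally above the prior variance
#' (numerical noise) is clipped with a warning.
#'
#' @param pev Prediction error variance(s).
#' @param prior_variance The genetic variance of the component.
#' @return Accuracies in `[0, 1]`.
#' @export
accuracy_from_pev <- function(pev, prior_variance) {
  if (any(prior_variance <= 0)) stop("prior variance must be positive")
  if (any(pev < 0)) stop("PEV must be non-negative")
  over <- pev > prior_variance
  if (any(over)) {
    if (any(pev > prior_variance * 1.05))
      stop("PEV substantially exceeds the prior variance")
    warning("PEV marginally above the prior variance clipped")
    pev <- pmin(pev, prior_variance)
  }
  sqrt(1 - pev / prior_variance)
}

#' Share of slope variance due to scale-type GxE
#'
#' With intercept-slope genetic correlation `r`, the fraction of slope
#' variance attributable to scale-type (variance heterogeneity) interaction
#' is `r^2`, reported as a percentage.
#'
#' @param r_a0a1 Genetic correlation between intercept and slope.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' scale_type_share(0.04) # 0.16
scale_type_share <- function(r_a0a1) {
  if (any(abs(r_a0a1) > 1)) stop("correlation must lie in [-1, 1]")
  100 * r_a0a1^2
}

#' Ratio of slope to intercept genetic variance
#'
#' @param varcomp An `rn_varcomp` with K.
#' @return `sigma2_a1 / sigma2_a0`.
#' @export
slope_intercept_ratio <- function(varcomp) {
  K <- varcomp$K
  if (is.null(K)) stop("varcomp must contain K")
  K[2, 2] / K[1, 1]
}

#' Convert a slope between per-SD-EC and per-(g/day) scales
#'
#' The EC enters the model standardized to unit variance; slopes are
#' therefore per SD of EC. Dividing by the EC standard deviation (g/day)
#' gives kg per g/day; variances scale by the square.
#'
#' @param slope Slope value(s) per SD of EC.
#' @param ec_sd EC standard deviation in g/day.
#' @return Slope per g/day.
#' @export
slope_per_gday <- function(slope, ec_sd) {
  if (!is.finite(ec_sd) || ec_sd <= 0) stop("ec_sd must be positive")
  slope / ec_sd
}
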