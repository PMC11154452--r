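# Packaged final population model and reference values.

#' Reference covariate values used for centering
#'
#' Continuous covariates enter the model as deviations from rounded
#' population-typical reference values: total body water 10 L, serum albumin
#' 30 g/L, infusion duration 3 h. Missing covariate values are replaced by
#' these references (equivalently, their centered term is set to 0).
#'
#' @return Named list with elements `tbw` (L), `albumin` (g/L) and `tinf_h` (h).
#' @export
bu_reference_values <- function() {
  list(tbw = 10, albumin = 30, tinf_h = 3)
}

#' Final population-pharmacokinetic model for twice-daily IV busulfan
#'
#' Packaged parameter set of the final covariate model: a one-compartment
#' multi-infusion model whose elimination rate constant declines
#' exponentially over therapy time (amplitude `d_k`, rate `kappa_k`),
#' with covariates
#' \itemize{
#'   \item `ln V`: intercept, centered `ln TBW`, infusion-duration shift;
#'   \item `ln k`: intercept, centered `ln TBW`, `ln F_mat` (maturation),
#'     centered `ln albumin`, ALL indicator, infusion-duration shift;
#'   \item `d_k`: intercept and HLH/XLP indicator.
#' }
#' Random effects (diagonal) act on `ln V`, `ln k` and `d_k`; the residual
#' error model is additive on the concentration scale (mg/L).
#'
#' @return A `bu_popmodel` object: list with `spec` (a [bu_model_spec()]),
#'   `theta` (named fixed effects), `omega2` (random-effect variances),
#'   `sigma` (additive residual SD, mg/L), `se` (standard errors of the fixed
#'   effects) and `boot_ci` (tibble of 95% bootstrap confidence intervals).
#' @examples
#' m <- bu_final_model()
#' exp(m$theta[["lnV_0"]])  # typical distribution volume at reference covariates
#' @export
bu_final_model <- function() {
  theta <- c(
    lnV_0        = 2.459,
    lnV_dln_tbw  = 0.931,
    lnV_dtinf    = 0.226,
    lnk_0        = -1.007,
    lnk_dln_tbw  = -0.189,
    lnk_ln_fmat  = 0.697,
    lnk_dln_alb  = 0.331,
    lnk_all      = -0.210,
    lnk_dtinf    = -0.161,
    dk_0         = -0.167,
    dk_hlh_xlp   = -0.145,
    lnkappa      = -2.965
  )
  se <- c(
    lnV_0 = 0.0189, lnV_dln_tbw = 0.0233, lnV_dtinf = 0.0356,
    lnk_0 = 0.0329, lnk_dln_tbw = 0.0411, lnk_ln_fmat = 0.2001,
    lnk_dln_alb = 0.1073, lnk_all = 0.0592, lnk_dtinf = 0.0420,
    dk_0 = 0.0191, dk_hlh_xlp = 0.0540, lnkappa = 0.1094
  )
  boot_ci <- tibble::tibble(
    term  = names(theta),
    lower = c(2.432, 0.872, 0.134, -1.065, -0.291, 0.348, 0.090, -0.398,
              -0.264, -0.198, -0.255, -3.204),
    upper = c(2.491, 0.987, 0.329, -0.952, -0.106, 1.061, 0.653, -0.030,
              -0.085, -0.122, -0.030, -2.390)
  )
  structure(
    list(
      spec = bu_final_model_spec(),
      theta = theta,
      omega2 = c(lnV = 0.029, lnk = 0.033, dk = 0.032),
      sigma = 0.076,
      se = se,
      boot_ci = boot_ci,
      n_subjects = 124
    ),
    class = "bu_popmodel"
  )
}

#' @export
print.bu_popmodel <- function(x, ...) {
  cat("<bu_popmodel>\n")
  cat("Fixed effects:\n")
  print(round(x$theta, 4))
  cat("Random-effect variances (Omega^2):\n")
  print(round(x$omega2, 4))
  cat("Additive residual SD (mg/L):", x$sigma, "\n")
  invisible(x)
}

# Coarse median weight/height-for-age table used by the cohort generator.
# Values approximate pediatric growth medians (pooled sexes); adequate to
# induce the W-H-age-TBW correlation structure the model needs.
bu_growth_table <- function() {
  tibble::tibble(
    age    = c(0.2, 0.5, 1, 2, 4, 6, 8, 10, 14, 18, 27),
    weight = c(5.5, 7.5, 9.5, 12, 16, 20, 25, 31, 48, 62, 68),
    height = c(58, 66, 75, 86, 102, 115, 128, 138, 160, 170, 172)
  )
}
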