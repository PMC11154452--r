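# Model specification: which derived covariates enter which parameter, and
# construction of individual parameters from fixed effects + random effects.

#' Specify a population PK model
#'
#' Defines the covariate map of the nonlinear mixed-effects model. Each
#' parameter is modeled on its transformed scale as a linear combination of
#' an intercept and derived-covariate terms (columns produced by
#' [derive_covariates()]), plus a subject random effect:
#' `ln V = th_V0 + sum(th * x) + eta_V`, `ln k` analogous, and (for the
#' dynamic model) `d_k = th_dk0 + sum(th * z) + eta_dk` with
#' `kappa = exp(th_kappa)` shared across subjects (no random effect).
#'
#' @param lnV,lnk,dk Character vectors of derived-covariate column names.
#' @param dynamic If `FALSE`, the elimination rate constant is constant over
#'   therapy time (`d_k` and `kappa` absent).
#' @param random Parameters carrying a random effect.
#' @param comed Optional tibble with columns `drug` and `param` (`"lnV"` or
#'   `"lnk"`): multiplicative co-medication effects, active for dosing
#'   intervals whose infusion started within `comed_window_h` hours after a
#'   recorded administration.
#' @param comed_window_h Look-back window for co-medication activity (h).
#' @return A `bu_model_spec` object.
#' @export
bu_model_spec <- function(lnV = character(), lnk = character(),
                          dk = character(), dynamic = TRUE,
                          random = if (dynamic) c("lnV", "lnk", "dk")
                                  else c("lnV", "lnk"),
                          comed = NULL, comed_window_h = 24) {
  if (!dynamic && length(dk) > 0) {
    abort("`dk` covariates require `dynamic = TRUE`.")
  }
  random <- match.arg(random, c("lnV", "lnk", "dk"), several.ok = TRUE)
  if (!dynamic) random <- setdiff(random, "dk")
  structure(
    list(lnV = lnV, lnk = lnk, dk = dk, dynamic = dynamic, random = random,
         comed = comed, comed_window_h = comed_window_h),
    class = "bu_model_spec"
  )
}

#' Covariate map of the final busulfan model
#'
#' Centered `ln TBW` and the infusion-duration shift on `ln V`; centered
#' `ln TBW`, `ln F_mat`, centered `ln albumin`, the ALL indicator and the
#' infusion-duration shift on `ln k`; the HLH/XLP indicator on `d_k`.
#'
#' @return A [bu_model_spec()].
#' @export
bu_final_model_spec <- function() {
  bu_model_spec(
    lnV = c("dln_tbw", "dtinf"),
    lnk = c("dln_tbw", "ln_fmat", "dln_alb", "all", "dtinf"),
    dk = "hlh_xlp"
  )
}

#' @export
print.bu_model_spec <- function(x, ...) {
  cat("<bu_model_spec>", if (x$dynamic) "dynamic" else "static",
      "elimination\n")
  cat("  lnV ~ 1", if (length(x$lnV)) paste("+", paste(x$lnV, collapse = " + ")), "\n")
  cat("  lnk ~ 1", if (length(x$lnk)) paste("+", paste(x$lnk, collapse = " + ")), "\n")
  if (x$dynamic) {
    cat("  dk  ~ 1", if (length(x$dk)) paste("+", paste(x$dk, collapse = " + ")), "\n")
  }
  cat("  random effects:", paste(x$random, collapse = ", "), "\n")
  if (!is.null(x$comed) && nrow(x$comed) > 0) {
    cat("  co-medication effects:",
        paste(x$comed$drug, "on", x$comed$param, collapse = "; "), "\n")
  }
  invisible(x)
}

# Names of the fixed-effect vector for a spec.
theta_names <- function(spec) {
  nm <- c(term_names("lnV", spec$lnV), term_names("lnk", spec$lnk))
  if (spec$dynamic) {
    nm <- c(nm, term_names("dk", spec$dk), "lnkappa")
  }
  if (!is.null(spec$comed) && nrow(spec$comed) > 0) {
    nm <- c(nm, paste0("comed_", spec$comed$param, "_",
                       gsub("[^A-Za-z0-9]", "", spec$comed$drug)))
  }
  nm
}

# Per-parameter design matrices from derived covariates.
design_matrices <- function(spec, dcov) {
  mk <- function(terms) {
    miss <- setdiff(terms, names(dcov))
    if (length(miss) > 0) {
      abort(paste0("Derived covariate(s) not available: ",
                   paste(miss, collapse = ", ")))
    }
    cbind(`0` = rep(1, nrow(dcov)),
          as.matrix(dcov[, terms, drop = FALSE]))
  }
  out <- list(lnV = mk(spec$lnV), lnk = mk(spec$lnk))
  if (spec$dynamic) out$dk <- mk(spec$dk)
  out
}

#' Individual parameters from a population model
#'
#' Applies the covariate map and random-effect vector of a population model
#' to derived subject covariates, yielding each subject's `V`, `k`, `d_k`
#' and `kappa_k`.
#'
#' @param pop A `bu_popmodel` (e.g. [bu_final_model()]) or `bu_fit`.
#' @param dcov Derived covariates from [derive_covariates()].
#' @param eta Matrix (or data frame) of random effects with columns among
#'   `lnV`, `lnk`, `dk` and one row per subject; defaults to zeros
#'   (population-typical subjects).
#' @return Tibble with `subject_id`, `V` (L), `k` (1/h), `dk`, `kappa` (1/h).
#' @examples
#' cov <- tibble::tibble(subject_id = "a", weight = 17.2, height = 105,
#'                       age = 4.3, sex = "male", disease_group = "CGD",
#'                       albumin = 34, tinf_h = 3)
#' individual_params(bu_final_model(), derive_covariates(cov))
#' @export
individual_params <- function(pop, dcov, eta = NULL) {
  spec <- pop$spec
  theta <- pop$theta
  X <- design_matrices(spec, dcov)
  n <- nrow(dcov)
  if (is.null(eta)) {
    eta <- matrix(0, n, length(spec$random),
                  dimnames = list(NULL, spec$random))
  }
  eta <- as.matrix(eta)
  getcol <- function(p) if (p %in% colnames(eta)) eta[, p] else rep(0, n)
  blk <- function(p) theta[term_names(p, spec[[p]])]
  lnV <- drop(X$lnV %*% blk("lnV")) + getcol("lnV")
  lnk <- drop(X$lnk %*% blk("lnk")) + getcol("lnk")
  if (spec$dynamic) {
    dk <- drop(X$dk %*% blk("dk")) + getcol("dk")
    kappa <- exp(theta[["lnkappa"]])
  } else {
    dk <- rep(0, n); kappa <- NA_real_
  }
  if (any(1 + dk <= 0)) {
    abort("Invalid individual parameters: 1 + dk must stay positive.")
  }
  tibble(subject_id = dcov$subject_id, V = as.numeric(exp(lnV)),
         k = as.numeric(exp(lnk)), dk = as.numeric(dk), kappa = kappa)
}

# theta-vector names of one parameter block (intercept + covariate slopes)
term_names <- function(p, terms) {
  c(paste0(p, "_0"), paste0(p, "_", terms, recycle0 = TRUE))
}
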