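# broom-style summaries of fitted objects.

#' Tidy a SAEM fit
#'
#' @param x A `bu_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `block` (`fixed`,
#'   `variance`, `residual`), `estimate` and, for fixed effects of `ln`
#'   parameters, `exp_estimate`.
#' @method tidy bu_fit
#' @export
tidy.bu_fit <- function(x, ...) {
  fixed <- tibble(
    term = names(x$theta), block = "fixed", estimate = unname(x$theta),
    exp_estimate = ifelse(grepl("^ln|_0$", names(x$theta)) &
                            !startsWith(names(x$theta), "dk"),
                          exp(unname(x$theta)), NA_real_)
  )
  fixed$exp_estimate[!fixed$term %in%
                       c("lnV_0", "lnk_0", "lnkappa")] <- NA_real_
  vars <- tibble(
    term = paste0("omega2_", names(x$omega2)), block = "variance",
    estimate = unname(x$omega2), exp_estimate = NA_real_
  )
  resid <- tibble(term = "sigma", block = "residual", estimate = x$sigma,
                  exp_estimate = NA_real_)
  bind_rows(fixed, vars, resid)
}

#' Glance at a SAEM fit
#'
#' @inheritParams tidy.bu_fit
#' @return One-row tibble: subjects, observations, residual SD, convergence
#'   flag and shrinkage per random effect.
#' @method glance bu_fit
#' @export
glance.bu_fit <- function(x, ...) {
  out <- tibble(
    n_subjects = x$n_subjects, n_obs = x$n_obs, sigma = x$sigma,
    converged = x$converged
  )
  for (p in names(x$shrinkage)) {
    out[[paste0("shrinkage_", p)]] <- x$shrinkage[[p]]
  }
  out
}

#' Tidy a bootstrap result
#'
#' @param x A `bu_boot`.
#' @param ... Unused.
#' @return Tibble `term`, `lower`, `upper` (95% percentile interval).
#' @method tidy bu_boot
#' @export
tidy.bu_boot <- function(x, ...) x$ci

#' Tidy a packaged population model
#'
#' @param x A `bu_popmodel`.
#' @param ... Unused.
#' @return Tibble with fixed effects, their SEs and bootstrap CIs.
#' @method tidy bu_popmodel
#' @export
tidy.bu_popmodel <- function(x, ...) {
  tibble(term = names(x$theta), estimate = unname(x$theta),
         se = unname(x$se[names(x$theta)])) |>
    left_join(x$boot_ci, by = "term")
}
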