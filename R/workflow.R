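# Stepwise covariate model building: basic structural model, greedy forward
# inclusion, backward elimination and co-medication effect testing.

#' Covariate selection criteria
#'
#' Thresholds of the model-building procedure: a candidate is kept in a
#' forward round if it gives the largest likelihood improvement and
#' `-2LL` drops by more than the chi-square(1) critical value 3.84
#' (p = 0.05), and its maximal effect across the observed covariate range is
#' at least 0.1 on the log scale (~10%); a covariate survives backward
#' elimination if its removal raises `-2LL` by more than 6.63 (p = 0.01).
#' Random effects are retained when their shrinkage in the basic model is
#' below 0.4. Co-medication counts as active within 24 h before an infusion.
#'
#' @param include_delta_2ll,exclude_delta_2ll,min_effect_magnitude,shrinkage_cap,comed_window_h
#'   Override individual thresholds.
#' @return Named list of thresholds.
#' @export
bu_selection_criteria <- function(include_delta_2ll = 3.84,
                                  exclude_delta_2ll = 6.63,
                                  min_effect_magnitude = 0.1,
                                  shrinkage_cap = 0.4,
                                  comed_window_h = 24) {
  list(include_delta_2ll = include_delta_2ll,
       exclude_delta_2ll = exclude_delta_2ll,
       min_effect_magnitude = min_effect_magnitude,
       shrinkage_cap = shrinkage_cap,
       comed_window_h = comed_window_h)
}

spec_add_term <- function(spec, param, term) {
  spec[[param]] <- c(spec[[param]], term)
  bu_model_spec(lnV = spec$lnV, lnk = spec$lnk, dk = spec$dk,
                dynamic = spec$dynamic, random = spec$random,
                comed = spec$comed, comed_window_h = spec$comed_window_h)
}

spec_drop_term <- function(spec, param, term) {
  spec[[param]] <- setdiff(spec[[param]], term)
  bu_model_spec(lnV = spec$lnV, lnk = spec$lnk, dk = spec$dk,
                dynamic = spec$dynamic, random = spec$random,
                comed = spec$comed, comed_window_h = spec$comed_window_h)
}

# |theta| times the observed covariate range: the maximal effect (log scale)
# the covariate exerts across the population.
effect_magnitude <- function(theta_hat, term, dcov) {
  if (!term %in% names(dcov)) return(NA_real_)
  x <- dcov[[term]]
  abs(theta_hat) * diff(range(x, na.rm = TRUE))
}

#' Build the basic structural model
#'
#' Fits the static-elimination model (parameters `ln V`, `ln k` with random
#' effects on both) and the dynamic extension (`d_k`, `ln kappa` added;
#' random effects on `ln V`, `ln k` and `d_k`, none on `ln kappa`), and
#' selects the dynamic model if it lowers the importance-sampling `-2LL` by
#' more than the chi-square critical value for the 3 added parameters
#' (7.82, p = 0.05).
#'
#' @param ds A [bu_dataset()].
#' @param settings [saem_settings()] used for both fits.
#' @param n_mc Importance-sampling draws for the likelihoods.
#' @param seed Seed for the likelihood comparison (shared by both models).
#' @return List with the selected `fit`, the `comparison` tibble
#'   (model, df, -2LL, delta) and the static/dynamic fits.
#' @export
build_basic_model <- function(ds, settings = saem_settings(), n_mc = 1000,
                              seed = 1) {
  fit_static <- fit_saem(ds, bu_model_spec(dynamic = FALSE), settings)
  fit_dyn <- fit_saem(ds, bu_model_spec(dynamic = TRUE), settings)
  if (!fit_static$converged && !fit_dyn$converged) {
    abort("Neither basic-model candidate converged.")
  }
  ll_static <- loglik_is(fit_static, n_mc, seed)
  ll_dyn <- loglik_is(fit_dyn, n_mc, seed)
  delta <- ll_dyn - ll_static
  pick_dynamic <- delta <= -7.82
  comparison <- tibble(
    model = c("static k", "dynamic k (no eta on ln kappa)"),
    df = c(2 + 2 + 1, 4 + 3 + 1),
    neg2ll = c(ll_static, ll_dyn),
    delta_2ll = c(0, delta),
    selected = c(!pick_dynamic, pick_dynamic)
  )
  list(fit = if (pick_dynamic) fit_dyn else fit_static,
       comparison = comparison,
       static = fit_static, dynamic = fit_dyn)
}

#' Default forward-selection candidate set
#'
#' Body-size alternates (`W`, `H`, `BSA`, `FFM`, `TBW`, mutually exclusive
#' per parameter), maturation, albumin, disease indicators, infusion
#' duration and laboratory values, mapped to the parameters on which they
#' were screened.
#'
#' @return Tibble with columns `term`, `param`, `group`.
#' @export
bu_candidate_covariates <- function() {
  body <- c("dln_w", "dln_h", "dln_bsa", "dln_ffm", "dln_tbw")
  bind_rows(
    tibble(term = body, param = "lnV", group = "bodysize_lnV"),
    tibble(term = "dtinf", param = "lnV", group = NA),
    tibble(term = "dtinf", param = "lnk", group = NA),
    tibble(term = "all", param = "lnk", group = NA),
    tibble(term = "hlh_xlp", param = "dk", group = NA),
    tibble(term = "dln_alb", param = "lnk", group = NA),
    tibble(term = "dln_tbw", param = "lnk", group = "bodysize_lnk"),
    tibble(term = "ln_fmat", param = "lnk", group = NA)
  )
}

#' Greedy forward covariate inclusion
#'
#' In each round, every remaining candidate `(term, parameter)` is added
#' singly to the current model and refitted; the candidate with the largest
#' `-2LL` reduction is included if the reduction exceeds the inclusion
#' threshold and its maximal effect across the covariate range is at least
#' the magnitude threshold. Mutually exclusive candidates (same `group`,
#' e.g. alternative body-size metrics) leave the pool once one of them is
#' included. Rounds repeat until no candidate qualifies.
#'
#' @param ds A [bu_dataset()].
#' @param basic A fitted `bu_fit` to start from.
#' @param candidates Tibble `term`, `param` and optional `group`; defaults
#'   to [bu_candidate_covariates()].
#' @param criteria [bu_selection_criteria()].
#' @param settings,n_mc,seed Passed to [fit_saem()] and [loglik_is()]; the
#'   same likelihood seed is used for all nested comparisons.
#' @return List with the final `fit`, its `neg2ll` and the selection `trace`
#'   (round, candidate, delta -2LL, effect size, magnitude, decision).
#' @export
forward_select <- function(ds, basic, candidates = bu_candidate_covariates(),
                           criteria = bu_selection_criteria(),
                           settings = saem_settings(), n_mc = 1000,
                           seed = 1) {
  if (nrow(candidates) == 0) {
    return(list(fit = basic, neg2ll = loglik_is(basic, n_mc, seed),
                trace = tibble()))
  }
  if (!"group" %in% names(candidates)) candidates$group <- NA_character_
  dcov <- derive_covariates(ds$covariates)
  current <- basic
  ll_ref <- loglik_is(basic, n_mc, seed)
  pool <- candidates
  trace <- list()
  round <- 0
  repeat {
    round <- round + 1
    rows <- list()
    fits <- list()
    for (i in seq_len(nrow(pool))) {
      cand <- pool[i, ]
      spec_i <- spec_add_term(current$spec, cand$param, cand$term)
      fit_i <- fit_saem(ds, spec_i, settings)
      ll_i <- loglik_is(fit_i, n_mc, seed)
      th <- unname(fit_i$theta[paste0(cand$param, "_", cand$term)])
      rows[[i]] <- tibble(
        round = round, term = cand$term, param = cand$param,
        delta_2ll = ll_i - ll_ref, effect = th,
        magnitude = effect_magnitude(th, cand$term, dcov),
        decision = "deferred"
      )
      fits[[i]] <- fit_i
    }
    rows <- bind_rows(rows)
    best <- which.min(rows$delta_2ll)
    pass_ll <- rows$delta_2ll[best] <= -criteria$include_delta_2ll
    pass_eff <- isTRUE(rows$magnitude[best] >=
                         criteria$min_effect_magnitude)
    if (pass_ll && pass_eff) {
      rows$decision[best] <- "included"
      current <- fits[[best]]
      ll_ref <- rows$delta_2ll[best] + ll_ref
      grp <- pool$group[best]
      keep <- rep(TRUE, nrow(pool))
      keep[best] <- FALSE
      if (!is.na(grp)) keep[pool$group %in% grp] <- FALSE
      pool <- pool[keep, ]
      trace[[round]] <- rows
      if (nrow(pool) == 0) break
    } else {
      rows$decision[best] <- if (!pass_ll) "rejected-d2LL" else
        "rejected-effect"
      trace[[round]] <- rows
      break
    }
  }
  list(fit = current, neg2ll = ll_ref, trace = bind_rows(trace))
}

#' Backward elimination of covariates
#'
#' Each covariate of the fitted model is removed singly and the model
#' refitted; the covariate is kept only if its removal raises `-2LL` by
#' more than the exclusion threshold (6.63, p = 0.01). Covariates failing
#' the check are removed and the reduced model refitted.
#'
#' @inheritParams forward_select
#' @param full A fitted `bu_fit` containing at least one covariate.
#' @return List with the final `fit`, `neg2ll` and the elimination `trace`.
#' @export
backward_eliminate <- function(ds, full, criteria = bu_selection_criteria(),
                               settings = saem_settings(), n_mc = 1000,
                               seed = 1) {
  spec <- full$spec
  terms <- bind_rows(
    tibble(param = "lnV", term = spec$lnV),
    tibble(param = "lnk", term = spec$lnk),
    if (spec$dynamic) tibble(param = "dk", term = spec$dk)
  )
  if (nrow(terms) == 0) {
    return(list(fit = full, neg2ll = loglik_is(full, n_mc, seed),
                trace = tibble()))
  }
  ll_full <- loglik_is(full, n_mc, seed)
  trace <- list()
  for (i in seq_len(nrow(terms))) {
    spec_i <- spec_drop_term(spec, terms$param[i], terms$term[i])
    fit_i <- fit_saem(ds, spec_i, settings)
    ll_i <- loglik_is(fit_i, n_mc, seed)
    delta <- ll_i - ll_full
    trace[[i]] <- tibble(
      term = terms$term[i], param = terms$param[i], delta_2ll = delta,
      decision = if (delta > criteria$exclude_delta_2ll) "kept" else
        "rejected-backward"
    )
  }
  trace <- bind_rows(trace)
  dropped <- trace[trace$decision == "rejected-backward", ]
  fit_final <- full
  ll_final <- ll_full
  if (nrow(dropped) > 0) {
    spec_f <- spec
    for (i in seq_len(nrow(dropped))) {
      spec_f <- spec_drop_term(spec_f, dropped$param[i], dropped$term[i])
    }
    fit_final <- fit_saem(ds, spec_f, settings)
    ll_final <- loglik_is(fit_final, n_mc, seed)
  }
  list(fit = fit_final, neg2ll = ll_final, trace = trace)
}

#' Test co-medication effects
#'
#' For each (drug, parameter) pair, a multiplicative effect — active for
#' dosing intervals whose infusion started within the look-back window
#' after an administration of the drug — is added as a fixed effect to the
#' objective function and refitted. The inclusion criteria are the same as
#' for covariates; drugs never administered in the dataset are skipped.
#'
#' @inheritParams forward_select
#' @param model The current `bu_fit`.
#' @param drugs Character vector of drug labels, or a tibble with columns
#'   `drug` and `param` for specific pairs. Character input is expanded to
#'   both `lnk` and `lnV`.
#' @return Selection trace tibble (drug, param, delta -2LL, effect,
#'   decision).
#' @export
test_comedication <- function(ds, model, drugs,
                              criteria = bu_selection_criteria(),
                              settings = saem_settings(), n_mc = 1000,
                              seed = 1) {
  if (is.character(drugs)) {
    drugs <- tidyr::expand_grid(drug = drugs, param = c("lnk", "lnV"))
  }
  ll_ref <- loglik_is(model, n_mc, seed)
  out <- list()
  for (i in seq_len(nrow(drugs))) {
    drug <- drugs$drug[i]; param <- drugs$param[i]
    if (!drug %in% ds$comedication$drug) {
      out[[i]] <- tibble(drug = drug, param = param, delta_2ll = NA_real_,
                         effect = NA_real_, decision = "skipped-absent")
      inform(paste0("Drug '", drug, "' never administered; skipped."))
      next
    }
    spec_i <- model$spec
    spec_i$comed <- tibble(drug = drug, param = param)
    spec_i$comed_window_h <- criteria$comed_window_h
    spec_i <- bu_model_spec(lnV = spec_i$lnV, lnk = spec_i$lnk,
                            dk = spec_i$dk, dynamic = spec_i$dynamic,
                            random = spec_i$random, comed = spec_i$comed,
                            comed_window_h = spec_i$comed_window_h)
    fit_i <- fit_saem(ds, spec_i, settings)
    ll_i <- loglik_is(fit_i, n_mc, seed)
    nm <- paste0("comed_", param, "_", gsub("[^A-Za-z0-9]", "", drug))
    th <- unname(fit_i$theta[nm])
    delta <- ll_i - ll_ref
    decision <- if (delta > -criteria$include_delta_2ll) "rejected-d2LL"
      else if (abs(th) < criteria$min_effect_magnitude) "rejected-effect"
      else "included"
    out[[i]] <- tibble(drug = drug, param = param, delta_2ll = delta,
                       effect = th, decision = decision)
  }
  bind_rows(out)
}
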