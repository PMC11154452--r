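# Stochastic approximation EM engine for the nonlinear mixed-effects model.
#
# The individual parameter vector is phi_i = (lnV_i, lnk_i[, dk_i]) with
# phi_i = X_i theta + eta_i, eta_i ~ N(0, diag(Omega^2)); ln(kappa) and any
# co-medication effects are fixed effects without random effects and are
# updated by minimizing the complete-data residual sum of squares. The
# residual error model is additive on the concentration scale.

#' SAEM settings
#'
#' @param n_explore,n_smooth Iterations of the exploration phase (step size
#'   1, simulated-annealing variance decay) and smoothing phase (step size
#'   `1/iter`). Final-model fits use 2000/300; model building uses 600/100.
#' @param seed Integer seed for reproducibility.
#' @param starts Named numeric vector overriding default start values
#'   (defaults: `lnV_0 = 2.5`, `lnk_0 = -1`, `dk_0 = 0`,
#'   `lnkappa = log(log(2)/24)`, covariate effects 0).
#' @param perturb Half-width of a uniform random perturbation applied to the
#'   `lnV_0` and `lnk_0` start values (the final-model protocol samples
#'   starts within +/-1; bootstrap refits use fixed starts, `perturb = 0`).
#' @param ebe_iter MCMC iterations used for the empirical Bayes estimates
#'   after the SAEM run (second half is averaged).
#' @return List of settings.
#' @export
saem_settings <- function(n_explore = 600, n_smooth = 100, seed = NULL,
                          starts = NULL, perturb = 0, ebe_iter = 80) {
  list(n_explore = n_explore, n_smooth = n_smooth, seed = seed,
       starts = starts, perturb = perturb, ebe_iter = ebe_iter)
}

default_starts <- function(spec) {
  th <- setNames(rep(0, length(theta_names(spec))), theta_names(spec))
  th["lnV_0"] <- 2.5
  th["lnk_0"] <- -1
  if (spec$dynamic) {
    th["dk_0"] <- 0
    th["lnkappa"] <- log(log(2) / 24)
  }
  th
}

# ---- dataset -> evaluation design ------------------------------------------

build_pk_design <- function(ds, spec, refs = bu_reference_values()) {
  dcov <- derive_covariates(ds$covariates, refs)
  ids <- dcov$subject_id
  doses <- ds$doses
  obs <- ds$observations |>
    mutate(subj = match(.data$subject_id, ids)) |>
    left_join(select(doses, "subject_id", interval = "dose_index", "t_mid"),
              by = c("subject_id", dosing_interval = "interval"))
  if (anyNA(obs$subj)) abort("Observation for unknown subject.")
  if (anyNA(obs$t_mid)) {
    abort("Observation outside any dosing interval (before first dose?).")
  }
  obs$obs_i <- seq_len(nrow(obs))

  pair <- obs |>
    select("obs_i", "subject_id", "t") |>
    left_join(select(doses, "subject_id", "t0", "duration", "rate"),
              by = "subject_id", relationship = "many-to-many") |>
    mutate(
      a = pmin(pmax(.data$t - .data$t0, 0), .data$duration),
      e = pmax(.data$t - .data$t0 - .data$duration, 0)
    ) |>
    filter(.data$a > 0)  # only started infusions contribute

  # co-medication activity per observation (interval infusion start within
  # the look-back window after an administration)
  Z <- NULL
  if (!is.null(spec$comed) && nrow(spec$comed) > 0) {
    t0_obs <- doses$t0[match(paste(obs$subject_id, obs$dosing_interval),
                             paste(doses$subject_id, doses$dose_index))]
    Z <- lapply(seq_len(nrow(spec$comed)), function(r) {
      drug <- spec$comed$drug[r]
      cm <- ds$comedication[ds$comedication$drug == drug, ]
      act <- vapply(seq_len(nrow(obs)), function(i) {
        tt <- cm$time[cm$subject_id == obs$subject_id[i]]
        any(tt >= t0_obs[i] - spec$comed_window_h & tt <= t0_obs[i])
      }, logical(1))
      as.numeric(act)
    })
    names(Z) <- paste0("comed_", spec$comed$param, "_",
                       gsub("[^A-Za-z0-9]", "", spec$comed$drug))
  }

  list(
    spec = spec, dcov = dcov, ids = ids, n = length(ids),
    X = design_matrices(spec, dcov),
    y = obs$conc, obs_subj = obs$subj, t_mid = obs$t_mid,
    nobs = nrow(obs),
    pair_obs = pair$obs_i, pair_a = pair$a, pair_e = pair$e,
    pair_rate = pair$rate,
    Z = Z,
    n_i = tabulate(obs$subj, nbins = length(ids))
  )
}

rowsum_all <- function(x, g, n) {
  out <- numeric(n)
  r <- rowsum(x, g)
  out[as.integer(rownames(r))] <- r[, 1]
  out
}

# phi: n x p matrix with columns lnV, lnk[, dk] and possibly per-subject
# values of the no-variability parameters (lnkappa, comed effects); `extra`
# (named vector, e.g. theta) supplies any of those missing from phi.
# Returns predicted concentrations (length nobs).
eval_conc <- function(des, phi, extra) {
  has <- colnames(phi)
  lnV_o <- phi[des$obs_subj, "lnV"]
  lnk_o <- phi[des$obs_subj, "lnk"]
  if (!is.null(des$Z)) {
    for (nm in names(des$Z)) {
      b <- if (nm %in% has) phi[des$obs_subj, nm] else extra[[nm]]
      if (startsWith(nm, "comed_lnV")) lnV_o <- lnV_o + b * des$Z[[nm]]
      else lnk_o <- lnk_o + b * des$Z[[nm]]
    }
  }
  V_o <- exp(lnV_o)
  k_o <- exp(lnk_o)
  if (des$spec$dynamic) {
    lnkap <- if ("lnkappa" %in% has) phi[des$obs_subj, "lnkappa"] else
      extra[["lnkappa"]]
    kp <- k_avg_vec(des$t_mid, k_o, phi[des$obs_subj, "dk"], exp(lnkap))
  } else {
    kp <- k_o
  }
  inv_kpV <- 1 / (kp * V_o)
  kp_p <- kp[des$pair_obs]
  contrib <- des$pair_rate * inv_kpV[des$pair_obs] *
    (1 - exp(-kp_p * des$pair_a)) * exp(-kp_p * des$pair_e)
  rowsum_all(contrib, des$pair_obs, des$nobs)
}

ssr_by_subject <- function(des, conc) {
  rowsum_all((des$y - conc)^2, des$obs_subj, des$n)
}

# ---- the engine -------------------------------------------------------------

#' Fit the population model by SAEM
#'
#' Stochastic approximation EM: each iteration draws subject random effects
#' from their conditional distribution by Metropolis-Hastings (an
#' independent prior kernel plus componentwise random walks with adaptive
#' scales), updates sufficient statistics with step size 1 during
#' exploration (with simulated-annealing decay of the variance components)
#' and `1/iter` during smoothing, and maximizes: fixed effects of
#' random-effect parameters by weighted least squares, `ln(kappa)` and
#' co-medication effects by residual-sum-of-squares minimization, variances
#' and the additive residual SD in closed form. After the run, empirical
#' Bayes estimates are obtained by further conditional sampling at the final
#' estimates.
#'
#' @param ds A [bu_dataset()] with at least 2 subjects, each with at least
#'   one observation.
#' @param spec A [bu_model_spec()]; defaults to the final busulfan covariate
#'   map.
#' @param settings [saem_settings()].
#' @return A `bu_fit` object: estimates (`theta`, `omega2`, `sigma`),
#'   empirical Bayes estimates (`eta`, `ind_params`), conditional summaries
#'   (`cond`), shrinkage, a convergence `trace` and flag, and the data
#'   design. Use [loglik_is()] for the importance-sampling -2LL, [tidy()] /
#'   [glance()] for tabular summaries.
#' @export
fit_saem <- function(ds, spec = bu_final_model_spec(),
                     settings = saem_settings()) {
  stopifnot(inherits(ds, "bu_dataset"))
  if (length(unique(ds$covariates$subject_id)) < 2) {
    abort("Need at least 2 subjects.")
  }
  if (all(ds$observations$conc == 0)) {
    abort("Degenerate data: all observed concentrations are zero.")
  }
  if (!is.null(settings$seed)) set.seed(settings$seed)

  des <- build_pk_design(ds, spec)
  rp <- spec$random
  n <- des$n
  # parameters without inter-individual variability (ln kappa, co-medication
  # effects) are sampled like the others but with an annealed fictive
  # variance; their fixed effect is the mean of the sampled values
  fx <- c(if (spec$dynamic) "lnkappa", names(des$Z))
  cols <- c(rp, fx)
  p_r <- length(rp)
  p_all <- length(cols)

  theta <- default_starts(spec)
  if (!is.null(settings$starts)) {
    theta[names(settings$starts)] <- settings$starts
  }
  if (settings$perturb > 0) {
    theta["lnV_0"] <- theta["lnV_0"] +
      runif(1, -settings$perturb, settings$perturb)
    theta["lnk_0"] <- theta["lnk_0"] +
      runif(1, -settings$perturb, settings$perturb)
  }
  omega2 <- setNames(rep(0.4, p_r), rp)
  v_fix <- setNames(rep(0.1, length(fx)), fx)
  sigma2 <- var(des$y) / 4

  blk_idx <- lapply(c("lnV", "lnk", if (spec$dynamic) "dk"), function(p) {
    match(term_names(p, spec[[p]]), names(theta))
  })
  names(blk_idx) <- c("lnV", "lnk", if (spec$dynamic) "dk")
  XtX_inv <- lapply(names(blk_idx), function(p) solve(crossprod(des$X[[p]])))
  names(XtX_inv) <- names(blk_idx)

  mu_of <- function(theta) {
    m <- matrix(NA_real_, n, p_all, dimnames = list(NULL, cols))
    for (p in names(blk_idx)) {
      m[, p] <- drop(des$X[[p]] %*% theta[blk_idx[[p]]])
    }
    for (f in fx) m[, f] <- theta[[f]]
    m
  }

  mu <- mu_of(theta)
  eta <- matrix(0, n, p_all, dimnames = list(NULL, cols))
  conc <- eval_conc(des, mu, theta)
  ssr <- ssr_by_subject(des, conc)
  rw_scale <- setNames(rep(0.3, p_all), cols)

  valid_phi <- function(phi) {
    if (!spec$dynamic) return(rep(TRUE, n))
    (1 + phi[, "dk"]) > 0  # elimination must stay positive
  }

  var_all <- function() c(omega2, v_fix)

  mh_sweep <- function(mu, eta, ssr, sigma2) {
    vv <- var_all()
    # kernel 1: independent draws from the prior
    eta_new <- eta
    eta_new[, ] <- rnorm(n * p_all) * rep(sqrt(vv), each = n)
    phi_new <- mu + eta_new
    ok <- valid_phi(phi_new)
    ssr_new <- ssr_by_subject(des, eval_conc(des, phi_new, theta))
    logA <- (ssr - ssr_new) / (2 * sigma2)
    logA[!ok] <- -Inf
    acc <- log(runif(n)) < logA
    eta[acc, ] <- eta_new[acc, ]
    ssr[acc] <- ssr_new[acc]
    # kernel 2: componentwise random walk, adaptive scale
    for (c in seq_len(p_all)) {
      eta_new <- eta
      eta_new[, c] <- eta[, c] + rw_scale[c] * sqrt(vv[c]) * rnorm(n)
      phi_new <- mu + eta_new
      ok <- valid_phi(phi_new)
      ssr_new <- ssr_by_subject(des, eval_conc(des, phi_new, theta))
      logA <- (ssr - ssr_new) / (2 * sigma2) +
        (eta[, c]^2 - eta_new[, c]^2) / (2 * vv[c])
      logA[!ok] <- -Inf
      acc <- log(runif(n)) < logA
      eta[acc, ] <- eta_new[acc, ]
      ssr[acc] <- ssr_new[acc]
      rate <- mean(acc)
      rw_scale[c] <<- min(5, max(0.02, rw_scale[c] * exp(0.4 * (rate - 0.4))))
    }
    list(eta = eta, ssr = ssr)
  }

  n_iter <- settings$n_explore + settings$n_smooth
  s_phi <- mu * 0; s_phi2 <- mu * 0; s_ssr <- sum(ssr)
  trace <- matrix(NA_real_, n_iter, length(theta) + p_r + 1,
                  dimnames = list(NULL, c(names(theta),
                                          paste0("omega2_", rp), "sigma")))

  for (it in seq_len(n_iter)) {
    explore <- it <= settings$n_explore
    gamma <- if (explore) 1 else 1 / (it - settings$n_explore)

    sw <- mh_sweep(mu, eta, ssr, sigma2)
    eta <- sw$eta; ssr <- sw$ssr
    phi <- mu + eta

    # exploration-phase profile step for the no-variability parameters:
    # local 1-D argmin of the complete-data RSS, damped; accelerates travel
    # along the (d_k, kappa) likelihood ridge that pure sampling crosses
    # only slowly
    if (it > 50 && length(fx) > 0) {
      step <- if (explore) 0.3 else gamma
      for (f in fx) {
        cur <- theta[[f]]
        obj <- function(v) {
          phi2 <- phi
          phi2[, f] <- phi2[, f] + (v - cur)
          sum((des$y - eval_conc(des, phi2, theta))^2)
        }
        opt <- optimize(obj, interval = cur + c(-0.3, 0.3), tol = 0.01)
        theta[[f]] <- cur + step * (opt$minimum - cur)
        phi[, f] <- phi[, f] + (theta[[f]] - cur)
        eta[, f] <- phi[, f] - mu[, f]
      }
      conc <- eval_conc(des, phi, theta)
      ssr <- ssr_by_subject(des, conc)
    }

    # stochastic approximation of sufficient statistics
    s_phi <- s_phi + gamma * (phi - s_phi)
    s_phi2 <- s_phi2 + gamma * (phi^2 - s_phi2)
    s_ssr <- s_ssr + gamma * (sum(ssr) - s_ssr)

    # M-step: fixed effects (least squares on the phi statistics)
    for (p in names(blk_idx)) {
      theta[blk_idx[[p]]] <- drop(XtX_inv[[p]] %*%
                                    crossprod(des$X[[p]], s_phi[, p]))
    }
    for (f in fx) theta[[f]] <- mean(s_phi[, f])
    mu_new <- mu_of(theta)
    eta <- eta + mu - mu_new  # keep phi (hence ssr) unchanged
    mu <- mu_new

    # M-step: variance components (annealed during exploration)
    for (p in rp) {
      o2 <- mean(s_phi2[, p] - 2 * mu[, p] * s_phi[, p] + mu[, p]^2)
      o2 <- max(o2, 1e-8)
      omega2[p] <- if (explore) max(o2, 0.95 * omega2[p]) else o2
    }
    # fictive variance of the no-variability parameters: kept wide enough
    # to explore during most of the exploration phase, collapsed during
    # smoothing so their fixed effects settle
    v_fix <- if (explore) pmax(v_fix * 0.98, 0.04) else
      pmax(v_fix * 0.85, 1e-5)
    s2 <- max(s_ssr / des$nobs, 1e-12)
    sigma2 <- if (explore) max(s2, 0.95 * sigma2) else s2

    trace[it, ] <- c(theta, omega2, sqrt(sigma2))
  }

  # convergence: relative drift over the smoothing phase
  sm <- trace[seq(settings$n_explore + 1, n_iter), , drop = FALSE]
  half <- nrow(sm) %/% 2
  drift <- abs(colMeans(sm[seq_len(half), , drop = FALSE]) -
                 colMeans(sm[seq(half + 1, nrow(sm)), , drop = FALSE]))
  scale <- pmax(abs(trace[n_iter, ]), 0.05)
  converged <- all(drift / scale < 0.15)

  # empirical Bayes estimates: conditional mean/sd at the final estimates
  keep <- max(2, settings$ebe_iter %/% 2)
  draws <- array(NA_real_, c(keep, n, p_r))
  for (it in seq_len(settings$ebe_iter)) {
    sw <- mh_sweep(mu, eta, ssr, sigma2)
    eta <- sw$eta; ssr <- sw$ssr
    if (it > settings$ebe_iter - keep) {
      draws[it - (settings$ebe_iter - keep), , ] <- eta[, seq_len(p_r)]
    }
  }
  cond_mean <- apply(draws, c(2, 3), mean)
  cond_sd <- apply(draws, c(2, 3), sd)
  cond_sd <- pmax(cond_sd, 1e-4)
  colnames(cond_mean) <- colnames(cond_sd) <- rp

  eta_hat <- cond_mean
  pop <- list(spec = spec, theta = theta)
  ind <- individual_params(pop, des$dcov, eta_hat)
  shrink <- 1 - apply(eta_hat, 2, var) / omega2

  fit <- structure(
    list(
      spec = spec, theta = theta, omega2 = omega2, sigma = sqrt(sigma2),
      eta = as_tibble(cbind(tibble(subject_id = des$ids),
                            as_tibble(eta_hat))),
      ind_params = ind,
      cond = list(mean = cond_mean, sd = cond_sd),
      shrinkage = shrink,
      converged = converged,
      trace = as_tibble(cbind(tibble(iteration = seq_len(n_iter)),
                              as_tibble(trace))),
      settings = settings, seed = settings$seed,
      data = ds, design = des,
      n_obs = des$nobs, n_subjects = n
    ),
    class = "bu_fit"
  )
  fit
}

#' @export
print.bu_fit <- function(x, ...) {
  cat("<bu_fit> SAEM fit:", x$n_subjects, "subjects,", x$n_obs,
      "observations\n")
  cat(if (x$converged) "converged" else "NOT converged (flagged)", "\n")
  cat("Fixed effects:\n"); print(round(x$theta, 4))
  cat("Omega^2:\n"); print(round(x$omega2, 4))
  cat("sigma (mg/L):", round(x$sigma, 4), "\n")
  invisible(x)
}

# population and individual predictions for the fitted data
predict_fit <- function(fit, level = c("individual", "population")) {
  level <- match.arg(level)
  des <- fit$design
  mu <- sapply(names(fit$design$X), function(p) {
    idx <- match(term_names(p, fit$spec[[p]]), names(fit$theta))
    drop(des$X[[p]] %*% fit$theta[idx])
  })
  colnames(mu) <- names(fit$design$X)
  phi <- mu
  if (level == "individual") {
    eta <- as.matrix(fit$eta[, fit$spec$random, drop = FALSE])
    phi[, fit$spec$random] <- phi[, fit$spec$random] + eta
  }
  extra <- fit$theta[c(if (fit$spec$dynamic) "lnkappa", names(des$Z))]
  eval_conc(des, phi, extra)
}

#' Importance-sampling marginal likelihood
#'
#' Estimates `-2 ln L` of a fitted model by importance sampling: random
#' effects are proposed from a scaled Student-t around each subject's
#' conditional mean/SD (obtained during the fit) and weighted by the ratio
#' of the joint density to the proposal density.
#'
#' @param fit A `bu_fit`.
#' @param n_mc Number of importance-sampling draws (a warning is issued
#'   below 100, where the estimator is very noisy).
#' @param seed Seed controlling the draws; fits compared by likelihood ratio
#'   should use the same seed.
#' @return The -2 log-likelihood (scalar).
#' @export
loglik_is <- function(fit, n_mc = 1000, seed = 1) {
  stopifnot(inherits(fit, "bu_fit"))
  if (n_mc < 100) warn("n_mc < 100: the -2LL estimate will be very noisy.")
  set.seed(seed)
  des <- fit$design
  rp <- fit$spec$random
  p_r <- length(rp)
  n <- des$n
  mu <- sapply(names(des$X), function(p) {
    idx <- match(term_names(p, fit$spec[[p]]), names(fit$theta))
    drop(des$X[[p]] %*% fit$theta[idx])
  })
  colnames(mu) <- names(des$X)
  extra <- fit$theta[c(if (fit$spec$dynamic) "lnkappa", names(des$Z))]
  sigma2 <- fit$sigma^2
  m <- fit$cond$mean; s <- fit$cond$sd * 1.2
  df <- 4
  logw <- matrix(NA_real_, n_mc, n)
  for (r in seq_len(n_mc)) {
    tdev <- matrix(stats::rt(n * p_r, df = df), n, p_r)
    eta_r <- m + s * tdev
    phi <- mu
    phi[, rp] <- phi[, rp] + eta_r
    bad <- if (fit$spec$dynamic) 1 + phi[, "dk"] <= 0 else rep(FALSE, n)
    phi[bad, rp] <- mu[bad, rp]  # evaluate at the mean; weight -Inf below
    ssr <- ssr_by_subject(des, eval_conc(des, phi, extra))
    ll <- -des$n_i / 2 * log(2 * pi * sigma2) - ssr / (2 * sigma2)
    lprior <- rowSums(sapply(seq_len(p_r), function(c) {
      stats::dnorm(eta_r[, c], 0, sqrt(fit$omega2[rp[c]]), log = TRUE)
    }))
    lprop <- rowSums(sapply(seq_len(p_r), function(c) {
      stats::dt(tdev[, c], df = df, log = TRUE) - log(s[, c])
    }))
    w <- ll + lprior - lprop
    w[bad] <- -Inf
    logw[r, ] <- w
  }
  lse <- apply(logw, 2, function(col) {
    mx <- max(col)
    if (!is.finite(mx)) return(-Inf)
    mx + log(mean(exp(col - mx)))
  })
  -2 * sum(lse)
}

#' Random-effect shrinkage
#'
#' `1 - var(EBE)/Omega^2` per random effect: values near 1 mean the data
#' cannot individualize the parameter (the study dropped random effects with
#' shrinkage above 0.4).
#'
#' @param fit A `bu_fit`.
#' @return Named numeric vector of shrinkage fractions (NA where
#'   `Omega^2 = 0`).
#' @export
shrinkage <- function(fit) {
  stopifnot(inherits(fit, "bu_fit"))
  out <- fit$shrinkage
  out[fit$omega2 <= 0] <- NA_real_
  out
}

#' Evaluate a population model on a dataset without re-estimating
#'
#' Builds a `bu_fit` object at fixed population parameters (e.g. the
#' packaged final model): empirical Bayes estimates are sampled
#' conditionally on the data, but fixed effects, variances and the residual
#' SD are taken as given. Useful for diagnostics of a known model on new or
#' simulated data.
#'
#' @param ds A [bu_dataset()].
#' @param pop A `bu_popmodel` (or any list with `spec`, `theta`, `omega2`,
#'   `sigma`).
#' @param n_iter Conditional MCMC iterations (second half averaged for the
#'   EBEs).
#' @param seed Seed.
#' @return A `bu_fit`.
#' @export
bu_fit_at <- function(ds, pop = bu_final_model(), n_iter = 100, seed = 1) {
  stopifnot(inherits(ds, "bu_dataset"))
  set.seed(seed)
  spec <- pop$spec
  des <- build_pk_design(ds, spec)
  rp <- spec$random
  n <- des$n
  p_r <- length(rp)
  theta <- pop$theta
  omega2 <- pop$omega2[rp]
  sigma2 <- pop$sigma^2
  mu <- matrix(NA_real_, n, p_r, dimnames = list(NULL, rp))
  for (p in rp) {
    mu[, p] <- drop(des$X[[p]] %*% theta[term_names(p, spec[[p]])])
  }
  eta <- matrix(0, n, p_r, dimnames = list(NULL, rp))
  ssr <- ssr_by_subject(des, eval_conc(des, mu + eta, theta))
  keep <- max(2, n_iter %/% 2)
  draws <- array(NA_real_, c(keep, n, p_r))
  for (it in seq_len(n_iter)) {
    # prior-independent kernel
    eta_new <- matrix(rnorm(n * p_r), n, p_r, dimnames = list(NULL, rp)) *
      rep(sqrt(omega2), each = n)
    ok <- if (spec$dynamic) (1 + mu[, "dk"] + eta_new[, "dk"]) > 0 else TRUE
    ssr_new <- ssr_by_subject(des, eval_conc(des, mu + eta_new, theta))
    acc <- ok & (log(runif(n)) < (ssr - ssr_new) / (2 * sigma2))
    eta[acc, ] <- eta_new[acc, ]
    ssr[acc] <- ssr_new[acc]
    # componentwise random walk
    for (c in seq_len(p_r)) {
      eta_new <- eta
      eta_new[, c] <- eta[, c] + 0.4 * sqrt(omega2[c]) * rnorm(n)
      ok <- if (spec$dynamic) (1 + mu[, "dk"] + eta_new[, "dk"]) > 0 else TRUE
      ssr_new <- ssr_by_subject(des, eval_conc(des, mu + eta_new, theta))
      logA <- (ssr - ssr_new) / (2 * sigma2) +
        (eta[, c]^2 - eta_new[, c]^2) / (2 * omega2[c])
      acc <- ok & (log(runif(n)) < logA)
      eta[acc, ] <- eta_new[acc, ]
      ssr[acc] <- ssr_new[acc]
    }
    if (it > n_iter - keep) draws[it - (n_iter - keep), , ] <- eta
  }
  cond_mean <- apply(draws, c(2, 3), mean)
  cond_sd <- pmax(apply(draws, c(2, 3), sd), 1e-4)
  colnames(cond_mean) <- colnames(cond_sd) <- rp
  ind <- individual_params(list(spec = spec, theta = theta), des$dcov,
                           cond_mean)
  structure(
    list(spec = spec, theta = theta, omega2 = omega2, sigma = pop$sigma,
         eta = as_tibble(cbind(tibble(subject_id = des$ids),
                               as_tibble(cond_mean))),
         ind_params = ind,
         cond = list(mean = cond_mean, sd = cond_sd),
         shrinkage = 1 - apply(cond_mean, 2, var) / omega2,
         converged = TRUE, trace = NULL,
         settings = list(fixed_parameters = TRUE), seed = seed,
         data = ds, design = des, n_obs = des$nobs, n_subjects = n),
    class = "bu_fit"
  )
}
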