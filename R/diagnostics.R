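# Model evaluation: residual diagnostics, simulation-based checks,
# bootstrap, train/test split, covariate-stripped clearance comparison,
# dose linearity, and the population CL(t) trend simulation.

#' Conditional individual weighted residuals
#'
#' `(observed - individual conditional prediction) / sigma`, using the
#' empirical Bayes estimates; roughly symmetric about 0 under a correct
#' model.
#'
#' @param fit A `bu_fit`.
#' @return Tibble with `subject_id`, `t`, `conc`, `ipred`, `icwres`.
#' @export
icwres <- function(fit) {
  stopifnot(inherits(fit, "bu_fit"))
  ipred <- predict_fit(fit, "individual")
  tibble(
    subject_id = fit$data$observations$subject_id,
    t = fit$data$observations$t,
    conc = fit$design$y,
    ipred = ipred,
    icwres = (fit$design$y - ipred) / fit$sigma
  )
}

# simulate one replicate dataset (same design, new eta and residual error)
simulate_from_fit <- function(fit, truncate = TRUE) {
  des <- fit$design
  rp <- fit$spec$random
  n <- des$n
  eta <- matrix(rnorm(n * length(rp)), n, length(rp),
                dimnames = list(NULL, rp))
  eta <- sweep(eta, 2, sqrt(pmax(fit$omega2[rp], 0)), "*")
  mu <- sapply(names(des$X), function(p) {
    idx <- match(term_names(p, fit$spec[[p]]), names(fit$theta))
    drop(des$X[[p]] %*% fit$theta[idx])
  })
  colnames(mu) <- names(des$X)
  phi <- mu
  phi[, rp] <- phi[, rp] + eta
  if (fit$spec$dynamic) {
    bad <- 1 + phi[, "dk"] <= 0.05
    phi[bad, "dk"] <- 0.05 - 1  # clamp rare extreme draws
  }
  extra <- fit$theta[c(if (fit$spec$dynamic) "lnkappa", names(des$Z))]
  conc <- eval_conc(des, phi, extra)
  y <- conc + rnorm(des$nobs, 0, fit$sigma)
  if (truncate) y <- pmax(y, 0)
  y
}

#' Normalized prediction distribution errors
#'
#' Simulates the fitted design `n_sim` times, decorrelates each subject's
#' observation vector with the simulated mean and covariance (Cholesky), and
#' transforms the rank of each decorrelated observation among its simulated
#' counterparts to a standard-normal score. Approximately N(0,1) under a
#' correct model.
#'
#' @param fit A `bu_fit`.
#' @param n_sim Number of simulated replicates (warning below 1000).
#' @param seed Seed.
#' @return Tibble with `subject_id`, `t`, `npde`.
#' @export
npde <- function(fit, n_sim = 10000, seed = 1) {
  stopifnot(inherits(fit, "bu_fit"))
  if (n_sim < 1000) warn("n_sim < 1000 gives coarse npde resolution.")
  set.seed(seed)
  des <- fit$design
  sims <- matrix(NA_real_, des$nobs, n_sim)
  for (r in seq_len(n_sim)) sims[, r] <- simulate_from_fit(fit)
  out <- numeric(des$nobs)
  for (s in seq_len(des$n)) {
    idx <- which(des$obs_subj == s)
    Yi <- sims[idx, , drop = FALSE]
    mi <- rowMeans(Yi)
    Vi <- stats::cov(t(Yi))
    Vi <- Vi + diag(1e-10 + 1e-8 * mean(diag(Vi)), length(idx))
    L <- chol(Vi)
    dec_obs <- backsolve(L, des$y[idx] - mi, transpose = TRUE)
    dec_sim <- backsolve(L, Yi - mi, transpose = TRUE)
    # smoothed rank with randomized tie-breaking (ties arise from the
    # truncation of concentrations at 0)
    less <- rowSums(dec_sim < dec_obs - 1e-12)
    ties <- rowSums(abs(dec_sim - dec_obs) <= 1e-12)
    pde <- (less + runif(length(idx)) * (ties + 1)) / (n_sim + 1)
    out[idx] <- qnorm(pde)
  }
  tibble(subject_id = fit$data$observations$subject_id,
         t = fit$data$observations$t, npde = out)
}

#' Visual predictive check
#'
#' Simulates the design of the fitted data `n_sim` times and compares the
#' observed median and 5th/95th percentiles per sampling time point (no
#' binning) with the 95% confidence band of the same percentiles across
#' simulations.
#'
#' @param fit A `bu_fit`.
#' @param n_sim Number of simulated replicates.
#' @param seed Seed.
#' @param digits Time values are grouped after rounding to this many
#'   decimals.
#' @return A `bu_vpc` tibble: one row per (time point, percentile) with the
#'   observed value, simulation band (`lo`, `hi`), median simulated value
#'   and the number of observations; time points with fewer than 5
#'   observations are flagged.
#' @export
vpc <- function(fit, n_sim = 1000, seed = 1, digits = 6) {
  stopifnot(inherits(fit, "bu_fit"))
  set.seed(seed)
  des <- fit$design
  tt <- round(fit$data$observations$t, digits)
  probs <- c(0.05, 0.5, 0.95)
  obs_q <- split_quantiles(des$y, tt, probs)
  sim_q <- array(NA_real_, c(n_sim, nrow(obs_q), 3))
  for (r in seq_len(n_sim)) {
    yr <- simulate_from_fit(fit)
    sim_q[r, , ] <- as.matrix(split_quantiles(yr, tt, probs)[, -c(1, 2)])
  }
  out <- list()
  for (k in seq_along(probs)) {
    out[[k]] <- tibble(
      t = obs_q$t, n = obs_q$n, percentile = 100 * probs[k],
      observed = obs_q[[k + 2]],
      sim_median = apply(sim_q[, , k, drop = FALSE], 2, median),
      lo = apply(sim_q[, , k, drop = FALSE], 2, quantile, 0.025),
      hi = apply(sim_q[, , k, drop = FALSE], 2, quantile, 0.975),
      sparse = obs_q$n < 5
    )
  }
  structure(bind_rows(out), class = c("bu_vpc", class(tibble())))
}

split_quantiles <- function(y, tt, probs) {
  grp <- split(y, tt)
  qs <- t(vapply(grp, quantile, numeric(length(probs)), probs = probs,
                 names = FALSE))
  tibble(t = as.numeric(names(grp)), n = lengths(grp),
         q1 = qs[, 1], q2 = qs[, 2], q3 = qs[, 3])
}

#' Bootstrap confidence intervals
#'
#' Resamples subjects with replacement (same cohort size), refits each
#' replicate with fixed start values, and reports per-parameter percentile
#' confidence intervals (2.5 and 97.5 positions).
#'
#' @param ds A [bu_dataset()].
#' @param spec Model specification.
#' @param n Number of bootstrap replicates (the study used 500).
#' @param settings [saem_settings()]; starts are fixed (no perturbation).
#' @param seed Seed for the resampling.
#' @return A `bu_boot` object: `replicates` (tibble of estimates),
#'   `ci` (tibble term/lower/upper), `n_converged`.
#' @export
bootstrap_fit <- function(ds, spec = bu_final_model_spec(), n = 500,
                          settings = saem_settings(), seed = 1) {
  stopifnot(inherits(ds, "bu_dataset"))
  set.seed(seed)
  ids <- unique(ds$covariates$subject_id)
  settings$perturb <- 0
  reps <- list()
  n_conv <- 0
  for (b in seq_len(n)) {
    pick <- sample(ids, length(ids), replace = TRUE)
    dsb <- resample_subjects(ds, pick)
    settings$seed <- sample.int(2^30, 1)
    fitb <- tryCatch(fit_saem(dsb, spec, settings), error = function(e) NULL)
    if (is.null(fitb)) next
    if (fitb$converged) n_conv <- n_conv + 1
    reps[[length(reps) + 1]] <-
      as_tibble(as.list(c(fitb$theta,
                          setNames(fitb$omega2,
                                   paste0("omega2_", names(fitb$omega2))),
                          sigma = fitb$sigma))) |>
      mutate(replicate = b, converged = fitb$converged)
  }
  reps <- bind_rows(reps)
  est <- reps |> filter(.data$converged)
  if (nrow(est) == 0) est <- reps
  ci <- est |>
    select(-"replicate", -"converged") |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "term") |>
    group_by(.data$term) |>
    summarise(lower = quantile(.data$value, 0.025),
              upper = quantile(.data$value, 0.975), .groups = "drop")
  structure(list(replicates = reps, ci = ci, n_converged = n_conv,
                 n_requested = n),
            class = "bu_boot")
}

#' @export
print.bu_boot <- function(x, ...) {
  cat("<bu_boot>", nrow(x$replicates), "replicates (",
      x$n_converged, "converged of", x$n_requested, "requested )\n")
  print(x$ci)
  invisible(x)
}

resample_subjects <- function(ds, pick) {
  new_id <- sprintf("B%03d_%s", seq_along(pick), pick)
  grab <- function(tbl) {
    bind_rows(lapply(seq_along(pick), function(i) {
      rows <- tbl[tbl$subject_id == pick[i], , drop = FALSE]
      if (nrow(rows) > 0) rows$subject_id <- new_id[i]
      rows
    }))
  }
  bu_dataset(grab(ds$doses[, c("subject_id", "dose_index", "t0", "amount",
                               "duration")]),
             grab(ds$observations), grab(ds$covariates),
             grab(ds$comedication), provenance = "bootstrap resample")
}

#' Train/test split evaluation
#'
#' Splits subjects into training and test sets (75/25 by default; 124
#' subjects give 93/31), fits the model on the training set, and reports the
#' sum of squared residuals divided by the number of observations for both
#' sets (population-level predictions, so the test set is scored without
#' subject-level information).
#'
#' @param ds A [bu_dataset()].
#' @param spec Model specification.
#' @param ratio Training fraction.
#' @param settings [saem_settings()].
#' @param seed Seed for the split.
#' @return List with `train_ids`, `test_ids`, the training `fit` and a
#'   `report` tibble (set, n_subjects, n_obs, ssr_per_obs).
#' @export
train_test_split <- function(ds, spec = bu_final_model_spec(), ratio = 0.75,
                             settings = saem_settings(), seed = 1) {
  ids <- unique(ds$covariates$subject_id)
  if (length(ids) < 8) abort("Need at least 8 subjects to split.")
  set.seed(seed)
  n_train <- round(length(ids) * ratio)
  train_ids <- sample(ids, n_train)
  test_ids <- setdiff(ids, train_ids)
  subset_ds <- function(keep) {
    bu_dataset(
      ds$doses[ds$doses$subject_id %in% keep,
               c("subject_id", "dose_index", "t0", "amount", "duration")],
      ds$observations[ds$observations$subject_id %in% keep, ],
      ds$covariates[ds$covariates$subject_id %in% keep, ],
      ds$comedication[ds$comedication$subject_id %in% keep, ],
      provenance = ds$provenance
    )
  }
  train <- subset_ds(train_ids)
  test <- subset_ds(test_ids)
  fit <- fit_saem(train, spec, settings)
  ssr_pop <- function(d) {
    des <- build_pk_design(d, spec)
    mu <- sapply(names(des$X), function(p) {
      idx <- match(term_names(p, spec[[p]]), names(fit$theta))
      drop(des$X[[p]] %*% fit$theta[idx])
    })
    colnames(mu) <- names(des$X)
    extra <- fit$theta[c(if (spec$dynamic) "lnkappa", names(des$Z))]
    pred <- eval_conc(des, mu, extra)
    c(sum((des$y - pred)^2), des$nobs)
  }
  tr <- ssr_pop(train); te <- ssr_pop(test)
  report <- tibble(
    set = c("train", "test"),
    n_subjects = c(length(train_ids), length(test_ids)),
    n_obs = c(tr[2], te[2]),
    ssr_per_obs = c(tr[1] / tr[2], te[1] / te[2])
  )
  list(train_ids = train_ids, test_ids = test_ids, fit = fit,
       report = report)
}

#' Clearance ratios after stripping covariates
#'
#' Refits the model without the named covariate terms and returns each
#' subject's empirical-Bayes clearance as a multiple of the population
#' prediction, exposing the effect of the stripped covariates: an ALL-group
#' comparison (two-sided Student's t-test) and the regression of the ratio
#' on serum albumin.
#'
#' @param ds A [bu_dataset()].
#' @param fit The full-model `bu_fit`.
#' @param drop Tibble of covariates to remove, columns `param` and `term`
#'   (default: the ALL and albumin effects on `ln k`).
#' @param settings [saem_settings()] for the refit.
#' @return List with `ratios` (tibble subject_id, cl_subject, cl_population,
#'   ratio, all, albumin), `all_test` (t-test results) and `albumin_trend`
#'   (slope, p).
#' @export
covariate_stripped_cl <- function(ds, fit,
                                  drop = tibble(param = "lnk",
                                                term = c("all", "dln_alb")),
                                  settings = saem_settings()) {
  spec <- fit$spec
  for (i in seq_len(nrow(drop))) {
    if (!drop$term[i] %in% spec[[drop$param[i]]]) {
      abort(paste0("Covariate '", drop$term[i], "' is not on ",
                   drop$param[i], " in the model."))
    }
    spec <- spec_drop_term(spec, drop$param[i], drop$term[i])
  }
  refit <- fit_saem(ds, spec, settings)
  ip <- refit$ind_params
  pop <- individual_params(list(spec = spec, theta = refit$theta),
                           refit$design$dcov)
  ratios <- tibble(
    subject_id = ip$subject_id,
    cl_subject = ip$k * ip$V,
    cl_population = pop$k * pop$V,
    ratio = (ip$k * ip$V) / (pop$k * pop$V),
    all = refit$design$dcov$all,
    albumin = refit$design$dcov$albumin %||% NA_real_
  )
  all_test <- if (length(unique(ratios$all)) == 2) {
    t.test(ratio ~ all, data = ratios)
  } else NULL
  trend <- if (!all(is.na(ratios$albumin))) {
    m <- lm(ratio ~ albumin, data = ratios)
    s <- summary(m)$coefficients
    list(slope = s["albumin", "Estimate"], p = s["albumin", "Pr(>|t|)"])
  } else NULL
  list(ratios = ratios, all_test = all_test, albumin_trend = trend,
       fit = refit)
}

#' Dose-proportionality of non-compartmental exposure
#'
#' For subjects whose doses were adjusted, relates the dose-normalized AUC
#' of the third, fifth or seventh dosing interval to that of the first:
#' `(AUC/dose)_m / (AUC/dose)_1` against `dose_m / dose_1`, with an OLS
#' slope test per interval. Even-numbered measured intervals are excluded.
#'
#' @param nca_tbl Output of [nca()].
#' @param intervals Later intervals to compare with the first.
#' @return A tibble (subject_id, interval, dose_ratio, auc_dose_ratio) with
#'   attribute `"regression"`: per-interval OLS slope and p-value (skipped
#'   when fewer than 3 subjects contribute).
#' @export
dose_linearity <- function(nca_tbl, intervals = c(3, 5, 7)) {
  ok <- nca_tbl |> filter(.data$ok, .data$interval %% 2 == 1)
  first <- ok |> filter(.data$interval == 1) |>
    select("subject_id", dose1 = "dose", auc1 = "auc")
  out <- ok |>
    filter(.data$interval %in% intervals) |>
    dplyr::inner_join(first, by = "subject_id") |>
    mutate(
      dose_ratio = .data$dose / .data$dose1,
      auc_dose_ratio = (.data$auc / .data$dose) / (.data$auc1 / .data$dose1)
    ) |>
    select("subject_id", "interval", "dose_ratio", "auc_dose_ratio")
  reg <- out |>
    group_by(.data$interval) |>
    dplyr::group_modify(function(d, g) {
      if (nrow(d) < 3 || var(d$dose_ratio) < 1e-12) {
        return(tibble(slope = NA_real_, p = NA_real_, n = nrow(d),
                      skipped = TRUE))
      }
      m <- summary(lm(auc_dose_ratio ~ dose_ratio, data = d))$coefficients
      tibble(slope = m["dose_ratio", "Estimate"],
             p = m["dose_ratio", "Pr(>|t|)"], n = nrow(d), skipped = FALSE)
    }) |>
    ungroup()
  attr(out, "regression") <- reg
  out
}

#' Simulated population trend of clearance over therapy time
#'
#' Draws `n` values of the amplitude `d_k` from N(fixed effect, Omega of
#' `d_k`) and of `kappa_k` from N(estimate, SE x sqrt(n_subjects)) (negative
#' draws rejected), and summarizes the relative clearance
#' `CL(t)/CL(0) = 1 + d_k (1 - exp(-kappa_k t))` as the fixed-effect curve
#' plus 80% and 95% bands. A separate fixed-effect curve is produced for the
#' HLH/XLP group.
#'
#' @param pop A `bu_popmodel` with `se` available (e.g. [bu_final_model()]).
#' @param n Number of sampled parameter sets.
#' @param horizon Simulation horizon (h), positive.
#' @param step Time step (h).
#' @param seed Seed.
#' @return A `bu_cl_trend` tibble: `t`, `mean_curve`, `hlh_xlp_curve`,
#'   `lo95`, `lo80`, `hi80`, `hi95`.
#' @export
simulate_cl_trend <- function(pop = bu_final_model(), n = 100000,
                              horizon = 72, step = 0.5, seed = 1) {
  if (horizon <= 0) abort("`horizon` must be positive.")
  set.seed(seed)
  dk0 <- pop$theta[["dk_0"]]
  dk_hlh <- dk0 + (pop$theta[["dk_hlh_xlp"]] %||% 0)
  kap_hat <- exp(pop$theta[["lnkappa"]])
  se_kap <- pop$se[["lnkappa"]] * kap_hat  # delta method to the kappa scale
  sd_kap <- se_kap * sqrt(pop$n_subjects %||% 124)
  dk <- rnorm(n, dk0, sqrt(pop$omega2[["dk"]]))
  kap <- rnorm(n, kap_hat, sd_kap)
  bad <- which(kap <= 0)
  while (length(bad) > 0) {
    kap[bad] <- rnorm(length(bad), kap_hat, sd_kap)
    bad <- bad[kap[bad] <= 0]
  }
  tgrid <- seq(0, horizon, by = step)
  qs <- vapply(tgrid, function(t) {
    r <- 1 + dk * (1 - exp(-kap * t))
    quantile(r, c(0.025, 0.1, 0.9, 0.975), names = FALSE)
  }, numeric(4))
  structure(
    tibble(
      t = tgrid,
      mean_curve = 1 + dk0 * (1 - exp(-kap_hat * tgrid)),
      hlh_xlp_curve = 1 + dk_hlh * (1 - exp(-kap_hat * tgrid)),
      lo95 = qs[1, ], lo80 = qs[2, ], hi80 = qs[3, ], hi95 = qs[4, ]
    ),
    class = c("bu_cl_trend", class(tibble()))
  )
}
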