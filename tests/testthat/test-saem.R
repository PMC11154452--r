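# The SAEM engine: construction of individual parameters, determinism,
# recovery on easy data, likelihood and shrinkage behavior.

test_that("individual parameters reproduce the worked examples", {
  pop <- bu_final_model()
  ref <- tibble::tibble(subject_id = "ref", weight = 17.2, height = 105,
                        age = 25, sex = "male", disease_group = "CGD",
                        albumin = 30, tinf_h = 3)
  dref <- derive_covariates(ref)
  # force exactly the reference covariates
  dref$dln_tbw <- 0; dref$ln_fmat <- 0; dref$dln_alb <- 0; dref$dtinf <- 0
  ip <- individual_params(pop, dref)
  expect_equal(signif(ip$V, 4), 11.69)   # exp(2.459)
  expect_equal(signif(ip$k, 3), 0.365)   # exp(-1.007)
  expect_equal(ip$dk, -0.167)
  expect_equal(ip$kappa, exp(-2.965))

  # doubling TBW scales k by 2^-0.189 (about a 12% reduction)
  d2 <- dref; d2$dln_tbw <- log(2)
  ip2 <- individual_params(pop, d2)
  expect_equal(ip2$k / ip$k, 2^-0.189, tolerance = 1e-12)
  expect_equal(round(100 * (1 - ip2$k / ip$k)), 12)

  # HLH/XLP amplifies the amplitude to -0.312
  d3 <- dref; d3$hlh_xlp <- 1
  expect_equal(individual_params(pop, d3)$dk, -0.167 - 0.145)

  # a 5 g/L albumin shift moves k by about 6%
  d4 <- dref; d4$dln_alb <- log(25 / 30)
  expect_equal(individual_params(pop, d4)$k / ip$k, (25 / 30)^0.331)

  # invalid random effect on dk is rejected
  eta_bad <- matrix(c(0, 0, -1.2), 1, 3,
                    dimnames = list(NULL, c("lnV", "lnk", "dk")))
  expect_error(individual_params(pop, dref, eta_bad), "dk")
})

test_that("the fit is reproducible given a seed and flags degenerate data", {
  co <- cached_cohort("saem_small", n = 25, seed = 41)
  st <- saem_settings(n_explore = 120, n_smooth = 40, seed = 99)
  f1 <- fit_saem(co$dataset, bu_model_spec(dynamic = TRUE), st)
  f2 <- fit_saem(co$dataset, bu_model_spec(dynamic = TRUE), st)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$omega2, f2$omega2)

  ds0 <- co$dataset
  ds0$observations$conc <- 0
  expect_error(fit_saem(ds0, bu_model_spec(dynamic = TRUE), st),
               "Degenerate")
  one <- co$dataset$covariates$subject_id[1]
  expect_error(
    fit_saem(bu_dataset(
      co$dataset$doses[co$dataset$doses$subject_id == one,
                       c("subject_id", "dose_index", "t0", "amount",
                         "duration")],
      co$dataset$observations[co$dataset$observations$subject_id == one, ],
      co$dataset$covariates[co$dataset$covariates$subject_id == one, ]),
      bu_model_spec(dynamic = TRUE), st),
    "2 subjects")
})

test_that("near-noise-free data with null random effects are recovered", {
  # eta = 0, tiny residual error: the population fit should agree with the
  # generating values and with a direct least-squares optimizer within 1%
  pop0 <- bu_final_model()
  pop0$omega2[] <- 1e-12
  pop0$sigma <- 0.01
  co <- suppressWarnings(simulate_cohort(
    bu_cohort_spec(n_subjects = 30, sigma = 0.01, tdm = FALSE),
    pop = pop0, seed = 43))
  fit <- fit_saem(co$dataset, bu_final_model_spec(),
                  saem_settings(n_explore = 400, n_smooth = 100, seed = 2))
  for (nm in c("lnV_0", "lnk_0", "lnV_dln_tbw")) {
    expect_equal(unname(fit$theta[nm]), unname(pop0$theta[nm]),
                 tolerance = 0.01)
  }
  expect_equal(unname(fit$theta["dk_0"]), -0.167, tolerance = 0.05)
  expect_lt(fit$sigma, 0.05)

  # independent oracle: Nelder-Mead on the population residual sum of
  # squares (no random effects), started from the same default values
  spec <- bu_final_model_spec()
  des <- busulfanpk:::build_pk_design(co$dataset, spec)
  nm_all <- names(busulfanpk:::default_starts(spec))
  obj <- function(th) {
    th <- setNames(th, nm_all)
    mu <- sapply(c("lnV", "lnk", "dk"), function(p) {
      drop(des$X[[p]] %*% th[busulfanpk:::term_names(p, spec[[p]])])
    })
    if (any(1 + mu[, "dk"] <= 0)) return(1e10)
    sum((des$y - busulfanpk:::eval_conc(des, mu, th))^2)
  }
  opt <- optim(busulfanpk:::default_starts(spec), obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  for (r in 1:3) {
    opt <- optim(opt$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
  }
  for (nm in c("lnV_0", "lnk_0", "lnV_dln_tbw", "lnk_dln_tbw")) {
    expect_equal(unname(fit$theta[nm]), unname(opt$par[nm]),
                 tolerance = 0.01)
  }
})

test_that("importance-sampling likelihood is deterministic and warns", {
  co <- cached_cohort("saem_small", n = 25, seed = 41)
  fit <- bu_fit_at(co$dataset, bu_final_model())
  l1 <- loglik_is(fit, n_mc = 300, seed = 5)
  l2 <- loglik_is(fit, n_mc = 300, seed = 5)
  expect_identical(l1, l2)
  expect_true(is.finite(l1))
  expect_warning(loglik_is(fit, n_mc = 50, seed = 5), "noisy")
})

test_that("the likelihood prefers the generating model over a distorted one", {
  co <- cached_cohort("saem_mid", n = 40, seed = 47, tdm = FALSE)
  good <- bu_fit_at(co$dataset, bu_final_model())
  worse_pop <- bu_final_model()
  worse_pop$theta["lnk_0"] <- worse_pop$theta["lnk_0"] + 0.3
  worse <- bu_fit_at(co$dataset, worse_pop)
  expect_lt(loglik_is(good, n_mc = 400, seed = 5),
            loglik_is(worse, n_mc = 400, seed = 5))
})

test_that("shrinkage is small with rich data and near 1 with sparse data", {
  co <- cached_cohort("saem_mid", n = 40, seed = 47, tdm = FALSE)
  rich <- bu_fit_at(co$dataset, bu_final_model())
  expect_true(all(shrinkage(rich)[c("lnV", "lnk")] < 0.4))

  # one observation per subject: the data cannot individualize parameters
  ds <- co$dataset
  sparse_obs <- ds$observations |>
    dplyr::group_by(subject_id) |>
    dplyr::slice(3) |>
    dplyr::ungroup()
  ds_sparse <- bu_dataset(
    ds$doses[, c("subject_id", "dose_index", "t0", "amount", "duration")],
    sparse_obs, ds$covariates)
  sparse <- bu_fit_at(ds_sparse, bu_final_model())
  expect_gt(mean(shrinkage(sparse)), 0.4)
  expect_true(all(shrinkage(sparse) > shrinkage(rich)))
})

test_that("subject relabeling leaves the estimates statistically unchanged", {
  co <- cached_cohort("saem_small", n = 25, seed = 41)
  ds <- co$dataset
  relab <- function(tbl) {
    tbl$subject_id <- paste0("Z", tbl$subject_id)
    tbl
  }
  ds2 <- bu_dataset(
    relab(ds$doses[, c("subject_id", "dose_index", "t0", "amount",
                       "duration")]),
    relab(ds$observations), relab(ds$covariates))
  st <- saem_settings(n_explore = 150, n_smooth = 50, seed = 99)
  f1 <- fit_saem(ds, bu_final_model_spec(), st)
  f2 <- fit_saem(ds2, bu_final_model_spec(), st)
  expect_identical(unname(f1$theta), unname(f2$theta))
})

test_that("tidy and glance summarize fits", {
  co <- cached_cohort("saem_small", n = 25, seed = 41)
  fit <- bu_fit_at(co$dataset, bu_final_model())
  td <- tidy(fit)
  expect_true(all(c("term", "block", "estimate") %in% names(td)))
  expect_equal(td$exp_estimate[td$term == "lnV_0"],
               exp(td$estimate[td$term == "lnV_0"]))
  gl <- glance(fit)
  expect_equal(gl$n_subjects, 25)
  expect_true(all(c("sigma", "converged", "shrinkage_lnV") %in% names(gl)))
})
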