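# Diagnostics on self-simulated data (non-adaptive designs, so observed and
# simulated datasets are exchangeable).

test_that("icwres vanish on noise-free data at the true parameters", {
  co <- suppressWarnings(simulate_cohort(
    bu_cohort_spec(n_subjects = 10, sigma = 0, tdm = FALSE), seed = 63))
  fit <- bu_fit_at(co$dataset, bu_final_model(), n_iter = 150, seed = 2)
  ic <- icwres(fit)
  # sigma in the denominator is the packaged 0.076, so residuals are in SD
  # units; conditional estimates on noise-free data sit on the curve
  expect_lt(mean(abs(ic$icwres)), 0.25)
})

test_that("icwres are calibrated under the correct model and trend under misfit", {
  co <- cached_cohort("diag", n = 60, seed = 65, tdm = FALSE)
  fit <- bu_fit_at(co$dataset, bu_final_model(), n_iter = 120, seed = 2)
  ic <- icwres(fit)
  expect_lt(abs(mean(ic$icwres)), 0.1)
  expect_lt(abs(sd(ic$icwres) - 1), 0.25)

  # static-k misfit: residuals drift with time (later intervals
  # over-predicted), detected by comparing early vs late residual means
  pop_static <- bu_final_model()
  pop_static$spec <- bu_model_spec(
    lnV = pop_static$spec$lnV, lnk = pop_static$spec$lnk, dynamic = FALSE)
  pop_static$theta <- pop_static$theta[
    !names(pop_static$theta) %in% c("dk_0", "dk_hlh_xlp", "lnkappa")]
  pop_static$omega2 <- pop_static$omega2[c("lnV", "lnk")]
  fit0 <- bu_fit_at(co$dataset, pop_static, n_iter = 120, seed = 2)
  ic0 <- icwres(fit0)
  early <- ic0$icwres[ic0$t < 12]
  late <- ic0$icwres[ic0$t > 36]
  expect_gt(abs(mean(late) - mean(early)),
            abs(mean(ic$icwres[ic$t > 36]) - mean(ic$icwres[ic$t < 12])))
})

test_that("npde are near N(0,1) under self-simulation and seed-stable", {
  co <- cached_cohort("diag", n = 60, seed = 65, tdm = FALSE)
  fit <- bu_fit_at(co$dataset, bu_final_model(), n_iter = 120, seed = 2)
  nd <- suppressWarnings(npde(fit, n_sim = 600, seed = 7))
  expect_lt(abs(mean(nd$npde)), 0.1)
  expect_lt(abs(var(nd$npde) - 1), 0.15)
  nd2 <- suppressWarnings(npde(fit, n_sim = 600, seed = 7))
  expect_identical(nd$npde, nd2$npde)
  expect_warning(npde(fit, n_sim = 200, seed = 7), "n_sim")
})

test_that("vpc covers observed percentiles and collapses without noise", {
  co <- cached_cohort("diag", n = 60, seed = 65, tdm = FALSE)
  fit <- bu_fit_at(co$dataset, bu_final_model(), n_iter = 120, seed = 2)
  v <- vpc(fit, n_sim = 300, seed = 7)
  vn <- v[!v$sparse, ]
  expect_gte(mean(vn$observed >= vn$lo & vn$observed <= vn$hi), 0.85)
  expect_true(all(v$lo <= v$hi))
  v2 <- vpc(fit, n_sim = 300, seed = 7)
  expect_identical(v$lo, v2$lo)

  # no residual error and no random effects: the bands collapse
  fit0 <- fit
  fit0$sigma <- 1e-12
  fit0$omega2[] <- 1e-18
  v0 <- vpc(fit0, n_sim = 50, seed = 7)
  expect_lt(max(v0$hi - v0$lo), 1e-6)
})

test_that("bootstrap resampling is reproducible and reports replicates", {
  co <- cached_cohort("boot", n = 20, seed = 67)
  st <- saem_settings(n_explore = 80, n_smooth = 30)
  b1 <- bootstrap_fit(co$dataset, bu_model_spec(dynamic = TRUE), n = 2,
                      settings = st, seed = 11)
  expect_s3_class(b1, "bu_boot")
  expect_equal(nrow(b1$replicates), 2)
  expect_true(all(b1$ci$lower <= b1$ci$upper))
  b2 <- bootstrap_fit(co$dataset, bu_model_spec(dynamic = TRUE), n = 2,
                      settings = st, seed = 11)
  expect_equal(b1$replicates, b2$replicates)
  expect_equal(tidy(b1), b1$ci)
})

test_that("train/test split is subject-disjoint with sensible reports", {
  co <- cached_cohort("diag", n = 60, seed = 65, tdm = FALSE)
  st <- saem_settings(n_explore = 150, n_smooth = 50, seed = 1)
  tt <- train_test_split(co$dataset, ratio = 0.75, settings = st, seed = 4)
  expect_length(intersect(tt$train_ids, tt$test_ids), 0)
  expect_equal(length(tt$train_ids), 45)
  expect_equal(length(tt$test_ids), 15)
  expect_true(all(tt$report$ssr_per_obs > 0))
  tiny <- cached_cohort("boot", n = 20, seed = 67)
  expect_error(train_test_split(
    bu_dataset(tiny$dataset$doses[tiny$dataset$doses$subject_id %in%
                                    tiny$dataset$covariates$subject_id[1:4],
                                  c("subject_id", "dose_index", "t0",
                                    "amount", "duration")],
               tiny$dataset$observations[
                 tiny$dataset$observations$subject_id %in%
                   tiny$dataset$covariates$subject_id[1:4], ],
               tiny$dataset$covariates[1:4, ])), "at least 8")
})

test_that("stripping planted covariates exposes them in the CL ratios", {
  co <- cached_cohort("strip", n = 124, seed = 71, tdm = FALSE)
  ds <- co$dataset
  fit <- bu_fit_at(ds, bu_final_model())
  st <- saem_settings(n_explore = 250, n_smooth = 80, seed = 1)
  res <- covariate_stripped_cl(ds, fit, settings = st)
  # ALL reduces k: the subject-level/population CL ratio drops in ALL
  expect_lt(res$all_test$p.value, 0.05)
  m_all <- mean(res$ratios$ratio[res$ratios$all == 1])
  m_rest <- mean(res$ratios$ratio[res$ratios$all == 0])
  expect_lt(m_all, m_rest)
  # albumin raises k: positive regression slope of the ratio
  expect_gt(res$albumin_trend$slope, 0)
  expect_lt(res$albumin_trend$p, 0.05)
  # asking to strip an absent covariate errors
  expect_error(covariate_stripped_cl(
    ds, fit, drop = tibble::tibble(param = "lnk", term = "leukocytes"),
    settings = st), "not on")
})

test_that("dose-linearity ratios are 1 for constant-k PK and regression runs", {
  ds <- one_subject_dataset(k = 0.3, V = 12, dose = 50, n_dose = 8,
                            measured = c(1, 3, 5, 7))
  dl <- dose_linearity(nca(ds))
  expect_equal(dl$auc_dose_ratio, rep(1, 3), tolerance = 0.06)
  expect_true(all(is.na(attr(dl, "regression")$slope) |
                    attr(dl, "regression")$skipped))

  co <- cached_cohort("strip", n = 124, seed = 71, tdm = FALSE)
  tab <- suppressWarnings(nca(co$dataset))
  dl2 <- dose_linearity(tab)
  expect_true(all(dl2$interval %% 2 == 1))
  # declining clearance raises AUC/dose at later intervals on average
  expect_gt(mean(dl2$auc_dose_ratio), 1)
})

test_that("the simulated clearance trend reproduces the final-model anchors", {
  tr <- simulate_cl_trend(n = 50000, horizon = 96, seed = 3)
  expect_equal(tail(tr$mean_curve, 1), 1 - 0.167, tolerance = 0.005)
  expect_equal(tail(tr$hlh_xlp_curve, 1), 1 - 0.312, tolerance = 0.005)
  expect_equal(round(100 * (1 - tr$mean_curve[tr$t == 24])), 12)
  expect_true(all(tr$lo95 <= tr$lo80 & tr$lo80 <= tr$hi80 &
                    tr$hi80 <= tr$hi95))
  expect_error(simulate_cl_trend(horizon = -1), "positive")
  tr2 <- simulate_cl_trend(n = 50000, horizon = 96, seed = 3)
  expect_identical(tr$lo95, tr2$lo95)
})
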