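table3_params <- function() {
  bu_params(V = exp(2.459), k = exp(-1.007), dk = -0.167,
            kappa = exp(-2.965))
}

test_that("instantaneous rate constant has the right limits and trend", {
  p <- table3_params()
  expect_equal(k_inst(p, 0), p$k)
  expect_equal(k_inst(p, 1e7), p$k * (1 + p$dk), tolerance = 1e-9)
  tt <- seq(0, 96, by = 0.5)
  expect_true(all(diff(k_inst(p, tt)) < 0))  # dk < 0: decreasing
  # relative reduction at 24 h is 12% to the nearest percent
  red24 <- 100 * (1 - k_inst(p, 24) / p$k)
  expect_equal(round(red24), 12)
  expect_error(k_inst(p, -1), "non-negative")
})

test_that("averaged rate constant equals the quadrature of k*(t)", {
  p <- bu_params(V = 11.7, k = 0.365, dk = -0.167, kappa = 0.0516)
  expect_equal(k_avg(p, 0), p$k)
  p0 <- bu_params(V = 11.7, k = 0.365, dk = 0, kappa = 0.0516)
  expect_equal(k_avg(p0, 17.3), p0$k)
  for (t in c(0.5, 6, 12, 30, 54)) {
    q <- integrate(function(u) k_inst(p, u), 0, t,
                   rel.tol = 1e-12)$value / t
    expect_equal(k_avg(p, t), q, tolerance = 1e-10)
  }
  # continuity at 0
  expect_equal(k_avg(p, 1e-9), p$k, tolerance = 1e-6)
})

test_that("single-infusion concentration matches the closed form", {
  p <- bu_params(V = 11.70, k = 0.365)
  s <- bu_schedule(tibble::tibble(subject_id = 1, dose_index = 1, t0 = 0,
                                  amount = 60, duration = 3))
  # end of a 3 h infusion at rate 20 mg/h
  expect_equal(concentration(p, s, 3),
               20 * (1 - exp(-0.365 * 3)) / (0.365 * 11.70),
               tolerance = 1e-12)
  expect_equal(round(concentration(p, s, 3), 2), 3.12)
  # elimination phase
  expect_equal(concentration(p, s, 7),
               concentration(p, s, 3) * exp(-0.365 * 4), tolerance = 1e-12)
  # before the first dose
  expect_equal(concentration(p, s, 0), 0)
})

test_that("multi-infusion model with constant k matches an ODE solution", {
  skip_if_not_installed("deSolve")
  p <- bu_params(V = 11.7, k = 0.365)
  doses <- tibble::tibble(subject_id = 1, dose_index = 1:4,
                          t0 = c(0, 12, 24, 36), amount = c(60, 50, 70, 60),
                          duration = 3)
  s <- bu_schedule(doses)
  rate_fun <- function(t) {
    r <- 0
    for (j in seq_len(nrow(doses))) {
      if (t >= doses$t0[j] && t < doses$t0[j] + doses$duration[j]) {
        r <- r + doses$amount[j] / doses$duration[j]
      }
    }
    r
  }
  rhs <- function(t, y, parms) list(rate_fun(t) / p$V - p$k * y)
  tt <- sort(c(seq(0, 48, by = 0.5), doses$t0 + 1e-9, doses$t0 + 3))
  sol <- deSolve::lsoda(c(C = 0), times = c(0, tt), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12, hmax = 0.25)
  num <- sol[-1, "C"]
  ana <- concentration(p, s, tt)
  expect_lt(max(abs(num - ana) / pmax(abs(num), 1e-3)), 1e-6)
})

test_that("superposition and dose linearity hold", {
  p <- table3_params()
  d1 <- tibble::tibble(subject_id = 1, dose_index = 1, t0 = 0, amount = 60,
                       duration = 3)
  d2 <- tibble::tibble(subject_id = 1, dose_index = 1:2, t0 = c(0, 12),
                       amount = 60, duration = 3)
  s2 <- bu_schedule(d2)
  tt <- seq(0, 30, by = 0.25)
  # single-dose evaluations with the same k' sequence as the 2-dose schedule
  kp <- k_avg(p, s2$t_mid[findInterval(tt, s2$t0)])
  single <- function(t0d) {
    a <- pmin(pmax(tt - t0d, 0), 3)
    e <- pmax(tt - t0d - 3, 0)
    20 / (kp * p$V) * (1 - exp(-kp * a)) * exp(-kp * e)
  }
  expect_equal(concentration(p, s2, tt), single(0) + single(12),
               tolerance = 1e-12)
  # doubling every rate doubles the concentration
  d2x <- d2; d2x$amount <- d2x$amount * 2
  expect_equal(concentration(p, bu_schedule(d2x), tt),
               2 * concentration(p, s2, tt), tolerance = 1e-12)
})

test_that("concentration is continuous within intervals; k' switches at bounds", {
  p <- table3_params()
  s <- bu_schedule(tibble::tibble(subject_id = 1, dose_index = 1:3,
                                  t0 = c(0, 12, 24), amount = 60,
                                  duration = 3))
  # continuity across an infusion end (inside interval 1)
  eps <- 1e-9
  expect_equal(concentration(p, s, 3 - eps), concentration(p, s, 3 + eps),
               tolerance = 1e-6)
  # the jump at an interval boundary (where k' switches) stays small
  # relative to the scale of the profile for moderate |dk|
  jump <- abs(concentration(p, s, 12 - eps) - concentration(p, s, 12 + eps))
  expect_lt(jump, 0.02 * concentration(p, s, 3))
})

test_that("predict_profile is an elementwise wrapper", {
  p <- table3_params()
  s <- bu_schedule(tibble::tibble(subject_id = 1, dose_index = 1, t0 = 0,
                                  amount = 60, duration = 3))
  expect_equal(nrow(predict_profile(p, s, numeric(0))), 0)
  tt <- c(5, 1, 3, 8)
  prof <- predict_profile(p, s, tt)
  expect_equal(prof$conc, concentration(p, s, tt))
  expect_equal(prof$conc[order(tt)],
               predict_profile(p, s, sort(tt))$conc)
})

test_that("schedule midpoints lie inside their intervals", {
  d <- tibble::tibble(subject_id = 1, dose_index = 1:4,
                      t0 = c(0, 12, 24, 36), amount = 60, duration = 3)
  s <- bu_schedule(d)
  expect_equal(s$t_mid[1:3], c(6, 18, 30))
  expect_equal(s$t_mid[4], 36 + 6)  # half the median gap
  expect_error(bu_schedule(dplyr::mutate(d, duration = 0)), "> 0")
  expect_error(bu_params(V = 1, k = 0.3, dk = -1.2), "1 \\+ dk")
})
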