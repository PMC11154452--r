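# Structural concentration-time model: one-compartment superposition of
# intravenous infusions with an interval-wise averaged, exponentially
# time-varying elimination rate constant.

#' Individual pharmacokinetic parameter set
#'
#' @param V Distribution volume (L), positive.
#' @param k Baseline elimination rate constant (1/h), positive.
#' @param dk Fractional amplitude of the change in `k` over therapy time
#'   (dimensionless; negative values mean elimination slows down).
#'   `1 + dk` must stay positive.
#' @param kappa Rate constant of the change in `k` (1/h), positive;
#'   `ln(2)/kappa` is the half-life of the change.
#' @return A named list of class `bu_params`.
#' @examples
#' bu_params(V = 11.70, k = 0.365, dk = -0.167, kappa = 0.0516)
#' @export
bu_params <- function(V, k, dk = 0, kappa = 0.05) {
  if (V <= 0 || k <= 0 || kappa <= 0 || 1 + dk <= 0) {
    abort("Require V > 0, k > 0, kappa > 0 and 1 + dk > 0.")
  }
  structure(list(V = V, k = k, dk = dk, kappa = kappa), class = "bu_params")
}

#' Instantaneous elimination rate constant
#'
#' `k*(t) = k * (1 + dk * (1 - exp(-kappa * t)))`: equals `k` at the start of
#' therapy and tends to `k * (1 + dk)`; monotone decreasing when `dk < 0`.
#'
#' @param p A [bu_params()] object.
#' @param t Time since first infusion start (h), non-negative; vectorized.
#' @return Rate constant(s) in 1/h.
#' @export
k_inst <- function(p, t) {
  if (any(t < 0)) abort("`t` must be non-negative.")
  p$k * (1 + p$dk * (1 - exp(-p$kappa * t)))
}

#' Time-averaged elimination rate constant
#'
#' Exact integral average of [k_inst()] over `[0, t]`:
#' `k'(t) = k (1 + dk) + k dk (exp(-kappa t) - 1) / (kappa t)`,
#' continuously extended to `k'(0) = k`. This is the rate constant held fixed
#' within a dosing interval (evaluated at the interval midpoint).
#'
#' @inheritParams k_inst
#' @return Rate constant(s) in 1/h.
#' @export
k_avg <- function(p, t) {
  if (any(t < 0)) abort("`t` must be non-negative.")
  k_avg_vec(t, p$k, p$dk, p$kappa)
}

# Vectorized over all arguments; small-x series keeps the limit exact.
k_avg_vec <- function(t, k, dk, kappa) {
  x <- kappa * t
  frac <- ifelse(x < 1e-8, -1 + x / 2, (exp(-x) - 1) / pmax(x, 1e-300))
  k * (1 + dk) + k * dk * frac
}

#' Dosing schedule with interval midpoints
#'
#' Augments a dose-event table with the half-open dosing-interval end and the
#' interval midpoint `t_mid` at which the averaged elimination rate constant
#' is evaluated. The final interval (no successor) gets
#' `t0 + median inter-dose gap / 2` (`default_gap/2` for single-dose
#' schedules).
#'
#' @param doses Tibble with columns `subject_id`, `dose_index`, `t0` (h),
#'   `amount` (mg), `duration` (h); one subject or several.
#' @param default_gap Gap (h) assumed when a subject has a single dose;
#'   default 12 (twice-daily dosing).
#' @return The input with columns `rate` (mg/h), `t_end` (interval end) and
#'   `t_mid` added.
#' @export
bu_schedule <- function(doses, default_gap = 12) {
  doses <- as_tibble(doses)
  if (any(doses$duration <= 0)) abort("Infusion `duration` must be > 0.")
  doses |>
    group_by(.data$subject_id) |>
    arrange(.data$t0, .by_group = TRUE) |>
    mutate(
      rate = .data$amount / .data$duration,
      gap = if (n() > 1) median(diff(.data$t0)) else default_gap,
      t_end = dplyr::lead(.data$t0, default = Inf),
      t_mid = ifelse(is.finite(.data$t_end),
                     (.data$t0 + .data$t_end) / 2,
                     .data$t0 + .data$gap / 2)
    ) |>
    select(-"gap") |>
    ungroup()
}

#' Predicted plasma concentration
#'
#' Evaluates the multi-infusion superposition model for one subject. The
#' elimination rate constant used at time `t` is the time-averaged constant
#' [k_avg()] evaluated at the midpoint of the dosing interval containing `t`
#' and held fixed across all superposed terms; it changes only between
#' dosing intervals. Each past infusion `j` with rate `R0` contributes
#' `R0/(k' V) (1 - exp(-k' a)) exp(-k' e)` where `a` is the elapsed infusion
#' time (capped at the infusion duration) and `e` the time since infusion
#' end. Times before the first infusion return 0.
#'
#' @inheritParams k_inst
#' @param sched Schedule for a single subject, from [bu_schedule()].
#' @param t Times (h), vectorized.
#' @return Concentrations in mg/L.
#' @examples
#' p <- bu_params(V = 11.70, k = 0.365)
#' s <- bu_schedule(tibble::tibble(subject_id = 1, dose_index = 1,
#'                                 t0 = 0, amount = 60, duration = 3))
#' concentration(p, s, t = 3)
#' @export
concentration <- function(p, sched, t) {
  if (any(t < 0)) abort("`t` must be non-negative.")
  if (nrow(sched) == 0) abort("`sched` must contain at least one dose.")
  if (length(unique(sched$subject_id)) > 1) {
    abort("`sched` must describe a single subject.")
  }
  sched <- arrange(sched, .data$t0)
  # interval membership: half-open [t0_j, t0_{j+1})
  idx <- findInterval(t, sched$t0)
  kp <- numeric(length(t))
  pos <- idx >= 1
  kp[pos] <- k_avg(p, sched$t_mid[idx[pos]])
  out <- numeric(length(t))
  for (j in seq_len(nrow(sched))) {
    a <- pmin(pmax(t - sched$t0[j], 0), sched$duration[j])
    e <- pmax(t - sched$t0[j] - sched$duration[j], 0)
    contr <- ifelse(pos,
                    sched$rate[j] / (kp * p$V) * (1 - exp(-kp * a)) *
                      exp(-kp * e),
                    0)
    out <- out + contr
  }
  out
}

#' Predicted concentration profile
#'
#' Vectorized wrapper around [concentration()]; returns a tibble suitable for
#' plotting or joining to observations.
#'
#' @inheritParams concentration
#' @param times Vector of times (h).
#' @return Tibble with columns `t` and `conc`.
#' @export
predict_profile <- function(p, sched, times) {
  tibble(t = times, conc = concentration(p, sched, times))
}
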