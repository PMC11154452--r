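# Non-compartmental (non-parametric) per-interval exposure estimation.

#' Terminal slope elimination rate constant
#'
#' Negative ordinary-least-squares slope of `ln(conc)` versus time over the
#' supplied points. Non-positive concentrations are dropped with a warning.
#'
#' @param times Sampling times (h).
#' @param concs Concentrations (mg/L).
#' @return Elimination rate constant (1/h).
#' @examples
#' slope_k(1:4, c(8, 4, 2, 1))  # exact halving per hour -> ln 2
#' @export
slope_k <- function(times, concs) {
  keep <- is.finite(concs) & concs > 0
  if (any(!keep)) {
    warn("Non-positive concentrations excluded from the log-linear slope.")
  }
  times <- times[keep]; concs <- concs[keep]
  if (length(times) < 2) abort("Need at least 2 positive concentrations.")
  -unname(coef(lm(log(concs) ~ times))[2])
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

descending_phase <- function(times, concs) {
  imax <- which.max(concs)
  seq_along(times) > imax
}

#' AUC and AUMC of the first dosing interval
#'
#' Linear trapezoids from the pre-dose sample through the last measurement
#' `t_n`, plus a mono-exponential tail to infinity: `C(t_n)/k_n` for AUC and
#' `C(t_n) t_n / k_n + C(t_n) / k_n^2` for AUMC, with `k_n` the negative
#' log-linear slope of the last three measurements.
#'
#' @param times Sampling times (h) of the first interval (relative to first
#'   infusion start, i.e. starting at 0).
#' @param concs Concentrations (mg/L).
#' @return List with `auc` (mg.h/L), `aumc` (mg.h^2/L), `auc_tail`,
#'   `aumc_tail`, `k_tail` and `extrapolated_fraction` of the AUC.
#' @export
interval_auc_first <- function(times, concs) {
  o <- order(times)
  times <- times[o]; concs <- concs[o]
  if (length(times) < 3) abort("Need at least 3 samples in the interval.")
  last3 <- tail(seq_along(times), 3)
  k_tail <- slope_k(times[last3], concs[last3])
  if (!is.finite(k_tail) || k_tail <= 0) {
    abort("Terminal slope is not positive; cannot extrapolate to infinity.")
  }
  cn <- tail(concs, 1); tn <- tail(times, 1)
  auc_obs <- trapz(times, concs)
  aumc_obs <- trapz(times, concs * times)
  auc_tail <- cn / k_tail
  aumc_tail <- cn * tn / k_tail + cn / k_tail^2
  list(auc = auc_obs + auc_tail, aumc = aumc_obs + aumc_tail,
       auc_tail = auc_tail, aumc_tail = aumc_tail, k_tail = k_tail,
       extrapolated_fraction = auc_tail / (auc_obs + auc_tail))
}

#' AUC and AUMC of a steady-state dosing interval
#'
#' Linear trapezoids between two infusion starts. If the last sample
#' precedes the next infusion start, the endpoint concentration is
#' log-linearly extrapolated from the last three measurements (exact for
#' mono-exponential decline).
#'
#' @param times Sampling times (h) within the interval.
#' @param concs Concentrations (mg/L).
#' @param start Interval start (h), i.e. this infusion's start time.
#' @param next_start Next infusion's start time (h).
#' @return List with `auc`, `aumc` and logical `extrapolated`.
#' @export
interval_auc_ss <- function(times, concs, start, next_start) {
  o <- order(times)
  times <- times[o]; concs <- concs[o]
  if (length(times) < 3) abort("Need at least 3 samples in the interval.")
  extrapolated <- FALSE
  if (max(times) < next_start) {
    last3 <- tail(seq_along(times), 3)
    fitk <- slope_k(times[last3], concs[last3])
    c_end <- tail(concs[concs > 0], 1) *
      exp(-fitk * (next_start - tail(times[concs > 0], 1)))
    times <- c(times, next_start)
    concs <- c(concs, c_end)
    extrapolated <- TRUE
  }
  keep <- times <= next_start
  list(auc = trapz(times[keep], concs[keep]),
       aumc = trapz(times[keep], concs[keep] * times[keep]),
       extrapolated = extrapolated)
}

#' Non-compartmental analysis of every measured dosing interval
#'
#' For each subject and each dosing interval with concentration measurements,
#' estimates the elimination rate constant (log-linear slope of the
#' descending phase), AUC and AUMC (first interval: trapezoids plus
#' extrapolation to infinity; later intervals: trapezoids between infusion
#' starts assuming steady state), `C_max`, clearance `CL = dose/AUC`,
#' `V = dose/(AUC k)`, half-life `ln 2 / k` and mean residence time
#' `AUMC/AUC`.
#'
#' @param ds A [bu_dataset()].
#' @param min_points Minimum number of descending-phase points required for
#'   the slope (default 3).
#' @return Tibble with one row per (subject, measured interval): columns
#'   `subject_id`, `interval`, `dose`, `k`, `auc`, `aumc`, `cmax`, `cl`,
#'   `v`, `t_half`, `mrt`, `n_points`, `extrapolated_fraction`, `ok`,
#'   `note`. Intervals failing the point rules are reported with `ok =
#'   FALSE` rather than dropped.
#' @export
nca <- function(ds, min_points = 3) {
  stopifnot(inherits(ds, "bu_dataset"))
  out <- list()
  for (id in unique(ds$observations$subject_id)) {
    doses <- filter(ds$doses, .data$subject_id == id)
    obs <- filter(ds$observations, .data$subject_id == id)
    for (j in sort(unique(obs$dosing_interval))) {
      oj <- filter(obs, .data$dosing_interval == j) |> arrange(.data$t)
      out[[length(out) + 1]] <-
        nca_one_interval(oj, doses, id, j, min_points)
    }
  }
  bind_rows(out)
}

nca_one_interval <- function(oj, doses, id, j, min_points) {
  res <- tibble(
    subject_id = id, interval = j, dose = NA_real_, k = NA_real_,
    auc = NA_real_, aumc = NA_real_, cmax = NA_real_, cl = NA_real_,
    v = NA_real_, t_half = NA_real_, mrt = NA_real_,
    n_points = nrow(oj), extrapolated_fraction = NA_real_,
    ok = FALSE, note = ""
  )
  if (j < 1 || j > nrow(doses)) {
    res$note <- "observations outside any dosing interval"
    return(res)
  }
  res$dose <- doses$amount[doses$dose_index == j]
  res$cmax <- max(oj$conc)
  desc <- descending_phase(oj$t, oj$conc)
  if (sum(desc & oj$conc > 0) < max(2, min_points - 1) || nrow(oj) < 3) {
    res$note <- "too few descending-phase points"
    return(res)
  }
  kij <- tryCatch(slope_k(oj$t[desc], oj$conc[desc]), error = function(e) NA)
  if (!is.finite(kij) || kij <= 0) {
    res$note <- "non-positive terminal slope"
    return(res)
  }
  area <- tryCatch({
    if (j == 1) {
      interval_auc_first(oj$t, oj$conc)
    } else {
      t0j <- doses$t0[doses$dose_index == j]
      nxt <- if (j < nrow(doses)) doses$t0[doses$dose_index == j + 1] else
        t0j + 12
      # interval-relative time so that AUMC (and hence MRT) refers to time
      # since the interval's infusion start
      interval_auc_ss(oj$t - t0j, oj$conc, start = 0, next_start = nxt - t0j)
    }
  }, error = function(e) NULL)
  if (is.null(area)) {
    res$note <- "area estimation failed"
    return(res)
  }
  res$k <- kij
  res$auc <- area$auc
  res$aumc <- area$aumc
  res$cl <- res$dose / area$auc
  res$v <- res$dose / (area$auc * kij)
  res$t_half <- log(2) / kij
  res$mrt <- area$aumc / area$auc
  res$extrapolated_fraction <- area$extrapolated_fraction %||% 0
  res$ok <- TRUE
  res
}
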