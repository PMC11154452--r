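# Synthetic cohort generator: emulates the study design (mostly pediatric
# HSCT cohort, twice-daily 3 h or 4 h busulfan infusions, exposure-targeted
# dosing with therapeutic drug monitoring, rich sampling after morning
# infusions) so that every pipeline stage is testable without clinical data.

#' Cohort design specification
#'
#' Defaults reproduce the study design: 124 subjects, 72% male, 18% younger
#' than 1 year (ages 0.2-27 y), disease-group mix ALL 10% / AML 10% /
#' CGD 26% / HLH-XLP 11% / hemoglobinopathies 10% / PID 11% / metabolic 6% /
#' neuroblastoma 5% / other 11%, albumin 19-50 g/L, hematocrit
#' 0.17-0.41 L/L, leukocytes 0.16-20.9 G/L, 12-hourly infusions of 3 h
#' (post-2014 arm, 65%) or 4 h (35%), first dose targeting an AUC of
#' 9-12 mg.h/L (midpoint 10.5 used), cumulative AUC target 45-70 mg.h/L for
#' reduced-intensity and 80-100 mg.h/L for myeloablative conditioning,
#' 4-10 doses, morning-dose sampling at pre-dose and 0/30/60/120/240/360 min
#' after infusion end, 1-5 measured doses per subject with median 3.
#'
#' @param n_subjects Number of subjects.
#' @param p_male,p_age_lt1 Proportions of males and of infants (< 1 y).
#' @param age_range Postnatal age range (years).
#' @param disease_probs Named probabilities over the nine disease groups.
#' @param albumin_range,hematocrit_range,leukocyte_range Lab value ranges.
#' @param p_tinf4 Probability of the 4 h infusion arm.
#' @param first_dose_auc Target AUC (mg.h/L) of the first dosing interval.
#' @param cauc_ric,cauc_mac Cumulative-AUC windows (mg.h/L).
#' @param dose_range Allowed number of doses.
#' @param interval_h Inter-dose interval (h).
#' @param measured_probs Probabilities of 1..5 measured (morning) doses.
#' @param sample_offsets_min Sampling times after infusion end (min).
#' @param sigma Additive residual SD (mg/L).
#' @param tdm Apply dose adjustment after each measured interval.
#' @return A `bu_cohort_spec` list.
#' @export
bu_cohort_spec <- function(
    n_subjects = 124,
    p_male = 0.72,
    p_age_lt1 = 0.18,
    age_range = c(0.2, 27),
    disease_probs = c(ALL = 0.10, AML = 0.10, CGD = 0.26, `HLH/XLP` = 0.11,
                      hemoglobinopathies = 0.10, PID = 0.11,
                      metabolic = 0.06, neuroblastoma = 0.05, other = 0.11),
    albumin_range = c(19, 50),
    hematocrit_range = c(0.17, 0.41),
    leukocyte_range = c(0.16, 20.9),
    p_tinf4 = 0.35,
    first_dose_auc = 10.5,
    cauc_ric = c(45, 70),
    cauc_mac = c(80, 100),
    dose_range = c(4, 10),
    interval_h = 12,
    measured_probs = c(0.1, 0.2, 0.4, 0.2, 0.1),
    sample_offsets_min = c(0, 30, 60, 120, 240, 360),
    sigma = 0.076,
    tdm = TRUE) {
  if (abs(sum(disease_probs) - 1) > 1e-9) {
    abort("`disease_probs` must sum to 1.")
  }
  structure(as.list(environment()), class = "bu_cohort_spec")
}

mac_groups <- function() {
  c("ALL", "AML", "neuroblastoma", "metabolic", "other")
}

#' Generate subject covariates
#'
#' Ages are log-uniform with the infant fraction enforced; weight and height
#' come from a coarse built-in growth table with correlated lognormal
#' scatter; laboratory values are uniform within the study ranges.
#'
#' @param spec A [bu_cohort_spec()].
#' @param seed Optional seed.
#' @return Covariate tibble (one row per subject) accepted by
#'   [derive_covariates()].
#' @export
generate_covariates <- function(spec = bu_cohort_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_subjects
  if (n == 0) {
    return(tibble(subject_id = character(), weight = numeric(),
                  height = numeric(), age = numeric(), sex = character(),
                  disease_group = character(), albumin = numeric(),
                  total_protein = numeric(), hematocrit = numeric(),
                  leukocytes = numeric(), tinf_h = numeric()))
  }
  infant <- runif(n) < spec$p_age_lt1
  lo <- spec$age_range[1]; hi <- spec$age_range[2]
  age <- ifelse(infant,
                exp(runif(n, log(lo), log(1))),
                exp(runif(n, log(1), log(hi))))
  gt <- bu_growth_table()
  w_med <- exp(approx(log(gt$age), log(gt$weight), log(age), rule = 2)$y)
  h_med <- exp(approx(log(gt$age), log(gt$height), log(age), rule = 2)$y)
  zw <- rnorm(n)
  zh <- 0.6 * zw + 0.8 * rnorm(n)
  weight <- w_med * exp(0.15 * zw)
  height <- h_med * exp(0.035 * zh)
  tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    weight = weight, height = height, age = age,
    sex = ifelse(runif(n) < spec$p_male, "male", "female"),
    disease_group = sample(names(spec$disease_probs), n, replace = TRUE,
                           prob = spec$disease_probs),
    albumin = runif(n, spec$albumin_range[1], spec$albumin_range[2]),
    total_protein = runif(n, 34, 84),
    hematocrit = runif(n, spec$hematocrit_range[1], spec$hematocrit_range[2]),
    leukocytes = exp(runif(n, log(spec$leukocyte_range[1]),
                           log(spec$leukocyte_range[2]))),
    tinf_h = ifelse(runif(n) < spec$p_tinf4, 4, 3)
  )
}

#' Plan an exposure-targeted dosing schedule
#'
#' The first dose is the population-predicted clearance times the first-dose
#' AUC target; the number of 12-hourly doses is chosen so the planned
#' cumulative AUC lands inside the regimen window (reduced-intensity for
#' non-malignant disease other than metabolic, myeloablative otherwise).
#'
#' @param dcov One row of derived covariates (see [derive_covariates()]).
#' @param pop A `bu_popmodel` used for the population clearance prediction.
#' @param spec A [bu_cohort_spec()].
#' @return Dose tibble (`subject_id`, `dose_index`, `t0`, `amount`,
#'   `duration`) with attribute `"planned_cauc"`.
#' @export
plan_dosing <- function(dcov, pop = bu_final_model(),
                        spec = bu_cohort_spec()) {
  ip <- individual_params(pop, dcov)
  cl_pop <- ip$k * ip$V
  dose1 <- spec$first_dose_auc * cl_pop
  mac <- dcov$disease_group %in% mac_groups()
  window <- if (mac) spec$cauc_mac else spec$cauc_ric
  target <- mean(window)
  n_dose <- round(target / spec$first_dose_auc)
  n_dose <- min(max(n_dose, spec$dose_range[1]), spec$dose_range[2])
  out <- tibble(
    subject_id = dcov$subject_id,
    dose_index = seq_len(n_dose),
    t0 = (seq_len(n_dose) - 1) * spec$interval_h,
    amount = dose1,
    duration = if ("tinf_h" %in% names(dcov)) dcov$tinf_h else 3
  )
  attr(out, "planned_cauc") <- n_dose * spec$first_dose_auc
  attr(out, "target_cauc") <- target
  attr(out, "regimen") <- if (mac) "MAC" else "RIC"
  out
}

#' Simulate a synthetic study cohort
#'
#' Generates covariates, draws subject random effects from the population
#' model, plans exposure-targeted dosing, and simulates observed
#' concentrations (additive residual error, truncated at 0) on the study
#' sampling schedule for the measured morning doses. With `spec$tdm = TRUE`,
#' remaining doses are re-scaled after each measured interval from its
#' non-compartmental AUC, emulating therapeutic drug monitoring.
#'
#' @param spec A [bu_cohort_spec()].
#' @param pop The simulating `bu_popmodel`; defaults to the packaged final
#'   model.
#' @param seed Seed; the cohort is fully reproducible from `(spec, seed)`.
#' @return A `bu_cohort` list: `dataset` (a [bu_dataset()]), `truth`
#'   (per-subject random effects and individual parameters), `spec`, `pop`,
#'   `seed`.
#' @export
simulate_cohort <- function(spec = bu_cohort_spec(), pop = bu_final_model(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cov <- generate_covariates(spec)
  dcov <- derive_covariates(cov)
  n <- nrow(cov)
  rp <- pop$spec$random
  eta <- matrix(rnorm(n * length(rp)), n, length(rp),
                dimnames = list(NULL, rp))
  eta <- sweep(eta, 2, sqrt(pop$omega2[rp]), "*")
  # keep elimination positive: resample invalid dk draws
  if ("dk" %in% rp) {
    mu_dk <- individual_params(pop, dcov)$dk
    bad <- which(1 + mu_dk + eta[, "dk"] <= 0.05)
    while (length(bad) > 0) {
      eta[bad, "dk"] <- rnorm(length(bad), 0, sqrt(pop$omega2["dk"]))
      bad <- bad[1 + mu_dk[bad] + eta[bad, "dk"] <= 0.05]
    }
  }
  ind <- individual_params(pop, dcov, eta)

  morning_first <- runif(n) < 0.5
  n_meas_draw <- sample(seq_along(spec$measured_probs), n, replace = TRUE,
                        prob = spec$measured_probs)

  all_doses <- list(); all_obs <- list()
  for (i in seq_len(n)) {
    sub <- simulate_subject(dcov[i, ], ind[i, ], pop, spec,
                            morning_first = morning_first[i],
                            n_meas = n_meas_draw[i])
    all_doses[[i]] <- sub$doses
    all_obs[[i]] <- sub$obs
  }
  ds <- bu_dataset(bind_rows(all_doses), bind_rows(all_obs), cov,
                   provenance = "synthetic cohort (simulate_cohort)")
  truth <- dplyr::bind_cols(ind, as_tibble(eta) |>
                              rlang::set_names(paste0("eta_", rp)))
  structure(list(dataset = ds, truth = truth, spec = spec, pop = pop,
                 seed = seed, morning_first = morning_first),
            class = "bu_cohort")
}

# One subject: schedule, measured-dose selection, sequential simulation with
# optional TDM dose re-scaling.
simulate_subject <- function(dcov_i, ind_i, pop, spec, morning_first,
                             n_meas) {
  doses <- plan_dosing(dcov_i, pop, spec)
  target <- attr(doses, "target_cauc")
  n_dose <- nrow(doses)
  morning <- if (morning_first) seq(1, n_dose, by = 2) else
    seq(2, n_dose, by = 2)
  measured <- head(morning, max(1, n_meas))
  p <- bu_params(ind_i$V, ind_i$k,
                 ifelse(is.na(ind_i$dk), 0, ind_i$dk),
                 ifelse(is.na(ind_i$kappa), 0.05, ind_i$kappa))

  obs <- list()
  auc_per_mg <- NA_real_
  auc_acc <- 0
  for (j in measured) {
    sched <- bu_schedule(doses)
    t_dose <- doses$t0[j]
    times <- c(t_dose, t_dose + doses$duration[j] + spec$sample_offsets_min / 60)
    conc <- concentration(p, sched, times)
    y <- pmax(conc + rnorm(length(times), 0, spec$sigma), 0)
    obs[[length(obs) + 1]] <- tibble(
      subject_id = dcov_i$subject_id, t = times, conc = y,
      dosing_interval = j
    )
    if (!spec$tdm) next
    # non-compartmental AUC of this interval from the noisy observations
    auc_j <- tryCatch({
      if (j == 1) {
        interval_auc_first(times, y)$auc
      } else {
        nxt <- if (j < n_dose) doses$t0[j + 1] else t_dose + spec$interval_h
        interval_auc_ss(times, y, t_dose, nxt)$auc
      }
    }, error = function(e) NA_real_)
    if (!is.finite(auc_j)) next
    auc_per_mg <- auc_j / doses$amount[j]
    auc_acc <- auc_acc + auc_j
    # accrued exposure: measured intervals by NCA, unmeasured past ones
    # scaled from the latest AUC-per-mg estimate
    past <- seq_len(j)
    meas_past <- intersect(past, measured[measured <= j])
    est_past <- auc_acc +
      sum(doses$amount[setdiff(past, meas_past)]) * auc_per_mg
    remaining <- which(seq_len(n_dose) > j)
    if (length(remaining) == 0) next
    if (est_past >= target) {
      warn(paste0("Subject ", dcov_i$subject_id,
                  ": target exposure already reached; remaining doses set to ~0."))
      doses$amount[remaining] <- 1e-6
      next
    }
    new_amt <- (target - est_past) / (length(remaining) * auc_per_mg)
    doses$amount[remaining] <- max(new_amt, 1e-6)
  }
  list(doses = doses, obs = bind_rows(obs))
}

#' @export
print.bu_cohort <- function(x, ...) {
  cat("<bu_cohort> synthetic cohort of", nrow(x$truth), "subjects\n")
  print(x$dataset)
  invisible(x)
}
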