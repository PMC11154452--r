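# Shared synthetic fixtures, built once per test run.

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, n, seed, tdm = FALSE, ...) {
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- suppressWarnings(
      simulate_cohort(bu_cohort_spec(n_subjects = n, tdm = tdm, ...),
                      seed = seed)
    )
  }
  .cohort_cache[[key]]
}

# a single-subject dataset with a known schedule, handy for NCA/structural
one_subject_dataset <- function(k = 0.2, V = 10, dose = 60, tinf = 3,
                                n_dose = 5, sigma = 0, measured = c(1, 3)) {
  p <- bu_params(V = V, k = k)
  doses <- tibble::tibble(
    subject_id = "X", dose_index = seq_len(n_dose),
    t0 = (seq_len(n_dose) - 1) * 12, amount = dose, duration = tinf
  )
  sched <- bu_schedule(doses)
  obs <- list()
  for (j in measured) {
    t0j <- doses$t0[j]
    times <- c(t0j, t0j + tinf + c(0, 30, 60, 120, 240, 360) / 60)
    conc <- concentration(p, sched, times)
    if (sigma > 0) conc <- pmax(conc + rnorm(length(conc), 0, sigma), 0)
    obs[[length(obs) + 1]] <- tibble::tibble(
      subject_id = "X", t = times, conc = conc, dosing_interval = j)
  }
  cov <- tibble::tibble(subject_id = "X", weight = 17.2, height = 105,
                        age = 4.3, sex = "male", disease_group = "CGD",
                        albumin = 34, total_protein = 61, hematocrit = 0.3,
                        leukocytes = 4, tinf_h = tinf)
  bu_dataset(doses, dplyr::bind_rows(obs), cov, provenance = "test fixture")
}
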