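# Dataset container, CSV reader/writer and validation.

#' Construct a study dataset
#'
#' Bundles dose events, concentration observations, subject covariates and
#' co-medication records into a validated `bu_dataset`.
#'
#' @param doses Tibble: `subject_id`, `dose_index`, `t0` (h), `amount` (mg),
#'   `duration` (h). `rate` is derived.
#' @param observations Tibble: `subject_id`, `t` (h), `conc` (mg/L).
#'   `dosing_interval` is derived if absent.
#' @param covariates Tibble, one row per subject: `subject_id`, `weight`,
#'   `height`, `age`, `sex`, `disease_group`, `albumin`, `total_protein`,
#'   `hematocrit`, `leukocytes`, `tinf_h`.
#' @param comedication Optional tibble: `subject_id`, `drug`, `time` (h of
#'   administration).
#' @param provenance Free-text provenance note.
#' @return A `bu_dataset` object.
#' @export
bu_dataset <- function(doses, observations, covariates,
                       comedication = NULL, provenance = "unspecified") {
  doses <- as_tibble(doses)
  observations <- as_tibble(observations)
  covariates <- as_tibble(covariates)
  comedication <- if (is.null(comedication)) {
    tibble(subject_id = character(), drug = character(), time = numeric())
  } else {
    as_tibble(comedication)
  }

  validate_doses(doses)
  if (!"dosing_interval" %in% names(observations) ||
      anyNA(observations$dosing_interval)) {
    observations <- assign_intervals(observations, doses)
  }
  validate_observations(observations, doses)
  validate_covariates(covariates, doses)

  structure(
    list(doses = bu_schedule(doses), observations = observations,
         covariates = covariates, comedication = comedication,
         provenance = provenance),
    class = "bu_dataset"
  )
}

#' @export
print.bu_dataset <- function(x, ...) {
  cat("<bu_dataset> ", nrow(x$covariates), " subjects, ",
      nrow(x$doses), " doses, ", nrow(x$observations),
      " observations\n", sep = "")
  cat("provenance:", x$provenance, "\n")
  invisible(x)
}

# Half-open interval membership [t0_j, t0_{j+1}).
assign_intervals <- function(observations, doses) {
  obs <- as_tibble(observations)
  obs$dosing_interval <- NA_integer_
  for (id in unique(obs$subject_id)) {
    t0 <- sort(doses$t0[doses$subject_id == id])
    sel <- obs$subject_id == id
    obs$dosing_interval[sel] <- findInterval(obs$t[sel], t0)
  }
  obs
}

validate_doses <- function(doses) {
  need <- c("subject_id", "dose_index", "t0", "amount", "duration")
  miss <- setdiff(need, names(doses))
  if (length(miss) > 0) {
    abort(paste0("dose table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(doses$duration <= 0)) {
    abort("Infusion duration must be > 0 for every dose event.")
  }
  if ("rate" %in% names(doses)) {
    rel <- abs(doses$rate - doses$amount / doses$duration) /
      pmax(abs(doses$amount / doses$duration), 1e-300)
    if (any(rel > 1e-9 & doses$amount > 0)) {
      abort("`rate` inconsistent with amount/duration.")
    }
  }
  for (id in unique(doses$subject_id)) {
    d <- doses[doses$subject_id == id, ]
    d <- d[order(d$dose_index), ]
    if (any(diff(d$t0) <= 0)) {
      abort(paste0("Dose times not strictly increasing for subject ", id, "."))
    }
    if (!identical(as.integer(d$dose_index), seq_len(nrow(d)))) {
      abort(paste0("`dose_index` must be consecutive from 1 (subject ",
                   id, ")."))
    }
  }
  invisible(doses)
}

validate_observations <- function(observations, doses) {
  need <- c("subject_id", "t", "conc")
  miss <- setdiff(need, names(observations))
  if (length(miss) > 0) {
    abort(paste0("observation table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(observations$conc < 0, na.rm = TRUE) || any(observations$t < 0)) {
    abort("Observations require conc >= 0 and t >= 0.")
  }
  orphan <- setdiff(unique(observations$subject_id), unique(doses$subject_id))
  if (length(orphan) > 0) {
    abort(paste0("Observations for subject(s) without doses: ",
                 paste(orphan, collapse = ", ")))
  }
  invisible(observations)
}

validate_covariates <- function(covariates, doses) {
  if (!"subject_id" %in% names(covariates)) {
    abort("covariate table needs a `subject_id` column.")
  }
  nodose <- setdiff(unique(covariates$subject_id), unique(doses$subject_id))
  if (length(nodose) > 0) {
    abort(paste0("Subject(s) without any dose event: ",
                 paste(nodose, collapse = ", ")))
  }
  if ("tinf_h" %in% names(covariates)) {
    ok <- is.na(covariates$tinf_h) | covariates$tinf_h %in% c(3, 4)
    if (!all(ok)) abort("`tinf_h` must be 3 or 4 (hours).")
  }
  if ("disease_group" %in% names(covariates)) {
    ok <- is.na(covariates$disease_group) |
      covariates$disease_group %in% bu_disease_groups()
    if (!all(ok)) {
      abort(paste0("`disease_group` must be one of: ",
                   paste(bu_disease_groups(), collapse = ", ")))
    }
  }
  invisible(covariates)
}

bu_csv_covariate_cols <- function() {
  c(WT = "weight", HT = "height", AGE = "age", SEX = "sex",
    DISEASE = "disease_group", ALB = "albumin", TPROT = "total_protein",
    HCT = "hematocrit", LEU = "leukocytes", TINF = "tinf_h")
}

#' Read a study dataset from CSV
#'
#' Reads a long-format event table (one row per dose event, concentration
#' observation or co-medication record) into a [bu_dataset()]. Required
#' columns: `ID`, `TIME`, `EVID`, `AMT`, `DUR`, `DV`. Rows with `EVID = 1`
#' are dose events (`AMT` mg over `DUR` h), `EVID = 0` are observations
#' (`DV` mg/L), `EVID = 2` are co-medication records (`COMED`, `COMED_TIME`).
#' Subject covariates (`WT`, `HT`, `AGE`, `SEX`, `DISEASE`, `ALB`, `TPROT`,
#' `HCT`, `LEU`, `TINF`) are taken from each subject's first row; missing
#' values are kept as `NA` (reference substitution happens downstream in
#' [derive_covariates()]).
#'
#' @param path CSV file path.
#' @return A `bu_dataset`.
#' @export
read_pk_dataset <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("ID", "TIME", "EVID", "AMT", "DUR", "DV")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0("Missing required column(s): ", paste(miss, collapse = ", ")))
  }
  raw$ID <- as.character(raw$ID)

  doses <- raw |>
    filter(.data$EVID == 1) |>
    group_by(ID = .data$ID) |>
    arrange(.data$TIME, .by_group = TRUE) |>
    mutate(dose_index = row_number()) |>
    ungroup() |>
    select(subject_id = "ID", "dose_index", t0 = "TIME",
           amount = "AMT", duration = "DUR")

  observations <- raw |>
    filter(.data$EVID == 0) |>
    select(subject_id = "ID", t = "TIME", conc = "DV")

  cov_map <- bu_csv_covariate_cols()
  present <- intersect(names(cov_map), names(raw))
  covariates <- raw |>
    group_by(subject_id = .data$ID) |>
    summarise(across(all_of(present), first), .groups = "drop")
  names(covariates) <- c("subject_id", unname(cov_map[present]))

  comed <- NULL
  if ("COMED" %in% names(raw)) {
    comed <- raw |>
      filter(.data$EVID == 2, !is.na(.data$COMED)) |>
      select(subject_id = "ID", drug = "COMED",
             time = dplyr::any_of("COMED_TIME"))
    if (!"time" %in% names(comed)) comed$time <- NA_real_
  }

  bu_dataset(doses, observations, covariates, comed,
             provenance = paste0("read from ", path))
}

#' Write a study dataset to CSV
#'
#' Inverse of [read_pk_dataset()]: emits the long event-table schema at full
#' numeric precision, with missing covariates written as explicit `NA`.
#'
#' @param ds A `bu_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "bu_dataset"))
  cov_map <- bu_csv_covariate_cols()
  cov <- ds$covariates
  for (col in unname(cov_map)) if (!col %in% names(cov)) cov[[col]] <- NA

  dose_rows <- ds$doses |>
    transmute_event(TIME = .data$t0, EVID = 1, AMT = .data$amount,
                    DUR = .data$duration, DV = NA_real_)
  obs_rows <- ds$observations |>
    transmute_event(TIME = .data$t, EVID = 0, AMT = NA_real_,
                    DUR = NA_real_, DV = .data$conc)
  rows <- bind_rows(dose_rows, obs_rows)
  if (nrow(ds$comedication) > 0) {
    rows <- bind_rows(rows, ds$comedication |>
      transmute_event(TIME = .data$time, EVID = 2, AMT = NA_real_,
                      DUR = NA_real_, DV = NA_real_, COMED = .data$drug,
                      COMED_TIME = .data$time))
  }
  if (!"COMED" %in% names(rows)) {
    rows$COMED <- NA_character_
    rows$COMED_TIME <- NA_real_
  }

  out <- rows |>
    left_join(cov, by = c(ID = "subject_id")) |>
    arrange(.data$ID, .data$TIME, dplyr::desc(.data$EVID))
  names(out)[match(unname(cov_map), names(out))] <- names(cov_map)
  readr::write_csv(out, path, na = "NA")
  invisible(path)
}

transmute_event <- function(df, ...) {
  df |>
    mutate(ID = as.character(.data$subject_id)) |>
    dplyr::transmute(.data$ID, ...)
}
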