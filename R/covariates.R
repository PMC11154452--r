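# Derived body-size and maturation covariates.

#' Body surface area (Mosteller)
#'
#' `BSA = sqrt(H * W / 3600)` with height in cm and weight in kg.
#'
#' @param weight Body weight (kg), positive.
#' @param height Body height (cm), positive.
#' @return Body surface area in m^2.
#' @examples
#' bsa(weight = 32, height = 140)
#' @export
bsa <- function(weight, height) {
  check_positive(weight, "weight")
  check_positive(height, "height")
  sqrt(height * weight / 3600)
}

#' Total body water
#'
#' `TBW = exp(-2.952 + 0.551 ln W + 0.796 ln H + 0.008 age - 0.047 female)`
#' with weight in kg, height in cm and age in years.
#'
#' @inheritParams bsa
#' @param age Postnatal age (years), positive.
#' @param sex `"male"` or `"female"`.
#' @return Total body water in L.
#' @examples
#' tbw(weight = 32, height = 140, age = 10, sex = "male")
#' @export
tbw <- function(weight, height, age, sex) {
  check_positive(weight, "weight")
  check_positive(height, "height")
  check_positive(age, "age")
  female <- as_female(sex)
  exp(-2.952 + 0.551 * log(weight) + 0.796 * log(height) +
        0.008 * age - 0.047 * female)
}

#' Fat-free mass
#'
#' Sexed hyperbolic fat-free mass model; height is converted to meters
#' internally. The result is always smaller than total body weight.
#'
#' @inheritParams bsa
#' @param sex `"male"` or `"female"`.
#' @return Fat-free mass in kg.
#' @examples
#' ffm(weight = 32, height = 140, sex = "male")
#' @export
ffm <- function(weight, height, sex) {
  check_positive(weight, "weight")
  check_positive(height, "height")
  female <- as_female(sex)
  hm2 <- (height / 100)^2
  num <- ifelse(female == 1, 37.99, 42.92) * hm2 * weight
  den <- ifelse(female == 1, 35.98, 30.93) * hm2 + weight
  num / den
}

#' Postmenstrual age in weeks
#'
#' Postnatal age plus a fixed gestation of 40 weeks. Years are converted with
#' 52.1775 weeks/year (mean calendar year).
#'
#' @param age Postnatal age (years), non-negative.
#' @param weeks_per_year Conversion factor, default 52.1775.
#' @return Postmenstrual age in weeks.
#' @export
pma_weeks <- function(age, weeks_per_year = 52.1775) {
  if (any(age < 0)) abort("`age` must be non-negative.")
  age * weeks_per_year + 40
}

#' Maturation function of elimination
#'
#' Sigmoid Hill function of postmenstrual age,
#' `F_mat = 1 / (1 + (PMA / 46)^-2.3)`: 0.5 at 46 weeks PMA, approaching 1
#' with increasing age. Scales the elimination rate constant in infants.
#'
#' @inheritParams pma_weeks
#' @return Dimensionless maturation fraction in (0, 1).
#' @examples
#' fmat(0.2)   # young infant
#' fmat(10)    # close to 1
#' @export
fmat <- function(age, weeks_per_year = 52.1775) {
  pma <- pma_weeks(age, weeks_per_year)
  1 / (1 + (pma / 46)^(-2.3))
}

#' Derive model covariates for each subject
#'
#' Computes body-size metrics (BSA, TBW, FFM), maturation (PMA, `F_mat`),
#' reference-centered log terms and disease indicators from raw subject
#' covariates. Missing continuous covariates are replaced by their reference
#' values (so their centered term is 0), with a warning.
#'
#' @param covariates Tibble with one row per subject: `subject_id`, `weight`
#'   (kg), `height` (cm), `age` (y), `sex`, `disease_group`, `albumin` (g/L),
#'   `tinf_h` (3 or 4). Extra columns are carried through untouched.
#' @param refs Reference values, see [bu_reference_values()].
#' @return The input tibble with derived columns: `bsa`, `tbw`, `ffm`, `pma`,
#'   `fmat`, `dln_tbw`, `ln_fmat`, `dln_alb`, `all`, `hlh_xlp`, `dtinf`.
#' @export
derive_covariates <- function(covariates, refs = bu_reference_values()) {
  cov <- as_tibble(covariates)
  need <- c("subject_id", "weight", "height", "age", "sex", "disease_group")
  miss <- setdiff(need, names(cov))
  if (length(miss) > 0) {
    abort(paste0("`covariates` is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!"albumin" %in% names(cov)) cov$albumin <- NA_real_
  if (!"tinf_h" %in% names(cov)) cov$tinf_h <- refs$tinf_h

  if (anyNA(cov$albumin)) {
    warn("Missing albumin replaced by the reference value (30 g/L).")
  }
  alb <- ifelse(is.na(cov$albumin), refs$albumin, cov$albumin)
  tinf <- ifelse(is.na(cov$tinf_h), refs$tinf_h, cov$tinf_h)

  cov |>
    mutate(
      bsa = bsa(.data$weight, .data$height),
      tbw = tbw(.data$weight, .data$height, .data$age, .data$sex),
      ffm = ffm(.data$weight, .data$height, .data$sex),
      pma = pma_weeks(.data$age),
      fmat = fmat(.data$age),
      dln_tbw = log(.data$tbw) - log(refs$tbw),
      ln_fmat = log(.data$fmat),
      dln_alb = log(alb) - log(refs$albumin),
      dln_hct = if ("hematocrit" %in% names(cov)) {
        log(.data$hematocrit) - log(stats::median(.data$hematocrit,
                                                  na.rm = TRUE))
      } else {
        0
      },
      dln_leu = if ("leukocytes" %in% names(cov)) {
        log(.data$leukocytes) - log(stats::median(.data$leukocytes,
                                                  na.rm = TRUE))
      } else {
        0
      },
      dln_w = log(.data$weight) - log(stats::median(.data$weight)),
      dln_h = log(.data$height) - log(stats::median(.data$height)),
      dln_bsa = log(.data$bsa) - log(stats::median(.data$bsa)),
      dln_ffm = log(.data$ffm) - log(stats::median(.data$ffm)),
      all = as.numeric(.data$disease_group == "ALL"),
      hlh_xlp = as.numeric(.data$disease_group == "HLH/XLP"),
      dtinf = tinf - refs$tinf_h
    )
}

bu_disease_groups <- function() {
  c("ALL", "AML", "CGD", "hemoglobinopathies", "HLH/XLP", "PID",
    "metabolic", "neuroblastoma", "other")
}

as_female <- function(sex) {
  s <- tolower(as.character(sex))
  bad <- !s %in% c("male", "female")
  if (any(bad)) abort("`sex` must be \"male\" or \"female\".")
  as.numeric(s == "female")
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(paste0("`", name, "` must be positive and finite."))
  }
  invisible(x)
}
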