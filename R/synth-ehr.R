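#' Default condition-group catalog for simulation
#'
#' A small catalog of pediatric condition groups with per-visit baseline
#' prevalences, loosely reflecting common primary-care diagnosis frequencies.
#' "Preventive care" is present at every simulated visit: the analysis only
#' ever considers encounters that carry at least one clinical finding, so
#' the generator encodes that design fact as a universal routine-care code
#' (lower it to stress the no-findings exclusion paths). It belongs to the
#' default exclusion policy, so mined patterns built on it are filtered
#' before testing.
#'
#' @return A named numeric vector: condition group -> per-visit probability.
#' @export
default_condition_prevalence <- function() {
  c(
    "Acute upper respiratory tract infection" = 0.15,
    "Otitis media" = 0.12,
    "Asthma" = 0.10,
    "Allergic Rhinitis" = 0.08,
    "Dermatitis and eczema" = 0.08,
    "Fever" = 0.08,
    "Constipation" = 0.05,
    "Headaches" = 0.05,
    "Sleep apnea" = 0.02,
    "Preventive care" = 1.00
  )
}

#' Default planted case/control effects
#'
#' Timing-class-specific prevalence odds ratios applied to eventual cases,
#' sized like the strongest associations reported for incident pediatric
#' obesity: asthma and allergic rhinitis enriched before and at the index
#' visit, sleep apnea enriched across all three classes.
#'
#' @return A tibble with columns `condition`, `timing_class`, `odds_ratio`.
#' @export
default_planted_effects <- function() {
  tibble(
    condition = c("Asthma", "Asthma", "Allergic Rhinitis",
                  "Sleep apnea", "Sleep apnea", "Sleep apnea"),
    timing_class = c(1L, 2L, 2L, 1L, 2L, 3L),
    odds_ratio = c(1.31, 1.73, 1.51, 2.80, 2.37, 2.33)
  )
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic longitudinal EHR
#' generator. Defaults describe a pediatric primary-care population: ages 2-18
#' years (730-6935 days), 55.3% male, overdispersed visit counts, and an
#' obesity threshold at the 95th BMI percentile (z = 1.6449).
#'
#' @param n_patients Number of patients to simulate (>= 2).
#' @param sex_fraction_male Proportion of male patients.
#' @param age_range_days Two integers, the (min, max) patient age in days over
#'   which visit streams start.
#' @param visits_per_patient List with `mean` (mean documented visits per
#'   patient, >= 2) and `dispersion` (negative-binomial size; smaller is more
#'   overdispersed). Every patient receives at least two visits.
#' @param obesity_fraction Proportion of patients whose BMI z-score trajectory
#'   drifts upward and crosses the obesity threshold.
#' @param condition_catalog Character vector of condition-group names.
#' @param baseline_prevalence Named numeric vector, per-visit presence
#'   probability for each catalog entry.
#' @param planted_effects Tibble (`condition`, `timing_class`, `odds_ratio`):
#'   for eventual cases, the per-visit presence odds at the visit occupying
#'   that timing class (pre-index, index, post-index) are multiplied by
#'   `odds_ratio` relative to baseline. Use `NULL` or a zero-row tibble for a
#'   null simulation.
#' @param bmi_z_threshold Obesity threshold on the BMI z-score scale.
#' @param obesity_dx_prob Probability that a case's index visit also carries a
#'   formal "Obesity" diagnosis code (most incident obesity goes formally
#'   undiagnosed, so the default is well below 1).
#' @param overweight_noncase_fraction Fraction of non-case patients given one
#'   overweight (but non-obese) measurement; these patients are screened out
#'   of the control pool by the no-unhealthy-BMI rule.
#' @param pair_dependence Optional comorbidity coupling in \[0, 1\]: with this
#'   probability the presence of the second catalog condition at a visit is
#'   copied from the first, emulating correlated diagnoses (default 0 =
#'   independence).
#' @param code_fanout If `TRUE`, emit granular diagnosis codes drawn from
#'   [demo_condition_mapping()] instead of condition-group names, so the code
#'   -> group mapping stage has real work to do.
#' @param seed Integer seed; a fixed seed makes [simulate_ehr()] byte-identical.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_patients,
                       sex_fraction_male = 0.553,
                       age_range_days = c(730L, 6935L),
                       visits_per_patient = list(mean = 6, dispersion = 1.2),
                       obesity_fraction = 0.3,
                       condition_catalog = names(default_condition_prevalence()),
                       baseline_prevalence = default_condition_prevalence(),
                       planted_effects = default_planted_effects(),
                       bmi_z_threshold = 1.6449,
                       obesity_dx_prob = 0.143,
                       overweight_noncase_fraction = 0.15,
                       pair_dependence = 0,
                       code_fanout = FALSE,
                       seed = 1L) {
  n_patients <- check_count(n_patients, "n_patients", min = 2L)
  check_prob(sex_fraction_male, "sex_fraction_male")
  check_prob(obesity_fraction, "obesity_fraction")
  check_prob(obesity_dx_prob, "obesity_dx_prob")
  check_prob(overweight_noncase_fraction, "overweight_noncase_fraction")
  check_prob(pair_dependence, "pair_dependence")
  if (length(age_range_days) != 2L || age_range_days[1] >= age_range_days[2]) {
    abort("`age_range_days` must be (min, max) with min < max.")
  }
  if (!is.list(visits_per_patient) ||
      !all(c("mean", "dispersion") %in% names(visits_per_patient)) ||
      visits_per_patient$mean < 2 || visits_per_patient$dispersion <= 0) {
    abort("`visits_per_patient` needs `mean` >= 2 and `dispersion` > 0.")
  }
  if (length(condition_catalog) == 0) {
    abort("`condition_catalog` must not be empty.")
  }
  if (anyDuplicated(condition_catalog)) {
    abort("`condition_catalog` contains duplicate names.")
  }
  check_prob(baseline_prevalence, "baseline_prevalence")
  missing_prev <- setdiff(condition_catalog, names(baseline_prevalence))
  if (length(missing_prev) > 0) {
    abort(sprintf("`baseline_prevalence` lacks entries for: %s.",
                  paste(missing_prev, collapse = ", ")))
  }
  if (is.null(planted_effects)) {
    planted_effects <- tibble(condition = character(),
                              timing_class = integer(),
                              odds_ratio = double())
  }
  planted_effects <- as_tibble(planted_effects)
  check_columns(planted_effects, c("condition", "timing_class", "odds_ratio"),
                "planted_effects")
  if (nrow(planted_effects) > 0) {
    if (!all(planted_effects$timing_class %in% 1:3)) {
      abort("`planted_effects$timing_class` must be 1, 2 or 3.")
    }
    if (any(planted_effects$odds_ratio <= 0)) {
      abort("`planted_effects$odds_ratio` must be positive.")
    }
    bad <- setdiff(planted_effects$condition, condition_catalog)
    if (length(bad) > 0) {
      abort(sprintf("Planted effect condition(s) not in catalog: %s.",
                    paste(bad, collapse = ", ")))
    }
  }
  if (!is.numeric(bmi_z_threshold) || bmi_z_threshold <= 0) {
    abort("`bmi_z_threshold` must be positive.")
  }
  structure(
    list(n_patients = n_patients,
         sex_fraction_male = sex_fraction_male,
         age_range_days = as.integer(age_range_days),
         visits_per_patient = visits_per_patient,
         obesity_fraction = obesity_fraction,
         condition_catalog = condition_catalog,
         baseline_prevalence = baseline_prevalence[condition_catalog],
         planted_effects = planted_effects,
         bmi_z_threshold = bmi_z_threshold,
         obesity_dx_prob = obesity_dx_prob,
         overweight_noncase_fraction = overweight_noncase_fraction,
         pair_dependence = pair_dependence,
         code_fanout = code_fanout,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  patients:", x$n_patients,
      "| obesity fraction:", x$obesity_fraction,
      "| seed:", x$seed, "\n")
  cat("  catalog:", length(x$condition_catalog), "condition groups;",
      nrow(x$planted_effects), "planted effect(s)\n")
  invisible(x)
}

# Scale a baseline probability by an odds ratio on the odds scale.
apply_odds_ratio <- function(p, or) {
  plogis(qlogis(p) + log(or))
}

#' Simulate synthetic longitudinal EHR tables
#'
#' Generates the four relational tables of a minimal longitudinal EHR:
#' `patients` (id, sex, birth ordinal), `visits` (ordinal day, age, care
#' setting), `measurements` (BMI z-score per face-to-face visit), and
#' `conditions` (per-visit diagnosis codes). Case patients follow a BMI
#' z-score random walk with upward drift that first crosses the obesity
#' threshold at a face-to-face visit with at least one earlier visit; planted
#' condition effects act at the visits flanking that crossing (the eventual
#' pre-index, index and post-index visits).
#'
#' @param config A [sim_config()] object.
#' @return A list of class `raw_ehr` with tibbles `patients`, `visits`,
#'   `measurements`, `conditions`, and the generating `config` attached as an
#'   attribute.
#' @export
simulate_ehr <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created by sim_config().")
  }
  n <- config$n_patients
  zthr <- config$bmi_z_threshold

  ## ---- patients -----------------------------------------------------------
  set.seed(config$seed + 1L)
  patients <- tibble(
    patient_id = seq_len(n),
    sex = ifelse(runif(n) < config$sex_fraction_male, "M", "F"),
    birth_ordinal = sample.int(4000L, n, replace = TRUE),
    is_case = runif(n) < config$obesity_fraction
  )

  ## ---- visits -------------------------------------------------------------
  set.seed(config$seed + 2L)
  vp <- config$visits_per_patient
  n_visits <- 2L + rnbinom(n, size = vp$dispersion, mu = max(vp$mean - 2, 0.1))
  total <- sum(n_visits)
  pid <- rep(patients$patient_id, n_visits)
  # entry age leaves room for follow-up before the age ceiling
  lo <- config$age_range_days[1]
  hi <- config$age_range_days[2]
  entry_age <- round(runif(n, lo, max(lo + 1, hi - 730)))
  gaps <- 1L + round(rgamma(total, shape = 1.2, scale = 100))
  cs <- cumsum(gaps)
  block_base <- rep(c(0, cs[cumsum(n_visits)])[seq_len(n)], n_visits)
  age_days <- rep(entry_age, n_visits) + (cs - block_base)
  care_setting <- sample(c("outpatient", "emergency", "inpatient", "telephone"),
                         total, replace = TRUE,
                         prob = c(0.85, 0.08, 0.02, 0.05))
  visits <- tibble(
    patient_id = pid,
    visit_id = seq_len(total),
    age_days = as.integer(age_days),
    care_setting = care_setting
  )

  # choose each case's threshold-crossing visit: any but the first, and force
  # it face-to-face (BMI is only measured in person)
  case_ids <- patients$patient_id[patients$is_case]
  cross_idx <- integer(0)
  if (length(case_ids) > 0) {
    per_case_n <- n_visits[patients$is_case]
    offset <- cumsum(c(0L, n_visits))[match(case_ids, patients$patient_id)]
    # uniform over 2..m (avoiding sample()'s scalar expansion)
    k <- 1L + vapply(per_case_n, function(m) sample.int(m - 1L, 1L),
                     integer(1))
    cross_idx <- offset + k
    visits$care_setting[cross_idx] <- sample(
      c("outpatient", "emergency", "inpatient"),
      length(cross_idx), replace = TRUE, prob = c(0.90, 0.087, 0.013))
  }
  visits$visit_ordinal <- rep(patients$birth_ordinal, n_visits) +
    visits$age_days
  visits <- select(visits, "patient_id", "visit_id", "visit_ordinal",
                   "age_days", "care_setting")

  ## ---- measurements (BMI z at face-to-face visits) ------------------------
  set.seed(config$seed + 3L)
  f2f <- visits$care_setting %in% c("outpatient", "emergency", "inpatient")
  is_case_row <- patients$is_case[match(visits$patient_id,
                                        patients$patient_id)]
  z <- numeric(total)

  # non-cases: fluctuate inside the healthy band
  base_z <- rnorm(n, mean = -0.2, sd = 0.55)
  z_noncase <- base_z[match(visits$patient_id, patients$patient_id)] +
    rnorm(total, 0, 0.15)
  z[!is_case_row] <- pmin(pmax(z_noncase[!is_case_row], -1.55), 0.95)

  # a slice of non-cases get one overweight (non-obese) value: they are
  # later barred from the control pool
  noncase_ids <- patients$patient_id[!patients$is_case]
  ow_ids <- noncase_ids[runif(length(noncase_ids)) <
                          config$overweight_noncase_fraction]
  if (length(ow_ids) > 0) {
    ow_rows <- vapply(ow_ids, function(id) {
      rows <- which(visits$patient_id == id & f2f)
      if (length(rows) == 0) NA_integer_ else rows[sample.int(length(rows), 1)]
    }, integer(1))
    ow_rows <- ow_rows[!is.na(ow_rows)]
    z[ow_rows] <- runif(length(ow_rows), 1.05, zthr - 0.01)
  }

  # cases: below threshold before the crossing, a drifting walk at/after it
  if (length(case_ids) > 0) {
    case_rows <- split(which(is_case_row), visits$patient_id[is_case_row])
    cross_of <- setNames(cross_idx, case_ids)
    for (id in as.character(case_ids)) {
      rows <- case_rows[[id]]
      kk <- cross_of[[id]]
      pre <- rows[rows < kk]
      post <- rows[rows >= kk]
      m_pre <- length(pre)
      if (m_pre > 0) {
        deficit <- seq(runif(1, 0.6, 1.6), runif(1, 0.05, 0.3),
                       length.out = m_pre) + rnorm(m_pre, 0, 0.08)
        z[pre] <- pmin(zthr - pmax(deficit, 0.01), zthr - 0.01)
      }
      walk <- cumsum(c(abs(rnorm(1, 0.25, 0.15)), rnorm(length(post) - 1,
                                                        0.02, 0.12)))
      z[post] <- zthr + walk
    }
  }

  measurements <- tibble(visit_id = visits$visit_id[f2f],
                         bmi_z = round(z[f2f], 4))

  ## ---- conditions ---------------------------------------------------------
  set.seed(config$seed + 4L)
  catalog <- config$condition_catalog
  prev <- config$baseline_prevalence
  # per-visit presence probabilities, then planted odds-ratio bumps at the
  # case visits occupying each timing class (crossing - 1, crossing, + 1)
  prob <- matrix(rep(prev, each = total), nrow = total,
                 dimnames = list(NULL, catalog))
  if (nrow(config$planted_effects) > 0 && length(cross_idx) > 0) {
    class_rows <- list(`1` = cross_idx - 1L, `2` = cross_idx,
                       `3` = cross_idx + 1L)
    # crossing+1 may fall into the next patient's block; keep in-patient rows
    class_rows[["3"]] <- class_rows[["3"]][
      class_rows[["3"]] <= total &
        visits$patient_id[pmin(class_rows[["3"]], total)] ==
          visits$patient_id[cross_idx]]
    for (i in seq_len(nrow(config$planted_effects))) {
      eff <- config$planted_effects[i, ]
      rows <- class_rows[[as.character(eff$timing_class)]]
      prob[rows, eff$condition] <- apply_odds_ratio(prev[[eff$condition]],
                                                    eff$odds_ratio)
    }
  }
  present <- matrix(runif(total * length(catalog)) < prob, nrow = total)
  colnames(present) <- catalog
  if (config$pair_dependence > 0 && length(catalog) >= 2) {
    copy <- runif(total) < config$pair_dependence
    present[copy, 2L] <- present[copy, 1L]
  }
  cond_idx <- which(present, arr.ind = TRUE)
  conditions <- tibble(
    visit_id = visits$visit_id[cond_idx[, 1]],
    condition_group = catalog[cond_idx[, 2]]
  )

  # occasional formal obesity diagnosis at the index visit
  if (length(cross_idx) > 0 && config$obesity_dx_prob > 0) {
    dx <- cross_idx[runif(length(cross_idx)) < config$obesity_dx_prob]
    if (length(dx) > 0) {
      conditions <- bind_rows(conditions,
                              tibble(visit_id = visits$visit_id[dx],
                                     condition_group = "Obesity"))
    }
  }
  conditions <- arrange(conditions, .data$visit_id, .data$condition_group)

  if (config$code_fanout) {
    map <- demo_condition_mapping()
    codes_of <- split(map$diagnosis_code, map$condition_group)
    grp <- conditions$condition_group
    pick <- vapply(grp, function(g) {
      cands <- codes_of[[g]]
      if (is.null(cands)) g else cands[sample.int(length(cands), 1)]
    }, character(1), USE.NAMES = FALSE)
    conditions$diagnosis_code <- pick
  } else {
    conditions$diagnosis_code <- conditions$condition_group
  }
  conditions <- select(conditions, "visit_id", "diagnosis_code")

  structure(
    list(patients = select(patients, "patient_id", "sex", "birth_ordinal",
                           "is_case"),
         visits = visits,
         measurements = measurements,
         conditions = conditions),
    class = "raw_ehr",
    config = config
  )
}

#' @export
print.raw_ehr <- function(x, ...) {
  cat("<raw_ehr>\n")
  cat(sprintf("  %d patients, %d visits, %d BMI measurements, %d diagnosis rows\n",
              nrow(x$patients), nrow(x$visits), nrow(x$measurements),
              nrow(x$conditions)))
  invisible(x)
}

#' Simulate matched-pair pattern presence directly
#'
#' Bypasses cohort construction and matching: draws independent Bernoulli
#' pattern presence for the case and control member of each matched pair.
#' Used to calibrate the McNemar machinery (type-I error, discordant-pair
#' odds ratios) against known presence probabilities.
#'
#' @param n_pairs Number of matched pairs.
#' @param pattern_probs Tibble with columns `pattern`, `p_case`, `p_control`.
#' @param seed Integer seed.
#' @return A tibble with one row per (pair, pattern): `pair_id`, `pattern`,
#'   `case_present`, `control_present`.
#' @export
simulate_paired_cohort <- function(n_pairs, pattern_probs, seed = 1L) {
  n_pairs <- check_count(n_pairs, "n_pairs")
  pattern_probs <- as_tibble(pattern_probs)
  check_columns(pattern_probs, c("pattern", "p_case", "p_control"),
                "pattern_probs")
  check_prob(pattern_probs$p_case, "p_case")
  check_prob(pattern_probs$p_control, "p_control")
  set.seed(seed)
  out <- tidyr::crossing(pair_id = seq_len(n_pairs),
                         pattern = pattern_probs$pattern) %>%
    left_join(pattern_probs, by = "pattern") %>%
    arrange(.data$pattern, .data$pair_id)
  out$case_present <- runif(nrow(out)) < out$p_case
  out$control_present <- runif(nrow(out)) < out$p_control
  select(out, "pair_id", "pattern", "case_present", "control_present")
}

#' Collapse paired presence draws into per-pattern 2x2 tables
#'
#' @param presence Output of [simulate_paired_cohort()].
#' @return A tibble with one row per pattern: `pattern`, `n11`, `n10`, `n01`,
#'   `n00`.
#' @export
paired_tables_from_presence <- function(presence) {
  check_columns(presence, c("pattern", "case_present", "control_present"),
                "presence")
  presence %>%
    group_by(.data$pattern) %>%
    summarise(n11 = sum(.data$case_present & .data$control_present),
              n10 = sum(.data$case_present & !.data$control_present),
              n01 = sum(!.data$case_present & .data$control_present),
              n00 = sum(!.data$case_present & !.data$control_present),
              .groups = "drop")
}

#' Write / read the raw EHR tables as CSV
#'
#' @param tables A `raw_ehr` list.
#' @param dir Directory to write into (created if needed).
#' @return `write_ehr_tables()` returns the paths invisibly;
#'   `read_ehr_tables()` returns a `raw_ehr` list.
#' @export
write_ehr_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(c("patients", "visits", "measurements",
                                   "conditions"), ".csv"))
  readr::write_csv(tables$patients, paths[1])
  readr::write_csv(tables$visits, paths[2])
  readr::write_csv(tables$measurements, paths[3])
  readr::write_csv(tables$conditions, paths[4])
  invisible(paths)
}

#' @rdname write_ehr_tables
#' @export
read_ehr_tables <- function(dir) {
  rd <- function(f, types) {
    readr::read_csv(file.path(dir, f), col_types = types, progress = FALSE)
  }
  structure(
    list(patients = rd("patients.csv", "icil"),
         visits = rd("visits.csv", "iiiic"),
         measurements = rd("measurements.csv", "id"),
         conditions = rd("conditions.csv", "ic")),
    class = "raw_ehr"
  )
}
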