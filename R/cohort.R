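# Index-visit phenotyping: find each case's first qualifying obese-BMI visit
# and assemble the pre-index / index / post-index timing-class itemsets.

#' Cohort configuration
#'
#' @param bmi_z_threshold Obesity threshold on the BMI z-score scale; the
#'   default 1.6449 is the 95th percentile of a standard normal.
#' @param index_age_range_days Allowed age at the index visit, in days
#'   (default 730-6935, about 2-18 years).
#' @param index_window (start, end) visit ordinals within which the index
#'   visit must fall; unbounded by default (synthetic data carry no
#'   meaningful calendar).
#' @param flank_window (start, end) ordinals within which pre-/post-index
#'   visits must fall; unbounded by default.
#' @param face_to_face_settings Care-setting labels counting as face-to-face
#'   encounters; only these can host an index visit.
#' @param plausibility_bounds (min, max) biologically plausible BMI z-scores;
#'   values outside are dropped during cleaning. A configurable band stands
#'   in for registry-specific implausibility cut-offs.
#' @param prior_visit_rule How the required visit before the index visit is
#'   interpreted: `"non_obese_or_no_bmi"` (default) accepts any prior visit
#'   without an obese BMI record, including visits with no BMI at all;
#'   `"recorded_non_obese"` additionally demands a recorded non-obese BMI at
#'   some prior visit.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(bmi_z_threshold = 1.6449,
                          index_age_range_days = c(730L, 6935L),
                          index_window = c(-Inf, Inf),
                          flank_window = c(-Inf, Inf),
                          face_to_face_settings = c("outpatient", "emergency",
                                                    "inpatient"),
                          plausibility_bounds = c(-5, 8),
                          prior_visit_rule = c("non_obese_or_no_bmi",
                                               "recorded_non_obese")) {
  prior_visit_rule <- match.arg(prior_visit_rule)
  if (bmi_z_threshold <= 0) abort("`bmi_z_threshold` must be positive.")
  for (w in list(index_age_range_days, index_window, flank_window,
                 plausibility_bounds)) {
    if (length(w) != 2L || w[1] >= w[2]) {
      abort("Windows and bounds must be (lo, hi) pairs with lo < hi.")
    }
  }
  structure(list(bmi_z_threshold = bmi_z_threshold,
                 index_age_range_days = index_age_range_days,
                 index_window = index_window,
                 flank_window = flank_window,
                 face_to_face_settings = face_to_face_settings,
                 plausibility_bounds = plausibility_bounds,
                 prior_visit_rule = prior_visit_rule),
            class = "cohort_config")
}

#' Clean BMI z-score measurements
#'
#' Drops measurements that cannot be linked to a visit, removes missing and
#' biologically implausible values, and resolves duplicates so that a single
#' BMI z-score remains per patient-date: when several values share a date the
#' most recently recorded row (last in input order) wins.
#'
#' @param measurements Tibble (`visit_id`, `bmi_z`), in recording order.
#' @param visits Visits table (`patient_id`, `visit_id`, `visit_ordinal`).
#' @param plausibility_bounds (min, max) plausible z-scores.
#' @return A tibble (`visit_id`, `bmi_z`) with one row per patient-date.
#'   Attribute `n_dropped` reports rows removed as
#'   (unlinked, implausible, duplicate).
#' @export
clean_measurements <- function(measurements, visits,
                               plausibility_bounds = c(-5, 8)) {
  check_columns(measurements, c("visit_id", "bmi_z"), "measurements")
  check_columns(visits, c("patient_id", "visit_id", "visit_ordinal"),
                "visits")
  n_in <- nrow(measurements)
  m <- measurements %>%
    mutate(.rec = row_number()) %>%
    left_join(select(visits, "visit_id", "patient_id", "visit_ordinal"),
              by = "visit_id")
  unlinked <- sum(is.na(m$patient_id))
  if (unlinked > 0) {
    warn(sprintf("%d measurement row(s) reference unknown visits; dropped.",
                 unlinked))
  }
  m <- filter(m, !is.na(.data$patient_id))
  ok <- !is.na(m$bmi_z) & m$bmi_z >= plausibility_bounds[1] &
    m$bmi_z <= plausibility_bounds[2]
  implausible <- sum(!ok)
  m <- m[ok, ]
  # keep the most recently recorded row per patient-date
  o <- order(m$patient_id, m$visit_ordinal, m$.rec, method = "radix")
  m2 <- m[o, ]
  keep <- !duplicated(paste(m2$patient_id, m2$visit_ordinal),
                      fromLast = TRUE)
  out <- m2[keep, ]
  dups <- nrow(m) - nrow(out)
  out <- out[order(out$.rec), c("visit_id", "bmi_z")]
  attr(out, "n_dropped") <- c(unlinked = unlinked, implausible = implausible,
                              duplicate = dups)
  out
}

# strict "before" on (visit_ordinal, visit_id); same-day ties resolved by
# lower visit_id
is_before <- function(ord_a, id_a, ord_b, id_b) {
  ord_a < ord_b | (ord_a == ord_b & id_a < id_b)
}

#' Identify index visits and case triplets
#'
#' The index visit is a patient's chronologically first visit satisfying the
#' full index predicate: cleaned, plausible BMI z-score at or above the
#' obesity threshold; face-to-face care setting; within the index window;
#' patient age within range; and at least one recorded clinical condition.
#' Patients are excluded when no visit qualifies, when no visit precedes the
#' index visit (under the configured prior-visit rule), or when no preceding
#' visit inside the flank window carries a clinical condition to serve as
#' the pre-index visit. The post-index visit (nearest later condition-bearing
#' visit in the flank window) is optional.
#'
#' @param tables A `raw_ehr` list (or any list with the same four tables).
#' @param config A [cohort_config()].
#' @param cleaned Optional pre-cleaned measurements (from
#'   [clean_measurements()]); cleaned internally when `NULL`.
#' @return A tibble of case triplets: `patient_id`, `sex`, `index_visit_id`,
#'   `index_age_days`, `index_ordinal`, `pre_visit_id`, `post_visit_id`
#'   (`NA` when absent), `prior_visit_count` (prior visits carrying at least
#'   one condition). Attribute `exclusions`: named counts per exclusion
#'   reason, summing to patients-in minus cases-out.
#' @export
find_index_visits <- function(tables, config = cohort_config(),
                              cleaned = NULL) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created by cohort_config().")
  }
  visits <- check_columns(tables$visits,
                          c("patient_id", "visit_id", "visit_ordinal",
                            "age_days", "care_setting"), "visits")
  if (is.null(cleaned)) {
    cleaned <- clean_measurements(tables$measurements, visits,
                                  config$plausibility_bounds)
  }
  conditions <- tables$conditions
  cond_col <- if ("condition_group" %in% names(conditions))
    "condition_group" else "diagnosis_code"
  has_cond_ids <- unique(conditions$visit_id[!is.na(conditions[[cond_col]])])

  v <- visits %>%
    left_join(cleaned, by = "visit_id") %>%
    mutate(has_cond = .data$visit_id %in% has_cond_ids)

  qualifies <- !is.na(v$bmi_z) & v$bmi_z >= config$bmi_z_threshold &
    v$care_setting %in% config$face_to_face_settings &
    v$visit_ordinal >= config$index_window[1] &
    v$visit_ordinal <= config$index_window[2] &
    v$age_days >= config$index_age_range_days[1] &
    v$age_days <= config$index_age_range_days[2] &
    v$has_cond

  q <- v[qualifies, ]
  q <- q[order(q$patient_id, q$visit_ordinal, q$visit_id,
               method = "radix"), ]
  idx <- q[!duplicated(q$patient_id), ] %>%
    select("patient_id", index_visit_id = "visit_id",
           index_ordinal = "visit_ordinal", index_age_days = "age_days")

  n_patients <- n_distinct(tables$patients$patient_id)
  excl <- c(no_qualifying_index_visit = n_patients - nrow(idx))

  # all visits of candidate cases, flagged relative to their index visit
  va <- v %>%
    inner_join(idx, by = "patient_id") %>%
    mutate(before = is_before(.data$visit_ordinal, .data$visit_id,
                              .data$index_ordinal, .data$index_visit_id),
           after = is_before(.data$index_ordinal, .data$index_visit_id,
                             .data$visit_ordinal, .data$visit_id),
           in_flank = .data$visit_ordinal >= config$flank_window[1] &
             .data$visit_ordinal <= config$flank_window[2])

  rule_ok_row <- if (config$prior_visit_rule == "recorded_non_obese") {
    va$before & !is.na(va$bmi_z) & va$bmi_z < config$bmi_z_threshold
  } else {
    va$before & (is.na(va$bmi_z) | va$bmi_z < config$bmi_z_threshold)
  }
  agg <- rowsum(cbind(prior = as.numeric(va$before),
                      rule = as.numeric(rule_ok_row)),
                va$patient_id)
  prior_ok <- tibble(patient_id = as.integer(rownames(agg)),
                     has_prior = agg[, "prior"] > 0,
                     has_prior_rule = agg[, "rule"] > 0)

  excl <- c(excl, no_prior_visit = sum(!prior_ok$has_prior))
  excl <- c(excl, prior_visit_rule = sum(prior_ok$has_prior &
                                           !prior_ok$has_prior_rule))
  keep1 <- prior_ok$patient_id[prior_ok$has_prior & prior_ok$has_prior_rule]
  va <- filter(va, .data$patient_id %in% keep1)

  pr <- va[va$before & va$has_cond & va$in_flank, ]
  pr <- pr[order(pr$patient_id, pr$visit_ordinal, pr$visit_id,
                 method = "radix"), ]
  pre <- pr[!duplicated(pr$patient_id, fromLast = TRUE), ] %>%
    select("patient_id", pre_visit_id = "visit_id")

  excl <- c(excl,
            no_preindex_conditions = length(keep1) - nrow(pre))

  po <- va[va$after & va$has_cond & va$in_flank, ]
  po <- po[order(po$patient_id, po$visit_ordinal, po$visit_id,
                 method = "radix"), ]
  post <- po[!duplicated(po$patient_id), ] %>%
    select("patient_id", post_visit_id = "visit_id")

  pvc_agg <- rowsum(as.numeric(va$before & va$has_cond), va$patient_id)
  pvc <- tibble(patient_id = as.integer(rownames(pvc_agg)),
                prior_visit_count = as.integer(pvc_agg[, 1]))

  out <- idx %>%
    inner_join(pre, by = "patient_id") %>%
    left_join(post, by = "patient_id") %>%
    left_join(pvc, by = "patient_id") %>%
    left_join(select(tables$patients, "patient_id", "sex"),
              by = "patient_id") %>%
    select("patient_id", "sex", "index_visit_id", "index_ordinal",
           "index_age_days", "pre_visit_id", "post_visit_id",
           "prior_visit_count") %>%
    arrange(.data$patient_id)
  attr(out, "exclusions") <- excl
  out
}

#' Exclusion tallies from cohort construction
#'
#' @param triplets Output of [find_index_visits()].
#' @return Named integer vector of per-criterion exclusion counts.
#' @export
cohort_exclusions <- function(triplets) {
  attr(triplets, "exclusions")
}

#' Build per-subject timing-class event sequences
#'
#' Reduces each case triplet to its event sequence: timing class 1 holds the
#' condition groups of the pre-index visit, class 2 the index visit, class 3
#' the post-index visit when one exists. Duplicate groups within a visit
#' collapse (itemsets are sets). Triplets referencing a pre-index or index
#' visit with no mapped condition group are excluded with a warning — every
#' included visit must carry a clinical finding.
#'
#' @param triplets Case triplets from [find_index_visits()] (or control
#'   triplets in the same shape).
#' @param grouped_conditions Tibble (`visit_id`, `condition_group`) from
#'   [map_conditions()].
#' @return An event table (`sid`, `timing_class`, `condition`), sid =
#'   patient id. Attribute `n_excluded` counts dropped triplets.
#' @export
build_event_sequences <- function(triplets, grouped_conditions) {
  check_columns(triplets, c("patient_id", "pre_visit_id", "index_visit_id",
                            "post_visit_id"), "triplets")
  check_columns(grouped_conditions, c("visit_id", "condition_group"),
                "grouped_conditions")
  long <- triplets %>%
    select("patient_id", `1` = "pre_visit_id", `2` = "index_visit_id",
           `3` = "post_visit_id") %>%
    tidyr::pivot_longer(cols = c("1", "2", "3"),
                        names_to = "timing_class", values_to = "visit_id") %>%
    mutate(timing_class = as.integer(.data$timing_class)) %>%
    filter(!is.na(.data$visit_id)) %>%
    inner_join(distinct(grouped_conditions, .data$visit_id,
                        .data$condition_group),
               by = "visit_id")
  have_core <- long %>%
    group_by(.data$patient_id) %>%
    summarise(ok = all(c(1L, 2L) %in% .data$timing_class), .groups = "drop")
  bad <- have_core$patient_id[!have_core$ok]
  bad <- union(bad, setdiff(triplets$patient_id, have_core$patient_id))
  if (length(bad) > 0) {
    warn(sprintf(
      "%d triplet(s) referenced a conditionless pre-index or index visit; excluded.",
      length(bad)))
  }
  out <- long %>%
    filter(!.data$patient_id %in% bad) %>%
    select(sid = "patient_id", "timing_class", condition = "condition_group") %>%
    arrange(.data$sid, .data$timing_class, .data$condition)
  attr(out, "n_excluded") <- length(bad)
  out
}
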