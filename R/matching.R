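# Greedy caliper matching of never-unhealthy-BMI control visits to cases,
# on sex, prior healthcare utilization and age.

#' Build the control candidate pool
#'
#' A candidate is one visit of a patient who (i) has at least one healthy
#' BMI measurement (5th-84th percentile band on the z scale) inside the
#' index window, (ii) has no unhealthy BMI record anywhere, and (iii) has at
#' least two documented visits. Candidate visits must carry at least one
#' clinical condition (they stand in for an index visit) and lie within 180
#' days of the age span of the cases. Each candidate carries its
#' prior-visit count: earlier visits with at least one recorded condition, a
#' proxy for healthcare utilization.
#'
#' @param tables A `raw_ehr` list.
#' @param cases Case triplets from [find_index_visits()] (their index ages
#'   bound the pool's age trim).
#' @param config A [cohort_config()]; supplies the index window and, via the
#'   obesity threshold, nothing else — the healthy band is given separately.
#' @param healthy_band (lo, hi) BMI z-score band counting as healthy;
#'   defaults to the 5th-84th percentiles (-1.6449, 0.9945). Any measurement
#'   outside the band is an unhealthy record.
#' @param age_trim_days Candidates older/younger than every case by more
#'   than this are excluded (default 180).
#' @param cleaned Optional pre-cleaned measurements.
#' @return A tibble of candidates: `patient_id`, `visit_id`, `sex`,
#'   `age_days`, `prior_visit_count`.
#' @export
build_control_pool <- function(tables, cases, config = cohort_config(),
                               healthy_band = c(-1.6449, 0.9945),
                               age_trim_days = 180L, cleaned = NULL) {
  visits <- check_columns(tables$visits,
                          c("patient_id", "visit_id", "visit_ordinal",
                            "age_days"), "visits")
  if (is.null(cleaned)) {
    cleaned <- clean_measurements(tables$measurements, visits,
                                  config$plausibility_bounds)
  }
  m <- cleaned %>%
    inner_join(select(visits, "visit_id", "patient_id", "visit_ordinal"),
               by = "visit_id")
  healthy <- m$bmi_z >= healthy_band[1] & m$bmi_z <= healthy_band[2]
  in_window <- m$visit_ordinal >= config$index_window[1] &
    m$visit_ordinal <= config$index_window[2]
  agg <- rowsum(cbind(ok = as.numeric(healthy & in_window),
                      bad = as.numeric(!healthy)), m$patient_id)
  eligible <- as.integer(rownames(agg))[agg[, "ok"] > 0 & agg[, "bad"] == 0]

  n_visits <- visits %>% count(.data$patient_id, name = "n_visits")
  multi <- n_visits$patient_id[n_visits$n_visits >= 2L]
  eligible <- intersect(eligible, multi)
  eligible <- setdiff(eligible, cases$patient_id)

  conditions <- tables$conditions
  cond_col <- if ("condition_group" %in% names(conditions))
    "condition_group" else "diagnosis_code"
  has_cond_ids <- unique(conditions$visit_id[!is.na(conditions[[cond_col]])])

  cv <- visits[visits$patient_id %in% eligible, ]
  cv <- cv[order(cv$patient_id, cv$visit_ordinal, cv$visit_id,
                 method = "radix"), ]
  cv$has_cond <- cv$visit_id %in% has_cond_ids
  # running count of earlier condition-bearing visits, reset per patient
  pre_cum <- cumsum(cv$has_cond) - cv$has_cond
  start <- !duplicated(cv$patient_id)
  cv$prior_visit_count <- pre_cum - pre_cum[start][cumsum(start)]

  age_lo <- min(cases$index_age_days) - age_trim_days
  age_hi <- max(cases$index_age_days) + age_trim_days

  cv %>%
    filter(.data$has_cond,
           .data$age_days >= age_lo, .data$age_days <= age_hi) %>%
    left_join(select(tables$patients, "patient_id", "sex"),
              by = "patient_id") %>%
    select("patient_id", "visit_id", "sex", "age_days",
           "prior_visit_count")
}

#' Greedy caliper matching of controls to cases
#'
#' Cases are processed youngest-first (ties by patient id). Each case is
#' matched to the same-sex candidate visit within the age caliper that
#' minimizes a normalized distance over age and prior-visit count:
#' `|age diff| / caliper + |prior-visit diff| / (1 + prior-visit spread)`,
#' with ties broken by smaller absolute age difference, then lower control
#' patient id, then lower visit id. Matching is without replacement: once a
#' control patient is used, all of their candidate visits leave the pool.
#' Unmatched cases are reported, not silently dropped.
#'
#' @param cases Case triplets (need `patient_id`, `sex`, `index_age_days`,
#'   `prior_visit_count`).
#' @param pool Candidate pool from [build_control_pool()].
#' @param caliper_days Maximum |age difference| in days (default 60).
#' @return A tibble of matched pairs: `case_id`, `control_patient_id`,
#'   `control_visit_id`, `age_diff_days` (control minus case, signed),
#'   `prior_visit_diff` (signed). Attribute `unmatched`: case ids with no
#'   admissible candidate.
#' @export
greedy_match <- function(cases, pool, caliper_days = 60L) {
  check_columns(cases, c("patient_id", "sex", "index_age_days",
                         "prior_visit_count"), "cases")
  check_columns(pool, c("patient_id", "visit_id", "sex", "age_days",
                        "prior_visit_count"), "pool")
  if (nrow(pool) == 0) abort("Control pool is empty.")
  pvc_spread <- diff(range(pool$prior_visit_count))

  ord <- order(cases$index_age_days, cases$patient_id, method = "radix")
  cases <- cases[ord, ]

  # per-sex pools sorted by candidate age for O(log n) caliper windows;
  # control patients coded 1..K so without-replacement removal is a vector op
  upid <- unique(pool$patient_id)
  pcode_all <- match(pool$patient_id, upid)
  pools <- lapply(split(seq_len(nrow(pool)), pool$sex), function(rows) {
    o <- rows[order(pool$age_days[rows], pool$patient_id[rows],
                    pool$visit_id[rows], method = "radix")]
    list(age = pool$age_days[o], pid = pool$patient_id[o],
         vid = pool$visit_id[o], pvc = pool$prior_visit_count[o],
         pcode = pcode_all[o])
  })
  used <- logical(length(upid))

  match_one <- function(sex, age, pvc) {
    p <- pools[[sex]]
    if (is.null(p)) return(NULL)
    lo <- findInterval(age - caliper_days - 0.5, p$age) + 1L
    hi <- findInterval(age + caliper_days + 0.5, p$age)
    if (lo > hi) return(NULL)
    win <- lo:hi
    win <- win[!used[p$pcode[win]]]
    if (length(win) == 0) return(NULL)
    age_diff <- abs(p$age[win] - age)
    dist <- age_diff / caliper_days +
      abs(p$pvc[win] - pvc) / (1 + pvc_spread)
    best <- win[order(dist, age_diff, p$pid[win], p$vid[win],
                      method = "radix")[1]]
    list(patient_id = p$pid[best], visit_id = p$vid[best],
         age_days = p$age[best], prior_visit_count = p$pvc[best],
         pcode = p$pcode[best])
  }

  n_cases <- nrow(cases)
  case_pid <- cases$patient_id
  case_sex <- cases$sex
  case_age <- cases$index_age_days
  case_pvc <- cases$prior_visit_count
  out_case <- out_ctrl <- out_visit <- rep(NA_integer_, n_cases)
  out_aged <- out_pvd <- rep(NA_real_, n_cases)
  unmatched <- integer(0)
  for (i in seq_len(n_cases)) {
    hit <- match_one(case_sex[i], case_age[i], case_pvc[i])
    if (is.null(hit)) {
      unmatched <- c(unmatched, case_pid[i])
      next
    }
    used[hit$pcode] <- TRUE
    out_case[i] <- case_pid[i]
    out_ctrl[i] <- hit$patient_id
    out_visit[i] <- hit$visit_id
    out_aged[i] <- hit$age_days - case_age[i]
    out_pvd[i] <- hit$prior_visit_count - case_pvc[i]
  }
  ok <- !is.na(out_case)
  out <- tibble(case_id = out_case[ok],
                control_patient_id = out_ctrl[ok],
                control_visit_id = out_visit[ok],
                age_diff_days = out_aged[ok],
                prior_visit_diff = out_pvd[ok])
  if (length(unmatched) > 0) {
    warn(sprintf("%d case(s) could not be matched within the caliper.",
                 length(unmatched)))
  }
  attr(out, "unmatched") <- unmatched
  out
}

#' Matching-quality summary
#'
#' @param pairs Output of [greedy_match()].
#' @return A one-row tibble with pair counts and the mean, SD and median of
#'   the absolute age and prior-visit differences.
#' @export
matching_summary <- function(pairs) {
  tibble(
    n_pairs = nrow(pairs),
    n_unmatched = length(attr(pairs, "unmatched") %||% integer(0)),
    mean_abs_age_diff = mean(abs(pairs$age_diff_days)),
    sd_age_diff = stats::sd(pairs$age_diff_days),
    median_abs_age_diff = median(abs(pairs$age_diff_days)),
    mean_abs_visit_diff = mean(abs(pairs$prior_visit_diff)),
    median_abs_visit_diff = median(abs(pairs$prior_visit_diff))
  )
}

#' Extract control event sequences
#'
#' For each matched control, timing class 2 is the matching visit's
#' condition-group itemset, class 1 the nearest earlier condition-bearing
#' visit, and class 3 the nearest later condition-bearing visit when one
#' exists. Pairs whose control lacks a condition-bearing visit before the
#' matching visit (or whose matching visit lost all conditions in mapping)
#' are rejected with a warning.
#'
#' @param pairs Matched pairs from [greedy_match()].
#' @param tables A `raw_ehr` list.
#' @param grouped_conditions Tibble (`visit_id`, `condition_group`).
#' @return An event table (`sid` = control patient id, `timing_class`,
#'   `condition`). Attributes: `pairs` — the retained pairs; `n_rejected`.
#' @export
extract_control_sequences <- function(pairs, tables, grouped_conditions) {
  check_columns(pairs, c("case_id", "control_patient_id",
                         "control_visit_id"), "pairs")
  visits <- tables$visits
  gc <- distinct(grouped_conditions, .data$visit_id, .data$condition_group)
  cond_ids <- unique(gc$visit_id)

  cv <- visits %>%
    filter(.data$patient_id %in% pairs$control_patient_id) %>%
    mutate(has_cond = .data$visit_id %in% cond_ids)
  anchor <- pairs %>%
    inner_join(select(visits, control_visit_id = "visit_id",
                      anchor_ordinal = "visit_ordinal"),
               by = "control_visit_id")

  flank <- cv %>%
    filter(.data$has_cond) %>%
    inner_join(select(anchor, patient_id = "control_patient_id",
                      "control_visit_id", "anchor_ordinal"),
               by = "patient_id")
  pre <- flank %>%
    filter(is_before(.data$visit_ordinal, .data$visit_id,
                     .data$anchor_ordinal, .data$control_visit_id)) %>%
    group_by(.data$patient_id) %>%
    arrange(.data$visit_ordinal, .data$visit_id, .by_group = TRUE) %>%
    slice(n()) %>%
    ungroup() %>%
    select("patient_id", pre_visit_id = "visit_id")
  post <- flank %>%
    filter(is_before(.data$anchor_ordinal, .data$control_visit_id,
                     .data$visit_ordinal, .data$visit_id)) %>%
    group_by(.data$patient_id) %>%
    arrange(.data$visit_ordinal, .data$visit_id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select("patient_id", post_visit_id = "visit_id")

  triplets <- pairs %>%
    select(patient_id = "control_patient_id",
           index_visit_id = "control_visit_id") %>%
    left_join(pre, by = "patient_id") %>%
    left_join(post, by = "patient_id")

  ok <- !is.na(triplets$pre_visit_id) &
    triplets$index_visit_id %in% cond_ids
  if (any(!ok)) {
    warn(sprintf(
      "%d matched pair(s) rejected: control lacks a condition-bearing visit before the matching visit.",
      sum(!ok)))
  }
  seqs <- suppressWarnings(
    build_event_sequences(triplets[ok, ], gc))
  kept <- pairs[pairs$control_patient_id %in% unique(seqs$sid), ]
  attr(seqs, "pairs") <- kept
  attr(seqs, "n_rejected") <- nrow(pairs) - nrow(kept)
  seqs
}
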