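fake_cases <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(patient_id = seq_len(n),
                 sex = sample(c("M", "F"), n, replace = TRUE),
                 index_age_days = sample(1000:4000, n, replace = TRUE),
                 prior_visit_count = rpois(n, 3))
}

fake_pool <- function(n, seed = 2, id0 = 10000L) {
  set.seed(seed)
  tibble::tibble(patient_id = id0 + sample.int(ceiling(n / 2), n,
                                               replace = TRUE),
                 visit_id = seq_len(n),
                 sex = sample(c("M", "F"), n, replace = TRUE),
                 age_days = sample(900:4100, n, replace = TRUE),
                 prior_visit_count = rpois(n, 3))
}

test_that("control pool applies every eligibility filter", {
  pats <- data.frame(patient_id = 1:5, sex = "F", birth_ordinal = 0,
                     is_case = FALSE)
  visits <- data.frame(patient_id = rep(1:5, each = 2),
                       visit_id = 1:10,
                       visit_ordinal = rep(c(10, 20), 5),
                       age_days = rep(c(1500, 1600), 5),
                       care_setting = "outpatient")
  # p1 healthy twice; p2 has one obese value; p3 underweight (unhealthy
  # low); p4 healthy; p5 healthy but will lose a visit below
  meas <- data.frame(visit_id = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                     bmi_z = c(0.1, 0.2, 0.1, 2.0, -1.8, 0.0, 0.3, 0.4,
                               0.2, 0.1))
  conds <- data.frame(visit_id = c(1:8, 9:10),
                      condition_group = "Fever")
  # single-visit patient: drop p5's second visit
  visits <- visits[visits$visit_id != 10, ]
  meas <- meas[meas$visit_id != 10, ]
  conds <- conds[conds$visit_id != 10, ]
  cases <- tibble::tibble(patient_id = 99L, index_age_days = 1550)
  pool <- build_control_pool(make_tables(pats, visits, meas, conds), cases)
  # p2 (obese record) and p3 (unhealthy-low record) and p5 (one visit) out
  expect_setequal(unique(pool$patient_id), c(1, 4))
  # prior-visit counts count earlier condition-bearing visits
  expect_equal(pool$prior_visit_count[pool$visit_id == 2], 1)
  expect_equal(pool$prior_visit_count[pool$visit_id == 1], 0)
})

test_that("control pool equals a brute-force predicate recount", {
  tab <- simulate_ehr(sim_config(n_patients = 400, seed = 17))
  tab$conditions$condition_group <- tab$conditions$diagnosis_code
  tri <- find_index_visits(tab)
  pool <- build_control_pool(tab, tri)

  cleaned <- clean_measurements(tab$measurements, tab$visits)
  m <- merge(cleaned, tab$visits, by = "visit_id")
  lo <- min(tri$index_age_days) - 180
  hi <- max(tri$index_age_days) + 180
  expected <- NULL
  for (pid in setdiff(tab$patients$patient_id, tri$patient_id)) {
    zz <- m$bmi_z[m$patient_id == pid]
    healthy <- zz >= -1.6449 & zz <= 0.9945
    vv <- tab$visits[tab$visits$patient_id == pid, ]
    if (length(zz) == 0 || any(!healthy) || !any(healthy) || nrow(vv) < 2) {
      next
    }
    vv <- vv[order(vv$visit_ordinal, vv$visit_id), ]
    has_cond <- vv$visit_id %in% tab$conditions$visit_id
    pvc <- cumsum(has_cond) - has_cond
    keep <- has_cond & vv$age_days >= lo & vv$age_days <= hi
    if (any(keep)) {
      expected <- rbind(expected,
                        data.frame(patient_id = pid,
                                   visit_id = vv$visit_id[keep],
                                   prior_visit_count = pvc[keep]))
    }
  }
  got <- as.data.frame(pool[order(pool$visit_id),
                            c("patient_id", "visit_id",
                              "prior_visit_count")])
  expected <- expected[order(expected$visit_id), ]
  rownames(got) <- rownames(expected) <- NULL
  expect_equal(got, expected)
})

test_that("greedy matching honors caliper, sex and uniqueness", {
  cases <- tibble::tibble(patient_id = 1L, sex = "F",
                          index_age_days = 2000, prior_visit_count = 2)
  pool <- tibble::tibble(patient_id = 100L, visit_id = 1L, sex = "F",
                         age_days = 2010, prior_visit_count = 3)
  pairs <- greedy_match(cases, pool)
  expect_equal(pairs$control_patient_id, 100L)
  expect_equal(pairs$age_diff_days, 10)

  # only candidate is 61 days away: unmatched, reported
  pool61 <- dplyr::mutate(pool, age_days = 2061)
  expect_warning(p2 <- greedy_match(cases, pool61), "could not be matched")
  expect_equal(nrow(p2), 0)
  expect_equal(attr(p2, "unmatched"), 1L)

  # wrong sex never matches even inside the caliper
  poolM <- dplyr::mutate(pool, sex = "M")
  expect_warning(p3 <- greedy_match(cases, poolM), "could not be matched")
  expect_equal(nrow(p3), 0)
})

test_that("greedy matching replays an independent step-by-step oracle", {
  cases <- fake_cases(200, seed = 5)
  pool <- fake_pool(1000, seed = 6)
  pairs <- suppressWarnings(greedy_match(cases, pool))
  oracle <- reference_greedy(as.data.frame(cases), as.data.frame(pool))
  got <- as.data.frame(pairs[order(pairs$case_id),
                             c("case_id", "control_patient_id",
                               "control_visit_id")])
  oracle <- oracle[order(oracle$case_id), ]
  rownames(got) <- rownames(oracle) <- NULL
  expect_equal(got, oracle, ignore_attr = TRUE)

  # invariants on the emitted pairs
  expect_true(all(abs(pairs$age_diff_days) <= 60))
  expect_false(any(duplicated(pairs$control_patient_id)))
  sex_case <- cases$sex[match(pairs$case_id, cases$patient_id)]
  sex_ctrl <- pool$sex[match(pairs$control_visit_id, pool$visit_id)]
  expect_equal(sex_case, sex_ctrl)

  # determinism: identical rerun
  expect_identical(pairs, suppressWarnings(greedy_match(cases, pool)))
})

test_that("control sequences pick nearest flanking condition visits", {
  visits <- data.frame(patient_id = rep(c(50L, 60L), c(4, 2)),
                       visit_id = 1:6,
                       visit_ordinal = c(10, 20, 30, 40, 10, 20),
                       age_days = c(1000, 1010, 1020, 1030, 2000, 2010),
                       care_setting = "outpatient")
  gc <- data.frame(visit_id = c(1L, 2L, 3L, 4L, 5L, 6L),
                   condition_group = c("Fever", "Asthma", "Fever", "Cough",
                                       "Fever", "Asthma"))
  pairs <- tibble::tibble(case_id = c(1L, 2L),
                          control_patient_id = c(50L, 60L),
                          control_visit_id = c(3L, 6L))
  tab <- make_tables(data.frame(patient_id = c(50L, 60L), sex = "F",
                                birth_ordinal = 0, is_case = FALSE),
                     visits)
  seqs <- extract_control_sequences(pairs, tab, gc)
  s50 <- seqs[seqs$sid == 50, ]
  expect_setequal(unique(s50$timing_class), c(1, 2, 3))
  expect_equal(s50$condition[s50$timing_class == 1], "Asthma")  # nearest
  expect_equal(s50$condition[s50$timing_class == 3], "Cough")
  s60 <- seqs[seqs$sid == 60, ]  # no later visit: classes 1-2 only
  expect_setequal(unique(s60$timing_class), c(1, 2))
  expect_equal(nrow(attr(seqs, "pairs")), 2)
})

test_that("pairs whose control lacks a prior condition visit are rejected", {
  visits <- data.frame(patient_id = 70L, visit_id = 1:2,
                       visit_ordinal = c(10, 20),
                       age_days = c(1000, 1010), care_setting = "outpatient")
  gc <- data.frame(visit_id = 2L, condition_group = "Fever")
  pairs <- tibble::tibble(case_id = 1L, control_patient_id = 70L,
                          control_visit_id = 2L)
  tab <- make_tables(data.frame(patient_id = 70L, sex = "F",
                                birth_ordinal = 0, is_case = FALSE), visits)
  expect_warning(seqs <- extract_control_sequences(pairs, tab, gc),
                 "rejected")
  expect_equal(nrow(seqs), 0)
  expect_equal(attr(seqs, "n_rejected"), 1)
})
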