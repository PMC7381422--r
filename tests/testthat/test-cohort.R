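# Fixtures are built in code: small hand-rolled visit tables exercising each
# inclusion rule, plus randomized recount oracles.

basic_visits <- function(pid, ords, ages = NULL, setting = "outpatient",
                         id0 = 0L) {
  n <- length(ords)
  data.frame(patient_id = pid, visit_id = id0 + seq_len(n),
             visit_ordinal = ords,
             age_days = if (is.null(ages)) 1000 + ords else ages,
             care_setting = rep_len(setting, n))
}

test_that("measurement cleaning dedups per date, keeping the latest record", {
  visits <- basic_visits(1, c(10, 20))
  # two identical values on one date, then a same-date revision at visit 2
  meas <- data.frame(visit_id = c(1L, 1L, 2L, 2L),
                     bmi_z = c(0.5, 0.5, 1.0, 1.2))
  out <- clean_measurements(meas, visits)
  expect_equal(nrow(out), 2)
  expect_equal(out$bmi_z[out$visit_id == 1], 0.5)
  expect_equal(out$bmi_z[out$visit_id == 2], 1.2)  # most recent wins

  # implausible and unlinked rows are dropped, with a warning for unlinked
  meas2 <- data.frame(visit_id = c(1L, 1L, 99L), bmi_z = c(0.2, -7, 0.3))
  expect_warning(out2 <- clean_measurements(meas2, visits), "unknown visits")
  expect_equal(out2$bmi_z, 0.2)
  expect_equal(attr(out2, "n_dropped")[["implausible"]], 1L)

  # empty in, empty out
  empty <- clean_measurements(data.frame(visit_id = integer(),
                                         bmi_z = double()), visits)
  expect_equal(nrow(empty), 0)
})

test_that("cleaning matches a brute-force filter-then-dedup recount", {
  set.seed(99)
  n_pat <- 40
  visits <- do.call(rbind, lapply(seq_len(n_pat), function(p) {
    basic_visits(p, sort(sample(1:400, 8)), id0 = (p - 1L) * 8L)
  }))
  rows <- visits[sample(nrow(visits), 1000, replace = TRUE), "visit_id",
                 drop = FALSE]
  rows$bmi_z <- round(rnorm(1000, 0, 1.5), 2)
  implaus <- sample(1000, 50)
  rows$bmi_z[implaus] <- sample(c(-9, 12), 50, replace = TRUE)
  out <- clean_measurements(rows, visits)

  # oracle: drop implausible, then per patient-date keep last row
  ok <- rows$bmi_z >= -5 & rows$bmi_z <= 8
  surv <- rows[ok, ]
  surv$patient_id <- visits$patient_id[match(surv$visit_id, visits$visit_id)]
  surv$ord <- visits$visit_ordinal[match(surv$visit_id, visits$visit_id)]
  n_expected <- length(unique(paste(surv$patient_id, surv$ord)))
  expect_equal(nrow(out), n_expected)
})

test_that("index predicate: first qualifying visit, prior visit required", {
  pats <- data.frame(patient_id = 1:4, sex = "F", birth_ordinal = 0,
                     is_case = TRUE)
  visits <- rbind(
    # p1: obese at very first visit ever -> excluded (no prior visit)
    basic_visits(1, c(10, 50), id0 = 0L),
    # p2: no-BMI visit, then obese at 1.5y (age 540), then at 3y (age
    # 1100): the index is the age-3 visit, the first one passing the age
    # filter; the underage obese visit serves as the pre-index visit
    data.frame(patient_id = 2, visit_id = 3:6,
               visit_ordinal = c(300, 540, 1100, 1300),
               age_days = c(300, 540, 1100, 1300),
               care_setting = "outpatient"),
    # p3: obese only at a telephone encounter -> no qualifying visit
    data.frame(patient_id = 3, visit_id = 7:8, visit_ordinal = c(10, 60),
               age_days = c(1000, 1050),
               care_setting = c("outpatient", "telephone")),
    # p4: clean case, second visit obese
    basic_visits(4, c(100, 200, 300), id0 = 8L))
  meas <- data.frame(visit_id = c(1L, 4L, 5L, 8L, 10L),
                     bmi_z = c(2.0, 2.1, 2.2, 1.9, 1.8))
  conds <- data.frame(visit_id = c(1:11),
                      condition_group = "Preventive care")
  tab <- make_tables(pats, visits, meas, conds)
  tri <- find_index_visits(tab, cohort_config())

  expect_setequal(tri$patient_id, c(2, 4))
  expect_equal(tri$index_visit_id[tri$patient_id == 2], 5L)  # age-3 visit
  expect_equal(tri$pre_visit_id[tri$patient_id == 2], 4L)
  expect_equal(tri$index_visit_id[tri$patient_id == 4], 10L)
  expect_equal(tri$post_visit_id[tri$patient_id == 4], 11L)
  # exclusion accounting: removals sum to input minus output
  expect_equal(sum(cohort_exclusions(tri)), 4 - nrow(tri))
})

test_that("no threshold crossers yields an empty case list", {
  pats <- data.frame(patient_id = 1:2, sex = "M", birth_ordinal = 0,
                     is_case = FALSE)
  visits <- rbind(basic_visits(1, c(1, 2)), basic_visits(2, c(3, 4),
                                                         id0 = 2L))
  meas <- data.frame(visit_id = 1:4, bmi_z = c(0.1, 0.5, -0.3, 0.9))
  conds <- data.frame(visit_id = 1:4, condition_group = "Fever")
  tri <- find_index_visits(make_tables(pats, visits, meas, conds))
  expect_equal(nrow(tri), 0)
})

test_that("index selection agrees with a brute-force predicate enumeration", {
  tab <- simulate_ehr(sim_config(n_patients = 400, seed = 21))
  tab$conditions$condition_group <- tab$conditions$diagnosis_code
  cfg <- cohort_config()
  tri <- find_index_visits(tab, cfg)

  cleaned <- clean_measurements(tab$measurements, tab$visits,
                                cfg$plausibility_bounds)
  v <- merge(tab$visits, cleaned, by = "visit_id", all.x = TRUE)
  v$has_cond <- v$visit_id %in% tab$conditions$visit_id
  for (pid in unique(tab$patients$patient_id)) {
    vv <- v[v$patient_id == pid, ]
    vv <- vv[order(vv$visit_ordinal, vv$visit_id), ]
    qual <- !is.na(vv$bmi_z) & vv$bmi_z >= cfg$bmi_z_threshold &
      vv$care_setting %in% cfg$face_to_face_settings &
      vv$age_days >= 730 & vv$age_days <= 6935 & vv$has_cond
    k <- which(qual)[1]
    row <- tri[tri$patient_id == pid, ]
    if (is.na(k) || k == 1) {
      # no qualifying visit, or no visit before it
      if (is.na(k)) expect_equal(nrow(row), 0)
      next
    }
    pre_cands <- which(vv$has_cond[seq_len(k - 1)])
    if (length(pre_cands) == 0) {
      expect_equal(nrow(row), 0)
    } else {
      expect_equal(row$index_visit_id, vv$visit_id[k])
      expect_equal(row$pre_visit_id, vv$visit_id[max(pre_cands)])
    }
  }
})

test_that("event sequences collapse duplicates and drop missing classes", {
  tri <- tibble::tibble(patient_id = c(1L, 2L), pre_visit_id = c(1L, 4L),
                        index_visit_id = c(2L, 5L),
                        post_visit_id = c(3L, NA))
  gc <- data.frame(
    visit_id = c(1L, 1L, 1L, 2L, 3L, 4L, 5L),
    condition_group = c("Asthma", "Asthma", "Allergic Rhinitis", "Asthma",
                        "Fever", "Fever", "Otitis media"))
  seqs <- build_event_sequences(tri, gc)
  s1 <- seqs[seqs$sid == 1, ]
  expect_equal(sort(s1$condition[s1$timing_class == 1]),
               c("Allergic Rhinitis", "Asthma"))  # duplicate collapsed
  expect_setequal(unique(seqs$timing_class[seqs$sid == 2]), c(1, 2))
  # a triplet with a conditionless index visit is excluded with a warning
  tri2 <- tibble::tibble(patient_id = 3L, pre_visit_id = 6L,
                         index_visit_id = 7L, post_visit_id = NA_integer_)
  expect_warning(out <- build_event_sequences(
    rbind(tri, tri2), rbind(gc, data.frame(visit_id = 6L,
                                           condition_group = "Fever"))),
    "conditionless")
  expect_false(3 %in% out$sid)
})

test_that("event sequences equal a direct join-and-group recount", {
  tab <- simulate_ehr(sim_config(n_patients = 300, seed = 31))
  tab$conditions$condition_group <- tab$conditions$diagnosis_code
  tri <- find_index_visits(tab)
  seqs <- build_event_sequences(tri, tab$conditions)
  # oracle: independent merge per class
  oracle <- NULL
  for (cl in 1:3) {
    col <- c("pre_visit_id", "index_visit_id", "post_visit_id")[cl]
    sub <- tri[!is.na(tri[[col]]), c("patient_id", col)]
    mm <- merge(sub, tab$conditions, by.x = col, by.y = "visit_id")
    oracle <- rbind(oracle, unique(data.frame(sid = mm$patient_id,
                                              timing_class = cl,
                                              condition = mm$condition_group)))
  }
  oracle <- oracle[order(oracle$sid, oracle$timing_class, oracle$condition), ]
  got <- as.data.frame(seqs)[order(seqs$sid, seqs$timing_class,
                                   seqs$condition), ]
  rownames(oracle) <- rownames(got) <- NULL
  expect_equal(got, oracle, ignore_attr = TRUE)
})

test_that("cohort extraction is a fixed point on its own output", {
  tab <- simulate_ehr(sim_config(n_patients = 200, seed = 41))
  tab$conditions$condition_group <- tab$conditions$diagnosis_code
  tri <- find_index_visits(tab)
  keep <- unique(stats::na.omit(c(tri$pre_visit_id, tri$index_visit_id,
                                  tri$post_visit_id)))
  tab2 <- tab
  tab2$patients <- tab$patients[tab$patients$patient_id %in%
                                  tri$patient_id, ]
  tab2$visits <- tab$visits[tab$visits$visit_id %in% keep, ]
  tab2$measurements <- tab$measurements[tab$measurements$visit_id %in%
                                          keep, ]
  tab2$conditions <- tab$conditions[tab$conditions$visit_id %in% keep, ]
  tri2 <- find_index_visits(tab2)
  expect_equal(tri2$patient_id, tri$patient_id)
  expect_equal(tri2$index_visit_id, tri$index_visit_id)
  expect_equal(tri2$pre_visit_id, tri$pre_visit_id)
})
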