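# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: the miner oracle enumerates
# patterns by containment counting on a presence matrix, the matching oracle
# replays the greedy rule step by step on plain data frames.

# Enumerate every class-tagged pattern up to `max_len` items and count
# containment per sequence via a presence-matrix subset test.
brute_force_mine <- function(sequences, minsup, max_len = 4) {
  sids <- unique(sequences$sid)
  n <- length(sids)
  ev <- unique(sequences[, c("sid", "timing_class", "condition")])
  items <- unique(ev[, c("timing_class", "condition")])
  items <- items[order(items$timing_class, items$condition,
                       method = "radix"), ]
  K <- nrow(items)
  ikey <- paste0(items$timing_class, "-", items$condition)
  M <- matrix(FALSE, n, K, dimnames = list(NULL, ikey))
  M[cbind(match(ev$sid, sids),
          match(paste0(ev$timing_class, "-", ev$condition), ikey))] <- TRUE
  pats <- character(0)
  cnts <- integer(0)
  for (len in seq_len(min(max_len, K))) {
    combos <- utils::combn(K, len)
    for (j in seq_len(ncol(combos))) {
      idx <- combos[, j]
      cnt <- sum(rowSums(M[, idx, drop = FALSE]) == len)
      if (cnt >= minsup * n - 1e-9) {
        pats <- c(pats, paste(ikey[idx], collapse = ", "))
        cnts <- c(cnts, cnt)
      }
    }
  }
  data.frame(pattern = pats, count = cnts, support = cnts / n,
             stringsAsFactors = FALSE)
}

# Naive containment: double loop over the pattern's timing classes.
naive_contains <- function(seq_events, pattern_items) {
  for (cl in unique(pattern_items$timing_class)) {
    want <- pattern_items$condition[pattern_items$timing_class == cl]
    have <- seq_events$condition[seq_events$timing_class == cl]
    for (w in want) if (!w %in% have) return(FALSE)
  }
  TRUE
}

# Random event tables for fuzzing the miner.
random_sequences <- function(n_seq, groups, p_class3 = 0.8, p_cond = 0.3) {
  rows <- list()
  for (s in seq_len(n_seq)) {
    classes <- c(1L, 2L, if (stats::runif(1) < p_class3) 3L)
    for (cl in classes) {
      present <- groups[stats::runif(length(groups)) < p_cond]
      if (length(present) == 0) present <- sample(groups, 1)
      rows[[length(rows) + 1L]] <- data.frame(sid = s, timing_class = cl,
                                              condition = present)
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}

# Step-by-step greedy matching replay, youngest case first, full pool scan.
reference_greedy <- function(cases, pool, caliper_days = 60) {
  spread <- diff(range(pool$prior_visit_count))
  cases <- cases[order(cases$index_age_days, cases$patient_id), ]
  used <- c()
  out <- NULL
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    cand <- pool[pool$sex == cs$sex &
                   abs(pool$age_days - cs$index_age_days) <= caliper_days &
                   !(pool$patient_id %in% used), , drop = FALSE]
    if (nrow(cand) == 0) next
    ad <- abs(cand$age_days - cs$index_age_days)
    d <- ad / caliper_days +
      abs(cand$prior_visit_count - cs$prior_visit_count) / (1 + spread)
    pick <- cand[order(d, ad, cand$patient_id, cand$visit_id)[1], ]
    used <- c(used, pick$patient_id)
    out <- rbind(out, data.frame(case_id = cs$patient_id,
                                 control_patient_id = pick$patient_id,
                                 control_visit_id = pick$visit_id))
  }
  out
}

# Hand-rolled EHR table builder for cohort/matching fixtures. `visits` is a
# data frame with patient_id, visit_id, visit_ordinal, age_days,
# care_setting; measurements and conditions default to empty.
make_tables <- function(patients, visits,
                        measurements = data.frame(visit_id = integer(),
                                                  bmi_z = double()),
                        conditions = data.frame(visit_id = integer(),
                                                condition_group = character())) {
  list(patients = tibble::as_tibble(patients),
       visits = tibble::as_tibble(visits),
       measurements = tibble::as_tibble(measurements),
       conditions = tibble::as_tibble(conditions))
}

# Wald CI for a discordant-pair odds ratio.
or_ci <- function(n10, n01, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / n10 + 1 / n01)
  exp(log(n10 / n01) + c(-1, 1) * z * se)
}
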