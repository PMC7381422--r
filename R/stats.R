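# Matched-pair McNemar tests of per-pattern prevalence, with effect sizes
# computed as odds ratios among the discordant pairs.

#' Construct a matched-pair 2x2 table
#'
#' Cell layout follows the matched-pair convention: `n11` both members
#' exhibit the pattern, `n10` case only, `n01` control only, `n00` neither.
#'
#' @param n11,n10,n01,n00 Non-negative cell counts (vectorized).
#' @return A tibble of class `paired_table` with one row per table.
#' @export
paired_table <- function(n11, n10, n01, n00) {
  cells <- cbind(n11, n10, n01, n00)
  if (anyNA(cells) || any(cells < 0) || any(cells != floor(cells))) {
    abort("Cell counts must be non-negative integers.")
  }
  out <- tibble(n11 = as.integer(n11), n10 = as.integer(n10),
                n01 = as.integer(n01), n00 = as.integer(n00))
  class(out) <- c("paired_table", class(out))
  out
}

#' Build the matched-pair table for one pattern
#'
#' Evaluates pattern containment on the case and control member of every
#' matched pair and tallies the 2x2 table. Pairs referencing a subject
#' absent from the corresponding event table are an error: a control that
#' truly lacks the timing class simply counts as pattern-absent, but a
#' dangling id means the inputs are inconsistent.
#'
#' @param pattern A single pattern string.
#' @param case_sequences,control_sequences Event tables.
#' @param pairs Tibble with `case_id`, `control_patient_id`.
#' @return A one-row [paired_table()].
#' @export
build_paired_table <- function(pattern, case_sequences, control_sequences,
                               pairs) {
  check_columns(pairs, c("case_id", "control_patient_id"), "pairs")
  case_sids <- unique(case_sequences$sid)
  ctrl_sids <- unique(control_sequences$sid)
  if (!all(pairs$case_id %in% case_sids) ||
      !all(pairs$control_patient_id %in% ctrl_sids)) {
    abort("`pairs` references subjects absent from the event tables.")
  }
  case_has <- contains_pattern(case_sequences, pattern)
  ctrl_has <- contains_pattern(control_sequences, pattern)
  a <- case_has$contains[match(pairs$case_id, case_has$sid)]
  b <- ctrl_has$contains[match(pairs$control_patient_id, ctrl_has$sid)]
  paired_table(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b))
}

#' McNemar's test on matched-pair tables
#'
#' Tests marginal homogeneity using only the discordant cells. Methods:
#' `"chi2"` (default) uses the uncorrected statistic
#' `(n10 - n01)^2 / (n10 + n01)` on one degree of freedom;
#' `"chi2_corrected"` applies the continuity correction
#' `(|n10 - n01| - 1)^2 / (n10 + n01)`; `"exact"` is the two-sided binomial
#' test of `n10` successes in `n10 + n01` trials at probability one half.
#' With no discordant pairs the statistic is 0 and p = 1.
#'
#' @param table A [paired_table()] (any number of rows; vectorized).
#' @param method Test variant.
#' @return The input tibble with `statistic` and `p_value` columns added.
#' @export
mcnemar_test <- function(table, method = c("chi2", "chi2_corrected",
                                           "exact")) {
  method <- match.arg(method)
  check_columns(table, c("n10", "n01"), "table")
  if (any(table$n10 < 0 | table$n01 < 0)) abort("Negative cell counts.")
  nd <- table$n10 + table$n01
  if (method == "chi2") {
    stat <- ifelse(nd == 0, 0, (table$n10 - table$n01)^2 / nd)
    p <- ifelse(nd == 0, 1, pchisq(stat, df = 1, lower.tail = FALSE))
  } else if (method == "chi2_corrected") {
    stat <- ifelse(nd == 0, 0,
                   (pmax(abs(table$n10 - table$n01) - 1, 0))^2 / nd)
    p <- ifelse(nd == 0, 1, pchisq(stat, df = 1, lower.tail = FALSE))
  } else {
    stat <- as.double(table$n10)
    p <- vapply(seq_along(nd), function(i) {
      if (nd[i] == 0) return(1)
      binom.test(table$n10[i], nd[i], p = 0.5)$p.value
    }, double(1))
  }
  out <- mutate(table, statistic = stat, p_value = pmin(p, 1))
  attr(out, "method") <- method
  out
}

#' Discordant-pair odds ratio
#'
#' The effect size of a matched-pair comparison: the ratio of the larger
#' discordant cell to the smaller, reported in the enriched direction
#' (`direction = "case"` when the pattern is more often case-only,
#' `"control"` when control-only, `"none"` when balanced). One empty
#' discordant cell gives an infinite ratio; both empty give `NA`.
#'
#' @param table A [paired_table()] (vectorized over rows).
#' @return The input with `effect_size` and `direction` columns added.
#' @export
effect_size <- function(table) {
  check_columns(table, c("n10", "n01"), "table")
  hi <- pmax(table$n10, table$n01)
  lo <- pmin(table$n10, table$n01)
  es <- ifelse(hi == 0, NA_real_, hi / lo)  # lo = 0 -> Inf, as intended
  dir <- dplyr::case_when(
    table$n10 > table$n01 ~ "case",
    table$n01 > table$n10 ~ "control",
    TRUE ~ "none")
  mutate(table, effect_size = es, direction = dir)
}

#' Test every mined pattern on the matched pairs
#'
#' For each pattern, builds the matched-pair 2x2 table, runs McNemar's test,
#' grades significance stars (* p < 0.05, ** p <= 0.01, *** p <= 0.001,
#' **** p <= 0.0001) and computes the discordant-pair odds ratio. Raw
#' p-values are reported by default, matching the conventional matched-pair
#' screening usage; set `p_adjust = "BH"` (or any [stats::p.adjust()]
#' method) for multiplicity control.
#'
#' @param patterns A `spade_patterns` tibble or character vector.
#' @param case_sequences,control_sequences Event tables.
#' @param pairs Matched pairs (`case_id`, `control_patient_id`).
#' @param method McNemar variant, see [mcnemar_test()].
#' @param p_adjust Multiple-testing adjustment method (default `"none"`).
#' @return A tibble of class `pattern_tests`: `pattern`, cells, `statistic`,
#'   `p_value`, `stars`, `effect_size`, `direction`.
#' @export
test_patterns <- function(patterns, case_sequences, control_sequences,
                          pairs, method = c("chi2", "chi2_corrected",
                                            "exact"),
                          p_adjust = "none") {
  method <- match.arg(method)
  pat <- if (is.character(patterns)) patterns else patterns$pattern
  check_columns(pairs, c("case_id", "control_patient_id"), "pairs")
  case_sids <- unique(case_sequences$sid)
  ctrl_sids <- unique(control_sequences$sid)
  if (!all(pairs$case_id %in% case_sids) ||
      !all(pairs$control_patient_id %in% ctrl_sids)) {
    abort("`pairs` references subjects absent from the event tables.")
  }
  if (length(pat) == 0) {
    out <- tibble(pattern = character(), n11 = integer(), n10 = integer(),
                  n01 = integer(), n00 = integer(), statistic = double(),
                  p_value = double(), stars = character(),
                  effect_size = double(), direction = character())
    class(out) <- c("pattern_tests", class(out))
    attr(out, "method") <- method
    attr(out, "n_pairs") <- nrow(pairs)
    return(out)
  }

  # per-pattern presence via the same id-list intersection the miner uses
  case_count <- count_presence_sets(pat, case_sequences)
  ctrl_count <- count_presence_sets(pat, control_sequences)
  a_idx <- match(pairs$case_id, case_count$sids)
  b_idx <- match(pairs$control_patient_id, ctrl_count$sids)

  cells <- vapply(seq_along(pat), function(i) {
    a <- case_count$present[[i]][a_idx]
    b <- ctrl_count$present[[i]][b_idx]
    c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b))
  }, integer(4))

  tab <- paired_table(cells[1, ], cells[2, ], cells[3, ], cells[4, ])
  res <- tab %>%
    mcnemar_test(method = method) %>%
    effect_size() %>%
    mutate(pattern = pat,
           p_value = stats::p.adjust(.data$p_value, method = p_adjust),
           stars = significance_stars(.data$p_value)) %>%
    select("pattern", "n11", "n10", "n01", "n00", "statistic", "p_value",
           "stars", "effect_size", "direction")
  class(res) <- c("pattern_tests", class(res))
  attr(res, "method") <- method
  attr(res, "n_pairs") <- nrow(pairs)
  res
}

# For each pattern, a logical presence vector over the population's sids.
count_presence_sets <- function(pat, sequences) {
  sids <- unique(sequences$sid)
  ev <- distinct(sequences, .data$sid, .data$timing_class, .data$condition)
  key <- paste0(ev$timing_class, "-", ev$condition)
  sid_code <- match(ev$sid, sids)
  idlists <- lapply(split(sid_code, key), function(x) sort.int(unique(x)))
  present <- lapply(parse_pattern(pat), function(items) {
    keys <- paste0(items$timing_class, "-", items$condition)
    out <- logical(length(sids))
    cur <- NULL
    for (k in keys) {
      il <- idlists[[k]]
      if (is.null(il)) return(out)
      cur <- if (is.null(cur)) il else cur[cur %in% il]
      if (length(cur) == 0) return(out)
    }
    out[cur] <- TRUE
    out
  })
  list(sids = sids, present = present)
}

#' Partition tested patterns into report tables
#'
#' Splits tested patterns by significance at `alpha` and enrichment
#' direction, mirroring the usual reporting layout: one table of patterns
#' significantly more supported among cases, one among controls, counts of
#' the non-significant leanings, and an inventory of the distinct condition
#' groups appearing in each significant set (exclusive to cases, exclusive
#' to controls, shared).
#'
#' @param tests A `pattern_tests` tibble.
#' @param alpha Significance level (default 0.05).
#' @return A list of class `pattern_summary`: `counts` (partition sizes),
#'   `case_table`, `control_table`, `condition_inventory`, `alpha`.
#' @export
summarize_pattern_tests <- function(tests, alpha = 0.05) {
  check_prob(alpha, "alpha")
  sig <- tests$p_value < alpha
  part <- dplyr::case_when(
    sig & tests$direction == "case" ~ "significant_case",
    sig & tests$direction == "control" ~ "significant_control",
    tests$direction == "case" ~ "nonsignificant_case",
    tests$direction == "control" ~ "nonsignificant_control",
    TRUE ~ "nonsignificant_tied")
  lv <- c("significant_case", "significant_control", "nonsignificant_case",
          "nonsignificant_control", "nonsignificant_tied")
  counts <- tibble(partition = lv,
                   n = vapply(lv, function(p) sum(part == p), integer(1)))
  case_table <- tests[part == "significant_case", ] %>%
    arrange(.data$pattern)
  control_table <- tests[part == "significant_control", ] %>%
    arrange(.data$pattern)

  conds_of <- function(df) {
    if (nrow(df) == 0) return(character(0))
    sort(unique(unlist(lapply(parse_pattern(df$pattern),
                              function(it) it$condition))))
  }
  cc <- conds_of(case_table)
  kc <- conds_of(control_table)
  inventory <- tibble(
    condition = union(cc, kc),
    category = dplyr::case_when(
      condition %in% cc & condition %in% kc ~ "shared",
      condition %in% cc ~ "case_only",
      TRUE ~ "control_only")) %>%
    arrange(.data$category, .data$condition)

  structure(list(counts = counts, case_table = case_table,
                 control_table = control_table,
                 condition_inventory = inventory, alpha = alpha),
            class = "pattern_summary")
}

#' @export
print.pattern_summary <- function(x, ...) {
  cat("<pattern_summary> alpha =", x$alpha, "\n")
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  %-24s %d\n", x$counts$partition[i], x$counts$n[i]))
  }
  cat(sprintf("  condition inventory: %d group(s)\n",
              nrow(x$condition_inventory)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.pattern_tests <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "pattern_tests")
  out
}

#' @export
glance.pattern_tests <- function(x, alpha = 0.05, ...) {
  sig <- x$p_value < alpha
  tibble(
    n_patterns = nrow(x),
    n_pairs = attr(x, "n_pairs") %||% NA_integer_,
    method = attr(x, "method") %||% NA_character_,
    n_significant = sum(sig),
    n_significant_case = sum(sig & x$direction == "case"),
    n_significant_control = sum(sig & x$direction == "control"),
    alpha = alpha)
}

#' @export
tidy.pattern_summary <- function(x, ...) x$counts

#' @export
glance.pattern_summary <- function(x, ...) {
  tibble(alpha = x$alpha,
         n_patterns = sum(x$counts$n),
         n_significant_case = x$counts$n[x$counts$partition ==
                                           "significant_case"],
         n_significant_control = x$counts$n[x$counts$partition ==
                                              "significant_control"])
}
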