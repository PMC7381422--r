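# SPADE frequent-sequence mining over timing-class-tagged condition itemsets.
#
# A subject's event sequence is a long "event table": one row per
# (sid, timing_class, condition). Timing classes order the itemsets
# (1 = pre-index visit, 2 = index visit, 3 = post-index visit), and each
# class holds an unordered set of condition groups. A pattern is a set of
# class-tagged items rendered in canonical order, e.g.
# "1-Allergic Rhinitis, 1-Asthma, 2-Asthma".
#
# The miner is vertical-format SPADE: each item carries an id-list of
# (sid, eid) occurrences with eid = timing class; k-patterns are grown
# depth-first from (k-1)-pattern id-lists by temporal joins. Because a
# timing class occurs at most once per sequence here, an itemset extension
# (equal eid) and a sequence extension (later eid) both reduce to an
# intersection of sid sets — the join code states which case it is in.

# Canonical item ordering: by timing class, then byte-order condition name
# (radix sort, locale-independent).
item_order <- function(timing_class, condition) {
  order(timing_class, condition, method = "radix")
}

render_pattern <- function(timing_class, condition) {
  paste(paste0(timing_class, "-", condition), collapse = ", ")
}

#' Parse pattern strings into class-tagged items
#'
#' Inverse of the `"1-Asthma, 2-Asthma"` rendering. Items are split on a
#' comma-space followed by a `class-` prefix, so condition names that
#' themselves contain commas (e.g. "Nausea, vomiting") survive round trips.
#'
#' @param pattern Character vector of pattern strings.
#' @return A list (one element per pattern) of tibbles with columns
#'   `timing_class` (integer) and `condition`.
#' @export
parse_pattern <- function(pattern) {
  lapply(strsplit(pattern, ", (?=[0-9]+-)", perl = TRUE), function(items) {
    m <- regmatches(items, regexpr("^[0-9]+", items))
    tibble(timing_class = as.integer(m),
           condition = sub("^[0-9]+-", "", items))
  })
}

check_event_table <- function(sequences) {
  check_columns(sequences, c("sid", "timing_class", "condition"), "sequences")
  if (!is.numeric(sequences$timing_class) ||
      any(sequences$timing_class < 1)) {
    abort("`timing_class` must contain positive integers.")
  }
  invisible(sequences)
}

#' Mine frequent class-tagged condition sequences (SPADE)
#'
#' Finds every pattern of class-tagged condition items whose support — the
#' proportion of distinct subjects whose event sequence contains it — is at
#' least `minsup`. Subjects lacking a timing class (e.g. no post-index
#' visit) stay in the denominator and simply cannot exhibit patterns using
#' that class.
#'
#' @param sequences Event table: tibble with columns `sid`, `timing_class`,
#'   `condition`.
#' @param minsup Minimum relative support in (0, 1]; the conventional mining
#'   floor for sparse clinical data is 0.01 (patterns in at least 1% of
#'   subjects).
#' @param max_len Optional cap on pattern length (number of items).
#' @return A tibble of class `spade_patterns` with columns `pattern`,
#'   `length`, `count`, `support`, in deterministic depth-first canonical
#'   order, plus attributes `n_sequences` and `minsup`.
#' @export
spade_mine <- function(sequences, minsup = 0.01, max_len = Inf) {
  check_event_table(sequences)
  if (!is.numeric(minsup) || length(minsup) != 1 || is.na(minsup) ||
      minsup <= 0 || minsup > 1) {
    abort("`minsup` must be a single number in (0, 1].")
  }
  if (nrow(sequences) == 0) abort("`sequences` is empty.")

  sids <- unique(sequences$sid)
  n <- length(sids)
  min_count <- minsup * n - 1e-9

  ev <- distinct(sequences, .data$sid, .data$timing_class, .data$condition)
  sid_code <- match(ev$sid, sids)

  # vertical layout: one id-list per item, eid = timing class
  item_key <- paste0(ev$timing_class, "-", ev$condition)
  items <- distinct(tibble(timing_class = as.integer(ev$timing_class),
                           condition = ev$condition,
                           key = item_key))
  items <- items[item_order(items$timing_class, items$condition), ]
  idlists <- split(sid_code, factor(item_key, levels = items$key))
  idlists <- lapply(idlists, function(x) sort.int(unique(x)))

  keep <- vapply(idlists, length, integer(1)) >= min_count
  items <- items[keep, , drop = FALSE]
  idlists <- idlists[keep]
  k_items <- nrow(items)

  out_pattern <- character(0)
  out_len <- integer(0)
  out_count <- integer(0)

  emit <- function(idx, count) {
    out_pattern[[length(out_pattern) + 1L]] <<- render_pattern(
      items$timing_class[idx], items$condition[idx])
    out_len[[length(out_len) + 1L]] <<- length(idx)
    out_count[[length(out_count) + 1L]] <<- count
  }

  # depth-first growth: extend pattern `idx` (item indices, increasing) by
  # any later item in canonical order. Equal timing class => itemset
  # extension (same eid); later class => sequence extension (later eid).
  # Either way the temporal join is a sid intersection because each class
  # occurs once per sequence.
  grow <- function(idx, sid_set) {
    last <- idx[length(idx)]
    if (length(idx) >= max_len || last >= k_items) return(invisible())
    for (j in (last + 1L):k_items) {
      joined <- sid_set[sid_set %in% idlists[[j]]]
      if (length(joined) >= min_count) {
        emit(c(idx, j), length(joined))
        grow(c(idx, j), joined)
      }
    }
  }

  if (k_items > 0) {
    for (i in seq_len(k_items)) {
      emit(i, length(idlists[[i]]))
      grow(i, idlists[[i]])
    }
  }

  res <- tibble(pattern = out_pattern,
                length = out_len,
                count = out_count,
                support = out_count / n)
  # canonical order: by length within shared prefixes is DFS order already;
  # keep DFS (prefix-lexicographic) order for determinism
  class(res) <- c("spade_patterns", class(res))
  attr(res, "n_sequences") <- n
  attr(res, "minsup") <- minsup
  res
}

#' @export
print.spade_patterns <- function(x, ...) {
  cat(sprintf("# SPADE patterns: %d pattern(s) over %d sequence(s), minsup %s\n",
              nrow(x), attr(x, "n_sequences") %||% NA,
              format(attr(x, "minsup") %||% NA)))
  NextMethod()
}

#' Does each subject's event sequence contain a pattern?
#'
#' A sequence contains a pattern iff, for every timing class the pattern
#' uses, the pattern's class-c items are a subset of the sequence's class-c
#' itemset. A subject lacking a class used by the pattern (e.g. no
#' post-index visit) does not contain it.
#'
#' @param sequences Event table (`sid`, `timing_class`, `condition`).
#' @param pattern A single pattern string.
#' @return A tibble (`sid`, `contains`) covering every distinct sid.
#' @export
contains_pattern <- function(sequences, pattern) {
  check_event_table(sequences)
  stopifnot(length(pattern) == 1L)
  items <- parse_pattern(pattern)[[1]]
  k <- nrow(items)
  hits <- sequences %>%
    distinct(.data$sid, .data$timing_class, .data$condition) %>%
    semi_join(items, by = c("timing_class", "condition")) %>%
    count(.data$sid, name = "n_hit") %>%
    filter(.data$n_hit == k)
  tibble(sid = unique(sequences$sid)) %>%
    mutate(contains = .data$sid %in% hits$sid)
}

#' Count pattern presence in an arbitrary population
#'
#' Applies case-mined patterns to any population's event table (typically
#' the matched controls) and counts, per pattern, the subjects containing
#' it. Counts need not reach the mining support floor in the new population.
#'
#' @param patterns A `spade_patterns` tibble or character vector of pattern
#'   strings.
#' @param sequences Event table of the population to scan.
#' @return A tibble (`pattern`, `count`, `support`) with support relative to
#'   the number of distinct sids in `sequences`.
#' @export
count_in_population <- function(patterns, sequences) {
  pat <- if (is.character(patterns)) patterns else patterns$pattern
  if (length(pat) == 0) {
    return(tibble(pattern = character(), count = integer(),
                  support = double()))
  }
  check_event_table(sequences)
  sids <- unique(sequences$sid)
  n <- length(sids)
  ev <- distinct(sequences, .data$sid, .data$timing_class, .data$condition)
  key <- paste0(ev$timing_class, "-", ev$condition)
  sid_code <- match(ev$sid, sids)
  idlists <- split(sid_code, key)
  idlists <- lapply(idlists, function(x) sort.int(unique(x)))
  counts <- vapply(parse_pattern(pat), function(items) {
    keys <- paste0(items$timing_class, "-", items$condition)
    cur <- NULL
    for (k in keys) {
      il <- idlists[[k]]
      if (is.null(il)) return(0L)
      cur <- if (is.null(cur)) il else cur[cur %in% il]
      if (length(cur) == 0) return(0L)
    }
    length(cur)
  }, integer(1))
  tibble(pattern = pat, count = counts, support = counts / n)
}
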