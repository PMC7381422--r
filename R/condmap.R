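# Mapping of granular diagnosis codes to medically homogeneous condition
# groups (EDC-style), plus the exclusion policy applied to mined patterns.

#' Read a diagnosis-code to condition-group mapping table
#'
#' The table is a two-column CSV (`diagnosis_code`, `condition_group`).
#' Many-to-one and many-to-many rows are allowed: a code mapped to several
#' groups fans out into one observation per group, each treated as a distinct
#' condition. Blank entries are rejected; exact duplicate rows collapse.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `diagnosis_code`, `condition_group`.
#' @export
read_condition_mapping <- function(path) {
  map <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  check_columns(map, c("diagnosis_code", "condition_group"), "mapping")
  validate_mapping(map)
}

validate_mapping <- function(map) {
  map <- as_tibble(map)
  check_columns(map, c("diagnosis_code", "condition_group"), "mapping")
  if (nrow(map) == 0) abort("Mapping table is empty.")
  if (any(is.na(map$diagnosis_code) | map$diagnosis_code == "" |
          is.na(map$condition_group) | map$condition_group == "")) {
    abort("Mapping table contains blank codes or groups.")
  }
  distinct(map, .data$diagnosis_code, .data$condition_group)
}

#' Demonstration condition-group mapping
#'
#' A small synthetic mapping (about 40 pediatric condition groups, some with
#' several codes and a few many-to-many codes) shipped with the package. Real
#' grouper content such as the ACG expanded diagnostic clusters is licensed
#' and cannot ship here; any user table in the same two-column shape is
#' accepted throughout the pipeline.
#'
#' @return A tibble with columns `diagnosis_code`, `condition_group`.
#' @export
demo_condition_mapping <- function() {
  read_condition_mapping(system.file("extdata", "condition_groups_demo.csv",
                                     package = "condseq", mustWork = TRUE))
}

#' Identity mapping for already-grouped codes
#'
#' When diagnosis codes are already condition-group names (the simulator's
#' default), the mapping is the identity over the observed codes.
#'
#' @param codes Character vector of codes/groups.
#' @return A tibble mapping each distinct code to itself.
#' @export
identity_mapping <- function(codes) {
  codes <- unique(as.character(codes))
  validate_mapping(tibble(diagnosis_code = codes, condition_group = codes))
}

#' Map per-visit diagnosis codes to condition groups
#'
#' Each conditions row fans out into one row per mapped group. Unmapped codes
#' are not dropped silently: they are returned in an `unmapped` attribute and
#' reported via a warning.
#'
#' @param conditions Tibble with columns `visit_id`, `diagnosis_code`.
#' @param mapping A mapping tibble (`diagnosis_code`, `condition_group`).
#' @return A tibble (`visit_id`, `condition_group`), distinct per visit-group
#'   pair not enforced (duplicates collapse later at itemset construction),
#'   with attribute `unmapped`: a tibble of unmapped code counts.
#' @export
map_conditions <- function(conditions, mapping) {
  check_columns(conditions, c("visit_id", "diagnosis_code"), "conditions")
  mapping <- validate_mapping(mapping)
  hit <- conditions$diagnosis_code %in% mapping$diagnosis_code
  unmapped <- conditions[!hit, ] %>%
    count(.data$diagnosis_code, name = "n_rows")
  if (nrow(unmapped) > 0) {
    warn(sprintf("%d condition row(s) over %d code(s) had no mapping entry.",
                 sum(unmapped$n_rows), nrow(unmapped)))
  }
  out <- conditions[hit, ] %>%
    inner_join(mapping, by = "diagnosis_code",
               relationship = "many-to-many") %>%
    select("visit_id", "condition_group")
  attr(out, "unmapped") <- unmapped
  out
}

#' Exclusion policy for mined patterns
#'
#' Patterns containing non-informative condition groups (administrative,
#' nonspecific, preventive) are removed before testing, as is any pattern
#' containing an obesity diagnosis group — obesity codes can only be common
#' among cases, so such patterns carry no comparative information.
#'
#' @param excluded_groups Character vector of non-informative groups.
#' @param obesity_groups Character vector of obesity diagnosis groups.
#' @return An object of class `exclusion_policy`.
#' @export
exclusion_policy <- function(
    excluded_groups = c("Administrative concerns",
                        "Nonspecific laboratory abnormalities",
                        "Other skin disorders",
                        "Preventive care",
                        "Nonspecific signs and symptoms"),
    obesity_groups = "Obesity") {
  structure(list(excluded_groups = as.character(excluded_groups),
                 obesity_groups = as.character(obesity_groups)),
            class = "exclusion_policy")
}

#' Filter mined patterns through an exclusion policy
#'
#' @param patterns A tibble of mined patterns (as returned by [spade_mine()]),
#'   with a `pattern` column in `"class-Group, class-Group"` rendering.
#' @param policy An [exclusion_policy()].
#' @return The retained rows, with attribute `removed`: a tibble of removal
#'   counts by reason (`non_informative`, `obesity`). Order-independent and
#'   idempotent.
#' @export
filter_patterns <- function(patterns, policy = exclusion_policy()) {
  check_columns(patterns, "pattern", "patterns")
  if (!inherits(policy, "exclusion_policy")) {
    abort("`policy` must be created by exclusion_policy().")
  }
  groups <- lapply(parse_pattern(patterns$pattern),
                   function(it) it$condition)
  has_any <- function(bad) {
    vapply(groups, function(g) any(g %in% bad), logical(1))
  }
  obese <- has_any(policy$obesity_groups)
  noninf <- has_any(policy$excluded_groups) & !obese
  out <- patterns[!(obese | noninf), , drop = FALSE]
  attr(out, "removed") <- tibble(
    reason = c("non_informative", "obesity"),
    n = c(sum(noninf), sum(obese))
  )
  attr(out, "n_sequences") <- attr(patterns, "n_sequences")
  out
}
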