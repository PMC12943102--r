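# Bioactivity standardization: filtering of activity records, conversion
# to pChEMBL, per-pair collapse to the strongest assay, target summaries
# and the flavonoid vs phenolic-acid class comparison.

STANDARD_ACTIVITY_TYPES <- c("IC50", "EC50", "Ki", "Kd")
STANDARD_UNITS <- c(nM = 1e-9, uM = 1e-6)
DIRECT_RELATIONSHIPS <- c("direct", "direct interaction", "D")

#' Convert an activity value to a pChEMBL score
#'
#' pChEMBL is the negative decadic logarithm of the molar activity value
#' (IC50, EC50, Ki or Kd); higher values indicate stronger binding.
#' Vectorized; nanomolar and micromolar inputs are supported.
#'
#' @param value Positive activity value(s).
#' @param units `"nM"` or `"uM"` (recycled).
#' @return pChEMBL value(s).
#' @examples
#' to_pchembl(1, "uM")    # 6
#' to_pchembl(10, "nM")   # 8
#' @export
to_pchembl <- function(value, units) {
  if (any(!units %in% names(STANDARD_UNITS))) {
    rlang::abort(paste0("unsupported unit(s): ",
                        paste(setdiff(unique(units), names(STANDARD_UNITS)),
                              collapse = ", ")))
  }
  if (any(!is.na(value) & value <= 0)) {
    rlang::abort("activity values must be positive to convert to pChEMBL")
  }
  -log10(value * unname(STANDARD_UNITS[units]))
}

#' Filter raw bioactivity records
#'
#' Applies the three inclusion criteria for activity standardization:
#' (1) a defined direct target relationship, (2) a standard activity type
#' (IC50, EC50, Ki, Kd), and (3) an activity value with a specified
#' standard unit (nM or uM) and a positive numeric value. Surviving
#' records get a `pchembl` column; a rejection report counts exclusions
#' per criterion (a record failing several criteria is counted under
#' each).
#'
#' @param raw Data frame with columns `compound_id`, `cls`, `target_id`,
#'   `target_name`, `target_class`, `activity_type`, `value`, `units`,
#'   `relationship`.
#' @param direct_values Relationship labels accepted as "direct".
#' @return List with `records` (standardized tibble) and `rejections`
#'   (tibble of per-criterion exclusion counts).
#' @export
filter_records <- function(raw, direct_values = DIRECT_RELATIONSHIPS) {
  raw <- tibble::as_tibble(raw)
  fail1 <- is.na(raw$relationship) |
    !tolower(trimws(raw$relationship)) %in% tolower(direct_values)
  fail2 <- is.na(raw$activity_type) |
    !raw$activity_type %in% STANDARD_ACTIVITY_TYPES
  val <- suppressWarnings(as.numeric(raw$value))
  fail3 <- is.na(raw$units) | !raw$units %in% names(STANDARD_UNITS) |
    is.na(val) | val <= 0
  keep <- !(fail1 | fail2 | fail3)
  records <- raw[keep, ]
  records$value <- val[keep]
  records$pchembl <- to_pchembl(records$value, records$units)
  list(
    records = records,
    rejections = tibble::tibble(
      criterion = c("target_relationship", "activity_type", "value_units"),
      n_excluded = c(sum(fail1), sum(fail2), sum(fail3))
    ),
    n_input = nrow(raw),
    n_retained = nrow(records)
  )
}

#' Collapse to the best activity per compound-target pair
#'
#' Retains, for every (compound, target) pair, the record with the
#' highest pChEMBL value; ties are broken by the earliest input row
#' (stable and deterministic).
#'
#' @param records Standardized activity tibble with `pchembl`.
#' @return Tibble with one row per (compound_id, target_id) pair.
#' @export
collapse_best <- function(records) {
  records |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$compound_id, .data$target_id) |>
    dplyr::arrange(dplyr::desc(.data$pchembl), .data$.row, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row")
}

#' Per-target activity summaries
#'
#' Distinct-compound count, mean and maximum pChEMBL per target over
#' collapsed records, sorted by mean descending (the layout of a
#' top-target ranking table).
#'
#' @param records Collapsed activity tibble.
#' @param by_class Also group by compound class.
#' @return Tibble of target summaries.
#' @export
target_summaries <- function(records, by_class = FALSE) {
  grp <- if (by_class) {
    dplyr::group_by(records, .data$cls, .data$target_id, .data$target_name)
  } else {
    dplyr::group_by(records, .data$target_id, .data$target_name)
  }
  grp |>
    dplyr::summarise(
      count = dplyr::n_distinct(.data$compound_id),
      mean = mean(.data$pchembl),
      max = max(.data$pchembl),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean))
}

#' Compare interaction strengths between compound classes
#'
#' Two-tailed independent-samples t-test of pChEMBL values between
#' flavonoids and phenolic acids (Welch by default; a pooled-variance
#' variant is available), with per-class target-diversity counts.
#'
#' @param records Activity tibble with `cls` and `pchembl` (typically
#'   collapsed to one row per compound-target pair).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return List with per-class `n`, `mean`, `sd`, `median`,
#'   `target_diversity`, and the test's `t_statistic`, `df`, `p_value`.
#' @export
compare_classes <- function(records, var_equal = FALSE) {
  classes <- sort(unique(records$cls))
  expected <- c("flavonoid", "phenolic_acid")
  missing_cls <- setdiff(expected, classes)
  if (length(missing_cls)) {
    rlang::abort(paste0("class comparison needs both classes; missing: ",
                        paste(missing_cls, collapse = ", ")))
  }
  x <- records$pchembl[records$cls == "flavonoid"]
  y <- records$pchembl[records$cls == "phenolic_acid"]
  if (length(x) < 2 || length(y) < 2) {
    rlang::abort("each class needs at least 2 records for the t-test")
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  div <- records |>
    dplyr::group_by(.data$cls) |>
    dplyr::summarise(k = dplyr::n_distinct(.data$target_id), .groups = "drop")
  list(
    n = c(flavonoid = length(x), phenolic_acid = length(y)),
    mean = c(flavonoid = mean(x), phenolic_acid = mean(y)),
    sd = c(flavonoid = stats::sd(x), phenolic_acid = stats::sd(y)),
    median = c(flavonoid = stats::median(x), phenolic_acid = stats::median(y)),
    target_diversity = stats::setNames(div$k, div$cls),
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    variant = if (var_equal) "pooled" else "welch"
  )
}
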