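# Food-source concentration mapping: unit standardization to mg/kg,
# per-pair statistics, per-food totals, food-group profiles and
# concentration tiers.

FOOD_GROUPS <- c("herbs and spices", "fruits", "vegetables",
                 "beverages (non-tea)", "teas",
                 "cereals and cereal products", "nuts and seeds",
                 "soy and soy products")

#' Standardize a concentration value to mg/kg
#'
#' mg/100 g values are multiplied by 10; mg/kg values pass through.
#' Anything else (unknown units, non-numeric or sub-detection entries) is
#' excluded with a reason, never silently coerced. Zero values are
#' retained and flagged.
#'
#' @param value Numeric (or numeric-like) concentration values.
#' @param unit Character units, `"mg/kg"` or `"mg/100g"`.
#' @return Tibble with `mg_per_kg`, `excluded`, `reason`, `zero_flag`.
#' @examples
#' standardize_concentration(450, "mg/100g")  # 4500 mg/kg
#' @export
standardize_concentration <- function(value, unit) {
  n <- max(length(value), length(unit))
  value <- rep_len(value, n); unit <- rep_len(unit, n)
  num <- suppressWarnings(as.numeric(value))
  unit_norm <- gsub("\\s", "", tolower(as.character(unit)))
  out <- rep(NA_real_, n); reason <- rep(NA_character_, n)
  known <- unit_norm %in% c("mg/kg", "mg/100g")
  reason[!known] <- "unknown_unit"
  reason[known & is.na(num)] <- "non_quantifiable_value"
  reason[known & !is.na(num) & num < 0] <- "negative_value"
  ok <- known & !is.na(num) & num >= 0
  out[ok] <- ifelse(unit_norm[ok] == "mg/100g", num[ok] * 10, num[ok])
  tibble::tibble(
    mg_per_kg = out,
    excluded = !ok,
    reason = reason,
    zero_flag = ok & num == 0
  )
}

#' Standardize a table of food concentration records
#'
#' @param raw Data frame with columns `compound_id`, `compound_name`,
#'   `food_name`, `food_group`, `concentration`, `unit` (and optionally a
#'   logical `below_detection`).
#' @return List with `records` (standardized, mg/kg) and `exclusions`
#'   (excluded rows with reasons).
#' @export
standardize_food_records <- function(raw) {
  raw <- tibble::as_tibble(raw)
  std <- standardize_concentration(raw$concentration, raw$unit)
  if ("below_detection" %in% names(raw)) {
    bd <- raw$below_detection %in% c(TRUE, "TRUE", "true", 1)
    std$excluded[bd & !std$excluded] <- TRUE
    std$reason[bd & is.na(std$reason)] <- "below_detection_limit"
  }
  bad_group <- !raw$food_group %in% FOOD_GROUPS
  if (any(bad_group)) {
    rlang::warn(sprintf("%d record(s) with food_group outside the declared set retained as-is",
                        sum(bad_group)))
  }
  rec <- raw[!std$excluded, ]
  rec$concentration <- std$mg_per_kg[!std$excluded]
  rec$original_unit <- raw$unit[!std$excluded]
  rec$unit <- NULL
  excl <- raw[std$excluded, ]
  excl$reason <- std$reason[std$excluded]
  list(records = rec, exclusions = excl)
}

#' Min / max / median per compound-food pair
#'
#' Summarizes replicate measurements for each (compound, food) pair;
#' the median uses linear interpolation.
#'
#' @param records Standardized food record tibble (mg/kg).
#' @return Tibble with one row per pair.
#' @export
per_pair_stats <- function(records) {
  records |>
    dplyr::group_by(.data$compound_id, .data$compound_name, .data$food_name,
                    .data$food_group) |>
    dplyr::summarise(
      n = dplyr::n(),
      min = min(.data$concentration),
      max = max(.data$concentration),
      median = stats::median(.data$concentration),
      .groups = "drop"
    )
}

#' Total content and rank per food source
#'
#' Total content per food is the sum over its compounds; replicate
#' measurements of a (compound, food) pair are first aggregated (median
#' by default, configurable).
#'
#' @param records Standardized food record tibble.
#' @param replicate_agg Aggregation for replicate pair measurements:
#'   `"median"` (default), `"mean"`, or `"max"`.
#' @return Tibble with `food_name`, `food_group`, `total`, `n_compounds`,
#'   `rank` (1 = richest source), sorted by rank.
#' @export
food_totals <- function(records, replicate_agg = c("median", "mean", "max")) {
  replicate_agg <- match.arg(replicate_agg)
  agg_fun <- switch(replicate_agg, median = stats::median, mean = mean, max = max)
  records |>
    dplyr::group_by(.data$food_name, .data$food_group, .data$compound_id) |>
    dplyr::summarise(conc = agg_fun(.data$concentration), .groups = "drop") |>
    dplyr::group_by(.data$food_name, .data$food_group) |>
    dplyr::summarise(
      total = sum(.data$conc),
      n_compounds = dplyr::n_distinct(.data$compound_id),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$total)) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Food-group concentration profiles
#'
#' Per food group: the total standardized concentration, the number of
#' distinct compounds, and the primary compound (largest summed
#' contribution across all foods of the group) with its percentage of
#' the group total. Ties on the primary compound are broken
#' lexicographically by compound name and reported.
#'
#' @inheritParams food_totals
#' @return Tibble of group profiles sorted by total descending, with a
#'   `primary_tie` flag column.
#' @export
group_profiles <- function(records, replicate_agg = c("median", "mean", "max")) {
  replicate_agg <- match.arg(replicate_agg)
  agg_fun <- switch(replicate_agg, median = stats::median, mean = mean, max = max)
  per_comp <- records |>
    dplyr::group_by(.data$food_group, .data$compound_id, .data$compound_name,
                    .data$food_name) |>
    dplyr::summarise(conc = agg_fun(.data$concentration), .groups = "drop") |>
    dplyr::group_by(.data$food_group, .data$compound_id, .data$compound_name) |>
    dplyr::summarise(contribution = sum(.data$conc), .groups = "drop")
  per_comp |>
    dplyr::group_by(.data$food_group) |>
    dplyr::group_modify(function(d, key) {
      total <- sum(d$contribution)
      top <- d[d$contribution == max(d$contribution), ]
      tie <- nrow(top) > 1
      top <- top[order(top$compound_name), ][1, ]
      if (tie) {
        rlang::inform(sprintf("primary-compound tie in group '%s'; lexicographic tie-break to '%s'",
                              key$food_group, top$compound_name))
      }
      tibble::tibble(
        total = total,
        n_compounds = dplyr::n_distinct(d$compound_id),
        primary_compound = top$compound_name,
        primary_pct = 100 * top$contribution / total,
        primary_tie = tie
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$total))
}

#' Concentration tier configuration
#'
#' @param high_min Totals strictly above this are high-content (mg/kg).
#' @param mid_min Lower bound (inclusive) of the medium tier.
#' @param low_min Lower bound (inclusive) of the lower tier.
#' @return A `tier_config` list.
#' @export
tier_config <- function(high_min = 7000, mid_min = 2000, low_min = 500) {
  stopifnot(low_min < mid_min, mid_min < high_min)
  structure(list(high_min = high_min, mid_min = mid_min, low_min = low_min),
            class = "tier_config")
}

#' Classify food totals into concentration tiers
#'
#' High is strictly above `high_min`; medium is the closed interval
#' `[mid_min, high_min]` (so a total of exactly 7000 mg/kg is medium);
#' lower is `[low_min, mid_min)`; anything smaller is `below_range`.
#'
#' @param total Numeric total concentrations (mg/kg).
#' @param config A [tier_config()].
#' @return Ordered factor with levels `below_range < lower < medium <
#'   high`.
#' @examples
#' tier_classify(c(14500, 4500, 1500, 100))
#' @export
tier_classify <- function(total, config = tier_config()) {
  stopifnot(all(total >= 0))
  lv <- c("below_range", "lower", "medium", "high")
  out <- ifelse(total > config$high_min, "high",
         ifelse(total >= config$mid_min, "medium",
         ifelse(total >= config$low_min, "lower", "below_range")))
  factor(out, levels = lv, ordered = TRUE)
}
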