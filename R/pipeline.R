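# End-to-end orchestration: validated run configuration, staged execution
# (registry -> descriptors -> drug-likeness -> bioactivity -> food), report
# tables written as CSV at full precision, and a machine-readable
# manifest. Presentation rounding (e.g. "58%") is left to a separate
# formatter so downstream comparisons see unrounded values.

#' Validate a run configuration
#'
#' Reads a YAML or JSON run configuration (or takes an equivalent list)
#' and collects every problem at once rather than failing fast.
#'
#' Recognized fields: `compound_tables` (list of `path`/`source_tag`
#' entries), `activity_table`, `food_table`, `score_table` (each a file
#' path), `output_dir`, `precedence`, `thresholds` (`ro5_mw_max`, ...,
#' `tier` block with `high_min`/`mid_min`/`low_min`, `outlier` block with
#' `z_threshold`), `t_test_variant` (`"welch"` or `"pooled"`), `seed`.
#'
#' @param config File path of a YAML/JSON config, or a list.
#' @return A validated `run_config` list, or an error of class
#'   `phenolprofiler_config_error` whose `errors` field lists every
#'   problem found.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      rlang::abort(sprintf("config file '%s' does not exist", config),
                   class = "phenolprofiler_config_error",
                   errors = "config file missing")
    }
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)

  for (ct in config$compound_tables) {
    if (is.null(ct$path) || !file.exists(ct$path)) {
      note(sprintf("compound table path missing or not found: '%s'",
                   ct$path %||% "<unset>"))
    }
    if (is.null(ct$source_tag)) note("compound table without source_tag")
  }
  for (f in c("activity_table", "food_table", "score_table")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      note(sprintf("%s not found: '%s'", f, config[[f]]))
    }
  }
  th <- config$thresholds %||% list()
  thresholds <- tryCatch(
    do.call(rule_thresholds,
            th[intersect(names(th), names(formals(rule_thresholds)))]),
    error = function(e) { note(paste("rule thresholds:", conditionMessage(e))); NULL })
  tier <- tryCatch(
    do.call(tier_config,
            (th$tier %||% list())[intersect(names(th$tier %||% list()),
                                            names(formals(tier_config)))]),
    error = function(e) { note(paste("tier thresholds:", conditionMessage(e))); NULL })
  outl <- tryCatch(
    do.call(outlier_config,
            (th$outlier %||% list())[intersect(names(th$outlier %||% list()),
                                               names(formals(outlier_config)))]),
    error = function(e) { note(paste("outlier config:", conditionMessage(e))); NULL })
  variant <- config$t_test_variant %||% "welch"
  if (!variant %in% c("welch", "pooled")) {
    note(sprintf("unknown t_test_variant '%s'", variant))
  }
  if (length(errors)) {
    rlang::abort(paste0("invalid run configuration:\n",
                        paste("-", errors, collapse = "\n")),
                 class = "phenolprofiler_config_error", errors = errors)
  }
  structure(list(
    compound_tables = config$compound_tables,
    activity_table = config$activity_table,
    food_table = config$food_table,
    score_table = config$score_table,
    score_key = config$score_key %||% "name",
    output_dir = config$output_dir %||% "phenolprofiler_out",
    precedence = config$precedence %||% c("phytohub", "phenol_explorer", "chembl"),
    thresholds = thresholds, tier = tier, outlier = outl,
    t_test_variant = variant,
    replicate_agg = config$replicate_agg %||% "median",
    seed = as.integer(config$seed %||% 1L)
  ), class = "run_config")
}

config_hash <- function(config) {
  format(str_hash(paste(utils::capture.output(utils::str(unclass(config))),
                        collapse = "\n")),
         scientific = FALSE)
}

write_stage_csv <- function(x, out_dir, name) {
  readr::write_csv(x, file.path(out_dir, paste0(name, ".csv")))
}

#' Run the full characterization pipeline
#'
#' Executes the stages in order: compound registry (load, reconcile,
#' coverage, mass outliers), molecular descriptors with Ro5/Veber
#' compliance, drug-likeness (QED, external score ingestion, distribution
#' summaries, correlation matrix), bioactivity (filter, pChEMBL,
#' per-pair collapse, target summaries, class comparison), and food
#' mapping (standardization, per-pair statistics, totals, group profiles,
#' tiers). Stages whose inputs are absent are marked skipped; a failing
#' stage is recorded in the manifest and stages not depending on it still
#' run. All report tables are written as CSV under the configured output
#' directory next to a `manifest.json` recording package version, config
#' hash, and per-stage status and record counts.
#'
#' @param config A `run_config` from [validate_config()] (or a list /
#'   path accepted by it).
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_all <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool = "phenolprofiler",
    version = as.character(utils::packageVersion("phenolprofiler")),
    config_hash = config_hash(config),
    stages = list()
  )
  results <- list()
  mark <- function(stage, status, n_in = NA, n_out = NA, message = NULL) {
    manifest$stages[[stage]] <<- list(
      status = status, rows_in = n_in, rows_out = n_out,
      message = message %||% "")
  }
  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e) {
      mark(stage, "failed", message = conditionMessage(e))
      NULL
    })
  }

  # --- registry ---------------------------------------------------------
  records <- NULL
  if (length(config$compound_tables)) {
    records <- run_stage("registry", {
      tables <- lapply(config$compound_tables, function(ct) {
        load_compound_table(ct$path, ct$source_tag,
                            col_map = unlist(ct$col_map %||% NULL))
      })
      n_in <- sum(vapply(tables, nrow, integer(1)))
      rec <- reconcile(tables, precedence = config$precedence)
      cov_merged <- coverage_summary(rec)
      cov_raw <- coverage_summary(dplyr::bind_rows(tables))
      out <- rec
      out$sources <- vapply(out$sources, paste, character(1), collapse = ";")
      write_stage_csv(out, out_dir, "compounds_reconciled")
      write_stage_csv(cov_merged, out_dir, "coverage_summary")
      write_stage_csv(cov_raw, out_dir, "coverage_summary_premerge")
      write_stage_csv(reconcile_conflicts(rec), out_dir, "merge_conflicts")
      write_stage_csv(skeleton_matches(rec), out_dir, "skeleton_matches")
      mark("registry", "ok", n_in, nrow(rec))
      results$coverage <- cov_merged
      results$coverage_premerge <- cov_raw
      rec
    })
  } else {
    mark("registry", "skipped")
  }

  # --- descriptors ------------------------------------------------------
  desc <- NULL
  if (!is.null(records)) {
    desc <- run_stage("descriptors", {
      with_structure <- records[!is.na(records$smiles), ]
      d <- compute_descriptors(with_structure$smiles,
                               compound_id = with_structure$compound_id)
      d <- assess_compliance(d, config$thresholds)
      write_stage_csv(d, out_dir, "descriptors")
      # mass-outlier screen on computed weights
      mw <- stats::setNames(d$mw, d$compound_id)
      mw <- mw[!is.na(mw)]
      flagged <- suppressWarnings(
        flag_mass_outliers(records[records$compound_id %in% names(mw), ],
                           mw, config$outlier))
      write_stage_csv(flagged, out_dir, "mass_outliers")
      results$mass_outliers <- flagged
      mark("descriptors", "ok", nrow(with_structure), nrow(d))
      d
    })
  } else {
    mark("descriptors", "skipped")
  }

  # --- druglikeness -----------------------------------------------------
  if (!is.null(records)) {
    run_stage("druglikeness", {
      reg <- records
      if (!is.null(config$score_table)) {
        ing <- ingest_scores(reg, config$score_table, key = config$score_key)
        reg <- ing$records
        write_stage_csv(ing$unmatched, out_dir, "scores_unmatched")
      }
      dl <- druglikeness_table(reg)
      write_stage_csv(dl, out_dir, "druglikeness")
      cc <- dl[dl$complete_structure & !is.na(dl$qed), ]
      summaries <- list(qed = summarize_distribution(cc$qed))
      if (any(!is.na(dl$dw_score))) {
        summaries$dw <- summarize_distribution(dl$dw_score)
      }
      write_stage_csv(dplyr::bind_rows(summaries, .id = "metric"),
                      out_dir, "score_distributions")
      if (!is.null(desc)) {
        mtab <- dplyr::left_join(dl, desc[, c("compound_id", "mw", "logp",
                                              "hbd", "hba_lipinski", "tpsa")],
                                 by = "compound_id")
        cm <- correlation_matrix(mtab[, c("qed", "dw_score", "mw", "logp",
                                          "hbd", "hba_lipinski", "tpsa")])
        utils::write.csv(cm, file.path(out_dir, "correlation_matrix.csv"))
        results$correlations <- cm
      }
      # subclass profile table (per-subclass means of scores + descriptors)
      if (!is.null(desc)) {
        prof <- records[, c("compound_id", "subclass")] |>
          dplyr::inner_join(dl, by = "compound_id") |>
          dplyr::left_join(desc, by = "compound_id") |>
          dplyr::group_by(.data$subclass) |>
          dplyr::summarise(
            count = dplyr::n(),
            qed_mean = mean(.data$qed, na.rm = TRUE),
            qed_sd = stats::sd(.data$qed, na.rm = TRUE),
            dw_mean = mean(.data$dw_score, na.rm = TRUE),
            mw = mean(.data$mw, na.rm = TRUE),
            logp = mean(.data$logp, na.rm = TRUE),
            hbd = mean(.data$hbd, na.rm = TRUE),
            hba = mean(.data$hba_lipinski, na.rm = TRUE),
            tpsa = mean(.data$tpsa, na.rm = TRUE),
            .groups = "drop") |>
          dplyr::arrange(dplyr::desc(.data$qed_mean))
        write_stage_csv(prof, out_dir, "subclass_profiles")
        results$subclass_profiles <- prof
      }
      top10 <- dl |>
        dplyr::filter(!is.na(.data$qed)) |>
        dplyr::arrange(dplyr::desc(.data$qed)) |>
        utils::head(10) |>
        dplyr::left_join(records[, c("compound_id", "name", "smiles")],
                         by = "compound_id")
      write_stage_csv(top10, out_dir, "top_compounds_qed")
      results$druglikeness <- dl
      results$qed_summary <- summaries$qed
      mark("druglikeness", "ok", nrow(reg), nrow(dl))
    })
  } else {
    mark("druglikeness", "skipped")
  }

  # --- bioactivity ------------------------------------------------------
  if (!is.null(config$activity_table)) {
    run_stage("bioactivity", {
      raw <- readr::read_csv(config$activity_table, show_col_types = FALSE,
                             progress = FALSE)
      filt <- filter_records(raw)
      collapsed <- collapse_best(filt$records)
      write_stage_csv(collapsed, out_dir, "activities_collapsed")
      write_stage_csv(filt$rejections, out_dir, "activity_rejections")
      ts <- target_summaries(collapsed, by_class = TRUE)
      write_stage_csv(ts, out_dir, "target_summaries")
      comparison <- compare_classes(
        collapsed, var_equal = config$t_test_variant == "pooled")
      jsonlite::write_json(comparison,
                           file.path(out_dir, "class_comparison.json"),
                           auto_unbox = TRUE, digits = NA)
      results$bioactivity <- list(collapsed = collapsed,
                                   rejections = filt$rejections,
                                   target_summaries = ts,
                                   comparison = comparison)
      mark("bioactivity", "ok", filt$n_input, nrow(collapsed))
    })
  } else {
    mark("bioactivity", "skipped")
  }

  # --- food mapping -----------------------------------------------------
  if (!is.null(config$food_table)) {
    run_stage("food", {
      raw <- readr::read_csv(config$food_table, show_col_types = FALSE,
                             progress = FALSE)
      std <- standardize_food_records(raw)
      pairs <- per_pair_stats(std$records)
      totals <- food_totals(std$records, replicate_agg = config$replicate_agg)
      totals$tier <- tier_classify(totals$total, config$tier)
      profiles <- group_profiles(std$records,
                                 replicate_agg = config$replicate_agg)
      write_stage_csv(pairs, out_dir, "food_pair_stats")
      write_stage_csv(totals, out_dir, "food_totals")
      write_stage_csv(profiles, out_dir, "food_group_profiles")
      write_stage_csv(std$exclusions, out_dir, "food_exclusions")
      results$food <- list(pairs = pairs, totals = totals,
                            profiles = profiles,
                            exclusions = std$exclusions)
      mark("food", "ok", nrow(raw), nrow(std$records))
    })
  } else {
    mark("food", "skipped")
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

#' Presentation formatter for coverage percentages
#'
#' Rounds coverage percentages half-up to whole percent for display;
#' report CSVs keep full precision.
#'
#' @param coverage Output of [coverage_summary()].
#' @return The tibble with a formatted `pct_label` column appended.
#' @export
format_coverage <- function(coverage) {
  coverage$pct_label <- paste0(round_half_up(coverage$pct_with_registry), "%")
  coverage
}
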