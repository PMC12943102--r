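# Compound registry: loading, cross-database reconciliation by InChIKey,
# identifier-coverage summaries and mass-outlier screening.

INCHIKEY_PATTERN <- "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"

#' Default subclass taxonomy
#'
#' Declared mapping from polyphenol subclass labels to compound class
#' (flavonoid / phenolic acid / other). Users may extend or replace it
#' wherever a taxonomy argument is accepted.
#'
#' @return Tibble with columns `subclass`, `cls`.
#' @export
default_taxonomy <- function() {
  tibble::tribble(
    ~subclass,                ~cls,
    "flavonols",              "flavonoid",
    "flavones",               "flavonoid",
    "flavanones",             "flavonoid",
    "flavan-3-ols",           "flavonoid",
    "isoflavonoids",          "flavonoid",
    "isoflavones",            "flavonoid",
    "anthocyanins",           "flavonoid",
    "chalcones",              "flavonoid",
    "hydroxycinnamic acids",  "phenolic_acid",
    "hydroxybenzoic acids",   "phenolic_acid",
    "ellagitannins",          "other"
  )
}

schema_error <- function(column, path) {
  rlang::abort(
    sprintf("missing mandatory column '%s' in %s", column, path),
    class = "phenolprofiler_schema_error", column = column
  )
}

blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  trimws(x)
}

#' Load a compound table from a database extract
#'
#' Reads a delimited compound table (comma- or tab-separated, inferred
#' from the file extension) into a standardized compound record tibble.
#' Missing identifiers are stored as `NA`, never as empty strings; row
#' count is preserved. Compounds lacking both an InChIKey and a SMILES
#' keep a surrogate identifier and are excluded downstream from
#' structure-dependent stages.
#'
#' @param path File path of the extract.
#' @param source_tag Short tag naming the source database (e.g.
#'   `"phytohub"`).
#' @param col_map Named character vector mapping standard fields (`name`,
#'   `subclass`, `cls`, `inchikey`, `registry_number`, `smiles`) to file
#'   column names. Defaults to identity for whichever standard columns are
#'   present.
#' @param taxonomy Subclass taxonomy used to derive `cls` when absent.
#' @return Tibble of compound records with a `sources` list column.
#' @export
load_compound_table <- function(path, source_tag, col_map = NULL,
                                taxonomy = default_taxonomy()) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("cannot read compound table '%s'", path),
                 class = "phenolprofiler_io_error")
  }
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  std <- c("name", "subclass", "cls", "inchikey", "registry_number", "smiles")
  if (is.null(col_map)) {
    col_map <- setNames(intersect(std, names(raw)), intersect(std, names(raw)))
  }
  get_col <- function(field) {
    if (!field %in% names(col_map)) return(rep(NA_character_, nrow(raw)))
    cn <- col_map[[field]]
    if (!cn %in% names(raw)) schema_error(cn, path)
    blank_to_na(raw[[cn]])
  }
  name <- get_col("name")
  if (!"name" %in% names(col_map)) schema_error("name", path)
  subclass <- get_col("subclass")
  cls <- get_col("cls")
  if (!"subclass" %in% names(col_map) && !"cls" %in% names(col_map)) {
    schema_error("subclass", path)
  }
  if (all(is.na(cls))) {
    cls <- taxonomy$cls[match(subclass, taxonomy$subclass)]
    if (any(is.na(cls) & !is.na(subclass))) {
      rlang::warn(sprintf("%d rows with subclass outside the declared taxonomy; cls set to 'other'",
                          sum(is.na(cls) & !is.na(subclass))))
    }
    cls[is.na(cls)] <- "other"
  }
  inchikey <- get_col("inchikey")
  bad_key <- !is.na(inchikey) & !grepl(INCHIKEY_PATTERN, inchikey)
  if (any(bad_key)) {
    rlang::warn(sprintf("%d malformed InChIKey value(s) treated as absent",
                        sum(bad_key)))
    inchikey[bad_key] <- NA_character_
  }
  tibble::tibble(
    compound_id = paste0(source_tag, "-", sprintf("%04d", seq_len(nrow(raw)))),
    name = name,
    cls = cls,
    subclass = subclass,
    inchikey = inchikey,
    registry_number = get_col("registry_number"),
    smiles = get_col("smiles"),
    sources = lapply(seq_len(nrow(raw)), function(i) source_tag)
  )
}

#' Reconcile compound collections across sources
#'
#' Records sharing an identical full 27-character InChIKey are merged into
#' a single record whose `sources` is the union and whose fields are
#' filled by first-non-absent precedence over the configured source
#' order. Records lacking an InChIKey are kept unmerged under their
#' surrogate ids. Records sharing only the 14-character connectivity
#' block (stereo or protonation variants) are reported as skeleton
#' matches but never merged. Conflicting class or subclass labels for one
#' key produce conflict-report entries (the precedence source wins), not
#' an error.
#'
#' @param collections A list of compound record tibbles (each from one
#'   source) or a single combined tibble.
#' @param precedence Character vector of source tags, highest priority
#'   first.
#' @return The reconciled record tibble, with attributes `conflicts`
#'   (tibble of field-level disagreements) and `skeleton_matches`
#'   (tibble of connectivity-block matches). Accessors:
#'   [reconcile_conflicts()], [skeleton_matches()].
#' @export
reconcile <- function(collections,
                      precedence = c("phytohub", "phenol_explorer", "chembl")) {
  if (is.data.frame(collections)) collections <- list(collections)
  all_rec <- dplyr::bind_rows(collections)
  if (nrow(all_rec) == 0) {
    out <- all_rec
    attr(out, "conflicts") <- tibble::tibble(
      inchikey = character(0), field = character(0),
      values = character(0), chosen = character(0))
    attr(out, "skeleton_matches") <- tibble::tibble(
      skeleton = character(0), inchikeys = character(0))
    return(out)
  }
  prim <- vapply(all_rec$sources, function(s) s[[1]], character(1))
  prec_rank <- match(prim, precedence)
  prec_rank[is.na(prec_rank)] <- length(precedence) + 1L
  ord <- order(prec_rank, seq_len(nrow(all_rec)))
  all_rec <- all_rec[ord, ]

  conflicts <- list()
  keyed <- !is.na(all_rec$inchikey)
  merged <- list()
  for (key in unique(all_rec$inchikey[keyed])) {
    grp <- all_rec[keyed & all_rec$inchikey == key, ]
    rec <- grp[1, ]
    for (field in c("name", "cls", "subclass", "registry_number", "smiles")) {
      vals <- grp[[field]][!is.na(grp[[field]])]
      if (length(vals) == 0) next
      rec[[field]] <- vals[1]
      if (field %in% c("cls", "subclass") && length(unique(vals)) > 1) {
        conflicts[[length(conflicts) + 1L]] <- tibble::tibble(
          inchikey = key, field = field,
          values = paste(unique(vals), collapse = " / "),
          chosen = vals[1])
      }
    }
    rec$sources <- list(unique(unlist(grp$sources)))
    merged[[length(merged) + 1L]] <- rec
  }
  out <- dplyr::bind_rows(c(merged, list(all_rec[!keyed, ])))
  # restore a stable order: by first appearance of the key in the input
  out <- out[order(match(out$compound_id, all_rec$compound_id)), ]

  skel <- substr(out$inchikey[!is.na(out$inchikey)], 1, 14)
  dup_skel <- unique(skel[duplicated(skel)])
  skeleton <- if (length(dup_skel)) {
    dplyr::bind_rows(lapply(dup_skel, function(s) {
      keys <- out$inchikey[!is.na(out$inchikey) & substr(out$inchikey, 1, 14) == s]
      tibble::tibble(skeleton = s, inchikeys = paste(keys, collapse = ";"))
    }))
  } else {
    tibble::tibble(skeleton = character(0), inchikeys = character(0))
  }
  conf <- if (length(conflicts)) dplyr::bind_rows(conflicts) else
    tibble::tibble(inchikey = character(0), field = character(0),
                   values = character(0), chosen = character(0))
  for (i in seq_len(nrow(conf))) {
    rlang::inform(sprintf("merge conflict for %s: %s = %s (kept '%s')",
                          conf$inchikey[i], conf$field[i], conf$values[i],
                          conf$chosen[i]))
  }
  attr(out, "conflicts") <- conf
  attr(out, "skeleton_matches") <- skeleton
  out
}

#' @rdname reconcile
#' @param x A reconciled record tibble.
#' @export
reconcile_conflicts <- function(x) attr(x, "conflicts")

#' @rdname reconcile
#' @export
skeleton_matches <- function(x) attr(x, "skeleton_matches")

#' Identifier coverage per subclass
#'
#' For each subclass: the number of unique compounds (distinct InChIKey,
#' or surrogate id when the key is absent) and how many carry a molecular
#' registry number. Percentages are reported unrounded; rounding belongs
#' to the presentation layer.
#'
#' @param records Compound record tibble.
#' @return Tibble with `subclass`, `n_unique`, `n_with_registry`,
#'   `pct_with_registry`, sorted by `n_unique` descending.
#' @export
coverage_summary <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(subclass = character(0), n_unique = integer(0),
                          n_with_registry = integer(0),
                          pct_with_registry = numeric(0)))
  }
  key <- ifelse(is.na(records$inchikey), records$compound_id, records$inchikey)
  records$.key <- key
  records |>
    dplyr::group_by(subclass) |>
    dplyr::summarise(
      n_unique = dplyr::n_distinct(.data$.key),
      n_with_registry = dplyr::n_distinct(.data$.key[!is.na(.data$registry_number)]),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_with_registry = 100 * .data$n_with_registry / .data$n_unique) |>
    dplyr::arrange(dplyr::desc(.data$n_unique))
}

#' Outlier screening configuration
#'
#' @param z_threshold Absolute z-score above which a compound is flagged.
#' @param robust Use a 10%-trimmed mean and the SD of the trimmed sample
#'   as location/scale.
#' @param location,scale Optional fixed reference location/scale (e.g. a
#'   published subclass mean and SD); when supplied they are used for
#'   every record instead of leave-one-out estimates.
#' @return An `outlier_config` list.
#' @export
outlier_config <- function(z_threshold = 3, robust = FALSE,
                           location = NULL, scale = NULL) {
  stopifnot(z_threshold > 0)
  structure(list(z_threshold = z_threshold, robust = robust,
                 location = location, scale = scale),
            class = "outlier_config")
}

#' Flag molecular-weight outliers within subclasses
#'
#' Screens each subclass for compounds whose molecular weight deviates
#' from the subclass's typical range. By default location and scale are
#' estimated leave-one-out (each candidate excluded from its own
#' reference set, so a gross outlier cannot mask itself); a fixed
#' reference mean/SD can be supplied through [outlier_config()]. Flagged
#' compounds are reported, never dropped.
#'
#' @param records Compound record tibble.
#' @param mw_lookup Named numeric vector mapping `compound_id` to
#'   molecular weight (g/mol).
#' @param config An [outlier_config()].
#' @return Tibble with `compound_id`, `subclass`, `mw`, `z_score`,
#'   `flagged`. Subclasses with fewer than 3 records are skipped with a
#'   warning.
#' @export
flag_mass_outliers <- function(records, mw_lookup, config = outlier_config()) {
  out <- list()
  for (sc in unique(records$subclass)) {
    grp <- records[records$subclass == sc, ]
    if (nrow(grp) < 3) {
      rlang::warn(sprintf("subclass '%s' has fewer than 3 records; skipped", sc))
      next
    }
    mw <- mw_lookup[grp$compound_id]
    if (any(is.na(mw))) {
      rlang::abort(sprintf("missing molecular weight for %d record(s) in subclass '%s'",
                           sum(is.na(mw)), sc))
    }
    z <- vapply(seq_along(mw), function(i) {
      if (!is.null(config$location) && !is.null(config$scale)) {
        loc <- config$location; sc_ <- config$scale
      } else {
        ref <- mw[-i]
        if (config$robust) {
          loc <- mean(ref, trim = 0.1)
          q <- stats::quantile(ref, c(0.1, 0.9), names = FALSE)
          sc_ <- stats::sd(ref[ref >= q[1] & ref <= q[2]])
        } else {
          loc <- mean(ref); sc_ <- stats::sd(ref)
        }
      }
      if (is.na(sc_) || sc_ == 0) return(0)
      (mw[i] - loc) / sc_
    }, numeric(1))
    out[[length(out) + 1L]] <- tibble::tibble(
      compound_id = grp$compound_id, subclass = sc, mw = unname(mw),
      z_score = z, flagged = abs(z) > config$z_threshold)
  }
  if (length(out) == 0) {
    return(tibble::tibble(compound_id = character(0), subclass = character(0),
                          mw = numeric(0), z_score = numeric(0),
                          flagged = logical(0)))
  }
  dplyr::bind_rows(out)
}
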