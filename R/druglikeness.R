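# Drug-likeness scoring layer: per-compound score table assembly,
# ingestion of externally computed scores, distribution summaries and
# correlation matrices.

#' Ingest externally computed drug-likeness scores
#'
#' Left-joins a score file (keyed by compound name or InChIKey) onto a
#' compound registry. Unmatched score rows are reported; duplicated keys
#' keep the first occurrence and report the rest.
#'
#' @param records Compound record tibble (with `name` and `inchikey`).
#' @param path CSV/TSV file of scores.
#' @param key_col Column in the score file holding the join key.
#' @param score_col Column holding the numeric score.
#' @param key Which registry field the key matches: `"name"` or
#'   `"inchikey"`.
#' @return List with `records` (input plus `dw_score` column),
#'   `unmatched` (score rows that joined nothing), `duplicates` (dropped
#'   duplicate-key rows).
#' @export
ingest_scores <- function(records, path, key_col = "name",
                          score_col = "dw_score",
                          key = c("name", "inchikey")) {
  key <- match.arg(key)
  if (!file.exists(path)) {
    rlang::abort(sprintf("cannot read score file '%s'", path),
                 class = "phenolprofiler_io_error")
  }
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  sc <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  for (cn in c(key_col, score_col)) {
    if (!cn %in% names(sc)) schema_error(cn, path)
  }
  sc <- tibble::tibble(.key = blank_to_na(sc[[key_col]]),
                       dw_score = suppressWarnings(as.numeric(sc[[score_col]])))
  dup <- duplicated(sc$.key) & !is.na(sc$.key)
  duplicates <- sc[dup, ]
  if (any(dup)) {
    rlang::warn(sprintf("%d duplicated score key(s); first occurrence kept", sum(dup)))
  }
  sc <- sc[!dup & !is.na(sc$.key), ]
  reg_key <- records[[key]]
  records$dw_score <- sc$dw_score[match(reg_key, sc$.key)]
  unmatched <- sc[!sc$.key %in% reg_key, ]
  list(records = records, unmatched = unmatched, duplicates = duplicates)
}

#' Assemble the per-compound drug-likeness table
#'
#' Computes QED for every record with a parseable structure and carries
#' an optional external/fragment drug-likeness score column; the
#' `complete_structure` flag marks complete-case rows for
#' structure-dependent statistics.
#'
#' @param records Compound record tibble with a `smiles` column (and
#'   optionally `dw_score`).
#' @param weights QED weight variant, see [qed()].
#' @param fragment_table Optional [fragment_score_table()]; when supplied
#'   and no `dw_score` column exists, fragment-sum scores are computed
#'   for parseable structures.
#' @return Tibble with `compound_id`, `qed`, `dw_score`,
#'   `complete_structure`.
#' @export
druglikeness_table <- function(records, weights = "mean",
                               fragment_table = NULL) {
  qs <- qed_scores(records$smiles, compound_id = records$compound_id,
                   weights = weights)
  out <- tibble::tibble(
    compound_id = records$compound_id,
    qed = qs$qed,
    dw_score = if ("dw_score" %in% names(records)) records$dw_score else NA_real_,
    complete_structure = qs$complete_structure
  )
  if (!is.null(fragment_table) && all(is.na(out$dw_score))) {
    out$dw_score <- vapply(seq_len(nrow(records)), function(i) {
      if (!out$complete_structure[i]) return(NA_real_)
      suppressWarnings(fragment_sum_score(records$smiles[i], fragment_table)$score)
    }, numeric(1))
  }
  out
}

#' Distribution summary of a score vector
#'
#' n, mean, SD, median, quartiles (linear interpolation), extremes, and
#' the moment-based Fisher-Pearson skewness coefficient g1 (no
#' small-sample correction). A constant vector has undefined skewness,
#' reported as 0 with `skewness_defined = FALSE`.
#'
#' @param x Numeric scores; `NA`s are dropped (complete-case).
#' @return One-row tibble.
#' @export
summarize_distribution <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    rlang::abort("cannot summarize an empty score vector",
                 class = "phenolprofiler_empty_error")
  }
  n <- length(x)
  m <- mean(x)
  s <- if (n > 1) stats::sd(x) else 0
  if (is.na(s)) s <- 0
  skew_defined <- s > 0
  g1 <- if (skew_defined) {
    m3 <- mean((x - m)^3)
    m2 <- mean((x - m)^2)
    m3 / m2^1.5
  } else 0
  tibble::tibble(
    n = n, mean = m, sd = s,
    median = stats::median(x),
    q1 = stats::quantile(x, 0.25, names = FALSE),
    q3 = stats::quantile(x, 0.75, names = FALSE),
    min = min(x), max = max(x),
    skewness = g1, skewness_defined = skew_defined
  )
}

#' Pairwise-complete Pearson correlation matrix
#'
#' Pearson correlations between metric columns using pairwise complete
#' cases; pairs with fewer than 2 complete observations yield `NA` and
#' are reported. The diagonal is exactly 1 and the matrix symmetric.
#'
#' @param table Data frame of numeric metric columns.
#' @return Matrix of correlations with an `insufficient_pairs` attribute
#'   listing pairs that could not be computed.
#' @export
correlation_matrix <- function(table) {
  table <- as.data.frame(table)
  num <- vapply(table, is.numeric, logical(1))
  table <- table[num]
  k <- ncol(table)
  if (k < 2) rlang::abort("need at least two numeric columns")
  out <- matrix(NA_real_, k, k, dimnames = list(names(table), names(table)))
  insufficient <- character(0)
  for (i in seq_len(k)) {
    out[i, i] <- 1
    for (j in seq_len(k)) {
      if (j <= i) next
      ok <- stats::complete.cases(table[[i]], table[[j]])
      if (sum(ok) < 2) {
        insufficient <- c(insufficient, paste(names(table)[i], names(table)[j], sep = "~"))
        next
      }
      r <- stats::cor(table[[i]][ok], table[[j]][ok])
      out[i, j] <- r
      out[j, i] <- r
    }
  }
  attr(out, "insufficient_pairs") <- insufficient
  out
}
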