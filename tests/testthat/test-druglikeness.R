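test_that("distribution summaries report the standard statistics", {
  s <- summarize_distribution(c(1, 2, 3, 4))
  expect_equal(s$mean, 2.5)
  expect_equal(s$median, 2.5)
  expect_equal(s$n, 4)
  expect_true(s$min <= s$q1 && s$q1 <= s$median &&
                s$median <= s$q3 && s$q3 <= s$max)

  const <- summarize_distribution(rep(5, 10))
  expect_equal(const$sd, 0)
  expect_equal(const$skewness, 0)
  expect_false(const$skewness_defined)

  expect_error(summarize_distribution(c(NA_real_, NA_real_)),
               class = "phenolprofiler_empty_error")
})

test_that("moment skewness matches an independent implementation", {
  set.seed(31)
  x <- rlnorm(500)
  expect_equal(summarize_distribution(x)$skewness,
               e1071::skewness(x, type = 1), tolerance = 1e-12)
})

test_that("summaries recover generative moments at n = 1000", {
  set.seed(202)
  mu <- 0.48; sigma <- 0.24; n <- 1000
  s <- summarize_distribution(rnorm(n, mu, sigma))
  expect_lt(abs(s$mean - mu), 3 * sigma / sqrt(n))
  expect_lt(abs(s$sd - sigma), 3 * sigma / sqrt(2 * n))
})

test_that("correlation matrix is exact against brute-force covariance", {
  set.seed(8)
  tab <- tibble::tibble(x = rnorm(10), y = rnorm(10), z = rnorm(10))
  cm <- correlation_matrix(tab)
  expect_equal(diag(cm), c(x = 1, y = 1, z = 1))
  expect_equal(cm, t(cm))
  brute <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  expect_equal(cm["x", "y"], brute(tab$x, tab$y), tolerance = 1e-12)
  expect_equal(cm["x", "z"], brute(tab$x, tab$z), tolerance = 1e-12)

  expect_equal(correlation_matrix(tibble::tibble(a = tab$x, b = -tab$x))["a", "b"], -1)
})

test_that("pairs with too few complete cases are reported, not guessed", {
  tab <- tibble::tibble(x = c(1, 2, 3, 4), y = c(1, NA, NA, NA), z = c(4, 3, 2, 1))
  cm <- correlation_matrix(tab)
  expect_true(is.na(cm["x", "y"]))
  expect_equal(attr(cm, "insufficient_pairs"), c("x~y", "y~z"))
  expect_equal(cm["x", "z"], -1)
})

test_that("external score ingestion joins, reports and deduplicates", {
  reg <- tibble::tibble(
    compound_id = c("c1", "c2", "c3"),
    name = c("quercetin", "naringenin", "unknown thing"),
    inchikey = NA_character_)
  f <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    name = c("quercetin", "naringenin", "quercetin", "not in registry"),
    dw_score = c(-1.2, 0.8, -9, 2.5)), f)
  expect_warning(out <- ingest_scores(reg, f), "duplicated")
  expect_equal(out$records$dw_score, c(-1.2, 0.8, NA))
  expect_equal(nrow(out$duplicates), 1)
  expect_equal(out$unmatched$.key, "not in registry")

  # empty score file -> every score absent
  f2 <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(name = character(0), dw_score = numeric(0)), f2)
  out2 <- ingest_scores(reg, f2)
  expect_true(all(is.na(out2$records$dw_score)))
})

test_that("fragment-sum scoring normalizes by the root of the match count", {
  # exactly one matched occurrence with contribution 2
  tab1 <- fragment_score_table("carbonyl", 2.0)
  r1 <- fragment_sum_score(ref_smiles("naringenin"), tab1)
  expect_equal(r1$score, 2.0)
  expect_equal(r1$n_matched, 1L)

  # naringenin: 3 phenols + 1 carbonyl = 4 occurrences, each worth 1
  tab4 <- fragment_score_table(c("phenol", "carbonyl"), c(1, 1))
  r4 <- fragment_sum_score(ref_smiles("naringenin"), tab4)
  expect_equal(r4$n_matched, 4L)
  expect_equal(r4$score, 4 / sqrt(4))

  # no match scores zero with a warning flag
  expect_warning(r0 <- fragment_sum_score("C", tab4), "no fragment")
  expect_equal(r0$score, 0)
  expect_true(r0$no_match)

  # invalid patterns fail at table construction, not scoring
  expect_error(fragment_score_table("made_up_group", 1),
               class = "phenolprofiler_table_error")
  expect_error(fragment_score_table(c("phenol", "phenol"), c(1, 2)),
               class = "phenolprofiler_table_error")
  expect_error(fragment_score_table("phenol", Inf),
               class = "phenolprofiler_table_error")
})

test_that("druglikeness table flags complete cases and carries both scores", {
  rec <- tibble::tibble(
    compound_id = c("a", "b"),
    smiles = c(ref_smiles("naringenin"), NA),
    dw_score = c(0.4, -1))
  dl <- druglikeness_table(rec)
  expect_equal(dl$complete_structure, c(TRUE, FALSE))
  expect_true(is.na(dl$qed[2]) && !is.na(dl$qed[1]))
  expect_equal(dl$dw_score, c(0.4, -1))

  # fragment table path when no external scores exist
  dl2 <- druglikeness_table(rec[, c("compound_id", "smiles")],
                            fragment_table = default_fragment_table())
  expect_false(is.na(dl2$dw_score[1]))
  expect_true(is.na(dl2$dw_score[2]))
})
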