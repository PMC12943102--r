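test_that("pChEMBL conversion matches hand-computed logarithms exactly", {
  expect_equal(to_pchembl(1, "uM"), 6)
  expect_equal(to_pchembl(10, "nM"), 8)
  expect_equal(to_pchembl(100, "nM"), 7)
  expect_equal(to_pchembl(1, "nM"), 9)
  expect_equal(to_pchembl(50, "uM"), -log10(50e-6))
  # grid of hand values
  vals <- c(0.5, 3, 42, 999)
  expect_equal(to_pchembl(vals, "nM"), -log10(vals * 1e-9))
  expect_equal(to_pchembl(vals, "uM"), -log10(vals * 1e-6))
  expect_error(to_pchembl(-1, "nM"))
  expect_error(to_pchembl(1, "mM"))
})

test_that("nM and uM conversions are mutually consistent", {
  set.seed(7)
  x <- 10^runif(50, -2, 5)
  expect_identical(to_pchembl(x, "nM"), to_pchembl(x / 1000, "uM"))
})

test_that("the three inclusion criteria filter a toy table as enumerated", {
  raw <- toy_activity_table()
  # by hand: row 2 fails type, row 4 fails relationship, row 5 fails units
  out <- filter_records(raw)
  expect_equal(out$n_retained, 3)
  expect_equal(out$records$compound_id, c("c1", "c2", "c5"))
  rej <- setNames(out$rejections$n_excluded, out$rejections$criterion)
  expect_equal(unname(rej["target_relationship"]), 1)
  expect_equal(unname(rej["activity_type"]), 1)
  expect_equal(unname(rej["value_units"]), 1)
  expect_equal(out$records$pchembl,
               c(-log10(100e-9), -log10(2e-6), -log10(5e-9)))
})

test_that("collapse keeps the strongest assay per pair, ties to first row", {
  rec <- tibble::tibble(
    compound_id = "c1", cls = "flavonoid", target_id = "t1",
    target_name = "t", target_class = "k",
    activity_type = "IC50", value = 1, units = "nM",
    relationship = "direct", pchembl = c(6.2, 7.4))
  expect_equal(collapse_best(rec)$pchembl, 7.4)
  one <- rec[1, ]
  expect_equal(collapse_best(one), one)

  tie <- rec; tie$pchembl <- c(7, 7); tie$value <- c(100, 200)
  expect_equal(collapse_best(tie)$value, 100)
})

test_that("collapse and target summaries match brute-force groupby", {
  set.seed(123)
  fx <- tibble::tibble(
    compound_id = sample(paste0("c", 1:5), 45, replace = TRUE),
    cls = "flavonoid",
    target_id = sample(paste0("t", 1:4), 45, replace = TRUE),
    activity_type = "Ki", value = 1, units = "nM", relationship = "direct",
    pchembl = round(runif(45, 5, 10), 3))
  fx$target_name <- paste0("protein ", fx$target_id)
  fx$target_class <- "kinase"
  coll <- collapse_best(fx)
  # brute force with tapply
  brute <- tapply(fx$pchembl, paste(fx$compound_id, fx$target_id), max)
  expect_equal(nrow(coll), length(brute))
  got <- setNames(coll$pchembl, paste(coll$compound_id, coll$target_id))
  expect_equal(got[names(brute)], c(brute))

  ts <- target_summaries(coll)
  for (t in unique(coll$target_id)) {
    sub <- coll[coll$target_id == t, ]
    row <- ts[ts$target_id == t, ]
    expect_equal(row$count, length(unique(sub$compound_id)))
    expect_equal(row$mean, mean(sub$pchembl))
    expect_equal(row$max, max(sub$pchembl))
    expect_gte(row$max, row$mean)
  }
  expect_true(all(diff(ts$mean) <= 0))  # sorted by mean descending

  single <- target_summaries(coll[1, ])
  expect_equal(single$count, 1)
  expect_equal(single$mean, single$max)
})

test_that("class comparison runs Welch by default with diversity counts", {
  rec <- tibble::tibble(
    cls = rep(c("flavonoid", "phenolic_acid"), each = 6),
    target_id = c(paste0("ft", 1:4), "sh1", "sh2", paste0("pt", 1:4), "sh1", "sh2"),
    pchembl = c(7.1, 7.4, 8.0, 6.8, 7.7, 7.2, 6.5, 6.9, 7.0, 6.6, 6.8, 7.1))
  cmp <- compare_classes(rec)
  expect_equal(unname(cmp$target_diversity), c(6, 6))
  expect_equal(cmp$variant, "welch")
  expect_true(cmp$p_value > 0 && cmp$p_value <= 1)

  # identical samples give t = 0, p = 1
  same <- tibble::tibble(cls = rep(c("flavonoid", "phenolic_acid"), each = 4),
                         target_id = "t", pchembl = rep(c(6, 7, 8, 9), 2))
  cmp0 <- compare_classes(same)
  expect_equal(cmp0$t_statistic, 0)
  expect_equal(cmp0$p_value, 1)

  expect_error(compare_classes(rec[rec$cls == "flavonoid", ]),
               regexp = "phenolic_acid")
})

test_that("Welch equals the pooled test on equal-variance equal-n data", {
  set.seed(99)
  rec <- tibble::tibble(
    cls = rep(c("flavonoid", "phenolic_acid"), each = 30),
    target_id = "t",
    pchembl = c(rnorm(30, 7, 1), rnorm(30, 6.8, 1)))
  # force exactly equal sample variances by standardizing each group
  x <- rec$pchembl[1:30]; y <- rec$pchembl[31:60]
  rec$pchembl <- c((x - mean(x)) / sd(x) + 7, (y - mean(y)) / sd(y) + 6.8)
  w <- compare_classes(rec, var_equal = FALSE)
  p <- compare_classes(rec, var_equal = TRUE)
  expect_equal(w$t_statistic, p$t_statistic, tolerance = 1e-10)
  expect_equal(w$p_value, p$p_value, tolerance = 1e-8)
})
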