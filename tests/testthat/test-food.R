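test_that("concentration standardization applies the x10 rule and excludes junk", {
  out <- standardize_concentration(c(450, 120, 0, "trace", 5, -1),
                                   c("mg/100g", "mg/kg", "mg/100g", "mg/kg",
                                     "ppm", "mg/kg"))
  expect_equal(out$mg_per_kg[1], 4500)
  expect_equal(out$mg_per_kg[2], 120)
  expect_equal(out$mg_per_kg[3], 0)
  expect_true(out$zero_flag[3])
  expect_true(out$excluded[4]); expect_equal(out$reason[4], "non_quantifiable_value")
  expect_true(out$excluded[5]); expect_equal(out$reason[5], "unknown_unit")
  expect_true(out$excluded[6]); expect_equal(out$reason[6], "negative_value")
})

test_that("per-pair statistics use interpolated medians", {
  rec <- tibble::tibble(
    compound_id = c(rep("a", 3), rep("b", 4), "c"),
    compound_name = c(rep("A", 3), rep("B", 4), "C"),
    food_name = "apple", food_group = "fruits",
    concentration = c(10, 20, 30, 1, 2, 3, 4, 7))
  st <- per_pair_stats(rec)
  a <- st[st$compound_id == "a", ]
  expect_equal(c(a$min, a$median, a$max), c(10, 20, 30))
  expect_equal(st$median[st$compound_id == "b"], 2.5)
  cc <- st[st$compound_id == "c", ]
  expect_equal(c(cc$min, cc$median, cc$max), c(7, 7, 7))
})

test_that("food totals are hand-checkable sums with descending ranks", {
  rec <- tibble::tibble(
    compound_id = c("q", "k", "q", "g", "q"),
    compound_name = c("quercetin", "kaempferol", "quercetin", "gallic", "quercetin"),
    food_name = c("evening primrose", "evening primrose", "grape", "grape", "walnut"),
    food_group = c("herbs and spices", "herbs and spices", "fruits", "fruits",
                   "nuts and seeds"),
    concentration = c(14000, 500, 3000, 1500, 1500))
  tot <- food_totals(rec)
  expect_equal(tot$total[tot$food_name == "evening primrose"], 14500)
  expect_equal(tot$rank[tot$food_name == "evening primrose"], 1)
  expect_equal(tot$total[tot$food_name == "grape"], 4500)
  expect_equal(tot$total[tot$food_name == "walnut"], 1500)
  # replicate measurements enter through the median by default
  rep_rec <- dplyr::bind_rows(rec, tibble::tibble(
    compound_id = "q", compound_name = "quercetin", food_name = "walnut",
    food_group = "nuts and seeds", concentration = 2500))
  tot2 <- food_totals(rep_rec)
  expect_equal(tot2$total[tot2$food_name == "walnut"], 2000)
  tot3 <- food_totals(rep_rec, replicate_agg = "max")
  expect_equal(tot3$total[tot3$food_name == "walnut"], 2500)
})

test_that("tier classification respects the printed boundaries", {
  expect_equal(as.character(tier_classify(c(14500, 9000, 7500, 7200))),
               rep("high", 4))
  expect_equal(as.character(tier_classify(4500)), "medium")
  expect_equal(as.character(tier_classify(1500)), "lower")
  # boundary convention: 7000 exactly is medium, 2000 medium, 500 lower
  expect_equal(as.character(tier_classify(c(7000, 2000, 500, 499.99, 0))),
               c("medium", "medium", "lower", "below_range", "below_range"))
  # monotone non-decreasing in total
  x <- sort(runif(100, 0, 16000))
  expect_true(all(diff(as.integer(tier_classify(x))) >= 0))
})

test_that("group profiles recover the primary compound and its share", {
  rec <- tibble::tibble(
    compound_id = c("q", "q", "k", "g"),
    compound_name = c("quercetin", "quercetin", "kaempferol", "gallic acid"),
    food_name = c("primrose", "hyssop", "primrose", "hyssop"),
    food_group = "herbs and spices",
    concentration = c(3000, 2000, 4000, 1000))
  gp <- group_profiles(rec)
  expect_equal(gp$n_compounds, 3)
  expect_equal(gp$total, 10000)
  # quercetin summed across foods (5000) beats kaempferol's single 4000
  expect_equal(gp$primary_compound, "quercetin")
  expect_equal(gp$primary_pct, 50)

  solo <- rec[1, ]
  gp1 <- group_profiles(solo)
  expect_equal(gp1$primary_pct, 100)

  # lexicographic tie-break is reported
  tie <- tibble::tibble(
    compound_id = c("a", "b"), compound_name = c("bcomp", "acomp"),
    food_name = "x", food_group = "teas", concentration = c(5, 5))
  expect_message(gpt <- group_profiles(tie), "tie")
  expect_equal(gpt$primary_compound, "acomp")
  expect_true(gpt$primary_tie)
})

test_that("group totals conserve the standardized mass", {
  cfg <- small_config(seed = 21)
  comp <- generate_compounds(cfg)
  food <- generate_foods(cfg, comp$compounds)
  std <- suppressWarnings(standardize_food_records(food$foods))
  gp <- group_profiles(std$records)
  # single measurement per (compound, food): totals must conserve the sum
  expect_equal(sum(gp$total), sum(std$records$concentration), tolerance = 1e-9)
  # brute-force check of every primary percentage
  for (g in gp$food_group) {
    sub <- std$records[std$records$food_group == g, ]
    contrib <- tapply(sub$concentration, sub$compound_name, sum)
    expect_equal(gp$primary_pct[gp$food_group == g],
                 100 * max(contrib) / sum(contrib), tolerance = 1e-9)
  }
})
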