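test_that("generation is deterministic and unique under a fixed seed", {
  cfg <- small_config(seed = 17)
  a <- generate_compounds(cfg)
  b <- generate_compounds(cfg)
  expect_identical(a, b)
  expect_equal(anyDuplicated(a$compounds$inchikey), 0)
  expect_equal(anyDuplicated(vapply(a$compounds$smiles,
                                    function(s) mol_hash(parse_smiles(s)),
                                    character(1))), 0)
  # byte-identical files on disk
  d1 <- tempfile(); d2 <- tempfile()
  write_synthetic_run(cfg, d1); write_synthetic_run(cfg, d2)
  for (f in c("compounds.csv", "activities.csv", "foods.csv",
              "ground_truth.json")) {
    expect_identical(readLines(file.path(d1, "run_seed17", f)),
                     readLines(file.path(d2, "run_seed17", f)),
                     label = f)
  }
})

test_that("every generated structure parses and matches its subclass chemistry", {
  cfg <- small_config(seed = 23)
  comp <- generate_compounds(cfg)$compounds
  for (i in seq_len(nrow(comp))) {
    m <- parse_smiles(comp$smiles[i])
    expect_equal(mol_hash(m), mol_hash(parse_smiles(comp$smiles[i])))
    expect_match(comp$inchikey[i], "^[A-Z]{14}-[A-Z]{10}-[A-Z]$")
  }
  # anthocyanins are cations, phenolic acids carry a carboxyl group
  antho <- comp[comp$subclass == "anthocyanins", ]
  expect_true(all(vapply(antho$smiles, function(s)
    sum(parse_smiles(s)$atoms$charge) == 1, logical(1))))
  acids <- comp[comp$cls == "phenolic_acid" & !comp$true_heavy, ]
  expect_true(all(grepl("O=C\\(O\\)", acids$smiles)))
})

test_that("empty requests give empty tables", {
  cfg <- synthesis_config(n_flavonoids = 0, n_phenolic_acids = 0,
                          misclass_n = 0, seed = 1)
  comp <- generate_compounds(cfg)
  expect_equal(nrow(comp$compounds), 0)
})

test_that("unknown scaffolds raise a generation error naming the scaffold", {
  expect_error(phenolprofiler:::build_structure("sesquiterpenes", list()),
               class = "phenolprofiler_generation_error",
               regexp = "sesquiterpenes")
})

test_that("registry coverage lands inside the binomial interval", {
  cfg <- synthesis_config(
    n_flavonoids = 50, n_phenolic_acids = 0, misclass_n = 0,
    subclass_proportions = c(flavonols = 1), seed = 29)
  comp <- generate_compounds(cfg)$compounds
  phat <- mean(!is.na(comp$registry_number))
  half <- 1.96 * sqrt(0.58 * 0.42 / 50)
  expect_gte(phat, 0.58 - half)
  expect_lte(phat, 0.58 + half)
})

test_that("activity draws respect the truncation bounds and ground truth", {
  cfg <- small_config(seed = 37)
  comp <- generate_compounds(cfg)
  act <- generate_activities(cfg, comp$compounds)
  tab <- act$activities
  clean <- tab[is.na(tab$violates), ]
  expect_true(all(clean$true_pchembl[clean$cls == "flavonoid"] >= 6.01))
  expect_true(all(clean$true_pchembl[clean$cls == "flavonoid"] <= 9.70))
  expect_true(all(clean$true_pchembl[clean$cls == "phenolic_acid"] <= 9.00))
  # back-conversion is exact: recomputed pChEMBL equals the generative draw
  filt <- filter_records(tab)
  expect_equal(filt$records$pchembl, filt$records$true_pchembl,
               tolerance = 1e-9)
})

test_that("filter bookkeeping matches the violating fraction exactly", {
  cfg <- synthesis_config(
    n_flavonoids = 30, n_phenolic_acids = 15,
    n_activities = c(flavonoid = 49, phenolic_acid = 21),
    redundant_assay_fraction = 0, violation_fraction = 0.3, seed = 41)
  comp <- generate_compounds(cfg)
  act <- generate_activities(cfg, comp$compounds)
  expect_equal(nrow(act$activities), 100)
  expect_equal(act$truth$n_clean, 70)
  expect_equal(act$truth$n_violating, 30)
  filt <- filter_records(act$activities)
  expect_equal(filt$n_retained, 70)
  expect_setequal(filt$records$record_id,
                  act$activities$record_id[is.na(act$activities$violates)])
})

test_that("collapse recovers the constructed per-pair maxima and diversity", {
  cfg <- small_config(seed = 43)
  comp <- generate_compounds(cfg)
  act <- generate_activities(cfg, comp$compounds)
  coll <- collapse_best(filter_records(act$activities)$records)
  expect_equal(nrow(coll), sum(unlist(act$truth$n_pairs)))
  div <- coll |>
    dplyr::group_by(cls) |>
    dplyr::summarise(k = dplyr::n_distinct(target_id))
  expect_equal(setNames(div$k, div$cls),
               unlist(act$truth$target_diversity)[div$cls])
  # shared targets appear in both classes
  shared <- intersect(coll$target_id[coll$cls == "flavonoid"],
                      coll$target_id[coll$cls == "phenolic_acid"])
  expect_length(shared, 3)
})

test_that("food construction hits its tier targets and dominant-compound share", {
  cfg <- small_config(seed = 47)
  comp <- generate_compounds(cfg)
  food <- generate_foods(cfg, comp$compounds)
  std <- suppressWarnings(standardize_food_records(food$foods))
  expect_equal(nrow(std$exclusions), food$truth$n_trace)
  tot <- food_totals(std$records)
  for (fn in names(food$truth$foods)) {
    expect_equal(as.character(tier_classify(tot$total[tot$food_name == fn])),
                 food$truth$foods[[fn]]$tier, label = fn)
  }
  gp <- group_profiles(std$records)
  bev <- gp[gp$food_group == "beverages (non-tea)", ]
  expect_gt(bev$primary_pct, 90)
  expect_equal(bev$primary_compound,
               food$truth$groups[["beverages (non-tea)"]]$primary_compound)
})
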