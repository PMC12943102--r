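test_that("loading preserves rows and records absent identifiers as NA", {
  tab <- tibble::tibble(
    name = c("a", "b", "c"),
    subclass = c("flavonols", "flavones", "flavonols"),
    inchikey = c(paste0(strrep("Q", 14), "-", strrep("Q", 10), "-N"), "", NA),
    registry_number = c("1", "", "3"),
    smiles = c("CCO", NA, "")
  )
  rec <- load_compound_table(write_compound_fixture(tab), "phytohub")
  expect_equal(nrow(rec), 3)
  expect_true(all(vapply(rec$sources, identical, logical(1), "phytohub")))
  expect_true(is.na(rec$inchikey[2]))
  expect_true(is.na(rec$registry_number[2]))
  expect_true(is.na(rec$smiles[3]))
  expect_equal(rec$cls, c("flavonoid", "flavonoid", "flavonoid"))
})

test_that("missing mandatory columns raise schema errors naming the column", {
  tab <- tibble::tibble(name = "x", inchikey = NA_character_)
  expect_error(load_compound_table(write_compound_fixture(tab), "s"),
               class = "phenolprofiler_schema_error", regexp = "subclass")
  tab2 <- tibble::tibble(subclass = "flavonols")
  expect_error(load_compound_table(write_compound_fixture(tab2), "s"),
               class = "phenolprofiler_schema_error", regexp = "name")
  expect_error(load_compound_table(tempfile(), "s"),
               class = "phenolprofiler_io_error")
})

test_that("malformed InChIKeys are treated as absent with a warning", {
  tab <- tibble::tibble(name = "x", subclass = "flavonols",
                        inchikey = "not-a-key")
  expect_warning(rec <- load_compound_table(write_compound_fixture(tab), "s"),
                 "malformed")
  expect_true(is.na(rec$inchikey))
})

test_that("reconciliation merges identical keys and reports conflicts", {
  fx <- two_source_fixture()
  rec <- suppressMessages(reconcile(fx))
  # 4 input records: one full-key merge -> 3 output records
  expect_equal(nrow(rec), 3)
  merged <- rec[!is.na(rec$inchikey) & startsWith(rec$inchikey, "AAAA"), ]
  expect_equal(sort(unlist(merged$sources)), c("phenol_explorer", "phytohub"))
  # precedence: phytohub name wins; phenol-explorer fills the gaps
  expect_equal(merged$name, "compound one")
  expect_equal(merged$subclass, "flavonols")
  expect_equal(merged$registry_number, "222")
  expect_false(is.na(merged$smiles))
  # exactly one subclass conflict recorded, phytohub's label chosen
  conf <- reconcile_conflicts(rec)
  expect_equal(nrow(conf), 1)
  expect_equal(conf$field, "subclass")
  expect_equal(conf$chosen, "flavonols")
  # record without a key survives unmerged
  expect_true(any(is.na(rec$inchikey)))
})

test_that("disjoint keys concatenate without merging", {
  a <- tibble::tibble(name = "a", subclass = "flavonols",
                      inchikey = paste0(strrep("C", 14), "-", strrep("C", 10), "-N"))
  b <- tibble::tibble(name = "b", subclass = "flavones",
                      inchikey = paste0(strrep("D", 14), "-", strrep("D", 10), "-N"))
  rec <- reconcile(list(
    load_compound_table(write_compound_fixture(a), "phytohub"),
    load_compound_table(write_compound_fixture(b), "chembl")))
  expect_equal(nrow(rec), 2)
  expect_equal(nrow(reconcile_conflicts(rec)), 0)
})

test_that("reconciliation is idempotent and order-insensitive", {
  fx <- two_source_fixture()
  once <- suppressMessages(reconcile(fx))
  twice <- suppressMessages(reconcile(once))
  expect_equal(tibble::as_tibble(once), tibble::as_tibble(twice),
               ignore_attr = TRUE)
  swapped <- suppressMessages(reconcile(rev(fx)))
  key_once <- ifelse(is.na(once$inchikey), once$name, once$inchikey)
  key_swap <- ifelse(is.na(swapped$inchikey), swapped$name, swapped$inchikey)
  expect_setequal(key_once, key_swap)
  m1 <- once[match(sort(key_once), key_once), ]
  m2 <- swapped[match(sort(key_once), key_swap), ]
  expect_equal(m1$subclass, m2$subclass)  # precedence fixed regardless of order
  expect_equal(lapply(m1$sources, sort), lapply(m2$sources, sort))
})

test_that("skeleton matches are reported but not merged", {
  a <- tibble::tibble(name = c("stereo1", "stereo2"),
                      subclass = c("flavanones", "flavanones"),
                      inchikey = c(paste0(strrep("E", 14), "-", strrep("A", 10), "-N"),
                                   paste0(strrep("E", 14), "-", strrep("B", 10), "-N")))
  rec <- reconcile(list(load_compound_table(write_compound_fixture(a), "phytohub")))
  expect_equal(nrow(rec), 2)
  sk <- skeleton_matches(rec)
  expect_equal(nrow(sk), 1)
  expect_equal(sk$skeleton, strrep("E", 14))
})

test_that("coverage summary computes unrounded percentages", {
  # the flavonol census case: 324 unique compounds, 187 with registry ids
  rec <- tibble::tibble(
    compound_id = sprintf("c%03d", 1:324),
    subclass = "flavonols",
    inchikey = vapply(1:324, function(i)
      paste0(sprintf("%014d", i), "-", strrep("A", 10), "-N"), character(1)),
    registry_number = c(sprintf("%d", 1:187), rep(NA, 137))
  )
  rec$inchikey <- gsub("[0-9]", "B", rec$inchikey)
  rec$inchikey <- NA_character_  # fall back to surrogate ids: still 324 unique
  cov <- coverage_summary(rec)
  expect_equal(cov$n_unique, 324)
  expect_equal(cov$n_with_registry, 187)
  expect_equal(cov$pct_with_registry, 100 * 187 / 324, tolerance = 1e-9)
  expect_equal(round(cov$pct_with_registry), 58)

  # inverting a printed 71% coverage for 89 anthocyanins gives 63 compounds
  expect_equal(round(0.71 * 89), 63)

  expect_equal(nrow(coverage_summary(rec[0, ])), 0)
})

test_that("unique-compound counts partition across subclasses", {
  cfg <- small_config(seed = 5)
  comp <- generate_compounds(cfg)$compounds
  cov <- coverage_summary(comp)
  key <- ifelse(is.na(comp$inchikey), comp$compound_id, comp$inchikey)
  expect_equal(sum(cov$n_unique), length(unique(key)))
})

test_that("mass outliers are flagged against a fixed reference or leave-one-out", {
  # fixed published-style reference: mean 357.41, SD 176.96
  rec <- tibble::tibble(
    compound_id = c("puni", "sang", "lamb", "plain"),
    subclass = "hydroxybenzoic acids")
  mw <- c(puni = 1084.72, sang = 1871.28, lamb = 2805.91, plain = 357.41)
  res <- flag_mass_outliers(rec, mw,
                            outlier_config(location = 357.41, scale = 176.96))
  expect_equal(res$z_score[res$compound_id == "puni"],
               (1084.72 - 357.41) / 176.96, tolerance = 1e-9)
  expect_equal(res$z_score[res$compound_id == "puni"], 4.11, tolerance = 1e-2)
  expect_equal(res$flagged, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(res$z_score[res$compound_id == "plain"], 0)

  # leave-one-out: a gross outlier cannot mask itself
  rec2 <- tibble::tibble(compound_id = sprintf("c%d", 1:12),
                         subclass = "hydroxybenzoic acids")
  mw2 <- setNames(c(rnorm(11, 350, 40), 2800), rec2$compound_id)
  set.seed(1)
  res2 <- flag_mass_outliers(rec2, mw2, outlier_config())
  expect_true(res2$flagged[res2$compound_id == "c12"])
  expect_false(any(res2$flagged[res2$compound_id != "c12"]))

  # tiny subclasses are skipped with a warning
  expect_warning(
    out <- flag_mass_outliers(
      tibble::tibble(compound_id = c("a", "b"), subclass = "chalcones"),
      c(a = 200, b = 300), outlier_config()),
    "fewer than 3")
  expect_equal(nrow(out), 0)
})
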