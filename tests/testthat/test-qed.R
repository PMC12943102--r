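# QED from first principles. Frozen expected scores were computed with an
# independent reference implementation (RDKit's weighted-QED) on identical
# structures; a live cross-check against that implementation runs at the
# end of the file.

test_that("ADS desirability normalizes to 1 at the mode and decays to its asymptotes", {
  for (prop in c("MW", "ALOGP", "HBD", "PSA", "ROTB")) {
    p <- phenolprofiler:::QED_ADS_PARAMS[[prop]]
    grid <- seq(p[["c"]] - 8 * abs(p[["e"]]) - 50, p[["c"]] + 8 * abs(p[["f"]]) + 50,
                length.out = 4000)
    d <- desirability(grid, prop)
    expect_lte(max(d), 1 + 1e-9)
    expect_equal(max(d), 1, tolerance = 1e-3)  # d_max is the function maximum
    # tails approach a / d_max
    expect_equal(desirability(-1e7, prop), p[["a"]] / p[["d_max"]], tolerance = 1e-9)
    expect_equal(desirability(1e7, prop), p[["a"]] / p[["d_max"]], tolerance = 1e-9)
    # monotone decrease on the right flank
    right <- d[grid >= grid[which.max(d)]]
    expect_true(all(diff(right) <= 1e-12))
  }
})

test_that("QED reproduces reference scores on named polyphenols", {
  cases <- c(
    "sativanone" = 0.9439, "dihydroformononetin" = 0.9113,
    "violanone" = 0.9046, "isosakuranetin" = 0.8874, "sakuranetin" = 0.8874,
    "liquiritigenin" = 0.8229, "naringenin" = 0.7421,
    "quercetin" = 0.4342, "genistein" = 0.6318, "catechin" = 0.5096,
    "rutin" = 0.1395, "gallic acid" = 0.4599, "ferulic acid" = 0.7153,
    "cyanidin" = 0.3473, "2-phenylethanol" = 0.6250
  )
  for (nm in names(cases)) {
    expect_equal(qed(ref_smiles(nm)), cases[[nm]], tolerance = 1e-3,
                 label = paste("QED of", nm))
  }
})

test_that("QED property vector matches reference counts for sativanone", {
  p <- qed_properties(ref_smiles("sativanone"))
  expect_equal(unname(p["HBA"]), 5)
  expect_equal(unname(p["HBD"]), 1)
  expect_equal(unname(p["ROTB"]), 3)
  expect_equal(unname(p["AROM"]), 2)
  expect_equal(unname(p["ALERTS"]), 0)
  expect_equal(unname(p["PSA"]), 64.99, tolerance = 1e-2)
})

test_that("QED stays within [0, 1] and is invariant to SMILES rewriting", {
  smis <- stats::na.omit(reference_compounds()$smiles)
  scores <- vapply(smis, qed, numeric(1))
  expect_true(all(scores >= 0 & scores <= 1))
  expect_equal(qed("O=C1CC(c2ccc(O)cc2)Oc2cc(O)cc(O)c21"),
               qed("Oc1ccc(C2CC(=O)c3c(O)cc(O)cc3O2)cc1"),
               tolerance = 1e-12)
})

test_that("unit-weight variant differs from the weighted default as designed", {
  s <- ref_smiles("naringenin")
  expect_equal(qed(s, weights = "unit"), 0.7521, tolerance = 1e-3)
  expect_false(isTRUE(all.equal(qed(s), qed(s, weights = "unit"))))
})

test_that("qed_scores handles unparseable structures as absent (complete case)", {
  out <- qed_scores(c(a = ref_smiles("naringenin"), b = "C1CC", c = NA))
  expect_equal(out$complete_structure, c(TRUE, FALSE, FALSE))
  expect_equal(sum(is.na(out$qed)), 2)
})

test_that("native QED agrees with the independent reference implementation", {
  # cross-validation against RDKit, available in the test environment
  smis <- c(ref_smiles("sativanone"), ref_smiles("quercetin"),
            ref_smiles("rutin"), ref_smiles("ferulic acid 4-sulfate"))
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "from rdkit.Chem import QED",
    "for s in sys.argv[1:]:",
    "    print('%.6f' % QED.qed(Chem.MolFromSmiles(s)))",
    sep = "\n")
  f <- tempfile(fileext = ".py"); writeLines(script, f)
  res <- tryCatch(
    system2("python", c(f, shQuote(smis)), stdout = TRUE, stderr = TRUE),
    error = function(e) NULL)
  expect_false(is.null(res))
  ref <- suppressWarnings(as.numeric(res))
  expect_false(any(is.na(ref)))
  mine <- vapply(smis, qed, numeric(1))
  expect_equal(unname(mine), ref, tolerance = 1e-3)
})
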