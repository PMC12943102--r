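# Shared fixtures built in code: small compound/activity/food tables and
# a lookup of reference structures by name.

ref_smiles <- function(name) {
  tab <- reference_compounds()
  s <- tab$smiles[match(name, tab$name)]
  stopifnot(!is.na(s))
  s
}

write_compound_fixture <- function(rows, path = tempfile(fileext = ".csv")) {
  readr::write_csv(rows, path)
  path
}

# a 4-record two-source fixture with one merge conflict, one clean merge
# and one unmergeable record (enumerated by hand in the tests)
two_source_fixture <- function() {
  key1 <- strrep("A", 14); key2 <- strrep("B", 14)
  ph <- tibble::tibble(
    name = c("compound one", "compound two"),
    subclass = c("flavonols", "flavones"),
    inchikey = c(paste0(key1, "-AAAAAAAAAA-N"), paste0(key2, "-BBBBBBBBBB-N")),
    registry_number = c(NA, "111"),
    smiles = c(NA, NA)
  )
  pe <- tibble::tibble(
    name = c("compound one pe", "compound three"),
    subclass = c("flavones", "hydroxybenzoic acids"),  # conflicts with ph row 1
    inchikey = c(paste0(key1, "-AAAAAAAAAA-N"), NA),
    registry_number = c("222", NA),
    smiles = c("O=c1c(O)c(-c2ccc(O)cc2)oc2cc(O)cc(O)c12", NA)
  )
  list(
    phytohub = load_compound_table(write_compound_fixture(ph), "phytohub"),
    phenol_explorer = load_compound_table(write_compound_fixture(pe), "phenol_explorer")
  )
}

toy_activity_table <- function() {
  tibble::tibble(
    compound_id = c("c1", "c1", "c2", "c3", "c4", "c5"),
    cls = c("flavonoid", "flavonoid", "flavonoid",
            "phenolic_acid", "phenolic_acid", "phenolic_acid"),
    target_id = c("t1", "t1", "t2", "t1", "t2", "t3"),
    target_name = paste("target", c(1, 1, 2, 1, 2, 3)),
    target_class = "kinase",
    activity_type = c("IC50", "Inhibition", "Ki", "EC50", "Kd", "IC50"),
    value = c(100, 50, 2, 1, 10, 5),
    units = c("nM", "nM", "uM", "uM", "%", "nM"),
    relationship = c("direct", "direct", "direct", "indirect", "direct", "direct")
  )
}

small_config <- function(seed = 11, ...) {
  synthesis_config(
    n_flavonoids = 40, n_phenolic_acids = 20,
    n_activities = c(flavonoid = 60, phenolic_acid = 40),
    seed = seed, ...
  )
}
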