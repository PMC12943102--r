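# Curated reference structures of well-characterized dietary polyphenols,
# used in examples, validation tests and the acceptance script. SMILES
# are standard aromatic-notation structures; the large ellagitannins are
# carried by molecular formula (their masses are what matters for the
# misclassification screen).

#' Reference polyphenol structures
#'
#' A small curated table of named dietary flavonoids and phenolic acids
#' with standard SMILES, plus three large ellagitannins identified by
#' molecular formula (punicalagin, sanguiin H-6, lambertianin C), whose
#' masses sit far outside the typical phenolic-acid range and which serve
#' as positive controls for the misclassification screen.
#'
#' @return Tibble with columns `name`, `subclass`, `cls`, `smiles`
#'   (NA for the formula-only ellagitannins), `formula`.
#' @export
reference_compounds <- function() {
  tibble::tribble(
    ~name, ~subclass, ~smiles,
    "sativanone",            "isoflavanones", "COc1ccc(C2COc3cc(O)ccc3C2=O)c(OC)c1",
    "dihydroformononetin",   "isoflavanones", "COc1ccc(C2COc3cc(O)ccc3C2=O)cc1",
    "violanone",             "isoflavanones", "COc1ccc(C2COc3cc(O)ccc3C2=O)c(O)c1OC",
    "vestitone",             "isoflavanones", "COc1ccc(C2COc3cc(O)ccc3C2=O)c(O)c1",
    "liquiritigenin",        "flavanones",    "O=C1CC(c2ccc(O)cc2)Oc2cc(O)ccc21",
    "naringenin",            "flavanones",    "O=C1CC(c2ccc(O)cc2)Oc2cc(O)cc(O)c21",
    "isosakuranetin",        "flavanones",    "COc1ccc(C2CC(=O)c3c(O)cc(O)cc3O2)cc1",
    "sakuranetin",           "flavanones",    "COc1cc(O)c2c(c1)OC(c1ccc(O)cc1)CC2=O",
    "quercetin",             "flavonols",     "O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12",
    "kaempferol",            "flavonols",     "O=c1c(O)c(-c2ccc(O)cc2)oc2cc(O)cc(O)c12",
    "luteolin",              "flavones",      "O=c1cc(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12",
    "apigenin",              "flavones",      "O=c1cc(-c2ccc(O)cc2)oc2cc(O)cc(O)c12",
    "genistein",             "isoflavonoids", "O=c1c(-c2ccc(O)cc2)coc2cc(O)cc(O)c12",
    "daidzein",              "isoflavonoids", "O=c1c(-c2ccc(O)cc2)coc2cc(O)ccc12",
    "formononetin",          "isoflavonoids", "COc1ccc(-c2coc3cc(O)ccc3c2=O)cc1",
    "catechin",              "flavan-3-ols",  "OC1Cc2c(O)cc(O)cc2OC1c1ccc(O)c(O)c1",
    "cyanidin",              "anthocyanins",  "Oc1cc(O)c2cc(O)c(-c3ccc(O)c(O)c3)[o+]c2c1",
    "rutin",                 "flavonols",     "CC1OC(OCC2OC(Oc3c(-c4ccc(O)c(O)c4)oc4cc(O)cc(O)c4c3=O)C(O)C(O)C2O)C(O)C(O)C1O",
    "gallic acid",           "hydroxybenzoic acids",  "O=C(O)c1cc(O)c(O)c(O)c1",
    "protocatechuic acid",   "hydroxybenzoic acids",  "O=C(O)c1ccc(O)c(O)c1",
    "caffeic acid",          "hydroxycinnamic acids", "O=C(O)C=Cc1ccc(O)c(O)c1",
    "p-coumaric acid",       "hydroxycinnamic acids", "O=C(O)C=Cc1ccc(O)cc1",
    "ferulic acid",          "hydroxycinnamic acids", "COc1cc(C=CC(=O)O)ccc1O",
    "ferulic acid 4-sulfate","hydroxycinnamic acids", "COc1cc(C=CC(=O)O)ccc1OS(=O)(=O)O",
    "2-phenylethanol",       "other",                 "OCCc1ccccc1",
    "ellagic acid",          "ellagitannins", "O=c1oc2c(O)c(O)cc3c(=O)oc4c(O)c(O)cc1c4c23",
    "punicalagin",           "ellagitannins", NA,
    "sanguiin H-6",          "ellagitannins", NA,
    "lambertianin C",        "ellagitannins", NA
  ) |>
    dplyr::mutate(
      cls = default_taxonomy()$cls[match(.data$subclass,
                                         default_taxonomy()$subclass)],
      cls = ifelse(is.na(.data$cls), "other", .data$cls),
      formula = dplyr::case_when(
        name == "punicalagin" ~ "C48H28O30",
        name == "sanguiin H-6" ~ "C82H54O52",
        name == "lambertianin C" ~ "C123H80O78",
        TRUE ~ vapply(.data$smiles, function(s)
          if (is.na(s)) NA_character_ else mol_formula(parse_smiles(s)),
          character(1))
      )
    ) |>
    dplyr::select("name", "subclass", "cls", "smiles", "formula")
}
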