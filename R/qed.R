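# Quantitative Estimate of Drug-likeness, implemented from first
# principles: eight property values are mapped through asymmetric
# double-sigmoid (ADS) desirability functions fitted by Bickerton and
# colleagues to the property distributions of approved oral drugs, and
# combined as a weighted geometric mean. Coefficients are the published
# parameter set of the weighted-desirability variant.

QED_ADS_PARAMS <- list(
  MW     = c(a = 2.817065973, b = 392.5754953, c = 290.7489764, d = 2.419764353,
             e = 49.22325677, f = 65.37051707, d_max = 104.9805561),
  ALOGP  = c(a = 3.172690585, b = 137.8624751, c = 2.534937431, d = 4.581497897,
             e = 0.822739154, f = 0.576295591, d_max = 131.3186604),
  HBA    = c(a = 2.948620388, b = 160.4605972, c = 3.615294657, d = 4.435986202,
             e = 0.290141953, f = 1.300669958, d_max = 148.7763046),
  HBD    = c(a = 1.618662227, b = 1010.051101, c = 0.985094388, d = 1e-09,
             e = 0.713820843, f = 0.920922555, d_max = 258.1632616),
  PSA    = c(a = 1.876861559, b = 125.2232657, c = 62.90773554, d = 87.83366614,
             e = 12.01999824, f = 28.51324732, d_max = 104.5686167),
  ROTB   = c(a = 0.01, b = 272.4121427, c = 2.55837997, d = 1.565547684,
             e = 1.271567166, f = 2.758063707, d_max = 105.4420403),
  AROM   = c(a = 3.21778897, b = 957.7374108, c = 2.274627939, d = 1e-09,
             e = 1.317690384, f = 0.375760881, d_max = 312.337261),
  ALERTS = c(a = 0.01, b = 1199.094025, c = -0.09002883, d = 1e-09,
             e = 0.185904477, f = 0.875193782, d_max = 417.725314)
)

# property weights of the weighted-mean QED variant
QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                 PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

# numerical floor applied to each desirability before the log transform
QED_DESIRABILITY_FLOOR <- 1e-6

#' ADS desirability function
#'
#' Maps a raw property value to (0, 1] through the asymmetric
#' double-sigmoid used by QED, normalized by the function's maximum
#' (`d_max`) so the property's drug-like mode maps to 1.
#'
#' @param x Property value (vectorized).
#' @param params Named numeric vector with elements `a`, `b`, `c`, `d`,
#'   `e`, `f`, `d_max`, or the name of a QED property (e.g. `"MW"`).
#' @return Desirability in (0, 1].
#' @examples
#' desirability(300, "MW")
#' @export
desirability <- function(x, params) {
  if (is.character(params)) {
    params <- QED_ADS_PARAMS[[match.arg(params, names(QED_ADS_PARAMS))]]
  }
  p <- as.list(params)
  stopifnot(p$d_max > 0)
  exp1 <- 1 + exp(-(x - p$c + p$d / 2) / p$e)
  exp2 <- 1 + exp(-(x - p$c - p$d / 2) / p$f)
  (p$a + p$b / exp1 * (1 - 1 / exp2)) / p$d_max
}

#' QED property vector of a structure
#'
#' Computes the eight QED properties: molecular weight, Crippen logP,
#' acceptor count (QED acceptor definition), donor count, TPSA, strict
#' rotatable bonds, aromatic rings, and structural-alert count.
#'
#' @param mol A `phmol` object or SMILES string.
#' @return Named numeric vector of the eight properties.
#' @export
qed_properties <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  c(MW = mol_weight(mol),
    ALOGP = crippen_logp(mol),
    HBA = count_hba_qed(mol),
    HBD = count_hbd_qed(mol),
    PSA = tpsa(mol),
    ROTB = count_rotatable_bonds(mol),
    AROM = count_aromatic_rings(mol),
    ALERTS = count_alerts(mol))
}

#' Quantitative Estimate of Drug-likeness (QED)
#'
#' Weighted geometric mean of the eight desirability-transformed
#' properties: `exp(sum(w_i log d_i) / sum(w_i))`. The default weights are
#' those of the weighted-mean variant; `weights = "unit"` gives the
#' unweighted variant. Desirabilities are floored at 1e-6 before the log
#' transform.
#'
#' @param mol A `phmol` object or SMILES string.
#' @param weights Either `"mean"` (default, weighted variant), `"unit"`,
#'   or a named numeric vector of eight non-negative weights.
#' @param props Optional precomputed property vector from
#'   [qed_properties()].
#' @return QED score in `[0, 1]`.
#' @examples
#' qed("COc1ccc(C2COc3cc(O)ccc3C2=O)cc1")  # dihydroformononetin
#' @export
qed <- function(mol, weights = c("mean", "unit"), props = NULL) {
  if (is.character(weights)) {
    weights <- switch(match.arg(weights),
                      mean = QED_WEIGHTS,
                      unit = stats::setNames(rep(1, 8), names(QED_WEIGHTS)))
  }
  stopifnot(all(names(QED_WEIGHTS) %in% names(weights)),
            all(weights >= 0), sum(weights) > 0)
  if (is.null(props)) props <- qed_properties(mol)
  d <- vapply(names(QED_WEIGHTS), function(nm)
    desirability(props[[nm]], QED_ADS_PARAMS[[nm]]), numeric(1))
  d <- pmax(d, QED_DESIRABILITY_FLOOR)
  w <- weights[names(QED_WEIGHTS)]
  exp(sum(w * log(d)) / sum(w))
}

#' Score a set of structures with QED
#'
#' Vectorized QED over a compound table; unparseable structures yield an
#' absent score (complete-case behaviour) and are reported.
#'
#' @param smiles Character vector of SMILES.
#' @param compound_id Optional identifier vector.
#' @param weights Passed to [qed()].
#' @return Tibble with `compound_id`, `smiles`, `qed`,
#'   `complete_structure`.
#' @export
qed_scores <- function(smiles, compound_id = NULL, weights = "mean") {
  if (is.null(compound_id)) {
    compound_id <- names(smiles) %||% as.character(seq_along(smiles))
  }
  rows <- lapply(seq_along(smiles), function(i) {
    smi <- smiles[[i]]
    score <- NA_real_
    ok <- FALSE
    if (!is.na(smi) && nzchar(smi)) {
      m <- tryCatch(parse_smiles(smi),
                    phenolprofiler_structure_error = function(e) NULL)
      if (!is.null(m)) { score <- qed(m, weights = weights); ok <- TRUE }
    }
    tibble::tibble(compound_id = compound_id[[i]], smiles = smi,
                   qed = score, complete_structure = ok)
  })
  dplyr::bind_rows(rows)
}
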