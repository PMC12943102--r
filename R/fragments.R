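# Fragment-sum drug-likeness scoring.
#
# The aggregation follows the fragment-contribution scheme popularized by
# DataWarrior: contributions of matched substructure fragments are summed
# and normalized by the square root of the number of matched
# substructures; positive scores indicate drug-like character, negative
# scores building-block character. The fragment dictionary is pluggable:
# scores are supplied as a table over the package's named functional-group
# catalog (the proprietary DataWarrior fragment dictionary itself is not
# reproduced; externally computed scores can be ingested instead, see
# [ingest_scores()]).

# functional-group occurrence counters over the molecular graph
FRAGMENT_CATALOG <- list(
  phenol = function(mol) {
    at <- mol$atoms
    sum(vapply(seq_len(nrow(at)), function(a) {
      at$element[a] == "O" && !at$aromatic[a] && at$h_count[a] == 1 &&
        any(at$aromatic[nbrs(mol, a)] & at$element[nbrs(mol, a)] == "C")
    }, logical(1)))
  },
  aliphatic_hydroxyl = function(mol) {
    at <- mol$atoms
    sum(vapply(seq_len(nrow(at)), function(a) {
      if (at$element[a] != "O" || at$aromatic[a] || at$h_count[a] != 1) return(FALSE)
      nb <- nbrs(mol, a)
      length(nb) == 1 && at$element[nb] == "C" && !at$aromatic[nb] &&
        !any(mol$bonds$order[mol$adj[[nb]]] > 1)
    }, logical(1)))
  },
  catechol = function(mol) {
    cnt <- 0L
    for (ring in aromatic_all_c_rings(mol)) {
      m <- length(ring)
      for (i in seq_len(m)) {
        j <- (i %% m) + 1
        if (oh_like_sub(mol, ring[i], ring, allow_n = FALSE) &&
            oh_like_sub(mol, ring[j], ring, allow_n = FALSE)) cnt <- cnt + 1L
      }
    }
    cnt
  },
  aryl_methoxy = function(mol) {
    at <- mol$atoms
    sum(vapply(seq_len(nrow(at)), function(a) {
      if (at$element[a] != "O" || at$aromatic[a] || at$h_count[a] != 0) return(FALSE)
      nb <- nbrs(mol, a)
      length(nb) == 2 &&
        any(at$aromatic[nb] & at$element[nb] == "C") &&
        any(!at$aromatic[nb] & at$element[nb] == "C" & at$h_count[nb] == 3)
    }, logical(1)))
  },
  carbonyl = function(mol) {
    at <- mol$atoms
    sum(at$element[mol$bonds$a1] == "C" & at$element[mol$bonds$a2] == "O" &
          mol$bonds$order == 2) +
      sum(at$element[mol$bonds$a1] == "O" & at$element[mol$bonds$a2] == "C" &
            mol$bonds$order == 2)
  },
  carboxylic_acid = function(mol) {
    at <- mol$atoms
    sum(vapply(seq_len(nrow(at)), function(a) {
      if (at$element[a] != "C") return(FALSE)
      bi <- atom_bond_info(mol, a)
      any(bi$order == 2 & at$element[bi$nbr] == "O") &&
        any(bi$order == 1 & at$element[bi$nbr] == "O" & at$h_count[bi$nbr] == 1)
    }, logical(1)))
  },
  ester = function(mol) length(ester_groups(mol)),
  glycosidic_acetal = function(mol) {
    at <- mol$atoms
    sum(vapply(seq_len(nrow(at)), function(a) {
      if (at$element[a] != "C" || at$aromatic[a] || at$ring_count[a] == 0) return(FALSE)
      bi <- atom_bond_info(mol, a)
      o_nb <- bi$nbr[at$element[bi$nbr] == "O" & bi$order == 1 & !at$aromatic[bi$nbr]]
      length(o_nb) >= 2 && any(at$ring_count[o_nb] > 0) && any(at$ring_count[o_nb] == 0)
    }, logical(1)))
  },
  sulfate_ester = function(mol) {
    at <- mol$atoms
    sum(vapply(seq_len(nrow(at)), function(s) {
      if (at$element[s] != "S") return(FALSE)
      bi <- atom_bond_info(mol, s)
      sum(bi$order == 2 & at$element[bi$nbr] == "O") >= 2 &&
        sum(bi$order == 1 & at$element[bi$nbr] == "O") >= 1
    }, logical(1)))
  },
  aromatic_ring = function(mol) count_aromatic_rings(mol),
  michael_acceptor = function(mol) as.integer(ALERT_MATCHERS$alert_104(mol)),
  oxocation = function(mol) sum(mol$atoms$element %in% c("O", "S") & mol$atoms$charge > 0)
)

#' Build a fragment score table
#'
#' Validates a mapping from fragment pattern names to contribution values
#' at load time; unknown pattern names raise an error immediately rather
#' than at scoring time.
#'
#' @param patterns Character vector of fragment names from the package
#'   catalog (see [fragment_catalog()]).
#' @param values Numeric contributions, one per pattern (positive =
#'   drug-like).
#' @return A `fragment_score_table` tibble with columns `pattern`, `value`.
#' @export
fragment_score_table <- function(patterns, values) {
  if (length(patterns) == 0) rlang::abort("fragment score table is empty")
  stopifnot(length(patterns) == length(values))
  unknown <- setdiff(patterns, names(FRAGMENT_CATALOG))
  if (length(unknown)) {
    rlang::abort(paste0("unknown fragment pattern(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "phenolprofiler_table_error")
  }
  if (any(!is.finite(values))) {
    rlang::abort("fragment contributions must be finite",
                 class = "phenolprofiler_table_error")
  }
  if (anyDuplicated(patterns)) {
    rlang::abort("duplicated fragment pattern in table",
                 class = "phenolprofiler_table_error")
  }
  structure(tibble::tibble(pattern = patterns, value = values),
            class = c("fragment_score_table", "tbl_df", "tbl", "data.frame"))
}

#' Names of available fragment patterns
#' @return Character vector of catalog pattern names.
#' @export
fragment_catalog <- function() names(FRAGMENT_CATALOG)

#' Fragment-sum drug-likeness score
#'
#' Sums the contribution of every matched fragment occurrence and divides
#' by the square root of the total number of matched substructures. A
#' structure matching no fragment scores 0 and is flagged.
#'
#' @param mol A `phmol` object or SMILES string.
#' @param table A [fragment_score_table()].
#' @return A list with `score`, `n_matched`, and `no_match` flag.
#' @examples
#' tab <- fragment_score_table(c("phenol", "carbonyl"), c(1, 1))
#' fragment_sum_score("O=C1CC(c2ccc(O)cc2)Oc2cc(O)ccc21", tab)
#' @export
fragment_sum_score <- function(mol, table) {
  if (!inherits(table, "fragment_score_table")) {
    rlang::abort("`table` must be a fragment_score_table",
                 class = "phenolprofiler_table_error")
  }
  if (is.character(mol)) mol <- parse_smiles(mol)
  counts <- vapply(table$pattern, function(p) FRAGMENT_CATALOG[[p]](mol), numeric(1))
  n_matched <- sum(counts)
  if (n_matched == 0) {
    rlang::warn("no fragment matched; score set to 0")
    return(list(score = 0, n_matched = 0L, no_match = TRUE))
  }
  list(score = sum(table$value * counts) / sqrt(n_matched),
       n_matched = as.integer(n_matched), no_match = FALSE)
}

#' Default fragment contribution table
#'
#' A small built-in contribution table over the functional-group catalog,
#' signed so that decorations associated with drug-like polyphenols
#' (methoxylation, moderate hydroxylation) score positive and
#' building-block or reactive features (quinone-forming catechols,
#' Michael acceptors, oxocations) score negative. Intended as a working
#' default for synthetic data; real analyses typically ingest externally
#' computed scores.
#'
#' @return A `fragment_score_table`.
#' @export
default_fragment_table <- function() {
  fragment_score_table(
    patterns = c("phenol", "aliphatic_hydroxyl", "catechol", "aryl_methoxy",
                 "carbonyl", "carboxylic_acid", "ester", "glycosidic_acetal",
                 "sulfate_ester", "aromatic_ring", "michael_acceptor",
                 "oxocation"),
    values = c(0.2, -0.1, -0.6, 0.5, 0.3, -0.2, -0.3, -0.8,
               0.4, 0.4, -0.9, -1.2)
  )
}
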