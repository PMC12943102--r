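# Molecular descriptors computed natively on the phmol graph.
#
# Atomic logP contributions follow the Wildman & Crippen atom-contribution
# scheme; TPSA follows the Ertl fragment-contribution method (N/O polar
# contributions; S and P excluded, the common default). Both are
# implemented as ordered rule lists over the molecular graph and
# validated against an independent reference implementation in the test
# suite.

# ---- helpers ---------------------------------------------------------------

atom_bond_info <- function(mol, a) {
  ks <- mol$adj[[a]]
  list(
    nbr = other_end(mol, ks, a),
    order = mol$bonds$order[ks],
    arom = mol$bonds$aromatic[ks]
  )
}

# connectivity (heavy degree + hydrogens), SMARTS "X"
conn <- function(mol, a) mol$atoms$degree[a] + mol$atoms$h_count[a]

# valence: total bond order + hydrogens
valence <- function(mol, a) {
  ceiling(sum(mol$bonds$order[mol$adj[[a]]])) + mol$atoms$h_count[a]
}

in_small_ring <- function(mol, a, size) {
  any(vapply(mol$rings, function(r) length(r) == size && a %in% r, logical(1)))
}

# ---- Crippen logP ----------------------------------------------------------

CRIPPEN_VALUES <- c(
  C1 = 0.1441, C2 = 0, C3 = -0.2035, C4 = -0.2051, C5 = -0.2783,
  C6 = 0.1551, C7 = 0.0017, C8 = 0.08452, C9 = -0.1444, C10 = -0.0516,
  C11 = 0.1193, C12 = -0.0967, C13 = -0.5443, C14 = 0, C15 = 0.245,
  C16 = 0.198, C17 = 0, C18 = 0.1581, C19 = 0.2955, C20 = 0.2713,
  C21 = 0.136, C22 = 0.4619, C23 = 0.5437, C24 = 0.1893, C25 = -0.8186,
  C26 = 0.264, C27 = 0.2148, CS = 0.08129,
  H1 = 0.123, H2 = -0.2677, H3 = 0.2142, H4 = 0.298, HS = 0.1125,
  N1 = -1.019, N2 = -0.7096, N3 = -1.027, N4 = -0.5188, N5 = 0.08387,
  N6 = 0.1836, N7 = -0.3187, N8 = -0.4458, N9 = 0.01508, N10 = -1.95,
  N11 = -0.3239, N12 = -1.119, N13 = -0.3396, N14 = 0.2887, NS = -0.4806,
  O1 = 0.1552, O2 = -0.2893, O3 = -0.0684, O4 = -0.4195, O5 = 0.0335,
  O6 = -0.3339, O7 = -1.189, O8 = 0.1788, O9 = -0.1526, O10 = 0.1129,
  O11 = 0.4833, O12 = -1.326, OS = -0.1188,
  S1 = 0.6482, S2 = -0.0024, S3 = 0.6237, P = 0.8612,
  F. = 0.4202, Cl = 0.6895, Br = 0.8456, I = 0.8857,
  Hal = -2.996
)

HETERO_SET <- c("N", "O", "P", "S", "F", "Cl", "Br", "I")

crippen_carbon_type <- function(mol, a) {
  at <- mol$atoms
  bi <- atom_bond_info(mol, a)
  h <- at$h_count[a]
  nb <- bi$nbr
  nb_el <- at$element[nb]
  nb_ar <- at$aromatic[nb]
  ali <- !nb_ar
  n_ali_C <- sum(nb_el == "C" & ali)
  n_ali_het <- sum(nb_el %in% HETERO_SET & ali)
  n_ali_heavy <- sum(ali)
  n_arom_nbr <- sum(nb_ar)
  dbl <- bi$order == 2
  x4 <- conn(mol, a) == 4 && !any(bi$order > 1.4)

  if (!at$aromatic[a]) {
    dbl_ali_het <- any(dbl & nb_el != "C" & ali)
    dbl_ali_C <- any(dbl & nb_el == "C" & ali)
    dbl_arom_C <- any(dbl & nb_el == "C" & nb_ar)
    if (h == 4 ||
        (h == 3 && length(nb) == 1 && n_ali_C == 1) ||
        (h == 2 && length(nb) == 2 && n_ali_C == 2)) return("C1")
    if ((h == 1 && length(nb) == 3 && n_ali_C == 3) ||
        (h == 0 && length(nb) == 4 && n_ali_C == 4)) return("C2")
    if ((h == 3 && length(nb) == 1 && n_ali_het == 1) ||
        (h == 2 && x4 && n_ali_het >= 1 && n_ali_heavy >= 2)) return("C3")
    if ((h == 1 && x4 && n_ali_het >= 1 && n_ali_heavy >= 3) ||
        (h == 0 && x4 && n_ali_het >= 1 && n_ali_heavy >= 4)) return("C4")
    if (dbl_ali_het) return("C5")
    if (dbl_ali_C) {
      if (h == 2) return("C6")
      if (h == 1 && n_ali_heavy >= 2) return("C6")
      if (h == 0 && sum(dbl & nb_el == "C" & ali) == 2) return("C6")  # allene
      if (h == 0 && n_ali_heavy >= 3) return("C6")
      # alkene carbon in an aromatic environment
      if (n_arom_nbr >= 1) return("C26")
    }
    if (any(bi$order == 3)) return("C7")
    if (h == 3 && n_arom_nbr == 1) {
      return(if (nb_el[nb_ar][1] == "C") "C8" else "C9")
    }
    if (x4 && n_arom_nbr >= 1) {
      if (h == 2) return("C10")
      if (h == 1) return("C11")
      if (h == 0) return("C12")
    }
    if (dbl_arom_C) return("C26")
    return("CS")
  }

  # aromatic carbon
  if (h >= 1) return("C18")
  n_arom_bonds <- sum(bi$arom)
  single_nb <- nb[!bi$arom & bi$order == 1]
  if (any(nb_el %in% c("F"))) return("C14")
  if (any(nb_el %in% c("Cl"))) return("C15")
  if (any(nb_el %in% c("Br"))) return("C16")
  if (any(nb_el %in% c("I"))) return("C17")
  if (n_arom_bonds >= 3) return("C19")
  if (length(single_nb) > 0) {
    sn <- single_nb[1]
    if (at$aromatic[sn]) return("C20")
    if (at$element[sn] == "C") return("C21")
    if (at$element[sn] == "N") return("C22")
    if (at$element[sn] == "O") return("C23")
    if (at$element[sn] == "S") return("C24")
    return("C13")
  }
  if (any(bi$order == 2 & nb_el %in% c("C", "N", "O"))) return("C25")
  "CS"
}

crippen_oxygen_type <- function(mol, a) {
  at <- mol$atoms
  bi <- atom_bond_info(mol, a)
  h <- at$h_count[a]
  nb <- bi$nbr
  nb_el <- at$element[nb]
  nb_ar <- at$aromatic[nb]
  chg <- at$charge[a]
  if (at$aromatic[a]) return("O1")
  if (h >= 1) return("O2")
  dbl_to <- nb_el[bi$order == 2]
  dbl_to_ar <- nb_ar[bi$order == 2]
  if (length(nb) == 2 && all(!nb_ar)) return("O3")
  if (length(nb) == 2 && any(nb_ar)) return("O4")
  if (length(dbl_to) && dbl_to[1] %in% c("N", "O") && !dbl_to_ar[1]) return("O5")
  if (chg < 0 && length(nb) == 1 && nb_el[1] == "N") return("O5")
  if (chg < 0 && length(nb) == 1 && nb_el[1] == "S") return("O6")
  if (length(dbl_to) && dbl_to[1] == "S") return("O6")
  if (chg < 0 && length(nb) == 1 && nb_el[1] == "C" && !nb_ar[1]) {
    cc <- atom_bond_info(mol, nb[1])
    if (any(cc$order == 2 & at$element[cc$nbr] == "O")) return("O12")
  }
  if (chg < 0) return("O7")
  if (length(dbl_to) && dbl_to[1] == "C" && dbl_to_ar[1]) return("O8")
  if (length(dbl_to) && dbl_to[1] == "C") {
    cb <- nb[bi$order == 2][1]
    cc <- atom_bond_info(mol, cb)
    oth <- cc$nbr[cc$nbr != a]
    oth_el <- at$element[oth]; oth_ar <- at$aromatic[oth]
    c_h <- at$h_count[cb]
    if (c_h == 2) return("O9")                         # formaldehyde
    if (c_h == 1 && any(oth_el == "C" & !oth_ar)) return("O9")
    if (c_h == 1 && any(oth_el %in% c("N", "O"))) return("O9")
    if (any(oth_el == "C" & !oth_ar) && sum(!oth_ar) >= 2) return("O9")
    if (all(oth_el == "O") && all(atom_bond_info(mol, cb)$order[cc$nbr != a] == 2)) return("O9")  # CO2
    if (c_h == 1 && any(oth_ar & oth_el == "C")) return("O10")
    if (any(oth_el == "C") && any(oth_ar)) return("O10")
    if (any(oth_ar & oth_el == "C") && any(!oth_ar)) return("O10")
    if (length(oth) >= 2 && all(!oth_el %in% c("C", "H"))) return("O11")
    return("O9")
  }
  "OS"
}

crippen_nitrogen_type <- function(mol, a) {
  at <- mol$atoms
  bi <- atom_bond_info(mol, a)
  h <- at$h_count[a]
  nb <- bi$nbr
  nb_ar <- at$aromatic[nb]
  chg <- at$charge[a]
  if (at$aromatic[a]) return(if (chg > 0) "N12" else "N11")
  if (chg > 0 && h >= 1) return("N10")
  if (chg > 0 && any(bi$order == 3)) return("N14")
  if (chg < 0) return("N14")
  if (chg > 0) return("N13")
  if (h == 2 && length(nb) == 1) return(if (nb_ar[1]) "N3" else "N1")
  if (h == 1 && length(nb) == 2) return(if (any(nb_ar)) "N4" else "N2")
  if (h == 1 && any(bi$order == 2)) return("N5")
  if (h == 0 && any(bi$order == 3)) return("N9")
  if (h == 0 && any(bi$order == 2)) return("N6")
  if (h == 0 && length(nb) == 3) return(if (any(nb_ar)) "N8" else "N7")
  "NS"
}

crippen_hydrogen_value <- function(mol, a) {
  # contribution of one H attached to heavy atom a
  at <- mol$atoms
  el <- at$element[a]
  if (el == "C") return(CRIPPEN_VALUES[["H1"]])
  if (el == "N") return(CRIPPEN_VALUES[["H3"]])
  if (el == "O") {
    bi <- atom_bond_info(mol, a)
    nb <- bi$nbr
    if (length(nb) == 0) return(CRIPPEN_VALUES[["HS"]])
    b <- nb[1]
    bel <- at$element[b]
    if (bel == "C") {
      if (at$aromatic[b]) return(CRIPPEN_VALUES[["H2"]])       # phenol
      cb <- atom_bond_info(mol, b)
      if (!any(cb$order > 1.4)) return(CRIPPEN_VALUES[["H2"]]) # alcohol
      if (any(cb$order == 2 & at$element[cb$nbr] %in% c("C", "N", "O", "S"))) {
        return(CRIPPEN_VALUES[["H4"]])                         # acid / enol
      }
      return(CRIPPEN_VALUES[["HS"]])
    }
    if (bel %in% c("O", "S")) return(CRIPPEN_VALUES[["H4"]])
    if (bel == "N") return(CRIPPEN_VALUES[["H3"]])
    return(CRIPPEN_VALUES[["H2"]])
  }
  # H on S or exotic atoms
  CRIPPEN_VALUES[["H2"]]
}

crippen_atom_type <- function(mol, a) {
  el <- mol$atoms$element[a]
  switch(el,
    C = crippen_carbon_type(mol, a),
    O = crippen_oxygen_type(mol, a),
    N = crippen_nitrogen_type(mol, a),
    S = {
      if (mol$atoms$aromatic[a]) "S3"
      else if (mol$atoms$charge[a] != 0) "S2"
      else {
        bi <- atom_bond_info(mol, a)
        if (any(bi$order == 2 &
                mol$atoms$element[bi$nbr] %in% c("N", "O", "P", "S"))) "S2"
        else "S1"
      }
    },
    P = "P",
    F = "F.", Cl = "Cl", Br = "Br", I = "I",
    "Hal"
  )
}

#' Crippen (Wildman-Crippen) logP
#'
#' Atom-contribution octanol/water partition coefficient. Each heavy atom
#' is assigned a published contribution according to its element,
#' aromaticity and bonding environment; implicit hydrogens contribute
#' according to the atom they sit on.
#'
#' @param mol A `phmol` object or SMILES string.
#' @return Estimated logP (dimensionless).
#' @export
crippen_logp <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  tot <- 0
  for (a in seq_len(nrow(mol$atoms))) {
    tot <- tot + CRIPPEN_VALUES[[crippen_atom_type(mol, a)]]
    if (mol$atoms$h_count[a] > 0) {
      tot <- tot + mol$atoms$h_count[a] * crippen_hydrogen_value(mol, a)
    }
  }
  unname(tot)
}

# ---- TPSA ------------------------------------------------------------------

tpsa_atom_contrib <- function(mol, a) {
  at <- mol$atoms
  el <- at$element[a]
  if (!el %in% c("N", "O")) return(0)
  bi <- atom_bond_info(mol, a)
  h <- at$h_count[a]
  chg <- at$charge[a]
  X <- conn(mol, a)
  n_sing <- sum(bi$order == 1)
  n_dbl <- sum(bi$order == 2)
  n_trp <- sum(bi$order == 3)
  n_arb <- sum(bi$arom)

  if (el == "O") {
    if (at$aromatic[a]) {
      if (chg == 0 && n_arb == 2) return(13.14)
    } else if (chg == 0) {
      if (h == 0 && n_sing == 2) {
        return(if (in_small_ring(mol, a, 3)) 12.53 else 9.23)
      }
      if (h == 0 && n_dbl == 1 && length(bi$nbr) == 1) return(17.07)
      if (h == 1 && n_sing == 1) return(20.23)
    } else if (chg == -1 && h == 0 && n_sing == 1) {
      return(23.06)
    }
    return(max(0, 28.5 - 8.6 * X + 1.5 * h))
  }

  # nitrogen
  if (at$aromatic[a]) {
    if (chg == 0) {
      if (h == 0 && n_arb == 2 && length(bi$nbr) == 2) return(12.89)
      if (h == 0 && n_arb == 3) return(4.41)
      if (h == 0 && n_arb == 2 && n_sing == 1) return(4.93)
      if (h == 0 && n_arb == 2 && n_dbl == 1) return(8.39)
      if (h == 1 && n_arb == 2) return(15.79)
    } else if (chg == 1) {
      if (h == 0 && n_arb == 3) return(4.10)
      if (h == 0 && n_arb == 2 && n_sing == 1) return(3.88)
      if (h == 1 && n_arb == 2) return(14.14)
    }
    return(max(0, 30.5 - 8.2 * X + 1.5 * h))
  }
  if (chg == 0) {
    if (h == 0) {
      if (n_sing == 3) return(if (in_small_ring(mol, a, 3)) 3.01 else 3.24)
      if (n_sing == 1 && n_dbl == 1) return(12.36)
      if (n_trp == 1 && length(bi$nbr) == 1) return(23.79)
      if (n_sing == 1 && n_dbl == 2) return(11.68)
      if (n_dbl == 1 && n_trp == 1) return(13.60)
    }
    if (h == 1) {
      if (n_sing == 2) return(if (in_small_ring(mol, a, 3)) 21.94 else 12.03)
      if (n_dbl == 1) return(23.85)
    }
    if (h == 2 && n_sing == 1) return(26.02)
  } else if (chg == 1) {
    if (h == 0 && n_sing == 4) return(0.00)
    if (h == 0 && n_sing == 2 && n_dbl == 1) return(3.01)
    if (h == 0 && n_sing == 1 && n_trp == 1) return(4.36)
    if (h == 1 && n_sing == 3) return(4.44)
    if (h == 1 && n_sing == 1 && n_dbl == 1) return(13.97)
    if (h == 2 && n_sing == 2) return(16.61)
    if (h == 2 && n_dbl == 1) return(25.59)
    if (h == 3 && n_sing == 1) return(27.64)
  }
  max(0, 30.5 - 8.2 * X + 1.5 * h)
}

#' Topological polar surface area (Ertl)
#'
#' Sum of fragment surface contributions over polar nitrogen and oxygen
#' atoms (sulfur and phosphorus excluded, the common default).
#'
#' @param mol A `phmol` object or SMILES string.
#' @return TPSA in square Angstrom.
#' @export
tpsa <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  tot <- 0
  for (a in seq_len(nrow(mol$atoms))) tot <- tot + tpsa_atom_contrib(mol, a)
  tot
}

# ---- counts ----------------------------------------------------------------

#' Hydrogen-bond donor and acceptor counts
#'
#' `count_hbd()` counts OH and NH group occurrences (each hydrogen on an
#' oxygen or nitrogen counts once, so a primary amine contributes 2).
#' `count_hba_lipinski()` is the plain nitrogen-plus-oxygen atom count used
#' by the Rule-of-5 convention. `count_hbd_qed()` and `count_hba_qed()`
#' follow the acceptor/donor definitions of the QED reference
#' implementation (donor atoms rather than hydrogens; acceptors from a
#' curated atom-environment list).
#'
#' @param mol A `phmol` object or SMILES string.
#' @return Integer count.
#' @export
count_hbd <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  sum(mol$atoms$h_count[mol$atoms$element %in% c("N", "O")])
}

#' @rdname count_hbd
#' @export
count_hba_lipinski <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  sum(mol$atoms$element %in% c("N", "O"))
}

#' @rdname count_hbd
#' @export
count_hbd_qed <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  at <- mol$atoms
  n <- 0L
  for (a in seq_len(nrow(at))) {
    el <- at$element[a]; h <- at$h_count[a]; chg <- at$charge[a]
    if (el %in% c("O", "S") && h == 1 && chg == 0) n <- n + 1L
    else if (el == "N" && h >= 1 && chg >= 0) n <- n + 1L
  }
  n
}

#' @rdname count_hbd
#' @export
count_hba_qed <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  at <- mol$atoms
  n <- 0L
  for (a in seq_len(nrow(at))) {
    el <- at$element[a]; h <- at$h_count[a]; chg <- at$charge[a]
    X <- conn(mol, a); v <- valence(mol, a)
    bi <- atom_bond_info(mol, a)
    hit <- FALSE
    if (el == "O") {
      if (at$aromatic[a] && h == 0) hit <- TRUE
      else if (chg == 0 && v == 2 && X %in% c(1, 2)) hit <- TRUE
      else if (chg < 0 && X == 1) hit <- TRUE
    } else if (el == "S" && !at$aromatic[a]) {
      if (chg == 0 && h == 0 && v == 2 && X %in% c(1, 2)) hit <- TRUE
      else if (chg < 0 && X == 1) hit <- TRUE
    } else if (el == "N") {
      if (at$aromatic[a] && h == 0 && X == 2) hit <- TRUE
      else if (!at$aromatic[a] && h == 0 && X == 1 && v == 3) hit <- TRUE
      else if (!at$aromatic[a] && chg == 0 && X == 3 && v == 3) {
        # exclude amide/sulfonamide nitrogens
        amide <- FALSE
        for (b in bi$nbr) {
          if (at$element[b] %in% c("C", "S")) {
            cb <- atom_bond_info(mol, b)
            if (any(cb$order == 2 & at$element[cb$nbr] == "O")) amide <- TRUE
          }
        }
        if (!amide) hit <- TRUE
      }
    }
    if (hit) n <- n + 1L
  }
  n
}

#' Rotatable bond count (strict definition)
#'
#' Counts acyclic single bonds between two non-terminal heavy atoms,
#' excluding bonds to linear (triple-bonded) atoms, bonds within
#' tert-butyl/trihalomethyl groups, and amide/ester-like C-[N,O,S] bonds
#' next to a carbonyl or analogous double bond.
#'
#' @param mol A `phmol` object or SMILES string.
#' @return Integer count of rotatable bonds.
#' @export
count_rotatable_bonds <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  at <- mol$atoms
  if (nrow(mol$bonds) == 0) return(0L)

  has_triple <- vapply(seq_len(nrow(at)), function(a)
    any(mol$bonds$order[mol$adj[[a]]] == 3), logical(1))
  is_tbu_like <- vapply(seq_len(nrow(at)), function(a) {
    if (at$element[a] != "C") return(FALSE)
    bi <- atom_bond_info(mol, a)
    term <- bi$nbr[at$degree[bi$nbr] == 1]
    sum(at$element[term] == "C" & at$h_count[term] == 3) >= 3 ||
      sum(at$element[term] %in% c("F", "Cl", "Br")) >= 3
  }, logical(1))
  acyl_c <- vapply(seq_len(nrow(at)), function(a) {
    if (at$element[a] != "C" || at$aromatic[a] || at$degree[a] != 3) return(FALSE)
    bi <- atom_bond_info(mol, a)
    any(bi$order == 2 & at$element[bi$nbr] %in% c("N", "O", "S"))
  }, logical(1))

  amide_like <- function(a, b) {
    # a = acyl-type carbon, b = heteroatom single-bonded to it
    acyl_c[a] && (at$element[b] == "N" || at$element[b] == "O" ||
                    (at$element[b] == "S" && at$degree[b] > 1))
  }

  n <- 0L
  for (k in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$order[k] != 1 || mol$bonds$aromatic[k] || mol$bonds$in_ring[k]) next
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    if (at$degree[a] < 2 || at$degree[b] < 2) next
    if (has_triple[a] || has_triple[b]) next
    if (is_tbu_like[a] || is_tbu_like[b]) next
    if (amide_like(a, b) || amide_like(b, a)) next
    n <- n + 1L
  }
  n
}

#' Aromatic ring count
#'
#' Number of rings in the smallest set of smallest rings whose bonds are
#' all aromatic.
#'
#' @param mol A `phmol` object or SMILES string.
#' @return Integer count.
#' @export
count_aromatic_rings <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  if (length(mol$rings) == 0) return(0L)
  sum(vapply(mol$ring_bonds, function(rb) all(mol$bonds$aromatic[rb]), logical(1)))
}

#' Stereocentre count
#'
#' Counts tetrahedral carbon stereocentres by branch-symmetry analysis: an
#' sp3 carbon with four pairwise-distinct substituent environments (at
#' most one of which is hydrogen). By default both assigned centres
#' (carrying a stereo mark in the input) and unassigned potential centres
#' are counted; `assigned_only = TRUE` restricts to marked centres.
#'
#' @param mol A `phmol` object or SMILES string.
#' @param assigned_only Count only centres carrying an input stereo mark.
#' @return Integer count.
#' @export
count_stereocenters <- function(mol, assigned_only = FALSE) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  at <- mol$atoms
  n <- 0L
  for (a in seq_len(nrow(at))) {
    if (at$element[a] != "C" || at$aromatic[a]) next
    if (at$h_count[a] > 1) next
    if (conn(mol, a) != 4) next
    bi <- atom_bond_info(mol, a)
    if (any(bi$order > 1)) next
    lab <- wl_ranks(mol, exclude = a)
    branch <- lab[bi$nbr]
    if (anyDuplicated(branch)) next
    if (assigned_only && !nzchar(at$chiral_mark[a])) next
    n <- n + 1L
  }
  n
}

# ---- descriptor vector and rule compliance ---------------------------------

#' Compute the oral drug-likeness descriptor panel
#'
#' Computes the eight-descriptor panel used for Rule-of-5 and Veber
#' assessment from one or more SMILES strings: molecular weight, Crippen
#' logP, hydrogen-bond donors (OH + NH occurrences), hydrogen-bond
#' acceptors (N + O atom count), rotatable bonds, Ertl TPSA, aromatic
#' rings, and stereocentres (assigned plus potential). The QED-convention
#' donor/acceptor counts are emitted as additional columns since the two
#' conventions differ.
#'
#' Structures that fail to parse yield a row with `parse_ok = FALSE` and
#' missing descriptor values; they are excluded from downstream
#' structure-dependent stages (complete-case analysis).
#'
#' @param smiles Character vector of SMILES strings.
#' @param compound_id Optional identifier vector (defaults to names or
#'   index).
#' @return A tibble with one row per input structure.
#' @examples
#' compute_descriptors("O=C1CC(c2ccc(O)cc2)Oc2cc(O)cc(O)c21")  # naringenin
#' @export
compute_descriptors <- function(smiles, compound_id = NULL) {
  if (is.null(compound_id)) {
    compound_id <- names(smiles) %||% as.character(seq_along(smiles))
  }
  stopifnot(length(compound_id) == length(smiles))
  rows <- lapply(seq_along(smiles), function(i) {
    smi <- smiles[[i]]
    mol <- tryCatch(parse_smiles(smi), phenolprofiler_structure_error = function(e) NULL)
    if (is.null(mol)) {
      return(tibble::tibble(
        compound_id = compound_id[[i]], smiles = smi, parse_ok = FALSE,
        mw = NA_real_, logp = NA_real_, hbd = NA_integer_,
        hba_lipinski = NA_integer_, rotb = NA_integer_, tpsa = NA_real_,
        arom_rings = NA_integer_, chiral_centers = NA_integer_,
        hbd_qed = NA_integer_, hba_qed = NA_integer_,
        n_fragments = NA_integer_
      ))
    }
    if (mol$n_fragments > 1) {
      rlang::inform(sprintf("structure '%s' has %d fragments; used as given",
                            smi, mol$n_fragments))
    }
    tibble::tibble(
      compound_id = compound_id[[i]], smiles = smi, parse_ok = TRUE,
      mw = mol_weight(mol), logp = crippen_logp(mol),
      hbd = count_hbd(mol), hba_lipinski = count_hba_lipinski(mol),
      rotb = count_rotatable_bonds(mol), tpsa = tpsa(mol),
      arom_rings = count_aromatic_rings(mol),
      chiral_centers = count_stereocenters(mol),
      hbd_qed = count_hbd_qed(mol), hba_qed = count_hba_qed(mol),
      n_fragments = mol$n_fragments
    )
  })
  dplyr::bind_rows(rows)
}

#' Rule thresholds for Ro5 and Veber assessment
#'
#' @param ro5_mw_max,ro5_logp_max,ro5_hbd_max,ro5_hba_max Lipinski limits.
#' @param ro5_violations_allowed Number of Ro5 breaches tolerated while
#'   still calling a compound compliant.
#' @param veber_rotb_max,veber_tpsa_max Veber limits.
#' @return A `rule_thresholds` list.
#' @export
rule_thresholds <- function(ro5_mw_max = 500, ro5_logp_max = 5,
                            ro5_hbd_max = 5, ro5_hba_max = 10,
                            ro5_violations_allowed = 1,
                            veber_rotb_max = 10, veber_tpsa_max = 140) {
  stopifnot(ro5_mw_max > 0, ro5_logp_max > 0, ro5_hbd_max > 0,
            ro5_hba_max > 0, ro5_violations_allowed >= 0,
            veber_rotb_max > 0, veber_tpsa_max > 0)
  structure(list(
    ro5_mw_max = ro5_mw_max, ro5_logp_max = ro5_logp_max,
    ro5_hbd_max = ro5_hbd_max, ro5_hba_max = ro5_hba_max,
    ro5_violations_allowed = ro5_violations_allowed,
    veber_rotb_max = veber_rotb_max, veber_tpsa_max = veber_tpsa_max
  ), class = "rule_thresholds")
}

#' Lipinski Rule-of-5 assessment
#'
#' All thresholds are inclusive ("no greater than"); a compound is
#' compliant if it breaches at most `ro5_violations_allowed` rules
#' (default one).
#'
#' @param d A one-row descriptor data frame (or list) with `mw`, `logp`,
#'   `hbd`, `hba_lipinski` fields.
#' @param thresholds A [rule_thresholds()] object.
#' @return List with `violations` (character vector of breached rule
#'   names) and `compliant` flag.
#' @export
assess_ro5 <- function(d, thresholds = rule_thresholds()) {
  v <- character(0)
  if (d$mw > thresholds$ro5_mw_max) v <- c(v, "mw")
  if (d$logp > thresholds$ro5_logp_max) v <- c(v, "logp")
  if (d$hbd > thresholds$ro5_hbd_max) v <- c(v, "hbd")
  if (d$hba_lipinski > thresholds$ro5_hba_max) v <- c(v, "hba")
  list(violations = v, compliant = length(v) <= thresholds$ro5_violations_allowed)
}

#' Veber rule assessment
#'
#' Compliant only when both criteria hold: rotatable bonds no more than
#' `veber_rotb_max` and TPSA no more than `veber_tpsa_max` (inclusive).
#'
#' @inheritParams assess_ro5
#' @return List with `violations` and `compliant`.
#' @export
assess_veber <- function(d, thresholds = rule_thresholds()) {
  v <- character(0)
  if (d$rotb > thresholds$veber_rotb_max) v <- c(v, "rotb")
  if (d$tpsa > thresholds$veber_tpsa_max) v <- c(v, "tpsa")
  list(violations = v, compliant = length(v) == 0)
}

#' Annotate a descriptor table with rule compliance
#'
#' @param desc Output of [compute_descriptors()].
#' @param thresholds A [rule_thresholds()] object.
#' @return The input tibble with `ro5_violations`, `ro5_compliant`,
#'   `veber_violations`, `veber_compliant` columns appended.
#' @export
assess_compliance <- function(desc, thresholds = rule_thresholds()) {
  res <- lapply(seq_len(nrow(desc)), function(i) {
    d <- desc[i, ]
    if (!isTRUE(d$parse_ok)) {
      return(list(rv = NA_integer_, rc = NA, vv = NA_integer_, vc = NA))
    }
    r <- assess_ro5(d, thresholds); ve <- assess_veber(d, thresholds)
    list(rv = length(r$violations), rc = r$compliant,
         vv = length(ve$violations), vc = ve$compliant)
  })
  desc$ro5_violations <- vapply(res, `[[`, integer(1), "rv")
  desc$ro5_compliant <- vapply(res, `[[`, logical(1), "rc")
  desc$veber_violations <- vapply(res, `[[`, integer(1), "vv")
  desc$veber_compliant <- vapply(res, `[[`, logical(1), "vc")
  desc
}
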