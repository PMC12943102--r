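# Structural alerts (Brenk-style unwanted-functionality screen).
#
# The full 116-pattern alert list used by the QED ALERTS property is
# bundled as a data file (inst/extdata/structural_alerts.tsv). Matching is
# performed by native molecular-graph matchers implemented for every
# pattern that can occur in polyphenol chemistry space (C/H/O/S
# functionality: quinones, catechols, Michael acceptors, esters, sulfate
# groups, fused aromatics, oxocations, ...). Patterns outside that space
# (organometallics, nitrogen/halogen warheads, isotopes) cannot fire on
# the structures this package handles and are marked unsupported in the
# pattern table.

ring_is <- function(mol, ring, pred) all(pred(ring))

# exocyclic substituent atoms of ring atom a (not in `ring`)
exo_nbrs <- function(mol, a, ring) setdiff(nbrs(mol, a), ring)

has_exo_double <- function(mol, a, elements) {
  bi <- atom_bond_info(mol, a)
  any(bi$order == 2 & mol$atoms$element[bi$nbr] %in% elements &
        !mol$atoms$aromatic[bi$nbr])
}

# -OH / -NH2 / -NH substituent on atom a (outside ring)
oh_like_sub <- function(mol, a, ring, allow_n = TRUE) {
  for (b in exo_nbrs(mol, a, ring)) {
    el <- mol$atoms$element[b]; h <- mol$atoms$h_count[b]
    if (el == "O" && !mol$atoms$aromatic[b] && h == 1) return(TRUE)
    if (allow_n && el == "N" && !mol$atoms$aromatic[b] && h >= 1) return(TRUE)
  }
  FALSE
}

aromatic_all_c_rings <- function(mol, size = 6) {
  keep <- vapply(seq_along(mol$rings), function(i) {
    r <- mol$rings[[i]]
    length(r) == size && all(mol$atoms$element[r] == "C") &&
      all(mol$bonds$aromatic[mol$ring_bonds[[i]]])
  }, logical(1))
  mol$rings[keep]
}

aromatic_rings <- function(mol) {
  keep <- vapply(seq_along(mol$rings), function(i)
    all(mol$bonds$aromatic[mol$ring_bonds[[i]]]), logical(1))
  list(rings = mol$rings[keep], bonds = mol$ring_bonds[keep])
}

# ortho/para OH pattern on an aromatic carbocycle
dihydroxy_arene <- function(mol, gap) {
  for (ring in aromatic_all_c_rings(mol)) {
    m <- length(ring)
    for (i in seq_len(m)) {
      j <- ((i - 1 + gap) %% m) + 1
      a <- ring[i]; b <- ring[j]
      if (oh_like_sub(mol, a, ring, allow_n = FALSE) &&
          oh_like_sub(mol, b, ring, allow_n = TRUE)) return(TRUE)
    }
  }
  FALSE
}

quinone_ring <- function(mol, ortho) {
  for (idx in seq_along(mol$rings)) {
    ring <- mol$rings[[idx]]
    if (length(ring) != 6) next
    if (!all(mol$atoms$element[ring] == "C") || any(mol$atoms$aromatic[ring])) next
    carbonyl <- vapply(ring, function(a) has_exo_double(mol, a, c("O", "N")), logical(1))
    if (sum(carbonyl) < 2) next
    pos <- which(carbonyl)
    for (i in pos) for (j in pos) {
      if (i >= j) next
      gap <- min(j - i, 6 - (j - i))
      if (ortho && gap == 1) return(TRUE)
      if (!ortho && gap == 3) {
        # both arcs between the carbonyls must carry a C=C
        rb <- mol$ring_bonds[[idx]]
        if (sum(mol$bonds$order[rb] == 2) >= 2) return(TRUE)
      }
    }
  }
  FALSE
}

ester_groups <- function(mol) {
  # list of acyl-carbon indices of C(=O)O-C groups
  at <- mol$atoms
  out <- integer(0)
  for (a in seq_len(nrow(at))) {
    if (at$element[a] != "C") next
    bi <- atom_bond_info(mol, a)
    dbl_o <- any(bi$order == 2 & at$element[bi$nbr] == "O" & !at$aromatic[bi$nbr])
    if (!dbl_o) next
    sing_o <- bi$nbr[bi$order == 1 & at$element[bi$nbr] == "O" & !at$aromatic[bi$nbr]]
    for (o in sing_o) {
      oc <- nbrs(mol, o)
      if (any(at$element[setdiff(oc, a)] == "C")) { out <- c(out, a); break }
    }
  }
  out
}

fused_aromatic_triple <- function(mol, angular) {
  ar <- aromatic_rings(mol)
  rings <- ar$rings; rbonds <- ar$bonds
  nr <- length(rings)
  if (nr < 3) return(FALSE)
  shared_edge <- function(i, j) intersect(rbonds[[i]], rbonds[[j]])
  for (mid in seq_len(nr)) {
    others <- setdiff(seq_len(nr), mid)
    for (i in others) for (j in others) {
      if (i >= j) next
      e1 <- shared_edge(mid, i); e2 <- shared_edge(mid, j)
      if (length(e1) != 1 || length(e2) != 1) next
      # position of the two fusion edges within the middle ring
      a1 <- c(mol$bonds$a1[e1], mol$bonds$a2[e1])
      a2 <- c(mol$bonds$a1[e2], mol$bonds$a2[e2])
      shared_atoms <- length(intersect(a1, a2))
      if (angular && shared_atoms == 0) {
        # angular: fusion edges separated by one ring bond on one side
        ring <- rings[[mid]]; m <- length(ring)
        p1 <- match(a1, ring); p2 <- match(a2, ring)
        gap <- min(abs(min(p1) - min(p2)), m - abs(min(p1) - min(p2)))
        if (gap <= 2) return(TRUE)
      }
      if (!angular && shared_atoms == 0) {
        ring <- rings[[mid]]; m <- length(ring)
        p1 <- match(a1, ring); p2 <- match(a2, ring)
        gap <- min(abs(min(p1) - min(p2)), m - abs(min(p1) - min(p2)))
        if (gap == 3) return(TRUE)
      }
    }
  }
  FALSE
}

ALERT_MATCHERS <- list(
  # id = RDKit/Brenk list position (1-based)
  alert_001 = function(mol) {  # three-membered heterocycle
    any(vapply(mol$rings, function(r)
      length(r) == 3 && any(mol$atoms$element[r] %in% c("O", "N", "S")),
      logical(1)))
  },
  alert_011 = function(mol) {  # aldehyde
    at <- mol$atoms
    any(vapply(seq_len(nrow(at)), function(a) {
      at$element[a] == "C" && !at$aromatic[a] && at$h_count[a] == 1 &&
        has_exo_double(mol, a, "O")
    }, logical(1)))
  },
  alert_012 = function(mol) {  # O-O bond
    any(mol$atoms$element[mol$bonds$a1] == "O" &
          mol$atoms$element[mol$bonds$a2] == "O")
  },
  alert_020 = function(mol) {  # isolated (di)alkyl alkene
    at <- mol$atoms
    is_cx4 <- function(a) at$element[a] == "C" && !at$aromatic[a] &&
      conn(mol, a) == 4 && !any(mol$bonds$order[mol$adj[[a]]] > 1)
    simple_end <- function(a) {
      if (at$element[a] != "C" || at$aromatic[a]) return(FALSE)
      h <- at$h_count[a]
      cx4_nbrs <- sum(vapply(nbrs(mol, a), is_cx4, logical(1)))
      h == 2 || (h == 1 && cx4_nbrs >= 1) || cx4_nbrs >= 2
    }
    for (k in seq_len(nrow(mol$bonds))) {
      if (mol$bonds$order[k] != 2) next
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
      if (simple_end(a) && simple_end(b)) return(TRUE)
    }
    FALSE
  },
  alert_021 = function(mol) quinone_ring(mol, ortho = FALSE),
  alert_022 = function(mol) quinone_ring(mol, ortho = TRUE),
  alert_023 = function(mol) fused_aromatic_triple(mol, angular = FALSE),
  alert_024 = function(mol) fused_aromatic_triple(mol, angular = TRUE),
  alert_029 = function(mol) {  # O-sulfate with anionic oxygen
    at <- mol$atoms
    any(vapply(seq_len(nrow(at)), function(s) {
      if (at$element[s] != "S") return(FALSE)
      bi <- atom_bond_info(mol, s)
      o_dbl <- sum(bi$order == 2 & at$element[bi$nbr] == "O")
      o_min <- any(bi$order == 1 & at$element[bi$nbr] == "O" & at$charge[bi$nbr] < 0)
      o_est <- sum(bi$order == 1 & at$element[bi$nbr] == "O") >= 2
      o_dbl >= 2 && o_min && o_est
    }, logical(1)))
  },
  alert_049 = function(mol) {  # benzo-fused aromatic lactone (coumarin-like)
    ar <- aromatic_rings(mol)
    carbo <- aromatic_all_c_rings(mol)
    for (ri in seq_along(ar$rings)) {
      ring <- ar$rings[[ri]]
      if (length(ring) != 6) next
      o_at <- ring[mol$atoms$element[ring] == "O"]
      if (length(o_at) != 1) next
      ring_nb <- intersect(nbrs(mol, o_at), ring)
      carbonyl <- vapply(ring_nb, function(c1)
        mol$atoms$element[c1] == "C" && has_exo_double(mol, c1, "O"), logical(1))
      if (!any(carbonyl)) next
      other <- ring_nb[!carbonyl]
      fused <- any(vapply(carbo, function(r2)
        !identical(sort(r2), sort(ring)) && length(intersect(r2, ring)) >= 2 &&
          any(other %in% r2), logical(1)))
      if (fused) return(TRUE)
    }
    FALSE
  },
  alert_050 = function(mol) {  # O+/S+ cation (e.g. flavylium oxygen)
    any(mol$atoms$element %in% c("O", "S") & mol$atoms$charge > 0)
  },
  alert_054 = function(mol) {  # acyclic conjugated diene
    at <- mol$atoms
    dbl <- which(mol$bonds$order == 2 &
                   at$element[mol$bonds$a1] == "C" & at$element[mol$bonds$a2] == "C" &
                   at$ring_count[mol$bonds$a1] == 0 & at$ring_count[mol$bonds$a2] == 0)
    if (length(dbl) < 2) return(FALSE)
    for (k1 in dbl) for (k2 in dbl) {
      if (k1 >= k2) next
      e1 <- c(mol$bonds$a1[k1], mol$bonds$a2[k1])
      e2 <- c(mol$bonds$a1[k2], mol$bonds$a2[k2])
      for (a in e1) for (b in e2) {
        k <- mol$adj[[a]][other_end(mol, mol$adj[[a]], a) == b]
        if (length(k) == 1 && mol$bonds$order[k] == 1) return(TRUE)
      }
    }
    FALSE
  },
  alert_058 = function(mol) dihydroxy_arene(mol, gap = 1),
  alert_072 = function(mol) dihydroxy_arene(mol, gap = 3),
  alert_087 = function(mol) {  # sulfonic/sulfate acid terminus
    at <- mol$atoms
    any(vapply(seq_len(nrow(at)), function(s) {
      if (at$element[s] != "S") return(FALSE)
      bi <- atom_bond_info(mol, s)
      o_dbl <- sum(bi$order == 2 & at$element[bi$nbr] == "O")
      acid_o <- any(bi$order == 1 & at$element[bi$nbr] == "O" &
                      (at$charge[bi$nbr] < 0 | at$h_count[bi$nbr] >= 1))
      o_dbl >= 2 && acid_o
    }, logical(1)))
  },
  alert_092 = function(mol) length(ester_groups(mol)) >= 3,
  alert_102 = function(mol) {  # four-in-a-row divalent acyclic linker atoms
    at <- mol$atoms
    ok <- which(at$degree == 2 & at$ring_count == 0)
    if (length(ok) < 4) return(FALSE)
    okset <- logical(nrow(at)); okset[ok] <- TRUE
    extend <- function(path) {
      if (length(path) == 4) return(TRUE)
      tail_a <- path[length(path)]
      for (b in nbrs(mol, tail_a)) {
        if (okset[b] && !b %in% path && extend(c(path, b))) return(TRUE)
      }
      FALSE
    }
    any(vapply(ok, function(a) extend(a), logical(1)))
  },
  alert_104 = function(mol) {  # Michael acceptor: acyclic C=C conjugated to C=O/S
    at <- mol$atoms
    for (k in seq_len(nrow(mol$bonds))) {
      if (mol$bonds$order[k] != 2 || mol$bonds$in_ring[k]) next
      ends <- c(mol$bonds$a1[k], mol$bonds$a2[k])
      if (!all(at$element[ends] == "C" & !at$aromatic[ends])) next
      for (a in ends) {
        for (b in nbrs(mol, a)) {
          if (b %in% ends) next
          if (at$element[b] == "C" && !at$aromatic[b] &&
              has_exo_double(mol, b, c("O", "S"))) return(TRUE)
        }
      }
    }
    FALSE
  },
  alert_105 = function(mol) length(ester_groups(mol)) >= 1,
  alert_106 = function(mol) {  # acyclic aryl ketone/thioketone
    at <- mol$atoms
    any(vapply(seq_len(nrow(at)), function(a) {
      if (at$element[a] != "C" || at$aromatic[a] || at$ring_count[a] > 0) return(FALSE)
      if (!has_exo_double(mol, a, c("O", "S"))) return(FALSE)
      nb <- nbrs(mol, a)
      has_ar_c <- any(at$element[nb] == "C" & at$aromatic[nb])
      # a second, distinct carbon neighbour (aromatic or not)
      c_nb <- nb[at$element[nb] == "C"]
      has_ar_c && length(c_nb) >= 2
    }, logical(1)))
  }
)

#' Structural alert pattern table
#'
#' Returns the bundled Brenk-style alert pattern list used for the QED
#' ALERTS property: pattern id (list position), SMARTS (provenance), and
#' whether a native graph matcher is available. Native matchers cover all
#' functionality expressible in the C/H/O/S chemistry of flavonoids and
#' phenolic acids; the remaining patterns cannot match such structures.
#'
#' @return A tibble with columns `id`, `smarts`, `native`.
#' @export
qed_alert_patterns <- function() {
  path <- system.file("extdata", "structural_alerts.tsv",
                      package = "phenolprofiler", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$native <- tab$id %in% names(ALERT_MATCHERS)
  tibble::as_tibble(tab)
}

#' Count structural alerts in a structure
#'
#' Number of distinct alert patterns present (each pattern counts once no
#' matter how many times it matches), as used by the QED ALERTS property.
#'
#' @param mol A `phmol` object or SMILES string.
#' @param which_patterns Optional character vector of pattern ids to
#'   restrict the screen (default: all natively supported patterns).
#' @return Integer count of distinct alerts firing.
#' @export
count_alerts <- function(mol, which_patterns = NULL) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  matchers <- ALERT_MATCHERS
  if (!is.null(which_patterns)) {
    unknown <- setdiff(which_patterns, names(ALERT_MATCHERS))
    if (length(unknown)) {
      rlang::abort(paste0("no native matcher for pattern(s): ",
                          paste(unknown, collapse = ", ")))
    }
    matchers <- matchers[which_patterns]
  }
  sum(vapply(matchers, function(f) isTRUE(f(mol)), logical(1)))
}

#' Which alerts fire in a structure
#'
#' @param mol A `phmol` object or SMILES string.
#' @return Character vector of pattern ids that match.
#' @export
matched_alerts <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  names(ALERT_MATCHERS)[vapply(ALERT_MATCHERS, function(f) isTRUE(f(mol)), logical(1))]
}
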