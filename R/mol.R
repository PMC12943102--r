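# Native molecular graph built from SMILES.
#
# The engine targets the chemistry of dietary polyphenols: C/H/O/N/S(/P,
# halogen) organic-subset atoms, aromatic lowercase notation, branches,
# ring closures (including %nn), charges and H counts in brackets, and
# tetrahedral stereo marks. Aromaticity is taken from the input notation
# (the convention of canonical SMILES as exported by compound databases);
# no aromatic re-perception is attempted, which is documented behaviour.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

# default valences used for implicit hydrogen assignment
DEFAULT_VALENCE <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

# average atomic weights (standard IUPAC values)
ATOMIC_WEIGHT <- c(
  H = 1.008, B = 10.812, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.067, Cl = 35.453, Br = 79.904, I = 126.904
)

structure_error <- function(smiles, msg) {
  rlang::abort(
    message = sprintf("cannot parse structure '%s': %s", smiles, msg),
    class = "phenolprofiler_structure_error",
    smiles = smiles
  )
}

#' Parse a SMILES string into a molecular graph
#'
#' Builds the molecular-graph object used by every structure-dependent
#' calculation in the package (descriptors, QED, alerts, fragment scores).
#' Aromatic atoms must be written in lowercase aromatic notation, as in
#' canonical SMILES from the major compound databases; the parser does not
#' re-perceive aromaticity from a Kekule drawing.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `phmol`: a list with `atoms` (data frame of
#'   element, aromatic flag, charge, hydrogen count, degree, ring
#'   membership), `bonds` (data frame of endpoint indices, bond order,
#'   aromatic and ring flags), `rings` (list of atom-index vectors for a
#'   smallest set of smallest rings), `adj` (adjacency list), and
#'   `n_fragments` (number of disconnected components).
#' @examples
#' m <- parse_smiles("O=C1CC(c2ccc(O)cc2)Oc2cc(O)ccc21")  # liquiritigenin
#' nrow(m$atoms)
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    structure_error(if (is.character(smiles) && length(smiles) == 1L) smiles else "<non-string>",
                    "input must be a single non-empty string")
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n_ch <- length(chars)

  element <- character(0); aromatic <- logical(0); charge <- integer(0)
  h_explicit <- integer(0); bracket <- logical(0); chiral <- character(0)

  b_a1 <- integer(0); b_a2 <- integer(0); b_order <- numeric(0)
  b_sym <- character(0)

  prev <- NA_integer_         # previous atom index
  stack <- integer(0)         # branch stack
  pending_bond <- ""          # bond symbol awaiting next atom
  ring_open <- list()         # closure number -> list(atom, bond)
  i <- 1L

  add_atom <- function(el, arom, chg, hexp, brk, chi) {
    element[length(element) + 1L] <<- el
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- chg
    h_explicit[length(h_explicit) + 1L] <<- hexp
    bracket[length(bracket) + 1L] <<- brk
    chiral[length(chiral) + 1L] <<- chi
    length(element)
  }
  add_bond <- function(a1, a2, sym) {
    if (a1 == a2) structure_error(smiles, "self bond")
    b_a1[length(b_a1) + 1L] <<- a1
    b_a2[length(b_a2) + 1L] <<- a2
    b_sym[length(b_sym) + 1L] <<- sym
  }

  while (i <= n_ch) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n_ch && chars[j] != "]") j <- j + 1L
      if (j > n_ch) structure_error(smiles, "unclosed bracket atom")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      mt <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?|\\*)(@{0,2})(H[0-9]*)?(\\+{1,3}|-{1,3}|\\+[0-9]+|-[0-9]+)?(:[0-9]+)?$",
        body))[[1]]
      if (length(mt) == 0L) structure_error(smiles, paste0("bad bracket atom [", body, "]"))
      sym <- mt[3]
      if (sym == "*") structure_error(smiles, "wildcard atoms unsupported")
      arom <- sym == tolower(sym) && nchar(sym) <= 2L &&
        tolower(sym) %in% c("b", "c", "n", "o", "p", "s", "se", "as")
      el <- if (arom) paste0(toupper(substr(sym, 1, 1)), substring(sym, 2)) else sym
      if (!el %in% names(ATOMIC_WEIGHT)) {
        structure_error(smiles, paste0("unsupported element '", el, "'"))
      }
      hexp <- 0L
      if (!is.na(mt[5]) && nzchar(mt[5])) {
        hexp <- if (mt[5] == "H") 1L else as.integer(substring(mt[5], 2))
      }
      chg <- 0L
      if (!is.na(mt[6]) && nzchar(mt[6])) {
        cstr <- mt[6]
        if (grepl("^[+-]+$", cstr)) {
          chg <- nchar(cstr) * if (substr(cstr, 1, 1) == "+") 1L else -1L
        } else {
          chg <- as.integer(substring(cstr, 2)) *
            if (substr(cstr, 1, 1) == "+") 1L else -1L
        }
      }
      idx <- add_atom(el, arom, chg, hexp, TRUE, mt[4])
      if (!is.na(prev)) add_bond(prev, idx, pending_bond)
      pending_bond <- ""; prev <- idx
      i <- j + 1L
    } else if (grepl("[A-Za-z]", ch)) {
      el2 <- if (i < n_ch) paste0(ch, chars[i + 1L]) else ""
      if (el2 %in% c("Cl", "Br")) {
        idx <- add_atom(el2, FALSE, 0L, NA_integer_, FALSE, "")
        i <- i + 2L
      } else {
        arom <- ch %in% c("b", "c", "n", "o", "p", "s")
        el <- toupper(ch)
        if (!el %in% ORGANIC_SUBSET) {
          structure_error(smiles, paste0("unknown organic-subset atom '", ch, "'"))
        }
        idx <- add_atom(el, arom, 0L, NA_integer_, FALSE, "")
        i <- i + 1L
      }
      if (!is.na(prev)) add_bond(prev, idx, pending_bond)
      pending_bond <- ""; prev <- idx
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- ch
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) structure_error(smiles, "branch with no preceding atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) structure_error(smiles, "unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n_ch || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L]))) {
          structure_error(smiles, "bad %nn ring closure")
        }
        rn <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else {
        rn <- ch; i <- i + 1L
      }
      if (is.na(prev)) structure_error(smiles, "ring closure with no atom")
      if (!is.null(ring_open[[rn]])) {
        op <- ring_open[[rn]]
        sym <- if (nzchar(pending_bond)) pending_bond else op$bond
        add_bond(op$atom, prev, sym)
        ring_open[[rn]] <- NULL
      } else {
        ring_open[[rn]] <- list(atom = prev, bond = pending_bond)
      }
      pending_bond <- ""
    } else if (ch == ".") {
      prev <- NA_integer_; pending_bond <- ""
      i <- i + 1L
    } else if (ch == " ") {
      break  # SMILES title/comment field
    } else {
      structure_error(smiles, paste0("unexpected character '", ch, "'"))
    }
  }
  if (length(stack) > 0L) structure_error(smiles, "unclosed branch")
  if (length(ring_open) > 0L) structure_error(smiles, "unclosed ring bond")
  if (length(element) == 0L) structure_error(smiles, "no atoms")

  n <- length(element)
  nb <- length(b_a1)
  # resolve bond orders
  b_arom <- logical(nb)
  b_ord <- numeric(nb)
  for (k in seq_len(nb)) {
    sym <- b_sym[k]
    if (sym == "=") { b_ord[k] <- 2 }
    else if (sym == "#") { b_ord[k] <- 3 }
    else if (sym %in% c("-", "/", "\\")) { b_ord[k] <- 1 }
    else if (sym == ":") { b_ord[k] <- 1.5; b_arom[k] <- TRUE }
    else { # default bond
      if (aromatic[b_a1[k]] && aromatic[b_a2[k]]) { b_ord[k] <- 1.5; b_arom[k] <- TRUE }
      else b_ord[k] <- 1
    }
  }

  # adjacency
  adj <- vector("list", n)
  for (k in seq_len(nb)) {
    adj[[b_a1[k]]] <- c(adj[[b_a1[k]]], k)
    adj[[b_a2[k]]] <- c(adj[[b_a2[k]]], k)
  }
  degree <- vapply(adj, length, integer(1))

  # implicit hydrogens for organic-subset atoms
  h_count <- integer(n)
  for (a in seq_len(n)) {
    if (bracket[a]) {
      h_count[a] <- h_explicit[a]
    } else {
      bsum <- ceiling(sum(b_ord[adj[[a]]]))
      vals <- DEFAULT_VALENCE[[element[a]]]
      v <- vals[vals >= bsum][1]
      h_count[a] <- if (is.na(v)) 0L else as.integer(v - bsum)
    }
  }

  mol <- list(
    atoms = data.frame(
      element = element, aromatic = aromatic, charge = charge,
      h_count = h_count, degree = degree, chiral_mark = chiral,
      stringsAsFactors = FALSE
    ),
    bonds = data.frame(
      a1 = b_a1, a2 = b_a2, order = b_ord, aromatic = b_arom,
      stringsAsFactors = FALSE
    ),
    adj = adj,
    smiles = smiles
  )
  mol <- perceive_rings(mol)
  class(mol) <- "phmol"
  mol
}

#' @export
print.phmol <- function(x, ...) {
  cat(sprintf("<phmol> %s\n  %d atoms, %d bonds, %d rings, formula %s\n",
              x$smiles, nrow(x$atoms), nrow(x$bonds), length(x$rings),
              mol_formula(x)))
  invisible(x)
}

# neighbouring atom indices of atom a
nbrs <- function(mol, a) {
  ks <- mol$adj[[a]]
  if (length(ks) == 0L) return(integer(0))
  other_end(mol, ks, a)
}

other_end <- function(mol, bond_idx, a) {
  ifelse(mol$bonds$a1[bond_idx] == a, mol$bonds$a2[bond_idx],
         mol$bonds$a1[bond_idx])
}

# smallest set of smallest rings via shortest-cycle candidates and GF(2)
# greedy selection up to the cyclomatic number
perceive_rings <- function(mol) {
  n <- nrow(mol$atoms); nb <- nrow(mol$bonds)
  comp <- integer(n); cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      for (b in nbrs(mol, a)) if (comp[b] == 0L) { comp[b] <- cid; queue <- c(queue, b) }
    }
  }
  n_rings <- nb - n + cid
  mol$n_fragments <- cid
  if (n_rings <= 0L) {
    mol$rings <- list()
    mol$ring_bonds <- list()
    mol$atoms$ring_count <- integer(n)
    mol$bonds$in_ring <- logical(nb)
    return(mol)
  }

  # shortest cycle through each bond (BFS in graph minus that bond)
  cand <- list()
  for (k in seq_len(nb)) {
    src <- mol$bonds$a1[k]; dst <- mol$bonds$a2[k]
    par <- rep(NA_integer_, n); dist <- rep(NA_integer_, n)
    dist[src] <- 0L; queue <- src
    while (length(queue) && is.na(dist[dst])) {
      a <- queue[1]; queue <- queue[-1]
      for (kk in mol$adj[[a]]) {
        if (kk == k) next
        b <- other_end(mol, kk, a)
        if (is.na(dist[b])) { dist[b] <- dist[a] + 1L; par[b] <- a; queue <- c(queue, b) }
      }
    }
    if (!is.na(dist[dst])) {
      path <- dst
      while (path[1] != src) path <- c(par[path[1]], path)
      cand[[length(cand) + 1L]] <- path
    }
  }
  if (length(cand) == 0L) {
    mol$rings <- list(); mol$ring_bonds <- list()
    mol$atoms$ring_count <- integer(n); mol$bonds$in_ring <- logical(nb)
    return(mol)
  }
  keys <- vapply(cand, function(p) paste(sort(p), collapse = ","), character(1))
  cand <- cand[!duplicated(keys)]
  cand <- cand[order(vapply(cand, length, integer(1)))]

  bond_lookup <- new.env(hash = TRUE)
  for (k in seq_len(nb)) {
    key <- paste(sort(c(mol$bonds$a1[k], mol$bonds$a2[k])), collapse = "-")
    assign(key, k, envir = bond_lookup)
  }
  ring_to_bonds <- function(path) {
    m <- length(path)
    vapply(seq_len(m), function(ii) {
      a <- path[ii]; b <- path[if (ii == m) 1L else ii + 1L]
      get(paste(sort(c(a, b)), collapse = "-"), envir = bond_lookup)
    }, integer(1))
  }

  basis <- matrix(FALSE, nrow = 0, ncol = nb)  # row-reduced GF(2) basis
  pivots <- integer(0)
  rings <- list(); ring_bonds <- list()
  for (r in cand) {
    if (length(rings) >= n_rings) break
    vec <- rep(FALSE, nb)
    rb <- ring_to_bonds(r)
    vec[rb] <- TRUE
    red <- vec
    for (rr in seq_len(nrow(basis))) {
      if (red[pivots[rr]]) red <- xor(red, basis[rr, ])
    }
    if (any(red)) {
      basis <- rbind(basis, red)
      pivots <- c(pivots, which(red)[1])
      rings[[length(rings) + 1L]] <- r
      ring_bonds[[length(ring_bonds) + 1L]] <- rb
    }
  }
  mol$rings <- rings
  mol$ring_bonds <- ring_bonds
  rc <- integer(n)
  for (r in rings) rc[r] <- rc[r] + 1L
  mol$atoms$ring_count <- rc
  br <- logical(nb)
  for (rb in ring_bonds) br[rb] <- TRUE
  mol$bonds$in_ring <- br
  mol
}

#' Molecular formula of a parsed structure
#'
#' @param mol A `phmol` object from [parse_smiles()].
#' @return Hill-order molecular formula string (charge appended as +/-).
#' @export
mol_formula <- function(mol) {
  counts <- table(mol$atoms$element)
  nH <- sum(mol$atoms$h_count)
  els <- names(counts)
  hill <- c(intersect(c("C"), els),
            if (nH > 0) "H",
            sort(setdiff(els, c("C", "H"))))
  out <- vapply(hill, function(el) {
    k <- if (el == "H") nH + sum(counts[names(counts) == "H"]) else counts[[el]]
    paste0(el, if (k > 1) k else "")
  }, character(1))
  net <- sum(mol$atoms$charge)
  paste0(paste(out, collapse = ""),
         if (net > 0) paste0("+", if (net > 1) net else "") else "",
         if (net < 0) paste0("-", if (net < -1) -net else "") else "")
}

#' Molecular weight from atomic composition
#'
#' Average-mass molecular weight, the sum of standard atomic weights over
#' all atoms including implicit hydrogens.
#'
#' @param mol A `phmol` object.
#' @return Molecular weight in g/mol.
#' @export
mol_weight <- function(mol) {
  sum(ATOMIC_WEIGHT[mol$atoms$element]) + sum(mol$atoms$h_count) * ATOMIC_WEIGHT[["H"]]
}

#' Molecular weight of a molecular formula
#'
#' Computes the average-mass molecular weight directly from a formula
#' string such as `"C48H28O30"`. Used for compounds whose identity is
#' known by formula (for example large ellagitannins) without requiring a
#' full structure.
#'
#' @param formula A molecular formula string (element symbols followed by
#'   optional counts).
#' @return Molecular weight in g/mol.
#' @examples
#' formula_weight("C48H28O30")  # punicalagin
#' @export
formula_weight <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!nzchar(formula) || paste(parts, collapse = "") != formula) {
    rlang::abort(paste0("cannot parse formula '", formula, "'"))
  }
  tot <- 0
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    k <- sub("^[A-Za-z]+", "", p)
    k <- if (nzchar(k)) as.integer(k) else 1L
    if (!el %in% names(ATOMIC_WEIGHT)) {
      rlang::abort(paste0("unknown element '", el, "' in formula"))
    }
    tot <- tot + ATOMIC_WEIGHT[[el]] * k
  }
  tot
}

# Weisfeiler-Lehman style canonical atom invariants: iterative
# neighbourhood refinement until the partition stabilizes. Signatures are
# built from sorted neighbour labels, so the resulting ranks are invariant
# to atom ordering in the input SMILES. `exclude` removes an atom from the
# graph (used for stereocentre branch comparison).
wl_ranks <- function(mol, exclude = integer(0)) {
  n <- nrow(mol$atoms)
  keep <- setdiff(seq_len(n), exclude)
  lab <- paste(mol$atoms$element, mol$atoms$aromatic, mol$atoms$charge,
               mol$atoms$h_count, sep = "|")
  lab[exclude] <- NA
  n_classes <- 0L
  for (it in seq_len(max(n, 2L))) {
    sig <- lab
    for (a in keep) {
      ks <- mol$adj[[a]]
      items <- character(0)
      for (k in ks) {
        b <- other_end(mol, k, a)
        if (b %in% exclude) next
        items <- c(items, paste0(mol$bonds$order[k], ":", lab[b]))
      }
      sig[a] <- paste0(lab[a], "{", paste(sort(items), collapse = ","), "}")
    }
    ranks <- match(sig, sort(unique(sig[keep])))
    new_lab <- as.character(ranks)
    new_lab[exclude] <- NA
    k_classes <- length(unique(new_lab[keep]))
    stable <- k_classes == n_classes
    lab <- new_lab
    n_classes <- k_classes
    if (stable) break
  }
  lab
}

# deterministic string hash -> non-negative integer < 2^31 (pure R, no
# platform dependence)
str_hash <- function(x) {
  v <- utf8ToInt(x)
  h <- 2166136261
  for (ch in v) {
    h <- (h * 16777619) %% 2147483647
    h <- (h + ch) %% 2147483647
  }
  h
}

#' Canonical constitution hash of a molecule
#'
#' A graph-invariant hash of element/bond constitution (stereo marks
#' included as atom properties when `stereo = TRUE`). Two SMILES writings
#' of the same molecular graph map to the same hash, which the synthetic
#' generator and the registry use for identity and uniqueness checks.
#'
#' @param mol A `phmol` object.
#' @param stereo Include tetrahedral stereo marks in the hash.
#' @return A character scalar.
#' @export
mol_hash <- function(mol, stereo = FALSE) {
  lab <- paste0(
    mol$atoms$element, ":", as.integer(mol$atoms$aromatic), ":",
    mol$atoms$charge, ":", mol$atoms$h_count, ":", wl_ranks(mol)
  )
  if (stereo) {
    lab <- paste0(lab, "/", mol$atoms$chiral_mark)
  }
  bsig <- character(nrow(mol$bonds))
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      ends <- sort(c(lab[mol$bonds$a1[k]], lab[mol$bonds$a2[k]]))
      bsig[k] <- paste(ends[1], mol$bonds$order[k], ends[2], sep = "~")
    }
  }
  key <- paste(paste(sort(lab), collapse = ";"),
               paste(sort(bsig), collapse = ";"),
               mol_formula(mol), sep = "||")
  format(str_hash(key), scientific = FALSE)
}

#' Synthetic structure key in InChIKey layout
#'
#' Derives a deterministic 27-character identifier in the InChIKey layout
#' (14-character constitution block, 10-character stereo/charge block, one
#' terminal letter) from the molecular graph. This is a surrogate key for
#' synthetic datasets, not a standard InChIKey: it hashes the package's own
#' canonical invariants, so it is stable across writings of the same
#' structure but is not interoperable with external InChIKey resolvers.
#'
#' @param mol A `phmol` object (or SMILES string).
#' @return A 27-character key such as `"ABCDEFGHIJKLMN-OPQRSTUVWX-N"`.
#' @export
structure_key <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  block <- function(seed_string, len) {
    out <- character(len)
    h <- str_hash(seed_string)
    for (i in seq_len(len)) {
      h <- (h * 48271) %% 2147483647
      out[i] <- LETTERS[(h %% 26) + 1]
    }
    paste(out, collapse = "")
  }
  b1 <- block(paste0("c:", mol_hash(mol, stereo = FALSE)), 14)
  b2 <- block(paste0("s:", mol_hash(mol, stereo = TRUE), ":", sum(mol$atoms$charge)), 10)
  paste0(b1, "-", b2, "-N")
}
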