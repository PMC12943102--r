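# Synthetic data generation.
#
# Structures are built by deterministic scaffold decoration (hydroxylation,
# O-methylation, O-glycosylation, sulfation on subclass-faithful cores)
# rather than random graph generation, so every generated SMILES parses,
# is chemically sensible for its subclass, and is unique within a run by
# canonical constitution hash. Activities are truncated-normal pChEMBL
# draws back-converted to assay values in deliberately mixed units; food
# tables are log-normal concentration profiles scaled to hit the
# configured tier structure. Ground truth is always returned (and written)
# alongside the tables.

# scaffold templates: placeholders {x} receive "" (ring CH) or a
# parenthesized substituent; digits 1-3 are reserved for the cores,
# glycoside rings are assigned digits from 4 upward at build time.
SCAFFOLD_TEMPLATES <- list(
  flavanones = list(
    template = "O=C1CC(c2c{b2}c{b3}c{b4}c{b5}c2)Oc2c{a8}c{a7}c{a6}c{a5}c12",
    sites = c("b2", "b3", "b4", "b5", "a8", "a7", "a6", "a5"),
    preferred = c("b4", "a7", "a5", "b3")
  ),
  flavones = list(
    template = "O=c1cc(-c2c{b2}c{b3}c{b4}c{b5}c2)oc2c{a8}c{a7}c{a6}c{a5}c12",
    sites = c("b2", "b3", "b4", "b5", "a8", "a7", "a6", "a5"),
    preferred = c("b4", "a7", "a5", "b3")
  ),
  flavonols = list(
    template = "O=c1c{c3}c(-c2c{b2}c{b3}c{b4}c{b5}c2)oc2c{a8}c{a7}c{a6}c{a5}c12",
    sites = c("c3", "b2", "b3", "b4", "b5", "a8", "a7", "a6", "a5"),
    preferred = c("c3", "b4", "a7", "a5", "b3"),
    required = "c3"
  ),
  isoflavonoids = list(
    template = "O=c1c(-c2c{b2}c{b3}c{b4}c{b5}c2)coc2c{a8}c{a7}c{a6}c{a5}c12",
    sites = c("b2", "b3", "b4", "b5", "a8", "a7", "a6", "a5"),
    preferred = c("b4", "a7", "a5", "b2")
  ),
  isoflavanones = list(
    template = "O=C1c2c{a5}c{a6}c{a7}c{a8}c2OCC1c1c{b2}c{b3}c{b4}c{b5}c1",
    sites = c("a5", "a6", "a7", "a8", "b2", "b3", "b4", "b5"),
    preferred = c("a7", "b4", "b2", "a5")
  ),
  `flavan-3-ols` = list(
    template = "OC1Cc2c{a5}c{a6}c{a7}c{a8}c2OC1c1c{b2}c{b3}c{b4}c{b5}c1",
    sites = c("a5", "a6", "a7", "a8", "b2", "b3", "b4", "b5"),
    preferred = c("a5", "a7", "b4", "b3")
  ),
  anthocyanins = list(
    template = "Oc1cc(O)c2cc{c3}c(-c3c{b2}c{b3}c{b4}c{b5}c3)[o+]c2c1",
    sites = c("c3", "b2", "b3", "b4", "b5"),
    preferred = c("c3", "b4", "b3"),
    required = "c3"
  ),
  chalcones = list(
    template = "O=C(C=Cc1c{b2}c{b3}c{b4}c{b5}c1)c1c{a2}c{a3}c{a4}c{a5}c1",
    sites = c("b2", "b3", "b4", "b5", "a2", "a3", "a4", "a5"),
    preferred = c("b4", "a2", "a4", "b3")
  ),
  `hydroxycinnamic acids` = list(
    template = "O=C(O)C=Cc1c{b2}c{b3}c{b4}c{b5}c1",
    sites = c("b2", "b3", "b4", "b5"),
    preferred = c("b4", "b3", "b5")
  ),
  `hydroxybenzoic acids` = list(
    template = "O=C(O)c1c{b2}c{b3}c{b4}c{b5}c1",
    sites = c("b2", "b3", "b4", "b5"),
    preferred = c("b4", "b3", "b5")
  )
)

# poly-galloylated glucose cores used for the deliberately misclassified
# heavy compounds (hydrolyzable-tannin-like masses around 0.9-1.3 kDa)
GALLOYL <- "OC(=O)c2cc(O)c(O)c(O)c2"
DEPSIDE <- "OC(=O)c2cc(O)c(OC(=O)c3cc(O)c(O)c(O)c3)c(O)c2"
HEAVY_TEMPLATES <- c(
  pentagalloyl = paste0("C1(", GALLOYL, ")OC(C", GALLOYL, ")C(", GALLOYL,
                        ")C(", GALLOYL, ")C1", GALLOYL),
  hexagalloyl = paste0("C1(", GALLOYL, ")OC(C", DEPSIDE, ")C(", GALLOYL,
                       ")C(", GALLOYL, ")C1", GALLOYL),
  heptagalloyl = paste0("C1(", DEPSIDE, ")OC(C", DEPSIDE, ")C(", GALLOYL,
                        ")C(", GALLOYL, ")C1", GALLOYL)
)

GLYCOSYL <- function(d) sprintf("OC%dOC(CO)C(O)C(O)C%dO", d, d)
SULFATE <- "OS(=O)(=O)O"

#' Synthetic run configuration
#'
#' Defaults encode the study conditions the generator emulates: 715
#' flavonoids and 239 phenolic acids split over subclasses in the
#' proportions of the cross-database census (flavonols the largest
#' subclass, anthocyanins with the highest registry coverage of 71%,
#' chalcones the lowest at 38%); per-class pChEMBL activity models
#' (flavonoids mean 7.26, SD 1.09, range 6.01-9.70; phenolic acids 6.98,
#' 0.94, 6.01-9.00) with 239 and 141 compound-target pairs; target pools
#' of 67 and 33 proteins sharing SLCO1B1, SLCO1B3 and p53; and eight food
#' groups whose totals span the three concentration tiers, with the
#' beverage group dominated (95%) by a single compound.
#'
#' @param n_flavonoids,n_phenolic_acids Compound counts per class.
#' @param subclass_proportions Named proportions within each class
#'   (normalized internally).
#' @param registry_coverage Named per-subclass probability of carrying a
#'   molecular registry number.
#' @param misclass_n Number of deliberately misclassified heavy compounds
#'   injected into the hydroxybenzoic-acid subclass.
#' @param activity_model Per-class list of `mu`, `sigma`, `min`, `max`
#'   for pChEMBL.
#' @param n_activities Named clean compound-target pair counts per class.
#' @param target_pools Named pool sizes of distinct targets per class.
#' @param shared_targets Target names present in both pools.
#' @param violation_fraction Fraction of emitted activity records that
#'   violate one inclusion criterion (ground-truthed).
#' @param redundant_assay_fraction Fraction of pairs that also emit 1-2
#'   weaker replicate assays (exercises the per-pair collapse).
#' @param food_model List with `n_foods` and `n_compounds` per group,
#'   log-normal dispersion `sdlog`, tier cycle, dominant group and share.
#' @param seed Integer seed; every downstream draw derives from it.
#' @return A `synthesis_config` list.
#' @export
synthesis_config <- function(
    n_flavonoids = 715,
    n_phenolic_acids = 239,
    subclass_proportions = c(
      flavonols = 324, isoflavonoids = 198, flavones = 156,
      anthocyanins = 89, chalcones = 45,
      `hydroxycinnamic acids` = 167, `hydroxybenzoic acids` = 89),
    registry_coverage = c(
      flavonols = 0.58, isoflavonoids = 0.52, flavones = 0.54,
      anthocyanins = 0.71, chalcones = 0.38,
      `hydroxycinnamic acids` = 0.62, `hydroxybenzoic acids` = 0.58,
      flavanones = 0.55, isoflavanones = 0.55, `flavan-3-ols` = 0.5),
    misclass_n = 3,
    activity_model = list(
      flavonoid = list(mu = 7.26, sigma = 1.09, min = 6.01, max = 9.70),
      phenolic_acid = list(mu = 6.98, sigma = 0.94, min = 6.01, max = 9.00)),
    n_activities = c(flavonoid = 239, phenolic_acid = 141),
    target_pools = c(flavonoid = 67, phenolic_acid = 33),
    shared_targets = c("SLCO1B1", "SLCO1B3", "Cellular tumor antigen p53"),
    violation_fraction = 0.1,
    redundant_assay_fraction = 0.25,
    food_model = list(
      n_foods = 3, n_compounds = c(4, 10), sdlog = 0.9,
      tiers = c("high", "medium", "lower"),
      dominant_group = "beverages (non-tea)", dominant_share = 0.95),
    seed = 1L) {
  stopifnot(n_flavonoids >= 0, n_phenolic_acids >= 0,
            all(registry_coverage >= 0 & registry_coverage <= 1),
            all(vapply(activity_model, function(m)
              m$sigma > 0 && m$min < m$max, logical(1))),
            all(target_pools >= length(shared_targets)),
            violation_fraction >= 0, violation_fraction < 1)
  structure(list(
    n_flavonoids = n_flavonoids, n_phenolic_acids = n_phenolic_acids,
    subclass_proportions = subclass_proportions,
    registry_coverage = registry_coverage, misclass_n = misclass_n,
    activity_model = activity_model, n_activities = n_activities,
    target_pools = target_pools, shared_targets = shared_targets,
    violation_fraction = violation_fraction,
    redundant_assay_fraction = redundant_assay_fraction,
    food_model = food_model, seed = as.integer(seed)
  ), class = "synthesis_config")
}

# instantiate one decorated scaffold; `subs` maps site -> substituent
build_structure <- function(subclass, subs) {
  sc <- SCAFFOLD_TEMPLATES[[subclass]]
  if (is.null(sc)) {
    rlang::abort(sprintf("no scaffold for subclass '%s'", subclass),
                 class = "phenolprofiler_generation_error")
  }
  smi <- sc$template
  for (site in sc$sites) {
    rep <- if (site %in% names(subs)) paste0("(", subs[[site]], ")") else ""
    smi <- sub(paste0("{", site, "}"), rep, smi, fixed = TRUE)
  }
  smi
}

# draw a decoration set for one compound
draw_decorations <- function(subclass) {
  sc <- SCAFFOLD_TEMPLATES[[subclass]]
  n_sub <- sample(1:min(4, length(sc$sites)), 1,
                  prob = c(0.3, 0.35, 0.25, 0.1)[1:min(4, length(sc$sites))])
  pref <- sc$preferred
  sites <- unique(c(
    if (!is.null(sc$required)) sc$required,
    sample(pref, min(n_sub, length(pref))),
    if (n_sub > length(pref)) sample(setdiff(sc$sites, pref), n_sub - length(pref))
  ))
  gly_digit <- 4L
  subs <- list()
  for (s in sites) {
    kind <- sample(c("oh", "ome", "gly", "sulf"), 1,
                   prob = c(0.62, 0.22, 0.12, 0.04))
    subs[[s]] <- switch(kind,
      oh = "O",
      ome = "OC",
      sulf = SULFATE,
      gly = { g <- GLYCOSYL(gly_digit); gly_digit <- gly_digit + 1L; g })
  }
  subs
}

#' Generate a synthetic compound table
#'
#' Builds the requested number of flavonoids and phenolic acids by
#' scaffold decoration, assigns registry numbers with the configured
#' per-subclass coverage probabilities, derives identifier keys from the
#' generated structures, and injects the configured number of
#' deliberately misclassified heavy (poly-galloylated) compounds labelled
#' as hydroxybenzoic acids. Generation is fully deterministic under the
#' config seed.
#'
#' @param config A [synthesis_config()].
#' @return List with `compounds` (record tibble ready for the registry)
#'   and `truth` (ground-truth list: true heavy compound ids, per-subclass
#'   registry assignment counts).
#' @export
generate_compounds <- function(config) {
  props <- config$subclass_proportions
  cls_of <- function(sc) {
    if (sc %in% c("hydroxycinnamic acids", "hydroxybenzoic acids")) "phenolic_acid"
    else "flavonoid"
  }
  fl <- props[vapply(names(props), cls_of, character(1)) == "flavonoid"]
  pa <- props[vapply(names(props), cls_of, character(1)) == "phenolic_acid"]
  alloc <- function(p, n) {
    if (n == 0 || length(p) == 0) return(integer(0))
    k <- floor(p / sum(p) * n)
    rem <- n - sum(k)
    if (rem > 0) {
      extra <- order(p / sum(p) * n - k, decreasing = TRUE)[seq_len(rem)]
      k[extra] <- k[extra] + 1L
    }
    stats::setNames(as.integer(k), names(p))
  }
  counts <- c(alloc(fl, config$n_flavonoids), alloc(pa, config$n_phenolic_acids))

  with_seed(child_seed(config$seed, "compounds"), {
    rows <- list()
    seen <- new.env(hash = TRUE)
    idx <- 0L
    for (sc in names(counts)) {
      n_sc <- counts[[sc]]
      if (n_sc == 0) next
      made <- 0L
      tries <- 0L
      while (made < n_sc) {
        tries <- tries + 1L
        if (tries > 60L * n_sc) {
          rlang::abort(sprintf("decoration space exhausted for scaffold '%s'", sc),
                       class = "phenolprofiler_generation_error")
        }
        smi <- build_structure(sc, draw_decorations(sc))
        mol <- parse_smiles(smi)
        h <- mol_hash(mol)
        if (!is.null(seen[[h]])) next
        seen[[h]] <- TRUE
        made <- made + 1L; idx <- idx + 1L
        cov <- config$registry_coverage[[sc]] %||% 0.5
        rows[[idx]] <- tibble::tibble(
          compound_id = sprintf("SYN%04d", idx),
          name = sprintf("synthetic %s %03d", sub("s$", "", sc), made),
          cls = cls_of(sc), subclass = sc, smiles = smi,
          inchikey = structure_key(mol),
          registry_number = if (stats::runif(1) < cov)
            sprintf("%06d", sample.int(999999, 1)) else NA_character_,
          mw = mol_weight(mol),
          true_heavy = FALSE
        )
      }
    }
    # deliberately misclassified heavy compounds
    heavy_ids <- character(0)
    if (config$misclass_n > 0 && "hydroxybenzoic acids" %in% names(counts)) {
      for (j in seq_len(config$misclass_n)) {
        tmpl <- HEAVY_TEMPLATES[[((j - 1L) %% length(HEAVY_TEMPLATES)) + 1L]]
        mol <- parse_smiles(tmpl)
        idx <- idx + 1L
        id <- sprintf("SYN%04d", idx)
        heavy_ids <- c(heavy_ids, id)
        rows[[idx]] <- tibble::tibble(
          compound_id = id,
          name = sprintf("synthetic tannin %02d", j),
          cls = "phenolic_acid", subclass = "hydroxybenzoic acids",
          smiles = tmpl, inchikey = structure_key(mol),
          registry_number = NA_character_, mw = mol_weight(mol),
          true_heavy = TRUE
        )
      }
    }
    compounds <- dplyr::bind_rows(rows)
    if (nrow(compounds) == 0) {
      compounds <- tibble::tibble(
        compound_id = character(0), name = character(0), cls = character(0),
        subclass = character(0), smiles = character(0),
        inchikey = character(0), registry_number = character(0),
        mw = numeric(0), true_heavy = logical(0))
    }
    compounds$sources <- lapply(seq_len(nrow(compounds)), function(i) "synthetic")
    list(
      compounds = compounds,
      truth = list(
        counts = as.list(counts),
        heavy_ids = heavy_ids,
        n_with_registry = as.list(
          tapply(!is.na(compounds$registry_number), compounds$subclass, sum))
      )
    )
  })
}

rtruncnorm_reject <- function(n, mu, sigma, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2L * (n - length(out)) + 10L, mu, sigma)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

# moments of a normal truncated to [lo, hi]
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  if (Z < 1e-12) return(c(mean = (lo + hi) / 2, sd = 0))
  pa <- stats::dnorm(a); pb <- stats::dnorm(b)
  m <- mu + sigma * (pa - pb) / Z
  v <- sigma^2 * (1 + (a * pa - b * pb) / Z - ((pa - pb) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Solve for the underlying normal whose truncation to [lo, hi] has the
# requested observed moments. Configured activity means/SDs describe the
# bounded data a study reports, not the latent normal, so the latent
# parameters are calibrated: the mean is matched exactly and the SD as
# closely as the bounds permit (a bounded interval caps the attainable
# SD).
calibrate_truncnorm <- function(mean_t, sd_t, lo, hi) {
  L <- hi - lo
  obj <- function(par) {
    mo <- truncnorm_moments(par[1], par[2], lo, hi)
    100 * (mo["mean"] - mean_t)^2 + (mo["sd"] - sd_t)^2
  }
  # latent parameters are box-constrained so the truncated density stays
  # non-degenerate and rejection sampling stays efficient
  fit <- stats::optim(c(mean_t, min(sd_t, L / 2)), obj, method = "L-BFGS-B",
                      lower = c(lo - L, 0.05), upper = c(hi + L, 1.5 * L),
                      control = list(maxit = 500, factr = 1e4))
  list(mu = fit$par[1], sigma = fit$par[2],
       achieved = truncnorm_moments(fit$par[1], fit$par[2], lo, hi))
}

target_pool <- function(cls, size, shared) {
  real <- if (cls == "flavonoid") {
    c("MAP kinase ERK2", "c-Jun N-terminal kinase 1", "Casein kinase I",
      "Thyroid hormone receptor beta-1",
      "Canalicular multispecific organic anion transporter 1",
      "Cyclooxygenase", "Bloom syndrome protein")
  } else {
    c("Estrogen receptor alpha", "CaM kinase II alpha",
      "Muscarinic acetylcholine receptor M1",
      "Nuclear factor NF-kappa-B p105 subunit",
      "Matrix metalloproteinase-2", "Androgen Receptor")
  }
  classes <- c("kinase", "transporter", "nuclear receptor", "DNA repair",
               "protease", "other enzyme")
  nm <- c(shared, real)
  extra_n <- size - length(nm)
  if (extra_n > 0) {
    nm <- c(nm, sprintf("%s target %02d",
                        if (cls == "flavonoid") "flavonoid" else "phenolic",
                        seq_len(extra_n)))
  } else {
    nm <- nm[seq_len(size)]
  }
  tibble::tibble(
    target_id = paste0("T", toupper(substr(cls, 1, 1)),
                       sprintf("%03d", seq_along(nm))),
    target_name = nm,
    target_class = rep_len(classes, length(nm))
  )
}

#' Generate a synthetic bioactivity table
#'
#' Draws per-class truncated-normal pChEMBL values, back-converts them to
#' IC50/EC50/Ki/Kd assay values in a deliberate mixture of nM and uM
#' units, assigns targets from per-class pools that include the shared
#' transporters/p53, adds weaker replicate assays for a fraction of pairs
#' (so the per-pair collapse has work to do), and appends records that
#' violate each inclusion criterion in turn, all ground-truthed.
#'
#' Shared-target identifiers are harmonized across classes so that target
#' ids refer to the same protein in both pools.
#'
#' @param config A [synthesis_config()].
#' @param compounds Compound table from [generate_compounds()].
#' @return List with `activities` (raw record tibble, filter-ready) and
#'   `truth` (clean pair count, per-class generative parameters, per-class
#'   target diversity, violating record ids).
#' @export
generate_activities <- function(config, compounds) {
  with_seed(child_seed(config$seed, "activities"), {
    recs <- list()
    truth_div <- list()
    shared_ids <- stats::setNames(
      paste0("TS", sprintf("%03d", seq_along(config$shared_targets))),
      config$shared_targets)
    for (cl in names(config$n_activities)) {
      n_pairs <- config$n_activities[[cl]]
      if (n_pairs == 0) next
      pool <- target_pool(cl, config$target_pools[[cl]], config$shared_targets)
      pool$target_id[match(names(shared_ids), pool$target_name)] <-
        unname(shared_ids)
      cand <- compounds$compound_id[compounds$cls == cl &
                                      !is.na(compounds$registry_number)]
      if (length(cand) == 0) cand <- compounds$compound_id[compounds$cls == cl]
      if (length(cand) == 0) {
        rlang::abort(sprintf("no compounds of class '%s' to assign activities", cl))
      }
      m <- config$activity_model[[cl]]
      cal <- calibrate_truncnorm(m$mu, m$sigma, m$min, m$max)
      p <- rtruncnorm_reject(n_pairs, cal$mu, cal$sigma, m$min, m$max)
      # distinct (compound, target) pairs: one pair per pool target first
      # (so the configured diversity is hit), then unused grid cells
      n_pool_t <- nrow(pool)
      n_cand <- length(cand)
      if (n_cand * n_pool_t < n_pairs) {
        rlang::abort(sprintf(
          "cannot draw %d distinct pairs from %d compounds x %d targets for class '%s'",
          n_pairs, n_cand, n_pool_t, cl))
      }
      t_idx <- seq_len(min(n_pool_t, n_pairs))
      c_idx <- ((seq_along(t_idx) - 1L) %% n_cand) + 1L
      n_more <- n_pairs - length(t_idx)
      if (n_more > 0) {
        used <- c_idx + (t_idx - 1L) * n_cand
        free <- setdiff(seq_len(n_cand * n_pool_t), used)
        cells <- sample(free, n_more)
        c_idx <- c(c_idx, ((cells - 1L) %% n_cand) + 1L)
        t_idx <- c(t_idx, ((cells - 1L) %/% n_cand) + 1L)
      }
      truth_div[[cl]] <- length(unique(t_idx))
      unit <- sample(c("nM", "uM"), n_pairs, replace = TRUE, prob = c(0.6, 0.4))
      primary <- tibble::tibble(
        compound_id = cand[c_idx], cls = cl,
        target_id = pool$target_id[t_idx],
        target_name = pool$target_name[t_idx],
        target_class = pool$target_class[t_idx],
        activity_type = sample(STANDARD_ACTIVITY_TYPES, n_pairs, replace = TRUE),
        value = ifelse(unit == "nM", 10^(9 - p), 10^(6 - p)),
        units = unit, relationship = "direct", true_pchembl = p,
        violates = NA_character_
      )
      # weaker replicate assays: the per-pair collapse must recover the
      # primary draw, so replicates never exceed it
      redo <- which(stats::runif(n_pairs) < config$redundant_assay_fraction)
      extras <- NULL
      if (length(redo)) {
        n_extra <- sample(1:2, length(redo), replace = TRUE)
        src <- rep(redo, n_extra)
        pk <- pmax(m$min, p[src] - abs(stats::rnorm(length(src), 0.5, 0.3)))
        unit2 <- sample(c("nM", "uM"), length(src), replace = TRUE)
        extras <- primary[src, ]
        extras$activity_type <- sample(STANDARD_ACTIVITY_TYPES, length(src),
                                       replace = TRUE)
        extras$value <- ifelse(unit2 == "nM", 10^(9 - pk), 10^(6 - pk))
        extras$units <- unit2
        extras$true_pchembl <- pk
      }
      recs[[cl]] <- dplyr::bind_rows(primary, extras)
    }
    act <- dplyr::bind_rows(recs)
    n_clean <- nrow(act)
    v <- config$violation_fraction
    n_bad <- round(v / (1 - v) * n_clean)
    if (n_bad > 0) {
      bad <- act[sample.int(n_clean, n_bad, replace = TRUE), ]
      kinds <- rep_len(c("target_relationship", "activity_type", "value_units"),
                       n_bad)
      bad$violates <- kinds
      bad$relationship[kinds == "target_relationship"] <- "indirect"
      bad$activity_type[kinds == "activity_type"] <- "Inhibition"
      bad$units[kinds == "value_units"] <- "%"
      act <- dplyr::bind_rows(act, bad)
    }
    act <- act[sample.int(nrow(act)), ]  # shuffle so violations are interleaved
    act <- dplyr::bind_cols(
      tibble::tibble(record_id = sprintf("A%05d", seq_len(nrow(act)))), act)
    list(
      activities = act,
      truth = list(
        n_clean = n_clean,
        n_violating = n_bad,
        model = config$activity_model,
        n_pairs = as.list(config$n_activities),
        target_diversity = truth_div
      )
    )
  })
}

#' Generate a synthetic food concentration table
#'
#' For each of the eight food groups, draws foods whose compound
#' concentrations are log-normal and rescaled so the per-food totals land
#' in the configured concentration tiers (the tier labels are therefore
#' known by construction). One group is generated with an extreme
#' single-compound share to exercise primary-compound logic. Units are a
#' deliberate mixture of mg/kg and mg/100 g; a few non-quantifiable
#' ("trace") rows are appended, all ground-truthed.
#'
#' @param config A [synthesis_config()].
#' @param compounds Compound table from [generate_compounds()].
#' @return List with `foods` (raw record tibble, standardization-ready)
#'   and `truth` (per-food tier and total, per-group primary compound and
#'   share, diversity, trace row count).
#' @export
generate_foods <- function(config, compounds) {
  fm <- config$food_model
  tier_range <- list(high = c(7500, 15000), medium = c(2000, 7000),
                     lower = c(500, 2000))
  with_seed(child_seed(config$seed, "foods"), {
    flav <- compounds[compounds$cls == "flavonoid", ]
    if (nrow(flav) < 3) flav <- compounds
    rows <- list(); food_truth <- list(); grp_truth <- list()
    fid <- 0L
    for (g in seq_along(FOOD_GROUPS)) {
      group <- FOOD_GROUPS[g]
      dominant <- identical(group, fm$dominant_group)
      grp_pool <- flav[sample.int(nrow(flav),
                                  min(nrow(flav), max(fm$n_compounds))), ]
      dom_comp <- grp_pool[1, ]
      for (f in seq_len(fm$n_foods)) {
        fid <- fid + 1L
        tier <- fm$tiers[((fid - 1L) %% length(fm$tiers)) + 1L]
        total <- stats::runif(1, tier_range[[tier]][1], tier_range[[tier]][2])
        lo <- min(fm$n_compounds); hi <- max(fm$n_compounds)
        n_comp <- if (lo == hi) lo else sample(seq(lo, hi), 1)
        n_comp <- min(n_comp, nrow(grp_pool))
        comp <- grp_pool[sample.int(nrow(grp_pool), n_comp), ]
        w <- stats::rlnorm(n_comp, 0, fm$sdlog)
        conc <- w / sum(w) * total
        if (dominant && n_comp > 1) {
          if (!dom_comp$compound_id %in% comp$compound_id) {
            comp[1, ] <- dom_comp
          }
          di <- which(comp$compound_id == dom_comp$compound_id)[1]
          share <- fm$dominant_share
          conc[-di] <- conc[-di] / sum(conc[-di]) * (1 - share) * total
          conc[di] <- share * total
        }
        food_name <- sprintf("%s food %02d", gsub("[^a-z]+", "_", group), f)
        for (i in seq_len(n_comp)) {
          unit <- sample(c("mg/kg", "mg/100g"), 1)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            compound_id = comp$compound_id[i],
            compound_name = comp$name[i],
            food_name = food_name, food_group = group,
            concentration = if (unit == "mg/kg") conc[i] else conc[i] / 10,
            unit = unit
          )
        }
        food_truth[[food_name]] <- list(tier = tier, total = total,
                                        group = group)
      }
    }
    foods <- dplyr::bind_rows(rows)
    # group-level truth from the constructed concentrations
    std_truth <- foods
    std_truth$mgkg <- ifelse(std_truth$unit == "mg/kg",
                             std_truth$concentration,
                             std_truth$concentration * 10)
    for (group in FOOD_GROUPS) {
      gg <- std_truth[std_truth$food_group == group, ]
      contrib <- tapply(gg$mgkg, gg$compound_name, sum)
      grp_truth[[group]] <- list(
        total = sum(gg$mgkg),
        n_compounds = length(unique(gg$compound_id)),
        primary_compound = names(which.max(contrib)),
        primary_pct = 100 * max(contrib) / sum(gg$mgkg)
      )
    }
    # non-quantifiable rows that standardization must exclude
    n_trace <- 4L
    trace <- foods[sample.int(nrow(foods), n_trace), ]
    trace$concentration <- NA_real_
    trace$unit <- "trace"
    foods <- dplyr::bind_rows(foods, trace)
    list(
      foods = foods,
      truth = list(foods = food_truth, groups = grp_truth, n_trace = n_trace)
    )
  })
}

#' Generate and write a full synthetic run
#'
#' Produces the compound, activity and food tables for a seed and writes
#' them (plus the ground-truth sidecar and the config) under a run
#' directory named by the seed.
#'
#' @param config A [synthesis_config()].
#' @param dir Parent output directory.
#' @return Invisibly, the run directory path.
#' @export
write_synthetic_run <- function(config, dir) {
  comp <- generate_compounds(config)
  act <- generate_activities(config, comp$compounds)
  food <- generate_foods(config, comp$compounds)
  run_dir <- file.path(dir, sprintf("run_seed%d", config$seed))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  ctab <- comp$compounds
  ctab$sources <- vapply(ctab$sources, paste, character(1), collapse = ";")
  readr::write_csv(ctab, file.path(run_dir, "compounds.csv"))
  atab <- act$activities
  readr::write_csv(
    atab[setdiff(names(atab), c("true_pchembl", "violates"))],
    file.path(run_dir, "activities.csv"))
  readr::write_csv(
    atab[c("record_id", "true_pchembl", "violates")],
    file.path(run_dir, "activities_truth.csv"))
  readr::write_csv(food$foods, file.path(run_dir, "foods.csv"))
  jsonlite::write_json(
    list(compounds = comp$truth, activities = act$truth, foods = food$truth),
    file.path(run_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(config), file.path(run_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(run_dir)
}
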