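---
title: "Methods: cross-database characterization of dietary polyphenols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-database characterization of dietary polyphenols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolprofiler)
```

## What the package models

Flavonoids and phenolic acids are documented piecemeal: registries
disagree on identifiers and class labels, bioactivity archives mix assay
types and units, and food composition tables mix concentration
conventions. `phenolprofiler` implements one integrated
characterization: identifier reconciliation, an oral drug-likeness
descriptor panel, QED scoring, pChEMBL bioactivity standardization with
a flavonoid vs phenolic-acid comparison, and food-source concentration
profiling — plus a synthetic-data generator that emulates all four table
kinds with known ground truth.

## The molecular-graph engine

R has no RDKit, so all structure handling is native. A SMILES parser
builds the molecular graph (organic subset plus bracket atoms, branches,
`%nn` ring closures, charges, tetrahedral marks); implicit hydrogens
follow standard valences, with aromatic bonds counted as 1.5 and the
sum rounded up. Rings come from shortest-cycle candidates filtered to a
GF(2)-independent smallest set (SSSR). Canonical atom invariants are
Weisfeiler–Lehman refinements iterated to a stable partition; they back
the constitution hash (generator uniqueness, identity checks) and the
branch-distinctness test for stereocentres.

One convention matters for users: **aromaticity is taken from the input
notation**. Canonical SMILES from the major databases write aromatic
systems in lowercase (including the 4H-chromen-4-one core of flavones,
which the reference toolchain also perceives as aromatic), and the
engine trusts that notation rather than re-perceiving aromaticity from a
Kekulé drawing. Kekulé-style inputs will undercount aromatic rings and
should be canonicalized upstream.

Descriptors:

* **MW** — sum of standard atomic weights, including implicit H. For
  compounds known only by formula (the large ellagitannins),
  `formula_weight()` computes the same quantity from the formula.
* **logP** — Wildman–Crippen atom contributions, implemented as an
  ordered rule list over the graph reproducing the published atom
  types for C/H/O/N/S chemistry.
* **HBD** — OH + NH group occurrences (a primary amine counts 2). This
  deliberately differs from toolkits that count donor *atoms*; the QED
  machinery uses its own donor/acceptor definitions (`count_hbd_qed()`,
  `count_hba_qed()`), and both conventions are emitted as separate
  columns because they genuinely differ.
* **HBA** — plain N + O atom count (Rule-of-5 convention).
* **TPSA** — Ertl fragment contributions over N/O (S and P excluded,
  the common default), with the standard fallback formula for
  unparameterized environments (e.g. the flavylium `[o+]`).
* **Rotatable bonds** — strict definition: acyclic single bonds between
  non-terminal atoms, excluding linear atoms, tert-butyl-like centres
  and amide/ester-like C–[N,O,S] bonds adjacent to a carbonyl.
* **Aromatic rings** — SSSR rings whose bonds are all aromatic.
* **Stereocentres** — sp3 carbons with four pairwise-distinct branch
  environments (WL labels with the centre excluded); assigned and
  potential centres both count by default (`assigned_only` restricts),
  since stereochemical complexity, not annotation completeness, is the
  quantity of interest.

Salts and multi-fragment inputs are used as given (the source databases
list parent structures); a message is logged when fragments > 1. Every
descriptor was validated during development against an independent
reference implementation across the reference set and the generator's
decorated-scaffold space; one cross-check against that implementation
remains in the test suite.

## QED

Each property value x is mapped through an asymmetric double-sigmoid
desirability

$$d(x) = \frac{1}{d_{max}}\left[a + \frac{b}{1+e^{-(x-c+d/2)/e}}
\left(1 - \frac{1}{1+e^{-(x-c-d/2)/f}}\right)\right]$$

with the published per-property coefficients of the weighted variant,
and the score is the weighted geometric mean
$\exp(\sum w_i \ln d_i / \sum w_i)$. Desirabilities are floored at
1e-6 before the log transform, matching reference behaviour; the
unit-weight variant sits behind `weights = "unit"`. The ALERTS property
screens the bundled 116-pattern Brenk-style list
(`inst/extdata/structural_alerts.tsv`); matching is done by native graph
matchers covering every pattern expressible in C/H/O/S polyphenol
chemistry (catechols, quinones, Michael acceptors, esters and
poly-esters, sulfate acids, fused aromatics, oxocations, ...). The
remaining patterns — organometallics, nitrogen/halogen warheads,
isotopes — cannot occur in structures this package handles; the table
records which patterns have native support, so the restriction is
inspectable rather than silent.

The fragment-sum drug-likeness aggregator
(`fragment_sum_score()`) implements the sum-over-matched-fragments /
sqrt(match count) scheme over a pluggable score table keyed to the
package's functional-group catalog. Proprietary fragment dictionaries
are not reproduced; externally computed scores are the primary route and
enter through `ingest_scores()`.

## Registry decisions

Records merge only on the **full 27-character InChIKey**; compounds
sharing just the 14-character connectivity block are reported as
skeleton matches but kept separate, because stereochemistry
distinguishes real compounds in this class (catechin/epicatechin).
Field conflicts are resolved by configurable source precedence
(default: phytohub > phenol_explorer > chembl, the primary
characterization sources) and logged per field, never fatal. Compounds
with neither key nor structure keep surrogate ids and are excluded from
structure-dependent stages only (complete-case analysis). Coverage
percentages are computed both before and after cross-source merging,
since the two denominators answer different questions; rounding happens
only in the presentation formatter.

The mass-outlier screen estimates each subclass's location and scale
**leave-one-out** (the candidate excluded from its own reference), so a
gross outlier cannot mask itself; a fixed published reference mean/SD
can be supplied instead, and a trimmed variant is available. Flagged
compounds are reported, never dropped.

## Bioactivity decisions

Only records with a direct target relationship, a standard activity
type (IC50, EC50, Ki, Kd) and positive values in nM or uM survive
filtering; unknown units are rejected, never coerced. pChEMBL is
−log10 of the molar value. Per compound–target pair the strongest
record is kept, ties broken by earliest input row (deterministic). The
class comparison uses Welch's t-test by default — sample sizes and
spreads differ between classes — with the pooled test behind a flag,
and runs on collapsed pair-level values (one value per compound–target
pair), which is the unit of analysis the distribution plots imply;
record-level mode is available by passing uncollapsed records.

## Food-mapping decisions

mg/100 g converts to mg/kg by ×10; sub-detection and unitless values
are excluded with reasons. Tier boundaries follow the printed
convention: high is strictly above 7000 mg/kg, medium the closed
interval [2000, 7000] (so exactly 7000 is medium), lower [500, 2000),
and anything smaller gets an explicit `below_range` tier rather than
silent omission. Replicate measurements of a (compound, food) pair feed
totals through their median (robust; mean and max are available);
min/max/median are all retained in the per-pair table. A group's
primary compound is the largest compound contribution summed across the
group's foods; ties break lexicographically and are flagged.

## The synthetic generator

The generator's defaults are the study conditions the package targets:
715 flavonoids and 239 phenolic acids split across subclasses in the
census proportions (flavonols largest; anthocyanins with the highest
registry coverage, 71%; chalcones the lowest, 38%); per-class pChEMBL
models with means 7.26/6.98, SDs 1.09/0.94 and ranges [6.01, 9.70] /
[6.01, 9.00]; 239/141 compound–target pairs over target pools of 67/33
proteins sharing SLCO1B1, SLCO1B3 and p53; and eight food groups whose
per-food totals span the three tiers, with the beverage group 95%
dominated by a single compound.

Structures are built by deterministic scaffold decoration —
hydroxylation, O-methylation, O-glycosylation and sulfation on
subclass-faithful cores — rather than random graphs, so every structure
parses, has subclass-typical descriptor ranges, and is unique by
constitution hash. Identifier keys are deterministic surrogates in
InChIKey layout derived from the canonical graph hash; they behave like
InChIKeys for matching purposes but are not interoperable with external
resolvers, and are documented as synthetic. Deliberately misclassified
heavy compounds (poly-galloylated glucose cores, 0.9–1.3 kDa) are
injected into the hydroxybenzoic-acid subclass with ground-truth flags
to exercise the mass screen.

Activity values need one calibration: the configured mean/SD describe
the *observed* moments of bounded assay data, while a normal truncated
to the configured range has a higher realized mean than its latent
mean. The generator therefore solves for the latent normal whose
truncated distribution matches the target mean exactly and the target
SD as closely as the bounds permit — an SD of 1.09 on a 3.69-wide
interval is mathematically unattainable (the uniform limit caps it near
1.06), and the calibrated value lands near 0.94. Draws use rejection
sampling with box-constrained latent parameters, keeping acceptance
rates bounded. pChEMBL draws are back-converted to assay values in a
deliberate nM/uM mixture; a fraction of pairs gains weaker replicate
assays (never exceeding the primary draw, so the collapse provably
recovers it), and a configured fraction of records violates each filter
criterion in turn, all ground-truthed in sidecar files.

What the generator does **not** emulate: real assay noise models beyond
truncated normals, correlation between structure and activity, the
marginal distributions of real food composition data, or genuine
InChIKey collisions/variants. Tests passing on synthetic data therefore
demonstrate the pipeline's correctness and bookkeeping, not
distributional fidelity to any real database.

## Numerical choices

Skewness is the moment-based Fisher–Pearson g1 without small-sample
correction; quartiles use linear interpolation — both the common
statistical-package defaults. Correlations are pairwise-complete
Pearson; pairs with fewer than 2 complete cases are reported as absent
rather than guessed. A constant score vector reports SD 0 and skewness
0 with an explicit undefined flag. Report CSVs carry full precision;
rounding (e.g. whole-percent coverage) lives in a separate formatter.

Test problem sizes are scaled to keep the suite fast while preserving
the statistical checks: compound sets of 40–60 per run for
structure-heavy tests, the full 239/141 activity sample sizes for the
parameter-recovery study (200 seeded replicates), and 1000-draw
recovery checks for distribution summaries.

## Known limitations

* No aromaticity perception: Kekulé-notation SMILES are parsed but
  their rings are not recognized as aromatic.
* The Crippen typer and alert matchers cover polyphenol chemistry
  (C/H/O/N/S); exotic elements fall back to generic contributions.
* Stereocentre detection is branch-symmetry based and can miss
  para-stereogenic or ring-symmetry edge cases that a full CIP
  implementation would catch.
* QED scores for compounds far outside drug-like property space are
  dominated by the desirability floor and should be read as "very
  undruglike" rather than compared quantitatively.
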