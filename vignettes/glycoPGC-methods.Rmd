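---
title: "Tissue membrane glycomics with glycoPGC: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue membrane glycomics with glycoPGC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoPGC)
```

# Scope

glycoPGC analyses N- and O-glycan alditol profiles measured by porous
graphitized carbon LC with negative-mode electrospray ion-trap MS/MS, the
workflow used to compare membrane glycosylation between high-grade serous
ovarian (OC) and peritoneal (PC) cancer tissue. The package covers the
chain from deconvoluted m/z observations to structure-level motif calls
and group-discrimination statistics, plus a seeded synthetic-data
generator so every stage is testable without access to raw instrument
data (none were deposited for this kind of cohort).

# The mass calculus

Glycans are handled at two resolutions. A **composition** counts residues
per mass class — Hex (162.05282 Da), HexNAc (203.07937), dHex
(146.05791), Neu5Ac (291.09542) — plus sulfate (+79.95682). Gal vs Man
and GalNAc vs GlcNAc are mass-identical, so specific identities live only
in **topologies** (rooted residue trees in condensed IUPAC-like
notation), where fragmentation and retention logic can distinguish them.

The neutral mass of a free glycan is the residue sum plus terminal water
(18.01056); released glycans are reduced to alditols with borohydride, so
the default adds two hydrogens (2.01565). Negative-mode ions are
deprotonated: m/z = (M − z·1.00728)/z for [M−zH]^z−^, z = 1–3. The
monoisotopic proton mass (1.00728, not the average 1.00794) is used
because it reproduces the printed ion-trap annotations to within 0.1 m/z.
m/z is carried to 4 decimals internally; display matching uses 0.1 Da and
mass search 0.5 Da (the tolerance used with GlycoMod on this ion-trap
data).

Composition enumeration (`enumerateCompositions()`) walks the bounded
integer lattice Hex 0–12, HexNAc 0–8, dHex 0–4, Neu5Ac 0–4, sulfate 0–2.
The bounds are a documented choice wide enough for tetra-antennary
trisialylated species, the largest structures reported in this tissue
type. N-glycan mode enforces the trimannosyl-chitobiose core (Hex ≥ 3,
HexNAc ≥ 2); O-glycan mode requires only the reducing-end HexNAc. The
tolerance is applied on the neutral-mass (charge-scaled) scale.
Candidates are sorted by |Δm|, ties broken by fewer residues, then
lexicographic counts — fully deterministic.

# Fragment model and diagnostic ions

Every glycosidic bond yields B/C (non-reducing side) and Y/Z (reducing
side) ions; Y retains the alditol hydrogens. Two double-cleavage ions
carry the structural evidence that matters on this data:

* **D ion** — the 6-arm antenna plus the bisecting GlcNAc (when present)
  plus the two branching core mannoses, computed as a B-type ion
  (residue sum − proton). This operational definition is the unique one
  that reproduces both printed D−221 values: 508.17 for the
  agalactosylated bisected context (GlcNAc + GlcNAc + 2 Man) and 670.22
  for the galactosylated one (Gal-GlcNAc + GlcNAc + 2 Man). **D−221**
  (loss of HexNAc + water, 221.08993) is emitted only when a bisecting
  GlcNAc exists and is the bisecting diagnostic. One source prints the
  agalacto value as 508.3 and another as 508.1; the package targets the
  theoretical 508.17 and matches either within tolerance.
* **F ion** — the ^1,3^A cross-ring cleavage on the branching mannose:
  antenna residues + 59.0133 (the O–CH=CH–O remnant). For a LacdiNAc
  antenna this is 465.17; with its B ion at 405.15 it is the LacdiNAc
  diagnostic pair. Sialylated antenna B ions at 696.25 (Neu5Ac-GalNAc-
  GlcNAc) and 655.22 (Neu5Ac-Gal-GlcNAc) distinguish sialyl-LacdiNAc
  from sialyl-LacNAc arms.

Only singly charged fragments are predicted — ion-trap MS2 of these
precursors shows singly charged diagnostics — and other cross-ring ions
are out of scope because they carry no diagnostic load here. The default
MS2 match tolerance is 0.3 Da (ion trap), configurable.

`classifyMotifs()` ranks candidate topologies by coverage (fraction of
predicted ions matched) and sets motif booleans only when the evidence
peak is actually matched: bisecting requires the candidate's own D−221
ion, LacdiNAc its B and/or F ion. The packaged peak lists for the two
m/z 913.9^2−^ compositional isomers (bisecting-type early eluter,
LacdiNAc-type late eluter) are synthetic fixtures: transcribed from the
printed diagnostic values with nominal intensities, with backbone ions at
one-decimal theoretical values.

# Chromatography and sialyl-linkage isomers

EIC peak integration uses a centered moving average (default window 5
points), peak delimiters at local minima below 10% of the neighbouring
apex, and trapezoid areas; the integration algorithm is a package choice,
as source descriptions only state that relative EIC areas were used.
Integration is scale invariant, which is all the downstream relative
quantification needs.

PGC retention resolves sialyl-linkage isomers on the same backbone, and
the package codifies the reported elution rule exactly as stated: α2,6
before α2,3, so a disialylated backbone elutes α2,6/α2,6 then α2,6/α2,3
then α2,3/α2,3. No quantitative retention prediction is attempted, and
retention order is compared within a run only. The global "α2,6 first"
rule is an extrapolation beyond the explicitly reported backbones; single
unresolved peaks are therefore labelled by the rule but flagged
low-confidence. `percentAlpha26()` computes the abundance-weighted α2,6
area share over a glycan subset, the statistic reported per isomer group
(hybrid monosialylated, complex mono- and disialylated).

# Profiling rules

Relative abundances are normalized to 100% per glycan class and sample;
N- and O-glycans are normalized separately because they are released and
measured separately. Isomers are carried as separate rows and merged into
their parent glycan mass (`mergeIsomers()`) for mass-level statistics —
the merged fraction equals the sum of the isomer fractions, and the
five-type summaries are computed over summed glycan masses.

The five-type classification uses precedence rules on compositions:
paucimannose (HexNAc = 2, truncated mannose arm, optionally fucosylated),
high mannose (HexNAc = 2, Hex 4–9, unfucosylated), hybrid (HexNAc = 3
with an unsubstituted mannose arm when the topology is known;
compositional fallback HexNAc = 3, Hex ≥ 4), then complex, split by
Neu5Ac count. Man4 (Hex4 HexNAc2, unfucosylated) is grouped with the
high-mannose family — a documented choice where the rule tables are
silent; the fucosylated Hex4 case goes to paucimannose.

Antenna counting requires the complete LacNAc (Gal-GlcNAc) or LacdiNAc
(GalNAc-GlcNAc) disaccharide: bare GlcNAc stubs and the bisecting GlcNAc
never count, and capping or fucosylation does not change the count.
Bisecting detection at profile level comes from the structure table built
by fragment annotation, not from composition — bisecting and LacdiNAc
isomers share compositions, which is exactly why the D−221 and 405/465
diagnostics exist.

# Statistics layer

The per-glycan test is Wilcoxon rank-sum (two groups; exact when both
n ≤ 25 and untied, normal approximation with continuity correction
otherwise) or Kruskal–Wallis (three sites), with Benjamini–Hochberg
adjustment across the glycans of a class. The source work does not name
its per-glycan test; the rank tests were chosen for robustness on
compositional percentages, with a t-test option exposed. Percent-scale
data are used as-is, matching how the cohort results are reported; a
centered-log-ratio transform would be a reasonable alternative but is
deliberately not the default.

Feature selection mirrors the published pairing of methods: an
L1-penalized (binomial/multinomial) logistic regression with standardized
predictors, 5-fold stratified cross-validation and the deviance-minimizing
penalty (glmnet); and a random forest (500 trees, √p features per split)
ranked by out-of-bag permutation importance with top-k = 4 reported, the
panel size used in the published tables. Both are seeded and
reproducible; exact hyperparameters were not published, so these defaults
are documented package choices.

ROC analysis is implemented at formula level: the empirical curve over
all thresholds, AUC by trapezoid (identical to the Mann–Whitney U
statistic over n₁n₂, ties counted half), and the operating point
maximizing Youden's J with ties broken towards higher specificity — the
published operating points (86.7/92.3 and 86.7/100) imply threshold
choices that were not stated, and Youden's J is the package's rule. Panel
scores for multi-glycan markers come from an unpenalized logistic fit on
the selected features. LDA computes Wilks' Λ = det(W)/det(T) directly
with Rao's F approximation for the p-value and up to two discriminant
projections from the eigendecomposition of W⁻¹B; a singular within-group
scatter is ridged (ε = 1e−8) and flagged. `pROC` and `stats::manova`
serve as independent cross-checks in the test suite, not as the
implementation.

qPCR support implements the reference-gene model: ΔCq against the mean of
three reference genes, expression 2^−ΔCq, rescaled so the
lowest-expressing sample is 1.

# The synthetic cohort generator

No per-sample abundances were deposited for this kind of tissue cohort,
so the generator (`generateCohort()`) emulates the published summary
structure and is the substrate for all cohort-level tests. Per sample and
glycan, a Bernoulli detection mask is applied (reproducing
presence/absence patterns such as 93% OC vs 22% PC detection of the
sialylated LacdiNAc/LacNAc species — 0.22 is stored as given even though
it is not an integer fraction of n = 14), an abundance is drawn from a
log-normal with the design's unconditional mean and SD (conditional mean
inflated by 1/detection), and the profile is renormalized to 100% per
class. Glycans are drawn independently: real compositional covariance,
batch structure and retention drift are *not* modelled, so passing tests
demonstrate that the pipeline recovers the designed effects under this
idealized sampling model, not that it would reproduce the original
cohort's exact AUCs.

The default panel (46 structures) encodes the published cohort summaries
as its targets: LacdiNAc totals 2.775 ± 2.005% (OC) vs 0.1247 ± 1.312%
(PC) split over the five member structures (per-species SD = total
SD/√5, independence assumed); total sialylation inside the 66.3–68.5%
band; bisecting-type structures ≈ 6.85%; biantennary ≈ 55% and branched
≈ 5%; α2,6 shares of 0.59 (hybrid monosialylated) and 0.65 (complex-type)
per isomeric species. Only group totals were published; the split across
member structures, the background panel and its coefficients of variation
(≈30%) are fixed design choices made once. The residual up to 100% per
class sits in the most abundant non-discriminatory species (Man5 for N,
the core-1 base peak for O). Group sizes default to the study's: OC/PC
14/14, sites 14/11/3.

Monte-Carlo problem sizes used by the tests and the acceptance script —
200 cohorts for generator fidelity and single-feature AUC, 100 seeds for
selection recovery, 1000 replicates for null calibration — were sized so
the whole suite completes in minutes on a single core while keeping the
Monte-Carlo standard errors a fraction of the tolerances tested.

# Numerical and degenerate-input policy

* Charge states 1–3 only; charge ≤ 0 is an error.
* Empty candidate lists are results, not errors; an unbounded search is.
* All-zero EIC traces integrate to an empty peak table; all-zero samples
  abort profile building with the sample named.
* Constant features get p = 1 with a flag rather than NA.
* Cross-validation folds are stratified by group, so no fold can
  degenerate to a single class.
* Every stochastic routine takes a seed and is bit-reproducible given it.

# Known limitations

* Average masses, positive-mode adducts and permethylation chemistry are
  out of scope; so are glycopeptides and intensity/collision-energy
  prediction.
* The fragment engine predicts singly charged ions only.
* Printed low-resolution mass pairs can deviate a few tenths of a Da from
  theoretical composition masses; the package always reports theoretical
  values and treats printed ones as observed quantities to be matched
  under tolerance.
* The generator's independence assumption understates the negative
  correlation that closure imposes on compositional data; its effect on
  the tested summaries is below the Monte-Carlo error at the panel size
  used, but analyses of strongly covarying panels should not rely on it.
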