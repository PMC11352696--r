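---
title: "Methods: spatial TiME quantification in mifscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial TiME quantification in mifscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mifscape quantifies the spatial tumor immune microenvironment (TiME) from
segmented-cell tables produced by multiplex immunofluorescence (mIF) image
analysis, such as QuPath measurement exports. The motivating application is
the contrast between immune-low endometrial stromal sarcomas (LG-ESS,
HG-ESS) and the immune-high microenvironment of SMARCA4-deficient
undifferentiated uterine sarcoma (SDUS), but every stage is generic: the
inputs are per-cell centroids (micrometres) and mean marker intensities for
a 13-marker panel (CD3, CD4, CD8, CD14, CD20, CD68, PD-1, PD-L1, CD31,
alpha-SMA, FAP, Ki67, Granzyme B).

This vignette explains each model, its assumptions and tunable parameters,
the synthetic-scene generator used for validation, and the numerical and
design choices that were genuinely open.

## Phenotyping model

A cell is *positive* for marker $m$ iff its mean intensity satisfies
$I_m \ge \theta_m$. The gate is closed (boundary cells are positive), which
makes thresholds interpretable as "the lowest intensity still called
positive"; this convention is tested explicitly. Exclusive lineages are
assigned by the first matching rule in a fixed precedence order

CTL (CD3+CD8+) > Th (CD3+CD4+CD8-) > T_other (CD3+) > B (CD20+CD3-) >
Mac (CD68+CD3-CD20-) > Myeloid (CD14+CD68-CD3-CD20-) > Endothelial (CD31+) >
Fibroblast (FAP+) > SmoothMuscle (aSMA+) > Other,

so every cell gets exactly one lineage and unmatched cells fall through to
"Other" (in tumor tissue, mostly tumor cells). CD3+CD4+CD8+ doubles land in
CTL because the CTL rule precedes the Th rule; the Th rule additionally
requires CD8- so the two rules partition CD3+CD4+ cells cleanly. PD-1,
PD-L1, Ki67 and Granzyme B are *functional flags*, assigned independently
and non-exclusively, because the populations of interest are composites
such as "PD-1+ CD3+ T cells" or "Ki67+ CTLs".

Thresholds must be supplied explicitly per marker; the defaults are the
log-space midpoints of the synthetic intensity model below and are only
meaningful for synthetic data. We deliberately ship no automatic gating
(e.g. Otsu) in this version: fixed, recorded thresholds keep the
classification auditable, which matters more than convenience when
phenotype densities feed significance claims. Raising a threshold can only
shrink that marker's positive set (monotonicity, tested as a property).

## Hotspot densities

Immune infiltration in these tumors is spatially heterogeneous, so
whole-slide average densities are misleading. Following common practice,
per-case statistics are computed in the *hotspot*: the axis-aligned square
window (default side 500 um, i.e. 0.25 mm^2) that maximises the cell count
over an anchor grid with stride 250 um. Window membership is half-open,
$[x_0, x_0+w) \times [y_0, y_0+w)$, so tiling windows never double-count a
cell, and the conservation identity
$\sum_p \mathrm{density}_p \times \mathrm{area} = \#\text{cells in window}$
holds exactly. Ties between equal-count windows resolve to the smallest
(y, x) anchor. The window side is configurable and echoed in every report;
0.25 mm^2 is a compromise between statistical stability of the count and
locality of the "greatest density" notion. The stride of half a window side
keeps the chosen count provably close to the exhaustive 1-um-stride
maximum; validation asserts the chosen count is at least 90% of that
exhaustive maximum on random scenes.

Group differences in hotspot densities are assessed with a two-factor
(group x phenotype) ANOVA on the per-case densities: the pooled residual
variance from `density ~ group * phenotype` feeds pairwise group contrasts
within each phenotype, with Sidak family adjustment
$p_{\mathrm{adj}} = 1 - (1-p)^m$ across all contrasts (computed via
`expm1`/`log1p` so tiny p-values do not underflow to zero). Because group
sizes in rare-tumor studies are tiny (two SDUS cases against seven ESS
cases is the motivating shape), a rank-based per-phenotype fallback
(Wilcoxon rank-sum, same adjustment) and per-group medians with ranges are
reported alongside; with n = 2 the parametric contrast leans on the pooled
variance and should be read together with the raw densities. A 500-run
null simulation in the test suite checks the familywise rejection rate at
$\alpha = 0.05$ stays within two binomial standard errors of 0.05 for the
2-vs-7 design.

## Proximity graph and interaction enrichment

Two cells are *potential interacting partners* when their centroid distance
is at most 15 um — roughly touching at typical cell diameters. The
boundary is closed (distance exactly 15 um is a partner) and coincident
distinct centroids are connected; self-pairs are not. The graph is built
with a uniform-grid spatial index (bucket side = radius) whose output is
required, and tested, to equal O(n^2) brute-force enumeration exactly —
the index is a performance device, never an approximation.

Interaction strength between phenotypes A and B is the number of A-B edges.
Its null distribution is obtained by permuting the phenotype labels
uniformly over cells while keeping every position and edge fixed: this
conditions on the spatial architecture and the composition, and asks only
"are these labels arranged on the graph more adjacently than chance?". For
each pair we report

$$z = \frac{\mathrm{obs} - \overline{\mathrm{null}}}{\mathrm{sd}(\mathrm{null})},
\qquad
p = \frac{1 + \#\{\mathrm{null} \ge \mathrm{obs}\}}{1 + n_{\mathrm{perm}}}$$

with $z = 0$ when the null standard deviation is zero (degenerate labels).
The p-value is one-sided for enrichment and includes ties, so it is valid
but discrete: with few edges it is conservative. The permutation count
(default 1000) and seed are recorded in the result. Functional flags ride
with their cell during permutation; composite populations (e.g. "Ki67+
CTL") can be tested by passing `composite_labels()` as the label vector.
Both the raw count matrix and z are emitted, since heatmap conventions
differ between tools.

## Cellular niches

Each cell's *neighborhood profile* is the phenotype composition of its 20
nearest neighbours (reference cell excluded; ties at the 20th distance
break by row order). The 20-NN convention follows the CODEX-style
neighborhood literature; a radius mode exists for users who prefer a fixed
physical scale, in which isolated cells yield flagged all-zero rows.
Profiles are pooled across cases — niches must live in a shared space for
per-case proportions to be comparable — and clustered with k-means
(k-means++ initialisation, 10 restarts, Lloyd iterations, best
within-cluster sum of squares kept). k defaults to 6, the niche count
observed in the motivating study; `niche_k_scan()` emits the WSS-vs-k curve
so the choice is inspectable. Cluster ids are re-indexed by descending cell
count, so "niche 1" is always the largest and summaries are invariant to
input row order. The report gives each niche's mean composition, each
case's distribution over niches (rows sum to 1 exactly) and the
predominant niche per case (ties to the lower id). A per-case clustering
can be had by simply not pooling profiles.

## The synthetic-scene generator

No patient-level mIF data are published for the motivating study, so
validation rests on synthetic scenes with planted ground truth. A
`scene_spec()` describes: rectangular/disc regions, each a homogeneous
Poisson process (count ~ Poisson(density x area), positions uniform) with
its own phenotype mixture and true niche id; marker intensities drawn from
a two-component log-normal model (negative component log-mean log 5,
positive log 100, both log-sd 0.35 — a ~4.3-pooled-SD separation chosen so
that threshold gating recovers planted phenotypes essentially exactly,
which the recoverability test pins at >= 99%); optional attraction pairs
realised by thinning-and-displacement (a fraction of B-phenotype cells is
relocated uniformly into the attraction disc of a random A cell; clamping
to the ROI is a convex projection, so planted pairs stay within the
radius); an optional invasive-margin band of PD-1+ T cells and PD-L1+
tumor cells; and scene-wide per-phenotype Ki67/GzmB flag rates. All draws
flow from one seed, making scenes byte-reproducible.

Two case profiles encode the study conditions. "ESS-like" draws its Th /
CTL / B / Mac hotspot densities per case from log-normal spreads around
medians 10.4 / 9.8 / 1.2 / 6.6 per mm^2, truncated to the observed
immune-low ranges. "SDUS-like" plants a lymphocyte-aggregation region
(true niche 3) whose combined density puts the hotspot CTL/Th/B/Mac
densities near 780 / 360 / 160 / 145 per mm^2, a vascular-rich region
(true niche 2), Th-B and Th-CTL attraction at 15 um, a margin band, and
Ki67 rates planted so the expected proliferating-cell composition is 20%
CTL, 14% Th, 14% B. The SDUS background CTL density (120/mm^2) keeps the
ROI-wide expected CTL density at least ten times the top of the emulated
immune-low range — the immune-high/immune-low separation is a design
parameter of the emulation, set once from the published densities.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: segmentation errors and doublets, spatial
intensity gradients and autofluorescence, marker spillover, cell-size
effects on mean intensities, tissue holes and necrosis, and any
non-Poisson clustering beyond the planted regions and attractions.
Conclusions about real slides still require per-marker threshold
validation against the images.

## Numerical choices and degenerate inputs

* Closed gates ($\ge$) and closed graph radius ($\le$); half-open hotspot
  windows. Each boundary convention is asserted by a dedicated test.
* Permutation z with sd 0 maps to 0; permutation p never reaches 0 by
  construction (the +1 in numerator and denominator).
* k-means++ restarts draw from squared-distance weights; duplicate profile
  rows cannot be chosen twice as seeds, and k larger than the number of
  distinct rows is an error.
* Empty tables: readable and writable (header-only files, with a warning);
  hotspot search on an empty table is an error, as is a zero-area window.
* Sub-seeds for pipeline stages come from a polynomial string hash of
  (global seed, stage, case id) reduced mod $2^{31}-1$, so adding a case
  to a run never changes another case's draws.

## Validation design and problem sizes

The test suite validates each primitive against an independent oracle
(brute-force pair enumeration, a separately written nested-conditional
gate, exhaustive window scans, brute-force k-NN), calibrates the two
statistical procedures under their nulls, and checks planted-signal
recovery end to end. The chosen problem sizes — scenes up to ~2000 cells
for exact oracles, 1200-cell CSR scenes with 200 permutations and 500
replicates for calibration, 5000-cell scenes for attraction power, ~12,000
cells for six-niche recovery, and a 9-case suite for the group contrast —
are large enough for the asymptotics each check relies on while keeping
the whole suite in the order of two minutes. The CSR calibration fixture
in particular uses a density giving hundreds of within-radius edges per
scene: at very low edge counts the permutation p-value is visibly
conservative because the count statistic is coarse (ties with the null
inflate p), which is a property of discrete permutation tests generally,
not of this implementation; calibration is asserted in the regime the test
is actually used in.

## Known limitations

* Gating is threshold-based and deterministic; no uncertainty propagates
  from borderline intensities into downstream statistics.
* The two-factor ANOVA treats per-case hotspot densities as homoscedastic
  across groups; with immune-high groups this is optimistic, which is why
  the rank-based fallback and raw medians are always emitted.
* The permutation null conditions on the graph; it does not test whether
  the *point pattern* itself is clustered, only label arrangement.
* Niche k-means inherits the usual caveats (spherical clusters in profile
  space, sensitivity to k); the WSS scan is descriptive, not a selection
  rule.
* The 1-um-stride hotspot guarantee is empirical (>= 90% of the exhaustive
  maximum on tested scenes), not a worst-case bound.
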