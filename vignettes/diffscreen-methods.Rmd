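---
title: "diffscreen methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{diffscreen methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffscreen)
```

# The problem

A differential viability screen tests thousands of compounds against the
same cell line under two isogenic conditions — here labelled `HIGH` and
`LOW`, e.g. normal expression of an oncogenic transcription factor versus
its inducible knockdown. The scientific questions are: which compounds
kill cells at all (hits), which kill selectively in one condition
(condition-selective compounds), and which of their protein targets
explain that selectivity. `diffscreen` implements the full chain from raw
plate-reader signals to an annotated compound–target network, with a
synthetic-data generator that carries a complete ground truth so that every
stage can be validated quantitatively without external data.

# Plate normalization (LOESS-log)

Raw luminescence on a plate is modelled multiplicatively:

$$y_{rc} = \beta \cdot S(r, c) \cdot v_{rc} \cdot \varepsilon_{rc},$$

with plate baseline $\beta$, a smooth spatial artifact surface $S$
(dispensing gradients, incubator temperature fields, evaporation edge
effects), true viability $v \in [0,1]$ and lognormal measurement noise
$\varepsilon$. Because the model is multiplicative, the surface is
estimated on the $\log_2$ scale: a locally weighted quadratic regression of
$\log_2 y$ on $(r, c)$ with tricube weights over the nearest
$\lceil \mathrm{span} \cdot n \rceil$ wells, followed by bisquare
reweighting of residuals (Cleveland's robust LOESS, via `stats::loess`
with `family = "symmetric"`). Corrected signals are

$$\tilde y_{rc} = y_{rc} \cdot \frac{\mathrm{GM}(\hat S)}{\hat S(r,c)},$$

where $\mathrm{GM}$ is the plate geometric mean — the correction is exactly
mean-neutral on the log scale, so it reshapes but never rescales a plate.
Viability is then $\tilde y$ divided by the plate's median corrected
DMSO-control signal, and $\log_2$-transformed.

**Parameters.**

* `span` (default 0.5): fraction of plate wells in each local
  neighbourhood. Large spans assume artifacts vary smoothly over half the
  plate; the default suits gradient- and edge-type artifacts and is the
  conventional choice for robust 2-D plate smoothers.
* `robust_iters` (default 6): bisquare reweighting passes. Strong actives
  are genuine biology, not artifact, and must not bend the surface. Six
  passes are used because convergence experiments on synthetic plates show
  that a block of adjacent strongly inhibited wells (a compound's dose
  series) sitting at a plate corner — a high-leverage position — is still
  visibly bending the surface after two passes (control-well CV
  *increases* up to 3-fold on such plates), while the fit stabilizes and
  the distortion disappears by about six passes. The cost is a few extra
  milliseconds per plate.
* Normalization is strictly per plate: both the surface and the control
  median are plate-local, so plate-to-plate drift never leaks across
  plates. The 2-D (row, column) formulation was chosen over a 1-D well
  index because the artifacts being corrected are areas of the plate, not
  runs of the dispensing order.

Wells driven to non-positive viability are floored at the smallest
positive double and flagged, which keeps downstream medians finite without
inventing signal.

# Hit calling and selectivity classification

Per screen and condition, the location and spread of compound-well
$\log_2$ viability are summarized by the median and the **unscaled** MAD
($\mathrm{median}|x - \mathrm{median}(x)|$, no 1.4826 factor — the rule is
stated in raw MAD units; the scaled variant is a flag). A compound ×
concentration pair is a hit when its replicate-median $\log_2$ viability
falls at or below

$$\mathrm{median} - k \cdot \mathrm{MAD}, \qquad k = 3,$$

and a compound is a hit when this holds at one or more concentrations.
Control wells are excluded from the statistics by default ("all screened
wells" is read as screened compound wells; a flag includes them). Hit sets
are monotone in $k$ by construction.

Selectivity uses the linear-scale two-fold criterion: a compound is
`HIGH_SELECTIVE` when it is a hit in the HIGH screen **and** at some
concentration tested in both conditions $v_{LOW}/v_{HIGH} \ge 2$;
`LOW_SELECTIVE` is symmetric; hits meeting neither ratio are
`NONSELECTIVE_ACTIVE`. The conjunction (hit status **and** fold ratio) is
the default reading; `fold_only = TRUE` relaxes it to the ratio alone. The
HIGH and LOW screens keep separate median/MAD statistics, since the two
conditions are physically separate screens. Compounds appearing in several
screens are merged by canonical id beforehand, keeping the minimum
viability per concentration (the most sensitive evidence). In the rare
case that a compound qualifies in both directions at different
concentrations, the direction with the larger fold ratio wins — a
tie-break the four-class partition needs but the rule itself does not
define.

# Drug–target evidence filtering

Affinity-type records (ChEMBL-like) survive only with: a supporting
reference, a named human target, an IC50 or Ki measurement with a
recognized unit, affinity strictly below 1 µM after conversion to nM, and
assay confidence ≥ 4. Interaction-type records (STITCH-like) survive with
channel `experimental` or `databases` and score ≥ 0.8 (inclusive — "equal
or above"). Note the deliberate asymmetry against the protein–protein
filter used at the network stage, which is *strictly above* 0.8 and
`experimental` only, following the different wording of the two rules.
Unknown unit tokens drop a record as "missing measurement units" rather
than guessing a scale. An optional manually curated table is merged after
filtering, bypassing it but flagged as `curated`. Per-compound target sets
are unions over surviving records; compounds with no surviving record are
absent from the map, keeping "no target information" distinct from "an
empty target set" — this matters because the enrichment background is
exactly the compounds *with* target information.

# Exclusive and overrepresented targets

For each gene targeted by at least one background compound, a 2×2 table
splits the background into hit/non-hit × targeting/non-targeting. A gene
is **exclusive** when targeted by ≥ 1 hit and 0 non-hits, and **enriched**
when its one-sided Fisher exact p (hypergeometric upper tail), BH-adjusted
across all tested genes, satisfies q < 0.05 with the hit-side fraction
larger. One-sided is the default because the question is
overrepresentation; two-sided (point-probability rule) is a flag. The
candidate list is the union, each gene flagged exclusive/enriched/both.
With very small hit sets an empty candidate list is the expected outcome,
not an error.

Functional term enrichment applies the same Fisher/BH machinery to a
user-supplied (term, gene) annotation table against the targeted-gene
background, with the conservative EASE variant (overlap cell reduced by
one) available as a flag; the package deliberately ships no ontology.

# Network assembly

Nodes are the hit compounds linked to ≥ 1 candidate gene plus the
candidate genes; edges are compound→target pairs and protein–protein edges
(`experimental` channel, score > 0.8) between included genes. Gene nodes
carry an expression-regulation flag — UP/DOWN when $|\log_2 FC| \ge 1$ at
FDR ≤ 0.01, i.e. a two-fold linear change ("a minimum of 1-fold change" is
read as one log2 unit, since a literal 1-fold change is a no-op; both
thresholds are configurable) — and a direct-binding flag from a
ChIP-derived gene list. Export is deterministic (sorted nodes and edges)
in SIF, GraphML and plain attribute tables, all openable in Cytoscape.

# Dose-response fitting

The 4PL model $v(c) = b + (t - b) / (1 + (c/\mathrm{IC50})^h)$ is fitted
by bounded Levenberg–Marquardt least squares (`minpack.lm`), internally on
log concentration with IC50 log-parameterized for conditioning. Starts:
$t = \max v$, $b = \min v$, IC50 at the dose nearest the half-range
crossing, $h = 1$; IC50 is bounded to $[\min c/100, \max c \cdot 100]$.
Flat or non-crossing data converge to a bound and are reported with
`converged = FALSE` rather than silently returning a number. Asymptotes
can be pinned (`fix_bottom = 0`, `fix_top = 1`) for percent-viability data.

# The synthetic-data generator

`simulation_config()` defaults describe the study conditions all recovery
tests run under: 200 compounds on 384-well plates at the six-dose grid
25 / 8.3 / 2.8 µM, 926 / 308 / 103 nM; 5% of compounds selective per
condition and 5% active non-selectively; 32 DMSO wells in the first and
last plate columns (deliberately inside the edge-artifact region, to
stress normalization); spatial amplitude 0.3; lognormal noise σ = 0.05
(a tight, realistic CellTiter-Glo replicate CV of ≈ 5%); mean 4 annotated
targets per compound (shifted geometric — most compounds have few targets,
a promiscuous tail has many); 10 planted selective-target genes in a
300-gene universe; 15% of drug–target records corrupted with realistic
defects (missing references or units, wrong organism, weak affinity, low
confidence — roughly the rejection rate of raw public exports).

The spatial surface is a random bilinear gradient plus one Gaussian bump
(σ 2.5–4.5 wells) and a smooth edge attenuation decaying exponentially
with distance from the border (depth 0.4 × amplitude, scale 2 wells) —
an evaporation-style profile. The surface is smooth by design: the
generator emulates the artifact class the LOESS corrector is built for.
Selective compounds have their sensitive-condition IC50 drawn log-uniformly
so that mid-grid inhibition is at least 75%, and the resistant-condition
IC50 multiplied by 8 (configurable, floor 4) — about one log unit, the
scale of potency shift the two-fold viability criterion is meant to
detect. Wells on a partially filled plate are spread uniformly over the
plate rather than packed, so the surface fit never faces a large empty
region. One RNG stream per screen is derived from (seed, screen id), so
adding screens never reshuffles existing ones, and a fixed seed makes all
outputs byte-identical.

**What the generator does not emulate** — and what passing tests therefore
do not demonstrate about real data: reagent decay and inter-day batch
effects; liquid-handling failures (sharp single-well or single-row
dropouts); compound identity errors and cross-library id mismatches;
correlated (striped) noise from dispensing heads; assay floor
nonlinearity at very low ATP signal. Real screens also interleave
libraries and replicate plates in ways the single-layout generator does
not model.

# Numerical and testing choices

Degenerate inputs fail loudly: zero MAD aborts hit calling for the screen,
an all-zero control column is a degenerate-control error, fewer than 20
wells refuse a surface fit, fewer than 4 distinct doses refuse a 4PL fit.
The test suite checks the statistics against independent oracles —
exhaustive hypergeometric enumeration for every 2×2 table with total ≤ 12,
the literal BH step-up formula, sort-based medians — and checks recovery
against the generator's ground truth at the default conditions above (one
two-condition screen of 200 compounds, eight 384-well plates; 100 noisy
dose-response curves; five null screens against a 300-replicate
Monte-Carlo of the hit rule). These sizes keep the whole suite under half
a minute while leaving the Monte-Carlo error well below the tolerances
being asserted.

Two behaviours worth knowing about. First, applying a flexible smoother to
a truly flat plate slightly *inflates* the hit rate (the smoother absorbs
part of the noise, shrinking the MAD a few percent); the null-screen check
therefore compares the pipeline to the Monte-Carlo reference within
sampling error rather than expecting exact equality. Second, CV reduction
for control wells holds pooled across a screen whenever spatial artifacts
are present, but an individual plate whose control columns happen to carry
almost no spatial variation can see a marginal CV increase from residual
smoother noise.

# Known limitations

* The affinity filter trusts the provided organism and unit encodings;
  identifier resolution (synonym mapping to canonical compound ids) is out
  of scope and assumed done upstream.
* The enrichment background is the target-annotated compound set; if
  target annotation is strongly biased towards certain gene families, the
  Fisher test inherits that bias.
* The network stage drops candidate genes not linked to any hit compound
  (with a warning); they remain in the candidate table.
* LOESS correction assumes artifacts smooth at the span scale; sharp
  discontinuities (broken dispensing tip) are not recoverable and are
  better handled by excluding the affected wells upstream.
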