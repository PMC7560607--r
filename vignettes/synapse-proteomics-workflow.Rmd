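---
title: "From sorted synaptosomes to ligand-receptor pairs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sorted synaptosomes to ligand-receptor pairs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synscreen)
```

# Scope

`synscreen` implements the computational stages of a synapse type-specific
proteomics and interactome workflow: (1) label-free enrichment analysis of
spectral counts from sorted mossy-fiber (MF) synaptosomes against a crude
P2 synaptosome reference; (2) calling of an ELISA-based pairwise
extracellular interaction screen between AP-tagged baits and Fc-tagged
preys; (3) spectral-count filters for ecto-Fc pull-down validation
experiments; and (4) one-site steady-state affinity fitting of biolayer
interferometry (BLI) titrations. Each stage has a seeded synthetic-data
generator so the whole pipeline is testable end to end without any
external data. Upstream wet-lab steps (sorting, MS acquisition, database
search) and downstream annotation (GO analysis, curation of cell-surface
proteins) are out of scope; the package consumes already-searched count
tables and already-extracted binding responses.

# Enrichment model

For protein $i$ with length $L_i$ (amino acids) and spectral count
$\mathrm{SpC}_{is}$ in sample $s$, the normalized spectral abundance
factor is

$$\mathrm{NSAF}_{is} = \frac{\mathrm{SpC}_{is}/L_i}
{\sum_j \mathrm{SpC}_{js}/L_j},$$

so each sample column sums to one over detected proteins. Before
normalization, proteins must reach at least `min_peptides` (default 3)
peptide identifications summed over all six samples. Proteins not
identified in a sample carry NSAF exactly 0 there, and those zeros enter
all downstream calculations.

Enrichment is $\log_2(\bar{\mathrm{NSAF}}_{\mathrm{MF}} /
\bar{\mathrm{NSAF}}_{\mathrm{P2}})$ on group means. Significance uses a
two-sided equal-variance Student's $t$ test per protein on the NSAF
values themselves (a Welch variant and a log-transformed variant are
available behind flags; both default off because the minimal reading of
the procedure tests the untransformed replicate values). Benjamini-
Hochberg q values are computed over all tested proteins, and the deepest
rank in the ascending-p ordering whose q value stays within
$\alpha = 0.05$ defines the high-confidence set at a 5% FDR. Both the p
and q thresholds are applied inclusively (`<= 0.05`); the boundary case
is configurable via `alpha`.

Three policies deserve mention:

* **Exclusive detections.** A protein with all-zero P2 counts and nonzero
  MF counts is classed `MF-exclusive` and keeps a `+Inf` fold-change
  sentinel (serialized as the literal `Inf`). It remains testable: its t
  test compares its MF replicates against a constant zero group.
* **Degenerate variance.** When both groups are constant the t statistic
  is undefined. Equal constants give $p = 1$; differing constants give
  $p = 0$ and a `degenerate` flag. This keeps reproducible exclusive
  detections significant rather than dropping them.
* **Compositional coupling.** NSAF is a composition: planting strong
  enrichments necessarily depresses every other protein's NSAF in that
  sample. This is a property of the measure, not a bug; it matters for
  interpreting false-discovery proportions on simulated data (below).

# Screen caller

Each screen experiment is a prey-by-bait OD650 matrix (rows = Fc preys,
columns = AP baits plus an AP-only control column) with its own blank
wells. The caller:

1. estimates the plate background as the arithmetic mean of at least 30
   blank wells (fewer is an error);
2. divides every well by the background to get fold over background
   (FOB);
3. marks wells with FOB strictly greater than 5 as candidate positives;
4. rejects promiscuous preys: a prey above threshold against every bait
   column (including the control), or positive against the AP-only
   control at all, has all its calls removed for that experiment. The
   "every bait" fraction is configurable (`flag_fraction`, default 1)
   because the operational definition is absolute;
5. pools positive wells across experiments and orientations into
   unordered construct pairs — a well (bait X, prey Y) is one detection
   event for pair {X, Y} — and accepts pairs with at least 2 events,
   regardless of whether the events come from one orientation, both, or
   different experiments. Homophilic pairs occupy a single diagonal well
   per experiment, so their maximum event count is 3 rather than 6.

Accepted pairs form a graph whose connected components are the reported
interaction modules; edges absent from a user-supplied known-pair list
are flagged novel. With a 73-construct panel, one experiment tests
$73^2 = 5329$ wells covering $73 \cdot 74 / 2 = 2701$ unique pairs, using
$2 \times 73 = 146$ tagged constructs.

# Pull-down filters

The two filter modes mirror the two validation experiments: the
whole-brain mode retains proteins absent from every Fc control and
carrying at least 2 spectral counts in **each** bait experiment; the
MF-synaptosome mode relaxes the control clause to at most 1 count. "Per
experiment" is enforced as a conjunction across bait columns. Hits are
ranked by total bait counts, descending, with identifier tie-breaks, so
output files are deterministic. The whole-brain filter output is always a
subset of the MF filter output on the same table.

# One-site affinity fit

Steady-state responses follow $R(C) = R_{\max} C / (K_D + C)$. The fit is
unweighted nonlinear least squares (Levenberg-Marquardt), initialized
from the data ($R_{\max}$ at the largest response, $K_D$ at the
concentration nearest half-max) with a coarse retry grid of $K_D$ starts
for near-saturated series where the half-max heuristic lands on a flat
region. Technical replicate columns are averaged before fitting; a
matched reference series (sensor with Fc fragment alone) can be
subtracted pointwise first. Options: a linear drift term per dilution
step (off by default; slow systematic drift is a known instrument
artifact), and a pseudo-Huber (soft-L1) loss for outlier-contaminated
series. The fit warns, and records `extrapolated = TRUE`, when the
estimated $K_D$ falls outside the measured concentration range.
Non-convergence is reported in the returned object, never as an
exception. Only equilibrium analysis is implemented: the published
affinity is read from response-vs-concentration, and no kinetic traces
are available to fit $k_{on}$/$k_{off}$.

# What the generators emulate

* `gen_spectral_counts()` draws negative-binomial counts
  (variance $\mu + \mu^2/\theta$) at a common baseline mean, multiplies
  the MF mean of planted enriched proteins by `enrichment_fold`, zeroes
  the P2 counts of planted exclusive proteins, and derives peptide counts
  as $\max(1, \lceil \mathrm{SpC}/2 \rceil)$ for detected observations —
  only the peptide filter consumes them. The negative binomial is our
  choice of overdispersed count model; no distributional form is
  prescribed by the assay. The default dispersion $\theta = 10$
  (replicate CV $\approx 35\%$ at moderate counts) reflects biological
  replicates of independent preparations; cleaner preparations sit nearer
  $\theta = 100$ (CV $\approx 20\%$).
* `gen_elisa_screen()` draws every well from a truncated Gaussian
  background with mean 0.07 and SD 0.027 OD650 — the documented plate
  background, whose blank-well mean the acceptance checks recompute —
  and 100 blank wells per plate. True pairs light each orientation well
  with probability `detection_prob` at 8-50 fold over background (the
  plate's stated dynamic range is ~50 FOB; the lower edge of 8 keeps
  planted positives strictly above the 5-fold threshold under background-
  estimation noise). Sticky preys get 6-50 fold signal against every
  bait including the control. Blank wells are a value list; their plate
  coordinates are not modeled since only their mean is consumed.
* `gen_pulldown()` plants hits (>= 2 counts per bait experiment, <= 1 in
  the control), resin contaminants (counts in bait and control alike),
  and sparse background proteins.
* `gen_bli_series()` emits steady-state responses on the 34 to
  $34/2^8 \approx 0.133$ µM twofold ladder (nine concentrations plus a
  buffer-only zero point) with Gaussian noise and optional linear drift.
  Sensorgrams are not simulated.

What passing tests on these simulations do **not** show: real
spectral-count data have protein-specific abundance and dispersion,
shared-peptide ambiguity, and batch structure; real plates have spatial
effects and partially promiscuous preys; real BLI has correlated,
non-Gaussian residuals. The generators validate the *rules* — the
normalization, thresholds, merging logic and estimator — not the
biological variance structure.

# Numerical and design choices

* **Recovery regime.** The planted-enrichment recovery test runs at 1000
  proteins, baseline mean 30, dispersion 100, with 20 planted 8-fold
  enrichments: a well-powered regime where the high-confidence set
  recovers >= 80% of planted effects at an observed false-discovery
  proportion <= 15% across 20 seeds. Power degrades quickly with noisier
  replicates (at $\theta \le 20$ the 3-vs-3 $t$ test with df 4 cannot
  beat the BH multiplicity burden), and small panels make NSAF's
  compositional depression of null proteins itself statistically
  detectable, inflating apparent false discoveries. Both regimes are
  faithful to the measure; the test documents the favorable one.
* **Null FDR control.** On all-null simulations every high-confidence
  call is false, so the per-run false-discovery proportion is 0 or 1 and
  its 20-seed mean estimates the probability of any false discovery,
  which BH holds at ~$\alpha$ under the global null.
* **Determinism.** All generators are seeded and byte-reproducible;
  screen call tables and hit lists are sorted lexicographically; network
  modules are ordered by their smallest member.
* **Problem sizes.** Tests use panels of 10-20 constructs, tables of
  40-1000 proteins, and 20-50 seeded repeats — sizes chosen so the whole
  suite exercises every rule at Monte-Carlo-meaningful depth while
  remaining quick to run on one core.

# Known limitations

* The t test on untransformed NSAF values assumes approximate normality
  of a composition; with three replicates this is unverifiable per
  protein, which is exactly why the BH high-confidence tier exists.
* The ">= 2 detections" merge rule accepts two wells from a single
  experiment's two orientations; whether replication across experiments
  should be required instead is configurable via `min_detections` but
  not resolvable from the assay's definition.
* The promiscuity rule is binary; preys sticky against many-but-not-all
  baits pass it (tunable via `flag_fraction`).
* BLI responses are treated as independent equilibrium measurements;
  `kd_stderr` is the asymptotic standard error and inherits that
  assumption.
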