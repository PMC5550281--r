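---
title: "Methods: wiring statistics and spatial motifs in the mushroom-body alpha lobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wiring statistics and spatial motifs in the mushroom-body alpha lobe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbwiring)
```

# The circuit and the counting conventions

The mushroom-body α lobe contains the parallel axons of ~1000 Kenyon
cells (KCs) running through three serial compartments (α1, α2, α3), each
defined by the dendrites of a few output neurons (MBONs) and the
terminals of dopaminergic neurons (DANs). Synapses here are polyadic: a
single presynaptic density can contact several postsynaptic partners.
Throughout the package **one synapse = one (presynaptic site,
postsynaptic neuron) contact**, so a site with four partners contributes
four synapses; this is the convention under which published per-cell
totals exceed presynaptic-density totals. Multiple contacts between the
same cell pair at different sites are always distinct synapses. All
positions are in nanometres; compartments are annotations on sites (not
re-derived from geometry), and compartment adjacency is serial only
(α1–α2, α2–α3).

# The Poisson wiring null model

The central statistical idea is a zero-parameter null: if each of $N$
synapses is assigned independently and uniformly at random among $M$
candidate cells, the expected number of cells receiving exactly $k$
synapses is

$$c_k = M \, \frac{(N/M)^k}{k!} \, e^{-N/M},$$

i.e. $M$ times the Poisson pmf with mean $\lambda = N/M$. Both $N$ and
$M$ are observed, so nothing is fitted; the variance of each expected
count equals the count, and the reported spread is $\sqrt{c_k}$. The
untruncated $c_k$ sum to $M$ exactly — a normalization the test suite
asserts.

`poisson_expected_counts()` implements $c_k$; `poisson_fit()` tabulates a
per-cell count vector (zeros included — the model's $M$ is *candidates*,
not connected cells) and evaluates the fit.

## Goodness of fit and its degrees of freedom

`chi2_gof()` retains every count bin whose expected value is at least
0.5 (the `min_expected` parameter), computes
$\chi^2 = \sum (o_k - e_k)^2 / e_k$ over the retained bins, and converts
to a p-value with the $\chi^2$ distribution. Two degrees-of-freedom
conventions are offered:

* `"bins"` (default): df = number of retained bins. This is the
  convention under which the package reproduces the classic worked
  example for this circuit — 78 posterior KCs, 151 synapses, observed
  counts (10, 23, 24, 12, 3, 4, 2), giving $\chi^2 = 5.3$ on 7 bins.
* `"bins_minus_2"`: the textbook correction, subtracting one df for the
  fixed total and one for the mean estimated from the same data.

The default convention is knowingly conservative: with the mean taken
from the data the statistic's true null distribution has roughly
(bins − 2) degrees of freedom, so comparing it against a χ² with more
degrees of freedom inflates p-values and deflates the type-I rate
(measured at roughly 0.02–0.04 instead of 0.05, depending on $M$ and
$\lambda$). The package therefore uses `"bins"` wherever the goal is to
reproduce the published numbers, and `"bins_minus_2"` wherever the goal
is a calibrated test — in particular, the test suite’s calibration
property (empirical type-I $\approx 0.05 \pm 0.02$ over 1000
generator-drawn replicates) is asserted under `"bins_minus_2"`.

One printed value in the worked example is internally inconsistent: the
published $k = 0$ expectation (11.1) does not equal
$M e^{-N/M} = 11.26$, while the $k = 1, 2, 3$ values (21.8, 21.1, 13.6)
all match $M \cdot \text{pmf}$ to one decimal. The $k = 0$ cell is
treated as a transcription slip and excluded from reproduction checks.
(The source also displays the formula with a leading $N$; only a leading
$M$ reproduces its own worked values, so the leading factor is
implemented as $M$.)

## Fit classification

`classify_fit()` maps p-values to the three-colour scheme used to scan
whole connection grids: **green** for p > 0.05 (indistinguishable from
Poisson), **magenta** for p < 0.003 (beyond three sigma), **yellow**
between. `poisson_fit_grid()` applies this per (presynaptic type,
postsynaptic cell).

## Independence and association tests

* `fisher_shared_partners()` cross-classifies a candidate-partner
  universe by membership in two cells' target sets and applies a
  **two-sided** Fisher exact test (summing tables with probability at
  most the observed table's). The source does not state sidedness;
  two-sided is the standard choice and is documented as such. Exact
  Fisher p-values are discrete and slightly conservative, so under a
  simulated independent null their distribution is only approximately
  uniform; the corresponding test therefore asserts uniformity at a
  discreteness-tolerant level and bounds the rejection rate from above.
* `paired_target_correlation()` is the plain Pearson coefficient on
  per-cell counts toward two targets, with zero-variance inputs
  signalled explicitly (`NA` + warning) rather than silently propagated.
* `ks_two_sample()` reports the asymptotic two-sample
  Kolmogorov–Smirnov test.
* `rosette_repeat_test()` asks whether KC pairs that co-occur in one
  rosette co-occur again elsewhere more often than chance. The statistic
  is the number of unordered KC pairs appearing in ≥ 2 rosettes; the
  null keeps every rosette's size and redraws its members without
  replacement from the KC pool. Because the statistic is a small
  integer, its permutation p-value is strongly discrete; uniformity
  under the null is asserted on the randomized probability integral
  transform of the permutation distribution, which is exactly
  Uniform(0,1) under exchangeability.

# Spatial motifs

A **convergence** is a tight grouping — within 300 nm — of presynaptic
sites from at least two distinct KCs sharing a postsynaptic neuron. The
published definition names the radius but not the grouping procedure;
the package uses **single-linkage components** at the 300 nm threshold
(every member joined by a chain of pairwise distances ≤ 300 nm), the
weakest assumption consistent with "within 300 nm" pairs, implemented
exactly (grid-bucketed union–find; validated against an independent
hclust single-linkage oracle). Choices fixed here:

* "Common target" means the same postsynaptic *neuron* (the testable
  reading of "target"/"dendritic process").
* Distances are Euclidean, site-to-site (membrane-to-membrane distance
  is not available in a synapse table).
* Ties at exactly the threshold count as within (closed ball).

A **rosette** is a convergence that also contains a KC→KC synaptic
contact whose presynaptic site lies within the radius of the cluster and
whose two endpoints are member KCs. A **KC↔KC→MBON triangle** is an
unordered KC pair with a KC→KC contact (either direction, anywhere in
the lobe) whose members co-occur in one convergence cluster on the same
MBON; `triangle_motifs()` reports each (pair, MBON) once.

`motif_fractions()` uses as denominator all KC presynaptic sites with at
least one contact onto the selected postsynaptic type, and as numerator
those participating in a detected convergence (resp. rosette).

# Volume-transmission coverage

Dopamine acts in part beyond the anatomical synapse. The package models
this purely geometrically: `dan_proximity_fraction()` reports the
fraction of KC→MBON contacts with a DAN presynaptic site within a
radius (default 300 nm), and `coverage_curve()` sweeps a radius grid
(default 0–5000 nm in 100 nm steps, spanning the 2–2.5 µm range usually
discussed for dopamine's effective reach) separately for DAN sites of
the same and of adjacent compartments. `nearest_modulation_stats()`
reports, per KC→MBON contact, the distance to the nearest DAN→KC
synapse and how many other presynaptic sites lie strictly closer. No
diffusion PDE is solved; "coverage" is ball membership.

# Dendritic input positions

`geodesic_from_root()` accumulates Euclidean edge lengths along the
unique tree path of an SWC skeleton (validated to be a single connected
tree with positive edge lengths). The measuring root — the point where
the dendrites become a single axonal fiber — is an anatomical judgment
and therefore an explicit argument, defaulting to the SWC root.
`input_profile()` snaps each contact to its nearest skeleton node
(Euclidean), with a default snap tolerance of 500 nm: contacts sit on
the membrane while the skeleton follows the centerline, and unmappable
contacts are excluded with a reported count rather than silently
dropped. Distances are geodesic by default (Euclidean behind a flag,
since the published figures do not state which was used) and are
histogrammed in base-10 log-spaced bins from 0.1 µm, because the
published plots use a log distance axis without stated bin edges.

# The synthetic generator: what it emulates, and what it does not

`generate_connectome()` produces α-lobe-like connectomes with complete
ground truth, so that every downstream statistic can be checked against
a known answer. It emulates:

* the published **cell census** — 480 surface, 132 outer-core, 259
  inner-core and 78 posterior KCs (949 total), two MBONs and two DANs
  each in α3 and α1's census equivalents, the α2 MBON quartet, sixteen
  α1 DANs;
* **per-pair Poisson wiring**: every ordered (pre cell, post cell) pair
  of a configured connection type receives an independent Poisson count.
  Draws are per pair (not per-cell totals multinomially split), which
  makes the ground truth analytic and matches the model's
  independent-assignment reading. Default rates are derived from the
  published tables as unconditional per-pair means (per-subtype
  connected-fraction × mean-among-connected for KC→MBON; whole-lobe
  totals divided by cells for the DAN links);
* **spatial clustering**: a configurable fraction of KC→MBON contacts
  is planted into convergence clusters (members uniform in a 140 nm
  ball, so pairwise distances stay ≤ 280 nm < 300 nm), and a fraction of
  clusters receives a member-to-member KC→KC contact, becoming planted
  rosettes. Cluster centres can be forced apart
  (`min_cluster_separation`) to make planted-motif recovery exact;
  placement fails loudly when the geometry cannot honour the
  separation.

Geometry is a stylized cylinder: radius 5 µm, three 10 µm compartments
in series, KC axons as straight axial lines at a fixed radial position
(jittered laterally at each release site), extrinsic innervation
spanning the full compartment cross-section. The real lobe is larger
and far less isotropic, and the spatial point process of synapses along
real axons is unknown — uniform-with-jitter is a modelling choice,
recorded in the ground truth. Two consequences matter when reading
synthetic results:

* absolute spatial fractions (DAN proximity, coverage at a given
  radius, accidental convergence) are **higher** in the compact
  synthetic lobe than in the real one; the package's spatial validation
  therefore compares against closed-form spatial-process oracles on the
  synthetic geometry, not against the published absolute percentages;
* at full density, independently planted clusters can fall within the
  clustering radius of each other and merge, so realized motif
  fractions exceed the planted rates unless separation is enforced.

The generator does not emulate membrane morphology, vesicle classes,
α2 sub-zone innervation masks, background KC→KC wiring beyond planted
rosettes, polyadicity beyond the rosette contacts, or electrophysiology.

Randomness uses R's Mersenne–Twister via `set.seed()`; a counter-based
generator would also have served, but none ships with base R, and the
determinism contract — identical configuration and seed give a
bit-identical connectome — holds and is tested either way.

# Numerical choices

* Spatial predicates use closed balls; a small squared-distance epsilon
  (10⁻⁶ nm²) guards strict comparisons against BLAS rounding, so a point
  exactly at a threshold never flips category.
* Nearest-neighbour and counting queries are exact chunked brute force;
  the single-linkage components use an exact grid-bucketed union–find.
  Both match all-pairs oracles bit for bit, which the suite asserts.
* Display rounding is two decimals, half-up; all internal values are
  unrounded. Percentages are computed on synapse counts, not cell
  counts.
* Means in wiring summaries are over *connected* cells by default (the
  published tables' convention), with zero-inclusive means behind a
  flag — the Poisson fits always use the zero-inclusive count vectors.

# Problem sizes used by the test suite

The suite validates statistical properties at deliberately compact
sizes: parameter recovery over 100 seeded replicates of a 50-KC lobe;
type-I calibration on 1000 generator-drawn count vectors (100 KCs,
λ = 2); planted-motif recovery on ~25-KC lobes with 900 nm cluster
separation; oracle comparisons on instances up to ~500 sites; coverage
against the slab-clipped analytic form over 8 replicate lobes; p-value
uniformity over 200 simulated nulls. The shipped demo pipeline runs a
~1/20-scale lobe (48 KCs) and completes in well under five minutes.

# Known limitations

* The published DAN→MBON percentage column cannot be reproduced exactly
  for the α1 and α2p3p rows from the published tables themselves (e.g.
  727/9303 = 7.81% vs a printed 7.77%); the denominator used there is
  ambiguous. `dan_mbon_percent()` defines the percentage as DAN→MBON
  count over the KC→MBON total and reports the computed column
  alongside the printed one.
* Whole-lobe KC→DAN totals differ slightly between the published table
  and the running text for α2 (1600 vs 1699); the fixtures transcribe
  the table. The KC→DAN / DAN→KC ratio rounds to 1.5 under either.
* Compartment assignment comes from annotations; no geometric
  re-derivation is attempted (the real lobe shows no boundary
  structure).
* The reader's file schema is self-defined (documented in
  `read_synapse_table()`); no public deposition schema exists to match.
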