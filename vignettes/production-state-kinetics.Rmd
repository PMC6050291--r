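---
title: "Production-state kinetics of the lambda switch: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Production-state kinetics of the lambda switch: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lambdaswitch)
```

## The scientific problem

The lambda switch couples two mutually repressive transcription factors: CI
(lysogeny) binds the right operators $O_R1$/$O_R2$, activating its own
promoter $P_{RM}$ and silencing Cro's promoter $P_R$; Cro (lysis) binds
$O_R3$ and silences $P_{RM}$. Classically this circuit is bistable: cells
express either CI or Cro. Dual single-molecule reporters that count *newly
produced* molecules of both proteins in the same cell every 5 minutes
(photobleaching between frames, so each frame reads out promoter activity
directly) reveal four production states rather than two: $[L,L]$ (neither
produced), $[H,L]$ (Cro only), $[L,H]$ (CI only) and $[H,H]$ (both).

This package implements the full analysis chain for such data — and,
because no public dataset exists, a generator that produces statistically
matched synthetic data for every stage.

## The hidden Markov production model

A lineage's per-frame counts $(c_t, i_t)$ (Cro, CI molecules produced in
frame $t$) are modeled by a $K$-state HMM. Conditional on the hidden
production state $S_t = k$, counts in the two channels are independent
Poisson draws with means $(\lambda^{cro}_k, \lambda^{ci}_k)$
(molecules/frame); the per-frame transition matrix $A$ is row-stochastic.
The Poisson family is the minimal count-emission model consistent with
unimodal per-state spread; a negative-binomial family with a shared
dispersion is available (`family = "nbinom"`) for overdispersed data. The
four-state default uses emission means $(0,0)$, $(5.2,0)$, $(0,4.7)$,
$(4.5,4.7)$.

Dwell times of a state are geometric with mean
$\Delta t / (1 - A_{kk})$ minutes. `build_transition_matrix()` calibrates
$A$ from observable summaries: the diagonal from target mean dwell times
$(7, 36, 127, 47)$ min, the off-diagonal entries by non-negative least
squares so the stationary distribution matches the observed per-state frame
fractions $391\!:\!1733\!:\!3145\!:\!3069$ (ties broken toward a uniform
split of each row's exit mass). Feasibility is the transportation
condition: no state's stationary exit flux may exceed what the other
states can return; infeasible targets raise an error naming the state.

Fitting is standard Baum–Welch EM over all traces (scaled forward–backward
in compiled code), k-means initialization of the emission means, sticky
($A_{kk}=0.9$) initialization of the chain, 10 restarts by default, and
convergence at relative log-likelihood change $<10^{-6}$ (max 500
iterations). Restarts in which a state's expected occupancy falls below
one frame are flagged degenerate and excluded when a clean restart exists.
Cell-division frames do *not* break the chain — the production state is a
promoter/operator configuration that daughters inherit — but young-cell
filtering boundaries do (`filter_young_cells()` tags segments, and every
downstream routine treats segments as independent chains).

Model selection (`select_model()`) reports two criteria. BIC uses
$p = K^2 + 2K - 1$ free parameters. The histogram-match mode compares the
model's stationary predicted 2D production histogram (closed form, no
sampling) with the observed one by total-variation distance and picks the
*smallest* $K$ within a 1.2× parsimony margin of the best distance;
without such a margin, refits with duplicated states are statistically
indistinguishable and the selected $K$ would be decided by noise.

### Dwell times and transition time constants

`dwell_times()` offers three censoring policies. Excluding runs that touch
trace ends (`"uncensored"`) is unbiased only when dwells are much shorter
than traces; with 69-frame traces and a 127-min state this truncation bias
is severe. The `"exit_rate"` policy — total decoded time in a state
divided by the number of observed exits, the maximum-likelihood rate
estimator under geometric dwells — is robust to censoring and is what the
package's own acceptance checks use. Transition time constants are
$\tau_{ij} = $ (time decoded in $i$)/(number of $i\to j$ switches), and
the analytic counterpart $\tau_{ij} = \Delta t / A_{ij}$ from the fitted
matrix (`tau_from_model()`) provides a cross-check; by construction the
exit-rate dwell satisfies $1/\text{dwell}_i = \sum_{j\ne i} 1/\tau_{ij}$.

## The potential landscape

`histogram2d()` pools all frames into unit integer bins (overflow into the
top bin), and `potential()` maps probabilities to
$U = -\ln(P + \epsilon)$, shifted so $\min U = 0$. Natural log is used
(the landscape is read in units of $k_BT$-like nats). Empty bins are
regularized with a Jeffreys-style pseudocount of 0.5 counts so $U$ is
finite everywhere. `interpolate_landscape()` refines the grid with
tensor-product interpolating cubic splines (original nodes preserved
exactly); it is a display aid, while basin and barrier analysis runs on
the raw grid, where the minimax statistics are exact and directly
comparable to the enumeration oracles in the test suite.

Basins are strict local minima (8-neighborhood) that (i) hold at least
0.1% of the probability mass — a production state must be supported by a
non-negligible number of frames, which suppresses one-count outlier bins
whose pseudocount contrast can reach $\ln 3 \approx 1.1$ nats — and (ii)
survive a 0.5-nat persistence filter against deeper minima. Barriers are
minimax path statistics on the 8-connected grid graph:
$\text{barrier}(b_1, b_2)$ is the minimum over paths of the maximum $U$
en route, minus $U(b_1)$, computed by a widest-path Dijkstra search and
verified against threshold-connectivity and exhaustive-path oracles.

One structural caveat, worth stating because it shapes the acceptance
check: under the minimax definition the optimal path between two
*opposite* (diagonal) basins typically routes *through* an adjacent basin,
so the diagonal saddle equals the highest saddle along that route.
"Every opposite barrier exceeds every adjacent barrier" is therefore
impossible as a strict statement — e.g. the $[L,L]\!\leftrightarrow\![H,H]$
route passes the $[L,H]\!\leftrightarrow\![H,H]$ saddle, and measuring from
the deeper basin necessarily ranks that adjacent barrier at least as high.
The meaningful, testable ordering is the one between the opposite pairs
($[L,L]$–$[H,H]$, $[H,L]$–$[L,H]$) and the $[L,L]$-adjacent pairs
($[L,L]$–$[L,H]$, $[L,L]$–$[H,L]$), with barrier height measured as saddle
height above the deeper basin; the central peak of the landscape keeps the
diagonal crossings higher.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the stated
experimental world:

* 5-min frame interval, counts are newly produced molecules per frame
  (photobleach-interval counting);
* 94 lineages × 69 frames ≈ 6,450 frames, the scale of the real dataset;
* the four-state model above, simulated as a hidden Markov chain;
* cell cycles drawn from a normal with mean 71 min and s.d. 22 min,
  truncated below at one frame, rounded to whole frames; division does not
  reset the hidden state and counts are per cell, so no count partitioning
  occurs;
* optional fluorophore maturation lag: each molecule's detection is
  delayed by an exponential with configurable mean (default 7 min, the
  middle of the ~5–10 min Venus maturation range) and re-binned;
* optional binomial detection thinning.

Two maturation facts the tests encode deliberately: a displaced Poisson
process is still Poisson, so in a *single-state* model the lag leaves the
per-frame marginal distribution exactly unchanged (mean and variance); in
a multi-state model the lag smears counts across state switches, so the
spread *conditional on the underlying state* strictly increases while
long-run channel means are conserved. That is precisely "broadens but does
not create or destroy populations".

What a green test does **not** establish: the generator has no
segmentation or tracking errors, no photophysics beyond the optional lag
and thinning, no correlation between channels within a state, and
emission means that are exactly constant per state. Real data violate all
of these mildly; the pipeline's robustness to them is untested here.

### Mechanistic (Gillespie) simulator

`simulate_promoter_mechanism()` runs an exact stochastic simulation over
the $3^3$ occupancy states of $O_R1/O_R2/O_R3$ (free, CI, Cro). $P_R$
fires only when $O_R1$ and $O_R2$ are repressor-free; $P_{RM}$ only when
$O_R3$ is free. mRNAs live ~1.5 min; translation bursts average 1.3
proteins per transcript; translation events are binned into 5-min frames.
Binding propensities are per-molecule rate constants multiplied by the
current free repressor copy number — pseudo-first-order constants cannot
produce the fast-binding bistable regime, because without copy-number
feedback the time-averaged production is a single blob. Proteins dilute
at $\ln 2 / 71$ min$^{-1}$ (growth). `adiabaticity_scale` multiplies all
binding and unbinding rates, leaving occupancy equilibria unchanged while
sliding the switching speed: at 100× (adiabatic) a trajectory locks into
one of the classical branches and frames with both channels ≥2 are rare;
at 0.01× (non-adiabatic) operator states outlive protein relaxation and
all four production quadrants are populated.

Default rates were chosen once, by the stationary-occupancy reasoning
above, so that (i) an unobstructed promoter reproduces the observed
per-frame production means (5.2 Cro, 4.7 CI), and (ii) the two
adiabaticity regimes show the contracted quadrant behavior with margin.
They are illustrative, not fitted. The original aim of keeping all four
mechanistic dwell times within 2× of the HMM table is not jointly
achievable in this three-operator wiring: the $[L,L]$ state (all
operators bound) cannot be shorter-lived than the singly-bound states it
is built from, whereas the data's $[L,L]$ dwell (7 min) is the shortest.
The simulator is a mechanism illustration, not a quantitative fit — one
run starting from bare operators also begins in $[H,H]$ by construction,
which is why ensemble summaries discard an equilibration burn-in.

## Spot quantification

The normalized distance of a spot to the cell centroid is axial:
$d = |(p - c)\cdot u| / L_{1/2}$ with $u$ the long-axis unit vector,
clipped to $[0,1]$ (pole vs mid/quarter targeting differs along the axis;
whether the original analysis used axial or Euclidean distance is not
recoverable, and this convention is recorded, not asserted). Spots with
$d \ge 0.6$ are pole-localized (CI reporter), below are mid/quarter
(Cro reporter); the boundary goes to the pole side. Single-molecule
intensity calibration is a Gaussian fit to a sample of single-molecule
intensities (error if the fitted s.d. exceeds the peak — a bimodality
symptom), counts are `round(intensity / peak)` floored at zero, and
delocalized "cloud" signal is quantified as total cell fluorescence minus
pole-spot fluorescence, divided by the peak.

The synthetic spot frames place pole spots at axial fractions
$\sim N(0.87, 0.15)$ and mid spots as an equal mixture of midcell
$N(0, 0.12)$ and quarter-cell $N(\pm 0.5, 0.08)$, jittered by the 30–40 nm
localization precision, rendered as Gaussian PSF peaks with shot and read
noise. These widths emulate the observed ~92–95% separability at the 0.6
threshold; they were fixed from that separability figure, not tuned to
the classifier test. Detection is local-maximum candidates above a robust
(median + MAD) threshold with least-squares 2D Gaussian refinement;
saturated fits are flagged, near-duplicates merged (brighter wins).

## Numerical choices and degenerate inputs

* Likelihoods use scaled recursions; a frame impossible under every state
  yields $-\infty$ with a warning, not a crash. Zero emission means are
  legal (`dpois(0, 0) = 1`); EM floors fitted means at $10^{-6}$.
* Viterbi ties break toward the lower state index, deterministically.
* `stationary_distribution()` uses the eigen decomposition with a power
  -iteration fallback; `predicted_histogram()` errors if the chain has no
  unique stationary distribution.
* Flat landscapes report zero basins; single-well landscapes report an
  empty barrier matrix.
* All randomness descends from one root seed through a documented
  linear-congruential derivation (`derive_seed()`), keeping every derived
  seed a valid 32-bit R seed; fixed seed means bit-identical outputs.

## Acceptance checks and their design

`tests/testthat/test-acceptance.R` encodes the package's acceptance
criteria: generator fidelity at the ~6,450-frame scale; recovery of
emission means (≤10%) and dwell times (≤20%, exit-rate policy, medians
over 20 seeds); selection of $K = 4$ under both criteria in ≥18/20 seeds;
the four-basin landscape with the opposite-vs-adjacent barrier ordering
(a stochastic property, so it is assessed over a fixed five-seed panel
with majority thresholds rather than a single draw); exact agreement of
the forward, Viterbi and minimax-barrier implementations with independent
enumeration oracles; ≥90% spot-classifier accuracy per class; and the
quadrant signatures of the two adiabaticity regimes.
`scripts/acceptance.R` recomputes the reportable target (the 71-min mean
cell cycle) from scratch; it uses long lineages because the partially
observed cycle at a trace end is length-biased and would otherwise bias
the mean of completed cycles downward (inspection paradox).

## Known limitations

* The emission model is conditionally independent Poisson; real reporter
  counts may be over-dispersed or weakly correlated between channels.
* Barriers are descriptive minimax statistics on an empirical surface,
  not Freidlin–Wentzell actions; they quantify the histogram, not
  dynamics.
* The mechanistic simulator is a single-cell caricature: no replication,
  no partitioning at division, no CI857 temperature inactivation, no
  nonspecific binding reservoir.
* Spot detection assumes a flat background and isolated, circular PSFs;
  it degrades gracefully but untested on structured backgrounds.
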