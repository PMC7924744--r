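---
title: "Models and methods behind trapjawkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trapjawkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapjawkit)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, the numerical
choices, and what the synthetic-data tests do and do not demonstrate about
real data.

## The study system

*Strumigenys* ants divide into gripping forms (GRP) and trap-jaw forms
(S-TRAP, L-TRAP) whose mandibles are locked open by a labrum–mandible
latch and released explosively — latch-mediated spring actuation (LaMSA).
Three quantitative questions structure the pipeline: how often did the
trap mechanism evolve on a dated phylogeny; how much performance does it
buy; and how does mandible-system shape reorganize around it.

## Mk models and ancestral states

The trap character is modeled as a k-state continuous-time Markov chain
on a rooted, dated, binary tree with branch lengths in My. Two
parameterizations are fit: ER ("Mk1", one rate) and ARD ("Mk2", one rate
per ordered state pair). The likelihood is computed by Felsenstein
pruning with per-node rescaling; transition matrices come from a spectral
decomposition of `Q`, with scaling-and-squaring as the fallback when the
eigenvector basis is ill-conditioned (`rcond < 1e-10`). The two routes
agree to ~1e-10 on the small matrices used here and are cross-checked in
the tests against `Matrix::expm` and against closed-form 2-state and
k-state-ER kernels.

Assumptions worth stating: rates are homogeneous in time and across
lineages (no heterotachy), states at the tips are known (or explicitly
missing, contributing all-ones partial likelihoods), and the tree is
fixed and correct. Sensitivity to rooting is handled by re-running on
alternative rootings supplied as separate inputs, not by integrating over
trees.

Choices the literature leaves open, and what this package does:

- **Root prior**: flat (1/k) by default, with stationary and
  user-supplied options. Flat is the common default of the standard
  comparative toolkits; the choice is exposed because it can move
  marginal root states when rates are asymmetric.
- **AICc sample size**: n = number of tips, the conventional unit of
  independent information in comparative data.
- **Optimizer**: L-BFGS-B on log rates, five deterministic starts spread
  over `[0.01, 10] / tree depth`, bounds `1e-8`–`1e3` per My. The log
  parameterization keeps the boundary at a finite coordinate and avoids
  the zero-rate pathology; monomorphic data produce a warning and a
  lower-bound estimate rather than an error.

Marginal ancestral probabilities combine the downward (pruning)
conditional likelihoods with an upward pass, so each node's vector is
proportional to the probability of all data given the node's state. The
root vector weighted by the prior reproduces the pruning likelihood, an
identity the tests assert at 1e-10.

## Stochastic character mapping

Histories are sampled conditional on the tips at the ML rate estimate
(the empirical-Bayes convention of the standard `make.simmap`-style
workflow; rate uncertainty is deliberately not integrated). Node states
are drawn jointly — root from its marginal, children conditional on
parents — and each branch is then filled by an endpoint-conditioned CTMC
bridge sampled by **uniformization**: with dominating rate
`μ = max(-diag(Q))`, the number of candidate jumps is drawn from
`P(N = n | a, b) ∝ Pois(n; μt) (Rⁿ)_ab`, the state sequence from the
discrete bridge of `R = I + Q/μ`, and jump times as uniform order
statistics; self-jumps collapse. Rejection sampling — simulate forward,
keep paths hitting the required endpoint — is exponentially slow for
unlikely endpoints and is kept only as a test oracle, where the two
samplers' transition-count distributions are compared by chi-square.

"Independent origins" are transitions *into* the focal state anywhere on
the tree, counted per map; losses are counted separately. The package
reports the per-run distribution (histogram, mode, min–max, central 95%)
and leaves any synthesis across rootings or models to the user, because
that synthesis is narrative rather than algorithmic.

Biogeographic mapping reuses the identical machinery with k = 6 regions
under ER, fitting the single rate by ML first. This treats ranges as
single areas and does not model range expansion — a deliberate
simplification appropriate when nearly all species occupy one region.

Reproducibility: map i re-seeds the generator at `seed + i`, so a map
set is reproducible and insensitive to evaluation order, and larger sets
extend smaller ones.

## Strike kinematics

Digitized angle traces (uniform sampling enforced to 1e-9 s; at least 8
samples; degrees converted on ingest) are smoothed with a penalized cubic
smoothing spline; "auto" selects the penalty by generalized
cross-validation, and a fixed `spar` is available for regression tests.
Velocity and acceleration are the spline's analytic derivatives.

A numerical choice that matters: smoothing splines carry natural boundary
conditions (second derivative pinned to zero at the ends), which biases
derivative estimates near the trace edges — we measured a 27% overshoot
of the second derivative at the second knot on noiseless quadratic
traces, decaying geometrically inward and falling below 0.2% five knots
in. Derivative extrema are therefore located over an edge-trimmed window
(default 5 samples per side, configurable), which restores <1% accuracy
on polynomial traces at any sampling density.

Other conventions, each configurable and reported in the output row:

- **Strike duration**: time between the first crossings of 2% and 98% of
  the total excursion (endpoints robust to noise at the trace ends; the
  defining thresholds are not standardized in the literature).
- **Power denominator**: time from strike start to peak kinetic energy —
  the standard work ÷ time-to-peak convention.
- **Linear velocity/acceleration reference**: the mandible tip
  (radius = mandible length), the natural weapon-contact point; a radius
  fraction is exposed because the reference point is not standardized.
- **Mandible count**: kinetic energies of both mandibles (2×) enter the
  power numerator by default, since the stored elastic energy accelerates
  both.
- **Threshold**: 730 W/kg, the cited maximum mass-specific power of
  direct muscle contraction; strikes above it imply elastic storage.

Mass helpers implement the two CT-volume conventions: mean reference
density × target volume for mandibles, and single-reference equal-density
scaling for adductor muscles.

## Shape and linear morphometrics

Generalized Procrustes analysis centers each 12 × 3 configuration, scales
to unit centroid size, and iterates align-to-mean/update-mean until the
consensus moves < 1e-10. Rotations are proper (det +1): reflections are
excluded because mandible anatomy is chiral, with a deterministic
tie-break (sign flip on the smallest singular vector) for degenerate
cross-covariances. PCA is performed directly on the aligned coordinates —
the standard tangent-space approximation, adequate because shape
variation in this system is small relative to the curvature of shape
space; geodesic projection is not implemented. Each loading's
largest-magnitude element is made positive so scores reproduce across
platforms.

The latch angle is defined here as a projected planar angle: the two
mandible rays (basal-process base → apical-tooth base) are projected onto
the best-fit plane of the four points and each ray's angle from a
user-supplied anterior head axis is summed. This makes the measure
rigid-motion invariant and reflex-capable (parallel forward rays read 0°;
mandibles latched past straight read > 180°, up to the ~270° extreme),
at the cost of a declared convention — whether the original physical
measurements were planar projections is not recoverable from published
descriptions, so the convention is stated rather than inferred.

## Quartet-informative locus audit

For each internal branch, a locus is potentially quartet-informative if
present in ≥ 1 tip of each of the four subtrees surrounding the branch
(the two child subtrees, the sister subtree, and the rest of the tree).
At the root, the two root edges describe the same unrooted branch; each
is scored using the sibling's two child subtrees as the upper pair, and
branches whose upper side cannot supply two disjoint subtrees (sibling is
a tip) are reported `NA` rather than 0 — the four-subtree criterion
simply does not apply there, and published treatments do not specify root
handling. Counts are monotone under added presences, and the implementation
is tested against a per-locus brute-force oracle.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline reads, in the same file
formats, with exact ground truth:

- **Yule trees** (pure birth, default rates ~0.1–0.3/My giving realistic
  crown depths for a Miocene radiation). No extinction: tree *shape*
  realism is secondary to having dated, ultrametric, binary inputs.
- **Exact CTMC histories** branch by branch, recording every transition.
- **Engineered radiations**: the origin count is made exact by *painting*
  histories (disjoint derived clades of 5–40 tips, one 0→1 transition at
  each stem midpoint, no losses) rather than by tuning rates — so
  "recover the origin count" tests have an unambiguous truth.
- **Strike profiles** (linear, quadratic, logistic) with closed-form
  derivative maxima; the trap-jaw vs gripping contrast uses a 50 μs event
  at 800 kfps against a 10 ms event at 2.5 kfps, matching the two imaging
  regimes such experiments use.
- **Landmark samples**: group mean shapes + isotropic Gaussian landmark
  noise, wrapped in random rigid + scale nuisance transforms.
- **Presence matrices**: i.i.d. dropout (low-coverage-like) vs loci born
  on branches and lost at a disruption rate (clade-blocked,
  mutation-disruption-like).

What passing these tests shows: the algorithms are correct against
enumeration, closed forms, and engineered truth, and the pipeline's
qualitative contrasts (origin recovery, amplification calls, ecomorph
separation, deep-branch enrichment) emerge under the stated conditions.
What it does not show: robustness to the failure modes of real data —
rate heterogeneity across lineages, state-assignment error, tracking
noise far from Gaussian, landmark placement error correlated across
landmarks, phylogenetic error, or extinction-shaped tree imbalance. The
analysis scripts' problem sizes (470-tip trees, 500 maps, 27 landmark
specimens, 100-locus audits) were chosen to mirror a realistic single
study; the acceptance checks scale some replicate counts down (e.g., 20
rate-recovery replicates at 300 tips) to keep a full verification run in
minutes while preserving each check's statistical resolution.

## Known limitations

- No hidden-state, covarion, or lineage-heterogeneous (random local
  clock) character models; no explicit range-evolution (DEC-style)
  biogeography.
- Stochastic maps condition on point estimates of `Q`; the origin-count
  intervals understate total uncertainty accordingly.
- Spline derivatives remain untrustworthy within the edge-trim window;
  events whose true extrema occur in the first or last few frames need
  higher frame rates, not smaller trims.
- The latch-angle convention caps at 360° and assumes the four defining
  points admit a stable best-fit plane (a warning fires near degeneracy).
- GPA assumes identical landmark schemes across specimens; there is no
  support for missing landmarks or semilandmarks.
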