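# trapjawkit

Comparative phylogenetics and biomechanics of trap-jaw (latch-mediated
spring-actuated, LaMSA) mandible evolution, built for the *Strumigenys*
study system: a hyperdiverse ant genus in which a labrum–mandible latch
mechanism has arisen repeatedly, converting slow gripping mandibles (GRP)
into power-amplified short (S-TRAP) and long (L-TRAP) trap-jaws.

The package is aimed at evolutionary biologists who want to run — and
stress-test on data with known ground truth — the full analysis chain such
a study needs:

- **Discrete-character evolution.** Mk models on a dated phylogeny:
  the likelihood `L(Q) = π' ∏ P(t_e)`-style Felsenstein pruning, ML fitting
  of equal-rates (Mk1/ER) and all-rates-different (Mk2/ARD) generators
  `Q`, AICc comparison with the small-sample correction
  `AICc = −2ℓ + 2p + 2p(p+1)/(n−p−1)`, and marginal ancestral state
  probabilities per node.
- **Stochastic character mapping.** Full character histories conditional
  on tip data at the ML rates: joint node-state draws by
  forward-filter/backward-sample, then endpoint-conditioned CTMC paths on
  every branch by uniformization (Poisson candidate jumps of the
  discretized kernel `R = I + Q/μ`, bridged on the jump count). Per-map
  transition counts give the distribution of *independent origins* of the
  trap mechanism; the same machinery maps single-area biogeographic states
  under a 6-region ER model.
- **Strike kinematics.** Penalized smoothing splines (GCV) on digitized
  angle-vs-time traces with analytic first/second derivatives; strike
  duration from excursion-threshold crossings; mandible kinetic energy
  under the thin-rod model `KE = ½·(mL²/3)·ω²`; mass-specific adductor
  power `P = n·KE_max/(t_peak·m_muscle)`; and a power-amplification call
  against the 730 W/kg ceiling of direct muscle contraction. Helpers
  estimate mandible and muscle masses from CT volumes by reference
  densities.
- **Geometric and linear morphometrics.** Generalized Procrustes analysis
  (reflection-free) of 12-landmark 3D mandible-system configurations,
  tangent-space PCA, mandible index (mandible length / head length), and
  the reflex-capable latch angle (subparallel 0° up to ~270°).
- **Missing-data audit.** Per-branch counts of potentially
  quartet-informative loci in a taxa × loci presence matrix: a locus
  counts for a branch only if present in at least one tip of each of the
  four subtrees surrounding it.
- **Synthetic data with exact truth.** Yule trees, exact CTMC character
  histories, radiations *engineered* to contain an exact number of
  convergent origins, parametric strike profiles with closed-form
  derivative maxima, ecomorph landmark samples under nuisance transforms,
  and presence matrices with random vs clade-structured dropout.

## Worked example

The `analysis/` directory is a numbered workflow over the package
(`Rscript analysis/01_simulate.R --seed 1`, then `02_fit_mk.R`, …,
`06_quartet_audit.R`; all write under `results/`). On a synthetic
470-species radiation engineered with exactly three trap-jaw origins,
seed 1 prints:

```
   model n_params    loglik     aicc delta_aicc preferred
  Mk1_ER        1 -25.38123 52.77100   0.000000      TRUE
 Mk2_ARD        2 -25.06153 54.14876   1.377762     FALSE

independent trap-jaw origins across 500 maps: mode 3, range 3-5, 95% interval 3-4

 specimen   duration_s   alpha_max power_w_per_kg amplified
     trap 1.903166e-05 19269280430   1.437378e+07      TRUE
     grip 4.014720e-03      492138   7.921090e-01     FALSE
acceleration contrast: 4.6 orders of magnitude

ecomorph silhouette on PC1-2: 0.918
trap latch angle: 270 deg (reflex)
deep branches (clade >= 15 tips): mean informative loci 1.0 (random) vs 0.4 (clade-structured)
```

Reading this: AICc prefers the equal-rates model that generated the data;
the stochastic maps recover the engineered origin count (mode 3); the
trap-jaw strike trace is called power-amplified (1.4 × 10⁷ W/kg ≫ 730
W/kg) while the gripping strike is not, with a > 4 order-of-magnitude
angular-acceleration contrast; the three ecomorph groups separate cleanly
in tangent shape space; and random (coverage-like) locus dropout leaves
deep branches better informed than clade-structured
(mutation-disruption-like) dropout at matched missingness.

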