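---
title: "Methods: coiled-coil design search and hydrogel characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coiled-coil design search and hydrogel characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilgel)
```

coilgel implements two connected pieces of machinery for engineered
coiled-coil protein hydrogels: a stochastic sequence-design engine that
searches for variants with minimized terminal surface-charge patches, and
the analysis routines used to characterize the resulting hydrogels
(microrheology, circular dichroism, FTIR, phase behaviour, drug
loading/release, and caliper tumor volumes). This vignette records the
models, the tunable parameters, and the design decisions behind each, so
that a user can judge what a passing test suite does and does not
demonstrate.

## Sequence model

A `cc_seq` holds a protein sequence with three annotations: a His-tag
region (default residues 1–16) that is excluded from both mutation and
scoring because its random-coil structure is not modelled confidently; a
coiled-coil domain (38 residues by default); and a heptad register offset
mapping the first coiled-coil residue to one of the wheel classes a–g. All
index conventions are 1-based and inclusive, matching how such regions are
reported in practice.

Mutations are proposed per wheel class: core positions a/d draw from
{V, I, M, T, Q, L} (residues favoured in homopentameric coiled-coil
cores), and surface positions b, c, e, f, g from the charged/neutral set
{A, E, K, Q, N, T, D}. The proposal distribution is documented and simple:
a uniform choice among positions that have at least one alternative,
then a uniform choice among the alternatives. Self-mutations are excluded
— a "mutation" that changes nothing would only rescale acceptance counts.

The register offset of a given sequence is rarely printed in the
literature; `infer_register_offset()` recovers it as the offset that
maximizes Kyte–Doolittle hydrophobicity at the a/d core, which is the
standard heuristic, and the default offset is 0.

### Reference sequences

The package ships a synthetic stand-in family `q_family_sequences()`
(`Q`, `Q4`, `Q8`) because the real sequences of the system that motivated
this package are published only as a figure. The stand-ins are
deterministic and satisfy every sequence-level constraint stated in text:
Q8 is drawn entirely from the position alphabets with a positive
N-terminal and negative C-terminal surface patch, differs from Q at
exactly 25 of 38 coiled-coil sites (34% identity), and differs from the
search input Q4 at exactly 7 sites. They are labelled `_synthetic`
everywhere, including the packaged FASTA.

## Scorers

The design objectives in the original workflow are an all-atom stability
score and Poisson–Boltzmann surface potentials. Both require external
engines, so the package defines a *scorer contract* — any function
`cc_seq -> score_bundle` with fields `rs` (kcal/mol), `ne_bcf`, `ce_bcf`,
`dee_bcf` (kJ/mol) — and provides two routes:

* `parse_score_table()` ingests externally computed values from delimited
  text with declared units (kcal/mol for the stability score, kJ/mol for
  the potentials; a contradicting declaration is an error, units are never
  implicit).
* `surrogate_scorer()` is a fast, deterministic built-in used for testing
  and exploration. Its stability term sums negative Kyte–Doolittle
  hydrophobicity over the buried a/d core plus a charge-pair term over
  surface residues at sequence separations 3 and 4. Its patch term is a
  screened Coulomb sum over charged residues at the b, c, f wheel
  positions of one terminal half, on idealized helix coordinates (rise
  1.5 Å/residue, 100°/residue, side-chain radius 6 Å), with a Born-type
  self term (radius 2 Å), relative dielectric 80, and Debye length
  0.43 nm (≈500 mM 1:1 salt, the assembly buffer). Formal charges at the
  working pH 8 are D,E = −1, K,R = +1, H = 0 (pKa ≈ 6). These surrogates
  are the package's own constructions: their absolute values are *not*
  comparable to Rosetta or APBS outputs, and published absolute scores
  are treated as reference metadata, not reproduction targets.

Two genuinely open choices are exposed as configuration rather than
guessed. First, the "terminal half" over which each patch is evaluated is
the first or last ⌈L/2⌉ coiled-coil positions — the split is not defined
in the source material. Second, the sign convention of the patch
difference: `N_minus_C` (default), `C_minus_N`, or `abs_diff`; reported
values in the motivating system are not consistent with a single naive
subtraction order, so the convention is explicit in every `score_bundle`.

## The trimodal Monte Carlo search

Each proposed mutation faces three acceptance gates — one on the
stability score and one on each terminal patch potential. A gate accepts
an improving or neutral move with probability 1 and a worsening move with
probability

\[ P = \exp(-C\,\Delta), \]

where \(\Delta\) is the score increase converted to J/mol and \(C\) is
the gate's empirical constant in mol/J: \(3.93\times10^{-5}\) for the
stability gate and \(1.31\times10^{-4}\) / \(1.96\times10^{-4}\) for the
N-/C-terminal gates. This is the only dimensionally consistent
composition of the three quantities (\(\Delta\), \(C\), and \(RT\)) the
method description names: \(RT\) cancels in the exponent
(\(C\cdot RT\cdot\Delta/RT = C\Delta\)), so it is carried in the
configuration for unit bookkeeping (default temperature 298.15 K,
configurable) but does not alter the probability. The acceptance
functions are isolated in `p_accept_rs()` / `p_accept_ebcf()` so this
reading is auditable in one place.

How the three criteria compose per step is not stated in the source
material; the package evaluates **all three gates for every proposal**
(independent seeded Bernoulli draws, all must pass), because the language
of a "total probability" suggests conjunction. Every gate probability and
draw is logged per attempt, so other compositions can be studied from the
trajectory alone.

A simulation runs until a minimum number of mutations (default 150) has
been reached. The count refers to *accepted* (successful) mutations by
default, since successful mutations are what the motivating description
counts separately; `counting_mode = "attempted"` is available, and a
`max_attempts` cap (default 1e5) prevents spinning when the chain reaches
a state where every move is rejected. The running best state is tracked
by minimum `dee_bcf`; `select_design()` implements the selection rule
"fewest mutations among the per-simulation minima", with documented
tie-breaks (lower `dee_bcf`, then lower simulation id). Identical seed
and configuration replay byte-identical trajectories.

The oracle test for the engine uses a deliberately small design space: a
single heptad with classes b, c, and e mutable over {K, E, A} (27
states), stability held constant, so the C-terminal patch never changes
and greedy descent on the remaining objectives provably reaches the
enumerated global optimum — the screened-Coulomb self-energy dominates
the pair couplings, so no strict local minima exist. This is the regime
in which search correctness can be checked exactly; it does not exercise
objective conflict, which on real sequences is resolved by the gate
probabilities rather than by any guarantee of optimality.

## Microrheology

`compute_msd()` is the time-averaged, overlapping-window mean-squared
displacement per particle, ensemble-averaged across particles, with lags
capped at a quarter of the track length (default) and lags supported by
fewer than 10 displacement pairs dropped. It is tested for exact equality
against a brute-force double loop over all frame pairs. Irregular frame
intervals are rejected by default. `msd_log_slope()` is the least-squares
slope of log10 MSD versus log10 lag: 1 for free diffusion, 0 for arrested
probes.

`generate_tracks()` stands in for the microscopy: Brownian mode draws
Gaussian steps with variance \(2D\,dt\) per axis (so the 2-D MSD is
\(4D\tau\)); subdiffusive mode uses fractional Gaussian noise with Hurst
index \(\alpha/2\) (MSD \(\propto \tau^\alpha\)); arrested mode is an
Ornstein–Uhlenbeck probe whose stationary variance sets the MSD plateau.
Optional Gaussian localization noise adds \(4\sigma^2\) to every lag.
What the generator does *not* emulate: static/dynamic localization error
correlations, polydisperse probes, sample drift, and finite-field
truncation of long trajectories — so passing tests demonstrate estimator
correctness on idealized transport, not robustness to every microscopy
artefact.

### Gel-point estimation

Two estimators are provided. `fit_gelation_sigmoid()` fits a
four-parameter logistic (upper asymptote, lower plateau, midpoint,
steepness) to the relaxation exponent versus cure time, by
Levenberg–Marquardt from a small multi-start grid (4-parameter logistics
are sensitive to the initial midpoint and steepness). The gel time is
*defined* as the fitted midpoint — the source material says only
"best-fit sigmoidal analysis", and the midpoint is the only parameter
with a natural transition interpretation. A fit whose asymptote
separation is within three residual standard deviations of zero is
reported as "no gel point" rather than returned.

`time_cure_superposition()` implements the time–cure analysis: MSD
curves at several cure times are collapsed onto pre- and post-gel master
curves by vertical (`log a`) and horizontal (`log b`) log-shifts; the gel
time is the candidate (midpoints of the cure-time grid, at least four
curves per side) maximizing a quality score, and the critical relaxation
exponent is the ratio of the slopes of `log b` and `log a` against
log distance-to-gel-point. Numerical choices that matter, each adopted
after diagnosing a concrete failure mode on synthetic families:

* a candidate shift must keep at least half of a curve's points on the
  master — otherwise the mean-residual objective has spurious minima in
  which a curve slides until only a handful of points overlap;
* after a sequential nearest-first alignment pass, shifts are refined
  against a smoothing-spline master rebuilt each sweep, because a
  piecewise-linear master is biased (chord error) exactly in the curved
  crossover regions that make the two shifts jointly identifiable;
* the reference curve pins an arbitrary gauge. A reference misaligned
  along the master's local power law displaces every other curve's shift
  by a constant, so the slope regressions exclude the reference and fit
  free per-branch intercepts: only the slopes are observable;
* the quality score blends the linearity of the shift factors with how
  well the curves actually collapse — a wrong gel-time split can fake
  the former but not the latter.

`synth_msd_family()` generates critical-gel families from pre-/post-gel
master curves with power-law shift factors (vertical exponent 2.5,
horizontal 2.5 × n). Its default cure times stay within ~40% of the gel
point: further out, curves exit the crossover window of the lag grid and
become pure power laws whose shifts are genuinely unidentifiable — the
known limitation of the method, worst at high exponents. Recovery is
verified for n ∈ {0.4, 0.6, 0.8} at multiplicative log10 noise up to
0.01 (~2.3% MSD error, typical of ensemble-averaged tracking); at ~5%
error the n = 0.8 case can misselect the gel time, which users should
treat as the method's practical noise ceiling rather than a solved
problem.

## Spectroscopy

`compute_mre()` converts raw ellipticity to mean residue ellipticity,
\([\theta] = \theta_{\mathrm{mdeg}} / (10\,l\,c\,n_{\mathrm{res}})\) in
deg·cm²·dmol⁻¹ (path length cm, molar concentration, residue count), and
`ratio_222_208()` reports the coiled-coil diagnostic ratio at the nearest
sampled wavelengths within 1 nm, both at full precision and rounded to 2
significant figures as conventionally quoted.

`deconvolve_amide_I()` fits the 1700–1600 cm⁻¹ amide-I band as a sum of
Gaussians, adding components at the running residual maximum and
refitting until r² ≥ 0.99 (the conventional stop) or a peak cap, then
reports helical content as the helix-band area fraction. Band classes
follow standard amide-I windows (sheet 1620–1640 and 1670–1690, random
1640–1650, helix 1650–1660, turn 1660–1670 cm⁻¹; configurable). A caveat
the tests make explicit: at the r² ≥ 0.99 stop, bands closer than about
15 cm⁻¹ at typical widths are not identifiable — a smaller number of
broader Gaussians fits within the stop criterion — so recovery claims
hold for resolvable mixtures only, and an unreachable r² target yields a
warning with the best fit, not an error.

## Phase boundary

Tube-inversion outcomes are binary, so the "bivariate regression" for the
UCST boundary is implemented as a binary-response logistic model in
temperature and concentration, with the boundary at the 50% contour and
`UCST(c)` solving that contour. Both readings of "thermal dependence" are
reported and labelled: the regression coefficient on temperature, and the
boundary slope dT/dc = −b_c/b_T.

The estimator is Firth's bias-reduced penalized likelihood (implemented
as Newton iteration on the hat-adjusted score) rather than plain maximum
likelihood, for two reasons with small phase grids: complete separation —
every gel observation colder than every non-gel one, common with sharp
boundaries — leaves the MLE divergent but the Firth estimate finite; and
at n ≈ 60 observations the MLE's O(1/n) bias is 15–40% on these
coefficients, while the Firth estimate is within a few percent. A
`separation` flag still reports when the classes are separable.
`synth_phase_observations()` generates outcomes on a factorial
concentration × temperature grid (how tube-inversion diagrams are
actually collected), with a default boundary at 15 °C for 3 mM, slope
+1.5 °C/mM, and a 20–80% transition band ~7 °C wide — gradual enough to
be identifiable at those sample sizes.

`fit_tgel_exponential()` fits \(t_{gel} = A e^{B\,\Delta}\) by least
squares on log gel time and exposes the inverse (the patch difference
required for a target gel time); it exists because a linear gel-time
model extrapolates to negative times at extreme patch differences.

## Loading, release, and tumor volume

Drug loading is a mass balance: loaded = applied − Σ(recovered), with
concentrations from a linear standard curve (least squares, not forced
through the origin; negative fitted concentrations clip to zero with a
warning) and the in-gel concentration dividing by gel volume. Release
assumes full supernatant withdrawal and replacement at each timepoint —
the sampling procedure of the motivating protocol — so each increment is
conc × withdrawn volume and the cumulative sum needs no partial-residue
correction; cumulative release exceeding the loaded amount beyond a 1%
tolerance is an error, and the synthetic generator's noise-free series
close the balance (cumulative + residual = loaded) to within 1%.

Caliper tumor volume uses the simplified ellipsoid form
\(V = L W^2 / 2\) (mm³) from the greatest longitudinal diameter and
transverse width; a width exceeding the length warns (axes likely
swapped) but does not fail, since that is a data-entry issue the analyst
must resolve.

## Problem sizes and reproducibility

Every stochastic routine takes or derives an integer seed, restores the
caller's RNG state, and is replay-exact. The test suite's problem sizes
are chosen to make each claim sharp but quick: 100–200 particles and
300–1000 frames for transport laws, 12-curve families for superposition,
100 replicates at n = 60 for phase-boundary bias, 50 replicates for
sigmoid gel-time recovery, 1000 randomized cases for the mass-balance
properties, and 1e5 draws for acceptance-frequency checks; the full
suite runs in about two minutes on one core. `scripts/acceptance.R`
regenerates the headline Brownian-slope quantity from scratch at any
seed.
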