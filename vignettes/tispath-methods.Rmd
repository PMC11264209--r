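---
title: "Rare-event kinetics and dynamics-guided design with tispath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-event kinetics and dynamics-guided design with tispath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`tispath` implements a dynamics-guided enzyme-redesign workflow on
desk-scale surrogate systems: transition interface sampling (TIS) of
reactive and nonreactive turnover attempts, rate-constant assembly and
decomposition, umbrella-sampling/WHAM free-energy profiling, machine-learned
identification of reactive-like conformations, a multistate design
objective with a stability constraint, and the screening statistics used to
compare variants. The reaction progress coordinate throughout is

$$\lambda = d(\text{breaking bond}) - d(\text{forming bond})
\quad [\mathrm{\AA}],$$

with the reactant state A defined by $\lambda < -0.8$ Å and the product
state B by $\lambda > 0.8$ Å (strict inequalities; both thresholds are
arguments everywhere they appear). Units are kcal/mol, Å, fs, amu and K;
the force-to-acceleration conversion $4.184\times10^{-4}$ (Å/fs)² per
(kcal/mol)/amu is exact in this unit system.

The TIS rate constant is assembled as

$$k = \Phi_A\,P(\lambda_B\mid\lambda_A),\qquad
P(\lambda_B\mid\lambda_A) = P(\lambda_B\mid\lambda_n)
\prod_{i=1}^{n-1}P(\lambda_{i+1}\mid\lambda_i),$$

where $\Phi_A$ is the effective positive flux through the reactant-well
boundary (one count per excursion out of A, divided by the time assigned to
A under history-based state assignment) and each conditional is the
multiplicity-weighted fraction of interface-ensemble paths that reach the
next interface. The default interface grid mirrors the full-scale protocol
(29 interfaces from $-0.8$ to $0$ Å) and is configurable; on the bundled
bond-exchange surrogate the decisive crossing lies slightly past
$\lambda=0$, so rate calculations there extend the grid to $+0.45$ Å,
the committor-one region.

# Dynamics and path sampling

Propagation uses the BAOAB Langevin splitting with an exact
Ornstein--Uhlenbeck noise step, at the protocol conditions (1 fs time step,
friction 1 ps⁻¹, 300 K). At zero friction the scheme reduces to velocity
Verlet, which the tests use for energy-conservation checks; the noise
stream is an own Box--Muller generator over `mt19937_64`, so identical
seeds give bit-identical trajectories on any platform.

Shooting moves select a frame uniformly from the current path, perturb the
momenta by Gaussian displacements of scale `sigma_p` (in units of each
coordinate's thermal velocity), and regenerate the trial path by two-sided
propagation: forward until a basin is entered, and backward by forward
propagation from the momentum-reversed state with *fresh* noise, then
time-reversed and concatenated (the shared midpoint appears once). The
acceptance factor is
$\min\{1,\ e^{-\beta\,\Delta KE}\,N_\text{old}/N_\text{new}\}$,
the product of the phase-space-density ratio at the shooting point (only
the kinetic energy changes) and the uniform frame-selection correction for
flexible path lengths. Candidates that fail to commit within the step
budget count as rejections; rejected moves increment the current path's
Monte-Carlo multiplicity, so post-equilibration multiplicities sum to the
counted move number exactly. In the deterministic limit
(`sigma_p = 0`, friction 0) a shooting move reproduces the current path and
is accepted, which the tests assert.

The choice of stochastic re-noising for the backward segment is a
convention: with Langevin dynamics the time-reversed noise sequence is not
observable, and regenerating both segments from the shooting point leaves
the conditioned path measure invariant. The package validates the whole
machinery by a detailed-balance test: interface-ensemble $\lambda_{max}$
histograms agree (Kolmogorov--Smirnov) with unbiased excursions harvested
from long free dynamics (`harvest_excursion_paths()`), which also supplies
independent seed paths wherever a sampling chain would otherwise inherit
its seed's slow environment coordinates.

Time alignment sets $t=0$ at the last local minimum of the breaking-bond
distance before the final rupture (reactive paths) or before the frame of
$\lambda_{max}$ (nonreactive paths, where "rupture" is undefined; this
anchor is our convention). Monotone distance series raise an alignment
error; ensemble-level alignment drops such paths with a warning. Analysis
windows are half-open $[t_{lo}, t_{hi})$ so tiled windows never double
count, and sampled frames carry the path multiplicity as weight.

# Surrogate systems

Three built-in systems expose one interface (`potential`, `gradient`,
`lambda`), so everything downstream is system-agnostic:

* `make_harmonic()` — a 1D oscillator whose PMF is known exactly; the
  umbrella/WHAM oracle.
* `make_double_well()` — a quartic double well in a scalar $\lambda$ with
  harmonic environment coordinates (optionally bilinearly coupled). With
  the default 4 kcal/mol barrier at 300 K, transitions occur every few
  hundred ps: rare enough to exercise TIS, frequent enough that a
  brute-force transition count converges in minutes.
* `make_migration_mimic()` — the testbed for the learning and design
  stages. Three particles D, M, A in 3D; M (2 amu, hydride-like) migrates
  between tethered D and A over a two-state bond-exchange surface: each
  diabatic state is a Morse bond plus an exponential repulsion from the
  other partner, and the adiabatic ground state
  $V = \tfrac12(V_1+V_2) - \sqrt{\tfrac14(V_1-V_2)^2 + C^2}$
  produces a double well along $\lambda$ *with real bond vibrations* —
  these provide the compression troughs that anchor the time alignment.
  The coupling $C$ is calibrated at build time (root solve on the
  collinear profile) so the intrinsic barrier equals `barrier_height`;
  the product state is stabilized by `exothermicity`, which places most of
  the energetic ascent before the $-0.4$ Å bottleneck.

The planted signal is a *gate*: the first environment particle, on a soft
tether, modulates a product-side wall of height up to `gate_strength`
through a bounded switch on the gate--donor distance. Open gates (distance
beyond the switch midpoint `d_ref`) pass freely; closed gates bounce the
trajectory back into the reactant well. Three design points matter, all
chosen from ground-truth committor curves measured by brute force:

* the wall sits *past* the intrinsic barrier top, so the probability of
  merely reaching the $-0.4$ Å bottleneck is gate-neutral and the
  nonreactive ensemble retains the bulk gate distribution;
* `d_ref` sits about one thermal standard deviation into the favourable
  tail of the gate-distance distribution, so reactive events are strongly
  gate-selected and tether mutations have kinetic leverage;
* the gate is light (1 amu) on a soft tether: its distance sweep
  (~250 fs) outlives a 30 fs analysis window (the signal a classifier can
  read) but decorrelates along a shooting-move chain. With heavy gates the
  chains provably lock into the seed path's gate regime and interface
  conditionals stop marginalizing over the gate — the surrogate's version
  of TIS's known difficulty with slow orthogonal degrees of freedom.

`make_mimic_family()` wraps this into a one-site design space whose
"mutation" shifts the gate tether away from the donor (default +2.0 Å;
brute-force rate ratio about 4). The variant's energy model evaluates its
own potential at a conformation's coordinates, which links the design
objective to the same physics the classifiers and rate calculations see.

# Free-energy profiling

Umbrella windows restrain $\lambda$ with $k_f(\lambda-c)^2$,
$k_f = 200$ kcal/(mol Å²) and *no* ½ factor (the convention of the module
the protocol inherits; a `half_factor` switch is provided). Centers span
$-1.2$ to $1.2$ Å, spaced 0.0325 Å inside $|\lambda| < 0.5$ Å and
0.0975 Å outside. Screening mode runs 5 ps per window with no
equilibration; detailed mode 100 ps with the first 50 ps discarded (both
configurable). Windows are initialized sequentially from the neighbouring
window's final state, walking outward from the reactant state — the
protocol itself does not specify per-window initialization.

WHAM iterates the self-consistent equations on histogram counts until the
maximum change in window free energies falls below $10^{-7}$ kcal/mol
(default bin width: half the inner window spacing). Non-overlapping
windows raise an error naming the gap; the profile is anchored at zero.
Barrier heights are `max(F)` over a barrier region minus `min(F)` over a
reactant region, with SEM over replicate profiles (`n = 3` convention).
Because an extremum over many noisy narrow bins is upward-biased, the
analytic-oracle comparisons in the acceptance suite evaluate the barrier
on bins matching the inner window spacing (0.0325 Å), with regions tight
around the known stationary points, and use 200 ps windows for the
double-well barrier; with those analysis settings the recovered barrier is
within < 0.1 kcal/mol of truth across seeds.

# Classifiers

Datasets take one frame per unique path from a time window (default the
$-160$ to $-130$ fs window at full scale; $-30$ to $0$ fs on the surrogate,
whose prereaction timescale is tens of fs), weighted by path multiplicity,
with features from a user-configurable geometric schema (distances, angles,
torsions, and the minimum-absolute-dihedral-over-hydrogens kind). Two
model families:

* **LR** — logistic regression; for subset sizes 5/10/20 a LASSO
  regularization path (glmnet) is searched so exactly that many features
  survive (ties by coefficient magnitude, then schema order), followed by
  an unregularized refit.
* **NN** — one hidden layer of 70 ReLU units trained with Adam at learning
  rate 0.001, L2 penalty $10^{-4}$, batch size 200 (the conventional
  reading of that hyperparameter triple); greedy forward selection by
  cross-validated AUROC for subsets. Training is fully seeded and
  deterministic.

Cross-validation is 5-fold *by unique path* — conformation-level splitting
would leak near-duplicate frames across folds and inflate metrics.
Features are z-scored from training folds only. The decision threshold for
"reactive-like" is 0.5. Weighted rows and duplicated rows give identical
LR fits, which the tests assert.

What passing tests show — and what they do not: the surrogate plants a
single dominant slow coordinate whose committor the classifiers can
recover nearly perfectly (CV AUROC ≈ 0.98 on the mimic). Real active-site
data have many coupled, partially redundant coordinates and far longer
prereaction timescales; surrogate results certify the pipeline's
statistical machinery (weighting, fold hygiene, selection, calibration),
not classifier performance on any real enzyme.

# Design and screening

The multistate objective is
$f(s) = \sum_{i=1}^{N_R} E_{R,i}(s) - \sum_{i=1}^{N_{NR}} E_{NR,i}(s)$
over representative reactive-like and nonreactive-like structures
(default three each, chosen as the top frames by combined LR/NN confidence
within the truly-labeled pools; ties break by path id then frame index).
Scores are reported relative to the wild type, which is exactly zero by
construction. Stability requires the reactive-structure energies to be no
more than 5 kcal/mol less stable than wild type — applied to the *sum* by
default, mirroring the objective's sum; a per-structure variant is
available since the prose reading is ambiguous. The search returns every
stability-feasible sequence within 20 kcal/mol of the best feasible
objective, by exhaustive enumeration (vectorized over the toy effect
tables) or by depth-first branch and bound with an admissible bound from
per-site and per-pair minima; the two return identical result sets, which
the acceptance suite verifies on a 65,536-sequence space.

Screening a candidate runs equilibrium reactant-well dynamics (full-scale
protocol 30 × 400 ps; surrogate default 3 × 8 ps), classifies thinned
frames with both models, normalizes the reactive-like fractions by the
reference variant, and estimates the screening-mode barrier by a rapid
umbrella/WHAM pass; a failed PMF yields a null barrier with the reason
string. Priority tiers: (1) favourable objective *and* increased
population under both models *and* barrier at or below reference; (2) any
two; (3) the rest; stable-sorted by objective within tier.

# Statistics

Variant comparisons use a one-sided Mann--Whitney U test (alternative: the
mutant value is larger), exact for small untied samples and tie-corrected
normal otherwise, with Benjamini--Hochberg FDR control at $\alpha=0.05$
(boundary `<=`). A two-group gate runs Shapiro--Wilk normality and F-test
variance checks at 0.05 and dispatches an equal-variance t-test or the
Mann--Whitney test; zero-variance samples go directly to Mann--Whitney.
The underlying tests are `stats::wilcox.test`, `t.test`, `shapiro.test`,
`var.test` and `p.adjust`; the test suite checks them against independent
enumeration and brute-force definitions. (The protocol prose appears to
transpose the roles of the F-test and Shapiro--Wilk; the conventional
assignment is implemented.)

# Numerical choices and problem sizes

* WHAM tolerance $10^{-7}$ kcal/mol on window free energies, iteration cap
  $10^5$; conditional-probability estimates floor at $0.5/N$ (half count)
  so a finite sample with zero crossings never zeroes the assembled rate.
* Bottleneck ties break toward smaller $\lambda$; boundary $\lambda$
  exactly at a basin threshold is "neither".
* The acceptance suite runs at surrogate sizes chosen so the whole test
  suite completes in a few minutes on one core: 3 × 3 × 12 ns brute-force
  runs and 3 TIS replicates (10 interfaces × 1000 counted moves) for the
  rate cross-check; 12 TIS replicates over 5 independent seed paths per
  variant (2500 moves per ensemble) for the mutant-versus-wild-type
  comparison, with the harvested seed paths cycled across the interface
  ensembles — with a single seed path per replicate the per-interface
  estimation errors are correlated through the seed's slow gate
  coordinate, making replicate estimates heavy-tailed and the rank test
  underpowered.
* 95% confidence intervals over 3 replicates use Student-t critical
  values.

# Known limitations

* Path-space Monte Carlo mixes slowly along environment coordinates whose
  relaxation outlives a path; the package mitigates this with harvested
  independent seeds and a fast gate, and reports acceptance rates and
  multiplicities for diagnosis, but does not implement replica-exchange
  TIS.
* The surrogate's classifier task is easier than real trajectory data;
  see above.
* The design search's branch-and-bound requires the structured effect
  tables; arbitrary callable energy models enumerate exhaustively.
* Trajectory storage is RDS-backed rather than a chunked scientific
  binary format; lambda series export as plain text.
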