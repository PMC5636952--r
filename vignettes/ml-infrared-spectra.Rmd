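---
title: "Machine-learned potentials and infrared spectra from molecular dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Machine-learned potentials and infrared spectra from molecular dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nnpir)
```

## The problem

Infrared spectra computed from molecular dynamics capture anharmonicity,
band broadening and dynamical effects (e.g. proton transfer) that static
normal-mode analyses miss: the IR intensity is obtained as the Fourier
transform of the time autocorrelation of the dipole-moment derivative,

$$ I(\omega) \propto \int \langle \dot\mu(t)\cdot\dot\mu(t+\tau)\rangle\,
   e^{-i\omega\tau}\, d\tau . $$

Driving such simulations with an electronic-structure method is expensive:
tens of thousands of energy/force evaluations per spectrum. `nnpir`
implements the machine-learning shortcut: learn the potential energy surface
(and the dipole surface) from a small number of reference calculations, then
run the long dynamics on the learned models. The package provides every
stage — descriptors, potentials, training, committees, active learning,
fragmentation, dynamics and spectra — together with analytic surrogate
reference potentials, so the entire pipeline runs and is testable at desk
scale without any quantum-chemistry code.

## Model components

**Descriptors.** Each atom's chemical environment inside a cutoff radius
(default 4.0 Å) is encoded by atom-centered symmetry functions: radial
Gaussian shells $\sum_j e^{-\eta (r_{ij}-r_s)^2} f_c(r_{ij})$ per neighbor
element and angular three-body functions
$2^{1-\zeta}\sum_{j<k}(1+\lambda\cos\theta_{ijk})^\zeta
e^{-\eta(r_{ij}^2+r_{ik}^2+r_{jk}^2)} f_c f_c f_c$ per neighbor-element
pair, with the cosine cutoff $f_c(r) = \tfrac12(\cos(\pi r/r_c)+1)$. These
are invariant under rotation, translation and same-element permutation, and
their analytic jacobians are propagated through everything downstream. The
default parameter grid (radial $\eta \in \{0, 0.04, 0.1, 0.3, 1.0\}$ Å$^{-2}$;
angular $\eta \in \{10^{-4}, 0.01\}$, $\zeta \in \{1,4\}$,
$\lambda = \pm 1$) is a conventional log-spaced choice; tests and toy
studies often use reduced sets (e.g. radial-only for diatomics), which the
parameterization supports directly.

**Potential.** The molecular energy is a sum of atomic contributions, each
produced by a feed-forward network shared by all atoms of one element (tanh
hidden layers, linear output; the customary ceiling of two hidden layers of
35 nodes is the default, toy systems use much smaller nets). Forces are
analytic via the chain rule through the network input gradient and the
descriptor jacobian; the suite verifies them against finite differences to
better than $10^{-5}$ kcal/mol/Å. Descriptor components are standardized
per element over the training set, and per-element reference energies
(fitted by least squares on element counts) absorb the extensive part of
the energy, so the networks model only the interaction part.

**Training.** Energies and forces enter one cost,
$\frac1M \sum_m (\hat E_m - E_m)^2 + \frac{\eta}{3N M}\sum_{m,\alpha}
(\hat F_{\alpha m}-F_{\alpha m})^2$, minimized by an element-decoupled
extended Kalman filter: each element's parameters carry their own
covariance; every record contributes the energy plus all $3N$ force
components (scaled by $\sqrt\eta$) as measurements. The mixed second
derivative $\partial^2 E/\partial\theta\,\partial R$ needed for the force
rows is computed analytically by a forward-tangent/reverse-adjoint sweep
through the network. In the linear case the filter reduces exactly to
recursive least squares, which the suite checks against the normal
equations.

*Numerical choices.* The filter's gain depends strongly on the measurement
scale. We weight the measurement noise of every target by its training-set
standard deviation (energy residuals after removing the per-element
baseline; force components), so innovations are effectively dimensionless,
and anneal the noise from 1.0 down to $10^{-4}$ (decay 0.5 per epoch) with
initial covariance $1\cdot I$ and process noise $10^{-6}$. Larger initial
covariances or aggressive early noise make the first updates so large that
the tanh units saturate and force learning stalls; we observed exactly this
failure mode and chose the conservative schedule. All of these are exposed
in `training_config()`.

**Dipoles and charges.** A second set of elemental networks outputs atomic
partial charges $q_i$; the molecular dipole is
$\mu = \sum_i q_i (r_i - r_{\rm com})$ (reported in Debye, 1 e·Å =
4.80320 D) and the total charge is $Q = \sum_i q_i$. Training uses *only*
molecular observables — the reference dipole vector and total charge — with
cost $(\tilde Q - Q_m)^2 + \sum_l (\tilde\mu_l - \mu_{lm})^2$ (charge term
in e², dipole term in (e·Å)², weighted 1:1 since no physical scale prefers
either). The charges are therefore a statistical partitioning scheme
inferred indirectly. The same Kalman machinery trains this model (four
measurements per record); an Adam-style fallback is provided. On data
generated from fixed point charges the generating charges are identifiable
and the tests require recovery to 0.02 e.

**Ensembles and adaptive sampling.** A committee of $J$ potentials differing
in initialization predicts by arithmetic averaging; its disagreement — the
population (1/J) standard deviation of member energies — flags
extrapolation. (Whether the spread is normalized by $J$ or $J-1$, or per
atom, is a convention; we use 1/J and offer a per-atom variant plus a
force-based measure for fragment selection.) Adaptive sampling runs
ensemble MD until the disagreement of a visited structure exceeds a
threshold, labels *that* structure with the reference calculator, retrains
(warm-starting the Kalman state by default), and restarts the dynamics from
the problematic conformation; the loop ends when a full run stays below
threshold or the reference budget is spent. An "upscaling" step relabels
the accumulated geometries with a higher-level reference (independently per
configuration, so failures are collected rather than fatal) and retrains at
the new level.

**Fragmentation.** Because the energy is a sum of local atomic terms, a
macromolecule can be labeled through small fragments: every atom becomes the
center of one fragment holding all atoms within a cutoff (default 4.0 Å);
severed single bonds from heavy atoms are capped by hydrogens along the
original bond vector at standard X–H lengths (C–H 1.09, N–H 1.01, O–H
0.96 Å); if the free valency sits on a retained hydrogen, belongs to a
double bond, or two caps would approach within 0.9 Å, the missing heavy atom
is included instead and the rules re-applied until stable. Retained
coordinates are copied bitwise; equivalent fragments are deduplicated by
element multiset and sorted distance profile.

**Dynamics and spectra.** Velocity Verlet integrates the equations of
motion; the Langevin thermostat uses the BAOAB splitting (friction default
0.01 fs$^{-1}$, gentle enough not to broaden bands unduly; it reduces
exactly to NVE velocity Verlet at zero friction), and a Berendsen option
exists. The default timestep is 0.5 fs and the default sampling temperature
500 K. Dipoles recorded along the trajectory are differentiated by central
differences (a charge-velocity chain-rule variant is available), the vector
autocorrelation is computed by FFT up to half the trajectory length, a Hann
lag window controls leakage, and the zero-padded transform (factor 4) is
reported on a cm$^{-1}$ axis, normalized to unit maximum. The default
intensity is the transform magnitude, which is non-negative by
construction; the windowed real part can be selected instead. A
mass-weighted finite-difference normal-mode analysis with static
$|\partial\mu/\partial Q_k|^2$ intensities provides the harmonic
cross-check for MD peak positions.

## The surrogate reference and what tests do (not) show

The surrogate calculators (harmonic/Morse bonds, harmonic angles, cosine
torsions, optional Lennard-Jones, fixed or bond-increment point charges)
stand in for the electronic-structure reference. They are exact, cheap,
and expose a declared interaction range, so the locality assumptions behind
fragmentation can be asserted rather than hoped for. They emulate thermal
sampling of bonded molecules near equilibrium; they do not emulate
electronic effects (polarization, charge transfer, bond breaking beyond the
Morse form) — passing tests therefore validate the *pipeline machinery*
(descriptors, derivatives, filters, integrators, transforms) and the
method's internal consistency, not chemical accuracy on real systems, which
is always limited by the reference method feeding the models.

Problem sizes used by the suite and the acceptance script are deliberately
small — a diatomic for surface recovery (200 reference points), a triatomic
for dipole recovery (120 points), octane fragments (a few hundred records)
for the reconstruction experiment — chosen so a complete run stays in the
minutes range while still exercising every code path at meaningful
accuracy.

## Design choices in the open questions

* **Descriptor cutoff in the fragmentation experiment.** Fragments are cut
  at 4.0 Å, but the descriptor cutoff in the fragment-training experiment is
  3.2 Å. With the descriptor sphere strictly inside the fragment sphere
  (minus the cap-placement margin), every parent atom's environment appears
  *exactly* in the fragment centered on it, so whole-chain reconstruction
  tests the fragmentation logic rather than cap artifacts. With equal
  cutoffs (the production default) cap hydrogens intrude into the central
  atom's descriptor sphere and add a small systematic error — visible in our
  experiments as a few-times-larger whole-chain residual.
* **Uncertainty definition.** Population standard deviation of member
  energies; zero exactly on unanimity; invariant under adding a constant to
  every member.
* **Dipole optimizer.** The element-decoupled Kalman filter, reusing the
  potential's machinery on the four moment measurements; Adam fallback kept
  for robustness on poorly conditioned charge problems.
* **Degenerate inputs.** Coincident atoms abort featurization; non-finite
  forces abort dynamics with a partial trajectory; covariance blocks losing
  positive definiteness are reset and counted; training aborts to the last
  good checkpoint on non-finite parameters.

## Known limitations

No periodic boundary conditions, no long-range electrostatics in the
potential, no constraint algorithms or multiple time stepping, classical
nuclei only (no quantum corrections are applied to the spectra; a hook
exists), and no interfaces to real electronic-structure codes — the
`ReferenceCalculator` contract (`calc_evaluate()`) is the extension point.

## A minimal run

```{r example, eval = FALSE}
sys <- surrogate_system("morse_diatomic")
ds  <- generate_dataset(sys$calculator, sys$config, 200,
                        temperature = 500, seed = 11)
params <- descriptor_params(c("C", "O"), cutoff = 4,
                            angular_eta = numeric(0))
fit <- train_hdnnp(hdnnp(params, hidden = c(10, 10), seed = 5), ds,
                   training_config(eta = 1, epochs = 12,
                                   validation_fraction = 0.15, seed = 7))
mc <- md_config(timestep = 0.5, temperature = 400,
                thermostat = "langevin", friction = 0.005,
                n_steps = 16000, equilibration_steps = 1000, seed = 13)
traj <- run_md(fit$model, sys$config, mc, dipole_calc = sys$calculator)
sp <- ir_spectrum(traj)
spectrum_peak(sp, c(500, 3000))
```
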