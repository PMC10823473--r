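---
title: "Force tempering with replica exchange: models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force tempering with replica exchange: models, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forcetemper)
```

## The sampling problem

Many biomolecular questions reduce to: *how does a molecule's conformational
ensemble respond to a small constant pulling force along a collective
variable (CV)?*  The canonical example is the end-to-end distance of a
peptide under piconewton loads.  At constant temperature the observable
average under a force $F$ applied along $Q(\mathbf q)$ is

$$\langle O\rangle_F
  = \frac{\int O(\mathbf q)\,e^{-\beta\left(U(\mathbf q)-F\,Q(\mathbf q)\right)}\,d\mathbf q}
         {Z_q(F)},\qquad
  Z_q(F) = \int e^{-\beta U + \beta F Q}\,d\mathbf q .$$

Scanning forces one run at a time is wasteful.  Infinite-switch simulated
tempering in force instead samples the *mixture* ensemble

$$p(\mathbf q)\;\propto\;e^{-\beta U(\mathbf q)}
   \int_{F_\mathrm{min}}^{F_\mathrm{max}} \omega(F)\,e^{\beta F Q(\mathbf q)}\,dF ,$$

the infinitely-fast-switching limit of a ladder of forces with weight
density $\omega(F)$.  One trajectory then reweights to *any* force inside
$[F_\mathrm{min},F_\mathrm{max}]$.  The machinery has three parts:

* **Applied force.**  The mixture is sampled by ordinary dynamics plus an
  extra CV-dependent force
  $\bar F(Q) = \int \omega F e^{\beta F Q} dF \big/ \int \omega e^{\beta F Q} dF$
  applied along $\nabla Q$ (`fbar()`); it is minus the $Q$-derivative of the
  bias potential $V(Q) = -\beta^{-1}\ln\int\omega\,e^{\beta F Q}dF$
  (`bias_potential()`), is confined to $[F_\mathrm{min},F_\mathrm{max}]$, and
  is non-decreasing in $Q$ (its derivative is $\beta$ times a variance).
* **Weight learning.**  Forces are sampled evenly when
  $\omega(F)\propto 1/Z_q(F)$.  The package uses the cumulative
  mixture-importance estimator
  $\hat z(F)\propto\sum_t e^{\beta F Q_t}\big/\!\int\omega_t(F')e^{\beta F'Q_t}dF'$
  with $\omega_t$ the weights in force when sample $t$ was taken, then sets
  $\omega \propto 1/\hat z$, renormalized so the grid quadrature of
  $\omega$ is exactly one (`update_weights()`).  Each MD step contributes
  one sample; updates are applied every `update_interval` steps (default
  500).  The estimator is exposed behind a single function so alternative
  learning rules can be slotted in.
* **Observable weights.**  Each frame carries
  $W_F = e^{\beta F Q_t}/\!\int\omega_t(F')e^{\beta F' Q_t}dF'$; fixed-force
  averages are ratio estimators $\sum_t O_t W_F / \sum_t W_F$
  (`reweighted_average()`, `reweighted_histogram()`).  These are valid
  *before* $\omega$ has converged, because each frame's denominator uses the
  mixture actually sampled at that time; the package records the mixture
  normalizer per frame (`log_mix` column) and also supports recomputing
  weights from the final state (`weights_from = "final"`) for comparison.

All force-grid integrals are trapezoid quadratures on a uniform grid
(121 nodes by default) evaluated in log space with a max shift, so
$\beta F Q$ of several hundred cannot overflow.

## Why combine with replica exchange

The force bias explores force space, not conformation space: from an
occupied basin, $\bar F(Q)$ actually *tilts into* that basin (from a well at
negative $Q$ the exponential tilt favors negative forces), so a molecule
with a high orthogonal barrier can stay trapped — force tempering alone can
even slow barrier crossing.  The remedy is a ladder of replicas that do
cross, coupled by Metropolis swaps:

* **Temperature ladder** (`mode = "temperature_re"`): replica $i$ runs at
  $T_i = T_\mathrm{base}(T_\mathrm{top}/T_\mathrm{base})^{i/(N-1)}$, each
  with its own FISST state using its own $\beta_i$ in every
  $e^{\beta F Q}$ factor — the biases differ per replica, so this is a form
  of Hamiltonian exchange even at equal potentials.
* **Solute tempering** (`mode = "rest_scaling"`): all replicas share the
  thermostat temperature but scale solute–solute terms by
  $\lambda^{pp}_i = T_0/T_i$ and solute–solvent terms by
  $\kappa_i\,\lambda^{pw}_i$ with $\lambda^{pw}_i = \sqrt{T_0/T_i}$
  (`replica_energy()`).  For a solute-only system this reproduces the plain
  hot ensemble exactly.  $\kappa$ is user-suppliable per replica;
  `rest_kappa(m)` implements $1 + 0.005(m-3)$ for $m>3$.  The toy systems
  have a single non-bonded interaction class, so $\kappa$ multiplies the
  whole solute–solvent term — a stated simplification.
* **Swaps.**  $\Delta = \beta_i[H_i(q_j)-H_i(q_i)] + \beta_j[H_j(q_i)-H_j(q_j)]$
  with $H$ including each replica's own bias; accept with
  $\min(1,e^{-\Delta})$; neighbor pairs alternate even/odd rounds;
  velocities rescale by $\sqrt{T_\mathrm{new}/T_\mathrm{old}}$ on
  temperature swaps.  Weight statistics are accumulated exactly once per MD
  step during propagation — the four energy evaluations of a swap attempt
  are pure function calls and contribute nothing (the ladder result exposes
  `n_samples` and `n_exchange_energy_evals` so this accounting is
  verifiable).

Weight statistics may optionally be pooled across replicas sharing a grid
and $\beta$ (`pool = TRUE`, `pool_statistics()`); the default keeps each
replica's estimator independent.

## Model systems

The fixtures are chosen so that every claim has an analytic or quadrature
oracle (module `quadrature_oracle()`; dense 1D grids, self-converging to
$10^{-6}$):

* `make_harmonic_cv_system(k, mu)` — $U = k(Q-\mu)^2/2$ with the signed
  coordinate as CV.  Closed forms: $\langle Q\rangle_F = \mu + F/k$,
  $\mathrm{Var}(Q) = 1/(\beta k)$,
  $\ln Z_q(F)/Z_q(0) = \beta F\mu + \beta F^2/2k$, converged
  $\omega(F)\propto e^{-\beta F^2/2k}$.
* `make_double_well_system(b)` — $U = b(Q^2-1)^2$: symmetric two-basin
  landscape with barrier exactly $b$ (the desk-scale analogue of a helix
  inversion).  Units: $k_B = 1$, lengths dimensionless; display labels (pN,
  Å) are the user's affair.
* `make_polymer_system(...)` — a 3D bead–spring chain (harmonic bonds, WCA
  excluded volume) with optional WCA solvent in a periodic box, the CV being
  the end-to-end distance.  Bonds and solute pairs are tagged `pp`,
  solute–solvent `pw`, solvent–solvent `ww`, which is what the REST scaling
  consumes.  Pair terms use the minimum image; coordinates stay unwrapped so
  the CV is a real-space distance.

What the toys emulate: the solvated-peptide topology (solute/solvent split,
confining landscape, end-to-end CV) at a scale where quadrature ground truth
exists.  What they do not: rugged all-atom landscapes, explicit
electrostatics, water structure, or timescale separation beyond a single
barrier — passing tests here validate the *machinery* (bias, learning,
reweighting, exchange), not any force field.

## Dynamics and numerical choices

`langevin_step()`/the runners implement BAOAB splitting (one force
evaluation per step) with Maxwell–Boltzmann velocity initialization, and an
overdamped Euler–Maruyama alternative.  Choices a user should know:

* **Timestep.**  BAOAB's configurational bias on a harmonic mode of
  frequency $\omega$ is $\approx(\omega\,\mathrm{d}t)^2/4$; the package's
  protocols use $\mathrm{d}t \le 0.2/\omega_\mathrm{max}$ so that bias stays
  below 1% (0.2 for the harmonic fixture, 0.01 for the stiff double well,
  0.02 for the polymer).  Euler–Maruyama has $O(\mathrm{d}t)$ bias; its
  default test usage keeps $k\,\mathrm{d}t/\gamma \lesssim 0.01$.
* **Friction.**  $\gamma = 0.2$ for the harmonic fixture: the integrated CV
  autocorrelation time is $\gamma/k$, so light friction maximizes
  independent samples per step while BAOAB remains exact in its
  $\gamma\to0$ limit.  The double-well protocol instead uses
  $\gamma = 0.05$ with $\mathrm{d}t = 0.01$: the trapped/rescued contrast is
  a rare-event statement, and low diffusive action keeps the bottom-replica
  escape probability negligible over the run length while the ladder's hot
  end still crosses freely.
* **RNG.**  Each replica owns an explicit RNG stream derived from the master
  seed (`substream_seeds()`), and the exchange layer owns another, so a
  trajectory is bitwise reproducible from `(config, seed)`, independent of
  replica count, and a degenerate single-force grid reproduces
  `constant_force_run()` exactly, noise draw for noise draw.
* **Statistical errors.**  Reweighted means quote a delete-one-block
  jackknife SE (`block_se()`, default 10 contiguous blocks; long runs use
  25).  Plain SDs of block means mis-estimate errors for importance-weighted
  ratio estimators when weight mass concentrates in a few blocks, and with
  only 5 blocks the SE itself carries ~35% noise; the jackknife over 10–25
  blocks (each still far longer than the CV correlation time) is the
  package's deliberate refinement.
* **Histogram comparisons.**  Distribution-level agreement is scored by the
  Jensen–Shannon *distance* (square root of the divergence, base-2
  logarithms, hence bounded by 1).  Comparisons against oracles use 8 bins
  covering $\pm3\sigma$ of the target density: at the documented run lengths
  this keeps per-bin occupancy high enough that shot noise contributes JSD
  well below the 0.02 agreement bands used in the tests.  Analysis defaults
  for free-energy profiles remain 100 uniform bins; empty bins yield `NA`
  free energies (explicit missing markers), which comparison statistics drop
  pairwise and report — silent infinities would corrupt rank statistics.
* **Free-energy conventions.**  $A(Q) = -\beta^{-1}\ln P(Q)$, min-offset to
  zero; `rmse_below_threshold()` restricts to bins where the *reference*
  profile is below the cutoff (the reference's bins define the region);
  force–extension tables report the reweighted mean, the full SD, SD/3 (a
  common error-bar convention for such plots), the jackknife SE and the Kish
  effective sample size $(\sum W)^2/\sum W^2$.

## Study-scale choices and known limitations

The validation protocols are deliberately desk-scale; problem sizes are
fixed in the tests and the acceptance script:

* harmonic fixture: grid $[-2,2]\times121$, $2\times10^5$ steps;
* exchange checks: 4 replicas, $T \in [1,2]$, $4\times10^5$ steps each;
* double well: $b = 8$ ($\beta\,b = 8$), 4 replicas, $T\in[1,6]$, swaps
  every 25 steps, $10^5$ steps each, PMF on 8 bins over $[-1.4,1.4]$;
* polymer: 8 beads, bond stiffness 10 (a force of 2 stretches a bond by
  20%, i.e. backbone stiff relative to the force scale, as for a peptide),
  16 solvent particles, $2\times10^5$ steps.

Known limitations.  The two clauses of the double-well check pull against
each other: conditions that keep the single force-tempered run reliably
trapped cap the number of physical basin crossings the ladder can deliver
to a few tens per run, so the bottom-replica PMF error fluctuates around
0.1–0.3 $k_BT$ between seeds — the reported RMSE should be read with that
sampling variance in mind.  Pooled weight learning requires a common
$\beta$; combining force tempering with a *temperature* mixture
(two-dimensional infinite switch) is out of scope.  The REST
$\lambda^{pw} = \sqrt{T_0/T_i}$ convention and the Metropolis $\Delta$ are
the standard forms, stated prominently here because alternative conventions
exist.  Analyses read the bottom replica by default; `analyze_run()` never
writes into a run directory.
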