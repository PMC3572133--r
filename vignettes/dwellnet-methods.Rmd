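---
title: "Dwell-time analysis on chemomechanical networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dwell-time analysis on chemomechanical networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwellnet)
```

## The model

`dwellnet` describes a two-headed processive motor (myosin V) as a
continuous-time Markov chain on a network of chemomechanical states. A state
is the pair of nucleotide occupancies of the trailing and leading head
(T = ATP, D = ADP, E = empty) at a filament site; sites repeat every 36 nm.
Chemical transitions (nucleotide binding and release, lumped hydrolysis)
keep the motor at its site; mechanical transitions move it by exactly one
site and swap the head roles (forward: TD at x becomes DT at x + l).

Two networks are bundled:

* **Uni-cycle** (4 states): DD -> ED -> TD -> DT -> DD, plus the backstep
  DT -> TD and the (default-zero) reverse chemistry ATP dissociation and
  phosphate binding. All transitions belong to the chemomechanical cycle F.
* **Branched** (6 states): the uni-cycle plus ADP release from the leading
  head (DD -> DE, ED -> EE at rate `adp_release_trail / gating_g`),
  trailing-head release DE -> EE, ADP rebinding EE -> ED, EE -> DE,
  DE -> DD, and two purely mechanical slip steps EE -> EE at site offsets
  +1 / -1 (cycle M). The leading-head chemistry forms the enzymatic cycle E.

The network topology is data-driven: both networks ship as JSON files under
`inst/extdata/` and arbitrary topologies can be supplied through
`read_network()`. The branched file is a reconstruction: the published
account of this network names the states and the leading-head release and
slip transitions explicitly, but not every edge of the enzymatic cycle, so
the bundled file contains exactly the named transitions and nothing else.
The consequences of that choice are discussed under *Limitations*.

### Rate laws

Effective rates follow mass action and nonequilibrium thermodynamics:

* binding: `kappa * [X]` with second-order constants per uM per s;
* release: `kappa`;
* mechanical: `kappa * exp(-theta F l / kBT)` forward and
  `kappa * exp((1 - theta) F l / kBT)` backward.

The forward/backward pair satisfies the balance ratio
`exp(-F l / kBT)` for any load-sharing factor `theta`; `theta` defaults to
0.5 (symmetric sharing) because no published value pins it down, and it is
exposed in `force_model()`. Positive force resists forward motion; assisting
loads are negative. `kBT` defaults to 4.114 pN nm (298 K).

Chemical rates are load-independent by default. An optional `"threshold"`
policy suppresses only the two nucleotide *binding* rates (ATP and ADP)
above a threshold force by `exp(-scale (F - thr) l / kBT)` — release rates
never acquire load dependence. Defaults `thr = 2` pN, `scale = 1` are this
package's choices: they gate the suppression at roughly the stall force and
switch the branched network into its ratcheting regime at superstall, which
is what the policy exists to express.

### Default rate constants

`rate_constants()` defaults are the experimentally determined uni-cycle
values: ATP binding 0.9 /(uM s), ADP binding 4.5 /(uM s), trailing-head ADP
release 12 /s, lumped hydrolysis + P release 250 /s, bare forward step
7000 /s, bare backstep 0.65 /s; ATP dissociation and P binding default to 0
(in vitro conditions suppress the reverse cycle). The gating ratio
`gating_g >= 1` divides the leading-head release rate; `g = 1` means
symmetric heads.

The slip rates are not published for this parameterization. The packaged
default sets `slip_fwd = slip_bwd` (a purely mechanical slip transduces no
chemical free energy, so it cannot be biased at zero load) with magnitude
5e-10 /s chosen so that the backward slip rate under the shared Boltzmann
factor reaches ~1.5 /s at 5 pN — the order of the observed superstall
ratcheting step rate. This single anchor makes slips negligible below stall
and dominant above it without any extra force parameter.

## Dwell times as first-passage times

A dwell starts immediately after a mechanical step and ends at the next
one. The chain for one site keeps all chemical states as transients and
terminates every mechanical transition in an absorbing channel that
remembers its step direction and the state the motor lands in (DT after the
main forward step, TD after a backstep, EE after a slip). With transient
generator `Q` (columns are sources) and channel rate matrix `A`:

* absorption probabilities by first-step analysis: `Pi = A (-Q)^{-1}`;
* conditional densities as exponential mixtures over the spectrum of `-Q`;
* mean dwell by linear solve, `sum((-Q)^{-1} p0)`.

The forward, backward and total step densities mix the conditional
densities over initial states. The mixture weights are the stationary law
of the *embedded landing chain*: the sequence of post-step landing states
is itself a Markov chain with kernel assembled from the channel absorption
probabilities, and its stationary distribution is the long-run frequency
with which dwells start in each landing state. This is the unique weighting
consistent with dwell statistics harvested from one long trajectory, and it
reduces to the two-state (post-forward / post-backward) step chain for the
uni-cycle. The identity `v = l (p_f - p_b) / <tau>`, with step-type
frequencies and mean dwell from this construction and `v` from the periodic
steady state, is asserted to a relative 1e-6 across random conditions in the
tests (and is observed near machine precision) — the package's strongest
cross-module check.

## Periodic steady state

For velocities and fluxes the network is repeated along the filament, so
mechanical transitions wrap onto the same state set. The stationary
distribution is computed by GTH (Grassmann–Taksar–Heyman) elimination on
the closed communicating class of the rate digraph. GTH uses only additions
and multiplications of non-negative numbers, so it remains accurate when
Boltzmann factors spread the rates over tens of orders of magnitude — an
SVD null-space solve demonstrably cannot distinguish a genuine slow rate
from noise once the rate range exceeds ~1e10. More than one closed class
(possible when concentrations are exactly zero) is reported as an error
naming the classes. Velocity is step size times the net mechanical flux;
the flux divergence at every state is checked to < 1e-12 (relative) in the
tests.

`cycle_occupation()` apportions stationary probability among the tagged
cycles: states exclusive to one cycle contribute wholly; shared states are
split in proportion to outgoing flux through each cycle's transitions, a
transition with several tags splitting equally. This flux-proportional
apportioning is one defensible reading of cycle "occupation" and is
isolated in a single function.

## Stochastic simulation and synthetic data

`simulate_motor()` is a direct-method Gillespie simulation (single uniform
draw for the waiting time, one for the transition), justified by the small
state count; the inner loop is compiled and driven by R's RNG, so a seed
reproduces a trajectory bit-for-bit. For long dwell-collection runs the
`record = "mechanical"` mode stores only stepping events, keeping memory
flat when chemical events outnumber steps by orders of magnitude (at 400 uM
ADP a single dwell can contain thousands of binding/release events).

`generate_synthetic()` packages simulated dwells into the currency of
single-molecule experiments: an area-normalized histogram at a fixed bin
width, with optional detection dead time (dwells below it are discarded
before renormalization), plus the raw classified sample and the complete
generating parameters. The generator emulates finite sample size,
binning, and dead time. It does **not** emulate bead-position noise,
missed-event step detection, trap feedback dynamics, or substep structure —
so passing tests show that the estimators recover parameters from data
generated by the model family itself, not that the model family fits any
particular experiment.

`make_fixture_suite()` fixes six conditions: saturating ATP (1000 uM, trace
0.1 uM ADP), saturating ATP + 400 uM ADP, limiting ATP at 10 and 2 uM, a
substall load (1 pN) and a superstall load (5 pN under the threshold
policy), all from the branched network with `g = 10`, N = 2000 dwells each.
N = 2000 is large enough for stable RMSD scans and small enough for
desk-scale tests; trace ADP (0.1 uM) reflects nominally ADP-free
experimental buffers.

## The gating estimator

`fit_gating()` scans a gating grid (default 1, 2, 5, 10, 20, 50). For each
candidate the branched model is simulated at the observed condition with
the *same number of dwells as the observation* (so the objective carries
matched sampling noise), binned onto the observed histogram's edges (no
silent rebinning; model dwells beyond the last edge count in the
normalization so lost tail mass is visible), and scored by

    RMSD = sqrt( mean_over_bins (rho_obs - rho_model)^2 ).

The RMSD falls while gating is too weak — leading-head ADP release then
competes with rate-limiting ATP binding and broadens the model distribution
— and saturates once that competition is lost. The reported estimate is the
*saturation onset*: plateau = mean RMSD over the upper half of the grid,
and `g_hat` is the smallest grid point within one plateau standard
deviation of it. Because the curve is flat beyond the onset by
construction, `g_hat` is a lower bound, not a point estimate. The published
analysis defines the gating ratio verbally as leading/trailing yet
describes the RMSD as decreasing with increasing ratio; this package
standardizes on `g = trailing/leading >= 1`, so that gating strengthens as
`g` grows, and documents the inversion here rather than guessing silently.

All grid points are simulated with one common seed (common random numbers):
the scan is then a deterministic function of (observation, seed), and grid
ordering reflects the systematic effect of the parameter rather than
seed-to-seed noise. `fit_atp_binding()` applies the same objective to the
ATP binding constant at fixed gating, over a log-spaced grid (default 25
points on [0.3, 3] /(uM s), ~10 % spacing — finer than the recovery
tolerance of interest), returning the RMSD argmin.

## Numerical choices

* Dwell densities use the spectral decomposition of `Q` (4–6 states);
  if the eigenvector basis is ill-conditioned (reciprocal condition below
  1e-12), evaluation falls back to a `Matrix::expm()` propagator and the
  object reports `method = "propagator"`. Complex eigenvalue pairs are
  handled in complex arithmetic and flagged; densities are real.
* Linear solves are dense LU (`solve()`); normalization of every density is
  asserted to 1e-6 in tests, absorption-probability sums to 1e-12.
* Exported density grids are cubically graded towards t = 0 so trapezoidal
  integration of the file resolves fast decay components (unit area to
  1e-6 with the default 4000 points).
* Histogram bins start at 0 and are uniform by construction; non-uniform
  or non-contiguous bins are rejected on read.
* `stall_force()` brackets a sign change and bisects to 1e-3 pN; absence of
  a sign change returns `NA` with a diagnostic rather than a spurious root
  (the uni-cycle with blocked reverse chemistry is strictly positive at
  every load, so it genuinely has no stall force).

## Problem sizes in the shipped tests

Structural and spectral checks are exact and instantaneous. The
solver–simulator comparisons use 1e4–1e5 dwells (Kolmogorov–Smirnov
distance below 0.01 at 1e5); conservation and renewal-identity sweeps use
20 random conditions on both networks; gating recovery runs 5 independent
2000-dwell observations against 6-point scans; the ATP co-fit uses the same
observations with a 25-point grid. The full suite runs in well under a
minute on one core.

## Limitations

* **Branched wiring is a reconstruction.** With only the named transitions,
  the doubly-empty EE state can escape chemically only by ADP rebinding, so
  at trace ADP it is long-lived. Consequently (i) branched and uni-cycle
  dwell distributions do not coincide at saturating ATP (the published
  statement that they agree presumably relies on additional pathways or
  rates not recoverable from the text), (ii) the E cycle carries a large
  occupation weight at zero load, and (iii) adding ADP can *shorten*
  branched dwells by rescuing EE. Gating recovery is unaffected — it is
  self-consistent within the model family — but absolute branched
  dwell shapes at saturating ATP should not be compared to uni-cycle ones.
* The load dependence of chemical rates (threshold policy) and the slip
  magnitude are this package's calibrations, not published values; near
  stall (roughly 1.5–2.5 pN) the single-theta parameterization is known to
  be insufficient and dwell distributions there should not be interpreted
  quantitatively.
* No substep structure, power-stroke kinetics, filament detachment, or
  bead/trap dynamics are modelled; dwells are read from the model's
  mechanical transitions, not reconstructed from noisy position signals.
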