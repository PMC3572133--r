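# dwellnet

Dwell-time distributions of processive molecular motors on chemomechanical
networks, built around the two-headed motor myosin V.

## The problem

A myosin V dimer walks hand-over-hand along actin in 36-nm steps, powered by
ATP hydrolysis. In single-molecule experiments the observable between steps
is the **dwell time** — the sojourn at a fixed filament position between two
successive mechanical steps — and its distribution is distinctly
non-exponential, encoding the motor's chemical kinetics. `dwellnet` models
the motor as a continuous-time Markov chain on a small network of
chemomechanical states, where each state records the nucleotide occupancy of
the trailing and leading head (T = ATP, D = ADP, E = empty):

* the **uni-cycle network** — four states per filament site,
  DD → ED → TD → DT → DD: trailing-head ADP release, ATP binding, the 36-nm
  forward step that swaps head roles, and hydrolysis + phosphate release —
  valid below the stall force;
* the **branched (three-cycle) network** — six states, adding ADP release
  from the leading head (the **gating** pathway), the doubly-empty state EE,
  and purely mechanical slip steps that carry superstall ratcheting.

Dwell times are first-passage times: the network at one site is terminated
by absorbing states at the neighbouring sites, so every dwell-time density
is phase-type — a mixture of exponentials whose decay rates are the
eigenvalues of the negated transient generator,

    rho(t | i -> a) = d/dt P(a, t | i, 0) / pi(a | i),

with `pi(a | i)` the probability that a walk started in the post-step state
`i` is absorbed through step direction `a`. Transition rates follow mass
action in the nucleotide concentrations, and mechanical rates carry
Boltzmann load factors `exp(-theta F l / kBT)` (forward) and
`exp((1 - theta) F l / kBT)` (backward), satisfying
`omega_f / omega_b = exp(-F l / kBT)` for any load-sharing factor theta.

Head **gating** is quantified by the ratio `g` of trailing- to leading-head
ADP release rates (`g = 1`: no gating). The package estimates `g` from a
dwell-time histogram by scanning the branched model over a `g` grid and
measuring the root-mean-square deviation (RMSD) between binned densities;
the estimate is the onset of the RMSD plateau and is a *lower bound* on the
true gating ratio.

Intended users: single-molecule biophysicists and modellers who want exact
conditional dwell-time densities, force–velocity relations, stochastic
trajectories, and parameter recovery on known-ground-truth synthetic data.

## Worked example

```r
library(dwellnet)

net   <- build_unicycle()                       # Table-of-rates defaults
cond  <- condition(atp = 1000, adp = 0.1)       # saturating ATP, trace ADP
chain <- build_absorbing_chain(net, cond)

print(chain)
#> Absorbing chain ('unicycle'): 4 transient states, 2 absorption channels
#>   exit rates (1/s): DD: 12, ED: 900.45, TD: 7000, DT: 250.65

decay_spectrum(chain)
#> Decay spectrum (1/s): 11.993922, 250.65, 900.45608, 7000

sd <- step_densities(chain)
sd$p_b                                          # stationary backstep frequency
#> [1] 0.00259
print(sd$rho_total)
#> Dwell-time density [total], method = spectral
#>   4 exponential components; slowest decay rate 11.9939 1/s
#>   absorption probability pi = 1, mean = 0.0881709 s

velocity(net, cond)
#> [1] 406.2  # nm/s
```

The slowest decay rate (~12/s) is the trailing-head ADP release rate: at
saturating ATP the tail of the dwell distribution reads off ADP release
directly. The mean dwell (~88 ms) times the 36-nm step reproduces the
~406 nm/s velocity — the dwell machinery and the periodic steady state are
consistent by construction.

Gating recovery from synthetic data with known ground truth (`g = 10`):

```r
cond2 <- condition(atp = 2, adp = 0.1)          # limiting ATP: gating matters
obs   <- generate_synthetic("branched", cond = cond2, n_dwells = 2000,
                            bin_width = 0.1, seed = 42)
fit   <- fit_gating(obs$histogram, cond2, seed = 43)
print(fit)
#> Gating-parameter RMSD scan
#>   g     rmsd
#>   1 0.088232
#>   2 0.069491
#>   5 0.030202
#>  10 0.021033
#>  20 0.026939
#>  50 0.039192
#>   plateau 0.029055 +/- 0.0093 1/s; saturation onset g_hat = 5 (lower bound)
```

The RMSD falls steeply while the candidate gating is too weak to reproduce
the observed histogram and levels off once leading-head ADP release no
longer competes with ATP binding; the reported `g_hat` is the smallest `g`
compatible with the plateau.

A thin command-line wrapper over the same functions is included
(`inst/cli/dwellnet`, or `run_cli()` from R), with subcommands `dwell`,
`spectrum`, `velocity`, `fv-curve`, `simulate`, `synth` and `fit-gating`.

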