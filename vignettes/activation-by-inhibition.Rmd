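---
title: "Kinetic models of activation-by-inhibition in exosite enzymes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic models of activation-by-inhibition in exosite enzymes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exokin)
```

## The model

Many posttranslational-modification enzymes — proteases, protein kinases,
deacetylases — recognise their macromolecular substrates through an
*exosite*, a binding surface distinct and remote from the catalytic site.
Kinetically, recognition reduces to a two-step process: the substrate
first docks at the exosite, forming an *encounter complex* `SE`, which
then rearranges into the catalytically competent complex `ES` where both
sites are engaged:

```
E + S <=>[k1, k-1] SE <=>[k2, k-2] ES -->[kcat] E + P
```

Two further ingredients produce the phenomenon this package exists to
study. First, a reversible active-site inhibitor binds both the free
enzyme and the encounter complex (`E + I <=> EI`, `SE + I <=> SEI`, rates
`kon`/`koff`), and substrate can still dock at the exosite of the
inhibited enzyme (`EI + S <=> SEI`). Second, the free enzyme exchanges by
conformational selection between the substrate-accepting conformer `E`
and an alternative conformer `F` (`E <=> F`, rates `kfwd`/`kbkwd`,
equilibrium constant `Keq = kfwd/kbkwd`).

When `F` is inaccessible to both ligands (the **base** scheme), the
`E <=> F` equilibrium withholds a fraction `Keq/(1+Keq)` of the free
enzyme from the catalytic pathway. An active-site inhibitor then plays a
dual role: it sequesters `E` and `SE` (inhibition), but by pulling free
enzyme into `EI` it also drains the `F` reservoir (`F -> E -> EI`), and
`EI` re-enters turnover through the ternary complex
(`EI + S -> SEI -> SE + I`). At undersaturating substrate — where the
`E <=> F` partition, not catalysis, limits the rate — the recruitment
gain can exceed the sequestration loss and the inhibited reaction runs
*faster* than the uninhibited one: activation-by-inhibition. The package
quantifies this with the *inhibition degree*, `v(S, I) / v(S, 0)`;
values above 1 denote activation.

Site independence is assumed throughout: on- and off-rates for each
ligand are identical on every enzyme form (`k_m1_SEI`, the substrate
off-rate from the ternary complex, defaults to `k_m1` but is exposed
because the feasibility of activation hinges on it being no larger than
`koff`). The catalytic complex `ES` never binds inhibitor — its active
site is occupied by substrate.

## Scheme variants

`build_scheme()` constructs four variants that differ in what conformer
`F` can bind:

* **base** — `F` binds nothing. Activation at low `S` only.
* **f-active-open** — `F`'s active site is formed, its exosite closed:
  the inhibitor also binds `F` (`F + I <=> FI`, with the conformational
  step `EI <=> FI` mirroring `E <=> F`). A conformer-neutral inhibitor
  cannot shift the `E <=> F` partition, so no activation occurs at any
  concentration — a structural control.
* **f-exosite-open** — `F`'s exosite is open, its active site closed:
  substrate binds `F` into a *dead-end* encounter complex `SF`. The `SF`
  pool sequesters enzyme in proportion to `S`, so even saturating
  substrate cannot pull the enzyme out of the `F` state; the inhibitor
  can (via `F -> E -> EI`), and activation becomes quasi-constitutive,
  persisting at `S >> Km`.
* **two-conformer** — both conformers are catalytically active with
  identical kinetics except a 10-fold lower exosite on-rate on `F`
  (`k1_F = k1/10`, i.e. a 10-fold higher Michaelis constant on `F`);
  free and encounter forms exchange conformers. Activation survives,
  showing that a fully inactive conformer is not required — only
  conformers of differing substrate affinity in thermodynamic
  equilibrium.

Three connectivity questions were genuinely open, and the package takes
a documented position on each:

1. *Bound-form exchange direction.* Every conformational step of a
   ligand-bound pair mirrors the free-enzyme step with the E-like form
   converting forward at `kfwd` (`EI -> FI`, `SE -> SF`). The mirrored
   orientation is what makes binding of the conformer-neutral ligand
   leave the `E <=> F` partition untouched and closes every
   thermodynamic cycle with unit affinity at any `Keq`; the opposite
   orientation closes cycles only at `Keq = 1`.
2. *Dead-end `SF` in f-exosite-open.* If `SF` were allowed to rearrange
   into `SE` at the conformational rates, the `SF` pool would equilibrate
   with `SE` and the variant would show no activation at all (we verified
   this numerically: the maximum degree is exactly 1). The dead-end
   reading is the one that produces the variant's defining behaviour —
   constitutive activation at saturating substrate — so it is the
   default and only connectivity offered.
3. *Inhibitor binding in two-conformer.* If the inhibitor binds both
   conformers with equal affinity it is conformer-neutral and activation
   is provably impossible (we also confirmed this numerically on the full
   grid). The default therefore restricts inhibitor binding to the `E`
   conformer; `inhibitor_on_F = TRUE` restores the fully symmetric
   reading for sensitivity analyses.

In the two-conformer scheme the cycle `E–SE–SF–F–E` involves two
different substrate affinities, so the `SF -> SE` rate is rescaled by
`k1/k1_F` to keep the cycle affinity at 1 (`thermo_correct = FALSE`
disables the rescaling; `detailed_balance_report()` then flags the cycle
with affinity `k1/k1_F`).

## Parameters

All internal concentrations are molar and times seconds; user-facing
tables are in µM. The defaults of `default_params()` are the reference
simulation conditions:

| parameter  | default | units  | meaning |
|------------|---------|--------|---------|
| `k1`       | 1e7     | /M/s   | exosite on-rate for S (conformer E) |
| `k_m1`     | 10      | /s     | exosite off-rate from SE |
| `k2`       | 1e3     | /s     | rearrangement SE -> ES |
| `k_m2`     | 1       | /s     | reverse rearrangement |
| `kcat`     | 100     | /s     | catalysis, irreversible |
| `kon`      | 1e9     | /M/s   | inhibitor on-rate (active site) |
| `koff`     | 1e3     | /s     | inhibitor off-rate (Kd = 1 µM) |
| `kfwd`     | 1e3     | /s     | E -> F conversion |
| `kbkwd`    | 1e3     | /s     | F -> E conversion (Keq = 1) |
| `k_m1_SEI` | `k_m1`  | /s     | substrate off-rate from SEI |
| `k1_F`     | `k1/10` | /M/s   | exosite on-rate on F (two-conformer) |
| `E_total`  | 1e-10   | M      | enzyme (100 pM) |

`k2` and `k_m2` are first-order: the `SE <=> ES` step is a unimolecular
rearrangement of one complex. The reference grids span substrate
0.1–100 µM and inhibitor 0–100 µM (log-spaced, 12 points per decade),
with `E_total` four to six orders of magnitude below the ligands — the
regime in which the pseudo-first-order reduction below is essentially
exact.

## Velocity engines and numerical choices

**Steady-state engine (default).** With ligands clamped, the enzyme
forms follow a linear master equation whose generator
(`enzyme_state_matrix()`) has pseudo-first-order entries
(`k1*S`, `kon*I`, ...; catalysis enters as `ES -> E` at `kcat`). The
stationary distribution is obtained by a deterministic direct solve
(replace one balance row by the normalisation row), not an iterative
method, so grid sweeps are bit-reproducible; `v = kcat * E_total *
(occupancy of ES, plus FS in the two-conformer scheme)`. For the
uninhibited three-state chain the same reduction has the King–Altman
closed form

```
Km  = (k_m1*k_m2 + k_m1*kcat + k2*kcat) / (k1*(k2 + k_m2 + kcat))  ~ 9.17 uM
kcat_app = kcat*k2/(k2 + k_m2 + kcat)                              ~ 90.8 /s
```

against which the solver is tested to 1e-9 relative. The nominal
reference value of the Michaelis constant is 10 µM; the closed form
evaluates near 9.2 µM, and `fit_michaelis_menten()` on simulated data
reproduces the closed form, so both numbers are reported side by side
rather than reconciled.

**ODE engine (verification path).** `integrate_network()` integrates the
full mass-action system with `deSolve::lsoda` at `rtol = 1e-8`,
`atol = 1e-14` M (the absolute floor must sit well below the 100 pM
enzyme). `initial_velocity_ode()` fits the product progress curve on a
window that opens after the pre-steady-state transient and closes at 1%
substrate depletion (`depletion_max = 0.01`, standard initial-rate
practice). Two deliberate choices here:

* the transient is estimated as 10 slowest relaxation times of the
  clamped generator (from its eigenvalues), not from the smallest total
  exit rate — at 0.1 µM substrate the smallest exit rate (`k1*S` = 1/s)
  would suggest a 10 s transient, the length of the entire depletion
  window, while the true slowest relaxation rate there is ~101/s;
* the window is fitted with a quadratic in time and the derivative taken
  at the window start. A plain average slope over a window ending at 1%
  depletion measures the velocity at ~0.5% depleted substrate, an error
  of up to ~2.4e-3 relative near Km — larger than the 1e-3 agreement the
  two engines are required to show. The quadratic's linear coefficient
  removes that first-order bias.

The two engines agree to better than 1e-3 relative (typically ~1e-5)
across 50 random concentration pairs per scheme, which is the package's
main internal consistency check.

**Fitting.** `fit_mixed_inhibition()` fits
`v = Vmax*S / (Km*(1 + I/Kic) + S*(1 + I/Kiu))` with
`minpack.lm::nlsLM`, uniform weighting on velocities (the data are
noiseless simulations; 1/v weighting would overweight the baseline), and
an 8-point multi-start (Km from the uninhibited fit and 2x it; Kic, Kiu
from a 2-point log grid around the median positive `I`); the lowest
residual wins, ties to the first found. The exact stationary rate law of
the base scheme is *not* of mixed form, so the fitted constants are
operational summaries; the package also derives them in closed form from
the limiting behaviour of the exact rate law at `Keq = 0`:
`kic_closed_form()` (low-substrate slope asymptote,
`Kd*(k_m1 + k2*kcat/(k_m2 + kcat))/k_m1_SEI`, ~100 µM at defaults) and
`kiu_closed_form()` (saturating-velocity ratio,
`Kd*(1 + k2/(k_m2 + kcat))`, ~10.9 µM). The global fit on the reference
grid yields a Kic near 111 µM; fit and closed form differ by under 10%
because the competitive burden `s(0)/s(I)` is a rational, not linear,
function of `I` — the fit averages over the sampled range while the
closed form takes the asymptote. Both routes are reported.

**Dose–response.** `dose_response_profile()` classifies a degree-vs-I
curve as *biphasic* when its maximum exceeds `1 + 1e-3` at an interior
grid point and the curve declines afterwards; the 1e-3 tolerance
separates genuine activation from solver noise (bounded near 1e-6 by the
oracle-equivalence property). The IC50 is the crossing of degree = 0.5
on the descending limb, interpolated linearly in log concentration, and
is reported as undefined when the curve never reaches 50% inhibition on
the sampled range. At `Keq = 1.5` and 0.1 µM substrate the descending
limb crosses 50% only near ~4e2 µM inhibitor, outside the reference
0–100 µM surface range, so the dose–response analyses (and the `fig5b`
bundle) extend the inhibitor grid to 1e4 µM; surface and fitting grids
keep the reference range.

```{r dose, eval = FALSE}
p15 <- with_keq(default_params(), 1.5)
tab <- velocity_grid("base", p15,
                     I_grid = c(0, log_grid(1e-8, 1e-2, 12)))
dose_response_profile(tab, 1e-7)  # biphasic, IC50 ~ 3.6e2 uM
dose_response_profile(tab, 1e-4)  # monotone, IC50 ~ 14 uM
```

## What the simulations do and do not emulate

The velocity tables emulate *initial-rate measurements on an ideal
enzyme*: no observational noise, no ligand depletion (steady-state
engine) or at most 1% (ODE engine), no tight-binding corrections
(enzyme is never within four orders of magnitude of the ligands), free
rather than total ligand concentrations, and strictly mass-action
elementary steps. Passing tests therefore demonstrate internal
correctness of the kinetic model and its analysis chain — not that a
real enzyme follows the model. In particular, real exosite enzymes may
show allosteric cross-talk between the sites (explicitly excluded here),
multiple encounter complexes, or inhibitor off-rates slower than ternary
substrate release, all of which blunt or abolish activation.

## Problem sizes

The reference surfaces use 37 substrate x 49 inhibitor points (12 per
decade); each point is one linear solve of a 6–11 state system, so a
full surface takes well under a second. The ODE verification suite
integrates a few hundred stiff trajectories of ~10 species over seconds
of model time. The whole test suite runs in well under a minute on one
core; these sizes were chosen because refining the grids or tolerances
further changes no reported quantity beyond the stated tolerances.

## Known limitations

* Deterministic mass action only — no stochastic (Gillespie) path, no
  compartments, no arbitrary rate laws.
* No fitting of model parameters to experimental progress curves; the
  fitting functions target simulated initial-velocity tables.
* The Keq = 0 limit is encoded as an irreversible `F -> E` step (the
  constructor requires positive forward rates), which is behaviourally
  identical to deleting `F` — verified to 1e-10 relative.
* `fit_mixed_inhibition()` on nearly competitive data leaves `Kiu`
  weakly determined; it is reported with its large standard error rather
  than raising an error, and callers should inspect `se`.
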