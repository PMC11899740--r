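---
title: "Self-guided Langevin dynamics with spatial averaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-guided Langevin dynamics with spatial averaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfguide)
```

## The method

Self-guided molecular simulation (SGMD, and its Langevin variant SGLD)
accelerates conformational search without biasing potentials.  The idea is
that the slow, low-frequency component of the motion is what carries a
system across conformational space, while most of the kinetic energy sits
in fast vibrations that go nowhere.  A guiding force that selectively
pumps the low-frequency component lets the system diffuse and cross
barriers faster while the thermostat holds the temperature.

The equation of motion gains one term,

$$\dot p = F + g, \qquad
  g_i = \mu\,\Delta\hat F_i + \lambda\,\xi_i\,\hat p_i ,$$

where $\hat p$ and $\Delta\hat F$ are low-frequency (and optionally
spatially averaged) momenta and force differences, $\lambda$ and $\mu$ are
the momentum and force guiding factors, and $\xi$ is the *apparent
friction* that converts momentum into force units.

### Local time averaging

Low-frequency components are extracted with an exponential running
average with time constant $t_L$:

$$\tilde P_t = \Big(1 - \frac{\delta t}{t_L}\Big)\tilde P_{t-\delta t}
             + \frac{\delta t}{t_L} P_t .$$

Its gain at angular frequency $\omega$ is $1/\sqrt{1+(\omega t_L)^2}$:
$1/t_L$ acts as the cutoff between "slow" motion that passes and "fast"
motion that is filtered.  The implementation stores only the first- and
second-order position averages $\tilde r$, $\tilde{\tilde r}$ and the
low-frequency momentum $\tilde p$; everything else is reconstructed
algebraically,

$$\tilde p = \frac{m}{t_L}(r - \tilde r), \qquad
  \tilde F = \frac{p}{t_L} - \frac{m}{t_L^2}(r - \tilde r), \qquad
  \tilde{\tilde F} = \frac{m}{t_L^2}(r - 2\tilde r + \tilde{\tilde r}),$$

so the memory cost is three vectors regardless of run length.  At step 0
the averages are initialised to the instantaneous values
($\tilde r = \tilde{\tilde r} = r$, $\tilde p = 0$), which makes guiding
forces start at zero and grow smoothly over the first $\sim t_L$.

### Spatial averaging

Time averaging separates slow from fast; spatial averaging additionally
separates *shared* from *incoherent* motion.  Four neighbourhood types
are supported: (1) none; (2) bonded atoms within two bonds (1-2 and 1-3);
(3) within three bonds (adds 1-4); (4) all atoms in the surrounding grid
cell of spacing $d_L$.  Types 2-3 use the mass-weighted set average

$$\hat q_i = m_i\,
  \frac{\sum_{j\in\Omega_i} \tilde q_j w_{ij}}
       {\sum_{j\in\Omega_i} m_j w_{ij}}, \qquad w_{ij} = 1 ,$$

type 4 projects $m$, $\tilde p$ and $\Delta\tilde F$ onto the eight
surrounding grid points with trilinear weights, normalises per grid
point by the deposited mass, and interpolates back with the same
weights.  Anti-parallel contributions cancel in the average — vibration,
shaking and random walks are removed and only motion shared by the
neighbourhood survives, which is what "concerted motion" means here.
Three properties pin the scheme down and are enforced by tests: trilinear
weights sum to one; a uniform velocity field is a fixed point of every
type; and a single atom is returned unchanged by project-then-interpolate.

Design choices that the formal description leaves open:

* the type-4 grid is anchored at multiples of $d_L$ one cell below the
  coordinate minimum and rebuilt every step — deposition is then
  deterministic and translation-robust to within one cell;
* grid points that received no mass carry zero field (this avoids 0/0 in
  the normalisation and contributes nothing on interpolation);
* an atom always belongs to its own bonded neighbourhood, so a lone
  bonded pair averages over both partners rather than only the other one;
* the one-sided trilinear weight notation is read as standard
  $(1-|x|)(1-|y|)(1-|z|)$ weighting over the eight cell corners.

### Apparent friction and the guiding force

The apparent friction of each atom is estimated on the fly from two
scalar accumulators with a longer time constant
$t_{avg} = 10\,t_L$ (configurable):

$$FP \leftarrow \Big(1-\frac{\delta t}{t_{avg}}\Big)FP
      + \frac{\delta t}{t_{avg}}\,\Delta\hat F\cdot\hat p, \qquad
  PP \leftarrow \dots\; \hat p\cdot\hat p, \qquad
  \xi = -\frac{FP}{PP}.$$

On an equilibrium trajectory the low-frequency force opposes the
low-frequency momentum, so $\xi \ge 0$ statistically; it is large where
force fluctuations are strong (bonded, condensed systems) and tends to
zero for free diffusion, where there is nothing to guide against.  `PP`
starts at zero, so $\xi$ is reported as 0 until `PP` exceeds a floor of
$10^{-12}$ (internal units); on the first informative step the
$\delta t/t_{avg}$ factors cancel in the ratio, making the cold-start
estimate independent of $t_{avg}$.  A per-atom $\xi$ file from a previous
run can be supplied instead of the on-the-fly estimate.

The *balanced* momentum guiding factor — the $\lambda$ at which momentum
guiding cancels the effect of a given force guiding factor $\mu$ — is
implemented as

$$\lambda_\mu = \frac{\sqrt{1+\mu^2}-1}{1+\mu},$$

which vanishes at $\mu=0$ and is continuous for $\mu > -1$.  The printed
source for this relation is typographically ambiguous; this reading was
chosen because it keeps $\lambda_\mu$ second order in $\mu$ near zero,
consistent with a cancellation between two first-order effects, and only
the $\lambda_\mu(0)=0$ and continuity properties are asserted by tests.

### Energy conservation and the leap-frog loop

The guiding force injects energy.  An atom-specific scaling factor

$$\eta = \frac{(2+\gamma\delta t)\,g\cdot p_0}
              {2\,p_0\cdot p_0 - (g\cdot p_0)\,\delta t}, \qquad
  p_0 = m v_{t-\delta t/2} + (f + g - \gamma m v_{t-\delta t/2})
        \frac{\delta t}{2},$$

adds to the friction in the velocity update and removes per step exactly
the power the guiding force puts in, atom by atom, with no communication
between atoms:

$$v_{t+\delta t/2} =
  \frac{1-(\gamma+\eta)\delta t/2}{1+(\gamma+\eta)\delta t/2}
  v_{t-\delta t/2}
  + \frac{f+g}{1+(\gamma+\eta)\delta t/2}\frac{\delta t}{m}.$$

The step order is: forces (plus the Langevin random force), time
averages, spatial averages, friction accumulators, guiding force,
$\eta$, velocities, positions.  Modes: `md` and `sgmd` set $\gamma=0$
and draw no random force; `ld` and `sgld` use
$\mathrm{var}(R) = 2\gamma m k_B T/\delta t$ per component (internal
units).  With guiding off the scheme is exactly leap-frog Langevin, and
with $\gamma=0$ exactly leap-frog — the test suite asserts these
reductions bitwise against an independently coded reference.  $\eta$ is
guarded: it is zero when $g\cdot p_0=0$ or when the denominator falls
below $10^{-12}$ (near-zero momentum), and the update aborts with a
diagnostic if $(\gamma+\eta)\delta t/2 \le -1$.  In our runs $\eta$
holds guided runs at the Langevin reference temperature to within a
couple of percent — the acceptance checks compare the two directly over
matched seeds.

## Units

Å, ps, g/mol, kcal/mol, K, with $k_B = 0.0019872041$ kcal/mol/K.  One
g/mol (Å/ps)² equals $1/418.4$ kcal/mol (`sg_units$mv2_per_kcal`).
Dynamics are propagated in "internal" force units of g/mol Å/ps² — the
units in which the force reconstruction from position averages naturally
lives — and the force field converts its kcal/mol/Å forces once per step.
The apparent friction $\xi$ and $\eta$ then come out in 1/ps.

## The toy force field and the boundary box

The simulator ships a deliberately small force field — harmonic bonds
($\tfrac12 k(d-d_0)^2$), harmonic angles, optional cosine dihedrals and
Lennard-Jones with Lorentz-Berthelot mixing, 1-2/1-3 exclusions and a
plain $3\sigma$ cutoff — enough to exercise every part of the guiding
machinery on systems with realistic force fluctuations, not to model
chemistry.

Instead of periodic boundaries, a *map-based boundary box* confines the
system: a cubic density grid whose boundary layer (grid points within one
spacing of a face) carries density 1 and whose interior is zero,
interacting through

$$E_{map} = -c_{map}\sum_a m_a \hat\rho(x_a, y_a, z_a)$$

with trilinear interpolation of $\hat\rho$ and its analytic gradient.
With $c_{map} < 0$ (default $-1$ kcal/g) the walls repel.  The default
box is a 20 Å cube with 4 Å spacing.  Because the boundary layer is one
spacing deep on each face, the repulsive density ramp extends two cells
inward from every wall; demo runs therefore size the boundary box as the
chain placement cube plus $4\times$ the grid spacing, which makes the
placement volume exactly field-free and confines the chains only once
they wander beyond it (confinement artifacts are minimised by a
sufficiently large box).  Atoms outside the grid are clamped onto it
for interpolation,
which leaves them under the inward gradient at the clamp point.  The
boundary-layer density is fixed at 1 since only the product
$c_{map}\hat\rho$ matters.

## Fixtures: what the generators emulate

`make_bead_chains()` emulates a crowded box of short, aggregation-prone
peptides as bead-spring chains: by default 100 g/mol beads (one residue),
2 Å bonds with $k = 100$ kcal/mol/Å², straight-rest-angle bending
stiffness of 10 kcal/mol/rad² (bend fluctuations $\approx 0.25$ rad at
300 K, i.e. extended, strand-like chains), and bead attraction
$\epsilon = 0.6$ kcal/mol ($\approx k_BT$), strong enough that
side-by-side chain contact is worth several $k_BT$.  Chains are grown as
worm-like walks and placed with a 1.2 Å clash threshold; placement is
deterministic per seed and fails loudly when the box cannot host the
requested system.  `make_lj_cluster()` and `make_harmonic_dimer()` supply
the standard calibration systems.

What these fixtures do *not* contain: real amino-acid chemistry,
hydrogen-bond directionality, implicit solvent, or constraint algorithms
(no SHAKE; the time step must resolve the stiffest bond, and the defaults
do).  Consequences for interpreting tests are discussed below.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `dt` | 0.002 | ps | leap-frog step |
| `gamma` | 1 | 1/ps | Langevin friction |
| `lambda` | 0.2 | — | momentum guiding factor |
| `mu` | 0 | — | force guiding factor |
| `tL` | 0.2 | ps | local average time (cutoff $1/t_L$) |
| `tavg_factor` | 10 | — | $t_{avg}/t_L$ for the $\xi$ estimator |
| `sg_type` | 1 | — | spatial averaging type |
| `dL` | 5 | Å | type-4 grid spacing |
| `temperature` | 300 | K | target temperature |

## What the checks show — and what they cannot

The package's acceptance checks are property-based, at sizes a desk
machine integrates in minutes (bead systems of 48-240 atoms, runs of
4-50 ps, 10 matched seeds for the statistical comparisons; the
microcanonical drift check runs $10^5$ steps of a dimer).  At these
sizes the following reproduce robustly:

* the analytic attenuation, reconstruction and averaging identities;
* bitwise reduction of SGLD to LD to MD as guiding and friction are
  switched off;
* temperature control: guided runs match the LD reference temperature,
  demonstrating $\eta$;
* a systematic low-frequency kinetic-energy enhancement under
  SGLD($\lambda=0.2$) on matched seeds (a few percent on bonded systems
  — small per step, but this is the quantity that compounds into faster
  conformational search over long runs);
* faster and deeper early potential-energy relaxation of the crowded
  40-chain system under SGLD with grid averaging than under LD, across
  seeds.

One demo-scale claim did **not** reproduce within desk budgets in our
runs and its check is expected to be red: a *statistically significant*
shortening of the time for the 40-chain system's global nematic order
parameter to cross a threshold.  Global orientational ordering of a
240-bead melt is a collective rearrangement whose timescale (hundreds to
thousands of ps in the all-atom analogue) exceeds the desk-scale horizon
by orders of magnitude; within 12 ps the order parameter of 40 chains is
dominated by its sampling noise floor ($S \approx 3/\sqrt{2N_{chains}}
\approx 0.15$), and a few-percent mobility enhancement cannot separate
crossing times drawn from that noise.  The check is implemented exactly
as specified (threshold $S=0.22$, 12 ps horizon, one-sided paired
Wilcoxon over 10 seeds) and reports whatever the runs produce; the
energy-relaxation comparison above is the desk-scale observable that
*does* discriminate the methods.  The nematic order parameter itself —
the largest eigenvalue of the second-rank orientation tensor of
end-to-end vectors — stands in for secondary-structure analysis, whose
hydrogen-bond geometry bead chains do not have.

## Numerical choices

* EMA update validated with $0 < \delta t \le t_L$; $t_{avg} \ge t_L$.
* $\xi$ floor $10^{-12}$ on `PP`; $\eta$ denominator guard $10^{-12}$.
* LJ pair energies use a plain cutoff at $3\sigma$ without switching;
  coincident atoms produce an infinite energy and a clear error.
* Angle forces guard $\sin\theta$ against collinearity at $10^{-6}$.
* All randomness in a run flows from one seed (`run_config(seed=)`);
  the Langevin random force draws one n-by-3 Gaussian block per step,
  column-wise, and draws nothing when $\gamma=0$ or $T=0$ — this is the
  contract that makes cross-implementation bitwise tests possible.
* Kinetic temperature uses full-step velocities (mean of adjacent
  half-step values), the standard leap-frog convention.

## Worked example

```{r example, eval = FALSE}
fix <- make_bead_chains(40, 6, 20, seed = 1)
cfg <- run_config("sgld", lambda = 0.2, tL = 0.2, sg_type = 4, dL = 5,
                  gamma = 1, temperature = 300, dt = 0.002,
                  nsteps = 5000, seed = 1,
                  boundary = list(side = 36, spacing = 4, cmap = -1))
sys <- sg_run(sg_system(fix$topology, fix$positions, cfg))
tail(sys$log[, c("time", "Ep", "tempK", "xi_mean", "conc", "S")])
```

The log tracks potential energy and its local average, kinetic
temperature, mean apparent friction and conservation factor, the
concertedness index (mean $|\hat p|^2/|\tilde p|^2$ — how much
low-frequency motion is shared with the neighbourhood) and the nematic
order parameter of the chains.

## Known limitations

* The force field is a toy; nothing quantitative about real peptides
  follows from these demos.
* No constraints and no multiple time-stepping: `dt` must resolve bond
  vibrations.
* The boundary map is cubic with uniform layer density; no map file
  import from crystallographic formats.
* Spatial averaging type 4 rebuilds its grid every step; for the system
  sizes targeted here that cost is negligible, but it is the first thing
  to cache on larger systems.
* Reweighting guided ensembles back to the canonical distribution is out
  of scope; guided runs are for search, and observables should be
  re-evaluated with unguided dynamics.
```
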