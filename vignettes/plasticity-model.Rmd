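---
title: "A compartment model of epithelial-mesenchymal plasticity under treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A compartment model of epithelial-mesenchymal plasticity under treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidyn)
```

## The model and its assumptions

`plastidyn` tracks the abundances $x_1, \dots, x_N$ of $N$ tumor phenotypes
ordered along the epithelial-mesenchymal axis: compartment 1 is the most
epithelial (fastest-growing, non-motile) state, compartment $N$ the most
mesenchymal (slow-growing, invasive) state, and compartments in between are
hybrid states. The dynamics combine three mechanisms:

$$\dot x_i \;=\; \underbrace{r_i\, x_i \left(1 - \tfrac{X}{K}\right)}_{\text{logistic growth}}
\;+\; \underbrace{c\, r_1\!\left[(1{+}\lambda) x_{i-1} + (1{-}\lambda) x_{i+1} - 2 x_i\right]}_{\text{phenotype transitions}}
\;-\; \underbrace{(m_D r_i + m_I)\, x_i}_{\text{treatment}},$$

with $X = \sum_j x_j$ and one-sided transition terms in the terminal
compartments (compartment 1 has no epithelial neighbour, compartment $N$ no
mesenchymal one). The modelling assumptions are:

* **Shared resources.** All phenotypes compete for one carrying capacity $K$
  at a site; the competition load on every phenotype is the same total $X$.
* **Linearly decreasing growth.** $r_i = r_1 - (r_1 - r_N)(i-1)/(N-1)$,
  reflecting the higher proliferation of epithelial cells. The coexistence
  equilibrium turns out not to depend on this ladder at all, so the linear
  choice is a convenience, not a commitment.
* **Nearest-neighbour plasticity.** Cells step to an adjacent phenotype only.
  Mesenchymal-ward steps occur at rate $T_{EM} = c(1+\lambda)r_1$,
  epithelial-ward steps at $T_{ME} = c(1-\lambda)r_1$. The bias $\lambda$
  stands in for the concentration of a transition-modulating factor (e.g. a
  TGF-β-like signal) without modelling that factor explicitly.
* **Two treatment types.** Growth-dependent treatment (chemotherapy-like)
  kills phenotype $i$ at rate $m_D r_i$; growth-independent treatment
  (immunotherapy-like) kills every phenotype at rate $m_I$. Exactly one type
  is active at any instant.

Transitions only move cells between compartments: the transition terms
telescope to zero when summed, so plasticity never creates or destroys
abundance. Together with inflow-only derivatives at empty compartments this
keeps the nonnegative orthant forward-invariant; both properties are enforced
by tests.

## Parameters

| Parameter | Meaning | Unit | Default |
|---|---|---|---|
| $N$ | number of phenotype compartments | – | 3 |
| $r_1$ | epithelial growth rate; sets the time unit | per time | 1 |
| $r_N$ | mesenchymal growth rate | per time | 1/5 |
| $K$ | carrying capacity of a site | abundance | 1 |
| $c$ | transition speed relative to $r_1$ | – | 1 |
| $\lambda$ | transition bias ($>0$ mesenchymal-ward) | – | 0 |
| $m_D$ | growth-dependent treatment intensity | – (multiplier on $r_i$) | 1 |
| $m_I$ | growth-independent treatment intensity | per time | calibrated, $\approx 0.647$ |

Time is measured in units of $1/r_1$ and abundance relative to $K$, so the
defaults describe a dimensionless reference tumor. $c > 1$ means transitions
outpace proliferation (within-generation plasticity); $c < 1$ transitions
slower than growth (e.g. epigenetic, transgenerational change).

## Equilibrium, moments and stability

Untreated, the model has two equilibria. Extinction ($x = 0$) is linearly
unstable — an untreated tumor always progresses. The coexistence state

$$x_i^* = K\,\frac{(1-\lambda)^{N-i}(1+\lambda)^{i-1}}
{\sum_{j=1}^N (1-\lambda)^{N-j}(1+\lambda)^{j-1}}$$

is a geometric profile with ratio $(1+\lambda)/(1-\lambda)$, sums to $K$, and
depends only on $\lambda$ and $N$. `coexistence_equilibrium()` evaluates it
directly; it refuses $c = 0$, where transitions vanish and the long-run
composition depends on the initial condition instead.

`distribution_moments()` summarizes a composition by the mean, variance and
third central moment of **trait scores** $s_i = (i-1)/(N-1) \in [0, 1]$
(0 = epithelial, 1 = mesenchymal). A "mean phenotype" has no canonical
numeric scale; the normalized $[0,1]$ axis is this package's design choice,
made so that moments are comparable across different $N$. Under it, equilibrium heterogeneity (variance) is maximal at
$\lambda = 0$ and vanishes toward $\lambda = \pm 1$, and the skew is an odd
function of $\lambda$ — both consequences of the mirror symmetry
$x_i^*(\lambda) = x_{N+1-i}^*(-\lambda)$.

`stability_report()` evaluates the **analytic Jacobian** (growth/competition,
transition and treatment derivatives are each linear or bilinear, so the
entries are exact) and classifies the spectral abscissa with a tolerance band
of $10^{-9}$: `stable` below $-10^{-9}$, `unstable` above $+10^{-9}$,
`marginal` inside. The analytic entries are cross-checked against central
finite differences in the test suite. A symbolic global-stability certificate
is out of scope; instead, stability of coexistence and instability of
extinction are verified numerically across a $(\lambda, c)$ grid, and
long integrations from extreme initial conditions (epithelial-only founders,
mesenchymal-only founders, phenotype ablations) are checked to converge to
the same closed-form equilibrium.

## Treatment calibration and the decision boundary

The two treatment intensities are made comparable by **calibration**
(`calibrate_mI()`): $m_I$ is chosen so that a single 10-time-unit block of
either type, applied to a tumor at the coexistence equilibrium with
$c = 1, \lambda = 0, m_D = 1$, leaves the same total abundance $X(10)$.
Starting the calibration at the coexistence equilibrium is this package's
design choice, consistent with the treatment analyses (which all assume an
equilibrated pre-treatment tumor). The
endpoint gap is monotone in $m_I$, so calibration is solved as bracketed root
finding (`uniroot` on $[0, 10\,m_D r_1]$, tolerance $10^{-12}$, verified
residual $< 10^{-8}$) rather than generic minimization. At the defaults it
gives $m_I \approx 0.6475$.

At the equilibrium $x^*(\lambda)$, growth-dependent treatment kills at total
rate $\sum_i m_D r_i x_i^*$ and growth-independent at $\sum_i m_I x_i^*$.
Their difference $f(\lambda) = \sum_i (m_D r_i - m_I)\, x_i^*(\lambda)$ is a
low-degree polynomial in $\lambda$; its root $\tilde\lambda$ is the
**decision boundary**: below it the tumor is epithelial enough that
growth-dependent treatment exerts the higher mortality, above it
growth-independent does. `decision_boundary()` brackets sign changes on a
1001-point $\lambda$ grid and polishes by bisection to $|f| < 10^{-12}$ —
$f$ is smooth and low-degree, so this is both cheap and robust. When $f$ has
no sign change (e.g. $m_I > m_D r_1$, since the weighted mean of the growth
ladder never exceeds $r_1$), `NA` is returned: one type dominates for every
bias. With the calibrated $m_I$, $\tilde\lambda \approx -0.089$.

## Treatment schemes

`build_schedule()` splits a fixed treatment duration (default 10 time units)
into equal blocks: single-block growth-dependent or growth-independent,
alternating blocks starting with either type, or **adaptive** blocks whose
type is chosen at block start as the one with the higher instantaneous
mortality on the current composition (`adaptive_choice()`). Exact mortality
ties — a measure-zero coincidence — resolve deterministically to
growth-dependent; the tie-break only matters on that null set.

Because a one-block adaptive schedule decides once, at the equilibrated
pre-treatment composition, its outcome coincides exactly with the matched
single scheme on either side of $\tilde\lambda$; the test suite asserts this
equivalence to $10^{-9}$ (the runs are in fact identical integrations).

## Numerical choices

* **Integration.** `deSolve::ode` with `lsoda`, relative tolerance $10^{-8}$
  and absolute $10^{-10}$ by default (tighter, $10^{-10}/10^{-12}$, inside
  calibration). The system is small and smooth, so tight tolerances cost
  little and make reported quantities reproducible to printed precision;
  endpoint burdens under default and tightened tolerances agree to $10^{-6}$
  in tests.
* **Block boundaries.** Integration restarts at every schedule block edge, so
  intensity switches are exact rather than smoothed over a step.
* **Negativity.** Round-off can push abundances marginally below zero:
  values in $[-10^{-12}, 0)$ are clamped to zero and counted on the
  trajectory object; anything lower is treated as a solver failure and
  raises an error rather than being silently repaired.
* **Steady-state detection.** Open-horizon runs (`steady_state()`) integrate
  in chunks and stop when both $\|\dot x\|_\infty$ and the frequency drift
  per unit time fall below $10^{-10}$, capped at a horizon of 1000 time
  units — the same window over which post-treatment regrowth is tracked.
* **Output formatting.** CSV artifacts round to 12 significant digits with a
  fixed format, so identical configurations produce byte-identical files.

## Scenarios, sweeps and what they do (not) show

`scenario_initial_condition()` generates the study's initial states: a
primary-site tumor founded by epithelial cells only, $(K/10, 0, \dots, 0)$; a
secondary site seeded by disseminated mesenchymal cells,
$(0, \dots, 0, K/10)$; and phenotype ablations (the equilibrium with one
compartment emptied). The secondary-site founder is taken as purely
mesenchymal at $K/10$, mirroring the primary-site convention; whether a small
hybrid fraction would accompany real dissemination is not modelled.

`sweep_burden_reduction()` maps the end-of-treatment burden reduction
$(K - X)/K$ over a $(\lambda, c)$ grid, starting every cell from its own
coexistence equilibrium. The default grids — 41 evenly spaced biases in
$[-1, 1]$ and 25 log-spaced speeds in $[10^{-2}, 10^2]$ — are this package's
choice and span both the slower-than-growth and faster-than-growth
transition regimes. The default
block-count set $\{1, 2, 10\}$ for multi-block comparisons is likewise an
implementation choice. `adjuvant_shift()` models a transition-modulating
co-treatment purely as a shift of $(\lambda, c)$ applied before and during
treatment, with the initial condition re-equilibrated at the shifted
parameters; no extra dynamics are attached to the adjuvant.

These scenarios are synthetic by construction: they emulate the deterministic
mean-field behavior of a plastic tumor, not patient data. They contain no
demographic or measurement noise, no spatial structure or explicit
dissemination between sites, no resistance evolution, and no
pharmacokinetics — treatment intensities switch on and off instantaneously.
Passing tests therefore demonstrate internal correctness of the model and its
analysis, not clinical validity.

Test and acceptance runs keep problem sizes small by design — $N \le 6$,
coarse sweep grids (up to $5 \times 3$ cells), horizons up to 1000 time
units — which this smooth three-to-six-dimensional system resolves in
seconds.

## Variant hooks and open ends

Two generalizations are exposed as configuration hooks, implemented as
simple, documented stand-ins:

* `competition_matrix` replaces the shared load $X$ on phenotype $i$ by
  $\sum_j \alpha_{ij} x_j$ (unequal competitiveness). The all-ones default
  recovers the reference model exactly — bitwise, as a test asserts.
* `transition_scaling = "own_rate"` scales a phenotype's outgoing transitions
  by its own growth rate $r_i$ instead of $r_1$ (growth-rate-dependent
  plasticity).

The closed-form equilibrium, the decision boundary and the calibration
procedure are defined for the reference model; with the hooks engaged they
should be interpreted as approximations and cross-checked against
`steady_state()`. Known limitations beyond the hooks: $N = 1$ degenerates to
pure logistic growth (allowed, but none of the phenotype analyses apply);
$c = 0$ is a valid dynamical regime whose equilibrium composition is
initial-condition-dependent, so equilibrium-based routines reject it; and the
multi-block comparison is about splitting a fixed total duration, not about
dose optimization over continuous intensities.
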