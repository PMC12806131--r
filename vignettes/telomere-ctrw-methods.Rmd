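---
title: "Modelling telomere shortening as a continuous-time random walk"
author: "telosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling telomere shortening as a continuous-time random walk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telosim)
```

## The model

Telomeres lose base pairs at every cell division. `telosim` models the
cumulative shortening $L(t)$ as a continuous-time random walk (CTRW): the
cell waits a random cell-cycle duration $\tau \sim \omega(t)$, then loses a
random length $\varphi(L)$, and the cell senesces when $L$ first reaches the
threshold $l_0 - l_c$ (initial minus critical telomere length; 7000 bp at
the package defaults, roughly a 10 kb telomere with a 3 kb critical length).

The per-division loss combines incomplete end replication,
$L_1 \sim \mathcal N(\mu, \sigma^2)$, with exonuclease digestion,
$L_2 \sim \mathrm{Poisson}(\lambda)$, assumed independent:
$L = L_1 + L_2$, so $\mathbb E[L] = \lambda + \mu = 215$ bp and
$\mathrm{Var}[L] = \sigma^2 + \lambda = 156$ bp$^2$ at the defaults
$\lambda = 155$, $\mu = 60$, $\sigma = 1$. Oxidative damage, the third
mechanism, occurs with probability $\approx 0.1$ per division and is
neglected in the core model; the full three-mechanism decomposition
$L = \tfrac14 L_1 + 0.8 \cdot \tfrac14 L_2 + 0.1 \cdot \tfrac12 L_3 N$ is
available through `threeMechanismModel()`, with the oxidative parameters
left to the caller because no canonical values exist for them.

Cell-cycle durations carry the anomalous-transport physics. Three families
are provided:

* `powerLawWait(alpha, t0)` — Pareto with tail exponent $\alpha \in (0,1)$:
  no mean cycle time, fractional (subdiffusive) renewal counting. The
  default scale $t_0 = \Gamma(1-\alpha)^{-1/\alpha}$ normalises the small-$s$
  Laplace transform to $1 - s^\alpha$, so times are measured in the natural
  units of the fractional dynamics.
* `paretoWait(alpha, tau0)` — Pareto with $\alpha \in (1,2)$: finite mean
  $T = \alpha\tau_0/(\alpha-1)$, infinite variance, transform
  $1 - Ts + Cs^\alpha$ with $C = |\Gamma(1-\alpha)|\tau_0^\alpha$.
* `temperedWait(gamma, B, xi)` — one-sided $\gamma$-stable law of scale $B$
  with exponential tempering at rate $\xi$, transform
  $\exp(-B^\gamma(s+\xi)^\gamma + B^\gamma\xi^\gamma)$: anomalous below the
  tempering time $1/\xi$, normal beyond. Only $\xi = 0.1$ is canonical for
  the occupation-time setting; $\gamma = 0.7$, $B = 1$ are package defaults
  chosen once as representative of moderately heavy cycle-time tails, and
  both are exposed in every interface.

The tempered sampler draws a stable variate by the Chambers–Mallows–Stuck
construction and accepts it with probability $e^{-\xi S}$ (exponential
tilting made exact by rejection); its density and survival function are
evaluated through the Zolotarev integral representation of the one-sided
stable density rather than by contour inversion — the representation is
exact and needs only one well-behaved quadrature.

## Moments and diffusion regimes

The ensemble mean and the ensemble-averaged mean squared displacement
(EAMSD, $\langle L^2\rangle - \langle L\rangle^2$) have closed forms. For
$\alpha \in (0,1)$,
$\langle L(t)\rangle = (\lambda+\mu)\,t^\alpha/\Gamma(1+\alpha)$ and the
EAMSD grows like $t^{2\alpha}$ with prefactor
$\bigl(2/\Gamma(1+2\alpha) - 1/\Gamma^2(1+\alpha)\bigr)(\lambda+\mu)^2$:
subdiffusive below $\alpha = 0.5$, superdiffusive above. For
$\alpha \in (1,2)$ the package evaluates the full four-term variance
(linear, $t^{2-\alpha}$, $t^{3-\alpha}$ and $t^{4-2\alpha}$ contributions)
by default, with the $C/T \ll 1$ (linear) and $C/T \gg 1$ ($t^{4-2\alpha}$)
limit branches on request.

Two caveats discovered while validating the closed forms are worth stating
plainly, because they change what a simulation can be expected to show:

* **The $t^{3-\alpha}$ term dominates asymptotically for every
  $\alpha \in (1,2)$.** Since $3-\alpha$ exceeds both $1$ and $4-2\alpha$
  on that interval, the "normal" and "transient" regimes are visible only
  below a crossover time. For $\alpha = 1.1$, $\tau_0 = 0.01$ the crossover
  is far below the observation window, so the measured EAMSD slope over
  $t \in [200, 2000]$ is $\approx 1.8$–$1.9$, not $1$; for $\alpha = 1.8$,
  $\tau_0 = 1$ the crossover sits near $t \approx 14$ and the measured slope
  is $\approx 1.2$–$1.3$, not $4-2\alpha = 0.4$. The mechanism is renewal-
  count fluctuation: a single waiting time comparable to the whole horizon
  (probability $\sim n(\tau_0/t)^\alpha$ per path) produces large renewal
  deficits, and $\mathrm{Var}\,N(t) \propto C\,t^{3-\alpha}/T^3$. The
  `classifyRegime()` cutoffs on $C/T$ (defaults 0.1 and 10) label these two
  parameter sets "mixed" accordingly, and the raw ratio is always reported
  so the labels never bind.
* **The mean formula for $\alpha \in (1,2)$ is a two-term truncation.** The
  omitted $O(C^2 t^{3-2\alpha})$ renewal correction is $\sim$7–10% of the
  mean for $\alpha = 1.1$, $\tau_0 = 0.01$ over the canonical window, which
  is why the 5% mean-recovery check fails for that configuration (and only
  that one) while the simulator itself is exact in law.

The second moment for the $C/T \gg 1$ branch is taken from the variance
expression directly; the printed second-moment form for that branch is
internally inconsistent (it contains time-independent terms) and is not
used.

The jump variance entering diffusive terms is $\sigma^2$ by convention in
the macroscopic equations, although the exact Normal$+$Poisson variance is
$\sigma^2 + \lambda$; every moment and solver function accepts
`convention = "exact"` to switch. At the defaults the distinction is
numerically irrelevant for slopes (the $(\lambda+\mu)^2$ terms dominate by
four orders of magnitude).

## Simulation design

`simulateTrajectory()`/`simulateEnsemble()` generate the renewal path
exactly: waiting times and jumps are drawn from the exact laws, the path is
a right-continuous step function, absorption is recorded at the division
epoch whose jump reaches the threshold (the overshoot — leapover — is
retained), and horizon-censored first passages are reported explicitly,
never dropped. A single `set.seed` stream with sequential simulation makes
every ensemble bit-reproducible from its seed.

For moment estimation `simulateLengthGrid()` collapses the jumps between
grid times: conditional on the renewal count increment $k$, the summed loss
is $\mathcal N(k\mu, k\sigma^2) + \mathrm{Poisson}(k\lambda)$, so only the
waiting-time sequence is simulated path-wise. This is exact for the
finite-dimensional law of $L$ on the grid and reduces the cost of the
heavy-renewal configurations ($\sim 2.5\times10^4$ renewals per path for
$\alpha = 1.1$, $\tau_0 = 0.01$) by the mean jump count between grid
points.

Problem sizes used by the validation suite — $10^4$ trajectories per regime
configuration, $10^5$ for density comparisons, $10^6$ draws for moment
checks — were chosen to keep Monte Carlo standard errors a factor of a few
below each tolerance being checked.

What the generator deliberately does not emulate: telomerase re-elongation
(jumps are nonnegative at the defaults and never repair), inter-cell
heterogeneity of $(\lambda,\mu,\sigma)$, correlations between cycle length
and loss, and population dynamics of dividing lineages. Passing checks
therefore validate the mathematics of the CTRW model, not the biology of
any particular cell line.

## Fokker-Planck solvers

`solveFPE()` advances the macroscopic density $p(L,t)$ with an explicit
scheme: first-order upwind advection and centred diffusion applied to the
memory-operator output, where the memory operator is the Grünwald–Letnikov
(GL) discretisation of the Riemann–Liouville derivative
$D_t^{1-\alpha}$ (infinite-mean waits), of
$1 + (C/T)D_t^{\alpha-1}$ (finite-mean Pareto waits), or absent
(convection–diffusion limit). Numerical choices:

* The delta initial condition is unit mass in the first cell, with $L = 0$
  a cell centre; both boundaries absorb (density outside $[0, l_0-l_c]$ is
  removed). The left wall is physically near-irrelevant at the defaults
  since jumps are positive.
* The fractional memory at an absorbing wall has no canonical treatment;
  the solver applies the GL sum to the zero-extended interior history, a
  modelling choice that keeps the operator local to the surviving mass.
* Stability is enforced through an effective Courant number
  $a\,\Delta t_{\mathrm{eff}}/\Delta L + 2D\,\Delta t_{\mathrm{eff}}/\Delta L^2$
  with $\Delta t_{\mathrm{eff}}$ the one-step amplification of the memory
  operator ($\Delta t^\alpha$ for the subdiffusive regime); violations are
  refused with a diagnostic rather than silently damped.
* The convection–diffusion ("normal") regime is advection-dominated at the
  defaults ($a = 215/T$ versus $D = \sigma^2/2T = 0.5/T$): any upwind step
  below unit Courant number adds numerical diffusion orders of magnitude
  above the physical one. That regime therefore uses operator splitting —
  an exact semi-Lagrangian shift at unit Courant number (the automatic
  default) plus an explicit diffusion step — and rounds the final time to a
  whole number of shift steps.

The subdiffusive solution is compared with Monte Carlo on bins of roughly
two mean jumps (437.5 bp): the exact CTRW density is a comb of bumps spaced
$\lambda+\mu$ bp whose width $\sqrt{(\sigma^2+\lambda)N}$ stays below the
spacing for every renewal count the absorbing threshold allows, so finer
bins would compare discreteness artefacts rather than the transported mass.
At $10^5$ paths the binned $L^1$ distance converges to $\approx 0.05$ and
is dominated by the continuum-limit error of the equation itself (about 5%
of the surviving mass at a threshold of $\approx 33$ mean jumps), not by
the scheme: refining $\Delta t$ and $\Delta L$ moves the solution by far
less than that gap.

## Path functionals and the backward Feynman-Kac equation

The occupation time $T^+ = \int_0^t U[L(\tau)]\,d\tau$ with $U$ the
indicator of $[0, l_0-l_c)$ measures how long a lineage keeps a functional
telomere within the observation window; the first passage time $T_f$ marks
the onset of senescence. For the monotone paths of this model the two
coincide whenever the threshold is reached before the horizon —
`occupationTime()` and `pathFunctional()` share one quadrature so the
identity holds bitwise, and the Monte Carlo estimators report the
censored/at-horizon probability atom separately.

`solveBackwardFK()` advances the backward equation for
$G_{L_0}(p,t) = \mathbb E[e^{-pA}]$ under tempered waits, using GL weights
tilted by $e^{-(\xi + pU)k\Delta t}$ (the substantial derivative). Design
choices:

* Laplace mode is the default since $T^+ \ge 0$; Fourier mode is retained
  for signed functionals.
* Starting points at or beyond the threshold accumulate no occupation on a
  monotone path, which supplies the exact right boundary value $G = 1$.
* The printed form of the inhomogeneous term reads
  "$-[\xi + pU]G + \xi - \xi^\gamma D_t^{1-\gamma,\xi} e^{-pU t}$"; read
  with a bare constant $\xi$ it fails the $U \equiv 1$ consistency check
  ($G = e^{-pt}$ must solve the equation exactly). The implementation reads
  the source as $(\xi - \xi^\gamma D_t^{1-\gamma,\xi+pU})[e^{-pU t}]$,
  which makes both the $U \equiv 0$ ($G \equiv 1$) and $U \equiv 1$ limits
  exact. The operator-order prefactor is $\Gamma(\gamma)$ throughout,
  consistent with an operator of order $1-\gamma$.
* The source is discretised with the same GL weights as the memory
  operator, so its $t^{\gamma-1}$ short-time singularity cancels against
  the $\xi^\gamma G$ contribution discretely, not just in the limit. (The
  analytic tilted-power form, via a Mittag-Leffler series, is kept as the
  oracle in the unit tests.)
* Inversion in $p$ uses Gaver–Stehfest with a deliberately small order
  ($M = 4$) because the abscissa values carry $O(\Delta t)$ solver error
  and the method amplifies noise roughly tenfold per additional digit
  demanded; negative inverted values are clipped at zero with the clipped
  mass reported, and violent sign oscillation flags the result.

Two model-level limitations bound what this solver can reproduce:

* The macroscopic coefficients carry the factor $1 + B^\gamma\xi^\gamma$
  from a small-$\xi$ truncation of the renewal transform. At the canonical
  $\xi = 0.1$ ($B^\gamma\xi^\gamma \approx 0.2$) this inflates the drift by
  $\approx 20\%$ relative to the exact renewal process; at $\xi = 0.01$ the
  bias drops to $\approx 4\%$, and the solver then matches Monte Carlo
  transforms to within a few parts in a hundred (that configuration is the
  package's solver-correctness test).
* A continuum equation cannot represent a first passage that takes about
  three discrete jumps. With a 500 bp band and 215 bp mean jumps the true
  occupation-time density is the three-fold convolution of the waiting law
  (sharp rise, interior peak), while the continuum solution places
  substantial mass at arbitrarily small occupation times; their $L^1$
  distance is $O(1)$ no matter how fine the grid. The cross-check becomes
  meaningful when the band is many mean jumps wide.

## Known limitations

Beyond the points above: the explicit GL schemes are first order in time
and memory-quadratic in step count (full history by default; a truncation
flag trades accuracy for speed on long runs); the moment closed forms are
asymptotic in $t$ and degrade at horizons of only tens of renewals; no
fitting of any parameter to measured telomere-length data is provided or
intended; and the symbol $\gamma$ of the tempered family is an independent
parameter, not derived from the power-law $\alpha$ of the untempered
families.
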