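---
title: "An energy-driven swarm model of premyofibril z-body patterning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An energy-driven swarm model of premyofibril z-body patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(premyoswarm)
```

## The modelling problem

Premyofibrils — the earliest myofibril precursors — are identified by
punctate aggregates of the actin cross-linker α-actinin (z-bodies) spaced at
regular intervals along the fibre. How those clusters first self-organize
into a periodic pattern is largely unknown: most work on sarcomere assembly
starts from an already-patterned premyofibril. `premyoswarm` implements a
phenomenological model that asks whether α-actinin dynamics alone — mobility,
mutual interaction, and energetically gated recruitment — suffice to produce
the observed patterns, without reference to other sarcomeric proteins.

The model treats pattern formation as stochastic energy minimization carried
out by a particle swarm optimizer (PSO). A *swarm* is a population of `S`
candidate cluster configurations on the same simulated myofibril; each
configuration is a set of cluster positions constrained to a planar curve.
Configurations move under the standard PSO attraction toward their personal
best and the swarm-wide best solution, and the swarm grows by *energy state
transitions*: a new cluster is recruited into an under-populated fibre
segment whenever doing so lowers the objective.

## Objective and interaction energy

For a configuration with cluster locations $\mathbf r_1,\dots,\mathbf r_N$
the objective is

$$f(\mathbf r_1,\dots,\mathbf r_N)
  \;=\; \sum_{i<j} V(r_{ij}) \;+\; \sum_{k=1}^{K_l} E_k\,\delta_k ,$$

the energetic cost of the current state plus the cost–benefit of the
clusters proposed for recruitment this iteration. The pairwise interaction
is a Lennard-Jones potential

$$V(r) \;=\; \varepsilon\!\left[\left(\frac{r_m}{r}\right)^{12}
  - 2\left(\frac{r_m}{r}\right)^{6}\right],$$

with well depth $V(r_m) = -\varepsilon$ at the ideal inter-cluster distance
$r_m$ and zero crossing at $r_m 2^{-1/6}$: clusters repel strongly when
closer than about $0.89\,r_m$ and attract weakly beyond it. The two fibre
endpoints are treated as fixed clusters that participate in every pairwise
sum but never move; they anchor the pattern at the fibre ends (this choice
is recorded in each run's metadata, since a boundary-free reading is also
defensible — without it the outermost mobile clusters would be
unconstrained from one side).

A recruitment candidate $\mathbf s_k$ is scored against the current optimal
configuration and the candidates already accepted this iteration:

$$E_k=\sum_{(x_1,x_2)\in X} P(\mathbf s_k,x_1,x_2)
 \left[\sum_j V(|\mathbf s_k-\mathbf r_j|)
 +\sum_{m<k} V(|\mathbf s_k-\mathbf s_m|)\,\delta_m\right],$$

where $X$ is the partition of the fibre into segments between consecutive
clusters of the optimal configuration (pseudo-ordered by x after alignment)
and the indicator $P$ permits at most one recruit per segment per
iteration. A candidate is accepted ($\delta_k = 1$) exactly when $E_k < 0$,
i.e. when $\Delta f < 0$. Proposals are evaluated in left-to-right segment
order, which is also the order in which they are drawn; the $m<k$ cross
terms therefore refer to proposal time.

Because each accepted candidate strictly lowers $f$, the optimal
configuration's objective is non-increasing across the whole run, with
strict drops exactly at recruitment events — a property the test suite
checks on every simulated trajectory.

## The adapted PSO cycle

Each of `T_max` iterations updates all `S` configurations:

1. **Velocity** — per cluster,
   $v \leftarrow \omega(t)\,v + R_1 c_1 (p - r) + R_2 c_2 (g - r)$, with
   fresh uniform(0,1) draws $R_1, R_2$ per cluster per iteration and the
   linearly decaying inertia
   $\omega(t) = \omega_{max} - (\omega_{max}-\omega_{min})\,t/T_{max}$.
2. **Position** — $x \leftarrow x + v\,\Delta t$ along the aligned
   horizontal axis only; the vertical coordinate is recomputed from the
   curve so clusters never leave the fibre. Absorbing boundaries: a cluster
   predicted past a fibre end is reset to that end with zero velocity.
3. **Bests** — the personal best $p_k$ is replaced only on strict
   improvement of $f$; the global best $g$ is replaced by the best personal
   best only when strictly better, ties resolved to the lowest
   configuration index. Keeping $g$ as the best solution found so far (not
   the best *current* position) is what makes $f(g)$ monotone.
4. **Energy state transition** — every segment of $g$ whose neighbour
   distance exceeds the searching distance `d_th` draws one candidate
   uniformly in x within the segment; accepted candidates join $g$, and
   each individual configuration receives one cluster placed uniformly at
   random in the same segment, initialized like the initial clusters
   ($p = r$, $v = 0$). All configurations therefore always share one
   cluster count.

Initialization places the two endpoint clusters plus a single interior
cluster uniformly at random per configuration, with zero velocities and
$p = r$; $g$ starts as the most favourable initial configuration.

Two correspondence choices are open in this scheme and are resolved as
follows. First, $(p-r)$ and $(g-r)$ require matching clusters across
configurations whose identities may have permuted; clusters are matched by
pseudo-order rank (i-th leftmost to i-th leftmost), which keeps the
attraction geometric. Second, the random factors $R_1, R_2$ are drawn per
cluster rather than per configuration, so configurations do not move as
rigid bodies.

## Fibre geometry

The simulated myofibril is a degree-4 (five control point) Bézier curve of
prescribed arclength $L_c$ and radius of curvature $R_c$; a straight fibre
is represented by an explicit `Inf` sentinel rather than a large radius.
Since only the order, length and curvature are prescribed, the control
points are placed by a least-squares fit to a circular arc of radius $R_c$
subtending the angle $L_c / R_c$ — the minimal reading of "radius of
curvature" — with end control points pinned to the arc endpoints. The fit
is then verified: realized arclength (adaptive quadrature of the speed)
within 1% of $L_c$, maximum deviation from the target arc below 1% of
$R_c$, and arcs longer than a half circle are rejected as infeasible.

A rigid alignment transform takes the curve endpoints onto the horizontal
axis with the start at the origin; in this frame the curve must be a
single-valued, monotone function $y(x)$ (curves with $|dy/dx| > 10$ are
rejected), which is what lets the swarm move clusters in x only. $y(x)$ is
evaluated from a cubic-spline table over 4001 Bézier samples — accurate to
well below the 1e-6 µm tolerance the dynamics assume — and a calibrated
cumulative-chord table maps arclength to position for uniform-in-arclength
sampling.

## Pattern metrics

* **Mean inter-cluster distance** $\bar d$: 2D distances between
  consecutive on-curve clusters (endpoints included), averaged over a
  configuration's gaps, over the `S` configurations of a run, then over
  replicate runs. On a straight fibre a configuration's mean gap telescopes
  to fibre length over gap count, so $\bar d$ is driven by the final
  cluster count.
* **Rescaled distance** $\bar d_T$: grid sweeps express each cell's
  deviation $\bar d - r_m$ relative to the grid-wide maximum absolute
  deviation, giving values in $[-1, 1]$ (an all-cells-equal grid falls back
  to 0 with a warning).
* **Uniformity** $u = 1 - \lambda/\lambda_{rand}$, clamped to $[0,1]$:
  $\lambda$ is the coefficient of variation (population SD over mean) of
  the nearest-neighbour distances $\gamma_i$, and $\lambda_{rand}$ is the
  maximum $\lambda$ among 60 sets of the same number of points placed
  uniformly in arclength on the same fibre. Exactly equal spacing gives
  $u = 1$; spacing as irregular as the worst random set gives 0. Because
  $\lambda_{rand}$ is a maximum over finitely many draws, $\lambda$ can
  exceed it; such values clamp to 0. Monte-Carlo checks show the
  calibration level is *not* monotone in the point count from the smallest
  N (the spacing COV of a homogeneous process is asymptotically
  scale-free); it decreases once N reaches the order of tens, and the test
  suite asserts exactly that verified regime.
* **Ranking** $R = \bar u \exp(-\bar d_T^2 / 2\sigma^2)$ with $\sigma$ the
  SD of the rescaled-distance collection over the same grid: uniformity
  weighted by closeness of the achieved spacing to the ideal distance,
  optionally normalized to a grid maximum of 1. High-rank cells are those
  above mean + SD, or above a fixed normalized cutoff such as 0.56 when
  comparing behaviour sweeps.

## Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| $\varepsilon$ | 1 | energy | well depth; scales $f$ uniformly, so positions are unaffected — energies are reported in units of $\varepsilon$ |
| $r_m$ | 1.1 | µm | ideal spacing; 1.1 cardiac, 0.7 skeletal, 1.8 flight muscle |
| $d_{th}$ | 0.5 | µm | minimum segment length considered for recruitment |
| $S$ | 60 | — | swarm size used in the convergence studies |
| $c_1, c_2$ | 2, 2 | — | cognitive/social acceleration, admissible range [0, 4] |
| $\omega_{max}, \omega_{min}$ | 0.9, 0.4 | — | inertia schedule endpoints ("near 1" start, strong late damping) |
| $T_{max}$ | 200 | iterations | run length; convergence is typically well before |
| $\Delta t$ | 1 | iteration | standard PSO convention; velocities absorb the scale |

## Numerical choices and degenerate inputs

* Lennard-Jones evaluation is guarded below 1e-6 µm: the public energy
  functions raise an error on coincident clusters, while the engine scores
  a colliding configuration as $+\infty$ (it can arise transiently when
  absorbing boundaries stack clusters at a fibre end) so it simply never
  becomes a best.
* For the same reason, the uniformity aggregator over engine output
  computes $\lambda$ without the coincidence error: near-zero
  nearest-neighbour distances inflate $\lambda$ and clamp $u$ toward 0,
  which is the scientifically sensible score for a degenerate pattern.
* Ties: equal $f$ keeps the incumbent personal best; equal best objectives
  resolve to the lowest configuration index; duplicate x-coordinates in the
  pseudo-ordering keep their original order.
* Each run uses a single seeded Mersenne-Twister stream with a fixed draw
  order (velocity draws by iteration, configuration, cluster rank; then
  recruitment candidates left to right; then per-configuration
  placements), so a seed reproduces a run bit for bit. Sweeps derive every
  run's seed from the top-level seed and the (cell, replicate) indices
  only, making cell results independent of execution order.
* One-cell or all-tied sweep grids degenerate gracefully: the rescaled
  distance falls back to 0 and the ranking's Gaussian factor to an
  indicator, each with a warning.

## What the simulated conditions do and do not show

All experiments are self-generated; there is no external data. The study
conditions are a straight 40 µm fibre (and Bézier arcs of 20–60 µm at radii
20/56/110 µm for shape studies), $S = 60$, $T_{max} = 200$, $d_{th} = 0.5$
µm, and ten replicate runs per condition, with $r_m$ set per muscle type.
Under these conditions the model reproduces the qualitative biology the
approach was built to explore: converged mean spacings land slightly
*above* $r_m$ for every muscle type, cluster counts fall strictly as $r_m$
grows, and recruitment events coincide with strict drops in the objective.

What passing these checks does *not* show: the model is phenomenological,
so agreement says nothing about which proteins implement mobility or
binding differences between cell types; the fibre is a fixed 2D curve, so
nothing is learned about curvature feedback, 3D structure, or interactions
between neighbouring premyofibrils; and the synthetic conditions have no
imaging noise, cluster-size heterogeneity, or fibre-length dynamics, all
present in real micrographs.

Unit tests run on deliberately small instances (6–8 µm fibres, swarms of
6–20, tens of iterations) chosen to exercise every code path quickly; the
headline checks use the full study conditions above. The exhaustive-search
cross-check uses a 4$r_m$ fibre, where grid minimization over up to three
interior clusters is tractable (the engine's final energy agrees to well
within 1%, and the grid optimum is equal spacing at $r_m$ to within one
0.01 µm grid step).

## Known limitations

* The Bézier fitting procedure is this package's choice; any degree-4 curve
  with the same length and curvature radius would satisfy the stated
  constraints, and strongly curved fibres near the half-circle limit push
  the single-valuedness check.
* Recruitment evaluates candidates against the optimal configuration only;
  individual configurations receive their recruited cluster at a random
  position, so their objective can transiently worsen — by design, but it
  slows late-stage convergence of the swarm average toward $g$.
* $\lambda_{rand}$ is a maximum over 60 draws and therefore itself a random
  variable; uniformities within a few percent of each other should not be
  over-interpreted.
* ANOVA/Tukey–Kramer comparisons are plumbing over `stats::aov` and
  `stats::TukeyHSD` and inherit their normality and homoscedasticity
  assumptions.
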