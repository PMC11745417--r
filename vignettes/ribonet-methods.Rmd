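---
title: "Methods: quasi-steady-state kinetics of RNA replicator networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quasi-steady-state kinetics of RNA replicator networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribonet)
```

## The model in one page

ribonet simulates an RNA-world habitat: populations of RNA molecules that
replicate each other by template-directed polymerization. Species R1 is a
ribozyme polymerase (the only efficient catalyst), R2 its complementary
strand, P a molecular parasite (an excellent template with no catalytic
output for the host), and F a hyperparasite — a still smaller mutant of P
that binds parasites (and itself) into catalytically futile complexes,
sequestering them away from the polymerase.

The model has two coupled layers.

**Algebraic layer.** Every ordered pair (enzyme i, template j) can form a
complex $R_i\_R_j$ with Michaelis constant
$K_M[i,j] = (k_{off} + k_{cat})/k_{on}$. Under the Briggs–Haldane
quasi-steady-state approximation (QSSA) complexes equilibrate instantly on
the timescale of population change, so at each instant the $n^2$ complex
concentrations $c_l$ satisfy

$$K_M[i(l),j(l)]\, c_l = R^{free}_{i(l)}\, R^{free}_{j(l)}, \qquad
R^{free}_i = R_i - \sum_k (c_{ik} + c_{ki}) + c_{ii},$$

a nonlinear system indexed row-major ($l = (i-1)n + j$). The self-complex
correction $+c_{ii}$ prevents double-counting the complex that occupies both
slots of the same species.

**Differential layer.** Totals evolve by production rules: rule
$(e, t) \to p$ with yield $y$ contributes
$y\, k_{cat}[e,t]\, c_{e,t}\, \Pi$ to $dR_p/dt$, plus constant inflow
$\alpha_p$ and first-order decay $-d_p R_p$, with the habitat restriction
$\Pi = 1 - \frac1K \sum_i R_i/q_i$ multiplying all catalytic production (a
finite nucleotide pool of capacity $K$).

## Solving the complex system

`newton_solve()` implements a damped Newton iteration on the residual
$F_l = K_M c_l - R^{free}_i R^{free}_j$ with the analytic Jacobian assembled
from Kronecker-delta masks (`qssa_jacobian()`); the masks depend only on $n$
and are cached. The linear system $J\Delta = F$ is solved by dense LU —
mathematically the same as applying $J^{-1}$ but numerically safer. The
reference start is the complex-free state $c = 0$ (free = totals); the
integrator warm-starts from the previous step, and a test confirms warm and
cold starts agree.

Numerical choices, in decreasing order of consequence:

* **Root selection.** The system has multiple roots; only the branch with
  all free and all complex concentrations nonnegative is physical. The
  damping rule — halve the step (up to 30 times) whenever a full step would
  increase the residual norm or drive a free concentration negative — keeps
  the iterate in the feasible region, and feasibility is asserted on the
  returned solution. In the scalar case (total 2, $K_M = 1$, roots 1 and 4)
  the iteration lands on 1, the feasible root.
* **Tolerance.** Convergence is declared on $\max_l |F_l|$ at an absolute
  tolerance of $10^{-12}$ by default, with a floating-point floor of
  $64\,\varepsilon_{mach}\max(1, \max_i R_i)^2$: residual entries are
  differences of products of order $\max(R)^2$, which bounds the attainable
  absolute accuracy (during a parasite bloom totals reach $\sim 10^2$, where
  an absolute $10^{-12}$ would be below machine precision). The effective
  tolerance is recorded in the solve report; a report is never returned as
  converged above it.
* **Failure is explicit.** Non-convergence returns a report with the last
  residual; the integrator retries once from cold start and otherwise aborts
  with the failing time and state.

Two independent routes verify the solver: the tight-binding (Morrison)
closed form $c = \frac12(E+S+K_M) - \sqrt{\frac14(E+S+K_M)^2 - ES}$ for
instances where a single complex dominates, and `fixed_point_oracle()`, a
relaxed fixed-point iteration $c_l \leftarrow R^{free}_i R^{free}_j / K_M$
that shares no code path with Newton. Its relaxation factor starts at
$\min(0.5,\, 1/(1 + 4\max(R)/\min K_M))$ — tight binding needs heavy damping
— and halves on divergence or stall; convergence is linear, which is
acceptable for a test oracle. When comparing Newton against the one-complex
closed form, the suppressed complexes must actually be negligible at the
comparison tolerance: the tests keep the placeholder association rate at
$\varepsilon = 10^{-5}$ and raise the placeholder dissociation rate so the
suppressed complexes sit near $10^{-9}$, below the $10^{-8}$ agreement bound
(with the default $\eta = 0.1$ they sit near $10^{-4}$, which measures the
placeholder physics, not solver error).

## Time integration

The reference scheme is deliberately plain: explicit Euler with fixed
$\Delta t$, one converged Newton solve per step. Higher-order or adaptive
integrators would change the scheme being studied; the `model_rhs()`
contract (refusing unconverged complex states) permits adding them later.

* $\Delta t = 0.1$ by default. The fastest elementary rate in the presets is
  $k_{on} \le 0.2$, so $\Delta t \cdot k \approx 0.02 \ll 1$;
  `step_refinement_check()` confirms first-order self-convergence and the
  test suite verifies that halving $\Delta t$ moves the final totals of
  every preset by well under 1%.
* $\Pi$ is not clamped; a transient overshoot makes production negative,
  which is the formula as stated. Totals driven below zero by a step are
  clamped to zero; both event kinds are counted and reported once per run.
  None of the shipped presets triggers either.
* Inflow $\alpha$ is added outside $\Pi$: parasites drifting in from a
  neighbouring habitat are not limited by the local nucleotide pool.
* Everything is deterministic; repeated runs are bit-identical, and
  trajectory CSVs (10 significant digits) are byte-identical.

## Parameters and presets

All units are dimensionless. The shipped presets use the common parameters
$d_i = 0.005$, $K = 20$, host initials $(1, 1)$, placeholders
$\varepsilon = 10^{-5}$ (association) and $\eta = 0.1$ (dissociation) for
forbidden complexes — kept in the system at $K_M = \eta/\varepsilon = 10^4$
rather than removed, so the solver dimension is always $n^2$ and "forbidden"
is a limit, not a structural special case. Capacity weights are
$q_P = 5$ and $q_F = 10$: parasites and hyperparasites are successively
smaller molecules, so each copy consumes proportionally fewer resources, and
the weights *divide* the totals in $\Pi$. (The weight direction is a
genuinely open reading of the habitat formula; division matches the
smaller-molecules-cost-less rationale and the weights are ordinary config
fields, so the opposite convention is expressible by using $1/q$.)

Production rules are an explicit table rather than per-model code, so all
seven presets share one dynamics engine. Yields are stored symbolically —
`unit`, `one_minus_mu`, `mu`, `beta` — and resolved against the spec's
current $\mu$ and $\beta$; overriding $\mu$ therefore updates the routing
consistently (setting $\mu = 0,\ \alpha = 0$ in the parasite model
reproduces the host-cycle dynamics exactly, with P identically zero). The
mutation rate routes a fraction $\mu$ of each host replication event to the
parasite; the trigger $\beta = 1.5$ produces hyperparasites per polymerase
event on a parasite template. In the residual-catalysis variants
(3.0.1/3.0.2) the P_F and F_F complexes additionally produce F itself at
$k_{cat} = 0.04$ with unit yield and no mutation routing (the variants'
premise is that this catalysis is degenerating, not diversifying).

## Outcome classification

The dynamical regimes are qualitative; the classifier operationalizes them
with declared thresholds (all arguments of `classify_outcome()`):

* steady totals = mean over the final 10% of recorded samples;
* `parasite_collapse` if the summed host steady total falls below 5% of the
  host-cycle reference (an internally cached run of preset 1, scaled by the
  ratio of host initial loads);
* `fully_restored` if an explicit reference trajectory is supplied and the
  relative host gap is below 5%;
* `stabilized_parasites_prevalent` if hosts persist but a non-host species
  has the largest steady total; otherwise `sustained`.

The 5%/5%/10% numbers are operational choices, not measured constants; the
regime outcomes are robust to them in the presets (restoration gaps are
~4%, collapse leaves hosts at $10^{-7}$, prevalence margins are clear).

## Problem sizes and runtime

The test suite integrates every preset at its default horizon (1000 for the
host cycle, 5000 for the parasite models, 2000 for the hyperparasite
models, all at $\Delta t = 0.1$, i.e. $10^4$–$5\times10^4$ Newton solves per
run) plus a halved-step rerun of each for the convergence check; randomized
solver checks use 200 instances with $n \le 4$, totals in $[0,5]$ and $K_M$
in $[0.1, 10]$. The full suite runs in a few minutes on one CPU.

## Limitations

* Deterministic mean-field ODEs: no stochastic (Gillespie) fluctuations,
  which matter at low copy number and with dominant external inflow; no
  spatial structure or compartments.
* One intermediate complex per enzyme–template pair; no ternary complexes.
* No sequence-level evolution: "mutation" is a fixed-rate routing between
  predefined species, not an explored sequence space.
* The synthetic scenarios are parameterized to the regime of efficient
  ribozyme polymerases (catalytic rates ~0.1, $K_M$ ~ micromolar-like 0.1–1
  in model units); passing the regime tests shows the mechanism — parasite
  taming by tight-binding hyperparasites — operates there, not that real
  RNA habitats realize these rate constants.
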