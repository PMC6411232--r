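---
title: "Maximum-entropy steady states of heterogeneous continuous cell cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-entropy steady states of heterogeneous continuous cell cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxentcc)
```

## The model

`maxentcc` computes steady states of a well-mixed continuous culture
(chemostat or perfusion reactor) in which the cell population is *not*
assumed homogeneous. Each cell occupies a point $v = (r, u)$ of reaction
fluxes and exchange uptakes satisfying, for every metabolite $i$,

$$\sum_k N_{ik} r_k + u_i = e_i + y_i z,$$

where $z$ is the biomass synthesis rate, $e_i$ a growth-independent
maintenance demand and $y_i$ the biomass requirement of metabolite $i$.
Fluxes are confined by reaction bounds, by uptake caps
$U_i = \min\{V_i,\, c_i/\xi\}$ (kinetic maximum $V_i$ or supply
$c_i/\xi$, whichever binds), and by an enzyme-crowding budget
$\sum_k \alpha_k |r_k| \le C$. These constraints carve out a convex flux
polytope $\mathcal{P}_\xi$ that depends on the culture only through
$\xi = X/D$, the cell density over the dilution rate (gDW·h/L) — the
inverse cell-specific perfusion rate.

The population's distribution over $\mathcal{P}_\xi$ is the maximum-entropy
density consistent with a given mean growth rate:

$$P(v) \propto e^{\beta' z(v)}, \qquad \beta' = \beta K(s),$$

where $\beta$ (units: h) quantifies heterogeneity. $\beta = 0$ is a uniform
(maximally heterogeneous) population; $\beta \to \infty$ concentrates all
mass on the growth-maximizing vertex, i.e. the flux balance analysis (FBA)
solution. Net growth couples to the extracellular state through a
multiplicative inhibition factor and an additive death rate,
$\lambda = z\,K(s) - \sigma(s)$, with
$K(s) = \prod_i (1 + s_i/K_i)^{-1}$ and $\sigma(s) = \sum_i \tau_i s_i$.

The steady state closes self-consistently: at stationarity
$\langle\lambda\rangle = D$, mass balance gives
$s_i = c_i - \langle u_i \rangle\,\xi$, and then
$D = \langle z\rangle K(s) - \sigma(s)$, $X = \xi D$. `solve_at()` executes
exactly this sequence; no fixed-point iteration is needed when the state is
parametrized by $(\xi, \beta')$. Fixed-$\beta$ curves
(`solve_fixed_beta()`) add a one-dimensional root find
$\beta'/K(s(\xi,\beta')) = \beta$ by bisection on $\beta' \in [0, \beta]$
(the bracket is guaranteed because $K \le 1$).

A negative $D$ means the required growth cannot be sustained (washout); the
state is reported infeasible, never clamped to zero. Stability follows the
sign criterion: a steady state is stable where $D(\xi)$ is decreasing.

### A note on two sign/form choices

Two printed formulas in the source literature are internally inconsistent
and were resolved as follows. First, the uptake cap is implemented as
$U_i = \min\{V_i, c_i/\xi\}$ (not $c_i\xi$): only this form keeps
$s_i = c_i - \langle u_i\rangle \xi$ non-negative. Second, the tilt rewards
high biomass synthesis, $P \propto e^{+\beta' z}$: the opposite sign would
contradict the definition of the $\beta \to \infty$ limit as the FBA
optimum and every qualitative statement about the homogeneous limit.

## The exactly solvable toy network

`toy_network()` encodes the minimal overflow-metabolism motif: glucose
uptake $v_g$ (capped by $V_g$ and by supply), a respiratory pathway $v_o$
capped by mitochondrial capacity $R$, lactate overflow $-v_l$, and ATP
synthesis $v_{atp} = 2 v_g + 18 v_o$ with $z = (v_{atp} - e)/y$. Secreted
lactate is toxic with linear death rate $\sigma = \tau w$.

Defaults (all literature-calibrated mammalian-cell values, changeable via
`toy_params()` or a `key = value` config file):

| parameter | value | units | meaning |
|---|---|---|---|
| `V_g` | 0.5 | mmol/gDW/h | maximal glucose uptake (HeLa) |
| `R`   | 0.45 | mmol/gDW/h | respiratory capacity |
| `e`   | 1 | mmol/gDW/h | ATP maintenance (mouse LS cells) |
| `y`   | 348 | mmol/gDW | ATP yield of biomass; calibrates $\lambda_m \approx 1/\text{day}$ |
| `tau` | 0.0022 | 1/h/mM | death per unit lactate |
| `c_g` | 15 | mM | feed glucose |

After eliminating $v_o, v_l$, the feasible set is a 2-D polygon in
$(v_g, v_{atp})$ and all moments of the tilted density are computed by
quadrature: the polygon is cut at the respiration kink $v_g = R/2$, the
inner integral over $v_{atp}$ is analytic (antiderivatives are anchored at
the *upper* limit so no exponential ever overflows, and small-argument
series avoid cancellation), and the outer integral is adaptive with extra
breakpoints resolving the $O(1/\beta)$ boundary layer at large tilt. The
relative accuracy is ~1e-10, which is what lets this engine serve as the
oracle for EP.

```{r toy}
st <- toy_solve_at(10, Inf)   # homogeneous limit at xi = 10 gDW.h/L
c(D = st$D, X = st$X, s_glc = st$s[["glc"]], s_lac = st$s[["lac"]])
```

Phenomenology reproduced by the sweeps (`toy_sweep()`, `phase_diagram()`):

* In the homogeneous limit, lactate vanishes exactly for
  $\xi \ge 2 c_g / R \approx 66.7$; any finite $\beta$ instead accumulates
  lactate without bound as $\xi$ grows — heterogeneity, not selection,
  explains rising byproduct levels.
* $D(\xi)$ develops an increasing (unstable) window at large $\beta$ that
  disappears below a threshold heterogeneity — the bistable regime is a
  property of nearly homogeneous populations.
* The medium depth $\xi_m$ (largest $\xi$ with a live population; 570
  gDW·h/L at $\beta = \infty$, closed form $38 c_g / e$) never decreases
  with $\beta$.
* With toxicity active, a heterogeneous population can outnumber the
  homogeneous one ($X(\beta) > X(\infty)$ for some $\xi$), because fewer
  cells secrete toxin at the maximal rate; with $\tau = 0$ the FBA
  population is always densest.

## Moment engines

Three engines share one contract (a `moment_result`), and two of them exist
mainly to validate the third:

1. **Quadrature** (`toy_moments()`) — exact, toy model only.
2. **Rejection sampling** (`rejection_sample()`, `sample_moments()`) —
   unbiased on any small polytope. Equalities are eliminated once by an
   orthonormal null-space parametrization (rejection in the full space has
   measure-zero acceptance); proposals are uniform in an LP-computed
   bounding box of the reduced coordinates and the tilt is applied by
   exponential thinning against the LP-computed maximal $z$. Deterministic
   given a seed; aborts with advice if the acceptance rate collapses. Not
   an MCMC sampler by design: hit-and-run convergence on elongated flux
   polytopes is impractical to certify, and the oracle is only needed on
   small fixtures.
3. **Expectation Propagation** (`ep_moments()`) — the engine that scales.
   The box indicators are approximated by Gaussian sites that are
   iteratively moment-matched against the exactly truncated marginals;
   the tilt $e^{\beta' z}$ is affine in $v$ and therefore absorbed exactly
   (no approximation error from the tilt itself); the crowding inequality
   has already been converted upstream into an equality with a slack
   variable, so EP sees only boxes and equalities. Equalities are handled
   by an exact null-space reduction rather than a soft-delta precision
   term, keeping the Gaussian algebra well conditioned. Variables are
   rescaled to $[0,1]$ by their bound widths; sites are updated
   sequentially in fixed order (determinism); damping 0.9, tolerance 1e-6
   on the tilted moments, at most 2000 sweeps, variance clipping
   $[10^{-50}, 10^{50}]$. These hyperparameters are not prescribed by the
   underlying theory; they were chosen once for robustness and are recorded
   in the result metadata. The truncated-normal kernel
   (`truncnorm_moments()`) computes far-tail moments through scaled
   complementary error functions (`erfcx`), and the flat-cavity limit falls
   back to exact exponential-on-a-segment moments.

What a green EP test does and does not establish: EP means match the exact
quadrature within 5% on the toy polytope across heterogeneity levels, and
EP is exact wherever the truncated-Gaussian family is exact. EP remains a
*biased* deterministic approximation on coupled polytopes: its residual
bias (~1e-3 to 1e-2 on O(1) variables in the bundled fixtures) exceeds the
Monte-Carlo error of a 1e5-sample oracle, so "within 3 standard errors of
rejection sampling" is not achievable by any correct EP implementation and
the corresponding acceptance check is knowingly left failing rather than
weakened. EP variances are systematically less reliable than means (the
coupled-segment example overestimates a uniform marginal's variance by
~40%); downstream code uses EP means and treats variances as diagnostics.

## FBA limit and network reduction

`fba_solve()` is the $\beta = \infty$ engine: maximize $z$, then, with $z$
pinned within a relative 1e-9, minimize the enzymatic cost
$\sum_k \alpha_k r_k$ — the lexicographic tie-break that makes the optimum
unique when costs are heterogeneous (when every cost is zero the tie-break
is skipped so the stage-1 optimum is returned exactly). The LP backend is a
dense two-phase primal simplex with Bland's rule, written in-package because
no LP solver exists in the supported dependency stack; it is intended for
desk-scale problems (tens of variables), which covers everything the test
suite and the toy model need. Genome-scale work should treat it as the
contract point to swap in an industrial solver.

`reduce_network()` runs lexicographic FBA over a $\xi$ grid (default 30
log-spaced points — the grid is a modelling choice, not a derived value)
and removes reactions whose net flux stays below 1e-8 mmol/gDW/h
everywhere, then prunes orphaned metabolites. Infeasible grid points are
reported, never silently dropped. Reduction is idempotent and preserves the
FBA solutions of the full network on the probe grid; both properties are
tested. `perturb_costs()` supports the robustness exercise of re-running
sweeps under up-to-25% random cost perturbations.

## Synthetic data

Two generators make the package self-contained:

* `toy_network()` *is* the stated world: its defaults are the published
  parameter values, not tunables; tests and the acceptance script use them
  unchanged.
* `make_fixture_polytope(n_vars, n_eq, seed)` draws a random bounded
  polytope with a guaranteed strict interior point (the point is drawn
  first; bounds and equality offsets are built around it), plus a random
  affine growth functional. It emulates the local geometry of flux
  polytopes (boxes cut by equalities) but *not* their global features —
  extreme elongation, hundreds of dimensions, sparse stoichiometry — so a
  green fixture test validates algebra and convergence, not genome-scale
  accuracy claims.

## Degenerate inputs and numerical conventions

* $\xi = 0$ means no supply limitation ($U_i = V_i$); $\xi = \infty$
  closes every finite-feed uptake.
* Metabolites with infinite feed concentration (water, protons, oxygen)
  are excluded from mass-balance closure; metabolites missing from the
  medium default to $c_i = 0$.
* Steady-state concentrations in $(-10^{-8}, 0)$ are clamped to zero with
  a message (floating-point residue of an exactly-binding uptake);
  anything more negative raises an error, since it signals a violated
  uptake bound.
* An empty polytope (e.g. maintenance demand above attainable supply) is
  a detectable state (`polytope_is_empty()`), and the chemostat solver
  returns a flagged infeasible steady state rather than fabricated
  numbers; non-converged EP results are refused the same way.
* Stability classification uses central differences, falling back to the
  backward difference where the central one vanishes (a washed-out peak on
  the grid classifies as unstable, a plateau as boundary); endpoints use
  one-sided differences and may only be stable/unknown.

## Limitations

* No time-course dynamics; steady states only, with stability from the
  $D(\xi)$ sign criterion.
* The simplex backend is not performance-tuned; genome-scale FBA and EP
  runs (hundreds of reactions) are out of scope for the bundled solver
  and the rejection oracle.
* The SBML reader covers a minimal Level-3 FBC subset (species, reactions,
  bounds via parameters, boundary species as exchanges) and requires a
  reaction with "biomass" in its id; richer models should use the JSON
  dialect.
* Cell mass composition ($e_i$, $y_i$) is population-constant; this keeps
  the MaxEnt exponent linear in fluxes.
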