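---
title: "Rumour scotching: models, asymptotics and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rumour scotching: models, asymptotics and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumourscotch)
```

## The model

A population of `n` agents occupies three states: ignorant (has not heard
the rumour), spreader (transmits it) and stifler (actively suppresses,
or *scotches*, it). Two pairwise mechanisms drive the dynamics:

* a spreader informs an ignorant contact at rate $\lambda$ (the ignorant
  becomes a spreader);
* a stifler scotches a spreader contact at rate $\alpha$ (the spreader
  becomes a stifler).

Unlike the classical Maki–Thompson (MT) rumour dynamic — where a spreader
gives up after meeting anyone already informed — stiflers here are
*active*: suppression is a competition between the informed camps. States
only ever move $0 \to 1 \to 2$, so the stifler class absorbs and the
process ends at the absorption time $\tau^{(n)}$, the first time no
spreaders remain. With counts $(X, Y, Z)$, $X+Y+Z = n$, the
continuous-time Markov chain on the complete graph jumps

$$(X, Y) \to (X-1,\, Y+1) \text{ at rate } \lambda X Y, \qquad
  (X, Y) \to (X,\, Y-1) \text{ at rate } \alpha Y (n - X - Y).$$

Everything downstream is parameterised by the ratio
$\rho = \alpha/\lambda$ and the initial fractions $(x_0, y_0, z_0)$,
which must satisfy $x_0 > 0$ and $z_0 > 0$ (without initial stiflers
nothing can ever be scotched; `make_init()` enforces this). $y_0 = 0$ is
allowed and produces a genuine case split below.

## Deterministic limits

Rescaled by $n$, the trajectories converge to the mean-field system

$$x' = -\lambda x y, \qquad y' = \lambda x y - \alpha y z, \qquad
  z' = \alpha y z,$$

integrated by `solve_mean_field()`. A random time change (run the clock
at speed $1/Y$) turns the chain into a *density-dependent* family whose
limit is linear:

$$x' = -\lambda x, \qquad y' = (\lambda + \alpha)x + \alpha y - \alpha,$$

with the closed-form solution $x(t) = x_0 e^{-\lambda t}$,
$y(t) = f(x(t))$ where

$$f(x) = 1 - z_0\left(\frac{x_0}{x}\right)^{\rho} - x,
  \qquad x \in (0, x_0].$$

`solve_transformed()` integrates this system numerically and
`closed_form_xy()` evaluates the exact solution; their agreement on
random parameter draws is one of the package's standing oracle tests.
The power term in `f_eval()` is computed in log space,
$\exp(\rho(\log x_0 - \log x))$, so that tiny $x$ with large $\rho$
cannot overflow.

## Final-size asymptotics

The time change preserves the terminal state, so the final count
behaviour follows from where $y(t) = f(x(t))$ hits zero.

* **Law of large numbers.** $X(\tau^{(n)})/n \to x_\infty$, the root of
  $f(x) = 0$ in $(0, x_0]$ (`final_ignorant_fraction()`). When
  $y_0 > 0$ the root is interior. When $y_0 = 0$, $x_0$ is itself a
  root: if $x_0 > \rho z_0$ the process still takes off ($y'(0) > 0$)
  and the relevant root lies strictly below $x_0$; if
  $x_0 \le \rho z_0$ the process dies immediately and
  $x_\infty = x_0$, $\tau_\infty = 0$ (`case = "immediate_death"`).
* **Absorption time.** $\tau_\infty = -\lambda^{-1}\log(x_\infty/x_0)$
  (`extinction_time()`), cross-checked against the event-located zero
  crossing of the integrated transformed system.
* **Central limit theorem.** Under $y_0 > 0$, or $y_0 = 0$ with
  $\rho < x_0/z_0$,
  $\sqrt{n}\,(X(\tau^{(n)})/n - x_\infty) \Rightarrow N(0, \sigma^2)$
  with the closed-form variance implemented in `clt_variance()`:
  $$\sigma^2 = \frac{x_\infty z_\infty\left[x_0 x_\infty (1 - z_0 -
  x_\infty) + z_0 \rho^2 z_\infty (x_0 - x_\infty)\right]}
  {x_0 z_0 \left[\rho - x_\infty(\rho + 1)\right]^2},
  \quad z_\infty = 1 - x_\infty.$$

Because this formula is easy to mis-transcribe, the package carries an
independent derivation as a permanent cross-check.
`covariance_matrix()` evaluates the Gaussian fluctuation covariance
$\int_0^{\tau_\infty} \Phi\, G\, \Phi^{\mathsf T}\, ds$ by adaptive
quadrature along the closed-form path, with the diffusion matrix
$G = \begin{pmatrix}\lambda x & -\lambda x\\ -\lambda x &
(\lambda-\alpha)x - \alpha y + \alpha\end{pmatrix}$ assembled from the
two jump directions and $\Phi(t,s) = e^{A(t-s)}$ for the constant drift
Jacobian $A = \begin{pmatrix}-\lambda & 0\\ \lambda+\alpha &
\alpha\end{pmatrix}$, whose entries are used in closed form.
`clt_variance_from_covariance()` then applies the hitting-time delta
method: the limiting fluctuation is
$V_x(\tau_\infty) + c\,V_y(\tau_\infty)$ with
$c = -x'(\tau_\infty)/y'(\tau_\infty)
   = x_\infty / ((1+\rho)x_\infty - \rho)$,
so $\sigma^2 = C_{11} + 2c\,C_{12} + c^2 C_{22}$. The two routes agree
to better than $10^{-6}$ across random parameter draws (tested), which
pins down the intended reading of the printed formula. Only the
$(1,1)$ entry of the printed closed-form covariance matrix,
$x_\infty - x_\infty^2/x_0$, is asserted directly; the remaining
entries are validated implicitly through this combination.

```{r}
params <- make_params(0.5, 0.5)
init <- make_init(0.98, 0.01, 0.01)
asymptotic_summary(params, init, n = 1e4)
```

### Numerical choices

Root finding for $x_\infty$ works in the log variable
$u = \log(x_0/x)$, where $g(u) = 1 - z_0 e^{\rho u} - x_0 e^{-u}$ and
the upper bracket end is grown geometrically until the sign changes.
This matters: for small $\rho$ the root is of order
$x_0\, z_0^{1/\rho}$, far below any fixed bracket on the $x$ scale
(at $\rho = 0.1$, $z_0 = 0.01$ it is around $10^{-20}$), yet perfectly
conditioned in $u$. With $\alpha = 0$ and $y_0 > 0$ the equation
$f(x) = 0$ has no root in $(0, x_0]$ — every ignorant is eventually
informed — and the search reports the missing sign change rather than
fabricating a value. The ODE integrators run at `rtol = 1e-8`,
`atol = 1e-10` (the systems are non-stiff throughout the parameter
ranges of interest); "end of the process" states are event-located at
$y < 10^{-8}$ rather than read off a fixed horizon. All tolerances live
in one place, `rumour_control()`.

## Networks and node-level equations

On a fixed graph with adjacency $A$ and degrees $k$, the quenched
mean-field (QMF) approximation tracks per-node probabilities
$(x_i, y_i, z_i)$ with contact weights $P_{ji} = A_{ji}/k_j$
(`contact_weights()`, row-stochastic over neighbours):

$$x_i' = -\lambda x_i \textstyle\sum_j P_{ji} y_j, \qquad
  z_i' = \alpha y_i \textstyle\sum_j P_{ji} z_j,$$

implemented sparsely in `solve_scotching_qmf()` (cost per derivative
evaluation proportional to the edge count). The MT comparison model
(`solve_mt_qmf()`) replaces the scotching term by
$\alpha y_i \sum_j P_{ij}(x_j + z_j)$ — note the *outgoing* index order
$P_{ij}$, kept verbatim from the model definition. Since
$P_{ij} \ne P_{ji}$ on irregular graphs the choice is observable, so a
`mt_index_order = "flipped"` switch exposes the alternative for
sensitivity analysis.

On a complete graph all nodes are exchangeable and
$\sum_j P_{ji} y_j = y$ exactly, so the QMF system collapses to the
homogeneous equations; the aggregate agrees with `solve_mean_field()`
to well within the $2/n$ tolerance used in the tests.

Generators: `gen_complete()`, `gen_er()` (Bernoulli pairs),
`gen_ba()` (preferential attachment from an m-clique; tail exponent
near 3), `gen_regular()` (stub matching), and `gen_powerlaw_config()`.
The last is implemented in-package: degrees sampled from
$P(k) \propto k^{-\gamma}$ on $[k_{\min}, \sqrt{n}]$ — the structural
cutoff that suppresses degree correlations in uncorrelated
configuration models — the degree sum forced even by redrawing one
entry, then uniform stub matching with rejection of self-loops and
multi-edges (offending stubs re-shuffled among themselves for up to 100
rounds, then dropped). This sampler is a reasonable stand-in for any
uncorrelated sampler with the target degree law, not a reconstruction
of one specific published algorithm; `powerlaw_kmin_for_mean()` picks
$k_{\min}$ to match a target mean degree across $\gamma$ values.

## Stochastic simulation

Two engines with deliberately distinct contracts:

* `gillespie_complete()` — the exact chain on aggregate counts;
  $\lambda, \alpha$ are *rates* and may take any positive value.
  Implemented in C++; 1000 replicates at $n = 10^4$ run in about a
  second. When $\alpha = 0$ the total rate can vanish with spreaders
  standing ($X = Z = 0$); the run terminates and is flagged
  non-absorbed.
* `run_network_mc()` — the discrete asynchronous contact scheme on an
  arbitrary graph; $\lambda, \alpha$ are *per-trial success
  probabilities* and must lie in $[0, 1]$. Per step, the nodes active
  at step start (spreaders and stiflers) are visited in a fresh uniform
  shuffle; each acts according to its current state — so a node
  converted earlier in the same step acts in its new role — contacts
  one uniformly chosen neighbour, and conversions apply immediately.
  "Sequential asynchronous" admits several readings; this snapshot +
  immediate-update reading is the most common one and is isolated in a
  single scheduler loop so it can be audited or changed in one place.
  A complete graph can be requested via `complete_n` without
  materialising $O(n^2)$ edges.

Seeding strategies (`seed_states()`): `uniform` random placement with
exact counts from `counts_from_fractions()` (counts are fixed and
placement random — the natural reading of "random initial conditions"
at stated fractions), or hubs forced to be the spreaders
(`hub_spreaders`) or the stiflers (`hub_stiflers`), ties broken by node
id. Replication (`run_batch()`, `batch_gillespie()`,
`batch_network_mc()`) gives replicate $r$ the seed `base_seed + r` and
its own RNG stream, so batches are reproducible and order-independent.

### What the discrete scheme does and does not reproduce

With small per-trial probabilities the discrete scheme approaches the
continuous-time dynamics: on random regular graphs with
$\lambda' = \lambda/k$, $\alpha' = \alpha/k$ the mean final size is
statistically indistinguishable from the rate-$(\lambda, \alpha)$
homogeneous prediction by $k \approx 100$, with a small deficit
(under $0.002$ in absolute terms at $k = 20$, $n = 2000$) on sparser
graphs where local correlations bite. At large per-trial probabilities
the discretisation itself is visible: on the complete graph with
$\lambda = \alpha = 0.5$ the discrete scheme's final-size mean sits a
few theoretical standard deviations above $x_\infty$. For exact
distributional statements (KS tests against the CLT) the package
therefore uses the Gillespie engine, and the discrete scheme is used
where it is the object of study: relative comparisons across network
topologies and seeding strategies, where its bias is common to both
arms.

## Experiment drivers and scale choices

`clt_check()` (KS against $N(x_\infty, \sigma^2/n)$),
`phase_diagram()` (final size over the $(\lambda, \alpha)$ grid, by
default $0.05, 0.10, \ldots, 1$ in both rates),
`compare_sim_vs_qmf()` (Monte Carlo aggregates versus the QMF solution
on a common step grid, one MC step = one time unit, early-absorbed
replicates carried forward at their final state), and
`er_ba_final_distribution()` (matched ER/BA final-size samples with the
homogeneous Gaussian overlay).

The reference studies behind the defaults use $n = 10^4$ with up to
1000 replicates and $\langle k \rangle \approx 100$; the package's test
and acceptance configurations run the distributional checks at
$n = 10^4$ (Gillespie; cheap) and the network comparisons at
$n = 10^3$ with 20–200 replicates, sizes chosen so the full suite runs
in about a minute on a laptop while every qualitative ordering remains
well resolved. All stochastic tests fix their seeds, so failures are
diagnostic rather than flaky.

The synthetic graphs emulate the degree structure of the study systems
(Poissonian ER, $\gamma \approx 3$ preferential attachment, tunable-
$\gamma$ uncorrelated configuration models). They do not contain
triangles-enriched clustering, assortativity, communities or temporal
rewiring, so agreement on these graphs says nothing about such
features; the QMF equations additionally assume independence across
node states, which Monte Carlo does not.

## Known limitations

* The CLT machinery is undefined on the boundary
  $\rho = x_\infty(\rho+1)$ of its hypotheses and errors out there.
* The discrete network scheme is not an exact discretisation of the
  CTMC; see above for where that matters.
* No heterogeneous-mean-field (degree-class) equations, pair
  approximations, correlated/weighted/directed/temporal graphs, or
  time-varying rates.
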