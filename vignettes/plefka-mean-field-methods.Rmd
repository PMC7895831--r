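---
title: "Mean-field methods for asymmetric kinetic Ising models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean-field methods for asymmetric kinetic Ising models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kineticIsing)
```

## The model and its statistics

A kinetic Ising model is a parallel-update Markov chain of $N$ spins
$s_i \in \{-1,+1\}$ with conditionally independent unit updates,

$$P(\mathbf{s}_t \mid \mathbf{s}_{t-1}) =
  \prod_i \frac{e^{s_{i,t} h_{i,t}}}{2\cosh h_{i,t}}, \qquad
  h_{i,t} = H_i + \sum_j J_{ij}\, s_{j,t-1}.$$

Asymmetric couplings ($J_{ij} \neq J_{ji}$) make the chain irreversible:
the stationary state is a genuinely non-equilibrium one with positive
entropy production. The package tracks three statistics per time step —
activation rates $m_{i,t}$, equal-time covariances $C_{ik,t}$ and lag-one
delayed covariances $D_{il,t}$. For $\pm 1$ spins $C_{ii} = 1 - m_i^2$ is
an identity, so all approximations define off-diagonal entries only and
the package fills the diagonal with $1 - m^2$ throughout. $(m, D)$ are the
sufficient statistics of the model, which is why they drive inference;
$C$ is carried along because it is what neural-data analyses usually
report, and because two of the approximations consume $C_{t-1}$ as input.

All mean-field updates here arise from the same construction: choose a
tractable reference family (independent spins, or a two-spin model that
keeps one coupling), project the intractable marginal onto it by matching
moments (the m-projection, which preserves the moments spanned by the
family), and expand around the projection point to first or second order
in an interpolation parameter that switches the couplings on. Only the
endpoint equations are runtime code; the expansion itself is derivation
scaffolding.

## The one-step updates

**Independent reference at both times (`nmf_step`, `tap_step`).** First
order gives the classical naive mean field
$m_i = \tanh[H_i + \sum_j J_{ij} m_{j,t-1}]$ with
$D_{il} = J_{il}(1-m_i^2)(1-m_{l,t-1}^2)$ and no equal-time correlations.
Second order adds the Onsager reaction term inside the tanh,
$-\,m_i \sum_j J_{ij}^2 (1 - m_{j,t-1}^2)$, making the rate equation
self-consistent, and produces quadratic-in-$J$ expressions for $C$ and a
$(1 + 2 J_{il} m_i m_{l,t-1})$ correction to $D$.

**Independent reference at time $t$ only (`plefka_t_first`,
`plefka_t_second`).** Treating the previous-step distribution as known,
the updates become functions of $C_{t-1}$:
$D_{il} = (1-m_i^2)\sum_j J_{ij} C_{jl,t-1}$ at first order, and at
second order a rate correction $-m_i \sum_{jl} J_{ij} J_{il} C_{jl,t-1}$,
$C_{ik} = (1-m_i^2)(1-m_k^2) \sum_{jl} J_{ij} J_{kl} C_{jl,t-1}$, and the
same $(1 + 2Jmm)$ factor on $D$. Substituting the independent-model
covariance $C_{t-1} = \mathrm{diag}(1 - m_{t-1}^2)$ recovers TAP exactly —
a reduction identity the test suite asserts to ten digits.

**Gaussian effective fields (`plefka_tm1_step`).** With independence
assumed only at $t-1$, the local field $h_i$ is a sum of many weakly
dependent terms and is treated as Gaussian with mean
$g_i = H_i + \sum_j J_{ij} m_{j,t-1}$, variance
$\Delta_i = \sum_j J_{ij}^2(1 - m_{j,t-1}^2)$, and pair correlation
$\rho_{ik} \propto \sum_j J_{ij} J_{kj} (1 - m_{j,t-1}^2)$. Rates are
univariate Gaussian expectations of $\tanh$, equal-time covariances are
bivariate expectations under the correlated measure, and
$D_{il} = \big(\sum_j J_{ij} C_{jl,t-1}\big)\,
\langle 1 - \tanh^2 \rangle$. The printed form of the bivariate integrand
indexes one variance and the correlation denominator by $j$ where the pair
index $k$ is evidently meant; this package reads both as $\Delta_k$, which
is the only reading that leaves $C$ symmetric. The second-order variant of
this expansion is deliberately not implemented: its cost is far above the
other methods for modest accuracy gain.

**Pairwise reference (`plefka2_delayed`, `plefka2_equal_time`).** The
novel member of the family keeps one coupling in the reference model. For
the delayed pair $(s_{i,t}, s_{l,t-1})$ the active unit's parameter
$\theta^*_i(s)$ is solved separately for the conditioning spin at $\pm 1$
from

$$\theta^*_i(s) = H_i + \sum_j J_{ij} m_{j,t-1}
  + \Big(J_{il} + \sum_{j \neq l,\, n} J_{ij} J_{ln} D_{jn,t-1}\Big)
    (s - m_{l,t-1})
  - \tanh\theta^*_i(s) \sum_{j, n \neq l} J_{ij} J_{in} C_{jn,t-1},$$

while the conditioning unit keeps an independent parameter $\Theta^*_l$
given by the TAP-type equation one step back. The two-spin reference then
yields $m_{i,t}$ and $D_{il,t}$ directly; the equal-time analogue
conditions $s_{i,t}$ on $s_{k,t}$ and yields $C_{ik,t}$. Index ranges in
the double sums are typographically ambiguous in their printed source; we
read the variance correction as excluding the conditioned unit from *both*
indices and the $D$-mediated term as excluding it from the first index
only. This is recorded as an interpretation; the reduction and
convergence-order tests pass under it (the alternative readings change
results at the same order as the truncation error).

Two aggregation choices were genuinely open:

* Each pair $(i, l)$ produces its own estimate of $m_{i,t}$. The rollout
  propagates the average across conditioning units $l$ — symmetric, and
  identical to the common value whenever the pair estimates agree (they
  do exactly at $J = 0$; the maximum spread is returned as a diagnostic).
* $C_{ik}$ and $C_{ki}$ come from different conditionings; the returned
  matrix is their average, hence exactly symmetric.

At the first rollout step the conditioning parameter is
$\Theta^* = \mathrm{artanh}(m_0)$ (clamped at $|m| \le 1 - 10^{-12}$),
exact when the initial state is an independent distribution with known
rates — in particular for the deterministic all-ones start
($m_0 = \mathbf{1}$, $C_0 = D_0 = 0$) used by the forward experiments.

## Numerical choices

* **Self-consistent solves.** Every implicit equation above is an instance
  of $x = a - b\tanh x$, strictly monotone for $b > -1$ with the unique
  root bracketed by $a \pm |b|$. The solver iterates the plain fixed point
  (contraction factor $\le |b|$; at SK coupling scales $b = O(J^2 N)$ is
  small), retries with damping $0.5$, and falls back to elementwise
  bisection, which always terminates. Default residual tolerance
  $10^{-12}$, 200 iterations per stage. Newton steps are unnecessary at
  these coupling scales.
* **Quadrature.** Gaussian expectations use Gauss–Hermite rules (default
  40 nodes) — the integrands are smooth bounded functions of a Gaussian
  variable, for which the rule converges geometrically; doubling the node
  count moves results by less than $10^{-8}$ at ensemble scales.
  Bivariate integrals condition $y$ on $x$ ($y = \rho x +
  \sqrt{1-\rho^2}\,y'$) over the tensor grid; $\rho$ is clipped to
  $[-1+10^{-12},\, 1-10^{-12}]$ because rounding can push $|\rho|$
  marginally past one. Zero-variance fields take an exact point-mass
  branch rather than quadrature.
* **Enumeration oracle.** Exact propagation, moments, the stationary
  distribution and the path-KL entropy production are available for small
  $N$ via full state enumeration with a fixed little-endian encoding (the
  0-based state index carries unit $i$ at bit $i-1$). The transition
  matrix ($4^N$ doubles) is guarded at $N \le 12$, keeping memory under
  about a gigabyte; forward propagation alone runs matrix-free to
  $N \le 16$. Every approximation module is validated against this oracle,
  including a convergence-order test: scaling the couplings by
  $\varepsilon$, first-order truncations approach enumeration as
  $O(\varepsilon^2)$ and second-order ones as $O(\varepsilon^3)$
  (log–log slopes near 2 and 3).

## Inverse problem

Learning maximizes the log-likelihood
$\ell = \sum_{t,r,i} (S_{i,t} h_{i,t} - \log 2\cosh h_{i,t})$ by gradient
ascent on the moment mismatches $\langle S_i \rangle - m_i$ and
$\langle S_i S_{l,\mathrm{prev}}\rangle - (D_{il} + m_i \tilde m_l)$,
pooled over trials *and* time steps (stationary parameters; no per-step
fields). The model moments come either from the exact conditional average
over the pooled empirical distribution — stored as unique previous states
with weights, so the per-iteration cost is the number of distinct states,
not $RT$ — or from a single mean-field evaluation at the empirical
previous-step moments $(\tilde m, \tilde C)$ (plus the empirical lag
covariance for the pairwise method). Effective step sizes are $0.1$ on the
field mismatch and $1/\sqrt N$ on the coupling mismatch, from
$\mathbf{H} = \mathbf{J} = 0$. The stopping rule — max-norm of the
mismatch below $10^{-6}$, capped at $10^4$ iterations — is this package's
choice; the underlying scheme fixes only the step sizes.

A practical note the comparison experiments make vivid: the TAP delayed
covariance depends on the empirical covariance only through its diagonal,
so its coupling gradients carry an $O(J)$ bias wherever the data are
correlated, while the $C$-aware estimators (`plefka_t2`, `plefka_tm1`,
`plefka2_t`) deviate from the exact gradient only at $O(J^2)$. This is
exactly the large-$\epsilon_J$ offset of the classical method near
criticality.

## Stationary theory and the critical point

For the asymmetric SK ensemble — fields uniform on $[-\beta H_0, \beta
H_0]$, couplings Gaussian with mean $\beta J_0/N$ and variance
$\beta^2 J_\sigma^2/N$, no symmetry — the thermodynamic-limit stationary
state follows from the Gaussian effective-field picture. A unit's field
has mean $H + \beta J_0 \bar m$ and two Gaussian components: a *quenched*
one of variance $\beta^2 J_\sigma^2 q$ (frozen coupling disorder acting on
magnetized units, $q = \langle m_i^2 \rangle$) and a *dynamic* one of
variance $\beta^2 J_\sigma^2 (1 - q)$ (fluctuating presynaptic spins).
`stationary_mf()` solves the coupled $(\bar m, q)$ equations by damped
fixed point with nested Gauss–Legendre (64 nodes over the field disorder)
and Gauss–Hermite integration — fully deterministic, no disorder
sampling.

At $\bar m = 0$ the two variances sum to $\beta^2 J_\sigma^2$ regardless
of $q$, so the stability condition of the paramagnetic solution closes
without the $q$ equation:

$$\beta J_0 \,\big\langle \textstyle\int \mathrm{D}w\,
  \mathrm{sech}^2(H + \beta J_\sigma w) \big\rangle_H = 1 .$$

`critical_beta()` brackets this in $\beta$. Including the quenched
component is essential: dropping it (using the dynamic variance alone)
shifts the root from $1.1108$ to $1.1096$ at the default parameters. The
disorder-free, noise-free limit reduces to the Curie–Weiss condition
$\beta J_0 = 1$ exactly, and the critical temperature grows monotonically
with field disorder — both asserted in the tests.

Entropy production uses the steady-state identity
$\sigma = \sum_{ij} (J_{ij} - J_{ji}) D_{ij}$, which
`entropy_production_exact()` verifies against the symmetrized path-KL form
on the exact stationary joint to $10^{-8}$. The identity presumes a
steady-state $D$; callers pass a rollout tail or the exact stationary
value, not a transient $D_t$.

## The synthetic ensemble: what it does and does not emulate

`sample_sk()` *is* the study condition, not a tuning knob: uniform fields
with $H_0 = 0.5$, Gaussian couplings with $J_0 = 1$, $J_\sigma = 0.1$,
diagonal included (nothing in the ensemble definition excludes
self-couplings; a flag zeroes them for sensitivity checks), and $\beta$
multiplying both parameter sets so that one unit-$\beta$ draw rescaled by
`rescale_model()` shares its disorder across a whole temperature scan.
This emulates a densely, weakly, asymmetrically coupled random network
poised near a ferromagnetic transition — the regime where mean-field
methods are most stressed. It does not emulate real neural recordings:
no refractoriness, no common input or nonstationary drive, no heavy-tailed
degree structure, and couplings of order $1/N$ rather than sparse strong
synapses. Tests passing on this ensemble certify the approximations'
internal correctness and their relative ordering near criticality, not
performance on any particular dataset.

## Problem sizes and a finite-size caveat

The package's standard experiment sizes are $N = 64$, $T = 128$,
$R = 10^4$ trials for sampled ground truth, with enumeration-based checks
at $N \le 8$ and $10^2$-instance averages at $N = 4$; these run the full
comparison suite in minutes on one core while leaving the method ordering
(pairwise best on $C$ and $D$ near $\beta_c$; classical TAP gradients
visibly biased in $\epsilon_J$) cleanly resolved. A preset-scale
replication ($N = 512$, $R = 10^6$, 21 temperatures) is a matter of
passing larger arguments to the same functions.

One finite-size effect deserves flagging. The across-trial covariance at
the final step of an all-ones start develops a second, spurious maximum
above $\beta_c$ at $N = 64$: realizations whose summed fields oppose the
initial branch let a fraction of trials escape to the opposite
magnetization branch within 128 steps, and a mixed branch population
inflates every pairwise covariance (a bimodality term of order
$f(1-f)(2\bar m)^2$). The escape barrier grows with $N$, so the effect is
absent at $N = 512$ but displaces or widens the apparent fluctuation peak
at desk scale; with the package's standard scan (13 temperatures spanning
$[0.7, 1.3]\,\beta_c$) the sampled peak localizes only to about one grid
step around $\beta_c$, and single realizations scatter further. The
entropy-production maximum is less affected. Disorder-averaging does not
remove the bias — it is a property of the protocol at small $N$, not
noise.

## Known limitations

* Parallel (synchronous) discrete-time dynamics only; no asynchronous
  Glauber limit.
* The pairwise reference keeps exactly one coupling; reference models
  preserving larger cliques (with their $2^{M-1}$ coupled equations) are
  out of scope, as is the second-order Gaussian effective-field variant.
* Inference assumes stationary parameters and uses no regularization (an
  optional ridge would be a one-line addition to the update, but none of
  the standard experiments wants it).
* Exact validation is exponential in $N$ and guarded accordingly
  ($N \le 12$ where the transition matrix or stationary joint is needed).
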