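---
title: "Graphical multiple testing with exact epsilon arithmetic: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graphical multiple testing with exact epsilon arithmetic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtpgraph)
```

## The model

A graphical multiple testing procedure over hypotheses $H_1,\dots,H_n$ is a
pair $(w, G)$: weights $w_i \ge 0$ with $\sum_i w_i \le 1$, and a transition
matrix $G = (g_{ij})$ with $g_{ii} = 0$ and row sums at most 1. Hypothesis
$H_i$ is rejectable when its raw p-value satisfies $p_i \le \alpha w_i$.
Rejecting $H_j$ redistributes its level and rewires the graph:

$$w_\ell \leftarrow w_\ell + w_j g_{j\ell}, \qquad
  g_{\ell k} \leftarrow \frac{g_{\ell k} + g_{\ell j} g_{jk}}
                             {1 - g_{\ell j} g_{j\ell}},$$

with $g_{\ell k} \leftarrow 0$ when the denominator vanishes. The procedure
iterates until no hypothesis is rejectable. Every such procedure is a
sequentially rejective weighted Bonferroni test and strongly controls the
family-wise error rate at $\alpha$; the final rejection set does not depend
on the order in which simultaneously rejectable hypotheses are taken, which
is what makes the procedure well defined under tied p-values. Both
guarantees are exercised directly by the test suite (Monte Carlo FWER
estimation, and exhaustive enumeration of admissible testing orders).

## Why symbolic epsilon

Some designs want an edge that passes level across only *after* an entire
path has succeeded. The device is an edge of infinitesimal weight
$\varepsilon$: it keeps the target formally connected (so level eventually
reaches it) while sending a vanishing amount per step. Evaluating such
graphs with a small float (say $10^{-8}$) works until a comparison or a
renormalization like $(\varepsilon + (1-\varepsilon)\varepsilon)/(1 -
(1-\varepsilon)^2)$ has to be resolved; that particular ratio equals 1
*exactly* in the limit, but a float evaluation leaves round-off where a
knife-edge p-value comparison could flip.

`mtpgraph` therefore computes in the ring of polynomials
$\sum_k c_k \varepsilon^k$ with exact rational coefficients $c_k$
(integer-valued doubles, gcd-reduced after every operation, which is ample
for the denominator growth a graph of a dozen nodes can produce).
Comparison is lexicographic by ascending power of $\varepsilon$ — the order
induced by $\varepsilon \to 0^+$ — so $\varepsilon > 0$ but
$\varepsilon < q$ for every positive rational $q$. Division (needed for the
transition renormalization) factors out the common lowest power of
$\varepsilon$ and expands the ratio as a power series, truncated at order
$K$, which defaults to the number of hypotheses: a rejection path can
traverse at most $n$ edges, so products of edge weights along any path need
at most $\varepsilon^n$. Raw p-values and $\alpha$ enter comparisons as
exact rationals parsed from their decimal representation, so printed levels
such as $5\alpha/16 = 0.015625$ reproduce bit-exactly.

Numerical choices at the boundary:

- rejection uses $p_i \le \alpha w_i$ (the standard convention; with exact
  arithmetic the boundary case is decided deterministically by the sign of
  the lowest-order nonzero $\varepsilon$ coefficient of the difference);
- a hypothesis whose level is a pure $\varepsilon$ term (limit 0) is
  rejectable only by $p = 0$, the direct consequence of the limit order;
- among simultaneously rejectable hypotheses the engine takes the smallest
  ratio $p_i / \lim(\alpha w_i)$, ties by declaration order — this mirrors
  how such procedures are narrated step by step, and the final set is
  provably order-invariant anyway (and tested to be).

Graphs are immutable: each update returns a new state, and
`run_procedure()` returns a full trace of levels and decisions, the kind of
audit trail a regulatory submission needs.

## The design presets

The four constructors encode one three-arm, two-endpoint design
(H1/H2 dose-level non-inferiority on the primary endpoint, gatekeeping
H3/H4 and H5/H6, the within-dose superiority pairs):

- **gatekeeping** — α split between H1 and H2; each rejected primary
  hypothesis passes its level in halves to its own dose's pair; within a
  pair the full level recycles; nothing crosses doses.
- **recycling** — pair members split their level half to the partner, half
  to the *other* dose's primary hypothesis, so a fully successful dose path
  hands its whole α/2 across (and a partial pair hands α/8 across).
- **epsilon** — the cross-dose edges of the recycling design are demoted to
  weight $\varepsilon$ and the within-pair edges promoted to
  $1-\varepsilon$: the cross-over happens only once the whole pair is
  rejected, and then with the full level.
- **direct-path** — H1 and H2 exchange weight $1-2\varepsilon$ directly,
  with $\varepsilon$ edges to their own pairs; secondary pairs as in the
  epsilon design. This prioritizes showing both doses non-inferior before
  anything else. The exact placement of $\varepsilon$ on the remaining
  edges is a genuine design freedom; this package keeps row sums at 1 by
  using $1-2\varepsilon$ on the direct edges and $\varepsilon$ on both
  demoted edges, isolated in `build_direct_path()` so alternatives are a
  one-function change.

The initial split is a parameter (`split = c("1/2", "1/2")` by default; the
asymmetric `c("3/4", "1/4")` variant favours the high-dose path). The
figure-style layout of any graph can be exported with `export_dot()`.

`hochberg_pair()` is provided as a standalone step-up test for a separable
family of two (compare the larger p-value with the full level, then the
smaller with half), as one would apply to a secondary pair after its
gatekeeper falls; it is deliberately not fused into the graph engine, which
is strictly weighted-Bonferroni.

`adjusted_pvalues()` inverts the whole procedure by bisection on $\alpha$
to absolute tolerance $10^{-6}$ — far below any reporting precision — and
satisfies the duality “rejected at $\alpha$ iff adjusted $p \le \alpha$”
up to that tolerance.

## Non-inferiority margin

The margin module implements the fixed-margin (95–95) method. Historical
placebo-controlled trials of the active control supply per-study mean
differences $y_k$ (control − placebo; negative = improvement) with standard
errors. `pool_random_effects()` pools them with the DerSimonian–Laird
moment estimator — the standard default among random-effects estimators,
isolated behind one function so another estimator could be swapped — with a
normal-approximation CI (no small-sample adjustment, matching the plain
95% CI framing of the method). Geometry, for lower-is-better endpoints:
placebo mean $A$; $B = A + $ the CI bound of the pooled difference closest
to zero (the conservative statement of the control's effect); control mean
$C$; margin point $D = B - f (B - C)$ for a preserved fraction
$f \in [0,1]$. The margin is $D - C = (1-f)(B-C)$: $f=1$ is a pure
superiority test, $f = 0.5$ puts $D$ at the midpoint of $B$ and $C$. Both
$f = 0.5$ and $f = 2/3$ are conventional; the package defaults to 0.5 and
exposes $f$. If the conservative bound fails to show the control effective
(CI crossing zero) the function refuses to produce a margin, because none
can be justified. Direction is an explicit flag rather than inferred from
signs — the geometry silently inverts otherwise. The one-sided
non-inferiority test `ni_pvalue()` is the CI-duality companion:
$p < \alpha/2$ exactly when the upper $1-\alpha$ CI limit of
(test − control) is below the margin.

## The simulator

`trial_scenario()` defines the data-generating process the Monte Carlo
harness uses to verify error control: three arms, two endpoints per subject
drawn bivariate normal with endpoint correlation $\rho$, two-sample z-tests
per comparison (H1/H2 shifted by the margin, H3–H6 against zero). Because
the z statistics depend on the data only through the arm-by-endpoint sample
means, the generator draws those means directly from their exact sampling
distribution ($\mathcal N(\mu, \Sigma/n)$ per arm) — distributionally
identical to simulating subjects and summarizing, and fast enough for
$10^5$ replicates in well under a second. A `method = "t"` option simulates
subject-level data and pooled-variance t statistics for small-sample
checks. The Monte Carlo rejection loop itself runs in compiled code on a
numeric copy of the graph with $\varepsilon = 10^{-8}$; the suite verifies
(on the fixture graphs and random graphs) that this numeric engine returns
the same rejection sets as the exact symbolic engine, which is what
licenses the substitution at simulation scale.

Scenario defaults — $n = 200$ per arm, SD 1 on both endpoints,
$\rho = 0.3$, margin 0.2 SD units, means at the boundary global null (both
doses exactly at the margin on the primary endpoint, level with control on
the secondary) — are the package's choice of a realistic Phase III
configuration; none is derived from data. The boundary null is the
configuration where FWER is at its worst case for these designs, which is
why it is the default for error-rate checks ($10^5$ replicates gives a
Monte Carlo SE of about 0.0007 at rates near 0.05, so a true violation of
0.055 would sit several SEs out). What the simulator does *not* emulate:
dropout and missing data, unequal arm sizes, non-normal residuals,
group-sequential looks, and estimation of the margin from the same trial.
Passing FWER checks here therefore speak to the multiplicity adjustment
itself, not to robustness of the underlying z/t analysis.

## Known limitations

- Rational coefficients use integer-valued doubles with gcd reduction;
  pathological graphs (many nodes, adversarial denominators) could in
  principle overflow the 2^53 integer range. The intended regime — designs
  of a dozen or so hypotheses with human-chosen weights — stays many orders
  of magnitude below it.
- The engine is weighted-Bonferroni only: parametric (correlation-aware)
  graphical tests and Simes-based within-graph tests are out of scope;
  `hochberg_pair()` covers the separable two-hypothesis family case
  outside the graph.
- `adjusted_pvalues()` assumes monotonicity of rejection in $\alpha$
  (true for these procedures; also property-tested) and inherits the
  bisection tolerance.
- Order invariance is verified by exhaustive enumeration only for small
  graphs (≤ 6 nodes), which covers every preset here.

## Problem sizes used in the checks

The shipped test suite runs the worked example exactly as printed
(deterministic, sub-second), order-invariance enumeration on all presets,
mass-conservation and monotonicity sweeps over ~1000 random graphs of 3–5
nodes, FWER estimation at $10^5$ replicates per preset at the boundary
global null, and meta-analysis equivalence against closed-form
DerSimonian–Laird to $10^{-10}$ relative error.
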