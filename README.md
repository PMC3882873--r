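# mtpgraph

Graphical multiple testing procedures for confirmatory clinical trials, with
exact epsilon-edge arithmetic.

## The problem

A Phase III trial compares two doses of a test drug (high and low) against an
active control on two continuous endpoints, mixing non-inferiority and
superiority objectives. That yields six null hypotheses in two families:

- F1 (primary): H1/H2 — each dose is inferior to control on the primary
  endpoint beyond the non-inferiority margin;
- F2 (secondary): H3/H4 — the high dose is not superior to control on the
  primary/secondary endpoint; H5/H6 — the same for the low dose.

The family-wise error rate must be strongly controlled at a two-sided
α across all six tests. Graphical multiple testing procedures encode the
testing strategy as a directed graph: each hypothesis H_i holds a weight
w_i (so it is tested at local level α·w_i), and each edge (i, j) carries a
fraction g_ij of the level that moves from H_i to H_j when H_i is rejected.
Rejecting H_j updates the graph by the sequentially rejective rule

    w_l <- w_l + w_j · g_jl
    g_lk <- (g_lk + g_lj · g_jk) / (1 − g_lj · g_jl)

and testing continues until nothing more can be rejected.

Designs that should pass level across dose paths *only after a whole path
succeeds* need edges of infinitesimal weight ε. `mtpgraph` keeps all weights
as exact rationals extended with a symbolic ε and evaluates every comparison
in the limit ε → 0⁺, so ε-edge procedures are computed exactly rather than
with a fragile small float.

The package also implements the fixed-margin (95–95) construction of the
non-inferiority margin — a DerSimonian–Laird random-effects meta-analysis of
historical placebo-controlled trials of the control, followed by preserving
a fraction *f* of the conservatively estimated effect — and a Monte Carlo
harness that verifies family-wise error control of any graph by simulation.

## Worked example

Six p-values (0.005, 0.027, 0.020, 0.009, 0.133, 0.018) at α = 0.05:

```r
library(mtpgraph)
we <- worked_example()
run_procedure(build_recycling(), we$pvalues, we$alpha)
```

```
Sequentially rejective test at alpha = 0.05
  step 1: H1 at level alpha/2 = 0.0250; p = 0.005 -> reject
  step 2: H4 at level alpha/4 = 0.0125; p = 0.009 -> reject
  step 3: H2 at level 5*alpha/8 = 0.0312; p = 0.027 -> reject
  step 4: H3 at level 3*alpha/8 = 0.0187; p = 0.02 -> retain
  step 5: H6 at level 5*alpha/16 = 0.0156; p = 0.018 -> retain
  step 6: H5 at level 5*alpha/16 = 0.0156; p = 0.133 -> retain
Rejected: H1, H4, H2
```

Each line is one step of the sequentially rejective procedure: the
hypothesis tested, its local level both as an exact fraction of α and as a
decimal, the raw p-value, and the decision. Here the cross-dose recycling
design rejects high-dose non-inferiority (H1), high-dose secondary-endpoint
superiority (H4), and low-dose non-inferiority (H2); H3 narrowly misses its
final level 3α/8 = 0.01875. The ε-edge variant, which completes the
high-dose path before crossing over, rejects five of the six:

```r
rejections(build_epsilon(), we$pvalues, we$alpha)
#> [1] "H1" "H4" "H3" "H2" "H6"
```

Presets: `build_gatekeeping()`, `build_recycling()`, `build_epsilon()`,
`build_direct_path()` (initial α split configurable, e.g.
`build_recycling(c("3/4", "1/4"))`). Other entry points:
`adjusted_pvalues()`, `hochberg_pair()`, `pool_random_effects()` +
`compute_margin()`, `trial_scenario()` + `estimate_oc()`, `save_graph()` /
`load_graph()` / `export_dot()`, and a command-line wrapper
(`exec/mtpgraph run --preset epsilon --pvalues ...`).

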