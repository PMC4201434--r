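---
title: "Environmental outcome surfaces of duplicated gene pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Environmental outcome surfaces of duplicated gene pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathsurf)
```

## The model

`pathsurf` implements a static input–output model of a two-tier gene
cascade regulating the probability that a developmental or physiological
event occurs, as a function of two environmental factors `e1`, `e2` scaled
1–20. It is not a kinetic model: there is no time axis and no stochastic
gene expression. Each surface cell answers one question — given this
combination of environmental conditions, how likely is the end process?

Each gene copy carries one sensitivity function per factor,

$$f(e) = \exp(-r\,(e - o)^2),$$

with optimum $o$ and independent decay rates below and above the optimum.
This shape captures the biology the model is aimed at: enzyme- and
photoreceptor-like activities with intermediate optima. The two special
cases used throughout are the *insensitive* gene ($r = 0$, activity 1
everywhere) and the *monotone threshold* response ($r_{\mathrm{above}} = 0$,
photoperiod-style). A copy's environmental weight is the product of its two
factor responses, so it equals 1 exactly at its optimum pair.

Regulation uses the logistic link

$$\sigma(x) = \frac{1}{1 + e^{p_0 - p_1 x}},$$

with gain $p_1$ and inflection at $p_0/p_1$: the delta link maps the
upstream regulatory signal to downstream expression, the gamma link maps
total downstream activity to the outcome probability. In the printed
parameter pairs $(p_0, p_1) = (1, 2)$ and $(5, 7)$, the second value must be
the gain: the regulatory inputs are bounded by the activity scale, and only
with $p_1$ multiplying $x$ do both pairs place their inflection inside the
attainable input range, with $(5, 7)$ the steeper of the two at matched
span. Reading $p_0$ as a literal slope and $p_1$ as the inflection point
would put the $(5,7)$ inflection at $x = 7$, far beyond any attainable
input, and the link would be numerically dead. Because $\sigma(0) > 0$,
every outcome surface has a nonzero floor $\sigma_\gamma(0)$ — baseline
leakage of the outcome — and all breadth and prominence measures in the
package are taken relative to that floor, not to zero.

Two boundary conventions are fixed once: the cell $e =$ optimum uses the
above-optimum rate (irrelevant in the symmetric case), and grid coordinates
are always environmental values, never array indices.

## Pooled regulatory input is normalized per copy

Under pooled wiring every downstream copy is driven by the combined
activity of all upstream copies. The package combines activities as their
*mean* by default (`pooling = "mean"`), i.e. the summed activity divided by
the copy count, rather than the raw sum.

This is a deliberate modelling choice, and the only one in the package
where two readings of "combined activity" genuinely diverge. With a raw
sum, adding a copy is a pure dosage increase: $\sigma(U_1 + U_2) \ge
\sigma(U_j)$ for every cell, so a pooled pathway dominates the
corresponding independent pathway *pointwise*, and no pooled architecture
can ever show lower total outcome probability than its independent
counterpart — the ordering is forced by monotonicity before any parameter
is chosen. The qualitative contrasts this package is built to reproduce
point the other way: pooling is the architecture that blurs
copy-specific environmental information and *lowers* the total probability
mass of the outcome relative to parallel independent pathways (compare
panels 5A and 5B: mass 140.0 pooled vs 180.58 independent on the default
grid). Normalizing the pooled input keeps the regulatory signal on the same
[0, 1] scale as a single gene's activity regardless of copy number, makes a
duplication-without-divergence event neutral rather than an implicit
doubling of regulatory strength, and reproduces every pooled-versus-
independent ordering in the registry. The raw-sum variant remains available
as `pooling = "sum"` for explicit dosage questions.

A corollary: the undiversified panels (2A–2E, 3A–3C) are rendered as two
identical copies per tier, and under normalized pooling this is exactly
equivalent to the single-copy pathway, so none of their contrasts depend on
the copy-count rendering.

## Wiring of the divergent-copy panels

The registry encodes panels 4A–4D with independent wiring by default. Two
observations force this choice. First, with upstream copies divergent and
downstream copies not (panel 4B), pooling the upstream signal merges the
two activity peaks into a single central maximum — the sum of two
equal-width Gaussian weights whose optima sit closer than twice their
effective width is unimodal, and the downstream weight centred between them
reinforces that — whereas independent wiring preserves two distinct local
maxima, which is the defining feature of the panel. Second, panel 5A is
presented as the *pooled* counterpart sharing panel 4D's parameters, which
only carries information if 4D itself is not pooled. A `wiring` override on
`figure_config()`/`run_figure()` rebuilds any panel under the other mode
(the panel's encoded expectations are dropped when overridden, since they
describe the default rendering).

## Surface analysis definitions

* **Peaks.** A cell is a local maximum iff its probability is $\ge$ all of
  its 8-connected neighbours; edge cells compare existing neighbours.
  Connected plateaus of equal value merge into one peak reported at the
  lexicographically smallest cell — so a constant surface is one plateau
  peak, not 400. Peaks must exceed floor + `min_prominence`; the default
  0.05 suppresses floor-level ripple while sitting far below the secondary
  peaks of the registered panels (all > 0.3 above floor). These rules are
  deterministic and match visual peak counting on coarse grids.
* **Breadth.** The half-maximum level is floor + (max − floor)/2.
  `half_max_area` counts cells at or above it; `axis_halfwidths` counts
  such cells along the grid row/column through the global maximum. A
  perfectly flat surface (every copy insensitive) has no half-maximum
  region; it is flagged `degenerate` and assigned the full grid.
* **Mass.** `total_mass` is the plain sum of P over cells, reported with the
  cell count. The comparisons it supports are ordinal, so no continuous
  integration is attempted; masses are only comparable on identical grids.
* **Matching.** `peak_optimum_match()` reports Euclidean distances in
  environment units between each peak and each copy's optimum pair, per
  tier.

Ties in the global argmax are broken lexicographically by (e1, e2);
identical configurations always produce bit-identical surfaces, and the
pointwise composition `outcome_probability()` equals the vectorized
`evaluate_surface()` cell-for-cell (the arithmetic is ordered identically
on both paths).

## What the registry reproduces, and what it does not

All sixteen registered panels evaluate on the default grid in well under a
second. The qualitative expectations encoded per panel (forced argmax
cells, peak counts, peak locations) all pass, as do the cross-panel
orderings: the steeper upstream link narrows the outcome along its factor
(2E vs 2C), dual-tier sensitivity restricts at least as tightly as
single-tier (2D vs 2A), compensation lowers peak probability (3C vs 3A/3B),
upstream divergence splits the peak while downstream divergence does not
(4B vs 4C), and pooled regulation lowers total mass yet raises P at the
copy-optima cells when pairings are mismatched (5A/5B, 5C/5D).

Three published qualitative claims do **not** reproduce under these
functional forms, under any of the conventions examined (sum or mean
pooling, one or two copies per undiversified tier, either wiring for the
divergent panels); the corresponding test expectations are left failing
rather than weakened:

1. *Compensation landing exactly on the adaptive optimum.* With upstream at
   (15, 16) and downstream at (5, 8) (panel 3C), the computed global
   maximum is (8, 11), two cells from the midpoint (10, 12). The saturating
   delta link flattens upstream contrast near its top, so the downstream
   optimum pulls the peak toward itself; exact compensation would require a
   contrast-preserving (more nearly linear) upstream link. The direction of
   compensation does reproduce — the 3B peak at (7, 9) moves to (8, 11) —
   as do both probability-cost orderings.
2. *Peaks tracking upstream optima when the upstream link is steeper.* True
   for panels 4A and 4C, but panel 4B's peaks at (9, 11)/(11, 13) sit 1.4
   units from the shared downstream optimum and 5 units from the nearest
   upstream optimum. The same saturation argument applies: a sigmoid's top
   is always flatter than a Gaussian's, so the environmental weight of the
   downstream tier dominates peak placement near the maximum.
3. *A steeper outcome link alone restricting the outcome.* Sweeping the
   gamma gain with its intercept fixed (2, 4, 7 on the 2C configuration)
   gives half-max areas 313, 384, 400 — increasing, not decreasing —
   because raising the gain alone drags the inflection $p_0/p_1$ toward 0
   and saturates the link from below; as the gain grows the whole surface
   tends to 1 and the half-max region to the full grid. Steepness
   comparisons are meaningful when the inflection moves up with the gain,
   as in the printed (1, 2) to (5, 7) contrast, and that comparison does
   reproduce.

## What the built-in configurations do and do not emulate

The registry's parameters describe smooth, symmetric, moderately broad
sensitivity curves (rate 0.01 on the 1–20 scale, effective width of a few
environmental units) and copy optima separated by roughly half the
environmental range. Real reaction norms are typically asymmetric
(responses often collapse faster above a thermal optimum than below),
interact between factors rather than multiplying, and are measured with
noise; none of that is represented, so passing these checks shows the
architecture logic — not that any organism's measured reaction norms follow
Gaussian-times-Gaussian weights. Asymmetric rates are supported
(`rate_below`/`rate_above`) for users who want them; factor interactions
and stochasticity are out of scope.

## Problem sizes and determinism

Everything in the package and its tests runs on the default 20 x 20 grid
(400 cells) or finer grids up to a few thousand cells; a full registry
evaluation plus analysis completes in under a second, and the whole test
suite in a few seconds. The model contains no randomness: random inputs
appear only in property tests (architecture generators under a fixed seed)
and the acceptance script's `--seed` argument exists for interface
stability, not because any reported quantity depends on it.
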