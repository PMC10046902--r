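---
title: "Reconstructing 3D chromosome structures from Hi-C contact matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing 3D chromosome structures from Hi-C contact matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hi-C experiments count how often pairs of genomic segments (chromatin
bins) are captured in physical contact. The resulting interaction-frequency
(IF) matrix is an indirect readout of the chromosome's 3D fold: bins that
touch often must lie close together. `chromoswarm` is a distance-based
reconstruction method: it first converts IF values into expected pairwise
Euclidean distances and then searches for an N x 3 set of bead coordinates
whose realized distances match those expectations.

## The model

### From contacts to distances

The conversion is the standard power law

$$D_{ij} = \frac{1}{IF_{ij}^{\beta}},$$

where $\beta$ is a conversion factor. Pairs with $IF = 0$ are *unobserved*:
they are masked out of the objective rather than assigned an arbitrary
large distance, because a missing contact is not evidence of maximal
separation. The diagonal is likewise excluded.

The converted distances are scale-free and unbounded as $IF \to 0$, so all
masked targets are rescaled by one common positive factor such that the
largest expected distance equals 1.0 — the same scale as the default
particle initialization range. Rescaling by a common factor preserves every
distance ratio, so it changes nothing about which structures fit well; it
only keeps the optimizer's search volume and its targets commensurate. A
consequence worth knowing: multiplying the whole IF matrix by any positive
constant leaves the reconstruction *exactly* unchanged at a fixed seed (a
tested invariant).

When $\beta$ is not known, `search_beta()` reruns the reconstruction over a
grid (default 0.1 to 1.5 in steps of 0.1) and keeps the $\beta$ whose final
structure has the highest Spearman correlation with its own targets, ties
going to the smaller value. The default run uses a fixed $\beta = 1$;
searching is opt-in (`beta = "search"`), keeping the default run a single
optimization with predictable cost.

### The objective

Candidate structures are scored against the targets over masked unordered
pairs $(i < j)$ with residuals $r = d_{ij} - D_{ij}$ and
$n_{\text{count}}$ the number of masked pairs:

* **MSE** $= \mathrm{mean}(r^2)$
* **RMSE** $= \sqrt{\mathrm{MSE}}$
* **SSE** $= \sum r^2$
* **Huber** $= \mathrm{mean}\left(\tfrac12 r^2 \text{ if } |r| \le \alpha,\;
  \alpha(|r| - \tfrac{\alpha}{2}) \text{ otherwise}\right)$, with
  $\alpha = 0.5$ by default.

These are the standard textbook forms, which satisfy the algebraic
identities RMSE$^2$ = MSE and SSE = $n_{\text{count}}\cdot$MSE (both are
asserted over a thousand random residual vectors in the test suite), and
the Huber loss is continuous at $|r| = \alpha$ where both branches equal
$\alpha^2/2$. Averaging over unordered pairs rather than ordered ones
halves the bookkeeping without moving any optimum, since the distance
matrices are symmetric. The integer selector `lf` maps 0, 1, 2, 3 to RMSE,
MSE, SSE, Huber in that order.

### Particle swarm optimization

Each particle is one full candidate structure (N x 3 positions plus
velocities). Every coordinate cell updates as

$$V' = w V + c_1 R_1 (\Psi - P) + c_2 R_2 (G - P), \qquad P' = P + V',$$

with $\Psi$ the particle's personal best, $G$ the swarm's global best, and
$R_1, R_2$ fresh uniform $[0,1]$ draws *per cell per iteration* — per-cell
draws explore a strictly larger family of moves than a single draw per
particle. Personal and global bests are replaced only on strict
improvement, so ties deterministically keep the incumbent and the global
best score is non-increasing by construction (asserted on every tested
run).

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `swarm_size` (`ss`) | 15 | particles in the swarm |
| `max_iterations` (`itt`) | 30000 | hard iteration cap |
| `threshold` | 1e-6 | change-threshold exit condition |
| `rand_range` | 1.0 | initial coordinates uniform in ±`rand_range` |
| `lf` | 0 (RMSE) | loss selector 0–3 |
| `alpha` | 0.5 | Huber threshold |
| `w_start`, `w_end` | 0.9, 0.4 | inertia, linear decay over the run |
| `c1`, `c2` | 2.0, 2.0 | personal / global attraction weights |
| `patience` | 500 | stop-rule window, iterations |

The first five are the tool's published defaults. The swarm constants
`w`, `c1`, `c2` have no published values for this tool, so the package uses
the canonical linearly-decaying-inertia PSO settings and exposes all three
so other values can be substituted. Velocities are clamped to
±`rand_range` per component (a standard divergence safeguard at
$c_1 + c_2 = 4$; switch off with `clamp_velocity = FALSE`).

## Numerical choices

**Stop rule.** "Stop when the error stops improving" needs a window: the
run ends when the *decrease* of the global best score over the last
`patience` iterations falls below `threshold`. The window length matters
more than it looks. Swarm improvement arrives in bursts separated by idle
stretches; with a 100-iteration window, runs on the noiseless 20-bin helix
die at a few hundred iterations with near-zero correlation, while a
500-iteration window lets every tested seed converge (SCC ≈ 0.996). The
default is therefore 500, configurable.

**Initialization.** Coordinates uniform in ±`rand_range`, velocities zero,
each particle's best set to its initial state. Given a seed, initialization
and every subsequent draw are bit-reproducible.

**Tie-breaks.** Strict `<` for best replacement; $\beta$-search ties go to
the smaller candidate; Spearman ranking uses average ranks for ties (the
standard generalization, reducing to ordinary ranks when ties are absent).

**Degenerate inputs.** One-bin matrices are rejected by the optimizer
(no pairs); matrices whose IF values are all zero are rejected by the
converter; constant distance vectors make the correlation undefined and
raise an error rather than returning a silent zero.

**Input formats.** Square matrices slightly asymmetric from text rounding
(relative difference ≤ 1e-6) are repaired as $(M + M^T)/2$; anything worse
is treated as a corrupt file. Sparse 3-column files may carry raw 0-based
indices or genomic positions; positions are reduced to indices by dividing
by the greatest common divisor of all distinct nonzero coordinates (the
inferred resolution). The gcd rule handles both dialects uniformly, at the
cost of misreading a sparse file whose indices happen to share a common
factor — unlikely for contact maps, which are dense in consecutive bins.
Auto-detection treats a file whose data lines all have exactly three
fields as sparse, unless it is a valid 3 x 3 symmetric matrix; the
`input_kind` argument overrides the guess.

**PDB output.** Optimizer coordinates live at O(1) and would collapse at
the format's three-decimal precision, so structures are scaled (default:
maximum extent mapped to 100 units) before writing. Bins are rendered as
CA atoms of glycine pseudo-residues on one chain, with CONECT records
linking consecutive bins so viewers draw the chromatin chain.

## What the synthetic generator does and does not emulate

`make_structure()` provides a helix, a circle, and a seeded
self-avoiding-ish random walk; `structure_to_if()` inverts the distance
conversion ($IF = (1/d)^{1/\beta}$) so that converting back with the true
$\beta$ recovers the true distances up to one global factor — a round-trip
asserted to a pairwise-ratio constancy of 1e-9. Optional noise is
multiplicative log-normal on IF, keeping frequencies positive across their
orders of magnitude.

These fixtures validate the *mechanics* — conversion, optimization,
scoring, output — against a known answer. They do not emulate real Hi-C
statistics: no count overdispersion, no genomic-distance decay, no
TAD-block structure, no unmappable regions. Passing the recovery tests
therefore shows the optimizer solves the stated distance-matching problem;
it does not certify accuracy on real chromosomes, where the IF-to-distance
power law itself is an approximation.

Test and validation problem sizes are 10–30 bins with swarm size 15 and
budgets up to 5000 iterations — small enough to run in seconds while
leaving room for genuine swarm dynamics; the validation scripts state the
sizes they use.

## A worked run

```{r, eval = FALSE}
library(chromoswarm)

fx <- make_fixture("helix", 20L, beta_true = 1.0)
st <- pso_run(fx$if_matrix,
              swarm_config(max_iterations = 5000L, seed = 1L),
              loss_spec("rmse"))
st
#> <chromo_structure> 20 bins | beta 1 | max_iterations after 5000 iterations
#> <evaluation_record> SCC 0.9969 | PCC 1.0000 | rmse 0.000297 | 190 pairs

write_pdb(st, "helix.pdb")
```

## Known limitations

* Single chromosome, single resolution: no genome-wide multi-chromosome
  matrices, no `.hic`/`.cool` binary formats, no normalization of raw
  counts.
* PSO is a stochastic local-search method; it can stall in local optima.
  The `replicates` option reruns with shifted seeds and keeps the best
  structure, but offers no global-optimality guarantee.
* The $\beta$ grid search costs one full reconstruction per candidate.
* Masked (zero-IF) pairs are simply unconstrained; with very sparse
  matrices the structure is underdetermined and correlations are computed
  on few pairs.
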