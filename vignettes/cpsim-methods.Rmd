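---
title: "Methods: cross potential selection and the two-part breeding simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross potential selection and the two-part breeding simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Breeding programs for inbred crops such as soybean must turn a heterozygous
breeding population into fixed inbred varieties, and they must do it quickly:
a variety released two years earlier is often worth more than a slightly
better one released later. `cpsim` simulates a *two-part* recurrent genomic
selection program — a population improvement component (PIC) of 150
heterozygous individuals improved by 10 crosses of 15 progeny per cycle, two
cycles per year, and a segregation-and-fixation component (SFC) that each
year advances the 2 most promising individuals through 7 rounds of selfing
(single-seed descent after an initial 50-progeny selfing) to "Inbred8"
candidate varieties — and compares three rules for choosing the 10 crossing
pairs:

* **GS** — truncation selection: take the 10 individuals with the highest
  genomic estimated breeding values (GEBVs) and pair them at random, each
  used exactly twice.
* **OCS** — optimal cross selection: maximize the summed mid-parent GEBV of
  the chosen crosses subject to a genetic-diversity floor
  `Dsel > He(t)` that declines linearly from the initial expected
  heterozygosity `He0` to `0.01 He0` at cycle 60.
* **CPS** — cross potential selection: score every one of the
  `N(N-1)/2` candidate crosses by the usefulness criterion of its *future
  inbred progeny*, `UC_k = mu_k + i * h * sigma_k`, and pick the 10-cross
  plan maximizing the summed UC, solved exactly as an integer program.

The per-individual usage cap of 2 reflects the limited flowers/pollen of a
single soybean plant; no cross may be duplicated.

# The progeny-variance engine

The scientific core of the package is the exact computation of `sigma_k`,
the standard deviation of Inbred8 GEBVs for a cross between two *possibly
heterozygous* parents. Write the marker score `x = hap0 + hap1 - 1` in
{-1, 0, 1} and `s = 2 * allele - 1` for haplotype signs. For a pair of loci
(l, m) on the same chromosome with Haldane recombination fraction `r`,
track two moments of the diplotype distribution across the selfing chain:

* `D` — the expected within-haplotype sign product `(s0l s0m + s1l s1m)/2`,
* `C` — the expected cross-haplotype sign product `(s0l s1m + s1l s0m)/2`.

One generation of selfing (two independent gametes from the current
diplotype) is the linear map

```
D' = (1 - r) D + r C
C' = (D + C) / 2
```

whose eigenvalues are 1 and `lambda = (1 - 2r)/2`. After `n` selfings,

```
E[x_l x_m] = alpha(r, n) D0 + gamma(r, n) C0
alpha = (2 + (2r - 1) lambda^n) / (2 (1 + 2r))
gamma = (4r + (1 - 2r) lambda^n) / (2 (1 + 2r))
```

with founding moments `D0, C0` given by the cross (gamete from each parent,
recombination included) or — for the selfing usefulness criterion `UCS_i` —
by the individual's own diplotype. Per-locus means are conserved, so
`mu_k` is simply the mid-parent GEBV. The closed form reproduces the
classical checks exactly: a single heterozygous locus retains variance
`1 - (1/2)^n`; unlinked loci (`r = 1/2`) have zero covariance at every `n`;
and as `n -> Inf` the covariance for coupling-phase inbred parents tends to
`1 - 2R` with `R = 2r/(1 + 2r)`, the recombinant-inbred-line limit. The
residual distance to that complete-inbreeding (doubled-haploid-like) limit
shrinks as `(1/2)^n`, so Inbred8 (`n = 7`) sits within a percent of it.

Because `E[x_l x_m]` is bilinear in per-parent quantities, the whole
`N(N-1)/2` candidate set collapses to a handful of matrix products per
chromosome (`engine_sigma2_cross_all()`): per-individual quadratic forms in
precomputed weight matrices plus one `N x N` cross-product. This is what
makes evaluating all 11,175 crosses of a 150-individual population per cycle
affordable in plain R. Three independent routes are kept and cross-checked
in the tests: the closed form, an explicit 16-state diplotype Markov chain
(`pair_inbred_moments()`), and a gamete-dropping Monte-Carlo simulator
(`simulate_inbred_progeny()`). Between-chromosome covariances are exactly
zero under independent assortment and are never computed.

# Selection intensities

The usefulness criteria use `i = qnorm(1 - 1/pool)`: 3.004 for the cross
pool (15 progeny x 50 Inbred8 lines = 750) and 2.054 for the selfing pool
(50). These are the quantile-rank values, not the classical truncation
intensity `dnorm(z)/p` (which would give about 3.29 and 2.42); both are
exposed in `selection_intensity()`, and the quantile form is the default
because it reproduces the constants the criteria are defined with. `h = 1`
in `UC_k` deliberately ignores heritability shrinkage so that crosses with
outstanding progeny potential are rewarded in full.

# Model fitting

Phenotypes are simulated once for the initial 150 individuals:
`y = u + e`, with `sigma_e^2 = sigma_g^2 / h2 - sigma_g^2` and `sigma_g^2`
the *population* variance of `u` (denominator N, as the defining formula is
written). A single-kernel G-BLUP with `G = X X'/L` is fitted by EMMA-style
REML: one spectral decomposition of `G`, then a 1-D optimization of the
restricted likelihood over `log(delta)`, `delta = sigma_e^2/sigma_u^2`, on
[-12, 12]. Marker effects are recovered by the exact back-solve
`beta_hat = X'(X X')^{-1} g_hat` (ridge `1e-8 tr/N` added only if `X X'` is
ill-conditioned), so `X beta_hat` reproduces the GEBVs to 1e-8 relative
error and later generations are scored by `gebv()` with the same effects —
the model is *never* refitted, isolating the strategy comparison from
retraining effects. GEBVs are centered random effects; the intercept is not
folded into the back-solve.

# The optimizers

**CPS** is a max-weight degree-constrained subgraph problem: choose exactly
10 edges of the complete graph on N parents, each vertex incident to at most
2, maximizing summed UC. `cps_select()` solves it with branch and bound:
edges are scanned in decreasing weight (ties broken by lexicographic pair
id, so results are deterministic), the incumbent starts from the greedy
feasible plan, and a subtree is pruned when the admissible bound — current
value plus the largest `k` remaining weights among edges with unsaturated
endpoints — cannot beat the incumbent. Because the mid-parent part of UC
depends only on vertex degrees (any pairing of the same parents scores the
same `sum(mu)`), a second admissible bound handles the degree-dominated
regime: every completion contributes `w/2` per endpoint, each vertex at most
its residual capacity times and `2k` endpoint-slots in total, so a greedy
fill of that truncated partition matroid upper-bounds all completions. A
subtree survives only if it beats the incumbent under both bounds; a third
bound, available when the caller supplies vertex potentials (`g/2` for UC
weights), splits the objective into a degree-separable part (bounded exactly
by a matroid greedy over vertex-capacity slots) plus the sigma residuals
(top-k), which targets the same regime from the other side. Optimality is
proven to a relative tolerance `tol = 1e-6` — i.e. within
`tol * (1 + max|UC|)` of the true optimum. That tolerance is deliberate, not
a shortcut: the UC values themselves are only defined to roughly the REML
convergence tolerance (1e-8) times the effect scale, BLAS reductions are not
bit-reproducible, and in late cycles exponentially many pairings of the same
parents tie to within round-off; demanding separation below the input noise
floor makes any admissible-bound search enumerate that tie class. If a
pathological instance still exceeds the node cap (5e6), the solver errors
rather than returning a silently suboptimal plan, and the program layer
falls back to the greedy feasible plan with a warning and
`feasible = FALSE` recorded in the log. The published analysis solved the same
program with an off-the-shelf LP solver; an in-package exact solver keeps
the dependency surface minimal and the optimality contract explicit.

**OCS** is quadratic in the contribution vector through
`Dsel = 1 - c'Kc`, so an exact solver is not available cheaply; the
heuristic here is a steady-state genetic algorithm over feasible plans with
replace-one-cross and swap-parent mutations plus repair. Fitness is
lexicographic: any plan satisfying `Dsel > He(t)` (strict, tolerance 1e-12)
dominates every infeasible plan; feasible plans compare by summed mid-parent
GEBV, infeasible ones by `Dsel`, which drags the search into the feasible
region. If the budget expires with no feasible plan (possible in late cycles
when diversity is exhausted), the max-`Dsel` plan is returned flagged
`feasible = FALSE` — logged, never silent. The published work used a cited
heuristic whose internals are not reproduced here; the contract adopted
instead is measurable: on small instances the GA must reach at least 95% of
the enumerated constrained optimum with 100% constraint satisfaction, which
the acceptance suite verifies.

**GS** pairing is "random" in the source material; here it is made precise
as a uniform draw over labeled 2-regular simple graphs on the 10 selected
individuals (every individual used exactly twice, no duplicate cross),
sampled by stub-matching with rejection — conditioned on simplicity the
configuration model is exactly uniform, which the tests verify by
enumeration on 4 vertices.

# Synthetic founders

The real 198-accession resequenced soybean panel is not bundled; the
generator emulates the features of it that the downstream pipeline actually
consumes: 198 inbred accessions, 20 chromosomes x 200 SNPs after filtering
and subsampling, all MAF >= 0.1, block LD (mosaics of 8 ancestral
haplotypes, mean segment 0.25 Morgan), and 4 k-means-detectable
subpopulations (donor weights 0.85 toward own-group ancestors). Sites
failing the MAF floor are re-drawn with the mosaic held fixed. What it does
*not* emulate: realistic allele-frequency spectra, recombination hotspots,
population-specific LD decay, or any trait-marker enrichment — so a green
directional test on synthetic founders establishes that the machinery ranks
strategies as published under a plausible genome, not that the published
effect sizes are recovered. Import of real phased data (VCF with `|`
separators, or a marker-row TSV) is provided for users who have the panel.

Defaults are the stated world: 1 Morgan chromosomes with linear bp-to-Morgan
maps, 4,000 markers, 1,000 QTN with effects `N(0, 0.35)`, heritability 0.3
or 0.6, 60 cycles, schedule `t* = 60, s = 1, He* = 0.01 He0`. Where the
source is silent a single choice was made and kept: Haldane mapping (no
interference) because it is the standard no-interference choice and makes
meiosis and the variance engine mutually consistent; k-means on raw scores
with 10 restarts; founder accessions treated as fully inbred.

# Scaled acceptance run

The directional comparison in the acceptance suite runs 5 chromosomes x 40
SNPs, N = 60, 50 QTN (keeping the 1:4 causal ratio), 20 cycles, 20 matched
replicates at h2 = 0.6. N = 60 is split as 4 crosses x 15 progeny rather
than 10 x 6: the family size of 15 — and with it the 750-line usefulness
pool behind the printed intensity 3.004 — is part of the stated world, so
the cross count is what gets scaled. (A 10 x 6 split was tried first and
washes out the family structure CPS exploits; with 6-progeny families its
early advantage over GS sits at noise level.) Matched means every
strategy sees the identical founder subsample, QTN draw, initial population
and fitted model within a replicate, which sharpens the contrast without
biasing it. Expected outcomes, which the tests assert: CPS matches or beats
GS on mean Inbred8 gain at the early even cycles (t <= 12), and OCS retains
strictly more PIC genetic variance than GS at every cycle. Full-scale
magnitudes (gains of 5.0 vs 3.7, win fractions near 0.46, 5% retained
variance) belong to the 300-replicate, full-genome setting and are out of
desk scope.

# Numerical and design notes

* Variances returned by the engines are clipped at zero against
  floating-point negatives; the clip is inert in exact arithmetic.
* All stochastic operations accept an explicit seed and restore the global
  RNG state; program runs derive named substreams from one master seed, so
  adding a stage never perturbs another stage's stream and runs are
  bit-reproducible.
* Gain metrics divide by the initial genetic *variance* as the defining
  formula is printed; `denominator_mode = "sd"` is exposed because the
  conventional standardization uses the SD, and published magnitudes are
  easier to match in that mode. The default follows the printed formula.
* Win-fraction ties are split equally among tied strategies.
* SFC selection happens at even cycles (once per simulated year) on the
  just-formed population; the selected individuals remain available as
  crossing parents, and the time to produce Inbred8 lines is not modeled.
* Known limitations: no dominance or epistasis, no crossover interference,
  no mutation, no retraining of the prediction model, and the OCS heuristic
  carries no optimality proof — its quality is empirical, bounded by the
  acceptance contract on small instances.
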