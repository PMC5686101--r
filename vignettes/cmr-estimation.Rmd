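---
title: "Estimating critical mutation rates on two-peak fitness landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating critical mutation rates on two-peak fitness landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmrsim)
```

## The model

`cmrsim` simulates a diploid population of `N` individuals evolving on a
per-gene two-peak fitness landscape. Each individual carries a maternal and
a paternal sequence over a 4-letter alphabet (`0:3`), each split into `n`
genes of length `L`. Every gene has two target sequences: peak 0, narrow
and high (height `h0 = 15`, radius `r0 = 2`), and peak 1, broad and lower
(height `h1 = 10`, radius `r1 = 5`), a Hamming distance `D = 10` apart.
Peak heights are relative scores, so only their order matters; the
constructor enforces `h0 > h1`. A peak's *radius* is the Hamming distance
at which its fitness contribution reaches zero, so a broader peak is more
mutationally robust: a random mutation near its top is less likely to
change fitness. The region between the radii is neutral space.

Fitness of one strand at one gene is the larger of the two peak
contributions; because the peaks may not meet or overlap
(`S*D > S*(r0 + r1)`), at most one contribution is positive. The diploid
gene fitness combines the two strands through the dominance weight
`lambda`: `f = lambda * f_max + (1 - lambda) * f_min`. The default
`lambda = 0.999999999999999` makes the fitter allele effectively dominant
while still coupling the weaker allele to selection — with `lambda = 1`
exactly, one strand could drift anywhere in sequence space unseen. The
individual's fitness is the **minimum** over its genes, a strong-epistasis
rule: genes are treated as essential, so losing any one gene's peaks
cannot be masked by the rest.

Generations are discrete. Each generation a uniform random permutation of
the population is cut into trios; within a trio the three are ranked by
fitness (ties broken uniformly at random) and one slot is replaced: the
least fit with probability 0.5, each of the two fitter with probability
0.25. Replacement of even the fittest is what makes loss of the fitter
peak possible at all. The two survivors parent the child: each contributes
one gamete formed by meiosis-style recombination (per chromosome, a
uniform starting strand and `k` distinct crossover points among the
internal boundaries), and each child strand is then mutated per gene with
`K ~ Binomial(L, M)` changed positions, each set to one of the three other
symbols uniformly. The `N mod 3` leftover individuals pass through
unchanged, so each individual participates in at most one reproduction
event per generation.

A run starts with `ceiling(N/2)` individuals homozygous on the peak-0
targets and the rest homozygous on the peak-1 targets, and stops at the
first generation at which **any** gene has lost peak 0 — no individual
retains a strand strictly within the peak-0 radius for that gene — or at
the generation cap (10,000 by default).

## The critical mutation rate

The critical mutation rate (CMR) is the per-base mutation rate at which
95% of runs lose peak 0 within the generation cap: the transition from
survival-of-the-fittest to survival-of-the-flattest. It is estimated by an
ascending sweep:

1. **Coarse sweep** over `d * 10^-e` (`d = 1..9`, `e = 8` down to `3`,
   capped at `1e-2`) finds the decade containing the CMR.
2. **Fine sweep** within that decade (`0.1 * 10^-e` steps) pinpoints it.
   The batch CMR is the smallest rate at which at least 95% of a batch's
   runs lose peak 0; 20 batches of 100 runs give the mean, SD and a 95%
   Student-t interval (19 df).

A rate is abandoned early once enough runs keep peak 0 that 95% losses
have become arithmetically impossible: with `n` runs per batch that
happens at `floor(0.05 n) + 1` keepers (one more than 5%). At exactly 5%
keepers a batch can still reach exactly 95% losses, so advancing there
could flip a decision; the strict threshold never can.

Within a batch the same per-run seeds are reused at every rate (common
random numbers), which reduces the variance of comparisons along the
grid. All seeds derive from a single master seed, so a configuration is a
pure function from seed to results.

## Parameters at a glance

| Parameter | Meaning | Default |
|---|---|---|
| `L` | gene length (bases) | 1000 |
| `n` | genes per individual | 1 |
| `r0`, `r1` | peak radii (bases) | 2, 5 |
| `D` | inter-peak Hamming distance | 10 |
| `S` | integer scale on radii and distance | 1 |
| `h0`, `h1` | peak heights (relative) | 15, 10 |
| `k` | crossovers per chromosome per gamete | 1 |
| `c` | chromosomes per gene | 1 |
| `lambda` | dominance weight | 1 − 1e−15 |
| `N` | population size | swept, 10–1,000 |
| `M` | per-base mutation probability | swept |

The defaults are the canonical study conditions: a biologically plausible
minimal gene length (1,000 bp), allele distances within the published
range for real genes, and one obligate crossover per reproduction.

```{r}
footprint_stats(r0 = 2, r1 = 5, D = 10, S = 1, L = 1000)
```

Under this geometry the two peaks plus the gap between them cover 2.4% of
a 1,000 bp gene (1.4% for the peaks alone), doubling at `S = 2`. The
footprint convention counts each peak as `2 * radius` positions of the
1-D transect and adds the full inter-peak distance; a strict 1-D span
would instead give `r0 + D + r1`. The convention here is the one that
reproduces the published occupancy percentages, and is documented as such.

## Numerical and design choices

* **Decay shape.** Only the apex (height) and the zero point (radius) of
  a peak are fixed by the definitions; the decay in between is taken as
  linear, `height * (1 - d/radius)`, the simplest strictly decreasing
  interpolation. The shape matters little because presence/loss of peak 0
  is decided by the radius, not the slope.
* **"On a peak"** means Hamming distance *strictly* less than the radius;
  `d = radius` is the point of zero fitness. A tie at zero fitness
  (outside both radii) is reported as belonging to neither peak.
* **Mutation** samples `K` distinct positions (without replacement), so
  exactly `K` positions change; with replacement the realised count could
  fall short of the binomial draw. Mutation is applied per gene (`L`
  trials per gene per strand), equivalent in distribution to one
  `Binomial(n*L, M)` draw over the genome. Strands are mutated after
  gamete formation.
* **Chromosome partition.** Each gene splits into `c` contiguous blocks of
  `floor(L/c)` bases, the last block absorbing the remainder; crossover
  points are distinct internal boundaries (0-based, half-open segments).
  `k` may not exceed the shortest block's boundary count.
* **Loss checking** runs once per generation, not per tournament; the
  loss generation is the index at whose end the check first fails.
  Leftover (`N mod 3`) individuals are not re-used as parents elsewhere
  in the generation.
* **RNG order** inside a tournament is fixed: three rank tie-break
  uniforms (always drawn), one replacement-slot uniform, then gamete and
  per-gene mutation draws for the child's maternal strand (from the
  fitter surviving parent) and then the paternal strand. The compiled
  run loop and the R-driven per-generation loop consume the stream in the
  same order and produce bit-identical runs.
* **Censoring.** A batch whose CMR lies above the top of the sweep grid
  (1e-2) is recorded as censored (`NA`); for directional comparisons
  `cmr_values(est, "grid_top")` substitutes the grid top, which is
  conservative for "increases" claims.
* **Exponential fit.** The CMR-versus-N curve is fitted as
  `CMR(N) = a - b * exp(-c * N)` — a plateau `a` at large `N` with an
  exponential drop at small `N`. The published analyses name the family
  but not the parameterisation; any monotone saturating exponential is
  consistent, and this one is initialised directly from the data
  (`a` from the largest CMR, `b` from the drop, `c` from `1/median(N)`).
  An exactly flat curve is returned analytically (`b = 0`) rather than
  pushed through the optimiser. The gene-number curve is fitted as a
  quadratic in log10-log10 coordinates, where a pure power law shows up
  as zero curvature.

## Reduced protocol and what the tests show

Full-protocol estimation (20 batches × 100 runs × 10,000 generations ×
fine grids, for populations up to 1,000) is a cluster-scale computation.
The package therefore ships a first-class **reduced profile**: gene length
30, populations 10–60, a 2,000-generation cap, 5 batches × 20 runs, and
the coarse grid only. At these sizes the whole directional study — CMR
rising with `N`, falling with `L` and with gene number, rising with `S`
and with crossovers — runs in minutes on one core, and this is what the
test suite executes. Batch CMRs are then quantised to coarse-grid rates,
so ordering tests allow one grid step plus sampling error; small effects
(notably extra crossovers at short gene lengths) can tie at this
resolution, while the large effects order strictly.

What the reduced protocol does *not* show: the published full-scale CMR
magnitudes (e.g. the 2.8e-4 plateau for the canonical landscape at
`N = 1000`). Those values are bundled as the `reference_cmrs` fixture,
keyed by their exact run settings, for comparison against opt-in long
runs via `experiment_config(profile = "full")`.

One mechanistic observation worth knowing when interpreting mutation-free
controls: with obligate crossover, a heterozygote (one strand per peak)
produces gametes that are mosaics of the two targets, most of which fall
outside *both* radii. At very small `N` this drift-plus-recombination
channel alone loses peak 0 in a noticeable fraction of runs; it fades
quickly with population size.

## Limitations

* Two peaks per gene, identical geometry across genes; no landscapes with
  more peaks, plateaus, or inter-gene fitness interactions beyond the
  minimum rule.
* Constant crossover count per chromosome (no per-meiosis variation, no
  sex differences — the bundled *A. thaliana* crossover table is
  reference data only), no insertions/deletions, no lateral transfer.
* Non-overlapping generations with a fixed population size; no age or
  spatial structure, and off-peak individuals remain selectable.
* The simulated alphabet is abstract; FASTA export maps `0:3` to `ACGT`
  purely as a container format.

## A worked example

```{r, eval = FALSE}
land <- make_landscape(n = 1, L = 30, seed = 1)
cfg <- run_config(land, population_size = 10,
                  reproduction = reproduction_config(),
                  max_generations = 2000, seed = 1)
est <- estimate_cmr(cfg, n_batches = 5, batch_size = 20,
                    protocol = "coarse")
glance(est)

# full experiment from a config, written to disk
xcfg <- experiment_config(profile = "reduced", gene_length = 30,
                          population_sizes = c(10, 30, 60), seed = 1)
summary <- run_experiment(xcfg, "cmr-results")
fit_exponential(summary, n_col = "N", cmr_col = "cmr_mean")
```
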