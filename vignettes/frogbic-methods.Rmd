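---
title: "frogbic: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{frogbic: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
search is built the way it is. It complements the README's worked example;
nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# The model

An expression matrix is an *n × m* real matrix *D* with genes in rows and
conditions in columns. A bicluster *B = (g, c)* selects a gene subset and a
condition subset. Its coherence statistics, all with population
(divide-by-count) normalisation:

* dimension means: gene means *d_ic*, condition means *d_gj*, overall mean
  *d_gc* of the selected submatrix;
* residue of a cell: *r_ij = d_ij − d_ic − d_gj + d_gc*; mean squared
  residue `MSR = mean(r_ij²)`. MSR is exactly zero for any additive
  pattern *d_ij = a_i + b_j* and for any single-row or single-column
  bicluster (the row/column mean absorbs every cell; the implementation
  returns the exact zero rather than a rounding residual);
* row variance `RVAR = mean((d_ij − d_ic)²)`, which separates genuinely
  varying modules from flat submatrices.

The search minimises three conflicting objectives:
`f1 = n·m/|g||c|` (inverse relative size, ≥ 1 with equality only for the
full matrix), `f2 = MSR/δ` (residue on the scale of the homogeneity
threshold δ), `f3 = 1/RVAR`. A *flat* bicluster (RVAR ≤ 1e−12) would make
f3 infinite; it instead receives a large finite penalty (default 1e12,
configurable) so that dominance comparisons remain well defined — such
frogs simply rank worst on f3.

Candidates are encoded as binary strings of length *n + m*: the first *n*
bits select genes, the last *m* conditions. Decoding a string with no gene
or no condition bit set is an error at the mathematical core; the engine
repairs such positions before evaluation by switching on one uniformly
random bit in the empty section, so the core stays total over its declared
domain and the repair policy lives in one place.

# Dominance, the ε-archive, and guides

Pareto dominance is the usual componentwise order (minimisation, one strict
coordinate). The external archive enforces a relaxed, granular version:
objective space is gridded into boxes `floor(f_i/ε_i)` and the archive
keeps at most one mutually non-dominated member per box. Insertion rejects
a candidate whose box (or vector) is dominated by a member; within a box
the vector closer (Euclidean) to the box's lower corner wins, the incumbent
winning ties; an inserted candidate evicts every member whose box or vector
it dominates.

**Additive versus multiplicative ε.** The textbook relaxed relation is
multiplicative (`f_i ≤ (1+ε_i)·g_i` in minimisation form). The box grid
above, however, is additive, and the archive's coverage guarantee — every
rejected candidate is ε-dominated by some final member — holds for the
*additive* relation `f_i ≤ g_i + ε_i` but provably fails multiplicatively
whenever objective values drop below 1 (as f2 and f3 routinely do). The
package therefore uses the additive scheme for the archive and its
guarantee, and `epsDominates()` exposes both schemes. Both collapse to
weak dominance as ε → 0, and plain dominance implies either for any ε > 0.
Defaults: ε = (0.02, 0.02, 0.02), configurable per objective.

**Sigma-method guides.** Each frog follows the archive member whose
direction signature σ is nearest in Euclidean distance, with ties broken
uniformly at random. For two objectives σ = (f1²−f2²)/(f1²+f2²); for three,
σ = (f1²−f2², f2²−f3², f3²−f1²)/(f1²+f2²+f3²). The three-objective formula
is adopted from the method's original source, since only the two-objective
scalar appears in most summaries; σ is scale-invariant and undefined only
at the origin, which cannot occur here (f1 ≥ 1).

# The optimiser

One run: a GA-seeded swarm evolves for `nGenerations` shuffling
generations. Each generation: spawn candidates from the archive, deal the
swarm into `nMemeplexes` memeplexes by ranked round-robin (non-domination
rank, then crowding distance descending; rank *r* goes to memeplex
*r mod k*), run `cyclesPerMemeplex` worst-frog improvement cycles per
memeplex, recombine, offer the swarm to the archive, and shrink.

**Initialisation.** A compact non-dominated-sorting GA (binary tournament
on rank + crowding, uniform crossover, per-bit mutation at 1/(n+m),
elitist truncation) with 50 individuals for 20 generations seeds the
swarm. With `initGenerations = 0` the initial swarm is purely random.
Random positions use per-frog heterogeneous sparsity (gene inclusion
probability ~ U(0.02, 0.5), condition ~ U(0.07, 0.5)): a swarm whose
members all contain ~50% of the matrix has no small coherent fragments to
grow from, and the small end of the front would only be reached by drift.

**Worst-frog improvement.** Four sequential steps, each active by default:

1. *Leap*: per-bit velocity
   `v' = ξ(ωv + c1·r1·(Pb−x) + k·μ1·c2·r2·(gb−x) + μ2·c3·r3·(XB−x))`,
   with fresh uniform r's per bit, direction k = ±1 drawn once per update,
   clamp to ±vMax, and the hard threshold `x' = 1 iff x + v ≥ 0` applied
   exactly as stated (the boundary is inclusive: a zero bit with zero
   velocity switches on). Because of that rule, fresh velocities are drawn
   from U(−vMax/2, 0) rather than zero — a resting velocity of zero would
   switch on every unattracted bit and each leap would bloat the bicluster
   toward the full matrix. Velocity persists only when the move is kept.
2. *Mutation* of the worst frog's position.
3. *Crossover* with the archive guide (uniform by default; single-point
   available).
4. *Random replacement*, unconditional: a fresh random repaired frog with
   its own personal best.

**Move acceptance.** Steps 1–3 keep their candidate when the old position
does **not** weakly dominate it — i.e. dominating *and* mutually
non-dominated moves pass, dominated or identical ones fall through.
Requiring outright dominance was tried first and starves the search:
dropping a noisy gene improves f2 and f3 but always worsens f1, so every
purifying trade-off move would be rejected and the memetic steps reduce to
random restarts. With the relaxed rule the swarm explores along the front
while the archive (whose own rules are strict) enforces Pareto
monotonicity. Under a single active objective the rule reduces to strict
improvement, recovering canonical discrete shuffled frog-leaping.

**Personal bests** update on dominance; on mutual non-dominance the new
position is kept with probability 0.5.

**Every candidate evaluated anywhere** (leap, mutation, crossover, random
replacement, spawning) is offered to the archive, not only the
end-of-generation swarm: the ε-Pareto set is updated during the selection
operation, and discarding already-paid-for evaluations would waste most of
the run's information.

# Dynamic population

**Adding.** Each generation `growthStep` (default 120) candidates are
spawned from the archive: parents are chosen by size-4 tournament on the
row-variance objective, recombined uniformly with probability 0.7 (single
parent copied otherwise), and mutated at twice the mutation rate. The
swarm absorbs candidates only up to `popMax`; the rest still update the
archive. The row-variance end of the front is where coherent, structured
biclusters concentrate — spawning there focuses refinement, whereas
spawning from sparsely occupied boxes (the obvious "unexplored areas"
reading) mostly wanders the enormous size axis, because f1 spans three
orders of magnitude and almost every size class is its own box.

**Shrinking.** Each frog's σ-distance to its own guide is ranked
descending (farthest = most redundant); the top `selectionRatio` fraction
(default 0.2) are each removed independently with probability 0.5 — a
stochastic allocation that trims redundancy without mass extinction — and
the population never drops below `popMin`.

**Mutation balance.** Mutation is independent per-bit, but the configured
rate is split so that half the expected flips land in the gene section and
half in the condition section. With m ≪ n a uniform per-bit rate almost
never proposes condition moves (30 of 230 bits on the benchmark), and
condition membership then never converges.

# Parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `nFrogs` | 60 | nominal swarm size (random-init size when the GA seeder is off) |
| `nMemeplexes` | 6 | memeplexes per generation |
| `cyclesPerMemeplex` | 10 | worst-frog improvements between shuffles |
| `nGenerations` | 100 | shuffling generations |
| `delta` | 300 (yeast preset), 1200 (human preset) | homogeneity threshold, units of squared expression |
| `epsilon` | (0.02, 0.02, 0.02) | archive box widths per objective |
| `c1, c2, c3` | 2, 2, 2 | acceleration coefficients |
| `mu1, mu2` | 0.5, 0.5 | influence factors (guide, memeplex best) |
| `xi` | 0.729 | constriction factor (standard swarm value; none stated for this method) |
| `omegaStart → omegaEnd` | 0.9 → 0.4 | linearly decreasing inertia; the method's own inertia definition is circular, so a standard schedule is used |
| `vMax` | 4 | per-bit velocity clamp (binary-swarm convention) |
| `mutationRate` | 0.01 | overall per-bit flip rate, section-balanced |
| `crossoverType` | uniform | single-point available |
| `popMin, popMax` | 40, 120 | dynamic-population bounds around the nominal 60 |
| `selectionRatio` | 0.2 | shortlist fraction for removal |
| `growthStep` | 120 | archive-derived candidates per generation |
| `initPopSize, initGenerations` | 50, 20 | GA seeder size and length |
| `rvarPenalty` | 1e12 | finite stand-in for 1/RVAR on flat biclusters |

# The synthetic generator

`generateSyntheticMatrix()` draws i.i.d. background cells (normal or
uniform) and overwrites planted submatrices; overlapping plants resolve
last-writer-wins (overlap semantics are otherwise unspecified, so the rule
is documented rather than clever). Patterns: *constant* (μ + noise),
*additive* (μ + a_i + b_j + noise — zero MSR when noise-free, the pattern
MSR is designed for), *shifted* (μ + a_i + noise). Effect scales default
to row sd 1 and column sd 2 — column effects stronger than row effects,
as condition-driven modules in log-scale expression data typically are.

`syntheticBenchmark()` fixes the package's standard test instance: 200 ×
30, N(0, 1) background, one additive 40 × 10 plant with cell noise sd 0.5
(half the background sd) and δ = 1 — generous, about four times the
plant's expected residue of ≈ 0.9 × 0.975 × 0.25 ≈ 0.24, and at the scale
of the background variance. Problem sizes in the test suite (a 200 × 30
benchmark, smaller 100 × 15 and 40 × 10 instances for the
dynamics/engine tests) are chosen so the full suite exercises every code
path in a few minutes while the planted module remains a genuinely hard,
non-trivial target.

What the generator emulates: the scale and block structure of classic
yeast/human compendia (it can also produce value ranges like 0–600 via a
uniform background, and the imputation presets [0, 800] and [−800, 800]
mirror the published preprocessing, including its quirk of imputing yeast
values above the data range — the imputation range is a visible parameter
precisely because the random fill influences which biclusters are found).
What it does not emulate: correlated noise across conditions,
heavy-tailed measurement error, multiple overlapping modules with shared
genes, or normalisation artefacts. Passing the recovery tests therefore
shows the optimiser can assemble a coherent module against i.i.d. noise at
realistic signal-to-noise, not that it resolves every structure in real
compendia.

# Numerical and degenerate-input choices

* Box indices are stored as numeric floors: `f/ε` overflows 32-bit
  integers when f3 hits the flat-bicluster penalty.
* Archive ties: same box → smaller Euclidean distance to the box's lower
  corner; exact tie → insertion order (incumbent stays).
* Guide ties (equal σ-distance) break uniformly at random from the run's
  single RNG stream, so runs are bit-reproducible under a seed.
* `n < 2` or `m < 2` matrices, ragged TSV rows, duplicate identifiers,
  non-finite cells at run start, empty gene-set files, and out-of-range
  plant indices are all rejected with named errors rather than repaired.
* The whole run is a deterministic function of (matrix, config, seed); a
  single `set.seed(seed)` at run start drives every stochastic component.

# Known limitations

* Maximality of biclusters is not enforced (the size objective is the only
  pressure toward large modules); the printed definition of a maximal
  bicluster in the source literature is internally inconsistent, and no
  step of the algorithm uses it.
* The archive can still grow into hundreds of members along the size axis
  at the default ε; memory is not an issue at these scales, but
  downstream consumers should filter (e.g. residue < δ, ≥ 2 genes and
  conditions) as the README example does.
* Enrichment reports raw hypergeometric p-values (as the original analyses
  did) with a clearly labelled Bonferroni column as an extension; no FDR
  machinery is built in.
* Runtime grows linearly in evaluations × archive size; very large
  matrices (10⁴ genes) are feasible per evaluation but would warrant a
  smaller `growthStep` or fewer generations.
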