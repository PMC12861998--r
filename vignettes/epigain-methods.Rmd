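---
title: "Simulating long-term genomic selection with epistasis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating long-term genomic selection with epistasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`epigain` is a stochastic simulator for recurrent genomic selection (GS) in a
self-pollinated crop. This vignette documents the genetic and statistical
models, every tunable that materially affects results, the choices made where
the design was genuinely open, and the limits of what the simulations can
show.

## Founders and genome

The genome is a set of chromosomes (default 12, each 100 cM — equal lengths
are used because no per-chromosome map is imposed) carrying a fixed number of
segregating sites (default 1644), allocated to chromosomes proportionally to
genetic length and placed on an even cM grid. Per chromosome, 45 sites are
labelled as the SNP genotyping panel (uniformly spaced, emulating an evenly
designed array) and 30 disjoint sites are causal QTNs; the remainder are
neutral. Coordinates are 0-based locus indices with cM positions as floating
point.

Founders are `n` fully homozygous pure lines built as doubled haploids of
independently sampled haplotypes. Allele frequencies per locus follow
Wright's mutation–drift stationary distribution Beta(θ, θ) with
θ = 4·Ne·μ (defaults Ne = 10⁴, μ = 5·10⁻⁶, hence θ = 0.2), giving the
U-shaped spectrum of a neutral equilibrium population; monomorphic draws are
resampled so every retained locus segregates. Haplotypes are exchangeable —
the founder set carries **no ancestral linkage disequilibrium**. This is a
deliberate simplification: in the breeding scheme itself LD is created by the
biparental crossing structure, which is what the genomic-prediction step
exploits, and downstream comparisons among scheme designs depend only weakly
on founder LD. A coalescent founder generator could be substituted without
touching the rest of the pipeline.

## Trait architecture and calibration

The true genetic value is the bilinear form
`G_i = Σ_k a_k x_ik + Σ_(k,l) a_kl x_ik x_il − c₀`, with `x_ik` the −1/0/1
dosage centered at the founder mean of QTN *k*. Additive effects are N(0, 1)
by default; a gamma(shape 1, scale 1) magnitude with random sign is available
(`effect_distribution = "gamma"`) because the two readings of a
"shape/scale 1" effect distribution cannot be distinguished — the choice only
affects effect-size skew, as all variances are rescaled afterwards. QTNs are
paired into disjoint random pairs (one interaction per QTN, 180 pairs at the
default 360 QTNs); the pair effects are rescaled so the founder ratio
Vaa/Va equals the requested epistasis level (0, 0.5 or 1.0) exactly, and the
constant `c₀` plus a global rescaling set the founder mean of G to 0 and its
variance to 1. All reported responses are therefore in founder-genetic-SD
units. Phenotypes add the intercept μ (default 10, arbitrary) and Gaussian
noise with `σ_e² = (1 − H²)/H²` so the founder broad-sense heritability is
H² (default 0.63). `σ_e²` is fixed at this cycle-0 calibration and held
constant for all later generations; the ratio is calibrated against the
realized founder sample, not a theoretical equilibrium population.

## Meiosis and mating

Gametes follow the Haldane model: per chromosome, crossover counts are
Poisson(length/100 cM), positions uniform, no interference, random starting
haplotype (implemented in C++; all randomness flows through R's RNG, so a
single `set.seed` reproduces everything bit for bit). Selfing advances each
line by single-seed descent — one selfed offspring per line per generation —
which matches a program that tracks a fixed set of lines from F2 to F6.
"Random crosses" pair parents without replacement while the parent pool
allows it, otherwise uniformly with replacement excluding self-pairs (the
budget scenarios need up to 160 crosses from 40 parents).

## Burn-in

Three 5-year cycles of a conventional pedigree program establish the base
population: 160 random crosses × 100 F2 per cross, advancement to F6,
new parents at F5, best line at F6. The stage-wise "variable selection
intensities" of such programs are not fully specifiable, so they are
configuration (`burnin_config`): census retention fractions at F2/F3/F4
(default 20 % each) and a selection mode per stage. The default mode culls
**trait-blind** at F2 and F3 and selects **on phenotype** from F4 on
(plus the phenotypic choice of 40 parents at F5). Rationale: in a real
pedigree program most early-generation attrition is logistic rather than
trait-directed, and phenotypic truncation of single F2/F3 plants at 20 %
per stage would compound with the F5 parent choice into a per-cycle gain
far above what 15-year conventional rice programs realize; the chosen
default reproduces both a realistic cumulative burn-in gain and the
relative (cycle-0-anchored) response levels of long-term GS studies.
All-phenotypic burn-in remains one switch away
(`select_on = rep("phenotype", 3)`).

The cycle-0 baseline — the reference for the response to selection
`R_t = Ḡ_t(parents) − Ḡ_0(population)` and for all relativized
trajectories — is the population of 40 base parents returned by the
burn-in, so `R_0 = 0` by construction.

## The test-and-shelf GS cycle

Per cycle: (1) 40 crosses among the 40 parents (in the budget context,
`4000 / progeny size` crosses so the F2 census is exactly 4000); (2) a
random 20 % *test* / 80 % *shelf* split of the F2; (3) the test group is
advanced to F5 by single-seed descent and phenotyped there, while its
**marker genotypes are taken at F2** (the stage where GS acts; the F5 line
is the direct SSD descendant of its F2 plant); (4) a two-kernel GBLUP is
fitted on the test group and the shelf is predicted at F2; the top
0.8 × 40 = 32 shelf individuals on predicted value are advanced to F5;
(5) the 8 best test individuals on F5 phenotype join them, all are selfed
once, and the 40 F6 lines are the next cycle's parents; (6) the best F6
line is chosen on phenotype (true values are used only for metrics).
Prediction accuracy ρ is the Pearson correlation between projected
predictions and true genetic values **on the shelf** — the set where the
predictions actually act; the training (test) set would overstate it.
The training set is the current cycle's test group only; multi-cycle
training-set accumulation is out of scope of the default scheme.

If the marker panel is completely fixed in some late cycle (possible at
desk scale), the cycle falls back to prior-mean predictions: accuracy is
recorded as missing and the shelf choice is arbitrary.

## Genomic prediction

Markers are coded −1/0/1 and centered; the additive kernel is
`G_a = MM'/s` with `s = tr(MM')/n`, so the mean diagonal is exactly 1.
The classical VanRaden denominator `2Σp_k q_k` is available as an option;
the two differ by a scalar only, which the variance component absorbs, so
the likelihood is unchanged. The trace convention was preferred because the
epistatic kernel uses the same one: `G_aa = G_a ∘ G_a`,
`G_aa' = G_aa/(tr(G_aa)/n)`.

`fit_gblup()` maximizes the restricted likelihood of
`y = Xβ + Z_a a + Z_aa aa + ε` by Newton–Raphson with the Fisher
information, on the **log-variance scale** (which enforces nonnegativity),
with step halving, boundary clamping at `10⁻⁸·var(y)`, and an EM-REML
fallback: a few monotone multiplicative warm-up iterations, and an EM step
whenever a Newton step cannot improve (this rescues stalls at variance
boundaries). Convergence is declared when the restricted log-likelihood
changes by less than `tol` (default 10⁻⁸); flat-ridge stops with a small
score also count as converged, and non-convergence is flagged on the
result, not raised. The tests verify the optimizer against an independent
grid search of the restricted likelihood and the BLUPs against a Henderson
mixed-model-equation solve on a whitened scale.

Shelf individuals are predicted per component by kinship (kriging)
projection, `ĝ_c(shelf) = K_cross,c' K_test,c⁻ ĝ_c(test)` with a
Moore–Penrose pseudo-inverse (relative singular-value cutoff 10⁻⁸), and
`ŷ = μ̂ + ĝ_a + ĝ_aa`. Cross and test blocks are cut from **one** kernel
construction over the union of both sets, which makes the projection exact
kriging: it coincides with the conditional mean of the joint model, and for
a shelf individual genotypically identical to a test individual it returns
that individual's fitted value. Because both blocks derive from one marker
feature map, the projection algebraically reduces to
`σ_c² K_cross,c' P y`; the breeding loop uses this direct form (no
pseudo-inverse), and the equivalence of the two forms is asserted in the
test suite. Per-component projection was chosen over a combined (a+aa)
kernel; the union-refit equivalence test covers both readings.

## Metrics and comparisons

Per cycle: population mean G, best-line G, true Va and Vaa (variances of
the architecture-defined components, not REML estimates — the REML
estimates are logged alongside), shelf accuracy, parents' mean G. Across
cycles: `R_t`, relativized trajectories (cycle 0 = 1), and the annualized
relative response `R%/yr = (100/t)·(Ḡ_t − Ḡ_0)/|Ḡ_0|` with t in years.
`Ḡ_t` is read as the **parents' mean** (the same series as `R_t`) so the
cumulative and annualized metrics describe one trajectory; a population-mean
variant is a one-line change in `program_responses()`.

Replicate-level comparisons between progeny sizes use Welch's
heteroscedastic one-way ANOVA (`oneway.test`), the classical omega-squared
`ω² = (SSb − (k−1)MSw)/(SSt + MSw)` (negative estimates truncated at 0;
reported as the plain omega-squared, the partial/total distinction being
moot in a one-factor design), and Games–Howell pairwise tests (Welch t
referred to the studentized range with Welch–Satterthwaite df), Bonferroni
adjusted across the six size pairs. With two groups Games–Howell reduces
exactly to the Welch t-test, which the tests exploit as an oracle.

## Scenario grids, seeding, problem sizes

`scenario_grid()` crosses contexts {theoretical, budget} × progeny sizes
{25, 50, 100, 200} × epistasis {0, 0.5, 1.0} with a replicate count and a
master seed. Within a replicate the founder population is shared across
epistasis levels and the burn-in base population (per epistasis level) is
reused across all sizes and contexts — a paired design that couples the
comparisons and removes base-population noise from the contrasts.
Sub-seeds are drawn once from the master seed, so results are independent
of execution order and runs are resumable.

Two presets fix the problem sizes. The **full** preset is the canonical
configuration (1000 founders, 1644 loci with 360 QTN/540 SNP,
100 replicates, the whole test group trains the GBLUP). The **reduced**
preset is the desk scale used by the test suite and the acceptance script:
300 founders, 600 loci (120 QTN/180 SNP), 10 replicates (20 where an
effect size across four sizes is estimated), and the GBLUP trained on a
random 25 % of the test group. The training fraction is proportional
rather than a fixed cap so that the training-set-size contrast between
progeny sizes — one of the mechanisms separating them — is preserved at
reduced cost. At this scale a complete acceptance pass takes roughly a
quarter of an hour on one CPU.

## Numerical notes

* Variance floors at `10⁻⁸·var(y)`; singular information matrices fall
  back to a ridge-regularized solve with a warning.
* Ties in truncation selection resolve by candidate order; with continuous
  phenotypes they have probability zero.
* Zero-variance accuracy inputs return `NA` with a warning; zero baselines
  make relativized/annualized metrics `NA` rather than infinities.
* Degenerate inputs (role demand exceeding a chromosome's loci, progeny
  sizes not dividing the budget cap, selection demands exceeding
  candidates, unknown parent ids) raise immediate configuration errors.

## What the desk-scale results do and do not show

The reduced genome fixes faster (fewer QTNs, stronger drift), so late-cycle
variance exhaustion and accuracy decay are more pronounced than at the full
scale, and absolute response levels depend on the burn-in intensity
convention described above. The qualitative structure — larger progenies
win under unlimited resources, many small crosses win under an F2 budget,
epistasis raises long-term gains by releasing additive variance through
recombination, and Va/Vaa erode over cycles — is stable across the scales
we run. Real-data features deliberately not modeled: ancestral LD,
genotyping error, dominance and higher-order epistasis,
genotype-by-environment (including epistasis-by-environment) interaction,
multi-environment trials, and calendar/cost logistics beyond the F2 cap.
Passing tests therefore support the internal consistency of the simulator
and the statistical machinery, not field-level forecasts.
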