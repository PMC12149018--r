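---
title: "Models and methods in breedgain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in breedgain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(breedgain)
```

breedgain does two related jobs for a long-running self-pollinating crop
(rice-like) breeding program: it estimates *realized* genetic gain from
historical multi-environment trial records, and it simulates *prospective*
gain under alternative breeding frameworks — purely phenotypic pipelines,
genomic selection (GS) with ridge-regression BLUP, and GS combined with
high-throughput phenotyping (HTP). This vignette explains the models, the
defaults and their units, the numerical choices, and the places where the
design was genuinely open.

## 1. The realized-gain pipeline

Historical data arrive as plot records `(trial, year, location, replicate,
genotype, trait, value)` plus a pedigree `(id, parent1, parent2)`. The
analysis runs in three stages, in a fixed order: outlier removal, per-trial
models and heritability QC, a weighted across-year analysis, and finally
the gain regression.

**Outlier QC.** Within each trial and trait, the observation with the
largest absolute studentized residual of `value ~ genotype + replicate` is
tested as a mean-shift outlier; it is removed while the Bonferroni-adjusted
p-value `min(1, n p)` is below 0.05, refitting after each removal (at most
10 rounds, so a pathological trial cannot loop).

**Stage 1 — per-trial mixed models.** For each trial,
`value ~ genotype + (1 | replicate)` is fit by REML (genotype fixed),
giving one adjusted mean per genotype with its standard error; the weight
carried forward is `1 / SE^2`. Refitting with genotype random gives the
variance components and the plot-basis broad-sense heritability
`H2 = sigma2_G / (sigma2_G + sigma2_E)`. `H2` is used purely as trial QC:
trials with `H2` strictly below 0.35 are dropped (a trial at exactly 0.35
is retained). These per-trial fits use `lme4`; the genotype-random model
has two variance components, which is exactly the case our own one-ratio
REML profiler (below) cannot cover, and there is no reason to hand-roll
what `lmer` does well.

**Connectivity and the check audit.** Separating a genetic trend from year
effects is only possible because consecutive years share genotypes;
`connectivity()` reports, for each pair of years, the shared-genotype count
and `100 |shared| / |union|`. The union denominator is a choice (the
source data only report percentages): it is symmetric and bounded by 100.
Independently, `check_trend()` regresses long-term check genotypes
(present in at least 60% of years) on calendar year; the slope estimates
the *non-genetic* trend and is reported as an audit only — it never
adjusts the data.

**Stage 2 — across-year analysis, two routes.** The *joint* route is
weighted least squares of the stage-1 means on genotype and year (both
fixed), with the stage-1 weights as the diagonal residual weight matrix.
Genotype values are reported as the genotype effect plus the average
estimated year effect, i.e. on the scale of a typical evaluation year; a
disconnected genotype-by-year incidence graph is an error that names the
blocks. The *pedigree* route is the animal model: year fixed, additive
genetic effect random with covariance `A sigma2_a`, where `A` is the
additive relationship matrix from the full pedigree (tabular method,
unknown parents treated as non-inbred founders), and residual variance
`sigma2_e / w_i`. This route predicts breeding values for *every* pedigree
member, including never-phenotyped founders. Because BLUPs are shrunken
toward zero, the pedigree route systematically attenuates the regression
slope relative to the truth — that is a property of regressing predictions,
not a bug, and it is why the synthetic-recovery checks use the joint route.

**Stage 3 — the gain regression.** Ordinary least squares of the stage-2
genotype values on their origin time (the year the cross was made, or the
pedigree generation computed as one plus the highest parental generation,
zero for founders). Time is centred at the earliest origin so the intercept
`a` is the baseline performance and `gain = 100 * slope / a` is a
percentage of baseline per unit time. No weights here: after two stages of
adjustment they would be nearly homogeneous. Raw calendar-year coding
would make the intercept (performance extrapolated to year 0) meaningless,
hence the centring.

**One-ratio REML.** Every mixed model in the package that we fit ourselves
has exactly one genetic variance plus a weighted residual, so REML reduces
to a one-dimensional profile likelihood in `theta = sigma2_g / sigma2_e`.
After projecting out the fixed effects and rotating by the eigenvectors of
the projected genetic covariance, the profile is evaluated in closed form
per `theta`; the optimum is found by bounded 1-D optimization on
`log(theta)` over [1e-8, 1e8] with tolerance 1e-8. A boundary optimum
triggers a warning (animal model) or the fallback ridge rule (RRBLUP).

## 2. The forward simulator

**Genome and trait.** A diploid genome of 12 chromosomes x 137 equally
spaced loci (1644 total), each chromosome 1 Morgan. The map is a choice:
no map was available to pin, and one Morgan per chromosome with Poisson
crossovers and no interference is the simplest standard model. Founders
are 1000 fully inbred lines; per-locus allele frequencies are drawn from
Uniform(0.1, 0.9) and monomorphic loci are redrawn, so every locus
segregates with a realistic spectrum (the species history behind the
founders is not otherwise specified). The trait has 30 QTN and 45 SNP
markers per chromosome (360 QTN, 540 markers), never overlapping.
Additive effects are Gamma(shape 1, scale 1) with a random sign (gamma
draws are positive; zero-centred effects keep the mean-0 calibration
stable); dominance degrees are Normal(0.22, 0.125), so about 26% of loci
show negative (bidirectional) dominance and about 1% overdominance, and
the dominance effect is `|a| * delta`. Genetic values are affinely
rescaled so the founder population has mean 0 and genetic variance 1 —
the rescale is exact, and every later value is on this scale.

**Phenotyping.** A stage evaluation at broad-sense heritability `H2` adds
Gaussian noise with variance `var(G) * (1 - H2) / H2`, where `var(G)` is
the genetic variance of the evaluated cohort itself. Anchoring to the
cohort means each stage realizes its empirical `H2` *in that stage's
(selected) population* — which is what the observed stage table reports
(F2 0.06, F3 0.20, F4 0.45, F5 0.63, F6 0.72, F7 0.81 broad sense).

**Frameworks.** All five share the crossing block: 40 parents, 160
crosses (pairs drawn from the parents' distinct pairs, never selfs, every
parent used), 100 F2 per cross. `Previous` is the traditional pedigree
method: panicle-row phenotypic selection at F3 to 1500 preliminary-trial
(PYT) entries, PYT at F4 to 200 regional-trial (RYT) entries, RYT at F5
to 10 advanced-trial (AYT) entries, parents recycled as the 10 best AYT
plus the 30 best remaining PYT lines; 5 years per cycle. `Current_Trad`
inserts a second regional evaluation (H2 = 0.72) before the AYT. The GS
schemes replace early phenotypic selection with GEBV truncation: at F3
(3.75-year cycle) or at the screened F2 (3-year cycle), and
`GS.F2_HTP.F3` adds an HTP round at F3 — a proxy correlated 0.40 with the
true genetic value keeps 1200 of a 3000-strong GEBV-preselected pool. A
negative phenotypic F2 screen (H2 = 0.06, top 70% advance) is on for the
GS schemes, mirroring the practice that not every plant is genotyped.
Parent recycling in the GS schemes happens at the GS stage itself (top 40
GEBV among the stage's survivors): with 3-to-3.75-year cycles the parents
cannot wait for the PYT/AYT, and rapid recycling is precisely where the
cycle-length advantage comes from. Fractional cycle lengths (5, 5, 3.75,
3, 3 years) make {3, 3, 4, 5, 5} cycles fit a 15-year horizon exactly.
A `long_grain` switch scales cohort counts (not the parent number) to 80%,
the long-grain share of the program, and is on for the five-framework
comparison; the factorial uses its levels as given.

**GS engine.** RRBLUP: `y = 1 mu + Z u + e` with marker codes 1/0/-1 and
`u ~ N(0, I sigma2_u)`; `mu` is the GLS intercept and `u` solves
`(Z'Z + lambda I) u = Z'(y - 1 mu)`. The ridge parameter is
`lambda = sigma2_e / sigma2_u` with components from the one-ratio REML
profile on the training data; if the profile runs to a search boundary the
fallback `lambda = m (1 - h2) / h2` with `h2 = 0.60` is used. Monomorphic
markers are excluded from the solve and returned with zero effect.
Candidates are ranked on `GEBV = M u` (the intercept cannot change ranks).
The initial training set is 1152 F5 lines from 30 crosses among the top
60 PYT lines of the burn-in, phenotyped at the PYT heritability; training
then slides over the most recent three cycles' PYT-stage data (the F3:5
material of the F2-GS schemes). Selection on GEBVs uses additive effects
only — dominance exists in the trait but never enters the marker model.

**Burn-in and experiments.** One founder population and architecture are
simulated from the master seed; the top 40 founders by phenotype
(H2 = 0.63) seed three cycles of `Previous` (15 years), and the resulting
state is the single common starting point shared by *every* replicate of
*every* scheme and factorial cell. Replicates therefore differ only in
downstream stochasticity — recombination, selection, and phenotypic
expression — which keeps the between-replicate residual small and makes
all comparisons paired. The
trajectory records, per cycle: the mean genetic value of the newly
recycled parent pool (the "population mean"), the best advanced-trial
line, and the F2 genetic variance. Annualized gain is 100 x (OLS slope of
population mean on elapsed years within the horizon) / (population mean
at the horizon start); the reference is the post-burn-in mean, which the
phenotypic burn-in guarantees positive on the calibrated scale — the
percentage base was otherwise undefined on a trait that starts at mean 0.
The factorial crosses P in {20, 40, 60, 80} parents, C in {80, 120, 160,
200} crosses and S in {50, 100, 150, 200} progeny per cross (the text's
"12" crosses is read as 120, which is what the result tables enumerate)
on the `GS.F2_HTP.F3` base with the F2 screen on; each run's response is
its annualized gain. Stage targets exceeding a small cell's cohort are
capped at the available candidates; requesting more parents than
candidates is an error.

**Variance decomposition and means clustering.** The factorial responses
are analysed by the balanced three-way ANOVA; the reported `vc_pct` treats
all factors and interactions as random and solves the expected-mean-squares
equations by method of moments, truncating negative solutions at zero —
this decomposition (not the raw sum-of-squares shares, also reported as
`ss_pct`) is the one whose shares match a variance-components reading of
the ANOVA. Scott-Knott clustering then groups the 64 cell means: order by
mean, find the binary split maximizing the between-group sum of squares,
accept it when `pi/(2(pi-2)) * B0 / sigma0^2` exceeds the chi-squared
critical value with `k/(pi-2)` degrees of freedom at 5%, and recurse; with
zero error variance and tied means the result is a single group, and the
letters are disjoint by construction.

## 3. The synthetic historical archive

The generator exists so the realized-gain pipeline is testable with known
truth. Defaults emulate the structure of a ~24-year archive at one tenth
of its plot count (about 2,400 plots; `paper_scale = TRUE` gives ~27,000):
two RCBD trials per year with two replicates, ~25 entries per year,
consecutive-year connectivity targeted at 25% on the shared/union scale
(within the observed 14-36% band), two ever-present checks, a six-cohort
pedigree over ~600 individuals with founders, and kg/ha-like units
(baseline 6000, genetic SD 400 within a cohort, plot residual SD 300, so
plot-basis H2 ~ 0.64, matching archives whose H2 sits mostly above 0.6).
The injected additive trend defaults to 56.54 units per origin year.
Breeding values are mid-parent plus Mendelian noise (variance
`sigma2_g / 2`) plus a per-cohort selection shift that puts every cohort
mean *exactly* on the trend line — so in the noise-free limit the stage-3
regression on the truth recovers the trend exactly, which is what the
recovery tests lean on. Later trial years draw their fresh entries from
the newest cohorts (exponential preference), which is what makes calendar
year and genetic merit separable in stage 2; every plot value decomposes
exactly as baseline + BV + year + trial + replicate + residual, and all
components are stored.

What the generator does *not* emulate: genotype-by-environment
interaction, spatial field trend, trait correlations (milling and height
are not simulated jointly with yield), unbalanced replication, or missing
plots. Passing the recovery tests therefore shows the pipeline's algebra
and ordering are right under the stated error model — not that real
archives meet those assumptions.

## 4. Numerical and performance choices

The simulator stores haplotypes as raw byte matrices (loci x individuals)
and runs meiosis in compiled code: crossover counts are Poisson per
chromosome, positions uniform on the map, and whole segments between
breakpoints are copied. Progeny genetic values (and GEBVs, when a model
is supplied) are accumulated in the same pass while the fresh haplotypes
are cache-hot. Scheme simulations marginalize the genome to the 900
functional loci (QTN + markers, map positions preserved): under Poisson
crossovers the inheritance of the retained loci is statistically
unchanged, so this is exact, not an approximation. The sliding-window
RRBLUP refits use cached per-cycle sufficient statistics (`Z'Z`, `Z'y`,
column sums) that add across window blocks, and the ridge solve reuses
the REML eigendecomposition — verified against the Henderson
mixed-model-equations solution to 1e-10. All randomness flows through R's
RNG (also inside the compiled kernels), so a master seed reproduces any
run; replicate seeds are drawn once from the master stream.

Default problem sizes in the replication surfaces — 20 replicates for the
five-framework comparison and 10 per cell for the 64-cell factorial, with
the full cohort sizes (up to 40,000 F2 per cycle) — are the package's
desk-scale presets; both accept larger replicate counts for paper-scale
runs (100).

## 5. Open design points and known limitations

Several quantities were genuinely open and are pinned as package choices:
the founder frequency spectrum, the genetic map, the crossing-block pair
sampling, the PYT/AYT parent split (30/10), the composition of the second
`Current_Trad` evaluation, the connectivity denominator, the intercept
coding of the gain regression, and the population whose mean defines the
trajectory. Each is documented where it is implemented.

Two limitations deserve emphasis. First, the realized F2 GEBV accuracy
under this architecture and training design is about 0.42; compound
multi-stage phenotypic selection under the observed stage heritabilities
is competitive with that, so the simulated advantage of GS over the
phenotypic frameworks is smaller here than the advantage reported for the
program this package models itself on — the within-GS ordering (HTP over
F2-GS over F3-GS) and the faster loss of genetic variance under GS do
reproduce. The gap plausibly sits in the original simulation's realized
marker accuracy and in the unstated base of its percentage scale, neither
of which is recoverable from the published description; we chose not to
tune stage accuracies to force agreement. Second, the pedigree-BLUP route
attenuates trend slopes by construction (shrinkage), so joint-route and
pedigree-route gains are not interchangeable and the package reports them
separately.
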