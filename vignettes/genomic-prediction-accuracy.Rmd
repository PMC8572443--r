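---
title: "Reference population size and the accuracy of genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference population size and the accuracy of genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gpacc)
```

## The problem

Genomic selection predicts an animal's additive genetic merit (its GEBV)
from SNP genotypes, using a *reference population* of genotyped and
phenotyped animals. Accuracy — the correlation between true and estimated
breeding values in animals outside the reference — rises with the size of
the reference population, but with diminishing returns. Breeding programs
need to know where on that curve they sit: a national beef-cattle program
deciding whether 7,000 or 11,000 recorded carcasses justify replacing
progeny testing is asking a quantitative question about the curve's shape.

The curve's shape is governed by one population parameter. In the
deterministic theory of genomic prediction, the expected accuracy with a
reference of N animals for a trait of heritability $h^2$ is

$$ r(N) \;=\; w \sqrt{\frac{N h^2}{N h^2 + M_e}}, $$

where $M_e$ is the *number of independently segregating chromosome
segments* — a measure of how many effectively independent pieces of genome
the markers must track — and $w \in [0, 1]$ is the accuracy attainable with
an unbounded reference (less than 1 when markers do not capture all genetic
variance). Small $M_e$, as in populations with small effective size $N_e$
and long-range LD, means accuracy saturates early; large $M_e$ means tens of
thousands of records are needed. Everything in this package either simulates
data from populations with a controlled $M_e$-relevant structure or
estimates the pieces of this formula from data.

## What the package computes

1. **Cross-validated accuracy tables.** A fixed test set is held out; GBLUP
   is trained on nested reference sets of increasing size; accuracy per
   size × replicate is `cor(TBV, GEBV)` for simulated traits (TBV known), or
   `cor(y_adj, GEBV)/\sqrt{h^2}` for real-style traits, where the adjusted
   phenotype $y_{adj} = \hat g + \hat e$ removes fitted fixed effects.
2. **The ML inversion.** Replicate accuracies $r_{ij}$ at size $N_i$ are
   treated as normal around $E(r_i) = r(N_i)$ with per-size variance
   $\sigma_i^2$ (the empirical variance of the replicates). The objective
   $L(w, M_e) \propto -\sum_{ij} (r_{ij} - E(r_i))^2 / (2\sigma_i^2)$
   is maximised over $w \in [0,1]$ and $M_e > 0$ (`fit_w_me()`).
3. **Closed forms.** Expected-accuracy curves to any N
   (`accuracy_curve()`), $M_e = 2 N_e L / \ln(4 N_e L)$ from effective
   population size (`me_from_ne()`), $N_e$ from long-range LD
   (`ne_from_ld()`), and the progeny-test EBV accuracy
   $\sqrt{n h^2 / (4 + (n-1) h^2)}$ (`ebv_accuracy()`) for comparing GEBVs
   against conventional evaluation.

## The synthetic population

Real national-herd genotypes are not distributable, so the package ships a
forward-in-time simulator whose output is calibrated to the population
features that matter for this analysis: the LD level at short range and the
effective population size implied by long-range LD.

**Mechanism.** Discrete non-overlapping generations of Wright–Fisher random
mating (monoecious, selfing allowed): each gamete of each offspring comes
from an independently drawn parent, so expected heterozygosity decays by
exactly $(1 - 1/2N)$ per generation — a property the tests verify against
the closed form. Meioses place a Poisson number of crossovers per
chromosome (mean = map length in morgans) uniformly along the chromosome
(Haldane model, no interference) and there is no mutation: over the ~50
simulated generations mutation would contribute negligibly to either LD or
heterozygosity, and omitting it keeps the drift oracle exact.

**Default demography** (all constants live in `sim_config()`, not in code):
founders in linkage equilibrium with allele frequencies uniform on
(0.05, 0.5); 45 generations at a census of 92; one final expansion
generation of 5,000 offspring drawn from those 92 parents; five 100-Mb
chromosomes with 4,000 SNPs each at 1 cM/Mb; 5% of SNPs flagged as the
sparse "LD" prediction panel nested in the dense panel, mirroring the
low-density/high-density array pairing of routine genotyping.

**Why a census of 92 for a target $N_e \approx 100$?** The LD-based
estimator reads $r^2$ at a *map* distance of $c = 1/(2t)$ morgans, but under
Haldane recombination the realised recombination fraction at that distance
is $(1 - e^{-2c})/2 < c$. Plugging map-c into $N_t = (1/r^2 - 1)/(4c)$
therefore biases $N_t$ low by roughly 20% averaged over $t = 1..5$; a census
of 92 puts the *estimator* near 100, which is the quantity the study design
specifies. The 45-generation bottleneck length sets short-range LD: starting
from linkage-equilibrium founders, $r^2$ at 0.15 Mb approaches its
equilibrium $(1 + 4N\tilde c)^{-1}$ at rate $1/(2N) + 2\tilde c$ per
generation, and 45 generations leaves it near 0.2. The single-generation
expansion matters: expanding gradually would let long-range LD re-equilibrate
to the larger census within a few generations (its relaxation rate is
$\approx 2c$ per generation) and destroy the small-$N_e$ signal.

**What the simulator does not reproduce.** Real herds have overlapping
generations, artificial-insemination half-sib family structure, selection,
and a 29-autosome, 25-morgan genome. The synthetic genome is 5 morgans, so
its true segment number is an order of magnitude below a real cattle
genome's — comparisons between the Ne-based and CV-based $M_e$ estimates are
made *within* the synthetic genome (same L), and passing tests show the
estimators behave correctly, not that any particular cattle $M_e$ value is
right. Likewise the simulator emits no missing genotypes by default
(`missing_rate` exists purely to exercise the call-rate filters).

## Trait simulation

QTLs are sampled from dense-panel SNPs with MAF > 0.05 that are *not* on
the sparse prediction panel, so markers tag causal loci only through LD —
the situation genomic prediction actually faces. Effect magnitudes are
gamma(shape 0.4, scale 1.66): strongly leptokurtic, a few large QTLs and
many small ones, with fair random signs applied after the draw. The TBV is
the dosage-weighted effect sum; effects are then rescaled multiplicatively
so the realised TBV variance is **exactly** $100 h^2$ against a phenotypic
variance of 100, and residuals are drawn i.i.d. normal with variance
$100(1 - h^2)$ — equivalently $\sigma_g^2 (1/h^2 - 1)$ at the
post-rescaling $\sigma_g^2$. Rescaling effects (rather than inflating the
residual to match a realised genetic variance) keeps the phenotypic variance
pinned at 100; with the variance matched exactly, the two parameterisations
coincide. The scenario grid of routine use crosses
$h^2 \in \{0.1, 0.3, 0.5\}$ with $n_{QTL} \in \{100, 500, 2000\}$.

For the real-style validation arm, `simulate_covariates()` adds a
carcass-recording structure — feedlot prefecture (18 classes), sex (2),
slaughter year (13), and age at slaughter as centred linear + quadratic
covariates — with class effects a few trait-SD units wide, so fixed effects
absorb a visible variance share and the adjusted-phenotype machinery has
something to do.

## Quality control

The shipped order is: animal call rate (< 0.95 removed) → SNP filters
(MAF < 0.01, call rate < 0.95, HWE p < 1e-3 removed; all statistics on the
current animal set) → GRM-based pruning of close relatives (off-diagonal
> 0.4) → ±3 SD phenotype trimming for recorded traits. The order follows
the narrative order of routine pipelines; filters are idempotent, and each
removal carries exactly one primary reason tag (assessed maf → call rate →
HWE for SNPs).

Numerical choices worth stating:

* **HWE** is the asymptotic 1-df chi-square against expected counts from the
  observed allele frequency, no continuity correction — the convention of
  classic PLINK-era pipelines. An exact test would change decisions only for
  rare SNPs already near the MAF boundary.
* **Pruning** is greedy: repeatedly remove the animal in the most violating
  pairs, ties broken by the lowest position in `grm$ids`. The optimal
  removal set (minimum vertex cover) is NP-hard; the tests verify the greedy
  answer stays within one-per-component of the brute-force optimum on small
  graphs.
* **Trimming** computes means/SDs once on the input table (a single pass).
  A consequence: in a table of n rows, no point can be more than
  $(n-1)/\sqrt n$ SDs out, so very small tables cannot produce trims.
* Zero-variance traits are skipped with a warning rather than dividing by
  zero.

## GBLUP and REML

The GRM is VanRaden's $G = ZZ'/\sum_j 2p_j(1-p_j)$ with $z_{ij} = w_{ij} -
2p_j$, frequencies from the current sample, missing dosages mean-imputed at
$2p_j$ (they contribute zero after centring), and $10^{-5}$ added to the
diagonal. By default it uses only the sparse LD panel, matching routine
evaluation on the low-density array.

`solve_gblup()` solves Henderson's mixed-model equations with the variance
components held *fixed*: in cross-validation the scenario's setting
variances (simulated traits) or the full-data REML estimates (real-style)
are reused in every replicate, never re-estimated — re-estimating per
replicate would leak test information and add noise. Unphenotyped animals
get predictions through their genomic covariances. The tests check the MME
solution against the direct GLS identity
$\hat g = \sigma_g^2 G V^{-1}(y - X\hat b)$ at 1e-8.

`estimate_varcomp()` computes exact REML for the single-GRM animal model by
eigendecomposing G once and profiling the restricted likelihood down to a
one-dimensional search over $\log(\sigma_g^2/\sigma_e^2)$ — with one random
effect this is both faster and more robust than iterative AI-REML updates,
which can step outside the parameter space. The heritability SE comes from
the inverse observed information via the delta method. Two failure modes are
flagged rather than thrown: a boundary optimum, and a flat likelihood (a
GRM with a flat spectrum, e.g. $G = I$, cannot separate the variance
components; `identifiable = FALSE`).

Cross-validation exploits the nesting of reference sets: within a replicate,
$V = \sigma_g^2 G_{ref} + \sigma_e^2 I$ is factorised once at the largest
size, and the Cholesky factor of every smaller nested set is its leading
block, so smaller sizes cost only triangular solves. The engine's results
match `solve_gblup()` exactly on the same masks (tested to 1e-8).

## Fitting (w, Me) and the numerical choices

* Per-size variances $\sigma_i^2$ are the empirical replicate variances; a
  floor of $10^{-6}$ guards noiseless or degenerate tables (with a warning).
* The 2-D search runs L-BFGS-B over $(w, \log M_e)$ from a 5 × 5 grid of
  starts ($w$ from 0.2 to 1, $M_e$ from 10 to $10^5$), then polishes the
  best optimum at tight tolerance. The log-parameterisation keeps the
  problem well-conditioned across four orders of magnitude of $M_e$.
* Degenerate inputs: a table of identical accuracies has a flat likelihood
  and is flagged `identifiable = FALSE`; accuracies above 1 (possible in the
  real-style scheme, where the $\sqrt{h^2}$ scaling can exceed the
  correlation ceiling) are retained, not clipped, and flagged.
* Tie-break and rounding conventions: reported accuracies are conventionally
  rounded to 2 decimals; bins of the LD profile are half-open
  $[k\,\text{bin}, (k+1)\,\text{bin})$, so a pair at exactly one bin width
  falls in the second bin.

The Ne estimator reads $r^2$ from the bin whose midpoint, converted at a
configurable 1 cM/Mb, is nearest to $c = 1/(2t)$ for $t = 1..5$ — that is
10–50 Mb, far beyond the 1-Mb short-range profile, so `ne_from_ld()` takes a
long-range profile (1-Mb bins, thinned SNPs). How to map bins to $c$ is a
genuine free choice with array data (no genetic map); the nearest-midpoint
rule at 1 cM/Mb is the package's documented convention. Downstream,
$M_e = 2N_eL/\ln(4N_eL)$ uses the genome length of the *population being
analysed* — 31.6 morgans for cattle-scale questions, 5 morgans for the
synthetic genome — mixing the two scales would make the Ne-based and
CV-based $M_e$ incomparable.

## Problem sizes used by the tests

The shipped test suite runs the full chain at desk scale, chosen as the
largest sizes a laptop handles comfortably: the default synthetic
population (~5,000 animals before QC, 20,000 SNPs, 1,000 on the prediction
panel), a 500-animal test set with reference sizes 500/1,000/2,000/3,000 and
10 replicates, five trait scenarios covering the heritability ladder at 100
QTLs plus the QTL-count ladder at $h^2 = 0.3$, REML recovery at n = 500 and
n = 1,000, and a 2,000-animal fixed-effects arm for the adjusted-phenotype
path. At this scale the qualitative findings reproduce: accuracy rises with
N and $h^2$, is invariant to QTL count within sampling noise, replicate SD
shrinks with N, the fitted $(w, M_e)$ predicts held-out sizes, and the
Ne-based $M_e$ sits strictly below every CV-fitted $M_e$ — the direction
that makes Ne-only planning optimistic.

## Known limitations

* The simulator's demography is a stylised bottleneck-plus-expansion; it
  matches the target LD summaries but not pedigree structure, selection
  history, or genome size of a real herd.
* The real-style accuracy $\text{cor}(y_{adj}, \hat g)/\sqrt{h^2}$ inherits
  error in $\hat h^2$; with the SE of $h^2$ near 0.01 at n ≈ 12,000 this is
  negligible, but at desk scale it is visible and values can exceed 1.
* `fit_w_me()` treats replicate accuracies as independent normals; in truth
  accuracies across nested sizes within a replicate are positively
  correlated, so the (unreported) sampling variance of $\hat M_e$ would be
  optimistic if derived from the likelihood curvature.
* Single-trait, additive-only models: no dominance or epistasis in the
  traits, no multi-trait or single-step evaluation.
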