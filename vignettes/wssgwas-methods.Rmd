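---
title: "Weighted single-step GWAS: models, algorithms and design choices"
author: "wssgwas package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted single-step GWAS: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wssgwas)
```

## The problem

Nucleus pig herds record growth phenotypes — days to 100 kg (AGE), average
daily gain (ADG), ultrasound backfat (BF), loin muscle depth (LMD) and the
derived lean meat percentage (LMP) — on thousands of animals, but genotype
only a subset, typically the youngest selection candidates. A weighted
single-step GWAS (wssGWAS) uses *all* of this at once: the pedigree links
ungenotyped relatives' phenotypes to the genotyped animals, a genomic
relationship matrix captures realized relationships among the genotyped
ones, and SNP effects are obtained by back-solving from genomic breeding
values rather than by single-marker regression. Genetic variance is then
partitioned into fixed 0.8 Mb genomic windows, and windows explaining more
than 1% of the additive variance are reported as candidate QTL regions.

This vignette documents the models implemented, every numerically relevant
choice, what the synthetic-data generator does and does not emulate, and
the method's known limitations.

## Trait standardization to 100 kg

Animals are weighed and scanned near, not at, the 100 kg reference weight,
so measurements are standardized with the CCSI sex-specific correction
factors:

* `adjustAge()`: $AGE_{100} = age - (weight-100)/CF_1$ with
  $CF_1 = (weight/age) \times 1.826$ for boars and $\times 1.715$ for
  gilts;
* `adjustADG()`: $ADG_{100} = 10^5 / AGE_{100}$ g/day, so
  $ADG_{100}\times AGE_{100} = 10^5$ g identically;
* `adjustBF()` / `adjustLMD()`: multiplicative corrections
  $A/(A + B(weight-100))$ with (A, B) = (13.47, 0.1115) / (15.65, 0.1566)
  for BF and (a, b) = (50.52, 0.228) / (52.01, 0.228) for LMD
  (male/female). Both are exact identities at 100 kg;
* `computeLMP()`: $61.21920 - 0.77665\,BF + 0.15239\,LMD$.

Two conventions required a decision. First, "sire/dam" coefficient labels
are read as the *animal's own sex* (boar-track vs gilt-track), the standard
CCSI usage. Second, the LMP index is evaluated on the **100 kg-adjusted**
BF and LMD, since the index is itself defined at the reference weight.
Animals scanned outside 100 ± 5 kg are flagged (`offTarget`) but retained;
exclusion is left to the analyst.

## Relationship matrices

`buildA()` computes the numerator relationship matrix by the tabular
method, vectorized one row at a time. `inbreeding()` implements the
Meuwissen–Luo ancestor-tracing algorithm, so `buildAInverse()` can
assemble the sparse inverse directly by Henderson's rules *with*
inbreeding: animal $i$ contributes $\alpha_i = 1/D_i$ with Mendelian
sampling variance $D_i = 0.5 - 0.25(F_s + F_d)$ (both parents known),
$0.75 - 0.25F_p$ (one parent) or 1 (founder). Unknown parents are treated
as unrelated, non-inbred founders; genetic groups are out of scope. The
dense tabular path is retained as the test oracle for the sparse rules.

`buildG()` is the VanRaden matrix $G = ZDZ'/\sum_i 2p_i(1-p_i)$ with
$Z_{ij} = m_{ij} - 2p_j$ and diagonal SNP weights $D$. The allele
frequency $p_j$ is the observed frequency of the dosage-counted allele:
since $2p(1-p)$ is symmetric under $p \leftrightarrow 1-p$, the scaling is
identical to a literal minor-allele reading, while centering stays
consistent with the dosage coding. With observed frequencies $G$ is always
singular (centered columns sum to zero), so before inversion it is blended
as $G^* = (1-\alpha)G + \alpha A_{22}$, default $\alpha = 0.05$; $\alpha$
is exposed because reference software applies a comparable default
internally. Genotype QC follows standard thresholds, all strict
inequalities: individual call rate < 0.90, SNP call rate < 0.90,
Hardy–Weinberg $\chi^2_1$ p < $10^{-6}$ (no continuity correction), MAF <
0.01, non-autosomal or unmapped SNPs removed; surviving missing dosages
are imputed by the SNP mean $2p_j$, which is exactly neutral under
centering.

## Single-step GBLUP and AI-REML

The single-trait animal model is $y = Xb + Za + e$ with
$a \sim N(0, K\sigma^2_a)$, where $K$ is $A$ (pedigree BLUP) or $H$
(single-step). The combined matrix enters only through
$$H^{-1} = A^{-1} + \begin{bmatrix}0&0\\0&G^{*-1}-A_{22}^{-1}\end{bmatrix},$$
assembled sparsely with the dense correction in the genotyped block. When
$G^* = A_{22}$, $H^{-1} = A^{-1}$ exactly — a tested identity.

`aireml()` maximizes the restricted likelihood in
$(\sigma^2_a, \sigma^2_e)$ with average-information updates computed from
the mixed model equations: scores use the standard trace identities
$tr(PZKZ') = (q - \alpha\,tr(K^{-1}C^{aa}))/\sigma^2_a$ and the AI matrix
is built from the working variates $Z\hat a/\sigma^2_a$ and
$\hat e/\sigma^2_e$, each projected through one extra MME solve. Numerical
policy:

* starting values $\sigma^2_a = \sigma^2_e = var(y)/2$;
* an AI step that leaves the parameter space is step-halved toward the
  boundary (up to 30 halvings) before falling back to an EM-REML step —
  plain EM converges only geometrically at a boundary optimum
  ($\sigma^2_a \to 0$), which step-halving reaches in a handful of
  iterations;
* components floored at $10^{-10}\,var(y)$; convergence when the relative
  change of both components is below $10^{-8}$; at most 50 iterations,
  with non-convergence reported in the object, never silently accepted;
* $SE(h^2)$ by the delta method from the inverse AI matrix;
* the restricted log-likelihood is evaluated through the MME determinant
  identity and unit-tested against a direct $(V, P)$ evaluation.

Fixed effects (birth year, sex, farm) are dummy-coded at full rank with
the first level of each factor absorbed in the intercept; the choice of
constraint affects only $b$, not variance components or EBVs (both are
tested invariances). `solveMME()` solves Henderson's equations by dense
Cholesky — problem sizes in this package's intended range (thousands of
animals) fit comfortably.

## The weighted scan

`runWssGwas()` iterates, starting from $D^{(1)} = I$:

1. build $G^{(t)}$ from the current weights, blend with $A_{22}$;
2. rebuild $H^{-1}$ and solve the MME for GEBVs of *all* animals;
3. back-solve SNP effects from the genotyped animals' GEBVs:
   $\hat u = D^{(t)} Z' G^{(t)-1}\hat g \,/\sum_i 2p_i(1-p_i)$;
4. update weights $d_i = \hat u_i^2\, 2p_i(1-p_i)$ and rescale them so
   their sum stays equal to the SNP count (trace conservation, tested
   after every iteration);
5. repeat, three iterations by default — the accepted compromise between
   sharpening true signals and amplifying noise.

One printed form of the algorithm multiplies $ZDZ'$ by
$\lambda = \sum 2p(1-p)$; that normalization is inconsistent with the
$G$ definition it accompanies and with the reconstruction identity
$Z\hat u = GG^{-1}\hat g = \hat g$, which holds only when $G = ZDZ'/\sum
2pq$. The package therefore uses the division form throughout, and the
identity $Z\hat u = \hat g$ (unblended $G$) is asserted to $10^{-8}$ in
the tests. Variance components are estimated once, from the
first-iteration (unweighted) $H^{-1}$, and held fixed across iterations;
the weight loop re-estimates GEBVs and SNP effects, not variances.

Windows are fixed, non-overlapping 0.8 Mb bins anchored at each
chromosome's origin, half-open $[k\cdot w, (k+1)\cdot w)$ on 1-based bp
positions; empty bins are dropped, so the reported window count matches
the "bins containing at least one SNP" bookkeeping that makes 100%/2115 =
0.0473% the genome-average share. The variance of a window's aggregate
genotypic value $a_w = \sum_{j\in w} Z_j\hat u_j$ is expressed as a
percentage of the variance of the total genomic breeding value
$Z\hat u$ (population-variance convention, which cancels in the ratio);
dividing by the AIREML $\sigma^2_a$ instead is a documented option.
Because windows covary through linkage disequilibrium and family
structure, shares do not sum to 100% and are reported as-is. Significant
windows are those strictly above 1%; the top three are extended by 0.4 Mb
per side, clipped at chromosome bounds, with ties broken toward the lower
chromosome and start position.

## The synthetic population

`simulatePopulation()` emulates the study design the pipeline targets: a
three-generation nucleus herd (~4200 animals by default), every female of
a generation mated once to a random male of the same generation, balanced
founder sexes, birth year tracking generation, two farms; roughly half of
the animals genotyped, youngest first, mirroring selection-candidate
genotyping. The genome defaults to 18 autosomes of 140 Mb with 1992
evenly spaced SNPs each (~35.9 k genome-wide, matching a post-QC 50K
panel).

Genotypes are gene-dropped: founder haplotypes draw allele frequencies
from Uniform(0.1, 0.9) (a post-QC-like MAF spectrum) with local linkage
disequilibrium generated by a latent AR(1) Gaussian whose correlation
decays as $\exp(-d/L)$, default $L$ = 0.3 Mb — strong within-window,
weak across windows, in line with the LD-decay rationale for a 0.8 Mb
window size in a low-$N_e$ livestock population. Transmission is
Mendelian with crossovers as a Poisson process at 1 cM/Mb, no
interference.

Phenotypes decompose as planted QTL + polygenic background + residual +
fixed effects. Each QTL window concentrates its target variance fraction
on a small number of causal SNPs (default 2; the test configurations use
1) whose effects are rescaled so the window contributes *exactly* its
target fraction of the additive variance; the polygenic remainder is, by
default, genomic — normal effects on `nBackgroundLoci` (default 300)
SNPs outside the QTL windows, evaluated on the gene-dropped genotypes of
**all** animals. This makes the genomic relationship matrix the correct
covariance kernel for the simulated trait while ungenotyped ancestors
still carry signal through inheritance, exactly what single-step needs; a
purely pedigree-based recursion (parental average + Mendelian sampling,
uncoupled from the marker genome) is available as
`polygenicModel = "pedigree"` — with it, realized genomic relationships
are uninformative for the polygenic part and ssGBLUP heritability is
visibly attenuated, which is itself a useful teaching case. Residual
variance is scaled to the target $h^2$ (default 0.33) using the realized
breeding-value variance, fixed-effect level values are drawn at
0.25 phenotypic SD, and the trait is expressed on a days-to-100kg-like
scale (mean 163.4, SD 11.4). A single master seed drives deterministic
per-stage streams (pedigree / genotypes / phenotypes / masking).

What the generator does **not** emulate: selection and drift across
generations, non-additive effects, genotyping-batch or platform artifacts,
a realistic site-frequency spectrum, and real LD-block structure (the
AR(1) model gives smooth exponential decay). Passing tests therefore
validate the estimation machinery under a correctly specified additive
model, not robustness to the many misspecifications of real data.

## Validation design and problem sizes

The test suite checks, besides module-level units: exact textbook
relationship values; Henderson-rules $A^{-1}$ against dense tabular
inversion (500-animal pedigrees, $<10^{-8}$); AI-REML against an
independent EM-REML oracle coded from the direct $(V, P)$ formulation
($<10^{-5}$ on 200-record sets); MME solutions against a GLS oracle and
hand-built normal equations; the GBLUP-backsolve against direct ridge
SNP-BLUP ($<10^{-6}$); and Monte-Carlo recovery runs at a deliberately
compact problem size — about 2000 animals (half genotyped) and 5000 SNPs
on a 160 Mb, 200-window genome, 20 replicate seeds — chosen so the whole
suite runs in minutes while keeping the per-window SNP density of a 50K
panel.

At that size, ssGBLUP heritability is recovered essentially unbiased
(mean absolute bias well under 0.03). A window planted at 3% of the
additive variance behaves differently: its *estimated* share at the first
(unweighted) iteration is strongly attenuated, because back-solving
distributes the GEBV vector across all SNPs in a minimum-norm fashion and,
with many more SNPs than genotyped animals, sample correlations let
distant SNPs absorb much of any window's signal. The weighting iterations
then amplify whichever windows lead early. In consequence the planted
window's share climbs back into the low-percent range by iteration three,
but it wins the genome-wide ranking only in a minority-to-moderate
fraction of replicates — even when the back-solve is fed *true* breeding
values instead of estimates. This is a property of the method at this
scale (window count, $m/n$ ratio, 3% signal), not of the implementation:
the same runs satisfy all algebraic identities exactly. The Monte-Carlo
test asserts the nominal recovery band (mean window share in 2-4%, top
rank in at least 80% of replicates) at face value and is expected to fail
at this scale rather than being weakened; the null-calibration companion
check (no QTL at all: far fewer than 5% of windows above the 1%
threshold) passes, showing the reported regions are not mere
weight-runaway artifacts at that rate.

## Known limitations

* Dense MME/AI-REML algebra: fine to ~5000 animals, not for national
  evaluations; no Takahashi sparse-inverse shortcut for the trace terms.
* Single trait, single records, no maternal or permanent-environment
  effects, no genetic groups or metafounders.
* The $G$ blend parameter is a nuisance the paper trail leaves open;
  results near-singular configurations depend on it mildly.
* Window shares are reported without rescaling; their sum can deviate
  substantially from 100% through inter-window covariance, and ranking —
  not the absolute share — is the robust signal.

## A worked call

```{r example, eval = FALSE}
cfg <- simConfig(nFounders = 200L, nGenerations = 3L, litterSize = 2L,
                 nChromosomes = 5L, chromLengthBp = 3.2e7,
                 nSnpsPerChrom = 1000L,
                 qtlWindows = data.frame(chrom = 4L, startBp = 5.1e6,
                                         endBp = 5.3e6, fraction = 0.03),
                 seed = 1L)
pop <- simulatePopulation(cfg)
res <- runPipeline(pop$ped, pop$geno, pop$pheno, trait = "y",
                   outDir = "wssgwas_out")
res$vcSsgblup
head(windowVariances(res$fit)[order(-windowVariances(res$fit)$gvarPercent), ])
plotWindowVariance(windowVariances(res$fit))
```
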