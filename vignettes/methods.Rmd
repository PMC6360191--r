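---
title: "Models and methods in steppeadmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in steppeadmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

steppeadmix estimates population mixture histories from genome-wide
allele frequencies: which ancient groups were admixed, from which
source lineages, in what proportions, and how long before sampling.
This vignette describes the statistical models, the simulation world
the package tests itself against, the tunable parameters, and the
numerical choices that were genuinely open.

## 1. Data model

The central container is a genotype matrix of alternative-allele counts
(0/1/2, `NA` missing) over SNPs x individuals. Low-coverage ancient
genomes are represented pseudo-haploid: one sequencing read is drawn
uniformly per site and its allele doubled, so calls are 0/2 only and
each individual contributes a *single* allele observation. The allele
frequency table therefore records, per population and SNP, the estimated
frequency together with the *haploid* sample size (1 per pseudo-haploid,
2 per diploid individual). Every downstream finite-sample correction is
expressed in these haploid counts, which keeps mixed cohorts consistent.
This is also why the admixture-f3 "inbreed"-style handling is the
default: with true haploid sizes the correction h/(2n) is valid for
pseudo-haploid data, and a singleton pseudo-haploid target (n = 1) is
rejected rather than silently miscorrected.

EIGENSTRAT support is the ASCII dialect only — one digit per individual
per SNP row, 9 = missing — which is sufficient for desk-scale data and
bit-exactly specifiable. Merging datasets intersects SNP ids and
reconciles allele orientation against the first dataset: swapped
ref/alt flips calls (0 <-> 2); alleles that only match after strand
complementing are complemented unless the SNP is A/T or C/G, whose
orientation is ambiguous; unresolvable sites are dropped and counted.
Physical positions are 1-based, genetic positions Morgans.

## 2. f-statistics and the block jackknife

For per-SNP frequencies $a,b,c,d$ the per-site contributions are
$(a-b)^2$ for f2, $(c-a)(c-b)$ for f3, $(a-b)(c-d)$ for f4; D is the
ratio of summed f4 numerators to the summed normalizer
$(a+b-2ab)(c+d-2cd)$. f2 and f3 subtract $\hat p(1-\hat p)/(n-1)$ per
relevant population, the unbiased estimate of the sampling variance of
$\hat p$ from $n$ haploid draws; f4 needs no correction. Each statistic
uses all SNPs at which its own populations have data ("allsnps"
behaviour); f2(A,A) is defined as exactly zero rather than running the
correction against itself.

Standard errors use the weighted delete-one-block jackknife with block
weights equal to the number of usable SNPs per block. Blocks are
contiguous 5 cM spans within chromosomes (a 5 Mb physical fallback when
genetic positions are absent), matching the convention of the
established f-statistics toolkits; the size is configurable and the
suite verifies that on independent SNPs the jackknife SE tracks the
analytic standard error of the mean within 20% at 100 blocks.

## 3. qpWave- and qpAdm-style modelling

With left (test) populations $l_0..l_{L-1}$ and right (outgroup)
populations $r_0..r_{R-1}$, the matrix $X_{ij} = f_4(l_0, l_i; r_0,
r_j)$ has rank $r$ when the left set is related to the right set
through $r+1$ ancestry streams. The rank test fits the best rank-$r$
approximation under the block-jackknife covariance of $\mathrm{vec}(X)$
by alternating generalized least squares and refers the minimized
quadratic form to chi-square with $(L-1-r)(R-1-r)$ degrees of freedom.
Degrees-of-freedom conventions differ across published descriptions of
these methods; ours is validated by the property that null p-values are
approximately uniform under a true-rank simulation rather than by
matching any particular implementation bit for bit.

qpAdm writes the target as $\sum_i w_i\,\mathrm{source}_i$ with
$\sum w_i = 1$. Since f4 is bilinear in the frequency differences, the
weights must satisfy $w^\top X \approx 0$ where $X_{ij} = f_4(t, s_i;
r_0, r_j)$. The estimator minimizes $w^\top X M(w)^{-1} X^\top w$ with
$M(w)$ the covariance of $X^\top w$ assembled from the jackknife
covariance of $X$; because $M$ depends on $w$ the quadratic solve is
iterated to a fixed point (10 iterations, far more than needed).
Per-weight standard errors re-estimate $w$ on every delete-one-block
matrix. The model p-value is the rank test at $r = k-1$. Weights
outside [0,1] are returned as-is with `feasible = FALSE` — never
clipped — because infeasible-but-fitting models are an informative
failure mode (clade-like source pairs can pass the rank test with wild
weights, as the model-search driver demonstrates). The covariance gets
a relative ridge of 1e-8 on its diagonal; base populations are the
first of each list and results are invariant to permuting the remaining
outgroups (asserted in the suite).

## 4. Admixture graphs

A graph has drift edges with non-negative lengths and admixture nodes
mixing two parents (the simulator accepts more; fitting requires
cascades of two). Expected f2 between leaves follows the path algebra
$\sum_e d_e (m_A(e) - m_B(e))^2$ with $m_X(e)$ the lineage mass of $X$
on edge $e$; f3/f4 derive from f2 by linear identities, so all
f-identities hold by construction. Serialized graphs multiply lengths
by 1000, the convention of published graph figures.

Fitting minimizes $\sum((\mathrm{obs}-\mathrm{pred})/\mathrm{SE})^2$
over all-pairs observed f2. For fixed admixture proportions the
prediction is linear in edge lengths, so lengths are profiled out by
non-negative weighted least squares (active-set clamping) and only the
proportions are searched — multi-start (default 20) bounded
quasi-Newton with seeded uniform initialization, ties broken by score
then lexicographic parameters. Residual Z-scores are also evaluated for
f3/f4 against their own jackknife SEs; the grafting search accepts a
candidate attachment only if the worst |Z| over f2 and f4 stays within
3, mirroring the published procedure of adding populations one at a
time to every edge (and, optionally, every edge pair as a two-parent
admixture) and carrying survivors forward.

Two identifiability caveats matter for interpretation. First, f2 data
cannot place the root along the path between its two children, and an
admixture proportion is only identified when leaves attach to both
parent lineages above the mixing points; the test fixtures are built
accordingly. Second, attachments to either half of a chain through a
degree-2 node are equivalent, so graft tests use skeletons whose
internal nodes are genuine branchings.

## 5. The simulated world

The generator draws root frequencies uniform on [0.05, 0.95] (the
literature states no root distribution; this is configurable), applies
a Balding-Nichols beta step per drift edge — child frequency with mean
$p$ and variance $F p(1-p)$, the standard bounded-drift construction —
and mixes parents linearly at admixture nodes. Genotypes are binomial
draws (pseudo-haploid: one allele doubled) with independent
missingness, default 5%, 10 individuals per population.

Because the Balding-Nichols parameter is F while fitted edge lengths
are in f2 units, predicted and fitted drifts differ by a factor of the
local heterozygosity ($f_2 = F \cdot E[p(1-p)]$ per edge, computed
exactly by a linear moment recursion in `bn_expected_f2()`); admixture
*proportions* are invariant to this unit change, which is why recovery
tests target proportions, not drift lengths. The exact moment recursion
doubles as the independent oracle for the suite's central cross-module
property: empirical f2/f3/f4 from a simulated cohort agree with the
graph-predicted expectations within 3 jackknife SEs.

The default scenario (`fig5_graph()`) is the published joint model of
Mbuti, Loschbour, MA1, EHG, CHG, an Anatolian-farmer lineage, Globular
Amphora, Eneolithic steppe, Maykop and Yamnaya_Caucasus. Its admixture
proportions are the published point estimates — Maykop = 86.4% CHG +
9.6% farmer + 4% EHG; Yamnaya_Caucasus = 16% Globular-Amphora-related;
EHG 70% ANE-related; Globular Amphora 30% WHG; Eneolithic steppe fixed
at 65% EHG within the published "more than 60%" — while the drift
lengths are package defaults at realistic ancient-DNA scale (20-150 in
x1000 units), since per-edge values appear only in the original figure
artwork. Recovery experiments therefore measure proportions, which are
published numbers, and treat drifts as nuisance parameters.

Mosaic haplotypes for dating follow the pulse-admixture Markov model:
ancestry change points Poisson with rate $g$ per Morgan, each change
point redrawing source 1 with probability $p$; allele draws then follow
the segment's source frequencies. This yields weighted LD decaying as
$e^{-g d}$ with amplitude proportional to $p(1-p)$ and to the squared
source divergence; the default dating world uses one 250 cM
pseudo-chromosome, 25,000 SNPs, 500 haplotypes, source divergence
F = 0.2 per side. No coalescent machinery is used: frequency diffusion
plus mosaics is exactly the data-generating model the statistics under
test assume, which is the point of a parameter-recovery harness — and
also its limit. Green tests establish correctness of the estimators
under their own model (plus pseudo-haploid sampling and missingness),
not robustness to background LD, damage, contamination or reference
bias, which real cohorts add.

Sex-chromosome read counts are Poisson per compartment with 1240K-like
target counts (1,150,000 autosomal / 49,704 X / 32,670 Y) and relative
capture/mapping efficiencies X = 0.75, Y = 0.65. The efficiencies are
the one deliberately calibrated choice: the published male/female rate
thresholds (0.42/0.26 and 0.68/0.02) imply male X-rates near 0.37 and
female near 0.75 on real capture data, i.e. sex chromosomes capture
less efficiently than autosomes; the defaults place the simulated rate
distributions where those cohorts sit. A 0.005 mismapping rate puts a
trickle of reads on the Y of females.

## 6. Dating and kinship numerics

The weighted LD curve averages, in 0.1 cM bins up to 10 cM, the
haplotype covariance of each SNP pair weighted by the two references'
frequency differences at both loci; pairs are formed within
chromosomes, zero-distance pairs excluded, and the computation is
verified exactly against a naive pair enumeration. The exponential fit
$A e^{-g d} + c$ uses bins beyond a 0.5 cM cutoff (background-LD guard;
the affine term absorbs the remainder), weighted by pair counts, with a
log-linear start refined by Nelder-Mead; a non-positive fitted $g$ or
amplitude flags the fit as failed rather than erroring. Dates in years
multiply by a 28-year generation time. With multiple chromosomes the SE
of $g$ comes from a delete-one-chromosome jackknife.

Kinship follows the READ logic: pairwise pseudo-haploid mismatch rates
averaged over 1 Mb windows, normalized by the *median* pair score so
the expected-unrelated baseline needs no external panel (the median
pair is exactly 1 by construction), and classified at the
halved-midpoint boundaries 0.625 / 0.8125 / 0.90625 for identical,
first- and second-degree pairs. Genotype-likelihood kinship is
deliberately out of scope; the mismatch method covers the package's QC
needs.

## 7. Pipeline and reproducibility

`run_pipeline()` executes the stages in dependency order from a single
JSON config (JSON rather than YAML because the target environment
ships no R YAML parser), writes one TSV per stage plus a manifest with
package version, seed and output digests, and records per-stage
status — a failed stage aborts its dependents, completes independents.
All randomness flows from explicit seeds; every generator is
bit-reproducible given its seed, and the suite asserts byte-identical
reports for identical configs.

## 8. Known limitations

- The f2-based graph fit weights residuals by their marginal SEs,
  ignoring correlations between observed f2s; worst-|Z| acceptance is
  correspondingly conservative.
- The qpAdm covariance treats the estimated block covariance as known;
  with few blocks relative to outgroup pairs the ridge becomes active
  and p-values turn approximate.
- The grafting search caps survivors per round (default 5) for
  tractability; the published procedure's exhaustive variant is
  recovered by raising the cap.
- Drift lengths recovered from Balding-Nichols simulations are in f2
  units, not F; only proportions are comparable across the unit change.
- One pulse, two references for dating; multi-pulse deconvolution and
  one-reference curves are out of scope.
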