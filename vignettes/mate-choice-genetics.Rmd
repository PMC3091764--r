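---
title: "Detecting genetic assortative mating: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genetic assortative mating: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matescan)
```

# The scientific problem

If humans choose mates non-randomly with respect to genotype, spouses will
be more (assortative) or less (disassortative) genetically alike than
random opposite-sex pairs drawn from the same population. `matescan`
implements a layered battery of statistics to detect and localise such
effects in couple-paired SNP genotypes: a genome/region-level relatedness
coefficient, a per-SNP spousal correlation scan, a sign-restricted regional
meta-analysis, an HLA allele-sharing score, and two downstream consequences
of assortment — excess population homozygosity and depressed offspring
heterozygosity.

All statistics operate on diploid dosages (0/1/2 copies of the alternate
allele, coded as the minor allele at file load) in a `genotype_table`, with
couples given as ordered male/female ID pairs.

# The statistics

## Identity-in-state relatedness, R1

At one SNP, the identity between two individuals is 1 if both are
homozygous for the same allele, 0.5 if either is heterozygous, and 0
otherwise. With $Q_c$ the mean identity between spouses (averaged over SNPs
then couples) and $Q_m$ the mean over all male x female cross pairs,

$$R_1 = \frac{Q_c - Q_m}{1 - Q_m}.$$

$R_1$ is null-centred: random pairing gives $R_1 \approx 0$, genotypically
identical spouses give 1. $Q_m$ is computed in closed form from the two
sexes' per-SNP genotype frequency vectors (the sum over the 3 x 3 genotype
combinations weighted by identity); the test suite verifies this against
the brute-force all-pairs mean. "All possible pairs" means all male x
female cross pairs: the permutation null only ever forms cross-sex pairs,
so same-sex pairs would test a different hypothesis.

Significance comes from spouse reshuffling: wives are re-paired to husbands
by uniform random permutations, $Q_m$ held fixed, and the two-sided p value
is the fraction of permutations with $|R_1|$ at least the observed value.
Because the couple-level identities enter only through the male x female
mean-identity kernel $K_{ij}$, each permutation costs $O(n)$ after one
$O(n^2 m)$ kernel computation, so large permutation counts are cheap.
Both the raw proportion (the definition above) and the bias-corrected
$(b+1)/(B+1)$ are reported.

## Per-SNP spousal correlation, R2

$R_2$ is the Pearson correlation between husbands' and wives' dosages at
one SNP across couples (pairwise-complete; SNPs with fewer than three
complete couples or zero variance are flagged and excluded). Three
significance methods are provided:

* **t approximation** — $t = r\sqrt{(n-2)/(1-r^2)}$ on $t_{n-2}$; exact
  under bivariate normality, an excellent approximation for dosages at the
  sample sizes involved.
* **perm_normal** — per-SNP null mean and sd estimated from spouse
  reshuffles, p from the fitted normal (the method used for single
  PCR-genotyped SNPs, where very large shuffle counts are affordable).
* **genome_background** — a normal fitted to the genome-wide empirical
  $R_2$ distribution, each SNP referred to that common null; a robust
  (median/MAD) option resists a contaminated tail. The exact estimator
  behind the published genome-background p values is not specified in the
  source material, so this normal fit is a documented approximation; for a
  strong single SNP it gives the same order of magnitude as the t
  approximation but not the same digits.

One-sided p values are taken in each SNP's observed direction; two-sided
values feed the Benjamini-Hochberg correction in scans.

## Regional Fisher meta-analysis

For a candidate region, the one-sided p values of its member SNPs with
$R_2 > 0$ (similarity mode) are combined with Fisher's method,
$-2\sum\ln p_i \sim \chi^2_{2k}$; dissimilarity mode uses $R_2 < 0$, and
combined mode all non-zero SNPs with each p one-sided in its own
direction. Using direction-of-sign one-sided p values avoids
double-penalising a sign-conditioned two-sided p. The "combined" mode is
one plausible reading of how the two sign-restricted analyses are merged;
it is flagged as an interpretation.

A low meta value is only meaningful against a background. Two backgrounds
are implemented:

* **Genome-matched**: all chromosomes except the candidate's are tiled
  with windows of the candidate's bp length ("equally sized" is equal
  physical length, since regions are defined in Mbp), centromere-
  overlapping windows are dropped, and windows are kept when their mean
  recombination rate lies on the same side of the genome-average rate as
  the candidate's (low-recombination regions have systematically more
  extreme similarity statistics, so candidates must be compared with their
  like). The matching is tie-inclusive (`<=`/`>=`): with continuously
  varying rates this is identical to a strict inequality, while on flat
  synthetic maps a strict rule would leave no background at all. The
  genome-average rate is the unweighted mean over window-level rates, and
  the tiling step defaults to the 100 kb scan step (both choices the
  source leaves open).
* **Permutation**: when no genome is available (e.g. a dense single-region
  panel), spouses are reshuffled and the candidate's own meta value
  recomputed, giving a regional null.

The empirical p is the fraction of background meta values *smaller* than
the candidate's. For pre-specified candidates this raw fraction is
reported as-is. In hypothesis-neutral scans, where BH correction across
windows follows, the bias-corrected $(b+1)/(n+1)$ form is used instead: at
desk-scale background counts a raw value of exactly 0 reflects the
background's granularity, not evidence, and would make the BH step-up
meaningless.

## Sliding windows

Windows default to 3.6 Mb advanced in 100 kb steps, retained with at least
300 SNPs, never spanning chromosomes. The grid anchors at each
chromosome's first SNP position rounded down to a step multiple — a
deterministic choice independent of chromosome labels (the anchoring
convention is not specified by the source).

## HLA allele sharing

Per gene, a couple scores points equal to the multiset intersection of the
two unordered allele pairs, capped at 2 ("one point for sharing one
allele, two for both"). A homozygote paired with a heterozygote carrying
that allele scores 1: multiset semantics keep the score symmetric and equal
to the number of shared allele copies. Alleles are compared as two-digit
strings. The background is 20,000 couple reassignments; p values come from
a normal fitted to the background (upper tail = similarity, lower tail =
dissimilarity; both are emitted since the tail convention of the published
class II values is not stated), with the Anscombe-Glynn kurtosis test as a
normality diagnostic of the background.

## Population homozygosity link

Mate-choice similarity at a locus should leave excess homozygosity in the
general population. SNPs significant in both the couple scan and a
population panel's Hardy-Weinberg test (both at p < 0.024, chosen because
the pair Fisher-combines to p < 0.005) and with panel MAF >= 1% are
cross-classified by couple direction (sign of $R_2$) and HWE deviation
direction (sign of observed minus expected heterozygotes). The default
chi-square uses Yates' continuity correction — the form that reproduces
the published statistic on the published counts (12.6021; the uncorrected
form gives 14.33) — with the uncorrected version available by flag. The
odds ratio is oriented as odds of homozygote excess given similarity over
the same odds given dissimilarity, with Haldane-Anscombe +0.5 applied and
flagged when a cell is empty. The HWE test is the 1-df goodness-of-fit
chi-square from sample allele frequencies.

## Offspring heterozygosity

For each SNP, the exact Mendelian heterozygote probability of a couple's
offspring is averaged over couples (no children are sampled; the
supplement describes expectations) and divided by $2\hat p\hat q$ at the
offspring allele frequency, which equals the parental frequency because
Mendelian transmission preserves it. Under independent parents the mean of
this ratio is 1 per MAF bin; under assortment it drops below 1 for
similar-parent SNPs. Note that the per-SNP *correlation* between empirical
parental similarity and the het ratio is strongly negative even with
independent parents — a SNP whose sampled spousal correlation happens to
be high mechanically produces fewer expected heterozygotes
($\text{het}_{obs} \approx 2pq(1-\hat r)$). This sampling-level coupling is
the same mechanism the population-level analysis exploits, so the null
checks assert mean similarity ~ 0 and mean ratio ~ 1 rather than a null
correlation.

# The synthetic world

`simulate_couples()` generates the data every downstream test consumes.
Each spouse's marginal genotype distribution is exactly Hardy-Weinberg at
the SNP's MAF; at designated SNPs, spousal dosages are given a target
correlation $\rho$ by drawing a latent bivariate standard normal per
couple and thresholding each coordinate at the HW genotype quantiles. The
latent correlation is calibrated by root finding against the exact
thresholded-normal moments (one-dimensional numerical integration, no
bivariate-CDF dependency), so the induced dosage correlation equals $\rho$
up to integration tolerance. This mechanism was chosen because it
preserves HW marginals exactly while giving continuous control of the
spousal correlation; the source describes no generative mechanism, only
the statistical structure.

Not every $\rho$ is attainable: two HW-marginal dosages at MAF 0.05 cannot
be more anticorrelated than about -0.105 (a Fréchet-type bound). The
calibrator reports the attainable range and refuses targets outside it —
which is why disassortative test worlds use MAF >= 0.15.

Defaults mirror the stated study dimensions where given (930 couples;
5% MAF and 10% per-sex missingness QC; 3.6 Mb/100 kb/300-SNP windows;
0.024 joint thresholds; 20,000 HLA reassignments; 1,000 parent pairs x
2,500 SNPs per MAF bin in the offspring simulation). Where the source is
silent — SNP density, chromosome counts for desk-scale scans — the
generators default to 100 SNPs/Mb over a handful of multi-Mb chromosomes:
dense enough for windows to hold hundreds of SNPs, small enough for
hundreds of replicates per minute. SNPs carry no background LD by default;
the core statistics are per-SNP, and `ld_prune()` is exercised with
explicitly duplicated/correlated columns.

What a green test does **not** establish: the synthetic world has no
population structure, no genotyping-platform artefacts, no LD beyond what
is injected, and independent missingness. Real-data phenomena such as
ancestry-stratified mate choice (which mimics locus-specific assortment)
are out of scope; the genome-background comparisons are the design's
defence, but only real data can exercise them fully.

# Numerical and design notes

* Fisher combination clamps p = 0 to the smallest positive double (with a
  warning); meta values can underflow to 0 for strong regions, which is
  harmless for the rank-based background comparisons.
* Monomorphic or zero-variance SNPs: `Qm = 1` SNPs are flagged (R1 is
  undefined there and `compute_r1` refuses an all-monomorphic set);
  zero-variance SNPs get `r2 = NA` and drop out of all downstream stages.
* Missing dosages are excluded pairwise everywhere (identity means, Qm
  frequency vectors, Pearson sums) rather than imputed — the minimal
  assumption.
* MAF filtering is strictly "above" the threshold (a 5% MAF SNP fails a 5%
  filter); missingness is "at most" the threshold, separately per sex.
* The couple-subset comparison holds $Q_m$ at the full-sample value, so a
  subset changes only $Q_c$; whether the original analysis recomputed it
  within subsets is unstated, and holding it fixed isolates the couples'
  contribution.
* Permutation p values of exactly 0 are reported as such for single
  candidates (with $(b+1)/(B+1)$ alongside); scans BH-correct the
  corrected form only.
* Per-stage CLI seeds derive from the global seed and stage name, so stage
  order never changes results.

# Known limitations

* The genome-background $R_2$ p method is a normal approximation to an
  unspecified published estimator; tail digits differ from it.
* HLA imputation from SNPs is out of scope; the HLA table is an input.
* X-chromosome handling, phasing, and IBD-based ancestry filtering are
  out of scope (autosomal analyses only).
* `ld_prune()` is the greedy left-to-right tagger; it guarantees the
  retained-pair r^2 bound within windows, not a globally optimal tag set.
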