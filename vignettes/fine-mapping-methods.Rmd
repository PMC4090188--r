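---
title: "Methods: QTL fine-mapping in a two-breed F2 intercross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QTL fine-mapping in a two-breed F2 intercross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earmap)
```

# The problem and the design

`earmap` implements a complete fine-mapping workflow for a quantitative
trait — ear area (cm²) in pigs — measured in an F2 intercross between two
divergent founder breeds: a large-eared indigenous breed (Minzhu-like,
assumed QQ at the causal locus) and a small-eared commercial breed
(Large White-like, qq). The reference design is 314 F2 animals in 47
litters, produced by 9 F1 sires mated to 34 F1 dams, slaughtered in 28
batches, with a trait mean of 244 cm² and a coefficient of variation of
22%. Because the genotype data behind such studies are typically private,
the package ships a synthetic-data generator that reproduces this
statistical structure, so every stage is testable end to end.

The workflow is: iterative genotype quality control → GRAMMAR mixed-model
association with genomic control → conditional analysis on the top marker →
marker-assisted segregation analysis (MASS) of the F1 sires → haplotype
block detection, haplotype score tests and founder haplotype sharing →
breed-panel selective-sweep detection. The candidate region is the
intersection of the association interval, the shared-haplotype interval and
the sweep interval.

# The mixed model and the GRAMMAR residual scan

Step 1 fits, once per scan,

$$ y = Xb + wp + Tc + Za + e $$

with fixed effects $b$ (sex, parity, batch), body-weight covariate $w$ with
slope $p$, litter effect $c \sim N(0, I\sigma^2_c)$, polygenic effect
$a \sim N(0, A\sigma^2_a)$ with $A$ the pedigree numerator relationship
matrix (tabular method), and residual $e \sim N(0, I\sigma^2_e)$. Variance
components are estimated by average-information REML with step-halving so
the restricted log-likelihood never decreases, a scaled-gradient fallback
when the AI matrix is singular, components projected onto
$[10^{-8}\hat\sigma^2_y, \infty)$, and convergence declared when the
log-likelihood changes by less than $10^{-6}$. The returned residual is

$$ y^* = y - X\hat b - w\hat p - T\hat c - Z\hat a = \hat\sigma^2_e P y, $$

which is exactly orthogonal to every fixed-effect column.

Step 2 regresses $y^*$ on each marker's allele dosage (pairwise deletion of
missing genotypes; monomorphic markers are flagged, not errors), giving the
substitution effect $\hat k$, its sampling variance and
$T^2 = \hat k^2/\mathrm{var}(\hat k)$. Step 3 applies genomic control:
$\lambda = \mathrm{median}(T^2)/0.456$, $T^2_{adj} = T^2/\lambda$, P-values
from $\chi^2_{(1)}$. The constant 0.456 is the conventional printed value
of the $\chi^2_{(1)}$ median; the exact value 0.45494 can be requested via
`gc_constant = qchisq(0.5, 1)`. $\lambda$ is applied as estimated even when
below 1 — in family designs GRAMMAR is conservative and $\lambda$ is a
genuine *deflation* factor (see "Calibration" below). Significance uses
Bonferroni thresholds $\alpha/n_{tests}$; conditional analysis appends the
top marker's dosage to the fixed effects and re-runs all three steps with
that marker excluded from the rescan.

"Variance explained" per marker is reported as $100\,R^2$ of the Step-2
regression on $y^*$; the literature rarely states the formula behind such
columns, so the definition is fixed here and recorded with the output.

# The synthetic-data generator

`sim_config()` / `simulate_cross()` generate: founder haplotypes drawn from
per-breed allele frequencies; gametes by Poisson crossover counts on a
1 cM/Mb map with uniform placement (Haldane, no interference); a
three-generation pedigree with the reference counts above; and phenotypes

$$ y = \mu + \text{sex} + \text{parity} + \text{batch} + p\,w +
   \text{litter} + a + a_Q(g_Q - 1) + e. $$

Polygenic values use a Mendelian-sampling cascade (founders
$N(0,\sigma^2_a)$; offspring = parent mean $+\,N(0,\sigma^2_a/2)$,
inbreeding ignored), which is exact under the pedigree model used by $A$.

The variance budget is expressed as fractions of the phenotypic variance
implied by the trait mean and CV ($\sigma^2_P = (244 \times 0.22)^2 \approx
2882$): QTL 0.50, polygenic 0.14, litter 0.05, residual 0.29, sex 0.005,
parity 0.003, batch 0.010, body weight 0.002. The QTL fraction is the
design's headline (half the phenotypic variance); the non-QTL split is a
package choice — the source studies do not publish their variance
components — set to a moderate polygenic background with a small
common-litter effect, and rescaled proportionally when the QTL fraction is
changed so the total stays at $\sigma^2_P$.

Founder allele-frequency spectra are likewise unpublished; the generator
draws a shared baseline frequency per marker from Uniform(0.2, 0.8), adds
small breed-specific noise, and imposes elevated between-breed
differentiation in a 2-Mb half-width window around the QTL, with the QTL
allele itself alternatively fixed (frequency 1 in the QQ breed, 0 in the qq
breed). This emulates a region under divergent selection. What the
generator does **not** emulate: genotyping error, crossover interference,
X-linked dosage, mutation, linkage disequilibrium decay shaped by deep
breed history, and multi-chromosome genomes (the panel is one 60-Mb
chromosome with 200 markers, a desk-scale stand-in for a 60K chip).
Passing tests therefore demonstrate correctness of the algorithms under the
assumed generative model, not robustness to artefacts of real array data.

`plant_shared_haplotype()` overwrites the Q-bearing founder chromosomes
with one shared allele pattern over a chosen interval and regenerates all
descendant haplotypes from the stored founder-of-origin labels, creating a
ground-truth identity-by-descent segment for the sharing detector while
preserving Mendelian consistency. `simulate_breed_panels()` builds the
sweep fixture: a case breed fixed over a marker run (panel sizes 32 case /
38, 69, 95 controls) against controls bounded away from fixation.

# Quality control

`iterative_qc()` repeats {SNP call rate < 0.90, MAF < 0.03, exact HWE
P < 10⁻⁶; then sample call rate < 0.90} until a pass removes nothing, with
statistics recomputed on surviving data each pass (the alternative — testing
HWE only once — is not what an iterative filter means, so recomputation was
chosen and is stated here). A marker failing several filters is recorded
under the first, in the order listed. The HWE test is the exact conditional
test (sum of probabilities of heterozygote counts no more probable than the
observed one), well defined at all counts including the extreme tail the
10⁻⁶ threshold probes; a chi-square approximation would not be. Sex-linkage
screening needs array intensities and is out of scope; the report says so.

# MASS

Each F1 sire's offspring are sorted by the transmitted paternal homolog:
at every sire-heterozygous marker the transmitted allele is inferred
(directly from homozygous offspring, via a homozygous dam otherwise) and
votes for the matching homolog; the majority labels the offspring, ties
stay unassigned. The score is
$Z = \log_{10}(L_{H1}/L_{H0})$ with Gaussian likelihoods — group-specific
means and pooled maximum-likelihood variance under H1 (sire Qq), a common
mean and variance under H0 (sire homozygous) — which reduces to
$Z = (n/2)\log_{10}(RSS_0/RSS_1)$. Classification: Qq if $Z>2$, homozygous
if $Z<-2$, otherwise undetermined (boundaries inclusive in
"undetermined"). Two modelling choices are deliberate simplifications: H0
uses a single common mean rather than a QQ/qq mixture, and sorting uses a
multi-marker majority vote rather than pedigree peeling; both are
transparent and adequate at chip marker density. Power analysis under this
likelihood: with the QTL at half the phenotypic variance and Qq dams, the
expected group separation is about 1.15 within-group SD, so the $Z>2$
detection rate is ~64% at 40 offspring and ~84% at the design's average
family size of 53 — consistent with the reference study detecting 6 of 9
sires.

# Haplotype analysis

`em_haplotype_frequencies()` enumerates all diplotypes compatible with each
multilocus genotype (windows capped at 12 markers), starts flat, and
iterates EM to $10^{-8}$; individuals with a missing call in the window are
excluded rather than imputed. `ld_pair()` derives $D$, $D'$ and $r^2$ from
the two-locus EM frequencies. `detect_blocks()` is the Gabriel-style
confidence-interval method with the likelihood-grid bound used by
Haploview: pairs are "strong LD" when the 90% CI on $|D'|$ has lower bound
≥ 0.70 and upper ≥ 0.98, "recombinant" when the upper bound < 0.90; a run
is a block when its outermost pair is strong and ≥ 95% of informative pairs
are, taken greedily by bp span. The published analyses name Haploview but
not its settings (and cite two different versions), so these defaults are
the package's own and are exposed as arguments.

`hap_score_test()` is the Gaussian haplotype score test: expected haplotype
dosages from the EM posterior enter the score function of the linear model
at its null fit; each common haplotype (frequency ≥ 0.02, rarer ones
pooled out of scoring) gets a z score whose sign is the direction of its
trait effect, and the global statistic $U^\top V^- U$ uses a generalized
inverse with df = rank($V$) — one less than the number of scored haplotypes
when they exhaust the chromosomes. A single-marker window collapses to the
square of the marker's score-test z, which the tests assert to 8 digits.

`shared_segments()` reports every maximal run of markers at which all input
haplotypes are identical (exact identity; a mismatch budget would blur the
IBD interpretation, and the workflow's display convention marks exact
shared boxes). Interval refinement is plain intersection of 1-based bp
intervals with lengths reported as end − start.

# Selective sweep

A sweep is a maximal run of ≥ `min_run` consecutive markers at which the
case breed's observed minor allele frequency is exactly 0 while every
control breed stays polymorphic at the run ("any marker" by default,
"all markers" in strict mode). The reported interval runs between the
nearest non-fixed flanking markers, both exclusive. "More than three
consecutive SNPs" is read as ≥ 4, configurable; fixation is judged on
observed calls with the missing fraction reported.

# Calibration, problem sizes and known limitations

Monte-Carlo checks in the test-suite and acceptance script use desk-scale
problem sizes chosen to keep each property estimable in seconds-to-minutes:
20 null scans for calibration, 50 seeds for QTL recovery and conditional
clearance, 200 replicates for MASS power, 20 panels for sweep recovery.

Two measured properties deserve emphasis. First, on null scans with a
polygenic background the GRAMMAR statistic is *deflated*
($\lambda \approx 0.7$ in this 9-sire, 47-litter design): the
polygenic/litter BLUP absorbs between-family variation that marker dosages
also carry. A naive scan on the same data inflates ($\lambda \approx 2$),
and the genomic-control division restores nominal type-I error (~0.05).
This is the documented behaviour of residual-based association in family
designs and is precisely why the method carries a deflation factor;
$\lambda$ near 1 should only be expected in weakly structured cohorts.
Second, MASS power at the Z > 2 threshold is modest at small family sizes
(see above); the package reports the honest rate rather than tuning the
threshold.

Other limitations: the REML engine is dense ($O(n^3)$ per iteration), fine
for intercross-scale data but not for thousands of individuals; block
detection evaluates all marker pairs and is meant for candidate regions,
not genome-wide panels; the annotator is a toy nearest-feature lookup
against a BED file, not a genome-annotation client.

# A worked run

```{r pipeline, eval = FALSE}
report <- run_pipeline(list(seed = 1))
report
```

The report records the scan's $\lambda$, the significant-marker count and
top marker, the conditional-scan outcome, per-sire MASS classifications,
shared-haplotype segments, the refined interval, and the detected sweep
interval; with `out_dir` set, each stage also writes a TSV.
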