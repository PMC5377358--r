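---
title: "Allele-specific allelotyping of X inactivation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific allelotyping of X inactivation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padlockxci)
```

# The problem

In female mouse cells carrying one X from the 129 strain and one from
*Mus musculus castaneus* (Cast), every transcribed SNP reports which allele a
read came from. Padlock-capture sequencing concentrates reads onto a chosen
SNP panel, so each SNP is covered by thousands of reads and even strongly
skewed allelic ratios are measurable. This package implements the
computational half of such a study: from per-SNP base-call counts to

* per-SNP **allelotypes** (129-specific / cast-specific / biallelic /
  undetermined / undetected),
* gene-level **reactivation calls** along an inactive X from which *Xist*
  has been deleted,
* **expression-pattern classes** for non-coding SNPs across three cell
  types (pre-XCI ES cells, post-XCI fibroblasts, *Xist*-deleted mutants),
* **XCI-impairment calls** in an ES-cell differentiation time course under
  Pol III inhibition,
* **repeat-density enrichment** statistics (SINE/LINE tracks, sliding
  window TSS profiles), and
* **5C contact-map** processing (depth normalisation, median binning,
  sign-preserving subtractive log maps).

# The per-SNP model

At a SNP with allele bases $b_{129}$ and $b_{Cast}$, reads carrying either
of the two remaining bases must be miscalls. With $N_{err}$ reads on the two
non-allele bases out of $N_{tot}$ total, the per-substitution error rate is
estimated as

$$\hat\varepsilon = \frac{N_{err}}{2\,N_{tot}},$$

because $N_{err}$ pools two of the three possible substitution targets of
each genuine read. Under a uniform-miscall model the expected contamination
of the 129 count by miscalled Cast reads is $\hat\varepsilon\, c_{Cast}$,
and symmetrically, so the corrected counts are
$c_{129} = \max(0,\ c^{raw}_{129} - \hat\varepsilon\, c^{raw}_{Cast})$ and
vice versa. The correction is parameter-free and exact in expectation for
uniform miscalls; corrected counts are real-valued.

An allele with corrected count $\le$ the **detection threshold** (default
10 reads) is *undetected* and set to 0. If both alleles are undetected the
SNP is excluded. Otherwise the **allelotype ratio** is

$$r = \frac{c_{129} + \kappa}{c_{Cast} + \kappa}, \qquad \kappa = 10$$

with the pseudo-count $\kappa$ preventing division by zero. Classification
uses four thresholds $(t_1, t_2, t_3, t_4)$: cast-specific when
$r \le t_1$, biallelic when $t_2 < r < t_3$, 129-specific when $r \ge t_4$,
undetermined in the buffers. The default buffers are empty
($t_1 = t_2 = 0.01$, $t_3 = t_4 = 100$): the three informative labels then
partition all ratios, and alternative threshold sets (for robustness
re-analysis) are plain configuration changes.

Two details are deliberate design choices. The published description of the
coding-gene analysis states a per-SNP "reads count less than 10" rule while
the non-coding analysis states a per-allele "$\le 10$" rule; we apply the
per-allele rule uniformly, because it subsumes the per-SNP rule and gives a
single semantics for both panels. And error deduction precedes
thresholding; the reverse order would let error-dominated counts survive as
false detections.

# Gene aggregation and reactivation

SNPs map to genes by exonic overlap (intronic SNPs belong to the non-coding
analysis). Counts are summed over all annotation IDs sharing a gene name;
genes with zero reads on both alleles are un-allelotyped and dropped; one
annotation ID per gene name is chosen uniformly at random (seeded) as the
representative for positional analyses. A gene is **reactivated** in a
mutant when

$$\frac{r_{mut}}{r_{ctrl}} \ge 3 \quad\text{and}\quad 0.01 < r_{mut} < 100,$$

both ratios pseudo-counted. Escapee-class genes are evaluated with the same
rule but are exempt from the optional `exclude_control_biallelic` filter
(an escapee is *expected* to be partially expressed in the control, so
control biallelicity is not evidence against it). Genes reactivated in two
or more mutant lines are "frequently reactivated".

# Non-coding expression patterns and differentiation

A non-coding SNP allelotyped in all three cell types gets an **expression
pattern**. The *Xist*-regulated gate requires biallelic expression in ES
cells and cast-specific expression in the control; within the gate,
$R = r_{mut}/r_{ctrl} \ge 3$ with a biallelic mutant means *reactivated*,
otherwise *silenced*; every other combination is *non-Xist-regulated*
(including undetermined labels, which simply fail the gate). Because two
cell lines represent each cell type, the classification is repeated over
cell-line combinations ("combos") and consensus sets are formed: the union
and intersection of non-Xist-regulated calls, the subset never called
Xist-regulated anywhere ("only"), and the conflicted remainder.

For the differentiation course, the text never defines the two ratios it
plots, so the package uses the minimal construction consistent with their
described use: $R_c = r_{day4\,ctrl}/r_{day0}$ measures loss of 129
expression on differentiation (XCI detected when $R_c \le 1/3$), and
$R_i = r_{day4\,inh}/r_{day4\,ctrl}$ measures recovery under Pol III
inhibition (impairment when XCI was detected and $R_i \ge 3$). Both reuse
the global fold threshold and are configurable independently of it only by
changing that threshold — deliberately, since the original analysis used a
single 3-fold criterion throughout. Note that genuine escapees can
legitimately satisfy the $R_c$ criterion (escapee expression is repressed,
not abolished, on differentiation), so XCI-detected fractions slightly
exceed the implanted XCI-subject fraction on synthetic data.

# Repeat enrichment

Chromosome-scale correlation uses per-bin element counts (elements assigned
to the bin containing their start, so each element counts once) and
Spearman rank correlation with average ranks for ties; constant tracks are
reported as `NA` rather than an arbitrary number. The bin size is not
stated in the original analysis; the synthetic-scale default in the
examples (20–500 kb depending on chromosome size) is chosen so that a
track has on the order of 100 bins, enough rank variation for a stable
rho without empty-bin dominance.

TSS flank profiles scan 20 kb upstream and downstream with 3 kb windows at
1 kb steps — $((20-3)/1 + 1) = 18$ windows per side — counting family
elements whose start falls in the window. Upstream/downstream are
strand-aware; the TSS base itself is downstream distance 0. Gene-body
density is normalised as copies per 3 kb of intron, so genes of different
intron content are comparable; intronless genes have no defined value.
Group contrasts (e.g. reactivated vs silenced upstream SINE copy number)
use a two-sided Mann–Whitney test by default because copy-number
distributions are skewed and zero-inflated; a t-test is available.

# 5C processing

The subtractive pipeline follows the order: depth-normalise both samples to
a common total, subtract control from treated, median-bin the difference
$4 \times 4$, then apply the sign-preserving logarithm
$L = \mathrm{sign}(D)\,\log_{10}|D|$ with $|D| = 0$ replaced by the
pseudocount 1 (so $L = 0$ there). The transform has a sharp corner: a
binned difference with $0 < |D| < 1$ yields a log of opposite sign to $D$,
because the pseudocount applies only at exactly zero. With count-scale
data binned by medians this occurs rarely, and it is documented rather
than smoothed away to keep the transform exactly antisymmetric under
sample swap. The log base (10) and the normalisation target (mean of
sample totals) are not fixed by the original description; both are
arguments, and any common target yields the same subtractive structure up
to scale.

# The synthetic-data generator

The generator emulates the study conditions with known truth, so every
downstream caller can be validated by recovery:

* **Coverage**: read totals per SNP are Poisson with mean 9,000 (the
  study's per-SNP depth); allele of origin is Binomial; each read is
  miscalled to a uniformly chosen other base with probability
  `error_rate` (default 0.002, a typical short-read substitution rate).
* **Genes**: default 150 genes tiled on a 3 Mb toy chromosome, each with a
  5 kb three-exon body, three exonic SNPs, and a private 10 kb upstream
  region. 6% of genes are implanted as reactivated (the study's per-line
  rate), 4% as escapees expressing the 129 allele at $p_{129} = 0.2$ in
  all Xi-bearing genotypes (the magnitude is not reported; 0.2 is a
  configurable choice). Silenced genes emit exactly zero 129 reads by
  default (`leakage = 0`), keeping exactness tests exact.
* **Reactivation effect**: a reactivated gene expresses the 129 allele at
  `reactivation_effect` (default 0.05) in the mutant — a free parameter,
  since no per-gene effect size is reported; 0.05 is comfortably above
  the detection threshold at 9,000x yet far from biallelic balance.
* **Non-coding SNPs**: one per strand per 5 kb window (the probe-design
  density), rejection-sampled away from exons so that non-coding truth
  never contaminates exon-overlap gene aggregation. Each carries one of
  four truth patterns: *Xist*-silenced (0.4), *Xist*-reactivated (0.1),
  constitutively 129-silenced (0.25), constitutively biallelic (0.25) —
  the latter two are the non-*Xist*-regulated variants.
* **Differentiation**: 70% of genes are XCI subjects (the study detected
  XCI on 118/169 allelotyped genes) and 79% of those are impaired by
  inhibition (93/118), recovering 129 expression at `impair_effect`
  (default 0.1).
* **Repeats**: families L1, Alu, B2, ID, B4 at baseline densities of
  0.15/0.08/0.06/0.02/0.05 copies per kb (SINE-class densities of the
  right order for the mouse X at toy scale); `sine_coupling` multiplies
  SINE density in the 10 kb upstream of reactivated genes, implementing
  the coupling by Poisson thinning/superposition so that `coupling = 1`
  is exactly the uncoupled model.
* **5C**: two TADs with power-law distance decay, a 3x within-TAD
  enrichment, Poisson counts, and a treated sample whose expected counts
  gain `perturbation * exp(-(|i-b|+|j-b|)/5)` boundary-proximal
  interactions.

All generators are deterministic: annotation under `rng_seed`, and count
emission under a stream derived from `rng_seed` plus the sample label, so
different samples of one run get independent noise while the whole run is
reproducible. Truth labels are recorded from the flags actually used
during emission, so "truth is consistent with the emitted counts" is a
checkable invariant.

What the generator does *not* emulate — and hence what passing recovery
tests cannot show about real data: alignment artifacts and mapping bias
toward the reference allele, PCR duplicates, overdispersed coverage across
probes, genes of heterogeneous length and isoform structure, LINE-length
heterogeneity, and any *cis* correlation structure between neighbouring
SNPs beyond shared gene membership. Recovery at the defaults demonstrates
the correctness of the calling logic at the study's operating point, not
robustness to those real-data pathologies.

# Validation strategy and problem sizes

The test suite validates each operation against hand arithmetic or an
independently coded brute-force oracle (literal re-evaluation of the
quoted criteria, distance-membership window counting, sort-based medians),
and each caller against implanted truth. The recovery studies use 150
genes x 3 SNPs at 9,000x over 10 seeds for reactivation, 5–10 seeds of
~480 non-coding SNPs for patterns, 10–20 annotation draws for the repeat
correlations, and 10 two-TAD draws of 64 fragments for the 5C boundary
property; these sizes give stable averages while keeping the suite fast.
`scripts/acceptance.R` re-runs the same studies end to end from a
command-line seed and writes the recovered quantities as JSON.

The package's interface is its functions plus that script; the pipeline
stages (`simulate` → `allelotype` → `reactivate` / `pattern` / `xci` →
`enrich` / `fivec`) are exposed as composable functions rather than a
shell-level subcommand tool, which keeps the full intermediate state
(data frames) inspectable between stages.

# Known limitations

* The undetermined-buffer thresholds of the original figure-based analysis
  are not transcribed anywhere in text form; the defaults collapse the
  buffers, and users reproducing a buffered analysis must supply their own
  $(t_1, t_2, t_3, t_4)$.
* Escapee calls use the same fold rule as other genes; no significance
  test is fabricated for "significantly increased expression" because none
  is specified.
* The headline counts of the original study (276 genes allelotyped, 40
  reactivated, Spearman 0.62 for Alu, and so on) derive from the deposited
  sequencing data and mm9 annotations; they require those inputs and are
  not reproducible from synthetic data, which is why validation here is
  property- and recovery-based.
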