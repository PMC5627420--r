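---
title: "Methods: somatic landscape analysis of tumor-normal trios"
author: "somatrio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic landscape analysis of tumor-normal trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somatrio)
```

# Scope

`somatrio` analyzes whole-genome tumor–normal trios — a matched normal plus
two tumors from one patient — in the setting of mismatch-repair-deficient
(MMR-deficient) hypermutated cancers. Four analysis stages (consensus
somatic filtering, 96-context mutation spectra with signature matching,
windowed minor-allele-fraction detection of arm-level copy-number loss, and
inter-tumor comparison with truncating-mutation enrichment) sit on top of a
fully seeded synthetic-data generator that provides ground truth for every
stage. Read alignment and raw variant calling are upstream of this package:
it consumes per-caller VCFs and an annotation table, it does not produce
them.

# The synthetic trio generator

The generator is first-class, tested code, not a test fixture. It emulates
the *statistical* structure of a sequenced trio, not reads.

**Genome.** `n_chromosomes` toy chromosomes of i.i.d. uniform A/C/G/T
sequence, each split into a p and a q arm (`arm_length` bases per arm,
0-based half-open intervals). A uniform base composition makes every
trinucleotide context abundantly available, which the context-directed
somatic placement relies on.

**Depths.** Per site and per sample, read depth is Poisson(`mean_depth`)
truncated at 1. The default `mean_depth = 40` reflects typical ~37–40×
whole-genome coverage and comfortably exercises the coverage > 20 site
filter. Poisson is the simplest overdispersion-free model; real FFPE data
are overdispersed (see Limitations).

**Germline het sites.** `het_sites_per_arm` SNVs per arm at uniform
positions. The normal-sample alt-read count is Binomial(depth, 1/2). A
fraction `dbsnp_fraction = 0.95` carries a dbSNP flag and a fraction
`hom_fraction = 0.02` is homozygous-alt (alt count at Binomial(depth,
0.98)); both defaults exist so the high-quality site filter has something
to reject on every criterion while leaving the het majority intact.

**One-copy arm losses.** For a tumor with purity $\rho$ and a planted loss,
the deleted allele (chosen uniformly between ref and alt per site) is
carried only by contaminating normal cells — one copy in a fraction
$1-\rho$ of cells against a mean local copy number $2-\rho$ — so its
expected read fraction is

$$ f_{\text{del}} = \frac{1-\rho}{2-\rho}, \qquad
   f_{\text{ret}} = \frac{1}{2-\rho}, $$

and tumor alt counts are Binomial(depth, $f$). One-copy loss is the only
event simulated: the motivating data show arm losses only, and MSI tumors
are generally near-diploid; gains and copy-neutral LOH are out of scope.
Purity defaults to 0.6 — a free parameter chosen once as a realistic FFPE
tumor-cell fraction; it is not estimated anywhere (nor in the analysis
stages, which only compare curves).

**Somatic SNVs.** `n_somatic` per tumor. Contexts are drawn from a planted
catalog signature (or mixture); for each drawn context the generator picks
an unused reference position whose pyrimidine-collapsed trinucleotide
matches, so the spectrum ground truth matches the catalog by construction.
If a context class is exhausted the context is redrawn. Somatic loci are
disjoint from germline loci. Expected somatic VAF is $\rho/2$ (heterozygous
mutation in the tumor fraction). A configurable `indel_fraction` (default
0) adds small indels solely to exercise truncating classification — indels
carry no trinucleotide substitution class and are skipped by the spectrum.

**Pseudo-callers.** `n_callers = 4` noisy views of one truth: each caller
reports each true variant with probability `caller_sensitivity = 0.9` and
adds Poisson(`private_fp_rate = 20`) false positives drawn from positions no
other caller uses, so false positives are private by construction. All
callers see the same per-variant depths (one sequencing reality). A
fraction `common_snp_fraction = 0.1` of all candidate keys is assigned a
population frequency above 1% in the annotation, emulating residual common
polymorphisms.

**Determinism.** All draws flow from one root seed through named substreams
(reference, germline, somatic, callers, annotation), so a stage can be
regenerated independently and seeded runs are bit-reproducible.

# Consensus somatic filtering

Calls are merged by the caller-independent key (chrom, pos, ref, alt,
sample); a variant is retained when at least `min_callers = 2` callers
support it ("more than one"). Depth fields come from the first caller (in
input order) that reports them; callers never agree on depths in practice
and no reconciliation is attempted beyond recording the supporting set.
The population-frequency filter removes a variant only when its frequency
is *known* to exceed `max_pop_freq = 0.01`: an absent frequency means
"not a known common polymorphism" and is retained, and exactly 1% is
retained (the boundary is strict). Filter order (consensus, then
frequency) is immaterial when frequency is caller-independent — the two
orders provably commute there, and a test asserts it.

Non-silent consequences are missense, nonsense, nonstop, splicing and both
indel classes; synonymous and noncoding are silent. Variants with no
annotation are dropped from the non-silent subset with a warning by default
(`keep_unannotated = FALSE`), since a burden statistic built on
unclassifiable variants is not interpretable.

# Mutation spectra and signatures

SNVs are classified into 96 contexts: six substitution classes on a
pyrimidine reference base, each with 16 flank combinations. Purine-reference
variants are reverse-complemented (substitution *and* flanks) before
labeling — the standard catalog convention and the only one compatible with
a 96-bin scheme. A variant and its reverse-complement representation
therefore share a label (asserted by an exhaustive 192-representation
enumeration). Contexts at chromosome ends or with non-ACGT flanks are
counted as skipped, never silently dropped: `n_snv + n_skipped` equals the
number of SNV inputs.

Spectrum–signature similarity is the cosine; it is the field default for
spectrum matching, scale-invariant (a count vector and its normalization
match identically), and bounded in [0, 1] for non-negative vectors. Ties
are broken by catalog order with a message. The similarity metric is an
assumption of this package — stated here because the qualitative claim it
supports ("most similar to the MMR-deficiency-like profile") does not pin
one down.

`mixture_refit` estimates non-negative exposure weights summing to one by
least squares on the normalized spectrum. Implementation: non-negative
least squares (Lawson–Hanson, via `pracma::lsqnonneg`) on the system
augmented with a sum-to-one row weighted 100 (large enough to enforce the
constraint to ~1e-8 on a unit-scale system), then exact renormalization;
the residual is reported on the unaugmented system. NNLS is deterministic,
dependency-light and standard in signature refitting; a multinomial
likelihood would add nothing at these problem sizes.

The bundled catalog (`demo_signature_catalog()`) is synthetic: an
MMR-deficiency-like profile with 60% of its mass on the four `N[C>T]G` bins
plus four decoys (flat, C>A-heavy, T>C-heavy, APOBEC-like). Cosines between
the planted profile and the decoys are ≤ 0.33, so 300-SNV recovery is
clean. Matching against a real 30-signature catalog uses the same reader on
a user-supplied file.

# Arm-level SCNA and LOH

**Site selection.** High-quality germline het sites must have coverage
strictly greater than 20 in *every* sample of the trio (the "identified in
all samples" reading), a dbSNP entry, a heterozygous normal genotype and a
normal minor-allele fraction of at least 0.25 (inclusive boundary).

**Curves.** MAF values are summarized in sliding windows of
`window_size = 1000` SNVs with `step = 500` (half-window overlap), by the
window median. The median is preferred over the mean because site MAFs at
depth ~40 have heavy binomial tails; a handful of extreme sites should not
move a window. Windows are SNV-index-based, not base-pair-based. Trailing
sites that do not fill a window are reported as a remainder, not windowed.

**Arm call.** An arm is called `loss` when it has at least
`min_windows = 2` full windows, the median tumor window summary is below
`max_tumor_arm_maf = 0.40`, and the normal-minus-tumor median drop is at
least `min_maf_drop = 0.05`; with fewer windows the arm is
`insufficient_data` and never `loss`. These decision constants are this
package's own (no numeric criterion exists for "compare the curves"); they
were chosen so that a one-copy loss at purity ≥ 0.4 and depth ≥ 30 is
detected — the expected lost-arm MAF $(1-\rho)/(2-\rho)$ is ≤ 0.375 there,
against ~0.45 for a neutral arm at depth 40 — while neutral arms at
depth ≥ 20 are not, and they are validated by the seeded recovery
experiments in the test suite (exact recovery of planted arms in ≥ 95/100
seeds; ≤ 1/100 false-positive seeds on neutral genomes).

`min_windows = 2` rather than 3 is deliberate: with 2000 planted het sites
per arm, the site filter removes a handful of sites (coverage, MAF and
genotype criteria each claim ~0.1%), leaving just under 2000 — i.e.
$\lfloor(n-1000)/500\rfloor + 1 = 2$ full windows. Requiring 3 windows
would push every such arm to `insufficient_data` and make the recovery
experiment unsatisfiable at its own design point; two overlapping
1000-site windows already average 1500+ distinct sites per arm.

**LOH sites.** A high-quality normal-het site counts as LOH when the tumor
MAF falls below `loh_site_max_maf = 0.10` (strict). The per-site rule is a
package choice; at purity 1 it counts every het site on a lost arm
(deleted-allele fraction exactly 0), and at purity 0.8/depth 40 the count
matches a closed-form binomial computation (tested).

**Validation quantity.** The generator's closed form is checked on the
*deleted-allele read fraction*, whose expectation is exactly
$(1-\rho)/(2-\rho)$ at every purity. The folded statistic
$\min(v, 1-v)$ used by the detection pipeline has a strictly smaller mean
whenever the binomial distribution straddles 0.5 (low purity), which is a
fold-over bias of the statistic, not a simulator error; the ground truth
records which allele was deleted precisely so the unbiased quantity can be
measured.

# Inter-tumor comparison and enrichment

Overlap summaries are exact set arithmetic on site keys (chrom, pos, ref,
alt) or gene symbols, with the Jaccard index; gene-list tallies are set
intersections against user-supplied lists (a small synthetic stand-in for
curated driver/pathway lists ships with the package).

Truncating classification maps nonsense, nonstop, splicing and indels to
`truncating`, missense to `missense`, everything else (synonymous,
noncoding, unknown) to `other`. Inframe indels count as truncating because
the motivating classification groups indels wholesale; the vocabulary keeps
frameshift and inframe separate so a stricter definition can be re-run.

The germline-vs-somatic enrichment is a two-sided Fisher exact test on the
2×2 truncating/missense table (`other` excluded), with the sample odds
ratio $ad/bc$ (Haldane–Anscombe +0.5 correction when any cell is zero) and
a chi-square p-value reported alongside, since the test behind the headline
p-value is conventionally unnamed. The p-value is reported as computed,
never truncated to a display floor. Against an exhaustive hypergeometric
enumeration over all 2×2 tables with total ≤ 40, the implementation agrees
to ~1e-14 relative error (tested to 1e-12).

Reconstructing the published contingency table from printed totals
(378 germline variants at 89.6% truncating; 46 somatic at 32.6%) by
rounding gives [[339, 39], [15, 31]]; all four rounding candidates
(338/339 × 14/15) satisfy the p ≤ 2.2e-16 reporting floor, so the rounding
ambiguity — which cannot be resolved from printed percentages alone — does
not affect the conclusion.

# Problem sizes

The seeded experiments use, as the package's chosen design points: a 5 Mb
single-chromosome reference with 300 somatic SNVs for signature recovery
(100 seeds); three chromosomes × 2e5-base arms with 2000 het sites/arm,
purity 0.6 and depth 40 for arm-loss recovery and false-positive
measurement (100 seeds each); 10,000 lost-arm sites per purity in
{0.2, 0.4, 0.6, 0.8, 1.0} for the closed-form check; 200-key 4-caller
fixtures for the consensus oracle; and all 135,750 nonempty 2×2 tables
with total ≤ 40 for the Fisher oracle.

# Limitations

- Depth is Poisson: no FFPE overdispersion, GC bias, or mapping artifacts;
  real MAF curves are noisier than simulated ones, so the recovery rates
  measured here are upper bounds on real-data performance.
- No subclonality: losses are clonal and purity is a single number per
  tumor. No sub-arm (segment-level) events, no gains, no copy-neutral LOH,
  and no purity/ploidy estimation.
- The simulator plants non-silent consequences on true somatic SNVs and
  mixed consequences on false positives; it does not model a realistic
  silent/non-silent genome-wide ratio, so simulated burdens are burdens of
  planted variants, not genome-wide rates.
- The bundled signature catalog is a synthetic demonstration object; real
  refitting should use a published catalog file.
- Arm-call thresholds are tuned to one-copy losses at purity ≥ 0.4 and
  depth ≥ 30; shallower losses (purity 0.2 gives an expected MAF of 0.44)
  are by design not called.
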