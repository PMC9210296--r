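---
title: "Methods: stage-specific X misexpression and ampliconic copy number"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-specific X misexpression and ampliconic copy number}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`hybridmsci` packages the statistical machinery for dissecting hybrid male
sterility with stage-resolved testis expression data: cell populations
enriched for leptotene/zygotene (LZ, before meiotic sex chromosome
inactivation), diplotene (DIP, after MSCI) and round spermatids (RS,
postmeiotic), from two parental mouse lineages and their reciprocal F1
hybrids. The pipeline starts from gene-level count matrices and per-base
depth tracks; read trimming, alignment and counting are upstream of this
package.

# Differential expression model

Counts are modeled per gene as negative binomial with variance
$\mu + \phi\mu^2$; $\sqrt{\phi}$ is the biological coefficient of
variation (BCV). Each reported comparison is a two-group contrast within a
cell type (hybrid vs the parent sharing its X chromosome, or hybrid vs
hybrid), which is the design-matrix contrast of a single cross-by-cell-type
factor reduced to its minimal form. For every gene we fit the NB mean under
the null (one mean, per-sample library-size offsets) and the alternative
(one mean per group) by iteratively reweighted least squares with the
gene's dispersion held fixed, and refer twice the log-likelihood-ratio to
$\chi^2_1$. Log fold changes are offset-adjusted group-total ratios with a
0.5-count prior per group, so they are always finite.

**Dispersion estimation.** Per gene, a moment estimate
$\hat\phi_g = (s^2 - \bar y)/\bar y^2$ is pooled across replicate groups
(weighted by within-group degrees of freedom). The common dispersion is
the median of the positive $\hat\phi_g$, divided by the chi-square median
factor $q_{\chi^2}(0.5, d)/d$ (with $d$ the typical per-gene residual df):
the sampling distribution of a variance-ratio estimator is right-skewed,
so its raw median sits below its mean — about 16% low at $2\times3$
replicates — and uncorrected it makes the likelihood-ratio test visibly
anti-conservative. Tagwise values shrink the per-gene estimate toward the
common value with prior weight $w = 10$ (configurable):
$\phi_g^{tag} = (w\,\phi^{common} + d_g\hat\phi_g)/(w + d_g)$, floored at
$10^{-6}$. This is a deliberately transparent stand-in for adjusted-
profile-likelihood machinery; the operating characteristics that matter
here (raw-p calibration near the nominal 5%, Benjamini–Hochberg control,
recovery of planted effects) are exercised directly by the test suite.

**Filtering.** Genes enter a contrast only when FPKM
$= c_{gs} / ((L_g/10^3)(N_s/10^6))$ exceeds 1 (strictly) in at least 3 of
the 6 contrast samples; a global all-sample variant of the filter is also
provided, since published gene counts can be defined on either scope.
Genes failing the filter keep their raw p but are excluded from the BH
family and can never be called DE.

**Normalization.** The default uses total-count (library-size) offsets.
A trimmed-mean-of-M scaling option (`normalization = "trimmed"`) is
provided and is the right choice when a contrast involves strong
asymmetric misexpression: a few hundred strongly up-regulated genes
inflate that sample's library size and shift every null gene's apparent
fold change. On our planted simulations this composition bias leaves
X-linked truth recovery intact either way, but inflates the genome-wide
false-discovery proportion under total-count offsets; the trimmed option
roughly halves that inflation. Both are logged in the run summary.

# X-vs-autosome asymmetry

Per contrast and cell type, expressed genes are classified up
(`logfc > 0`) or down (`logfc < 0`); exact zeros carry no direction and
are dropped from both tallies (they arise only in degenerate synthetic
cases). Pearson's $\chi^2$ (1 df, no continuity correction — the
correction is available behind a flag) compares the X against the
autosomes on the 2-by-2 up/down table, over all expressed genes and over
DE genes only; both scopes are reported because published figures do not
always state which was used. BH adjustment is applied across every test
emitted in one run, mirroring an FDR correction across the displayed
panel. A test with any zero margin is reported as undefined rather than
computed.

# Sliding gene-window scan

Expressed genes (autosomes by default) are ordered by chromosome and
start position; windows of $W = 250$ consecutive genes advance by a
stride of 25 ($W/10$ — the published description says "sliding" without a
stride; a finer stride only adds overlapping windows). Windows never span
chromosomes and a final partial window is dropped. With genome-wide
direction rate $r_d$, the per-window null count is Poisson with
$\lambda_d = r_d W$; a window is flagged when its count strictly exceeds
the 99th-percentile threshold $\min\{k : P(\text{Pois}(\lambda_d)\le k)
\ge 0.99\}$ ("falls outside the 99th quantile", read conservatively).
$\lambda$ is estimated genome-wide by default (per-chromosome behind a
flag). Because adjacent windows overlap, the realized null flag rate runs
below the nominal 1% per-window rate but individual flags are correlated;
the suite calibrates both the null rate and the detection of a planted
60-gene cluster.

# Ampliconic copy number from relative depth

Ampliconic families (Slx/Slxl1 on the X, Sly on the Y) collapse in
assemblies, so copy number must come from relative read depth. Two
estimators are implemented.

**Region coverage.** Paralogs are found by seeding with exact 31-mers of
the query, extending each seeded locus ungapped over the full query span,
and keeping loci with $\ge 97\%$ identity over $\ge 90\%$ of the query
(both strands; overlaps merged keeping the higher identity). The estimate
is the sum of per-region mean depths divided by half the background
depth: half, because the bulk of the genome is diploid while the sex
chromosomes in males are haploid, so one haploid-depth region contributes
exactly one copy. "Summing coverage" is read as summing per-region mean
depths (region-count units): that is the only reading in which the
halved-background denominator is dimensionally consistent.

**Informative sites.** Every 101-bp kmer of the query is counted against
the genome (exact matches, both strands, counts capped at 500). The modal
nonzero count $m$ — smallest on ties, which conservatively assumes fewer
reference copies — is taken as the family's reference multiplicity; a
kmer that maps nowhere exactly does not map "$m$ times" for any $m$, so
zero counts do not vote. Kmers mapping exactly $m$ times are retained,
and for each, every genome location within 2 mismatches is enumerated
(pigeonhole chunk seeding with full-window verification, exact by
construction). Each location's relative depth is the window mean over
half the background depth, optionally GC-corrected; a kmer's contribution
is the sum over its locations and the estimate is the mean over retained
kmers. At the default 99% planted-copy identity, roughly 8% of
copy-kmer pairs exceed the 2-mismatch allowance, so this estimator
carries a structural downward bias of a similar magnitude when many
diverged copies are present — visible in the suite's recovery runs, and
within the cross-method tolerance the estimators are held to.

**Background depth.** Both estimators divide by a background estimated
from the track after masking the paralog (or site) regions, restricted to
intervals whose depth lies within 50% of the length-weighted median. On a
whole-genome track this is indistinguishable from the plain genome-wide
mean; on compact simulated genomes, where the amplicon is a substantial
fraction of all bases, the unmasked mean is visibly inflated by the
amplicon's own pile-up and would bias both estimators low. The plain
genome mean remains available (`background = "genome_mean"`).

**GC correction.** Site windows are binned by GC fraction (2% bins); each
window's relative depth is divided by its bin's median relative depth,
normalized to the global median so the correction removes trend without
rescaling, estimated from 1000 windows sampled from copy-neutral sequence
(windows overlapping the site mask are rejected — sampling the amplicon
itself would contaminate the bin medians). On GC-unbiased simulations the
correction moves estimates by well under 2%.

**Family ratios.** `compute_family_ratio()` reports
$\text{Sly}/(\text{Slx}+\text{Slxl1})$ rounded to a requested number of
significant digits (default 2). Published ratios are printed at two
significant digits except one exact value printed at three; the worked
examples in the suite use each value's printed precision.

# Phenotype statistics

Sperm-head morphology is scored in four categories (normal long apical
hook; shortened hook; short hook, rounded; amorphous) and summarized by
the weighted index $(3n_1 + 2n_2 + n_3)/\sum n_i$, which runs from 3 (all
normal) to 0 (all amorphous) — the weight map is forced by the stated
range and category order. Trait summaries report the per-cross median with
a seeded bootstrap SE (1000 resamples; no analytic SE is assumed for the
median). Hybrid-vs-parent comparisons use the two-sided Wilcoxon rank-sum
test (normal approximation with tie correction); direction arrows are
assigned post hoc from the medians rather than by one-sided testing, and
p-values are BH-adjusted across all trait-by-pair tests of a run.

# Zinc-finger allele typing

PRDM9 alleles are typed by the DNA-contacting residues of each C2H2
finger. Fingers are located with the consensus pattern
`C-x(2,4)-C-x(12)-H-x(3,5)-H`, scanning left to right without overlap;
PRDM9 arrays are regular 28-residue repeats with a fixed 12-residue
spacer between the second cysteine and the first histidine, so
spacer-length variants are rejected rather than aligned. With $H_1$ the
first zinc-coordinating histidine, the recognition-helix positions
$-1/3/6$ are the residues at $H_1-7$, $H_1-4$ and $H_1-1$ — forced by
canonical C2H2 numbering once the spacer is fixed. The first
(nonvariant) finger is excluded by default. Signatures are matched
exactly against a user-supplied allele table; a non-match is reported as
novel with per-finger Hamming distances to the nearest allele(s), ties
surfaced rather than broken. Reconstructing specific published allele
signatures requires their deposited sequences and is out of scope; the
module is generic over the allele table.

# What the generators emulate — and what they do not

The expression generator reproduces the study design (4 crosses, 3 cell
types, 3 replicates), NB counts at BCV 0.1748, per-gene cell-type offsets
(so samples cluster by cell type), log-uniform exonic lengths in
[500, 5000] bp (so FPKM filtering is non-trivial), MSCI as a
multiplicative silencing of X genes (default 0.02) in diplotene of
fertile crosses, and hybrid disruption as a planted $+2$ log2-fold effect
on a configurable fraction of X genes per hybrid and stage. Defaults
plant DIP disruption in both hybrids (0.5 in the direction with a
musculus X, 0.3 in the reciprocal) and RS disruption only in the
Sly-deficient direction (0.5 vs 0) — the qualitative pattern the study
design is built to resolve. Published work does not report effect sizes
for hybrid de-repression, only DE-gene proportions in a figure, so these
fractions are chosen for testability, not fidelity. The generator does
not emulate mapping bias, multi-mapped-read assignment, batch structure,
between-gene correlation, or cell-composition contamination of FACS
fractions; passing tests therefore demonstrate correctness of the
statistics on their assumed model, not robustness to those artifacts.

The amplicon generator plants `ref_copies` near-identical copies (default
identity 0.99) plus one decoy at 92% — below the 97% filter, so the
identity threshold is exercised on both sides — on a 200-kb backbone, and
simulates depth directly as per-base Poisson: rate $2c/2$ on the diploid
backbone and $(N/R)\,c/2$ inside planted copies (all $N$ sample copies
collapsing onto $R$ reference locations). No read-level simulation, GC
bias, or mappability structure is included; the GC correction is
therefore tested only for its null behavior.

The phenotype generator draws traits from per-cross normal distributions
(clipped at physical bounds) and morphology counts from per-cross
multinomials over 100 scored sperm, with defaults emulating a
reciprocal-cross sterility pattern: hybrid testis-weight and sperm-count
deficits, severe morphology loss in the musculus-X direction (index
around 0.7) and moderate loss in the reciprocal (around 1.3).

# Numerical choices and problem sizes

* All interval formats are 0-based half-open (BED/bedGraph convention);
  strand is read where present but ignored downstream.
* Every generator seeds a local RNG stream and restores global state;
  identical configs give byte-identical outputs.
* NB fitting: 50 IRLS iterations, step clipping at ±5 on the log scale,
  likelihood-ratio statistics floored at 0; agreement with a brute-force
  1-D likelihood maximizer is asserted to $|\Delta 2\log L| < 10^{-3}$.
* Ties: modal multiplicity breaks toward smaller $m$; `logfc == 0` genes
  count in neither direction; equidistant allele matches are all
  reported.
* The suite runs the full study design at 3000 genes for truth-recovery
  checks, 2000 genes for null calibration (10 seeds), 200 seeded panels
  for asymmetry null size, 100 seeds for window-scan power and null
  rates, and 10 seeds per planted copy-number configuration — sizes
  chosen so the entire suite completes in a few minutes on one CPU while
  keeping Monte-Carlo error far from each criterion's margin.

# Feeding in real data

Every stage consumes files in plain formats, so the synthetic generators
are not load-bearing: gene counts and sample metadata as TSV
(`read_count_table()`), annotation as BED-like TSV
(`read_gene_annotation()`), depth as bedGraph exported from any coverage
tool (`read_coverage_bedgraph()`), genomes/genes as FASTA, alleles as
TSV. To reproduce a published copy-number table, map whole-genome reads,
export per-base or windowed depth to bedGraph, and run
`find_paralogs()` / `build_informative_sites()` with the family's gene
sequence against the same reference — the estimators then report copies
per haploid genome exactly as in the synthetic runs.

# Known limitations

* The dispersion machinery is moment-based; it matches likelihood-based
  estimators in calibration at the study's replication level but is less
  efficient gene-by-gene, and the far tail of null p-values is mildly
  liberal — the BH family still controls false discoveries at the
  operating points tested.
* The informative-sites estimator inherits a downward bias of order
  $1 - P(\text{Binom}(k, 1-\text{id}) \le 2)$ per diverged copy; at high
  copy identity this is negligible, at 99% identity it is several
  percent.
* The window scan reports flagged windows, not merged regions, and does
  not annotate them against gene families.
* Wilcoxon p-values use the normal approximation throughout; at $n = 6$
  per group exact enumeration differs slightly (the suite checks the
  statistic against exhaustive enumeration and the approximation's
  decisions at its operating point).
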