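---
title: "Methods: joint single-cell methylome and chromatin-conformation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint single-cell methylome and chromatin-conformation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snm3c)
library(data.table)
```

# Scope and data model

`snm3c` analyses joint single-nucleus DNA-methylome + chromatin-conformation
profiles of the kind produced by snm3C-seq on developing brain tissue. Each
cell contributes two tables: an allc-style site table of methylated/total
basecall counts with trinucleotide context, and a pairs-style list of
chromatin contact endpoint pairs. Cell metadata (donor, age group, region,
hierarchical cell-type labels) and region annotations (genes, blocklist)
complete the inputs; clustering and annotation are treated as upstream and
are **not** re-derived here.

All coordinates are 0-based and half-open internally. allc input is treated
as 1-based (a flag overrides); BED and pairs follow their own conventions.
One convention everywhere prevents off-by-one drift between formats.
Contexts are collapsed to three classes: any trinucleotide with G in the
second position is CG; CCC is kept as its own class because methylation
calls at CCC estimate bisulfite non-conversion; everything else is CH.

# Per-cell statistics

**Global methylation.** Fractions are pooled counts, never means of
per-site fractions. The conversion-corrected mCH is
`max(0, (mCH - mCCC) / (1 - mCCC))`; it is reported alongside the raw value
and is never silently substituted.

**Contact QC.** The intra/inter-chromosomal ratio is undefined (not
infinite) for cells without interchromosomal contacts. Cohort summaries
report both the ratio of means and the mean of ratios, which differ for
heterogeneous cohorts.

**Distance decay.** Cis separations are histogrammed over cohort-shared
log-spaced bins and normalized within each cell by its total cis contacts,
so profiles are comparable across sequencing depths.

**SE/LE state.** The short/long statistic is
`r = log2(n[200 kb, 2 Mb) / n[20 Mb, 100 Mb))` on raw bp separations
(half-open bands, no binning), undefined unless both bands hold at least 50
contacts — shallow cells otherwise produce wild log ratios. Cohort states
come from a two-component Gaussian mixture fitted by EM (k-means
initialization, fixed seed); the component with the larger mean is the
short-range-enriched (SE) state and assignment is by maximum posterior, so
it coincides with the Bayes rule under the fitted model. Bimodality is
summarized as `|mu_SE - mu_LE| / pooled sd` and is only claimed above 2; a
vanishing component variance triggers a median-split fallback with a
warning rather than a crash.

**3C gene score (3CGS).** The per-gene score counts cis contacts with
*both* endpoints inside the gene body — the stricter reading of "total
chromatin interaction within a gene body" — with an `endpoint_rule = "any"`
switch for comparability. Because depth- and length-normalization
conventions both exist, the raw count, the per-100k-cis-contacts value and
its per-kb variant are all emitted.

# Methylome matrices and DMRs

Gene-body methylation is pooled `sum(mc)/sum(cov)` per gene per cell; a
gene with no covered site is `NA`, never 0, and the coverage matrix is
returned so callers can mask. Normalization divides each cell by its global
level in the same context, removing per-cell global offsets. Cell-to-cell
distance is the total absolute mCG change summed over genes defined in both
cells, with the shared-gene count reported. Group correlation z-scales each
gene across pseudobulks before Pearson correlation, making it invariant to
per-gene affine rescaling; constant genes are dropped with a warning count.

The DMR caller is deliberately transparent: a per-site two-sided Fisher
exact test on pooled counts between two groups, BH correction, then merging
of significant sites (`q < 0.05`, `|delta| >= 0.1`) within 250 bp of each
other with the same direction and at least two sites; each merged region is
re-scored on its pooled counts and regions are BH-corrected again. All four
thresholds are arguments. Trajectory mode compares succeeding stages;
branch mode compares each derived population against the shared progenitor.
Direction is the sign of the change in the later/derived group. The
vectorized hypergeometric p-value matches `stats::fisher.test` to machine
precision (tested) but runs at scan scale.

The regional-signature test operates on pseudobulk replicates (donors), not
single cells, to avoid pseudoreplication: per gene a Kruskal–Wallis test of
the region effect, BH-FDR, significant genes labeled by the region of
minimal methylation, and the headline percentage (share of signature genes
hypomethylated in the target region) reported to one decimal.

# Pseudobulk 3D-genome analyses

**O/E.** Expected counts per bin-distance are means over unmasked pairs;
masked bins are those with zero marginal counts. Each O/E diagonal has mean
1 by construction; entries with zero expected stay `NA`.

**Compartments.** PC1 of the Pearson correlation matrix of O/E columns,
unit-norm, sign-oriented so that A (positive) has the *lower* mean
pseudobulk mCG per bin (fallback: higher gene density) — eigenvector sign is
otherwise arbitrary. Compartment strength is a 5-quantile saddle statistic:
bins ranked by PC1, strength = (mean O/E of AA + BB corner pairs) / (2 x
mean O/E of AB pairs), pairs closer than 2 bins excluded; 1 means no
segregation. The formula is this package's concrete definition of a
concept that is usually stated qualitatively. Switch detection flags runs
of bins with opposite PC1 sign and `|delta| >=` a threshold between two
tracks. Variance partitioning is a per-bin sequential (type I)
sum-of-squares decomposition over design factors, averaged genome-wide;
with near-balanced designs the factor order is immaterial at the reported
precision.

**Insulation and boundaries.** Crane-style diamond insulation:
`log2(diamond mean / chromosome mean of diamond means)` with a 100-kb
window at 25-kb bins by default; edges are masked. Boundaries are local
minima with topographic prominence of at least 0.5 (log2 units), plateau
ties to the leftmost bin. For sparse pseudobulks `call_boundaries()` can
smooth the track with a short running mean first (`smooth_bins`); shot
noise in diamonds of a few counts otherwise fabricates deep minima. At the
pseudobulk depths used in this package's tests (tens of cells at tens of
thousands of contacts each — far below the study-scale pools) the
operating point is a 200-kb window with 3-bin smoothing; the defaults stay
at the conventional 100 kb / no smoothing.

**Boundary probability and age-DBs.** Single cells are far too sparse for
25-kb insulation, so per-group boundary probability is estimated on
bootstrap pseudobulks: cells resampled with replacement B times (fixed
seed, name-ordered cells, hence order-invariant), boundaries called per
replicate, and a bin's probability is the fraction of replicates calling a
boundary within one bin. Age-differential boundaries compare call counts
between two groups' replicates with a two-sided Fisher test, BH-FDR, the
sign of the probability change labelling gain vs loss. Swapping groups
flips every label.

**Loops.** Candidate 10-kb pixels (anchors >= 2 bins apart, observed >= 5)
are tested against the median of a donut annulus (Chebyshev radius in
(2, 5], anchor row/column excluded) with a Poisson upper tail and BH-FDR.
Differential looping Fisher-tests each loop's count against the remaining
cis total per group.

# Trajectories

Feature spaces per modality: mCG = 100-kb-bin methylation fractions
(feature-mean imputation, imputation count reported, cells under 20%
defined dropped with a log entry); 3C = the normalized decay profile
concatenated with per-chromosome-arm endpoint fractions; joint = z-scaled
concatenation.

Pseudotime builds a kNN graph (k = 15) on PCA scores (20 components). PC
coordinates are first denoised by averaging each cell with its 8 nearest
neighbours: sparse single-cell features carry a noise floor that otherwise
inflates early path lengths. The default score is the **graph geodesic
(arc-length) distance from the root-group medoid**, min-max scaled; the
root medoid scores 0. A diffusion-pseudotime mode (local Gaussian kernel,
spectral decomposition, lambda/(1-lambda) component weighting) is provided
for exploration, but its distances compress across discrete stage
bottlenecks — it orders cells well yet distorts the *cardinal* scale, and a
calibrated scale is exactly what comparing two modalities' maturation
requires. A disconnected kNN graph is an error naming component sizes,
never silently bridged; k must be large enough to bridge discrete stage
clusters.

The two-step maturation claim (chromatin conformation maturing before the
methylome in interneurons, synchronously in MSNs) is operationalized by
`modality_lag()`: per age group the median pseudotime of each modality;
each modality's median-vs-age curve is anchored so its first-age median is
0 and last-age median is 1 (pseudotime has no absolute scale; anchoring
removes per-modality offsets while keeping mid-course ordering); the lag is
the signed area between the anchored curves, positive when 3C runs ahead.
Composition enrichment is a per-stratum two-sided Fisher exact test with
the sample odds ratio and BH-FDR; immature fractions are exact tallies.

# The synthetic cohort generator

Every downstream stage is validated against data with planted truth, so
the generator is first-class, fully seeded code (per-cell substreams
derived by counter, so generation is order-independent and reproducible).

*Genome.* Three chromosomes of 60/40/20 Mb. A genome of uniform 20-Mb
chromosomes cannot carry the 20–100 Mb long-range band at all, so the two
larger chromosomes exist precisely to populate it.

*Cells.* ~300 cells across five ordered age groups (2T, 3T, 1mo, 4-7mo,
adult), in three lineages: MSN-like and interneuron-like neuronal lineages
(each with an immature 2T-only root state) and an OPC/ODC glial lineage
with 1-month transitional states. Each cell carries a maturation score `m`
(stage mean + noise, sd 0.06) that interpolates all m-dependent parameters,
giving a continuous trajectory; the interneuron lineage's 3C maturation
runs one stage (0.25) ahead of its mCG maturation, the MSN lineage is
synchronous, which is the planted truth for the lag analysis.

*Methylomes.* Site grids per context (defaults: CG every 2 kb, CH every
4 kb, CCC every 20 kb; denser CG inside planted DMRs), coverage 1 +
Poisson(1), `mc ~ Binomial(cov, p)`. Baseline mCG 0.75; neuronal mCH rises
from 0.01 to 0.06 with maturation while glial mCH stays flat; CCC sites
methylate at the conversion error 0.005. B-compartment blocks carry +0.04
mCG (which anchors compartment orientation). Most genes on the two
non-marker chromosomes belong to the neuronal maturation program, half
losing (up to −0.45·m) and half gaining (up to +0.20·m) methylation with
graded effect sizes — in the developing brain gene-body remodeling is
pervasive, and a generator with only a handful of responsive genes would
understate the real signal-to-noise. Each state also has three marker
genes (−0.35, contact-boosted). Planted DMRs (~1.8 kb, 12 sites at 150 bp)
come in trajectory (switching on at 3T in the MSN lineage; −0.4 hypo and
+0.2 hyper) and branch (derived interneurons vs progenitor) flavors, kept
outside gene bodies so effects compose within [0, 1]; configurations whose
combined effects leave [0, 1] are rejected at validation.

*Contacts.* Per cell (default 50,000): interchromosomal with probability
1/3 (uniform endpoints on two length-weighted distinct chromosomes), which
fixes the expected intra/inter ratio at 2; otherwise the cis separation is
drawn from the SE/LE mixture — with probability `w_se` log-uniform on
[200 kb, 2 Mb], else a power law `s^-1` on [1 kb, chrom length]. `w_se`
interpolates per state with maturation (neurons 0.25 to 0.55; LE glia 0.15;
transitional SE glia 0.55), creating the bimodal glial SE/LE structure.
Placement is thinned through the compartment plaid (1-Mb alternating A/B
blocks; cross-label contacts accepted at 1/c with the contrast c per age —
neurons start high, 2.0 at 2T, and decay; glia rise), through stage-specific
TAD boundaries (base set every 2 Mb plus extras appearing from 3T onward at
mid-block positions; crossing contacts under 3 Mb accepted at 0.4), and a
small fraction of contacts is re-assigned to planted loops (age-dependent
list, gains dominating later ages) or to the cell state's marker gene
bodies (the mCG–3CGS anticorrelation truth). A planted compartment-switch
region flips labels from 1mo onward.

Because plaid label switches thin cross-border contacts at *all* distances,
block borders weakly insulate by construction — exactly as compartment
transitions do in real insulation tracks. Recovery tests therefore score
boundary recall against planted TAD boundaries and precision against all
planted insulating structure (boundaries plus block borders).

*What the generator does not emulate:* read-level errors, mappability and
coverage biases, realistic chromosome counts/lengths, donor and batch
effects, doublets, and any coupling between methylation and contacts beyond
the planted gene-activity and compartment effects. Passing recovery tests
therefore demonstrates estimator correctness under the generative model,
not robustness to every artifact of real libraries.

# Numerical choices and degenerate inputs

- Fraction outputs are pooled-count ratios; undefined values propagate as
  `NA` and are never imputed silently (feature-space imputation reports its
  count).
- Band edges, blocklist and region membership are half-open everywhere;
  contact endpoints canonicalize by (chromosome order, position).
- EM degeneracy falls back to a median split with a warning; eigenvector
  sign is fixed by the methylation (or density) covariate; PC1 is
  unit-norm.
- BH-adjusted q-values satisfy `q >= p` for every emitted record.
- Bootstrap and mixture seeds are explicit arguments; pipeline stages
  persist the fully resolved configuration next to their outputs, and
  reruns from the same config + seed are byte-identical (tested via file
  digests).
- Ties: boundary plateaus break leftmost; PC1 quantile ranks use
  first-occurrence tie-breaking.

# Problem sizes used by the test-suite

The packaged tests and the acceptance script run the study's analyses at
desk scale, chosen so the whole suite completes in a few minutes on one
CPU: cohorts of 60–300 cells, 3,000–20,000 contacts per cell, site grids of
10–50 thousand CG sites, pseudobulks of 30–80 cells, 20 bootstrap
replicates per boundary-probability estimate, and 200 null repetitions for
the DMR false-discovery check. The methods themselves carry no such
limits; all sizes are configuration.

# Known limitations

- The DMR caller's thresholds are declared defaults, not values inferred
  from any particular dataset; site-level Fisher scans lose power below
  roughly 30 pooled reads per group per site.
- Compartment strength uses a fixed 5-quantile saddle; very short
  chromosome arms (< ~40 bins) make the corners unstable.
- Boundary probability assumes exchangeable cells within a group; donor
  structure within groups is not modelled.
- The lag statistic compares anchored median curves; it is robust to
  per-modality offsets but not to arbitrary nonlinear score distortions,
  which is why the geodesic (arc-length) pseudotime is the default.
- `variance_partition` uses sequential sums of squares and assumes a
  near-balanced design; heavily unbalanced designs should use a
  mixed-model decomposition instead.
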