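---
title: "Allele-specific structure of the inactive X: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific structure of the inactive X: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xistruct)
```

## The problem

In female mammalian cells one X chromosome is transcriptionally silenced
(the inactive X, Xi). Unlike its active homolog (Xa), the Xi folds into two
large "superdomains" of frequent long-range contacts separated by a hinge
region containing the *Dxz4* macrosatellite, shows strongly attenuated TADs
and A/B compartments, and expresses only a small set of genes that escape
X-chromosome inactivation (XCI). In an interspecific hybrid cell line
(*M. musculus* BL6 x *M. spretus*), SNPs between the parental genomes allow
sequencing reads to be assigned to a specific homolog, so chromosome
conformation (Hi-C), factor binding (ChIP-seq), accessibility (ATAC-seq) and
expression (RNA-seq) can all be resolved per allele. `xistruct` implements
the full analysis chain for such data: allelic segregation of read pairs,
contact-matrix processing, one-dimensional structure scores, allelic peak
classification, and escape-gene calling -- together with a synthetic-data
generator that produces every input with known ground truth.

## The synthetic generator

The generator is the package's reference instrument: each analysis is
validated by whether it recovers structure the generator planted.

Expected counts for cell $(i, j)$ of a binned intrachromosomal map are

$$\lambda_{ij} = C\, d_{ij}^{-\alpha}\; S_{ij}\; K_{ij}\; T_{ij}$$

with $d_{ij} = \max(|i-j|, 1)$ and

* $\alpha$ -- power-law contact decay exponent (default 1, the classic
  fractal-globule regime);
* $S$ -- cross-superdomain suppression: cells with one bin on each side of
  the superdomain seam are multiplied by $s \in (0, 1]$ (default 0.1).
  No quantitative insulation strength between Xi superdomains has been
  published, so $s$ is a free parameter, fixed per experiment and stated
  with each test;
* $K$ -- A/B compartment checkerboard ($1 \pm c$, default amplitude 0.3,
  used for the Xa-like control homolog);
* $T$ -- within-TAD enrichment (default 2);
* a one-sided *flame*: contacts of the hinge bin with bins on the flame
  side are set to $C\,d^{-\alpha} f$ (default $f = 6$), overriding the
  suppression. This models the line of unidirectional long-range contacts
  emanating from *Dxz4*; its direction is the generator's proxy for the
  locus's orientation.

Counts are independent Poisson draws, symmetrized; $C$ is set so the
expected total equals the configured pair count. Poisson sampling matches
the count nature of Hi-C data and the multiplicative-bias assumptions of
iterative correction; overdispersion is deliberately not modelled.

Two % of bins (placed away from the hinge) have their expected counts
multiplied by 0.05 on both axes, emulating low-mappability regions. These
are the intended targets of the low-coverage filter; without them the
filter would instead mask the genuinely sparse hinge-flanking bins of a
desk-scale simulation, which real filtering does not do (real maps always
contain far sparser unmappable bins).

Edits mirror the engineered cell lines: a *deletion* removes the edited
bins from the coordinate system and lifts the superdomain suppression
(bipartite structure lost); an *inversion* mirrors the flame direction and
changes nothing else.

Read pairs are sampled multinomially from the count matrix, with uniform
positions within bins and per-end allele evidence: the true allele with
probability $1 - a$, otherwise ambiguous (default ambiguity $a = 0.6$,
emulating a SNP density of roughly one per 93 bp against short read ends).
Peak and expression simulations draw SNP coverage from Poisson
distributions and allelic reads from binomials with class-specific
proportions (Xa-specific 0.95, common 0.5, Xi-specific 0.05; escapers
express from the Xi at a configurable fraction, silenced genes at exactly
zero).

The default scale is a 100 Mb chromosome in 200 bins of 500 kb with
2 x 10^5 pairs. Domain-calling analyses use a 200-bin, 40 kb configuration
(8 Mb with five TADs of 1.6 Mb), matching the resolution at which TADs are
realistically sized relative to the insulation window.

What the generator does **not** emulate: sequence-level reads (no FASTQ or
alignment), real mouse X coordinates or SNP catalogs, overdispersed counts,
trans contacts, copy-number aberrations, or distance-dependent structure
inside TADs. Passing tests therefore demonstrate correctness of the
*computations* under a faithful statistical cartoon of the data, not
robustness to every artifact of real libraries.

## Allelic segregation

Each read end is classified from its SNP evidence: only-BL6 SNPs, only
spretus SNPs, none (ambiguous), or both (conflict, reported separately but
treated as ambiguous downstream). A pair is kept for an allele when at
least one end is specific to it and no end is specific to the other; pairs
with two ambiguous ends, or one BL6 and one spretus end, are discarded --
the conflicting case is not addressed by the published procedure, so the
package discards it and counts it in the QC output, keeping either
convention auditable. Duplicates are pairs whose ends map to identical
coordinates; ends are first ordered lexicographically by (chromosome,
position) so end order cannot hide a duplicate. Count tables are produced
in the standard layout (all ends, trans ends, cis pairs, cis > 20 kb
pairs) with BL6/spretus ratios and ratios relative to genome-wide; a
chromosome with no spretus counts reports an undefined ratio rather than
failing.

## Matrix processing

Processing follows the canonical staged pipeline, and every stage
preserves symmetry and the bin mask:

1. **Binning**: 1-based position $p$ maps to 0-based bin
   $\lfloor (p-1)/\text{binsize} \rfloor$.
2. **Filtering**: the diagonal and the two adjacent diagonals are zeroed
   (self-ligation products); bins in the lowest 2% of marginal coverage
   (computed after the diagonal zeroing) are masked entirely. Ties at the
   percentile are all masked -- degenerate inputs with many tied marginals
   therefore mask every tied bin, which the tests pin explicitly.
3. **Balancing (ICE)**: symmetric square-root iterations divide each cell
   by $\sqrt{r_i r_j / \bar r^2}$ until the coefficient of variation of
   unmasked row sums falls below `tol` (default 1e-5, maximum 200
   iterations with a warning), then total mass is rescaled to the input.
   The accumulated bias vector is retained so the input is exactly
   reconstructable -- the tests verify reconstruction to 1e-8 relative
   error.
4. **Quantile normalization** across samples operates on unmasked
   upper-triangle cells (zeros included; the union of masks applies to
   all matrices), averaging sorted values rank-wise with ties averaged.
5. **Pearson transform**: entry $(i,j)$ becomes the correlation of columns
   $i$ and $j$. It is applied to balanced (or quantile-normalized)
   matrices rather than observed/expected so the distance effect is not
   normalized away. Constant columns yield missing rows and never poison
   neighbours.

Decay curves report, per separation $k$, both the probability form
(sum at $k$ over total mass; sums to one) and the raw per-cell mean; the
published definition says "normalized sum" without choosing, so both are
exposed, and the exponent fit uses the mean form, whose log-log slope is
$-\alpha$ for a pure-decay map. Between-sample depth differences are
removed by a least-squares scalar fit of each sample's autosomal curve to
a reference, applied to the X curves. Virtual 4C tracks are viewpoint row
sums with the viewpoint bins reported missing; any display clamp is
presentation-only.

## Structure scores

**Compartment PCs.** The balanced matrix is distance-corrected
(observed/expected with the expected value the mean unmasked contact at
each separation), turned into a Pearson correlation matrix, and
eigendecomposed; track $p$ is eigenvector $p$ times the square root of its
eigenvalue, with the sign fixed so the largest-magnitude entry is
positive. Observed/expected ratios are clipped at 5 (`oe_cap`) before the
correlation: at realistic shallow depth the long-range distance bands have
expected counts well below one, so single stray contacts otherwise
produce enormous ratios that dominate the correlations and inject
spurious sign flips into PC1. On a bipartite chromosome PC1 is a
two-block pattern whose single sign switch marks the superdomain seam; on
a compartmentalized control it tracks the A/B checkerboard. Note that a
rank correlation between PC1 and binary compartment labels cannot exceed
$\sqrt{3}/2 \approx 0.87$ even for perfect recovery, so agreement is
quantified by the sign pattern, not by Spearman's rho.

**Coverage score.** The raw score of bin $i$ is the mean contact over all
off-diagonal unmasked cells spanning it (a V-shaped region whose arms
reach the matrix edges, so all length scales contribute), normalized as
log2(score / chromosomal mean), smoothed with a five-window degree-two
Savitzky-Golay filter, and standardized or rescaled to [0, 1]. The filter
cannot produce the outermost bins, which are assigned linearly
interpolated values; interior missing bins are bridged by linear
interpolation before smoothing and restored to missing afterwards. An
optional edge exclusion drops bins within a configurable distance of the
chromosome ends (10 Mb in the reference analyses of unmerged samples).
The global minimum of the track marks the hinge; the maximal contiguous
run below a threshold (0.015 on the unit-rescaled track) containing that
minimum is the boundary region. Because the flame is one-sided, the
minimum sits on the non-flame side of the hinge bin, and inverting the
flame moves it to the opposite side -- the inversion phenotype. The
inversion edit being a pure mirror, the simulated boundary region
relocates but does not systematically widen.

**Insulation and TADs.** The insulation score of bin $i$ is the mean
contact in the off-diagonal square spanning `is` bins on each side,
log2-ratioed to the chromosomal mean; window presets convert the standard
bp options for 500 kb (3500001 / 2000001 / 1000001 for is / ids / ss) and
40 kb (520001 / 320001 / 160001) bins. Bins without a full square are
missing, as are windows with under half their cells unmasked. Within a
window, available cells are averaged per distance class and recombined
with the full square's distance composition: a plain mean over available
cells systematically dips next to masked bins, because masking removes
the square's nearest-diagonal (largest) cells preferentially. The delta
vector is the difference between mean insulation over `ids` bins to the
left and to the right; by default insulation is smoothed (moving mean of
span `ss`) before differencing, and the unsmoothed order is available.
Boundaries are the positive-to-negative zero crossings of delta; strength
is the delta local maximum to the left minus the local minimum to the
right within `bmoe` (3) bins; candidates at or below the noise threshold
`nt` (0.01) are dropped and near candidates within `bmoe` merge into the
stronger. TADs tile the span between surviving boundaries. TAD calls are
compared as per-bin partitions with the adjusted Rand index
(pair-counting form), and score tracks cluster hierarchically
(average linkage) under Euclidean or $1 - r$ distances. The boundary
variant implemented here (zero crossing + margin merge) is pinned by
synthetic-truth tests, not by byte-equality with any external tool, whose
exact internals are not published.

## Allelic peaks and expression

Peaks with at least five SNP reads get an allelic proportion
spretus/(spretus + BL6) and a d-score (proportion - 0.5); proportions
above 0.7 are spretus/Xa-specific, below 0.3 BL6/Xi-specific, and the
closed interval [0.3, 0.7] is common, matching the bracket notation of
the source procedure. Peaks are assigned to bins and genes by midpoint (a
choice the procedure leaves open; tests pin it). Binned densities scale
by the ratio of autosomal SNP-covered peak totals between samples; the
published factors are data-specific outputs of this rule, not constants.
Gene-level densities extend each gene 10 kb upstream of the TSS
(strand-aware, clipped at the chromosome start) through the TTS and
normalize per kb. Paired density differences are tested per gene group
with a one-sided signed-rank test, exact for n <= 25 via a dynamic
program over the rank-sum distribution (midranks doubled to integers, so
ties remain exact) and a continuity-corrected normal approximation above.
Colocalization uses the relative distance metric: each query midpoint's
distance to its nearest reference midpoint, normalized by the flanking
reference spacing; unassociated sets are flat on [0, 0.5] with mean 0.25.

Expression analysis converts counts to TPM
($10^6 (c_i/\ell_i) / \sum_j (c_j/\ell_j)$, annotated transcript length,
no effective-length correction), distributes each gene's counts to
alleles by its SNP read proportion (conserving the total exactly, with
the diploid TPM denominator shared so allelic TPMs add up), and calls
escape from XCI per sample by four criteria: the one-sided exact
(Clopper-Pearson) 99% lower confidence limit on the Xi read proportion
exceeds 0.01; diploid TPM >= 1; Xi-TPM >= 0.1; SNP coverage >= 5. The
lower bound is $\mathrm{qbeta}(\alpha, x, n - x + 1)$, exactly zero at
$x = 0$, so a fully silenced gene can never be called -- the caller's
specificity on true silenced genes is analytic, not statistical. The
published criterion is "parameterized by the expected proportion of reads
from the Xi"; in a fully skewed line that expectation is zero and the
0.01 threshold is the operative bound, so the package defaults to
`baseline = 0.01` and exposes it for lines with residual skew rather
than guessing an adjustment. Consensus requires calls in at least 2/3 of
samples.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on generated data:
200-bin chromosomes, 2 x 10^5 pairs per map, 20 replicate simulations for
hinge/inversion properties, 10^4 peaks, 10^3 genes -- sizes chosen so the
full suite exercises every code path in well under a minute per module on
one core. Convergence and tolerance defaults: ICE `tol` 1e-5 / 200
iterations; PCA sign fixed by largest-magnitude entry; quantile ties
averaged; percentile ties all masked; Savitzky-Golay window 5, degree 2.
Degenerate inputs (all-zero matrices, empty streams, all-tied marginals,
constant columns, zero-coverage peaks, zero-spretus chromosomes) return
defined values or targeted errors rather than propagating NaN.

## Limitations

Real allele-specific maps carry artifacts the generator does not model:
overdispersion, translocation/aneuploidy signals, distance-dependent
visibility biases, and SNP-density heterogeneity along the chromosome.
The escape caller presumes complete skewing of XCI; partially skewed
systems need the `baseline` parameter raised to the expected residual Xi
proportion. Trans (interchromosomal) maps, loop calling, peak calling
from reads, and differential expression are out of scope; differential
expression labels, where needed for density comparisons, are consumed
from external files.
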