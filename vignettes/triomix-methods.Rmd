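---
title: "Methods: comparing spectral-count proteomics, two-color arrays and RNA-seq"
author: "triomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing spectral-count proteomics, two-color arrays and RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomix)
```

# Scope

triomix compares gene-level signals measured in parallel, on the same
biological sample, by three technologies: label-free LC-MS/MS spectral
counting, two-color expression microarrays, and single-end RNA-seq. The
package quantifies each channel independently, translates all
identifiers into one gene namespace, partitions the detected genes into
the seven Venn regions of the three detection sets, and measures
cross-technology rank concordance (Spearman's rho) under nested
exclusion rules. A seeded generator produces synthetic raw inputs for
all three channels so the entire chain is testable without any external
download.

Upstream steps — spectrum database search, peptide/protein probability
modelling, base calling, read alignment, array feature extraction — are
out of scope: their outputs (PSM tables with probabilities, probe
intensity tables, alignment coordinates) are the package's inputs.

# The three quantification channels

## Proteomics: probability and FDR filtering, then spectral counting

Each peptide-spectrum match (PSM) arrives with an identification
probability $p \in [0,1]$ and a decoy flag from a target-decoy search.
Acceptance applies a dual criterion: a probability floor $p_{\min}$
(default 0.95) and a bound on the global decoy-estimated false-discovery
rate (default 1%). `filterPsms()` selects the smallest threshold
$t^\* \ge p_{\min}$ at which

$$\widehat{\mathrm{FDR}}_{\mathrm{decoy}}(t) =
  \frac{\#\{\text{decoys with } p \ge t\}}{\#\{\text{targets with } p \ge t\}}
  \le \mathrm{FDR}_{\max},$$

so both constraints hold simultaneously; decoys are then removed from
the accepted set. The estimator divides by accepted *targets* (not the
symmetrised $2d/(t+d)$ form), matching the convention for a concatenated
equal-size decoy database; a model-based estimate, the mean of $1-p$
over accepted targets, is reported alongside. When no target is
accepted the decoy estimate is reported as 0 with an explicit warning,
never as an undefined division.

A protein's abundance proxy is its spectral count: every accepted PSM
contributes one count to **every** protein of its group (group-level
counting, then expansion to members), because group members are not
independently quantified. Unique-peptide support counts distinct peptide
strings whose group is that single protein; peptide modifications are
ignored in this definition. Gene mapping expands each protein to its
mapped gene(s); rows that originate from a multi-protein group or from a
one-protein/many-genes mapping are flagged `multi_gene`, and proteins
without any mapping are tallied, never dropped silently.

## Microarray: background, loess, quantile, collapse

Two-color probe intensities are background-corrected by subtraction with
a floor, $\max(\mathrm{fg}-\mathrm{bg},\,0.5)$ fluorescence units, which
keeps log-ratios finite while remaining monotone. Each array is then
represented as $M = \log_2(\mathrm{Cy5}/\mathrm{Cy3})$ and
$A = \tfrac12(\log_2\mathrm{Cy5} + \log_2\mathrm{Cy3})$, and the
intensity-dependent dye bias is removed within each array by subtracting
a robust local regression of $M$ on $A$ (tricube weights, span 0.3, one
fit plus three robustifying iterations — the standard two-color default;
both are settable). The fit is delegated to limma's `loessFit`; when $A$
has no spread the fit degenerates to the global mean of $M$.

The two channel log-intensities are reconstructed from $(A, M_{\rm norm})$
and all channels are quantile-normalized between arrays: the rank-$k$
value in each channel is replaced by the cross-channel mean of rank-$k$
values, tied values receiving the mean of the quantile slots they cover
(limma's `normalizeQuantiles(ties = TRUE)`). Per-array probe expression
is the mean of the array's two normalized channels, i.e. an average
log2 background-corrected normalized intensity. Because every downstream
comparison is rank-based, any monotone choice of expression scale here
is equivalent.

Probe-to-gene collapse takes, per gene and array, the median over mapped
probes (mean and max are provided as alternatives; no standard choice
exists for this step), then averages across arrays. Probes without a
gene annotation are tallied per array; probes annotated to several genes
contribute to each and flag those genes `multi_gene`. Collapsing per
array and then averaging (rather than pooling channels first) is a
choice; with rank statistics downstream the alternative ordering is
practically indistinguishable.

## RNA-seq: exon-overlap counting and the gene filter

A read is assigned to a gene if and only if it overlaps at least one
base of any exon of that gene (the minimum overlap is settable). Strand
is ignored, matching an unstranded library protocol. Reads overlapping
exons of two or more genes are tallied as ambiguous and counted for
none — conservative and deterministic, rather than fractional
assignment. Reads overlapping no exon are tallied off-exon, and reads on
chromosomes absent from the annotation are tallied with a warning and
treated as off-exon. Input must contain one alignment per read;
duplicate read identifiers are an error. GFF3 input (1-based inclusive)
and BED input (0-based half-open) are converted by rtracklayer to the
in-memory convention, and exons are merged within each gene, so counts
are invariant to exon order and to splitting an exon into adjacent
pieces.

The exon-overlap filter defines the quantified gene set: genes with at
least one exon-overlapping read. A gene counts as a *detected locus*
when at least one read falls anywhere within its span — the package's
definition, since no standard one exists for pre-filter detection —
and detected loci with zero exonic reads are excluded and reported,
reproducing the bookkeeping "detected loci − no-exon-overlap loci =
quantified genes". No within-sample length normalization (RPKM/TPM) is
applied: a single sample is compared by ranks, for which any per-gene
monotone rescaling would be irrelevant.

# Unification, Venn partition and concordance

Identifier maps (protein to genes, probe to genes) are file inputs;
version suffixes (`.N`) are stripped before lookup. The unified table is
a `SummarizedExperiment` with genes in rows, technologies in columns and
three assays: values, detection flags and multi-gene flags. Duplicate
(gene, technology) rows are aggregated — sum for spectral counts, the
collapse statistic for arrays, sum for read counts — with the
multi-gene flag OR-ed over contributing rows; these aggregation rules
are settable since no standard exists. Genes absent from the gene-info
table are retained with biotype `unknown` and a warning. Non-coding
genes are removed from the *array* comparison set (the protein-coding
comparison-set bookkeeping); the RNA-seq set keeps them.

Every detected gene belongs to exactly one of seven disjoint Venn
regions. Per region and technology, detection levels are summarized by
the five-number summary with quartiles by linear interpolation of order
statistics (type-7); spectral and read counts are shown as
$\log_2(\max(x, 0.5))$ while array values are already on the log2 scale.
The log transform serves display only — concordance is computed on raw
values, which is equivalent under ranks.

Spearman's rho is computed as the product-moment correlation of midranks
(average ranks for ties); on tie-free data this equals
$1 - 6\sum d_i^2 / (n(n^2-1))$. Zero rank variance makes the coefficient
undefined and is reported as `NA` with a warning, never as 0. No
p-values are attached.

Concordance is evaluated on the triple-detected gene set by default
(the pairwise-detected universe is available) under three nested rules:
(a) all co-detected genes; (b) excluding genes flagged multi-gene in
either technology of the pair; (c) additionally excluding the three
discordance-prone categories. Categories are assigned with fixed
precedence ribosomal > histone > vitellogenin: ribosomal via the GO
cellular-component ribosome term (GO:0005840), histone and vitellogenin
via case-insensitive description keywords; term and keywords are
settable configuration. Results with fewer than 10 genes are flagged
low-n. The gene count is non-increasing across rules by construction.

# The synthetic tri-omics generator

The generator's purpose is statistical structure, not biological
realism: it provides ground truth against which every pipeline stage can
be checked.

**Truth layer.** Gene abundances are lognormal; for protein-coding genes
the (mRNA, protein) pair is drawn from a Gaussian copula whose latent
correlation $r = 2\sin(\pi\rho_S/6)$ is chosen so the population
Spearman correlation equals the configured `proteinRankCorr` — the
controlled parameter is exactly the statistic the pipeline estimates.
Category counts (ribosomal, histone, vitellogenin, plus a non-coding
biotype fraction with zero protein) are apportioned by largest-remainder
rounding so they are exact and testable. Defaults: 20,000 genes;
category fractions 1.5% / 0.5% / 0.2%, approximating the relative sizes
of these families in a fish genome; 5% non-coding; lognormal
$\sigma = 2$ (about six orders of magnitude of abundance).

**Discordance.** Vitellogenins are maternally deposited yolk proteins:
truth protein is multiplied up (default 30×) and truth mRNA down
(0.02×). Several ribosomal protein transcripts also act as untranslated
RNAs: truth mRNA is multiplied up (8×). Histone mRNAs are mostly
non-polyadenylated, so their depletion is a *library* artifact: the
capture factor (0.05) is applied at the read-sampling stage only, while
the array — which in this design sees the same truth mRNA — is not
depleted. These magnitudes are free parameters of the generator, not
estimates of any real data set.

**Proteomics channel.** 20,000 spectra are allocated to proteins
multinomially in proportion to protein abundance. Each spectrum is a
decoy with probability 0.1; 10% of target PSMs are incorrect matches
assigned to a uniformly chosen detectable protein. Correct targets draw
probabilities from Beta(30, 1); decoys and incorrect targets share one
low mixture (Beta(1, 10) with a 5% Beta(8, 1) tail), creating a
separable threshold regime around 0.95 with a realistic trickle of
high-scoring decoys. Shared peptides are modelled as homology: a
fraction of proteins form pairs whose peptide pools partly coincide, so
multi-protein groups are a protein-level property rather than a side
effect of abundance. The simulated table carries an `is_correct` truth
column that no pipeline consumer reads and the TSV writer omits; it
exists so decoy-FDR calibration can be tested against known false
matches.

**Array channel.** Each gene receives 2–5 probes; both channels are the
scaled truth mRNA with multiplicative lognormal noise (σ = 0.2) and an
additive background, and the Cy5 channel is distorted by
$2^{\,b + c A_0^2}$ with constant bias $b = 0.3$ and curvature
$c = 0.02$ in the squared log2 signal — precisely the smooth
intensity-dependent structure the loess step must remove. 60% of probes
are left without gene annotation (mirroring a custom design in which
most probes cannot be linked to a gene) and 2% map to two genes.

**RNA-seq channel.** Genes are tiled on one synthetic chromosome with
1–3 exons each, intron and intergenic gaps wide enough that loci never
overlap and a 51-nt read starting in one feature cannot reach the next
exon. Exonic reads are multinomial in truth mRNA (histones
down-weighted); a configured fraction (default 10%) is placed wholly
inside introns and intergenic gaps, which both populates the off-exon
tally and creates detected-but-unquantifiable loci. The default total of
$10^6$ reads is a deliberate desk-scale down-sample of a full sequencing
lane; the generator emulates structure, not scale.

**What the generator does not emulate** — and therefore what passing
tests do not establish about real data: spot-level image artifacts,
dye-swap designs, sequence-composition biases of library preparation and
ionization, saturation at high array intensities, correlated
measurement error between technologies, protein degradation and
isoform-level complexity. Determinism is exact: identical configurations
(including the seed) give identical outputs.

# Calibration experiments and problem sizes

**FDR calibration.** Decoys and incorrect targets share one score
distribution, and with decoy fraction $d = i/(1+i)$ (incorrect-target
fraction $i$) their expected counts match, so the decoy estimate should
track the true false-match fraction among accepted targets up to
binomial noise. The test suite runs 500 tables of 1,000 PSMs
($i = 0.3$); the pooled decoy count is required to fall within three
standard deviations of the pooled true false-match count.

**Parameter recovery.** The concordance statistic can only be compared
with the generator's setting when detection does not truncate the
copula: conditioning on detection of a sparse proteome selects high
protein abundance, and the conditional rank correlation of a truncated
bivariate normal drops far below the population value (top-10%
selection at $\rho_S = 0.6$ gives roughly 0.3). At the default dynamic
range (lognormal σ = 2) the bottom few percent of proteins are
undetectable at any feasible spectrum count, which alone costs about
0.05 in rho. The recovery experiment is therefore designed with a
moderate dynamic range (σ = 1.25) and deep coverage ($10^6$ spectra and
reads over 5,000 genes), under which the pipeline's rho after rule (c)
is required to land within ±0.05 of the configured 0.6. The direction
of the exclusion effect — rho(c) > rho(a) for RNA-seq vs MS — is
checked across 50 seeded replicates at lighter depth ($10^5$), where it
must hold in at least 95%.

These sizes (5,000-gene recovery runs, 500-replicate calibration,
100-instance oracle sweeps per operation with instances up to $10^4$)
are the package's chosen balance between statistical resolution and a
test suite that runs in minutes on one CPU.

# Numerical notes and limitations

* Quantile normalization is exactly idempotent, and makes all sorted
  columns exactly equal, on tie-free data (tested to 1e-9). Under ties,
  any slot-averaging tie rule — including the one used here — is
  idempotent only approximately, because per-column tie patterns perturb
  the reference distribution between passes.
* The background floor (0.5) produces ties at the low end by design;
  they are handled by midranks downstream.
* The probability-threshold search evaluates only observed probability
  levels plus the floor, which is exhaustive: the FDR step function can
  change only at observed values.
* With a single sample per technology there is no replication, so no
  uncertainty is attached to rho; the replicate analyses above
  characterize the generator, not a real data set.
* The single-channel extraction trick used by some two-color designs
  (replacing one channel by a control sample) is out of scope; arrays
  are normalized as given.

# Session

```{r}
sessionInfo()
```
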