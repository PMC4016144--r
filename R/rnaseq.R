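#' Count reads per gene by exon overlap
#'
#' Assigns each aligned read to a gene if and only if it overlaps at
#' least `minOverlap` bases of any exon of that gene (strand is ignored,
#' matching an unstranded library). Reads overlapping exons of two or
#' more genes are tallied as ambiguous and counted for none; reads
#' overlapping no exon are tallied off-exon. Reads on chromosomes absent
#' from the annotation raise a warning tally and count as off-exon.
#' Detected loci (genes with at least one read anywhere within the gene
#' span, exonic or not) are reported alongside for the exon-overlap
#' filter.
#'
#' @param reads a [GenomicRanges::GRanges] of alignments with a `read_id`
#'   metadata column (see [readBedAlignments()]); `read_id`s must be
#'   unique (one alignment per read).
#' @param geneModels list with `genes` and `exons` GRanges carrying
#'   `gene_id` (see [readGeneModelsGff3()] or [simulateReads()]).
#' @param minOverlap minimum overlap in bases for assignment (default 1).
#' @return list with `counts` (named integer vector over all annotated
#'   genes), `nOffExon`, `nAmbiguous`, `nUnknownChrom`, and
#'   `detectedLoci` (character vector of gene ids).
#' @export
countReadsPerGene <- function(reads, geneModels, minOverlap = 1) {
  stopifnot(is(reads, "GRanges"), !is.null(reads$read_id))
  if (anyDuplicated(reads$read_id)) {
    stop("duplicate read_id in alignments; expected one alignment per read")
  }
  genes <- geneModels$genes
  exons <- geneModels$exons
  stopifnot(is(genes, "GRanges"), is(exons, "GRanges"),
            !is.null(genes$gene_id), !is.null(exons$gene_id))
  geneIds <- genes$gene_id
  counts <- stats::setNames(integer(length(geneIds)), geneIds)

  known <- as.character(GenomeInfoDb::seqnames(reads)) %in%
    GenomeInfoDb::seqlevels(exons)
  nUnknown <- sum(!known)
  if (nUnknown > 0) {
    warning(sprintf("%d read(s) on chromosomes absent from the annotation; counted off-exon",
                    nUnknown))
  }
  n <- length(reads)
  if (n == 0L) {
    return(list(counts = counts, nOffExon = 0L, nAmbiguous = 0L,
                nUnknownChrom = nUnknown, detectedLoci = character()))
  }

  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    reads, exons, minoverlap = minOverlap, ignore.strand = TRUE))
  q <- S4Vectors::queryHits(hits)
  g <- exons$gene_id[S4Vectors::subjectHits(hits)]
  keep <- !duplicated(paste(q, g, sep = "\r"))
  q <- q[keep]; g <- g[keep]
  genesPerRead <- tabulate(q, nbins = n)
  assignedRead <- genesPerRead == 1L
  sel <- assignedRead[q]
  tab <- table(g[sel])
  counts[names(tab)] <- as.integer(tab)

  nAmbiguous <- sum(genesPerRead >= 2L)
  nOffExon <- sum(genesPerRead == 0L)

  spanHits <- suppressWarnings(GenomicRanges::findOverlaps(
    reads, genes, ignore.strand = TRUE))
  detected <- unique(genes$gene_id[S4Vectors::subjectHits(spanHits)])

  list(counts = counts, nOffExon = as.integer(nOffExon),
       nAmbiguous = as.integer(nAmbiguous),
       nUnknownChrom = as.integer(nUnknown),
       detectedLoci = detected)
}

#' Apply the exon-overlap gene filter
#'
#' Restricts quantification to genes with at least one exon-overlapping
#' read. Genes detected as loci (some read within the gene span) whose
#' alignments never overlap an annotated exon are excluded and reported —
#' the class of detected-but-unquantifiable genes.
#'
#' @param counts named integer vector of exon-overlap read counts per
#'   gene, from [countReadsPerGene()].
#' @param detectedLoci character vector of gene ids detected as loci.
#' @return list with `quantified` (gene ids with count >= 1), `excluded`
#'   (detected loci failing the filter), and a one-row `summary`
#'   data.frame (`n_detected_loci`, `n_excluded`, `n_quantified`).
#' @examples
#' counts <- c(g1 = 5L, g2 = 0L, g3 = 1L)
#' filterQuantifiedGenes(counts, detectedLoci = c("g1", "g2", "g3"))$summary
#' @export
filterQuantifiedGenes <- function(counts, detectedLoci = names(counts)) {
  stopifnot(!is.null(names(counts)))
  quantified <- names(counts)[counts >= 1L]
  excluded <- setdiff(detectedLoci, quantified)
  list(quantified = quantified, excluded = excluded,
       summary = data.frame(n_detected_loci = length(detectedLoci),
                            n_excluded = length(excluded),
                            n_quantified = length(intersect(detectedLoci,
                                                            quantified))))
}

#' Gene-level RNA-seq values for the unified table
#'
#' @param counts named exon-overlap counts from [countReadsPerGene()].
#' @param quantified gene ids passing [filterQuantifiedGenes()].
#' @return data.frame `gene_id`, `technology`, `value`, `multi_gene`
#'   (always `FALSE`: counting is already gene-level and unambiguous).
#' @export
rnaseqGeneValues <- function(counts, quantified = names(counts)[counts >= 1L]) {
  sel <- intersect(quantified, names(counts))
  data.frame(gene_id = sel, technology = "rnaseq",
             value = as.numeric(counts[sel]), multi_gene = FALSE,
             stringsAsFactors = FALSE)
}
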