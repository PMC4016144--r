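.writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTsv <- function(path, required = character()) {
  if (!file.exists(path)) stop("input file not found: ", path)
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         check.names = FALSE, quote = "",
                         na.strings = character())
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    stop(sprintf("file '%s' lacks required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  }
  x
}

#' Read and write PSM tables
#'
#' The PSM TSV schema is `spectrum_id`, `peptide`, `proteins`
#' (semicolon-separated protein group), `probability`, `is_decoy` (0/1).
#' Any extra columns (such as simulation truth) are dropped on write.
#'
#' @param path file path.
#' @param psms PSM data.frame.
#' @return `readPsmTable()` returns the PSM data.frame.
#' @export
readPsmTable <- function(path) {
  x <- .readTsv(path, c("spectrum_id", "peptide", "proteins",
                        "probability", "is_decoy"))
  x$probability <- as.numeric(x$probability)
  x$is_decoy <- as.integer(x$is_decoy)
  .checkPsmTable(x)
  x
}

#' @rdname readPsmTable
#' @export
writePsmTable <- function(psms, path) {
  .checkPsmTable(psms)
  cols <- c("spectrum_id", "peptide", "proteins", "probability", "is_decoy")
  .writeTsv(psms[, cols], path)
}

#' Read and write two-color probe intensity tables
#'
#' Schema: `probe_id`, `array_id`, `fg_cy3`, `bg_cy3`, `fg_cy5`,
#' `bg_cy5`.
#'
#' @param path file path.
#' @param probes probe intensity data.frame.
#' @return `readProbeTable()` returns the data.frame.
#' @export
readProbeTable <- function(path) {
  x <- .readTsv(path, c("probe_id", "array_id", "fg_cy3", "bg_cy3",
                        "fg_cy5", "bg_cy5"))
  for (cc in c("fg_cy3", "bg_cy3", "fg_cy5", "bg_cy5")) {
    x[[cc]] <- as.numeric(x[[cc]])
  }
  x
}

#' @rdname readProbeTable
#' @export
writeProbeTable <- function(probes, path) {
  cols <- c("probe_id", "array_id", "fg_cy3", "bg_cy3", "fg_cy5", "bg_cy5")
  .writeTsv(probes[, cols], path)
}

#' Read and write identifier maps
#'
#' The identifier map TSV has columns `entity_id`, `entity_type`
#' (`protein` or `probe`) and `gene_ids` (semicolon-separated, possibly
#' empty). `readIdMap()` returns ready-to-use lookup lists with version
#' suffixes stripped.
#'
#' @param path file path.
#' @param idmap identifier-map data.frame.
#' @return `readIdMap()` returns a list with `proteinToGenes` and
#'   `probeToGenes`, each a named list of character vectors.
#' @export
readIdMap <- function(path) {
  x <- .readTsv(path, c("entity_id", "entity_type", "gene_ids"))
  idMapToLookups(x)
}

#' @rdname readIdMap
#' @export
writeIdMap <- function(idmap, path) {
  .writeTsv(idmap[, c("entity_id", "entity_type", "gene_ids")], path)
}

#' @rdname readIdMap
#' @param idmap identifier-map data.frame (in-memory form).
#' @export
idMapToLookups <- function(idmap) {
  split1 <- function(sel) {
    ids <- stripVersion(idmap$entity_id[sel])
    genes <- lapply(strsplit(idmap$gene_ids[sel], ";", fixed = TRUE),
                    function(g) stripVersion(g[nzchar(g)]))
    stats::setNames(genes, ids)
  }
  list(proteinToGenes = split1(idmap$entity_type == "protein"),
       probeToGenes = split1(idmap$entity_type == "probe"))
}

#' Read and write the gene information table
#'
#' Schema: `gene_id`, `biotype`, `description`, `go_cc`
#' (semicolon-separated GO cellular-component terms).
#'
#' @param path file path.
#' @param geneInfo gene info data.frame.
#' @return `readGeneInfo()` returns the data.frame.
#' @export
readGeneInfo <- function(path) {
  .readTsv(path, c("gene_id", "biotype", "description", "go_cc"))
}

#' @rdname readGeneInfo
#' @export
writeGeneInfo <- function(geneInfo, path) {
  .writeTsv(geneInfo[, c("gene_id", "biotype", "description", "go_cc")], path)
}

#' Read aligned reads from a BED file
#'
#' Imports a BED6 file of read alignments (0-based half-open on disk,
#' converted to the in-memory 1-based convention by the importer) and
#' checks that read names are unique.
#'
#' @param path BED file path.
#' @return a [GenomicRanges::GRanges] with a `read_id` metadata column.
#' @export
readBedAlignments <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name)) stop("BED file lacks read names: ", path)
  gr$read_id <- gr$name
  if (anyDuplicated(gr$read_id)) {
    stop("duplicate read names in BED file; expected one alignment per read")
  }
  gr
}

#' @rdname readBedAlignments
#' @param reads GRanges with `read_id`.
#' @export
writeReadsBed <- function(reads, path) {
  gr <- reads
  gr$name <- gr$read_id
  gr$read_id <- NULL
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read and write gene models as GFF3
#'
#' The GFF3 (1-based inclusive on disk, per the standard) carries `gene`
#' and `exon` features with `gene_id` and, for genes, `biotype`
#' attributes. On read, exons are merged within each gene so that exon
#' intervals are non-overlapping.
#'
#' @param path GFF3 file path.
#' @return `readGeneModelsGff3()` returns a list with `genes` and
#'   `exons` GRanges.
#' @export
readGeneModelsGff3 <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  gr <- rtracklayer::import(path, format = "GFF3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  exons <- gr[type == "exon"]
  if (is.null(genes$gene_id)) genes$gene_id <- genes$ID
  if (is.null(exons$gene_id)) {
    exons$gene_id <- vapply(exons$Parent, function(p) p[1], character(1))
  }
  if (is.null(genes$biotype)) genes$biotype <- "protein_coding"
  exons <- .mergeExons(exons)
  keep <- c("gene_id", "biotype")
  S4Vectors::mcols(genes) <- S4Vectors::mcols(genes)[, keep]
  list(genes = genes, exons = exons)
}

.mergeExons <- function(exons) {
  byGene <- S4Vectors::split(exons, exons$gene_id)
  red <- GenomicRanges::reduce(byGene)
  flat <- unlist(red, use.names = TRUE)
  out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(flat),
                                IRanges::ranges(flat),
                                strand = BiocGenerics::strand(flat),
                                gene_id = names(flat))
  names(out) <- NULL
  GenomeInfoDb::seqlevels(out) <- GenomeInfoDb::seqlevels(exons)
  suppressWarnings(GenomeInfoDb::seqlengths(out) <-
                     GenomeInfoDb::seqlengths(exons))
  out
}

#' @rdname readGeneModelsGff3
#' @param geneModels list with `genes` and `exons` GRanges.
#' @export
writeGeneModelsGff3 <- function(geneModels, path) {
  genes <- geneModels$genes
  exons <- geneModels$exons
  g <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                              IRanges::ranges(genes),
                              strand = BiocGenerics::strand(genes))
  g$type <- "gene"
  g$ID <- genes$gene_id
  g$gene_id <- genes$gene_id
  g$biotype <- genes$biotype
  e <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(exons),
                              IRanges::ranges(exons),
                              strand = BiocGenerics::strand(exons))
  e$type <- "exon"
  e$Parent <- exons$gene_id
  e$gene_id <- exons$gene_id
  all <- suppressWarnings(c(g, e))
  all <- all[order(BiocGenerics::start(all), all$type != "gene")]
  rtracklayer::export(all, path, format = "GFF3")
  invisible(path)
}

#' Write a simulated tri-omics data set to a directory
#'
#' Writes every pipeline input produced by [simulateTriomics()] in its
#' standard on-disk format: `psms.tsv`, `probes.tsv`,
#' `probe_annotation.tsv`, `reads.bed` (BED6), `genes.gff3`,
#' `idmap.tsv`, `gene_info.tsv` and the simulation truth `truth.tsv`.
#'
#' @param sim list from [simulateTriomics()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writePsmTable(sim$psms, file.path(dir, "psms.tsv"))
  writeProbeTable(sim$probes, file.path(dir, "probes.tsv"))
  .writeTsv(sim$probeAnnotation, file.path(dir, "probe_annotation.tsv"))
  writeReadsBed(sim$reads, file.path(dir, "reads.bed"))
  writeGeneModelsGff3(sim$geneModels, file.path(dir, "genes.gff3"))
  writeIdMap(sim$idmap, file.path(dir, "idmap.tsv"))
  writeGeneInfo(sim$geneInfo, file.path(dir, "gene_info.tsv"))
  .writeTsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' @rdname readIdMap
#' @export
readProbeAnnotation <- function(path) {
  .readTsv(path, c("probe_id", "gene_ids"))
}
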