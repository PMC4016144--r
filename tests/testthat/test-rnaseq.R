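makeReads <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start, end = end),
                         read_id = sprintf("r%04d", seq_along(start)))
}

makeModels <- function(exonDf, geneDf = NULL) {
  exons <- GenomicRanges::GRanges(exonDf$chrom,
                                  IRanges::IRanges(exonDf$start, exonDf$end),
                                  gene_id = exonDf$gene_id)
  if (is.null(geneDf)) {
    spl <- split(seq_len(nrow(exonDf)), exonDf$gene_id)
    geneDf <- do.call(rbind, lapply(names(spl), function(g) {
      i <- spl[[g]]
      data.frame(chrom = exonDf$chrom[i[1]], start = min(exonDf$start[i]),
                 end = max(exonDf$end[i]), gene_id = g)
    }))
  }
  genes <- GenomicRanges::GRanges(geneDf$chrom,
                                  IRanges::IRanges(geneDf$start, geneDf$end),
                                  gene_id = geneDf$gene_id,
                                  biotype = "protein_coding")
  list(genes = genes, exons = exons)
}

test_that("overlap assignment honours the one-base boundary", {
  gm <- makeModels(data.frame(chrom = "c1", start = 121, end = 180,
                              gene_id = "g1"))
  # read ending exactly on the exon's first base: 1 base of overlap
  r <- makeReads("c1", c(101, 101, 185), c(150, 121, 200))
  res <- countReadsPerGene(r, gm)
  expect_equal(res$counts[["g1"]], 2L)   # 30-base and 1-base overlaps
  expect_equal(res$nOffExon, 1L)
  # the half-open convention on disk: BED end 120 abuts exon start 120
  bed <- tempfile(fileext = ".bed")
  writeLines("c1\t100\t120\trA\t0\t+", bed)
  abutting <- readBedAlignments(bed)
  resB <- countReadsPerGene(abutting, gm)
  expect_equal(resB$counts[["g1"]], 0L)
  expect_equal(resB$nOffExon, 1L)
})

test_that("ambiguous and off-exon reads are tallied, never counted", {
  gm <- makeModels(data.frame(chrom = "c1", start = c(100, 150), end = c(200, 250),
                              gene_id = c("g1", "g2")))
  r <- makeReads("c1", c(160, 90, 300), c(190, 95, 320))
  res <- countReadsPerGene(r, gm)
  expect_equal(res$nAmbiguous, 1L)
  expect_equal(res$nOffExon, 2L)
  expect_equal(unname(res$counts), c(0L, 0L))
  expect_equal(res$counts[["g1"]] + res$nAmbiguous + res$nOffExon, 3L)
})

test_that("counts match the quadratic all-pairs oracle on random instances", {
  set.seed(17)
  for (rep in 1:15) {
    nGenes <- sample(5:20, 1)
    exonDf <- do.call(rbind, lapply(seq_len(nGenes), function(g) {
      nE <- sample(1:3, 1)
      st <- sort(sample(seq(1, 5000, by = 10), nE))
      data.frame(chrom = sample(c("c1", "c2"), 1),
                 start = st, end = st + sample(20:200, nE, TRUE),
                 gene_id = sprintf("g%02d", g))
    }))
    n <- sample(100:400, 1)
    readDf <- data.frame(chrom = sample(c("c1", "c2"), n, TRUE),
                         start = sample(1:5200, n, TRUE))
    readDf$end <- readDf$start + 49
    r <- makeReads(readDf$chrom, readDf$start, readDf$end)
    gm <- makeModels(exonDf)
    mo <- sample(c(1, 10), 1)
    got <- countReadsPerGene(r, gm, minOverlap = mo)
    want <- bfCountReads(readDf, exonDf, minOverlap = mo)
    expect_equal(got$counts[sort(names(got$counts))],
                 want$counts[sort(names(want$counts))])
    expect_equal(got$nOffExon, want$nOffExon)
    expect_equal(got$nAmbiguous, want$nAmbiguous)
    # conservation
    expect_equal(sum(got$counts) + got$nAmbiguous + got$nOffExon, n)
  }
})

test_that("counts are invariant to exon order and adjacent splitting", {
  exonDf <- data.frame(chrom = "c1", start = c(100, 300), end = c(200, 400),
                       gene_id = "g1")
  r <- makeReads("c1", seq(80, 420, by = 20), seq(80, 420, by = 20) + 49)
  base <- countReadsPerGene(r, makeModels(exonDf))
  perm <- countReadsPerGene(r, makeModels(exonDf[2:1, ]))
  expect_equal(base$counts, perm$counts)
  # split the first exon into adjacent pieces
  splitDf <- data.frame(chrom = "c1", start = c(100, 151, 300),
                        end = c(150, 200, 400), gene_id = "g1")
  spl <- countReadsPerGene(r, makeModels(splitDf, geneDf = data.frame(
    chrom = "c1", start = 100, end = 400, gene_id = "g1")))
  expect_equal(base$counts, spl$counts)
})

test_that("duplicate reads error and unknown chromosomes warn", {
  gm <- makeModels(data.frame(chrom = "c1", start = 100, end = 200,
                              gene_id = "g1"))
  r <- makeReads("c1", c(100, 150), c(149, 199))
  r$read_id <- c("r1", "r1")
  expect_error(countReadsPerGene(r, gm), "duplicate read_id")

  r2 <- makeReads(c("c1", "cX"), c(100, 100), c(149, 149))
  expect_warning(res <- countReadsPerGene(r2, gm), "absent from the annotation")
  expect_equal(res$nUnknownChrom, 1L)
  expect_equal(res$nOffExon, 1L)
  expect_equal(res$counts[["g1"]], 1L)
})

test_that("the exon-overlap filter reports excluded loci", {
  counts <- c(g1 = 3L, g2 = 0L, g3 = 1L, g4 = 0L)
  fq <- filterQuantifiedGenes(counts, detectedLoci = c("g1", "g2", "g3"))
  expect_setequal(fq$quantified, c("g1", "g3"))
  expect_equal(fq$excluded, "g2")
  expect_equal(fq$summary$n_detected_loci, 3L)
  expect_equal(fq$summary$n_quantified, 2L)
  # threshold boundary: a single exonic read keeps a gene
  expect_true("g3" %in% fq$quantified)
})
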