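test_that("category counts are exact and degenerate inputs are handled", {
  empty <- simulateGroundTruth(simConfig(nGenes = 0))
  expect_s3_class(empty, "data.frame")
  expect_equal(nrow(empty), 0L)

  truth <- simulateGroundTruth(simConfig(nGenes = 1000, fracRibosomal = 0.1,
                                         seed = 3))
  expect_equal(sum(truth$category == "ribosomal"), 100L)
  expect_equal(nrow(truth), 1000L)

  # largest-remainder rounding apportions exactly
  expect_equal(sum(largestRemainder(c(0.21, 0.33, 0.46), 10)), 10L)
  expect_equal(largestRemainder(c(a = 0.5, b = 0.5), 7)[["a"]] +
                 largestRemainder(c(a = 0.5, b = 0.5), 7)[["b"]], 7L)

  expect_error(simConfig(fracRibosomal = 1.2), "fracRibosomal")
  expect_error(simConfig(fracRibosomal = 0.7, fracHistone = 0.6),
               "sum to at most 1")
})

test_that("noncoding genes carry no protein and categories carry markers", {
  truth <- simulateGroundTruth(simConfig(nGenes = 2000, seed = 8))
  nc <- truth$biotype == "noncoding"
  expect_true(any(nc))
  expect_true(all(truth$protein_abundance[nc] == 0))
  expect_true(all(truth$protein_abundance[!nc] > 0))
  expect_true(all(truth$mrna_abundance > 0))
  ribo <- truth$category == "ribosomal"
  expect_true(all(grepl("GO:0005840", truth$go_cc_terms[ribo])))
  expect_false(any(grepl("GO:0005840", truth$go_cc_terms[!ribo])))
  expect_true(all(grepl("histone", truth$description[truth$category == "histone"],
                        ignore.case = TRUE)))
  expect_true(all(grepl("vitellogenin",
                        truth$description[truth$category == "vitellogenin"],
                        ignore.case = TRUE)))
})

test_that("copula generator hits the target rank correlation", {
  cfg <- simConfig(nGenes = 5000, proteinRankCorr = 0.6, seed = 1)
  truth <- simulateGroundTruth(cfg)
  reg <- truth$category == "regular" & truth$biotype == "protein_coding"
  rho <- spearmanRho(truth$mrna_abundance[reg], truth$protein_abundance[reg])
  expect_gte(rho, 0.55)
  expect_lte(rho, 0.65)
})

test_that("identical configurations give identical outputs", {
  cfg <- quickConfig()
  s1 <- simulateTriomics(cfg)
  s2 <- simulateTriomics(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$psms, s2$psms)
  expect_identical(s1$probes, s2$probes)
  expect_identical(s1$idmap, s2$idmap)
  expect_true(identical(as.data.frame(s1$reads), as.data.frame(s2$reads)))
})

test_that("PSM simulation respects totals, decoy rates and degeneracies", {
  cfg <- quickConfig()
  truth <- simulateGroundTruth(cfg)
  psms <- simulatePsms(truth, cfg)
  expect_equal(nrow(psms), 2000L)
  expect_false(anyDuplicated(psms$spectrum_id) > 0)

  # decoy count within the binomial 99% interval
  cfg2 <- quickConfig(decoyFraction = 0.5, nSpectraTotal = 1000)
  psms2 <- simulatePsms(truth, cfg2)
  lim <- qbinom(c(0.005, 0.995), 1000, 0.5)
  expect_gte(sum(psms2$is_decoy), lim[1])
  expect_lte(sum(psms2$is_decoy), lim[2])

  expect_equal(nrow(simulatePsms(truth, quickConfig(nSpectraTotal = 0))), 0L)

  # all abundance on one gene: every target PSM maps to its protein
  t3 <- truth[1:3, ]
  t3$protein_abundance <- c(10, 0, 0)
  t3$biotype <- c("protein_coding", "noncoding", "noncoding")
  p3 <- simulatePsms(t3, quickConfig(nSpectraTotal = 500))
  tgt <- p3[p3$is_decoy == 0, ]
  expect_true(all(grepl(sub("^G", "P", t3$gene_id[1]), tgt$proteins,
                        fixed = TRUE)))

  t0 <- truth[1:5, ]
  t0$protein_abundance <- 0
  expect_error(simulatePsms(t0, cfg), "no detectable proteome")
})

test_that("decoy and target probabilities occupy separable regimes", {
  cfg <- quickConfig(nSpectraTotal = 5000, seed = 7)
  truth <- simulateGroundTruth(cfg)
  psms <- simulatePsms(truth, cfg)
  expect_gt(mean(psms$probability[psms$is_correct]), 0.9)
  expect_lt(mean(psms$probability[psms$is_decoy == 1]), 0.3)
  # incorrect targets score like decoys
  inc <- psms$is_decoy == 0 & !psms$is_correct
  expect_lt(abs(mean(psms$probability[inc]) -
                  mean(psms$probability[psms$is_decoy == 1])), 0.1)
})

test_that("array simulation produces the probe layout and dye structure", {
  cfg <- quickConfig(nGenes = 10, probesPerGeneRange = c(3, 3), nArrays = 2)
  truth <- simulateGroundTruth(cfg)
  arr <- simulateArray(truth, cfg)
  expect_equal(nrow(arr$probes), 30L * 2L)
  expect_equal(nrow(arr$annotation), 30L)

  # zero noise, zero dye distortion: channels identical, M == 0 everywhere
  cfg0 <- quickConfig(nGenes = 50, arrayNoiseSd = 0, dyeBias = 0,
                      dyeCurvature = 0)
  arr0 <- simulateArray(simulateGroundTruth(cfg0), cfg0)
  ma0 <- toMA(backgroundCorrect(arr0$probes))
  expect_true(all(abs(ma0$M) < 1e-12))

  # positive curvature shows up as a rising M trend in A
  cfgc <- quickConfig(nGenes = 500, dyeCurvature = 0.03, dyeBias = 0)
  arrc <- simulateArray(simulateGroundTruth(cfgc), cfgc)
  mac <- toMA(backgroundCorrect(arrc$probes))
  qs <- quantile(mac$A, c(0.1, 0.9))
  expect_gt(mean(mac$M[mac$A >= qs[2]]), mean(mac$M[mac$A <= qs[1]]))
})

test_that("read simulation respects off-exon fraction and conservation", {
  cfg <- quickConfig(nGenes = 50, nReadsTotal = 5000)
  truth <- simulateGroundTruth(cfg)

  simAll <- simulateReads(truth, quickConfig(nGenes = 50, nReadsTotal = 5000,
                                             fracOffExonReads = 1))
  expect_equal(length(simAll$reads), 5000L)
  ov <- GenomicRanges::countOverlaps(simAll$reads, simAll$geneModels$exons,
                                     ignore.strand = TRUE)
  expect_true(all(ov == 0))

  one <- truth[1, , drop = FALSE]
  simOne <- simulateReads(one, quickConfig(nGenes = 50, nReadsTotal = 500,
                                           fracOffExonReads = 0))
  ov1 <- GenomicRanges::countOverlaps(simOne$reads, simOne$geneModels$exons,
                                      ignore.strand = TRUE)
  expect_true(all(ov1 >= 1))

  # gene loci never overlap
  g <- simAll$geneModels$genes
  expect_equal(length(GenomicRanges::reduce(g, ignore.strand = TRUE)),
               length(g))
})

test_that("histone reads are depleted relative to their mRNA share", {
  cfg <- quickConfig(nGenes = 400, fracHistone = 0.2, nReadsTotal = 50000,
                     fracOffExonReads = 0,
                     discordanceFactors = list(ribosomal_mrna = 1,
                                               vitellogenin_protein = 1,
                                               vitellogenin_mrna = 1,
                                               histone_capture = 0.01))
  truth <- simulateGroundTruth(cfg)
  sim <- simulateReads(truth, cfg)
  hits <- GenomicRanges::findOverlaps(sim$reads, sim$geneModels$exons,
                                      ignore.strand = TRUE)
  gene <- sim$geneModels$exons$gene_id[S4Vectors::subjectHits(hits)]
  first <- !duplicated(S4Vectors::queryHits(hits))
  tab <- table(gene[first])
  hist <- truth$gene_id[truth$category == "histone"]
  readShare <- sum(tab[names(tab) %in% hist]) / sum(tab)
  mrnaShare <- sum(truth$mrna_abundance[truth$category == "histone"]) /
    sum(truth$mrna_abundance)
  expect_lt(readShare, 0.1 * mrnaShare)
})
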