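#' Simulate ground-truth genes
#'
#' Draws the latent gene layer behind the three simulated technologies:
#' gene identifiers, categories (regular / ribosomal / histone /
#' vitellogenin), biotypes, true mRNA and protein abundances, free-text
#' descriptions carrying the category keyword, and GO cellular-component
#' terms (the ribosome term `GO:0005840` for ribosomal genes).
#'
#' mRNA and protein abundances of protein-coding genes are lognormal with
#' a Gaussian-copula dependence whose latent correlation is chosen so the
#' population Spearman correlation equals `proteinRankCorr(config)`
#' (`r = 2 sin(pi * rho / 6)`). Category counts use largest-remainder
#' rounding so they are exact. Discordance factors shift ribosomal mRNA up
#' and vitellogenin protein up / mRNA down; the histone poly-A-capture
#' factor is applied later, at the read-sampling stage, because it is a
#' library artifact rather than a property of the transcriptome.
#'
#' @param config a [SimConfig-class].
#' @return a data.frame with one row per gene: `gene_id`, `category`,
#'   `biotype`, `mrna_abundance`, `protein_abundance`, `description`,
#'   `go_cc_terms` (semicolon-separated).
#' @examples
#' truth <- simulateGroundTruth(simConfig(nGenes = 1000, seed = 1))
#' table(truth$category)
#' @export
simulateGroundTruth <- function(config) {
  stopifnot(is(config, "SimConfig"))
  methods::validObject(config)
  n <- config@nGenes
  cols <- c("gene_id", "category", "biotype", "mrna_abundance",
            "protein_abundance", "description", "go_cc_terms")
  if (n == 0L) {
    out <- data.frame(gene_id = character(), category = character(),
                      biotype = character(), mrna_abundance = numeric(),
                      protein_abundance = numeric(), description = character(),
                      go_cc_terms = character(), stringsAsFactors = FALSE)
    return(out[, cols])
  }
  set.seed(config@seed)

  fr <- c(ribosomal = config@fracRibosomal,
          histone = config@fracHistone,
          vitellogenin = config@fracVitellogenin)
  fr <- c(fr, regular = 1 - sum(fr))
  counts <- largestRemainder(fr, n)
  category <- rep(names(counts), counts)

  # Gaussian copula: latent Pearson correlation giving the requested
  # population Spearman correlation for a bivariate normal.
  r <- 2 * sin(pi * config@proteinRankCorr / 6)
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
  mrna <- exp(config@mrnaLogMean + config@mrnaLogSd * z1)
  protein <- exp(config@proteinLogMean + config@proteinLogSd * z2)

  df <- config@discordanceFactors
  mrna[category == "ribosomal"] <- mrna[category == "ribosomal"] *
    df$ribosomal_mrna
  protein[category == "vitellogenin"] <- protein[category == "vitellogenin"] *
    df$vitellogenin_protein
  mrna[category == "vitellogenin"] <- mrna[category == "vitellogenin"] *
    df$vitellogenin_mrna

  biotype <- rep("protein_coding", n)
  regularIdx <- which(category == "regular")
  nNc <- largestRemainder(c(nc = config@fracNoncoding,
                            rest = 1 - config@fracNoncoding), n)[["nc"]]
  if (nNc > length(regularIdx)) {
    stop("'fracNoncoding' exceeds the available fraction of regular genes")
  }
  ncIdx <- if (nNc > 0) sample(regularIdx, nNc) else integer()
  biotype[ncIdx] <- "noncoding"
  protein[ncIdx] <- 0

  ord <- sample.int(n)  # shuffle so categories are not contiguous blocks
  category <- category[ord]
  mrna2 <- mrna[ord]; protein2 <- protein[ord]; biotype2 <- biotype[ord]

  geneId <- sprintf("G%06d", seq_len(n))
  description <- character(n)
  k <- cumsum(category == "ribosomal")
  description[category == "ribosomal"] <-
    sprintf("60S ribosomal protein L%d", k[category == "ribosomal"])
  k <- cumsum(category == "histone")
  description[category == "histone"] <-
    sprintf("histone H2A family member %d", k[category == "histone"])
  k <- cumsum(category == "vitellogenin")
  description[category == "vitellogenin"] <-
    sprintf("vitellogenin %d precursor", k[category == "vitellogenin"])
  reg <- category == "regular"
  description[reg & biotype2 == "protein_coding"] <-
    sprintf("uncharacterized protein %s",
            geneId[reg & biotype2 == "protein_coding"])
  description[reg & biotype2 == "noncoding"] <-
    sprintf("long intergenic non-coding RNA %s",
            geneId[reg & biotype2 == "noncoding"])

  goCc <- ifelse(category == "ribosomal", "GO:0005840;GO:0005737",
                 "GO:0005737")

  data.frame(gene_id = geneId, category = category, biotype = biotype2,
             mrna_abundance = mrna2, protein_abundance = protein2,
             description = description, go_cc_terms = goCc,
             stringsAsFactors = FALSE)
}

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Deterministic-for-the-RNG-stream random tryptic-looking peptide strings.
.randomPeptides <- function(n) {
  if (n == 0L) return(character())
  lens <- sample(8:14, n, replace = TRUE)
  core <- vapply(lens - 1L, function(l) {
    paste(sample(.AA, l, replace = TRUE), collapse = "")
  }, character(1))
  paste0(core, sample(c("K", "R"), n, replace = TRUE))
}

#' Simulate peptide-spectrum matches
#'
#' Allocates target spectra to proteins multinomially in proportion to true
#' protein abundance, emulating spectral counting. Each spectrum is a decoy
#' with probability `decoyFraction`; a fraction `fracIncorrectTargets` of
#' target PSMs are incorrect matches assigned to a uniformly chosen
#' detectable protein and scored from the same low-probability distribution
#' as decoys (the standard target-decoy assumption). Correct targets draw
#' identification probabilities from a high-probability Beta distribution,
#' so a 0.95 probability threshold separates the regimes. A fraction of
#' proteins (set by `fracSharedPeptides`) form homolog pairs whose
#' peptide pools partly coincide; PSMs on those shared peptides carry a
#' two-member protein group, so about `fracSharedPeptides` of target PSMs
#' are group-level evidence while the group flag stays a protein-level
#' property independent of abundance.
#'
#' @param truth ground-truth gene table from [simulateGroundTruth()].
#' @param config a [SimConfig-class].
#' @return a data.frame of PSMs: `spectrum_id`, `peptide`, `proteins`
#'   (semicolon-separated protein group), `probability`, `is_decoy` (0/1),
#'   plus the simulation truth column `is_correct` which downstream
#'   consumers ignore and the TSV writer omits.
#' @export
simulatePsms <- function(truth, config) {
  stopifnot(is(config, "SimConfig"), nrow(truth) > 0)
  n <- config@nSpectraTotal
  cols <- c("spectrum_id", "peptide", "proteins", "probability",
            "is_decoy", "is_correct")
  empty <- data.frame(spectrum_id = character(), peptide = character(),
                      proteins = character(), probability = numeric(),
                      is_decoy = integer(), is_correct = logical(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty[, cols])

  detectable <- truth$protein_abundance > 0
  if (!any(detectable)) stop("no detectable proteome")
  prot <- sub("^G", "P", truth$gene_id[detectable])
  abund <- truth$protein_abundance[detectable]

  set.seed(config@seed + 1L)
  isDecoy <- stats::runif(n) < config@decoyFraction
  nT <- sum(!isDecoy)
  isIncorrect <- rep(FALSE, n)
  isIncorrect[!isDecoy] <- stats::runif(nT) < config@fracIncorrectTargets

  protOf <- character(n)
  corr <- !isDecoy & !isIncorrect
  nCorr <- sum(corr)
  protOf[corr] <- sample(prot, nCorr, replace = TRUE, prob = abund)
  nInc <- sum(isIncorrect)
  protOf[isIncorrect] <- sample(prot, nInc, replace = TRUE)
  nDec <- sum(isDecoy)
  protOf[isDecoy] <- sprintf("DECOY_P%06d",
                             sample.int(max(length(prot), 1L), nDec,
                                        replace = TRUE))

  # Shared peptides arise from homology, a protein-level property: a
  # fraction of proteins form homolog pairs and half of a paired
  # protein's peptide pool is indistinguishable between the two members,
  # so the expected shared-PSM fraction ~ fracSharedPeptides while the
  # multi-protein-group flag stays independent of abundance.
  partnerOf <- character(0)
  nPairs <- round(config@fracSharedPeptides * length(prot))
  if (nPairs > 0 && length(prot) >= 2L) {
    paired <- sample(prot, min(2L * nPairs, length(prot) - length(prot) %% 2L))
    half <- length(paired) %/% 2L
    partnerOf <- stats::setNames(c(paired[half + seq_len(half)],
                                   paired[seq_len(half)]), paired)
  }
  pepIdx <- sample.int(6L, n, replace = TRUE)
  partner <- partnerOf[protOf]
  shared <- !isDecoy & !is.na(partner) & pepIdx <= 3L
  groups <- protOf
  groups[shared] <- paste(pmin(protOf[shared], partner[shared]),
                          pmax(protOf[shared], partner[shared]), sep = ";")
  key <- paste(groups, pepIdx, sep = "|")
  uk <- unique(key)
  pool <- stats::setNames(.randomPeptides(length(uk)), uk)
  peptide <- unname(pool[key])

  probability <- numeric(n)
  probability[corr] <- stats::rbeta(nCorr, 30, 1)
  low <- !corr
  nLow <- sum(low)
  highTail <- stats::runif(nLow) < 0.05
  pl <- numeric(nLow)
  pl[highTail] <- stats::rbeta(sum(highTail), 8, 1)
  pl[!highTail] <- stats::rbeta(sum(!highTail), 1, 10)
  probability[low] <- pl

  data.frame(spectrum_id = sprintf("S%06d", seq_len(n)),
             peptide = peptide, proteins = groups,
             probability = probability,
             is_decoy = as.integer(isDecoy),
             is_correct = corr, stringsAsFactors = FALSE)[, cols]
}

#' Simulate a two-color probe intensity table
#'
#' Assigns each gene a uniform number of probes in `probesPerGeneRange`,
#' then for each array draws two fluorescence channels from the scaled
#' true mRNA abundance with multiplicative lognormal noise, an additive
#' background, and a Cy5 dye distortion composed of a constant bias plus
#' an intensity-dependent (quadratic in log2 signal) curvature — the
#' structure the within-array loess normalization is meant to remove. A
#' configurable fraction of probes is left without gene annotation and a
#' small fraction is annotated to two genes.
#'
#' @param truth ground-truth gene table.
#' @param config a [SimConfig-class].
#' @return list with `probes` (long data.frame: `probe_id`, `array_id`,
#'   `fg_cy3`, `bg_cy3`, `fg_cy5`, `bg_cy5`) and `annotation`
#'   (`probe_id`, `gene_ids` semicolon-separated, empty when unannotated).
#' @export
simulateArray <- function(truth, config) {
  stopifnot(is(config, "SimConfig"), nrow(truth) > 0)
  set.seed(config@seed + 2L)
  rng <- config@probesPerGeneRange
  nG <- nrow(truth)
  kChoices <- rng[1]:rng[2]
  k <- if (length(kChoices) == 1L) rep.int(kChoices, nG)
       else sample(kChoices, nG, replace = TRUE)
  nP <- sum(k)
  geneOfProbe <- rep(truth$gene_id, k)
  probeId <- sprintf("PR%06d", seq_len(nP))

  # annotation: unannotated fraction, plus occasional two-gene probes
  geneIds <- geneOfProbe
  multi <- stats::runif(nP) < config@fracMultimapProbes
  if (any(multi) && nG > 1L) {
    second <- sample(truth$gene_id, sum(multi), replace = TRUE)
    keep <- second != geneOfProbe[multi]
    geneIds[multi][keep] <- paste(geneOfProbe[multi][keep], second[keep],
                                  sep = ";")
  }
  unann <- stats::runif(nP) < config@fracUnannotatedProbes
  geneIds[unann] <- ""
  annotation <- data.frame(probe_id = probeId, gene_ids = geneIds,
                           stringsAsFactors = FALSE)

  s <- config@arrayScale * truth$mrna_abundance[match(geneOfProbe,
                                                      truth$gene_id)]
  a0 <- log2(s)
  offset <- config@dyeBias + config@dyeCurvature * a0^2
  sd <- config@arrayNoiseSd

  probes <- do.call(rbind, lapply(seq_len(config@nArrays), function(a) {
    e3 <- stats::rlnorm(nP, 0, sd)
    e5 <- stats::rlnorm(nP, 0, sd)
    bg3 <- config@arrayBgLevel * stats::rlnorm(nP, 0, sd / 2)
    bg5 <- config@arrayBgLevel * stats::rlnorm(nP, 0, sd / 2)
    data.frame(probe_id = probeId, array_id = sprintf("A%d", a),
               fg_cy3 = s * e3 + bg3, bg_cy3 = bg3,
               fg_cy5 = s * e5 * 2^offset + bg5, bg_cy5 = bg5,
               stringsAsFactors = FALSE)
  }))
  rownames(probes) <- NULL
  list(probes = probes, annotation = annotation)
}

#' Simulate aligned reads and a matching gene annotation
#'
#' Lays the genes out on one synthetic chromosome, each with 1–3 exons
#' separated by introns and a fixed intergenic gap (so gene loci never
#' overlap), then samples exonic reads multinomially in proportion to true
#' mRNA abundance with histone genes down-weighted by the poly-dT capture
#' factor, and places the configured fraction of off-exon reads inside
#' introns and intergenic gaps (never touching an exon).
#'
#' @param truth ground-truth gene table.
#' @param config a [SimConfig-class].
#' @return list with `reads` (a [GenomicRanges::GRanges] with `read_id`)
#'   and `geneModels` (list of `genes` and `exons` GRanges, carrying
#'   `gene_id` and, for genes, `biotype`).
#' @export
simulateReads <- function(truth, config) {
  stopifnot(is(config, "SimConfig"), nrow(truth) > 0)
  set.seed(config@seed + 3L)
  nG <- nrow(truth)
  L <- config@readLength
  gap <- 1000L

  nE <- sample(1:3, nG, replace = TRUE)
  nElem <- 2L * nE - 1L
  geneOfElem <- rep(seq_len(nG), nElem)
  posInGene <- sequence(nElem)
  isExon <- posInGene %% 2L == 1L
  w <- integer(length(geneOfElem))
  w[isExon] <- sample(150:800, sum(isExon), replace = TRUE)
  w[!isExon] <- sample(200:2000, sum(!isExon), replace = TRUE)

  cs <- cumsum(as.numeric(w))
  lastIdx <- cumsum(nElem)
  geneCumEnd <- cs[lastIdx]
  prevEnd <- c(0, geneCumEnd[-nG])
  startInGene <- (cs - w) - prevEnd[geneOfElem]
  span <- geneCumEnd - prevEnd
  geneStart <- 500 + cumsum(c(0, (span + gap)[-nG]))  # 0-based
  elemStart <- geneStart[geneOfElem] + startInGene
  elemEnd <- elemStart + w
  chromLen <- geneStart[nG] + span[nG] + 2 * gap

  exStart <- elemStart[isExon]
  exEnd <- elemEnd[isExon]
  exGene <- geneOfElem[isExon]

  genesGr <- GenomicRanges::GRanges(
    seqnames = "chrS",
    ranges = IRanges::IRanges(start = geneStart + 1, end = geneStart + span),
    strand = "*", gene_id = truth$gene_id, biotype = truth$biotype
  )
  exonsGr <- GenomicRanges::GRanges(
    seqnames = "chrS",
    ranges = IRanges::IRanges(start = exStart + 1, end = exEnd),
    strand = "*", gene_id = truth$gene_id[exGene]
  )
  GenomeInfoDb::seqlengths(genesGr) <- c(chrS = as.integer(chromLen))
  GenomeInfoDb::seqlengths(exonsGr) <- c(chrS = as.integer(chromLen))
  geneModels <- list(genes = genesGr, exons = exonsGr)

  n <- config@nReadsTotal
  if (n == 0L) {
    reads <- GenomicRanges::GRanges(seqnames = character(),
                                    ranges = IRanges::IRanges(),
                                    read_id = character())
    return(list(reads = reads, geneModels = geneModels))
  }
  nOff <- round(config@fracOffExonReads * n)
  nEx <- n - nOff

  df <- config@discordanceFactors
  geneW <- truth$mrna_abundance *
    ifelse(truth$category == "histone", df$histone_capture, 1)
  exonicLen <- tapply(exEnd - exStart, exGene, sum)[as.character(seq_len(nG))]
  exW <- geneW[exGene] * (exEnd - exStart) / as.numeric(exonicLen[exGene])

  starts <- numeric(0)
  if (nEx > 0) {
    pick <- sample.int(length(exStart), nEx, replace = TRUE, prob = exW)
    off <- floor(stats::runif(nEx) * (exEnd[pick] - exStart[pick]))
    starts <- exStart[pick] + off
  }
  offStarts <- numeric(0)
  if (nOff > 0) {
    ivStart <- c(elemStart[!isExon],                 # introns
                 geneStart + span,                   # intergenic gaps
                 0)                                  # leading gap
    ivEnd <- c(elemEnd[!isExon], geneStart + span + gap, 500)
    ok <- ivEnd - ivStart >= L + 2
    ivStart <- ivStart[ok]; ivEnd <- ivEnd[ok]
    pick <- sample.int(length(ivStart), nOff, replace = TRUE,
                       prob = ivEnd - ivStart - L)
    off <- floor(stats::runif(nOff) * (ivEnd[pick] - ivStart[pick] - L + 1))
    offStarts <- ivStart[pick] + off
  }
  allStarts <- c(starts, offStarts)
  ord <- sample.int(n)  # interleave exonic and off-exon reads
  allStarts <- allStarts[ord]
  reads <- GenomicRanges::GRanges(
    seqnames = "chrS",
    ranges = IRanges::IRanges(start = allStarts + 1, width = L),
    strand = sample(c("+", "-"), n, replace = TRUE),
    read_id = sprintf("R%07d", seq_len(n))
  )
  list(reads = reads, geneModels = geneModels)
}

#' Simulate the protein/probe-to-gene identifier map and gene info table
#'
#' Each protein-coding gene's protein maps back to its gene; a fraction of
#' proteins is left out of the map (the unmapped-spectra class) and a
#' fraction maps to a second gene (paralog-style one-protein/two-gene
#' rows, rendered as multi-gene matches downstream). Probe mappings are
#' taken from the array annotation.
#'
#' @param truth ground-truth gene table.
#' @param probeAnnotation annotation table from [simulateArray()].
#' @param config a [SimConfig-class].
#' @return list with `idmap` (`entity_id`, `entity_type`, `gene_ids`) and
#'   `geneInfo` (`gene_id`, `biotype`, `description`, `go_cc`).
#' @export
simulateIdMap <- function(truth, probeAnnotation, config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(config@seed + 4L)
  coding <- truth[truth$biotype == "protein_coding", , drop = FALSE]
  prot <- sub("^G", "P", coding$gene_id)
  geneIds <- coding$gene_id
  nPr <- length(prot)
  multi <- stats::runif(nPr) < config@fracMultimapProteins
  if (any(multi) && nrow(truth) > 1L) {
    second <- sample(truth$gene_id, sum(multi), replace = TRUE)
    keep <- second != geneIds[multi]
    geneIds[multi][keep] <- paste(geneIds[multi][keep], second[keep], sep = ";")
  }
  unmapped <- stats::runif(nPr) < config@fracUnmappedProteins
  protMap <- data.frame(entity_id = prot[!unmapped],
                        entity_type = "protein",
                        gene_ids = geneIds[!unmapped],
                        stringsAsFactors = FALSE)
  probeMap <- data.frame(entity_id = probeAnnotation$probe_id,
                         entity_type = "probe",
                         gene_ids = probeAnnotation$gene_ids,
                         stringsAsFactors = FALSE)
  geneInfo <- data.frame(gene_id = truth$gene_id, biotype = truth$biotype,
                         description = truth$description,
                         go_cc = truth$go_cc_terms, stringsAsFactors = FALSE)
  list(idmap = rbind(protMap, probeMap), geneInfo = geneInfo)
}

#' Simulate a complete tri-omics data set
#'
#' Runs all four generators under one configuration and returns every
#' input the pipeline consumes. Identical configurations (including the
#' seed) give identical outputs.
#'
#' @param config a [SimConfig-class].
#' @return list with elements `truth`, `psms`, `probes`,
#'   `probeAnnotation`, `reads`, `geneModels`, `idmap`, `geneInfo`,
#'   `config`.
#' @examples
#' sim <- simulateTriomics(simConfig(nGenes = 300, nSpectraTotal = 2000,
#'                                   nReadsTotal = 20000, seed = 3))
#' nrow(sim$psms)
#' @export
simulateTriomics <- function(config) {
  truth <- simulateGroundTruth(config)
  psms <- simulatePsms(truth, config)
  arr <- simulateArray(truth, config)
  rna <- simulateReads(truth, config)
  maps <- simulateIdMap(truth, arr$annotation, config)
  list(truth = truth, psms = psms, probes = arr$probes,
       probeAnnotation = arr$annotation, reads = rna$reads,
       geneModels = rna$geneModels, idmap = maps$idmap,
       geneInfo = maps$geneInfo, config = config)
}
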