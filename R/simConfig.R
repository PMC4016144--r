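#' Build a simulation configuration
#'
#' Constructs a validated [SimConfig-class] with defaults emulating the
#' statistical structure of a deep zebrafish-embryo tri-omics experiment:
#' ~20,000 genes, a sparse proteome sampled by ~20,000 spectra, two
#' two-color arrays with a few probes per gene (a large fraction of probes
#' not linkable to a gene), and single-end 51-nt reads counted by exon
#' overlap. Category fractions approximate the zebrafish gene complement
#' (ribosomal protein genes, replication-dependent histones, vitellogenins).
#' The default read total is a desk-scale down-sample of a full lane.
#'
#' @param nGenes number of genes to simulate.
#' @param fracRibosomal,fracHistone,fracVitellogenin,fracNoncoding category
#'   and biotype fractions, each in [0, 1]; categories must sum to at most 1.
#' @param mrnaLogMean,mrnaLogSd,proteinLogMean,proteinLogSd lognormal
#'   (natural-log) abundance parameters.
#' @param proteinRankCorr target Spearman correlation between mRNA and
#'   protein abundance of regular protein-coding genes.
#' @param discordanceFactors named list of per-category multiplicative
#'   shifts; see [SimConfig-class].
#' @param nSpectraTotal,decoyFraction,fracIncorrectTargets,fracSharedPeptides
#'   LC-MS/MS depth and error structure.
#' @param fracUnmappedProteins,fracMultimapProteins identifier-map gaps and
#'   one-protein/two-gene mappings.
#' @param nArrays,probesPerGeneRange,arrayScale,arrayNoiseSd,dyeBias,dyeCurvature,arrayBgLevel,fracUnannotatedProbes,fracMultimapProbes
#'   two-color array design and noise.
#' @param nReadsTotal,fracOffExonReads,readLength RNA-seq depth and
#'   off-exon (intronic/intergenic) read fraction.
#' @param minSpectralCount,minArrayValue,minReadCount per-technology
#'   detection thresholds applied by the pipeline.
#' @param seed integer seed controlling every random draw.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nGenes = 500, seed = 7)
#' truth <- simulateGroundTruth(cfg)
#' table(truth$category)
#' @export
simConfig <- function(nGenes = 20000,
                      fracRibosomal = 0.015,
                      fracHistone = 0.005,
                      fracVitellogenin = 0.002,
                      fracNoncoding = 0.05,
                      mrnaLogMean = 2,
                      mrnaLogSd = 2,
                      proteinLogMean = 2,
                      proteinLogSd = 2,
                      proteinRankCorr = 0.6,
                      discordanceFactors = list(
                        ribosomal_mrna = 8,
                        vitellogenin_protein = 30,
                        vitellogenin_mrna = 0.02,
                        histone_capture = 0.05
                      ),
                      nSpectraTotal = 20000,
                      decoyFraction = 0.1,
                      fracIncorrectTargets = 0.1,
                      fracSharedPeptides = 0.05,
                      fracUnmappedProteins = 0.01,
                      fracMultimapProteins = 0.02,
                      nArrays = 2,
                      probesPerGeneRange = c(2, 5),
                      arrayScale = 100,
                      arrayNoiseSd = 0.2,
                      dyeBias = 0.3,
                      dyeCurvature = 0.02,
                      arrayBgLevel = 20,
                      fracUnannotatedProbes = 0.6,
                      fracMultimapProbes = 0.02,
                      nReadsTotal = 1e6,
                      fracOffExonReads = 0.1,
                      readLength = 51,
                      minSpectralCount = 1,
                      minArrayValue = -Inf,
                      minReadCount = 1,
                      seed = 1) {
  cfg <- new("SimConfig",
    nGenes = .asCount(nGenes, "nGenes"),
    fracRibosomal = as.numeric(fracRibosomal),
    fracHistone = as.numeric(fracHistone),
    fracVitellogenin = as.numeric(fracVitellogenin),
    fracNoncoding = as.numeric(fracNoncoding),
    mrnaLogMean = as.numeric(mrnaLogMean),
    mrnaLogSd = as.numeric(mrnaLogSd),
    proteinLogMean = as.numeric(proteinLogMean),
    proteinLogSd = as.numeric(proteinLogSd),
    proteinRankCorr = as.numeric(proteinRankCorr),
    discordanceFactors = discordanceFactors,
    nSpectraTotal = .asCount(nSpectraTotal, "nSpectraTotal"),
    decoyFraction = as.numeric(decoyFraction),
    fracIncorrectTargets = as.numeric(fracIncorrectTargets),
    fracSharedPeptides = as.numeric(fracSharedPeptides),
    fracUnmappedProteins = as.numeric(fracUnmappedProteins),
    fracMultimapProteins = as.numeric(fracMultimapProteins),
    nArrays = .asCount(nArrays, "nArrays"),
    probesPerGeneRange = as.integer(probesPerGeneRange),
    arrayScale = as.numeric(arrayScale),
    arrayNoiseSd = as.numeric(arrayNoiseSd),
    dyeBias = as.numeric(dyeBias),
    dyeCurvature = as.numeric(dyeCurvature),
    arrayBgLevel = as.numeric(arrayBgLevel),
    fracUnannotatedProbes = as.numeric(fracUnannotatedProbes),
    fracMultimapProbes = as.numeric(fracMultimapProbes),
    nReadsTotal = .asCount(nReadsTotal, "nReadsTotal"),
    fracOffExonReads = as.numeric(fracOffExonReads),
    readLength = .asCount(readLength, "readLength"),
    minSpectralCount = as.numeric(minSpectralCount),
    minArrayValue = as.numeric(minArrayValue),
    minReadCount = as.numeric(minReadCount),
    seed = as.integer(seed)
  )
  methods::validObject(cfg)
  cfg
}

.asCount <- function(x, field) {
  if (length(x) != 1L || is.na(x) || x < 0) {
    stop(sprintf("'%s' must be a single non-negative count", field),
         call. = FALSE)
  }
  as.integer(x)
}

#' @describeIn SimConfig-class compact display of the key settings.
#' @param object a `SimConfig`.
#' @export
setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  genes: %d (ribosomal %.3g, histone %.3g, vitellogenin %.3g, noncoding %.3g)\n",
              object@nGenes, object@fracRibosomal, object@fracHistone,
              object@fracVitellogenin, object@fracNoncoding))
  cat(sprintf("  mRNA/protein rank correlation: %.3g\n", object@proteinRankCorr))
  cat(sprintf("  spectra: %d (decoy %.3g)  arrays: %d  reads: %d (off-exon %.3g)\n",
              object@nSpectraTotal, object@decoyFraction, object@nArrays,
              object@nReadsTotal, object@fracOffExonReads))
  cat(sprintf("  seed: %d\n", object@seed))
  invisible(NULL)
})

# Apportion n into integer counts proportional to fracs (which sum to 1)
# using largest-remainder rounding, so counts are exact and reproducible.
largestRemainder <- function(fracs, n) {
  stopifnot(n >= 0, all(fracs >= 0))
  raw <- fracs * n
  base <- floor(raw)
  k <- n - sum(base)
  if (k > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(k)]
    base[idx] <- base[idx] + 1
  }
  stats::setNames(as.integer(base), names(fracs))
}
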