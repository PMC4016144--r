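#' Simulation configuration for the synthetic tri-omics generator
#'
#' An S4 container holding every tunable of the synthetic-data generator:
#' ground-truth gene structure (category and biotype fractions, lognormal
#' abundance parameters, the Gaussian-copula rank correlation between mRNA
#' and protein), per-category discordance factors, and the sampling depths
#' and noise parameters of the three simulated technologies. Construct with
#' [simConfig()]; all slots are validated.
#'
#' @slot nGenes number of ground-truth genes.
#' @slot fracRibosomal,fracHistone,fracVitellogenin fractions of genes in
#'   each discordant category; the remainder are regular genes.
#' @slot fracNoncoding fraction of genes that are non-protein-coding
#'   (drawn from the regular category; their protein abundance is zero).
#' @slot mrnaLogMean,mrnaLogSd natural-log scale lognormal parameters of
#'   true mRNA abundance.
#' @slot proteinLogMean,proteinLogSd lognormal parameters of true protein
#'   abundance.
#' @slot proteinRankCorr target Spearman correlation between mRNA and
#'   protein abundance for regular protein-coding genes, in [0, 1].
#' @slot discordanceFactors named list with elements `ribosomal_mrna`
#'   (mRNA multiplier, > 1 means transcript excess), `vitellogenin_protein`
#'   (protein multiplier), `vitellogenin_mrna` (mRNA multiplier, near zero
#'   for maternally deposited protein), `histone_capture` (poly-dT capture
#'   efficiency applied at the read-sampling stage only).
#' @slot nSpectraTotal,decoyFraction,fracIncorrectTargets,fracSharedPeptides
#'   LC-MS/MS simulation: total spectra, per-spectrum decoy probability,
#'   fraction of target PSMs that are incorrect matches (scored like
#'   decoys), and the fraction of proteins forming homolog pairs with
#'   partly shared peptide pools (creating protein groups on roughly that
#'   fraction of target PSMs).
#' @slot fracUnmappedProteins,fracMultimapProteins fraction of proteins
#'   absent from the identifier map, and mapping to two genes.
#' @slot nArrays,probesPerGeneRange,arrayScale,arrayNoiseSd,dyeBias,
#'   dyeCurvature,arrayBgLevel,fracUnannotatedProbes,fracMultimapProbes
#'   two-color array simulation: number of arrays, integer range of probes
#'   per gene, intensity scale, log-normal channel noise sd, constant and
#'   intensity-dependent (quadratic in log2 signal) dye bias of the Cy5
#'   channel, additive background level, fraction of probes left without
#'   gene annotation, fraction of probes annotated to two genes.
#' @slot nReadsTotal,fracOffExonReads,readLength RNA-seq simulation: total
#'   aligned reads, fraction placed off-exon (intronic/intergenic), read
#'   length in bases.
#' @slot minSpectralCount,minArrayValue,minReadCount per-technology
#'   detection thresholds used by the pipeline.
#' @slot seed integer seed; identical configurations give byte-identical
#'   simulated outputs.
#' @seealso [simConfig()], [simulateGroundTruth()], [simulateTriomics()]
#' @export
setClass("SimConfig",
  representation(
    nGenes = "integer",
    fracRibosomal = "numeric",
    fracHistone = "numeric",
    fracVitellogenin = "numeric",
    fracNoncoding = "numeric",
    mrnaLogMean = "numeric",
    mrnaLogSd = "numeric",
    proteinLogMean = "numeric",
    proteinLogSd = "numeric",
    proteinRankCorr = "numeric",
    discordanceFactors = "list",
    nSpectraTotal = "integer",
    decoyFraction = "numeric",
    fracIncorrectTargets = "numeric",
    fracSharedPeptides = "numeric",
    fracUnmappedProteins = "numeric",
    fracMultimapProteins = "numeric",
    nArrays = "integer",
    probesPerGeneRange = "integer",
    arrayScale = "numeric",
    arrayNoiseSd = "numeric",
    dyeBias = "numeric",
    dyeCurvature = "numeric",
    arrayBgLevel = "numeric",
    fracUnannotatedProbes = "numeric",
    fracMultimapProbes = "numeric",
    nReadsTotal = "integer",
    fracOffExonReads = "numeric",
    readLength = "integer",
    minSpectralCount = "numeric",
    minArrayValue = "numeric",
    minReadCount = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msgs <- character()
  fracSlots <- c(
    "fracRibosomal", "fracHistone", "fracVitellogenin", "fracNoncoding",
    "decoyFraction", "fracIncorrectTargets", "fracSharedPeptides",
    "fracUnmappedProteins", "fracMultimapProteins",
    "fracUnannotatedProbes", "fracMultimapProbes", "fracOffExonReads",
    "proteinRankCorr"
  )
  for (s in fracSlots) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      msgs <- c(msgs, sprintf("'%s' must be a single value in [0, 1]", s))
    }
  }
  catSum <- object@fracRibosomal + object@fracHistone + object@fracVitellogenin
  if (!is.na(catSum) && catSum > 1) {
    msgs <- c(msgs, "category fractions 'fracRibosomal' + 'fracHistone' + 'fracVitellogenin' must sum to at most 1")
  }
  countSlots <- c("nGenes", "nSpectraTotal", "nArrays", "nReadsTotal", "readLength")
  for (s in countSlots) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0L) {
      msgs <- c(msgs, sprintf("'%s' must be a single non-negative integer", s))
    }
  }
  ppr <- object@probesPerGeneRange
  if (length(ppr) != 2L || any(is.na(ppr)) || ppr[1] < 1L || ppr[2] < ppr[1]) {
    msgs <- c(msgs, "'probesPerGeneRange' must be two integers 1 <= lo <= hi")
  }
  need <- c("ribosomal_mrna", "vitellogenin_protein", "vitellogenin_mrna",
            "histone_capture")
  if (!all(need %in% names(object@discordanceFactors))) {
    msgs <- c(msgs, sprintf("'discordanceFactors' must contain %s",
                            paste(sQuote(need), collapse = ", ")))
  }
  if (length(object@seed) != 1L || is.na(object@seed)) {
    msgs <- c(msgs, "'seed' must be a single integer")
  }
  if (length(msgs)) msgs else TRUE
})

#' Target-decoy false-discovery-rate estimate at a chosen PSM threshold
#'
#' Returned by [filterPsms()]. Holds the probability threshold actually
#' applied, the accepted target/decoy counts, the decoy-based FDR estimate
#' (accepted decoys / accepted targets) and the model-based estimate (mean
#' of 1 - probability over accepted targets).
#'
#' @slot threshold probability threshold applied to PSMs.
#' @slot nTargetAccepted,nDecoyAccepted accepted counts at the threshold.
#' @slot fdrDecoy decoy-based FDR estimate (0 when no target is accepted).
#' @slot fdrModel posterior-probability-based FDR estimate in [0, 1].
#' @export
setClass("FdrEstimate",
  representation(
    threshold = "numeric",
    nTargetAccepted = "integer",
    nDecoyAccepted = "integer",
    fdrDecoy = "numeric",
    fdrModel = "numeric"
  )
)

setValidity("FdrEstimate", function(object) {
  msgs <- character()
  if (object@nTargetAccepted < 0L || object@nDecoyAccepted < 0L)
    msgs <- c(msgs, "accepted counts must be non-negative")
  if (object@fdrDecoy < 0)
    msgs <- c(msgs, "'fdrDecoy' must be non-negative")
  if (object@fdrModel < 0 || object@fdrModel > 1)
    msgs <- c(msgs, "'fdrModel' must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn FdrEstimate-class compact display.
#' @param object a `FdrEstimate`.
#' @export
setMethod("show", "FdrEstimate", function(object) {
  cat("FdrEstimate\n")
  cat(sprintf("  threshold       : %.4g\n", object@threshold))
  cat(sprintf("  targets accepted: %d\n", object@nTargetAccepted))
  cat(sprintf("  decoys accepted : %d\n", object@nDecoyAccepted))
  cat(sprintf("  FDR (decoy)     : %.4g\n", object@fdrDecoy))
  cat(sprintf("  FDR (model)     : %.4g\n", object@fdrModel))
  invisible(NULL)
})

.VENN_REGIONS <- c("MS:RNA:ARR", "MS:RNA", "MS:ARR", "RNA:ARR",
                   "MS", "RNA", "ARR")

#' Partition of detected genes into the seven Venn regions
#'
#' Every gene detected by at least one of the three technologies
#' (LC-MS/MS spectral counting, RNA-seq, microarray) is assigned to
#' exactly one of the seven disjoint overlap regions. Per-technology
#' tallies of signals that could not be linked to the gene namespace are
#' carried alongside.
#'
#' @slot regionOf factor named by gene id; levels are the seven regions
#'   `MS:RNA:ARR`, `MS:RNA`, `MS:ARR`, `RNA:ARR`, `MS`, `RNA`, `ARR`.
#' @slot regionSizes named integer vector of the seven region sizes.
#' @slot unannotated named numeric vector of per-technology tallies of
#'   unmapped/unannotated signals (outside the gene namespace).
#' @seealso [vennPartition()], [regionSizes()], [regionOf()]
#' @export
setClass("VennPartition",
  representation(
    regionOf = "factor",
    regionSizes = "integer",
    unannotated = "numeric"
  )
)

setValidity("VennPartition", function(object) {
  msgs <- character()
  if (!identical(levels(object@regionOf), .VENN_REGIONS))
    msgs <- c(msgs, "region levels must be the seven canonical Venn regions")
  if (!identical(names(object@regionSizes), .VENN_REGIONS))
    msgs <- c(msgs, "'regionSizes' must be named by the seven regions")
  if (sum(object@regionSizes) != length(object@regionOf))
    msgs <- c(msgs, "region sizes must sum to the number of assigned genes")
  if (anyDuplicated(names(object@regionOf)))
    msgs <- c(msgs, "each gene must be assigned to exactly one region")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn VennPartition-class compact display.
#' @param object a `VennPartition`.
#' @export
setMethod("show", "VennPartition", function(object) {
  cat("VennPartition of", length(object@regionOf), "detected genes\n")
  sz <- object@regionSizes
  for (r in names(sz)) cat(sprintf("  %-10s %d\n", r, sz[[r]]))
  if (length(object@unannotated)) {
    cat("  unannotated signals:",
        paste(sprintf("%s=%g", names(object@unannotated), object@unannotated),
              collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' @rdname VennPartition-class
#' @param x a `VennPartition`.
#' @return `regionSizes()` returns the named integer vector of the seven
#'   region sizes; `regionOf()` the gene-to-region factor;
#'   `unannotatedTallies()` the per-technology unmapped tallies.
#' @export
regionSizes <- function(x) {
  stopifnot(is(x, "VennPartition"))
  x@regionSizes
}

#' @rdname VennPartition-class
#' @export
regionOf <- function(x) {
  stopifnot(is(x, "VennPartition"))
  x@regionOf
}

#' @rdname VennPartition-class
#' @export
unannotatedTallies <- function(x) {
  stopifnot(is(x, "VennPartition"))
  x@unannotated
}

#' @rdname FdrEstimate-class
#' @param x a `FdrEstimate`.
#' @return `fdrThreshold()`, `fdrDecoy()`, `fdrModel()` return the
#'   corresponding scalar estimate.
#' @export
fdrThreshold <- function(x) {
  stopifnot(is(x, "FdrEstimate"))
  x@threshold
}

#' @rdname FdrEstimate-class
#' @export
fdrDecoy <- function(x) {
  stopifnot(is(x, "FdrEstimate"))
  x@fdrDecoy
}

#' @rdname FdrEstimate-class
#' @export
fdrModel <- function(x) {
  stopifnot(is(x, "FdrEstimate"))
  x@fdrModel
}

#' @rdname FdrEstimate-class
#' @export
acceptedCounts <- function(x) {
  stopifnot(is(x, "FdrEstimate"))
  c(target = x@nTargetAccepted, decoy = x@nDecoyAccepted)
}
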