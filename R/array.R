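#' Background-correct two-color probe intensities
#'
#' Subtracts the per-probe background estimate from each channel's
#' foreground and floors the result at a small positive constant so that
#' subsequent log-ratios stay finite.
#'
#' @param probes data.frame with `fg_cy3`, `bg_cy3`, `fg_cy5`, `bg_cy5`
#'   (plus identifier columns, which are carried through).
#' @param floor lower bound on corrected intensities, in fluorescence
#'   units (default 0.5).
#' @return the input data.frame with added columns `cy3` and `cy5`
#'   holding corrected intensities.
#' @examples
#' backgroundCorrect(data.frame(fg_cy3 = c(100, 10), bg_cy3 = c(30, 30),
#'                              fg_cy5 = c(80, 30), bg_cy5 = c(20, 30)))
#' @export
backgroundCorrect <- function(probes, floor = 0.5) {
  stopifnot(all(c("fg_cy3", "bg_cy3", "fg_cy5", "bg_cy5") %in% names(probes)))
  probes$cy3 <- pmax(probes$fg_cy3 - probes$bg_cy3, floor)
  probes$cy5 <- pmax(probes$fg_cy5 - probes$bg_cy5, floor)
  probes
}

#' Convert corrected channel intensities to M/A representation
#'
#' @param corrected data.frame with corrected `cy3` and `cy5` columns (see
#'   [backgroundCorrect()]).
#' @return the input with added `M = log2(cy5/cy3)` and
#'   `A = (log2(cy5) + log2(cy3)) / 2`.
#' @export
toMA <- function(corrected) {
  stopifnot(all(c("cy3", "cy5") %in% names(corrected)))
  corrected$M <- log2(corrected$cy5 / corrected$cy3)
  corrected$A <- (log2(corrected$cy5) + log2(corrected$cy3)) / 2
  corrected
}

#' Within-array loess normalization of log-ratios
#'
#' Removes intensity-dependent dye bias by subtracting a robust locally
#' weighted linear regression of M on A (tricube weights, `span` fraction
#' of points, with robustifying iterations), the standard within-array
#' normalization for two-color data. A is left unchanged. When A has no
#' spread the fit degenerates to the global mean of M.
#'
#' @param M,A numeric vectors of log-ratios and average log-intensities
#'   for one array (at least 10 probes).
#' @param span loess span as a fraction of points (default 0.3).
#' @param iterations number of local-regression fits; values above 1 add
#'   robustifying reweighting passes (default 4, i.e. three robust
#'   iterations after the initial fit).
#' @return numeric vector of normalized M values.
#' @export
loessNormalizeWithin <- function(M, A, span = 0.3, iterations = 4) {
  stopifnot(length(M) == length(A))
  if (length(M) < 10L) {
    stop("loess normalization needs at least 10 probes per array")
  }
  if (diff(range(A)) < sqrt(.Machine$double.eps)) {
    return(M - mean(M))
  }
  fit <- limma::loessFit(M, A, span = span, iterations = iterations)
  M - fit$fitted
}

#' Quantile normalization between arrays
#'
#' Forces every column of the matrix to share one empirical distribution:
#' the value of rank k in each array is replaced by the mean over arrays
#' of their rank-k values; tied values receive the mean of the quantile
#' slots they cover. A single column is returned unchanged. The operation
#' is idempotent.
#'
#' @param mat numeric matrix, probes in rows and arrays in columns, no
#'   missing values.
#' @return matrix of the same shape with identical sorted columns.
#' @examples
#' quantileNormalizeBetween(cbind(A = c(5, 1, 3), B = c(4, 2, 6)))
#' @export
quantileNormalizeBetween <- function(mat) {
  mat <- as.matrix(mat)
  stopifnot(is.numeric(mat), !anyNA(mat))
  if (ncol(mat) <= 1L) return(mat)
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Normalize a two-color probe table to per-array expression values
#'
#' The full array normalization chain: background correction, M/A
#' transformation, within-array loess normalization of M, reconstruction
#' of the two channel log-intensities from (A, normalized M), quantile
#' normalization of all channels between arrays, and per-array probe
#' expression as the mean of that array's two normalized channels (an
#' average log2 background-corrected normalized intensity).
#'
#' @param probes long data.frame as produced by [simulateArray()] or
#'   [readProbeTable()]: `probe_id`, `array_id`, and the four
#'   foreground/background channel columns. Every array must carry the
#'   same probe set.
#' @param span,iterations loess parameters, see [loessNormalizeWithin()].
#' @param floor background-correction floor, see [backgroundCorrect()].
#' @return numeric matrix of log2 expression values, probes in rows
#'   (named by `probe_id`), arrays in columns.
#' @export
normalizeArrays <- function(probes, span = 0.3, iterations = 4, floor = 0.5) {
  stopifnot(all(c("probe_id", "array_id") %in% names(probes)))
  bc <- toMA(backgroundCorrect(probes, floor = floor))
  arrays <- unique(bc$array_id)
  probeIds <- unique(bc$probe_id)
  channels <- matrix(NA_real_, nrow = length(probeIds),
                     ncol = 2L * length(arrays),
                     dimnames = list(probeIds, NULL))
  cn <- character(2L * length(arrays))
  for (i in seq_along(arrays)) {
    sel <- bc[bc$array_id == arrays[i], , drop = FALSE]
    if (nrow(sel) != length(probeIds) ||
        anyDuplicated(sel$probe_id) ||
        !setequal(sel$probe_id, probeIds)) {
      stop(sprintf("array '%s' does not carry the common probe set",
                   arrays[i]))
    }
    sel <- sel[match(probeIds, sel$probe_id), , drop = FALSE]
    mNorm <- loessNormalizeWithin(sel$M, sel$A, span = span,
                                  iterations = iterations)
    channels[, 2L * i - 1L] <- sel$A - mNorm / 2  # Cy3
    channels[, 2L * i] <- sel$A + mNorm / 2       # Cy5
    cn[c(2L * i - 1L, 2L * i)] <- paste(arrays[i], c("cy3", "cy5"), sep = ".")
  }
  colnames(channels) <- cn
  qn <- quantileNormalizeBetween(channels)
  expr <- vapply(seq_along(arrays), function(i) {
    rowMeans(qn[, c(2L * i - 1L, 2L * i), drop = FALSE])
  }, numeric(length(probeIds)))
  dimnames(expr) <- list(probeIds, arrays)
  expr
}

#' Collapse probe-level expression to gene-level values
#'
#' Summarizes, per gene and array, the expression of all probes mapped to
#' that gene (`median` by default, `mean` or `max` as alternatives), then
#' averages over arrays into one value per gene. Probes without a gene
#' mapping are tallied as unannotated rather than dropped silently; probes
#' mapping to several genes contribute to each of them and flag those
#' genes `multi_gene`.
#'
#' @param exprMat probe-by-array matrix from [normalizeArrays()], rows
#'   named by probe id.
#' @param probeToGenes named list mapping probe id to a character vector
#'   of gene ids (empty vector = unannotated); see [readIdMap()].
#' @param collapse per-gene summary statistic across probes.
#' @return list with `values` (data.frame `gene_id`, `technology`,
#'   `value`, `multi_gene`), `nUnannotatedProbes`, and `perGeneArray`
#'   (gene-by-array matrix of collapsed values).
#' @export
collapseProbes <- function(exprMat, probeToGenes,
                           collapse = c("median", "mean", "max")) {
  collapse <- match.arg(collapse)
  stat <- switch(collapse, median = stats::median, mean = mean, max = max)
  exprMat <- as.matrix(exprMat)
  probeIds <- rownames(exprMat)
  stopifnot(!is.null(probeIds))
  genes <- probeToGenes[stripVersion(probeIds)]
  genes[vapply(genes, is.null, logical(1))] <- list(character())
  genes <- lapply(genes, function(g) g[nzchar(g)])
  ng <- lengths(genes)
  nUnann <- sum(ng == 0L)
  if (all(ng == 0L)) {
    return(list(values = .emptyGeneValues("array"),
                nUnannotatedProbes = nUnann,
                perGeneArray = matrix(numeric(), 0, ncol(exprMat))))
  }
  probeRow <- rep(seq_along(probeIds), ng)
  geneOf <- unlist(genes, use.names = FALSE)
  multiProbe <- rep(ng > 1L, ng)
  byGene <- split(seq_along(geneOf), geneOf)
  geneIds <- names(byGene)
  perGeneArray <- t(vapply(byGene, function(ii) {
    apply(exprMat[probeRow[ii], , drop = FALSE], 2, stat)
  }, numeric(ncol(exprMat))))
  dimnames(perGeneArray) <- list(geneIds, colnames(exprMat))
  multiGene <- vapply(byGene, function(ii) any(multiProbe[ii]), logical(1))
  values <- data.frame(gene_id = geneIds,
                       technology = "array",
                       value = rowMeans(perGeneArray),
                       multi_gene = unname(multiGene),
                       stringsAsFactors = FALSE)
  rownames(values) <- NULL
  list(values = values, nUnannotatedProbes = nUnann,
       perGeneArray = perGeneArray)
}
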