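#' Filter peptide-spectrum matches by probability and global FDR
#'
#' Applies the dual acceptance criterion used for spectral counting: a
#' minimum identification probability and a global target-decoy FDR bound,
#' combined as the smallest probability threshold `t* >= minProbability`
#' at which the decoy-based FDR (accepted decoys / accepted targets, 0
#' when no target is accepted) does not exceed `maxFdr`. Decoys are
#' removed from the returned accepted set. Both FDR estimators at `t*`
#' (decoy-based, and model-based as the mean of `1 - probability` over
#' accepted targets) are reported.
#'
#' @param psms data.frame of PSMs with columns `spectrum_id`, `peptide`,
#'   `proteins` (semicolon-separated group), `probability` in [0, 1],
#'   `is_decoy` (0/1 or logical).
#' @param minProbability minimum identification probability (default 0.95).
#' @param maxFdr maximum global decoy FDR (default 0.01).
#' @return list with `accepted` (target PSMs with probability >= `t*`) and
#'   `fdr` (a [FdrEstimate-class]).
#' @examples
#' psms <- data.frame(spectrum_id = sprintf("S%d", 1:6),
#'                    peptide = "PEPTIDEK",
#'                    proteins = "P1",
#'                    probability = c(.99, .99, .97, .96, .2, .98),
#'                    is_decoy = c(0, 0, 0, 0, 1, 1))
#' filterPsms(psms, minProbability = 0.95, maxFdr = 0.5)$fdr
#' @export
filterPsms <- function(psms, minProbability = 0.95, maxFdr = 0.01) {
  stopifnot(minProbability >= 0, minProbability <= 1,
            maxFdr > 0, maxFdr <= 1)
  .checkPsmTable(psms)
  dec <- as.logical(psms$is_decoy)
  p <- psms$probability
  if (nrow(psms) == 0L) {
    est <- new("FdrEstimate", threshold = minProbability,
               nTargetAccepted = 0L, nDecoyAccepted = 0L,
               fdrDecoy = 0, fdrModel = 0)
    return(list(accepted = psms, fdr = est))
  }

  # distinct probability levels >= minProbability, descending; counts with
  # p >= level are cumulative sums down the levels
  lev <- sort(unique(p), decreasing = TRUE)
  idx <- match(p, lev)
  nTge <- cumsum(tabulate(idx[!dec], nbins = length(lev)))
  nDge <- cumsum(tabulate(idx[dec], nbins = length(lev)))
  fdrAt <- ifelse(nTge == 0L, 0, nDge / pmax(nTge, 1L))
  eligible <- which(lev >= minProbability)
  if (!length(eligible)) {
    # no PSM reaches minProbability: empty acceptance, FDR trivially met
    est <- new("FdrEstimate", threshold = minProbability,
               nTargetAccepted = 0L, nDecoyAccepted = 0L,
               fdrDecoy = 0, fdrModel = 0)
    warning("no PSM reaches the minimum probability; nothing accepted")
    return(list(accepted = psms[0, , drop = FALSE], fdr = est))
  }
  m <- max(eligible)  # smallest level still >= minProbability
  pass <- which(fdrAt[seq_len(m)] <= maxFdr)
  if (!length(pass)) {
    stop(sprintf(
      "no threshold >= %g achieves FDR <= %g (best achievable FDR: %g)",
      minProbability, maxFdr, min(fdrAt[seq_len(m)])))
  }
  kStar <- max(pass)
  tStar <- if (kStar == m) minProbability else lev[kStar]

  accIdx <- which(!dec & p >= tStar)
  nT <- length(accIdx)
  nD <- sum(dec & p >= tStar)
  est <- new("FdrEstimate",
             threshold = tStar,
             nTargetAccepted = nT,
             nDecoyAccepted = as.integer(nD),
             fdrDecoy = if (nT == 0L) 0 else nD / nT,
             fdrModel = if (nT == 0L) 0 else mean(1 - p[accIdx]))
  if (nT == 0L) warning("no target PSMs accepted at the chosen threshold")
  list(accepted = psms[accIdx, , drop = FALSE], fdr = est)
}

.checkPsmTable <- function(psms) {
  need <- c("spectrum_id", "peptide", "proteins", "probability", "is_decoy")
  miss <- setdiff(need, names(psms))
  if (length(miss)) {
    stop("PSM table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(psms) && anyDuplicated(psms$spectrum_id)) {
    stop("duplicate spectrum_id in PSM table")
  }
  if (nrow(psms) && (any(psms$probability < 0) || any(psms$probability > 1))) {
    stop("PSM probabilities must lie in [0, 1]")
  }
  invisible(TRUE)
}

#' Spectral counting over accepted PSMs
#'
#' Counts, for every protein, the number of accepted spectra matching any
#' of its peptides: each PSM contributes one count to every protein in its
#' group (group-level counting with expansion to members). Unique-peptide
#' support counts distinct peptide strings whose group consists of that
#' single protein; `shared_flag` marks proteins supported by at least one
#' multi-protein group.
#'
#' @param acceptedPsms data.frame of already-filtered target PSMs.
#' @return data.frame with `protein_id`, `spectral_count`,
#'   `unique_peptides`, `shared_flag`, ordered by decreasing count.
#' @export
spectralCount <- function(acceptedPsms) {
  .checkPsmTable(acceptedPsms)
  if (nrow(acceptedPsms) == 0L) {
    return(data.frame(protein_id = character(), spectral_count = integer(),
                      unique_peptides = integer(), shared_flag = logical(),
                      stringsAsFactors = FALSE))
  }
  groups <- strsplit(acceptedPsms$proteins, ";", fixed = TRUE)
  sizes <- lengths(groups)
  prot <- unlist(groups, use.names = FALSE)
  psmOf <- rep(seq_len(nrow(acceptedPsms)), sizes)

  counts <- table(prot)
  sharedBy <- tapply(sizes[psmOf] > 1L, prot, any)

  single <- sizes == 1L
  uniq <- integer(length(counts))
  names(uniq) <- names(counts)
  if (any(single)) {
    up <- unique(data.frame(protein = acceptedPsms$proteins[single],
                            peptide = acceptedPsms$peptide[single],
                            stringsAsFactors = FALSE))
    ut <- table(up$protein)
    uniq[names(ut)] <- as.integer(ut)
  }
  out <- data.frame(protein_id = names(counts),
                    spectral_count = as.integer(counts),
                    unique_peptides = uniq[names(counts)],
                    shared_flag = as.logical(sharedBy[names(counts)]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$spectral_count, out$protein_id), , drop = FALSE]
}

#' Expand protein quantifications to gene-level rows
#'
#' Translates each quantified protein to its gene(s): one output row per
#' mapped gene carrying the protein's spectral count. Rows originating
#' from shared (multi-protein-group) evidence or from proteins mapping to
#' more than one gene are flagged `multi_gene`. Proteins with no gene
#' mapping are tallied, never dropped silently.
#'
#' @param proteinQuant data.frame from [spectralCount()].
#' @param proteinToGenes named list mapping protein id to a character
#'   vector of gene ids (see [readIdMap()]); identifier version suffixes
#'   are stripped before lookup.
#' @return list with `values` (data.frame `gene_id`, `technology`,
#'   `value`, `multi_gene`), `nUnmappedProteins` and `nUnmappedSpectra`.
#' @export
expandGroups <- function(proteinQuant, proteinToGenes) {
  if (nrow(proteinQuant) == 0L) {
    return(list(values = .emptyGeneValues("proteomics"),
                nUnmappedProteins = 0L, nUnmappedSpectra = 0L))
  }
  genes <- proteinToGenes[stripVersion(proteinQuant$protein_id)]
  genes[vapply(genes, is.null, logical(1))] <- list(character())
  ng <- lengths(genes)
  unmapped <- ng == 0L
  multi <- proteinQuant$shared_flag | ng > 1L
  values <- data.frame(
    gene_id = unlist(genes, use.names = FALSE),
    technology = "proteomics",
    value = rep(proteinQuant$spectral_count, ng),
    multi_gene = rep(multi, ng),
    stringsAsFactors = FALSE
  )
  list(values = values,
       nUnmappedProteins = sum(unmapped),
       nUnmappedSpectra = sum(proteinQuant$spectral_count[unmapped]))
}

.emptyGeneValues <- function(technology) {
  data.frame(gene_id = character(), technology = character(),
             value = numeric(), multi_gene = logical(),
             stringsAsFactors = FALSE)
}

#' Strip identifier version suffixes
#'
#' Removes a trailing `.N` version from identifiers (`ENSDARG...​.3` ->
#' `ENSDARG...`), the usual cause of silent join failures between
#' annotation releases.
#'
#' @param x character vector of identifiers.
#' @return character vector without version suffixes.
#' @export
stripVersion <- function(x) {
  sub("\\.\\d+$", "", x)
}
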