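# Independent brute-force oracles. Deliberately naive: every one of them
# recomputes its quantity by direct enumeration, sharing no code with the
# implementation it checks.

# exhaustive scan over all distinct probability levels >= minProb; returns
# the smallest threshold achieving the decoy FDR bound, or NA
bfFdrThreshold <- function(p, isDecoy, minProb, maxFdr) {
  cand <- sort(unique(c(minProb, p[p >= minProb])))
  for (t in cand) {
    nT <- sum(!isDecoy & p >= t)
    nD <- sum(isDecoy & p >= t)
    fdr <- if (nT == 0) 0 else nD / nT
    if (fdr <= maxFdr) return(t)
  }
  NA_real_
}

# per-protein tally by looping over PSMs and group members
bfSpectralCount <- function(psms) {
  counts <- list()
  uniqPep <- list()
  shared <- list()
  for (i in seq_len(nrow(psms))) {
    members <- strsplit(psms$proteins[i], ";", fixed = TRUE)[[1]]
    for (m in members) {
      counts[[m]] <- (counts[[m]] %||% 0L) + 1L
      shared[[m]] <- isTRUE(shared[[m]]) || length(members) > 1L
      if (length(members) == 1L) {
        uniqPep[[m]] <- union(uniqPep[[m]] %||% character(), psms$peptide[i])
      }
    }
  }
  prot <- sort(names(counts))
  data.frame(protein_id = prot,
             spectral_count = vapply(prot, function(m) counts[[m]], 0L),
             unique_peptides = vapply(prot, function(m)
               length(uniqPep[[m]] %||% character()), 0L),
             shared_flag = vapply(prot, function(m) isTRUE(shared[[m]]),
                                  logical(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all-pairs quadratic overlap check on 1-based closed intervals
bfCountReads <- function(readDf, exonDf, minOverlap = 1) {
  genes <- unique(exonDf$gene_id)
  counts <- stats::setNames(integer(length(genes)), genes)
  nOff <- 0L; nAmb <- 0L
  for (i in seq_len(nrow(readDf))) {
    hit <- character()
    for (j in seq_len(nrow(exonDf))) {
      if (readDf$chrom[i] != exonDf$chrom[j]) next
      ov <- min(readDf$end[i], exonDf$end[j]) -
        max(readDf$start[i], exonDf$start[j]) + 1L
      if (ov >= minOverlap) hit <- union(hit, exonDf$gene_id[j])
    }
    if (length(hit) == 0L) nOff <- nOff + 1L
    else if (length(hit) >= 2L) nAmb <- nAmb + 1L
    else counts[hit] <- counts[hit] + 1L
  }
  list(counts = counts, nOffExon = nOff, nAmbiguous = nAmb)
}

# per-gene collapse by explicit loops
bfCollapse <- function(exprMat, probeToGenes, stat = stats::median) {
  acc <- list()
  for (pr in rownames(exprMat)) {
    for (g in probeToGenes[[pr]] %||% character()) {
      if (!nzchar(g)) next
      acc[[g]] <- rbind(acc[[g]], exprMat[pr, , drop = FALSE])
    }
  }
  vapply(sort(names(acc)), function(g) {
    mean(apply(acc[[g]], 2, stat))
  }, numeric(1))
}

# membership-test Venn region sizes
bfVennSizes <- function(ms, rna, arr) {
  all <- unique(c(ms, rna, arr))
  lab <- vapply(all, function(g) {
    key <- paste0(ifelse(g %in% ms, "M", ""), ifelse(g %in% rna, "R", ""),
                  ifelse(g %in% arr, "A", ""))
    switch(key, MRA = "MS:RNA:ARR", MR = "MS:RNA", MA = "MS:ARR",
           RA = "RNA:ARR", M = "MS", R = "RNA", A = "ARR")
  }, character(1))
  vapply(c("MS:RNA:ARR", "MS:RNA", "MS:ARR", "RNA:ARR", "MS", "RNA", "ARR"),
         function(r) sum(lab == r), 0L)
}

# five-number summary from first principles: sort, then linear
# interpolation of order statistics at h = (n - 1) p + 1
bfFiveNum <- function(v) {
  s <- sort(v)
  n <- length(s)
  q <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }, numeric(1))
  stats::setNames(q, c("min", "q1", "median", "q3", "max"))
}

# small, fast simulation settings for structural tests
quickConfig <- function(...) {
  args <- utils::modifyList(
    list(nGenes = 200, nSpectraTotal = 2000, nReadsTotal = 20000,
         fracUnannotatedProbes = 0.2, seed = 42),
    list(...))
  do.call(simConfig, args)
}

# build a unified table directly from per-technology value vectors
makeUnified <- function(prot, arr, rna, multi = character(),
                        geneInfo = NULL) {
  gv <- function(v, tech) {
    data.frame(gene_id = names(v), technology = tech, value = as.numeric(v),
               multi_gene = names(v) %in% multi, stringsAsFactors = FALSE)
  }
  suppressWarnings(buildUnifiedTable(proteomics = gv(prot, "proteomics"),
                                     array = gv(arr, "array"),
                                     rnaseq = gv(rna, "rnaseq"),
                                     geneInfo = geneInfo))
}
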