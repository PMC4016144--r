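#' Partition detected genes into the seven Venn regions
#'
#' Assigns every gene detected by at least one technology to exactly one
#' of the seven disjoint overlap regions of the three detection sets.
#'
#' @param ms,rna,arr character vectors of detected gene ids for LC-MS/MS,
#'   RNA-seq and microarray.
#' @param unannotated optional named numeric vector of per-technology
#'   tallies of signals outside the gene namespace, carried through.
#' @return a [VennPartition-class].
#' @examples
#' vp <- vennPartition(ms = c("g1", "g2", "g3"), rna = c("g2", "g3", "g4"),
#'                     arr = c("g3", "g5"))
#' regionSizes(vp)
#' @export
vennPartition <- function(ms, rna, arr, unannotated = numeric()) {
  ms <- unique(as.character(ms))
  rna <- unique(as.character(rna))
  arr <- unique(as.character(arr))
  all <- unique(c(ms, rna, arr))
  inMs <- all %in% ms
  inRna <- all %in% rna
  inArr <- all %in% arr
  region <- character(length(all))
  region[inMs & inRna & inArr] <- "MS:RNA:ARR"
  region[inMs & inRna & !inArr] <- "MS:RNA"
  region[inMs & !inRna & inArr] <- "MS:ARR"
  region[!inMs & inRna & inArr] <- "RNA:ARR"
  region[inMs & !inRna & !inArr] <- "MS"
  region[!inMs & inRna & !inArr] <- "RNA"
  region[!inMs & !inRna & inArr] <- "ARR"
  regionOf <- factor(region, levels = .VENN_REGIONS)
  names(regionOf) <- all
  sizes <- stats::setNames(as.integer(table(regionOf)), .VENN_REGIONS)
  new("VennPartition", regionOf = regionOf, regionSizes = sizes,
      unannotated = unannotated)
}

#' Five-number summaries of detection levels per Venn region
#'
#' For every Venn region and technology, computes the five-number summary
#' (minimum, lower quartile, median, upper quartile, maximum, with
#' quartiles by linear interpolation of the order statistics) of the
#' log-scale detection levels of that region's genes — the numbers behind
#' per-region boxplots. Spectral and read counts are log2-transformed
#' with a pseudo-value floor; array values are already on the log2 scale
#' and used as-is. Region/technology combinations with no detected value
#' are omitted.
#'
#' @param partition a [VennPartition-class].
#' @param se unified table from [buildUnifiedTable()].
#' @param pseudo floor applied to counts before log2 (default 0.5).
#' @return data.frame with `region`, `technology`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max`.
#' @export
regionSummaries <- function(partition, se, pseudo = 0.5) {
  stopifnot(is(partition, "VennPartition"))
  val <- SummarizedExperiment::assay(se, "values")
  det <- SummarizedExperiment::assay(se, "detected")
  regOf <- partition@regionOf
  out <- list()
  for (r in .VENN_REGIONS) {
    genes <- intersect(names(regOf)[regOf == r], rownames(val))
    if (!length(genes)) next
    for (t in colnames(val)) {
      v <- val[genes, t]
      v <- v[det[genes, t] & !is.na(v)]
      if (!length(v)) next
      if (t != "array") v <- log2(pmax(v, pseudo))
      q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7,
                           names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        region = r, technology = t, n = length(v),
        min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(region = character(), technology = character(),
                      n = integer(), min = numeric(), q1 = numeric(),
                      median = numeric(), q3 = numeric(), max = numeric()))
  }
  do.call(rbind, out)
}

#' Label genes by discordance-prone category
#'
#' Classifies genes as `ribosomal` (GO cellular-component annotation
#' contains the ribosome term), `histone` or `vitellogenin` (description
#' contains the keyword, case-insensitively), with fixed precedence
#' ribosomal > histone > vitellogenin on conflict, and `none` otherwise.
#'
#' @param geneInfo data.frame with `gene_id`, `description`, `go_cc`
#'   (semicolon-separated GO cellular-component terms).
#' @param ribosomeGo GO term identifying the ribosome cellular component
#'   (default `"GO:0005840"`).
#' @param histoneKeyword,vitellogeninKeyword description keywords.
#' @return factor named by gene id with levels `ribosomal`, `histone`,
#'   `vitellogenin`, `none`.
#' @export
annotateCategories <- function(geneInfo, ribosomeGo = "GO:0005840",
                               histoneKeyword = "histone",
                               vitellogeninKeyword = "vitellogenin") {
  stopifnot(all(c("gene_id", "description", "go_cc") %in% names(geneInfo)))
  go <- strsplit(ifelse(is.na(geneInfo$go_cc), "", geneInfo$go_cc), ";",
                 fixed = TRUE)
  isRibo <- vapply(go, function(g) ribosomeGo %in% g, logical(1))
  desc <- ifelse(is.na(geneInfo$description), "", geneInfo$description)
  isHist <- grepl(histoneKeyword, desc, ignore.case = TRUE)
  isVit <- grepl(vitellogeninKeyword, desc, ignore.case = TRUE)
  lab <- rep("none", nrow(geneInfo))
  lab[isVit] <- "vitellogenin"
  lab[isHist] <- "histone"
  lab[isRibo] <- "ribosomal"
  out <- factor(lab, levels = c("ribosomal", "histone", "vitellogenin",
                                "none"))
  names(out) <- geneInfo$gene_id
  out
}

#' Spearman rank correlation
#'
#' Computes Spearman's rho as the product-moment correlation of midranks
#' (ties receive average ranks), restricted to complete pairs. On
#' tie-free data this equals the closed form
#' `1 - 6 * sum(d^2) / (n (n^2 - 1))`. When either vector has zero rank
#' variance after tie-handling the coefficient is undefined and `NA` is
#' returned with a warning (never silently 0).
#'
#' @param x,y numeric vectors of equal length; at least 3 complete pairs.
#' @return Spearman's rho in [-1, 1], or `NA` when undefined.
#' @examples
#' spearmanRho(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 0.6
#' @export
spearmanRho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop("spearmanRho needs at least 3 complete pairs")
  }
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    warning("zero rank variance; Spearman's rho is undefined")
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

#' Cross-technology concordance under successive exclusion rules
#'
#' For each technology pair, computes Spearman's rho over the comparison
#' universe under three nested rule sets: (a) all co-detected genes, (b)
#' excluding genes flagged as multi-gene matches in either technology of
#' the pair, and (c) additionally excluding the ribosomal, histone and
#' vitellogenin categories. The default universe is the triple-detected
#' gene set; `"pairwise"` uses each pair's co-detected genes instead.
#'
#' @param se unified table from [buildUnifiedTable()].
#' @param categories factor from [annotateCategories()] (genes missing
#'   from it are treated as `none`); `NULL` derives it from the table's
#'   rowData.
#' @param universe `"triple"` (default) or `"pairwise"`.
#' @param lowN results with fewer genes than this are flagged (default 10).
#' @return data.frame with `pair`, `rule_set` (`all`, `drop_multi`,
#'   `drop_multi_and_categories`), `rho`, `n`, `low_n`.
#' @export
concordanceWithExclusions <- function(se, categories = NULL,
                                      universe = c("triple", "pairwise"),
                                      lowN = 10L) {
  universe <- match.arg(universe)
  val <- SummarizedExperiment::assay(se, "values")
  det <- SummarizedExperiment::assay(se, "detected")
  mg <- SummarizedExperiment::assay(se, "multiGene")
  if (is.null(categories)) {
    rd <- SummarizedExperiment::rowData(se)
    categories <- annotateCategories(data.frame(
      gene_id = rownames(se), description = rd$description,
      go_cc = rd$go_cc, stringsAsFactors = FALSE))
  }
  catOf <- rep("none", nrow(se))
  i <- match(rownames(se), names(categories))
  catOf[!is.na(i)] <- as.character(categories[i[!is.na(i)]])

  tripleOk <- rowSums(det) == 3L
  pairs <- list(c("array", "rnaseq"), c("rnaseq", "proteomics"),
                c("array", "proteomics"))
  rules <- c("all", "drop_multi", "drop_multi_and_categories")
  out <- list()
  for (pr in pairs) {
    base <- if (universe == "triple") tripleOk else det[, pr[1]] & det[, pr[2]]
    base <- base & !is.na(val[, pr[1]]) & !is.na(val[, pr[2]])
    sel <- list(
      all = base,
      drop_multi = base & !mg[, pr[1]] & !mg[, pr[2]],
      drop_multi_and_categories =
        base & !mg[, pr[1]] & !mg[, pr[2]] & catOf == "none"
    )
    for (rule in rules) {
      s <- sel[[rule]]
      n <- sum(s)
      rho <- if (n >= 3L) spearmanRho(val[s, pr[1]], val[s, pr[2]])
             else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        pair = paste(pr, collapse = "_vs_"), rule_set = rule,
        rho = rho, n = n, low_n = n < lowN, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
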