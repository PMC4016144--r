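#' Build the unified per-gene, per-technology table
#'
#' Joins gene-level values from the three technologies into one
#' [SummarizedExperiment::SummarizedExperiment] with genes in rows and
#' technologies (`proteomics`, `array`, `rnaseq`) in columns. Duplicate
#' (gene, technology) rows are aggregated — sum for spectral counts, the
#' chosen collapse for array values, sum for read counts — and the
#' `multi_gene` flag is the OR over contributing rows. Per-technology
#' unmapped/unannotated tallies are carried in the metadata so nothing is
#' dropped silently.
#'
#' @param proteomics,array,rnaseq data.frames with columns `gene_id`,
#'   `value`, `multi_gene` (`NULL` or empty for a missing technology).
#' @param geneInfo data.frame `gene_id`, `biotype`, `description`,
#'   `go_cc` (see [readGeneInfo()]); genes present in the values but
#'   absent here are retained with biotype `"unknown"` and a warning.
#' @param aggregate named character vector giving the per-technology
#'   aggregation rule (`"sum"`, `"median"`, `"mean"`, or `"max"`).
#' @param unmapped named list of per-technology unmapped tallies to carry
#'   through into `metadata()`.
#' @return a `SummarizedExperiment` with assays `values` (NA where not
#'   detected), `detected` (logical) and `multiGene` (logical), rowData
#'   `biotype`/`description`/`go_cc`, and metadata `unmapped` and
#'   `aggregate`.
#' @export
buildUnifiedTable <- function(proteomics = NULL, array = NULL, rnaseq = NULL,
                              geneInfo = NULL,
                              aggregate = c(proteomics = "sum",
                                            array = "median",
                                            rnaseq = "sum"),
                              unmapped = list(proteomics = 0, array = 0,
                                              rnaseq = 0)) {
  techs <- c("proteomics", "array", "rnaseq")
  inputs <- list(proteomics = proteomics, array = array, rnaseq = rnaseq)
  inputs <- lapply(inputs, function(x) {
    if (is.null(x) || nrow(x) == 0L) .emptyGeneValues("") else x
  })
  agg <- lapply(inputs, function(x) NULL)
  for (t in techs) {
    x <- inputs[[t]]
    if (nrow(x) == 0L) next
    stopifnot(all(c("gene_id", "value", "multi_gene") %in% names(x)))
    fun <- switch(match.arg(aggregate[[t]], c("sum", "median", "mean", "max")),
                  sum = sum, median = stats::median, mean = mean, max = max)
    val <- tapply(x$value, x$gene_id, fun)
    mg <- tapply(x$multi_gene, x$gene_id, any)
    agg[[t]] <- data.frame(gene_id = names(val), value = as.numeric(val),
                           multi_gene = as.logical(mg[names(val)]),
                           stringsAsFactors = FALSE)
  }
  geneIds <- sort(unique(unlist(lapply(agg, function(x) x$gene_id))))
  nG <- length(geneIds)
  values <- matrix(NA_real_, nG, 3, dimnames = list(geneIds, techs))
  detected <- matrix(FALSE, nG, 3, dimnames = list(geneIds, techs))
  multiGene <- matrix(FALSE, nG, 3, dimnames = list(geneIds, techs))
  for (t in techs) {
    x <- agg[[t]]
    if (is.null(x)) next
    i <- match(x$gene_id, geneIds)
    values[i, t] <- x$value
    detected[i, t] <- TRUE
    multiGene[i, t] <- x$multi_gene
  }

  biotype <- rep("unknown", nG)
  description <- rep("", nG)
  goCc <- rep("", nG)
  if (!is.null(geneInfo)) {
    i <- match(stripVersion(geneIds), stripVersion(geneInfo$gene_id))
    hit <- !is.na(i)
    if (any(!hit)) {
      warning(sprintf("%d gene id(s) absent from gene info; biotype set to 'unknown'",
                      sum(!hit)))
    }
    biotype[hit] <- geneInfo$biotype[i[hit]]
    description[hit] <- geneInfo$description[i[hit]]
    goCc[hit] <- geneInfo$go_cc[i[hit]]
  }

  SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values, detected = detected,
                  multiGene = multiGene),
    rowData = S4Vectors::DataFrame(biotype = biotype,
                                   description = description,
                                   go_cc = goCc, row.names = geneIds),
    colData = S4Vectors::DataFrame(technology = techs, row.names = techs),
    metadata = list(unmapped = unmapped, aggregate = as.list(aggregate))
  )
}

#' Exclude non-protein-coding genes from a comparison set
#'
#' Removes genes whose biotype is not `protein_coding` and reports how
#' many were removed, reproducing the bookkeeping that reduces an
#' annotated array gene set to the protein-coding comparison set.
#'
#' @param x a `SummarizedExperiment` from [buildUnifiedTable()] (biotype
#'   in `rowData`), or a data.frame with a `biotype` column.
#' @return the filtered object of the same class, with the number of
#'   removed genes in `metadata()$nNoncodingRemoved` (for a
#'   `SummarizedExperiment`) or in attribute `nNoncodingRemoved` (for a
#'   data.frame).
#' @examples
#' df <- data.frame(gene_id = c("g1", "g2", "g3"),
#'                  biotype = c("protein_coding", "noncoding",
#'                              "protein_coding"))
#' attr(excludeNoncoding(df), "nNoncodingRemoved")
#' @export
excludeNoncoding <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    biotype <- SummarizedExperiment::rowData(x)$biotype
    keep <- biotype == "protein_coding" | biotype == "unknown"
    out <- x[keep, ]
    S4Vectors::metadata(out)$nNoncodingRemoved <- sum(!keep)
    return(out)
  }
  stopifnot(is.data.frame(x), "biotype" %in% names(x))
  keep <- x$biotype == "protein_coding" | x$biotype == "unknown"
  out <- x[keep, , drop = FALSE]
  attr(out, "nNoncodingRemoved") <- sum(!keep)
  out
}

#' Per-technology detected gene sets from a unified table
#'
#' @param se unified table from [buildUnifiedTable()].
#' @param thresholds named numeric vector of minimum values per
#'   technology; a gene counts as detected when its flag is set and its
#'   value reaches the threshold.
#' @return named list of character vectors (`proteomics`, `array`,
#'   `rnaseq`).
#' @export
detectedSets <- function(se, thresholds = c(proteomics = 1, array = -Inf,
                                            rnaseq = 1)) {
  det <- SummarizedExperiment::assay(se, "detected")
  val <- SummarizedExperiment::assay(se, "values")
  out <- lapply(colnames(det), function(t) {
    thr <- if (t %in% names(thresholds)) thresholds[[t]] else -Inf
    rownames(se)[det[, t] & !is.na(val[, t]) & val[, t] >= thr]
  })
  stats::setNames(out, colnames(det))
}
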