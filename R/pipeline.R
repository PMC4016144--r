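.defaultParams <- function() {
  list(minProbability = 0.95, maxFdr = 0.01,
       span = 0.3, loessIterations = 4, collapse = "median",
       minOverlap = 1, universe = "triple",
       minSpectralCount = 1, minArrayValue = -Inf, minReadCount = 1)
}

#' Run the full tri-omics comparison pipeline
#'
#' Executes the stages in order — optional simulation, proteomics
#' (probability + FDR filtering, spectral counting, group expansion),
#' array (background correction, loess and quantile normalization, probe
#' collapse), RNA-seq (exon-overlap counting and gene filter), identifier
#' unification, and the comparison stage (Venn partition, per-region
#' summaries, category annotation, Spearman concordance under exclusion
#' rules) — and returns a machine-readable run report together with every
#' intermediate result. A failing stage aborts with an error naming the
#' stage. Identical configuration (including the simulation seed) gives
#' an identical report.
#'
#' @param config a list with either `simulate` (a [SimConfig-class] or a
#'   list of [simConfig()] arguments) or `inputs` (named file paths:
#'   `psms`, `probes`, `probe_annotation`, `reads`, `gff`, `idmap`,
#'   `gene_info`), plus an optional `params` list overriding the analysis
#'   defaults (`minProbability` 0.95, `maxFdr` 0.01, `span` 0.3,
#'   `collapse` "median", `minOverlap` 1, `universe` "triple", and the
#'   per-technology detection thresholds).
#' @param outDir optional output directory; when given, stage outputs
#'   (TSV) and `report.json` are written there.
#' @return list with `report` (the run report), `unified`
#'   (SummarizedExperiment), `venn` ([VennPartition-class]),
#'   `concordance`, `regionSummaries`, `fdr` ([FdrEstimate-class]),
#'   `proteinQuant`, `counts`, and (for simulated runs) `sim`.
#' @examples
#' res <- runPipeline(list(simulate = simConfig(
#'   nGenes = 300, nSpectraTotal = 3000, nReadsTotal = 30000, seed = 2)))
#' res$report$venn$union_size
#' @export
runPipeline <- function(config, outDir = NULL) {
  params <- utils::modifyList(.defaultParams(),
                              if (is.null(config$params)) list()
                              else config$params)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  inp <- stage("input", {
    if (!is.null(config$simulate)) {
      sc <- config$simulate
      if (!is(sc, "SimConfig")) sc <- do.call(simConfig, sc)
      simData <- simulateTriomics(sc)
      lookups <- idMapToLookups(simData$idmap)
      list(psms = simData$psms, probes = simData$probes,
           reads = simData$reads, geneModels = simData$geneModels,
           lookups = lookups, geneInfo = simData$geneInfo,
           seed = sc@seed, simConfig = sc, sim = simData)
    } else if (!is.null(config$inputs)) {
      fp <- config$inputs
      need <- c("psms", "probes", "reads", "gff", "idmap", "gene_info")
      miss <- setdiff(need, names(fp))
      if (length(miss)) {
        stop("missing input path(s): ", paste(miss, collapse = ", "))
      }
      list(psms = readPsmTable(fp$psms),
           probes = readProbeTable(fp$probes),
           reads = readBedAlignments(fp$reads),
           geneModels = readGeneModelsGff3(fp$gff),
           lookups = readIdMap(fp$idmap),
           geneInfo = readGeneInfo(fp$gene_info),
           seed = NA_integer_, simConfig = NULL)
    } else {
      stop("config must contain either 'simulate' or 'inputs'")
    }
  })

  prot <- stage("proteomics", {
    flt <- filterPsms(inp$psms, params$minProbability, params$maxFdr)
    pq <- spectralCount(flt$accepted)
    ex <- expandGroups(pq, inp$lookups$proteinToGenes)
    list(fdr = flt$fdr, quant = pq, values = ex$values,
         nUnmappedProteins = ex$nUnmappedProteins,
         nUnmappedSpectra = ex$nUnmappedSpectra,
         nAccepted = nrow(flt$accepted))
  })

  arr <- stage("array", {
    expr <- normalizeArrays(inp$probes, span = params$span,
                            iterations = params$loessIterations)
    coll <- collapseProbes(expr, inp$lookups$probeToGenes,
                           collapse = params$collapse)
    c(coll, list(nProbes = nrow(expr), nArrays = ncol(expr)))
  })

  rna <- stage("rnaseq", {
    cnt <- countReadsPerGene(inp$reads, inp$geneModels,
                             minOverlap = params$minOverlap)
    fq <- filterQuantifiedGenes(cnt$counts, cnt$detectedLoci)
    list(counts = cnt$counts, nOffExon = cnt$nOffExon,
         nAmbiguous = cnt$nAmbiguous, nUnknownChrom = cnt$nUnknownChrom,
         filter = fq,
         values = rnaseqGeneValues(cnt$counts, fq$quantified))
  })

  unified <- stage("unify", {
    buildUnifiedTable(
      proteomics = prot$values, array = arr$values, rnaseq = rna$values,
      geneInfo = inp$geneInfo,
      aggregate = c(proteomics = "sum", array = params$collapse,
                    rnaseq = "sum"),
      unmapped = list(proteomics = prot$nUnmappedProteins,
                      proteomics_spectra = prot$nUnmappedSpectra,
                      array = arr$nUnannotatedProbes, rnaseq = 0))
  })

  cmp <- stage("compare", {
    thresholds <- c(proteomics = params$minSpectralCount,
                    array = params$minArrayValue,
                    rnaseq = params$minReadCount)
    sets <- detectedSets(unified, thresholds)
    # protein-coding restriction of the array comparison set
    biotype <- SummarizedExperiment::rowData(unified)$biotype
    noncodingArr <- intersect(
      sets$array, rownames(unified)[!(biotype %in% c("protein_coding",
                                                     "unknown"))])
    sets$array <- setdiff(sets$array, noncodingArr)
    # reflect detection rules in the table used for concordance
    det <- SummarizedExperiment::assay(unified, "detected")
    for (t in colnames(det)) {
      det[, t] <- rownames(unified) %in% sets[[t]]
    }
    SummarizedExperiment::assay(unified, "detected") <- det
    venn <- vennPartition(
      ms = sets$proteomics, rna = sets$rnaseq, arr = sets$array,
      unannotated = c(proteomics = prot$nUnmappedProteins,
                      array = arr$nUnannotatedProbes))
    gi <- inp$geneInfo
    categories <- annotateCategories(data.frame(
      gene_id = gi$gene_id, description = gi$description,
      go_cc = gi$go_cc, stringsAsFactors = FALSE))
    conc <- concordanceWithExclusions(unified, categories,
                                      universe = params$universe)
    summ <- regionSummaries(venn, unified)
    list(unified = unified, venn = venn, concordance = conc,
         summaries = summ, nNoncodingRemoved = length(noncodingArr),
         sets = sets)
  })
  unified <- cmp$unified

  report <- list(
    schema_version = "1.0",
    tool_version = as.character(utils::packageVersion("triomix")),
    seed = inp$seed,
    params = params,
    sim_config = if (is.null(inp$simConfig)) NULL
                 else .simConfigAsList(inp$simConfig),
    proteomics = list(
      n_psms_input = nrow(inp$psms),
      threshold = fdrThreshold(prot$fdr),
      n_spectra_accepted = prot$nAccepted,
      n_spectra_after_expansion = sum(prot$quant$spectral_count),
      fdr_decoy = fdrDecoy(prot$fdr),
      fdr_model = fdrModel(prot$fdr),
      n_proteins = nrow(prot$quant),
      n_proteins_multi_peptide = sum(prot$quant$unique_peptides > 1L),
      n_unmapped_proteins = prot$nUnmappedProteins,
      n_unmapped_spectra = prot$nUnmappedSpectra,
      n_genes_detected = length(cmp$sets$proteomics)),
    array = list(
      n_probes = arr$nProbes,
      n_arrays = arr$nArrays,
      n_unannotated_probes = arr$nUnannotatedProbes,
      n_genes_annotated = nrow(arr$values),
      n_noncoding_removed = cmp$nNoncodingRemoved,
      n_genes_detected = length(cmp$sets$array)),
    rnaseq = list(
      n_reads = length(inp$reads),
      n_off_exon = rna$nOffExon,
      n_ambiguous = rna$nAmbiguous,
      n_unknown_chrom = rna$nUnknownChrom,
      n_detected_loci = rna$filter$summary$n_detected_loci,
      n_excluded_no_exon_overlap = rna$filter$summary$n_excluded,
      n_quantified = rna$filter$summary$n_quantified,
      n_genes_detected = length(cmp$sets$rnaseq)),
    venn = c(as.list(regionSizes(cmp$venn)),
             list(union_size = length(regionOf(cmp$venn)))),
    concordance = cmp$concordance
  )

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    .writeTsv(prot$quant, file.path(outDir, "protein_quant.tsv"))
    .writeTsv(prot$values, file.path(outDir, "gene_protein_values.tsv"))
    .writeTsv(arr$values, file.path(outDir, "gene_array_values.tsv"))
    .writeTsv(data.frame(gene_id = names(rna$counts),
                         count = as.integer(rna$counts)),
              file.path(outDir, "gene_counts.tsv"))
    .writeTsv(rna$filter$summary, file.path(outDir, "filter_report.tsv"))
    .writeTsv(.unifiedAsTable(unified), file.path(outDir, "unified_table.tsv"))
    .writeTsv(data.frame(region = names(regionSizes(cmp$venn)),
                         size = as.integer(regionSizes(cmp$venn))),
              file.path(outDir, "venn.tsv"))
    .writeTsv(cmp$summaries, file.path(outDir, "region_summaries.tsv"))
    .writeTsv(cmp$concordance, file.path(outDir, "concordance.tsv"))
    writeRunReport(report, file.path(outDir, "report.json"))
  }

  list(report = report, unified = unified, venn = cmp$venn,
       concordance = cmp$concordance, regionSummaries = cmp$summaries,
       fdr = prot$fdr, proteinQuant = prot$quant, counts = rna$counts,
       sim = inp$sim)
}

.simConfigAsList <- function(cfg) {
  out <- lapply(methods::slotNames("SimConfig"), function(s) slot(cfg, s))
  names(out) <- methods::slotNames("SimConfig")
  out
}

.unifiedAsTable <- function(se) {
  val <- SummarizedExperiment::assay(se, "values")
  det <- SummarizedExperiment::assay(se, "detected")
  mg <- SummarizedExperiment::assay(se, "multiGene")
  rd <- SummarizedExperiment::rowData(se)
  data.frame(gene_id = rownames(se),
             biotype = rd$biotype,
             proteomics = val[, "proteomics"],
             array = val[, "array"],
             rnaseq = val[, "rnaseq"],
             detected_proteomics = det[, "proteomics"],
             detected_array = det[, "array"],
             detected_rnaseq = det[, "rnaseq"],
             multi_gene = mg[, "proteomics"] | mg[, "array"] | mg[, "rnaseq"],
             stringsAsFactors = FALSE)
}

#' Write a run report as JSON
#'
#' @param report report list from [runPipeline()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeRunReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, null = "null", dataframe = "rows")
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file may contain a `simulate` mapping (arguments to
#' [simConfig()], with `discordanceFactors` as a nested mapping and
#' `probesPerGeneRange` as a two-element sequence), an `inputs` mapping
#' of file paths, and a `params` mapping of analysis settings. Paths are
#' resolved relative to the YAML file's directory.
#'
#' @param path YAML file path.
#' @return a config list suitable for [runPipeline()].
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$simulate)) {
    if (!is.null(cfg$simulate$probesPerGeneRange)) {
      cfg$simulate$probesPerGeneRange <-
        as.integer(unlist(cfg$simulate$probesPerGeneRange))
    }
    cfg$simulate <- do.call(simConfig, cfg$simulate)
  }
  if (!is.null(cfg$inputs)) {
    base <- dirname(normalizePath(path))
    cfg$inputs <- lapply(cfg$inputs, function(p) {
      if (file.exists(p)) p else file.path(base, p)
    })
  }
  cfg
}
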