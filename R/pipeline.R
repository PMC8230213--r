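# End-to-end pipeline: classification -> profiling -> association -> SKAT-O
# -> co-mutation graph, with a manifest and per-stage logging. Identical
# config + inputs produce byte-identical outputs.

#' Pipeline configuration
#'
#' Paths, filtration settings, stratification axes, SKAT settings, the
#' co-mutation graph threshold, seed and log level for [runPipeline()].
#' Round-trips losslessly through YAML via [writePipelineConfig()] /
#' [readPipelineConfig()].
#'
#' @slot vcfDir directory of per-sample VCFs (may be empty when a cohort is
#'   passed in memory)
#' @slot annotationsPath,patientsPath input TSV paths
#' @slot outDir output directory
#' @slot filter a [FilterConfig-class]
#' @slot axes stratification axes for the strata tables
#' @slot skatTraits trait axes screened with SKAT-O
#' @slot skatWeightsBeta Beta weight shapes
#' @slot rhoGrid SKAT-O rho grid
#' @slot usePermutation,nPermutations permutation safeguard settings
#' @slot pThreshold co-mutation graph edge threshold
#' @slot seed integer seed
#' @slot logLevel "quiet", "info" or "debug"
#' @export
setClass("PipelineConfig",
  representation(
    vcfDir = "character", annotationsPath = "character",
    patientsPath = "character", outDir = "character",
    filter = "FilterConfig", axes = "character",
    skatTraits = "character", skatWeightsBeta = "numeric",
    rhoGrid = "numeric", usePermutation = "logical",
    nPermutations = "integer", pThreshold = "numeric",
    seed = "integer", logLevel = "character"
  )
)

#' Construct a pipeline configuration
#'
#' @param vcfDir,annotationsPath,patientsPath,outDir paths
#' @param filter a [FilterConfig-class]
#' @param axes stratification axes
#' @param skatTraits SKAT-O trait axes
#' @param skatWeightsBeta,rhoGrid,usePermutation,nPermutations SKAT settings
#' @param pThreshold graph edge p threshold
#' @param seed integer seed
#' @param logLevel verbosity
#' @return a [PipelineConfig-class]
#' @export
PipelineConfig <- function(vcfDir = "", annotationsPath = "",
                           patientsPath = "", outDir = "cascade_out",
                           filter = FilterConfig(),
                           axes = c("gender", "age_group", "stage_group",
                                    "site", "lymph_node", "metastasis"),
                           skatTraits = c("gender", "age_group",
                                          "stage_group", "site"),
                           skatWeightsBeta = c(1, 25),
                           rhoGrid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25,
                                       0.5, 1),
                           usePermutation = FALSE, nPermutations = 2000L,
                           pThreshold = 0.05, seed = 1L,
                           logLevel = "info") {
  new("PipelineConfig", vcfDir = vcfDir, annotationsPath = annotationsPath,
      patientsPath = patientsPath, outDir = outDir, filter = filter,
      axes = axes, skatTraits = skatTraits,
      skatWeightsBeta = skatWeightsBeta, rhoGrid = rhoGrid,
      usePermutation = usePermutation,
      nPermutations = as.integer(nPermutations), pThreshold = pThreshold,
      seed = as.integer(seed), logLevel = logLevel)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [PipelineConfig-class]
#' @param path YAML file path
#' @return `writePipelineConfig` returns the path invisibly;
#'   `readPipelineConfig` the reconstructed [PipelineConfig-class]
#' @export
writePipelineConfig <- function(config, path) {
  f <- config@filter
  lst <- list(
    vcfDir = config@vcfDir, annotationsPath = config@annotationsPath,
    patientsPath = config@patientsPath, outDir = config@outDir,
    filter = list(minCoverage = f@minCoverage, minQuality = f@minQuality,
                  germlineBands = as.vector(t(f@germlineBands)),
                  germlineMafThreshold = f@germlineMafThreshold,
                  targetTissue = f@targetTissue,
                  popAfThreshold = f@popAfThreshold),
    axes = config@axes, skatTraits = config@skatTraits,
    skatWeightsBeta = config@skatWeightsBeta, rhoGrid = config@rhoGrid,
    usePermutation = config@usePermutation,
    nPermutations = config@nPermutations, pThreshold = config@pThreshold,
    seed = config@seed, logLevel = config@logLevel)
  yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  f <- lst$filter
  PipelineConfig(
    vcfDir = lst$vcfDir, annotationsPath = lst$annotationsPath,
    patientsPath = lst$patientsPath, outDir = lst$outDir,
    filter = FilterConfig(
      minCoverage = f$minCoverage, minQuality = f$minQuality,
      germlineBands = matrix(f$germlineBands, ncol = 2, byrow = TRUE),
      germlineMafThreshold = f$germlineMafThreshold,
      targetTissue = f$targetTissue,
      popAfThreshold = if (is.null(f$popAfThreshold)) NA_real_
                       else f$popAfThreshold),
    axes = lst$axes, skatTraits = lst$skatTraits,
    skatWeightsBeta = lst$skatWeightsBeta, rhoGrid = lst$rhoGrid,
    usePermutation = lst$usePermutation,
    nPermutations = lst$nPermutations, pThreshold = lst$pThreshold,
    seed = lst$seed, logLevel = lst$logLevel)
}

.log <- function(config, level, fmt, ...) {
  levels <- c(quiet = 0L, info = 1L, debug = 2L)
  if (levels[[config@logLevel]] >= levels[[level]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Export the co-mutation graph
#'
#' Open, structural stand-in for knowledge-base network analysis: nodes are
#' the (non-constant) genes of the correlation matrix and edges connect
#' gene pairs whose co-occurrence correlation p-value falls below the
#' threshold, with `r` and `p` edge attributes. Written as GraphML. Makes no
#' biological claims beyond the correlation structure.
#'
#' @param corMat a [CorrelationMatrix-class]
#' @param pThreshold edge inclusion threshold (default 0.05); 1 yields the
#'   complete graph on non-constant genes
#' @param path output GraphML path
#' @return the igraph object, invisibly
#' @export
exportComutationGraph <- function(corMat, pThreshold = 0.05, path) {
  genes <- corMat@genes
  # p-values live in (0, 1]; a threshold of 1 or more means every pair
  hit <- if (pThreshold >= 1) corMat@p <= 1 else corMat@p < pThreshold
  idx <- which(upper.tri(corMat@p) & !is.na(corMat@p) & hit,
               arr.ind = TRUE)
  if (nrow(idx)) {
    edges <- data.frame(from = genes[idx[, 1]], to = genes[idx[, 2]],
                        r = corMat@r[idx], p = corMat@p[idx],
                        stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = genes))
  } else {
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(genes)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}

#' Run the full cascade pipeline
#'
#' Quality-gates and classifies the calls, writes the classified table and
#' cascade counts, builds the incidence matrices, gene summary, strata and
#' cohort summary tables, the Fisher association screens, the co-occurrence
#' correlation with its star annotation and GraphML export, and the SKAT-O
#' screens, then records everything in a manifest (config fingerprint, seed,
#' package version, every written file).
#'
#' @param config a [PipelineConfig-class]
#' @param cohort optional in-memory [VariantCohort-class]; when NULL the
#'   inputs are read from the configured paths
#' @return invisibly, a list with `status` (0 on success), `manifest`
#'   data.frame and named `outputs` paths
#' @export
runPipeline <- function(config, cohort = NULL) {
  stopifnot(is(config, "PipelineConfig"))
  dir.create(config@outDir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(name) {
    p <- file.path(config@outDir, name)
    outputs[[name]] <<- p
    p
  }

  inputs <- .stage("inputs", {
    if (!is.null(cohort)) {
      list(calls = cohort@calls, ann = cohort@annotations)
    } else {
      if (!dir.exists(config@vcfDir))
        stop(sprintf("VCF directory not found: %s", config@vcfDir))
      if (!file.exists(config@annotationsPath))
        stop(sprintf("annotation table not found: %s",
                     config@annotationsPath))
      list(calls = readVcfDir(config@vcfDir),
           ann = readAnnotations(config@annotationsPath))
    }
  })
  .log(config, "info", "inputs: %d calls, %d annotated variants",
       nrow(inputs$calls), nrow(inputs$ann))

  classified <- .stage("classify", {
    kept <- qualityFilter(inputs$calls, config@filter)
    .log(config, "info", "quality gate: %d of %d calls retained",
         nrow(kept), nrow(inputs$calls))
    nS <- if (!is.null(cohort)) nrow(cohort@patients) else
      length(unique(inputs$calls$sample_id))
    cl <- classifyVariants(kept, inputs$ann, config@filter, nSamples = nS)
    writeClassified(cl, emit("classified.tsv"))
    counts <- cascadeCounts(cl)
    jsonlite::write_json(as.list(compositionCounts(counts)),
                         emit("cascade_counts.json"), auto_unbox = TRUE)
    .log(config, "info", "cascade: %d variants, %d novel vs both",
         counts@nTotal, novelVsBoth(counts))
    list(cl = cl, kept = kept, counts = counts, nSamples = nS)
  })

  prof <- .stage("profiling", {
    pts <- if (!is.null(cohort)) cohort@patients else {
      if (!file.exists(config@patientsPath))
        stop(sprintf("patient table not found: %s", config@patientsPath))
      readPatients(config@patientsPath)
    }
    samples <- sort(pts$patient_id)
    mats <- lapply(setNames(.CRITERIA, .CRITERIA), function(cr)
      geneSampleMatrix(classified$cl, classified$kept, cr,
                       samples = samples))
    for (cr in .CRITERIA)
      .writeTsv(as.data.frame(incidence(mats[[cr]])),
                emit(sprintf("matrix_%s.tsv", cr)))
    gs <- geneSummary(classified$cl, classified$kept, samples = samples)
    .writeTsv(gs, emit("gene_summary.tsv"))
    for (ax in config@axes)
      .writeTsv(stratifyMatrix(mats$tissue_specific_pathogenic, pts, ax),
                emit(sprintf("strata_%s.tsv", ax)))
    .writeTsv(cohortSummary(pts), emit("cohort_summary.tsv"))
    .log(config, "info", "profiling: %d genes, %d samples",
         nrow(gs), length(samples))
    list(pts = pts, mats = mats, gs = gs)
  })

  .stage("association", {
    for (ax in config@axes) {
      scr <- associationScreen(prof$mats$tissue_specific_pathogenic,
                               prof$pts, ax, test = "fisher")
      .writeTsv(scr, emit(sprintf("association_%s.tsv", ax)))
    }
    recurrent <- selectRecurrentGenes(prof$mats$tissue_specific_pathogenic,
                                      minPatients = 3L)
    .log(config, "info", "association: %d recurrent genes",
         length(recurrent))
    if (length(recurrent) >= 2L &&
        ncol(incidence(prof$mats$tissue_specific_pathogenic)) >= 3L) {
      sub <- prof$mats$tissue_specific_pathogenic[recurrent, ]
      corMat <- suppressMessages(pearsonBinaryCorrelation(sub))
      .writeTsv(as.data.frame(corMat@r), emit("correlation_r.tsv"))
      .writeTsv(as.data.frame(corMat@p), emit("correlation_p.tsv"))
      .writeTsv(as.data.frame(significanceStars(corMat)),
                emit("correlation_stars.tsv"))
      exportComutationGraph(corMat, config@pThreshold,
                            emit("comutation_graph.graphml"))
    }
    mh <- variantMafHwe(classified$cl, classified$nSamples)
    .writeTsv(mh, emit("variant_maf_hwe.tsv"))
    invisible(NULL)
  })

  .stage("skat", {
    for (tr in config@skatTraits) {
      scr <- skatOScreen(classified$cl, classified$kept, prof$pts, tr,
                         rhoGrid = config@rhoGrid,
                         weightsBeta = config@skatWeightsBeta,
                         usePermutation = config@usePermutation,
                         nPermutations = config@nPermutations,
                         seed = config@seed)
      .writeTsv(scr, emit(sprintf("skat_%s.tsv", tr)))
      .log(config, "info", "skat %s: top gene %s (p = %.3g)",
           tr, scr$SetID[1], scr$p.value[1])
    }
    invisible(NULL)
  })

  manifest <- .stage("manifest", {
    cfgTmp <- tempfile(fileext = ".yaml")
    writePipelineConfig(config, cfgTmp)
    hash <- unname(tools::md5sum(cfgTmp))
    unlink(cfgTmp)
    outputs[["manifest.tsv"]] <- file.path(config@outDir, "manifest.tsv")
    mf <- data.frame(
      key = c("config_md5", "seed", "package_version",
              paste0("output:", names(outputs))),
      value = c(hash, as.character(config@seed),
                as.character(utils::packageVersion("somaticCascade")),
                unname(outputs)),
      stringsAsFactors = FALSE)
    .writeTsv(mf, file.path(config@outDir, "manifest.tsv"))
    mf
  })

  invisible(list(status = 0L, manifest = manifest, outputs = outputs))
}
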