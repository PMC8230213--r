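#' @import methods
#' @importFrom stats rnorm runif rbinom rpois rbeta dbeta dchisq pchisq qchisq
#'   dhyper pt glm.fit lm.fit binomial integrate setNames sd complete.cases
#'   median quantile cor
#' @importFrom utils read.delim write.table
NULL

.CONSEQUENCES <- c("synonymous", "missense", "stop_gained", "frameshift",
                   "splice", "other")
.SIFT_LEVELS <- c("deleterious", "tolerated", "missing")
.POLYPHEN_LEVELS <- c("probably_damaging", "possibly_damaging", "benign",
                      "missing")
.SITES <- c("left_colon", "right_colon", "rectum", "other")
.STAGES <- c("I", "II", "III", "IV")
.CRITERIA <- c("any", "somatic", "pathogenic", "tissue_specific_pathogenic")
.AXES <- c("gender", "age_group", "stage_group", "site", "lymph_node",
           "metastasis")

# ---------------------------------------------------------------------------
# CascadeComposition
# ---------------------------------------------------------------------------

#' Cascade composition: node tallies of the variant filtration cascade
#'
#' Holds the counts at every node of the filtration/classification cascade:
#' the working total, variants absent from COSMIC ("novel"), the subset of
#' those present in ICGC, confirmed-somatic and pathogenic sets (with their
#' intersection), pathogenic variants with a prior report in the target
#' tissue, germline-suspect tallies, and SIFT/PolyPhen/consequence category
#' counts among the confirmed-somatic subset.
#'
#' The same class serves as the target composition a synthetic cohort
#' realizes count-exactly, and as the output of [cascadeCounts()].
#'
#' @slot nTotal working number of variants (post quality gate)
#' @slot nNovelCosmic variants absent from COSMIC
#' @slot nIcgcAmongNovel COSMIC-absent variants present in ICGC
#' @slot nConfirmedSomatic COSMIC confirmed-somatic variants
#' @slot nPathogenic COSMIC (FATHMM) pathogenic variants
#' @slot nSomaticAndPathogenic intersection of the two previous sets
#' @slot nPathogenicPriorTissue pathogenic variants previously reported in the
#'   target tissue (tissue-specific pathogenic)
#' @slot nGermlineBand variants with at least one carrier VAF in a germline
#'   band (49--51\% or 99--100\%)
#' @slot nGermlineMafSupport germline-band variants additionally supported by
#'   cohort MAF above the threshold
#' @slot nEnsemblCommon variants flagged as previously reported in Ensembl and
#'   not rescued by COSMIC somatic/pathogenic status (excluded as common)
#' @slot nSiftDeleterious,nSiftTolerated SIFT categories among somatic missense
#' @slot nPolyphenProbably,nPolyphenPossibly,nPolyphenBenign PolyPhen
#'   categories among somatic missense
#' @slot consequenceCounts named integer vector over consequence categories
#'   (confirmed-somatic subset)
#' @export
setClass("CascadeComposition",
  representation(
    nTotal = "integer",
    nNovelCosmic = "integer",
    nIcgcAmongNovel = "integer",
    nConfirmedSomatic = "integer",
    nPathogenic = "integer",
    nSomaticAndPathogenic = "integer",
    nPathogenicPriorTissue = "integer",
    nGermlineBand = "integer",
    nGermlineMafSupport = "integer",
    nEnsemblCommon = "integer",
    nSiftDeleterious = "integer",
    nSiftTolerated = "integer",
    nPolyphenProbably = "integer",
    nPolyphenPossibly = "integer",
    nPolyphenBenign = "integer",
    consequenceCounts = "integer"
  )
)

setValidity("CascadeComposition", function(object) {
  msg <- character()
  counts <- c(
    nTotal = object@nTotal, nNovelCosmic = object@nNovelCosmic,
    nIcgcAmongNovel = object@nIcgcAmongNovel,
    nConfirmedSomatic = object@nConfirmedSomatic,
    nPathogenic = object@nPathogenic,
    nSomaticAndPathogenic = object@nSomaticAndPathogenic,
    nPathogenicPriorTissue = object@nPathogenicPriorTissue,
    nGermlineBand = object@nGermlineBand,
    nGermlineMafSupport = object@nGermlineMafSupport,
    nEnsemblCommon = object@nEnsemblCommon,
    object@consequenceCounts
  )
  if (any(is.na(counts)) || any(counts < 0))
    msg <- c(msg, "all counts must be non-negative")
  .chkSub <- function(a, b, an, bn) {
    if (!is.na(a) && !is.na(b) && a > b)
      sprintf("%s (%d) exceeds its superset %s (%d)", an, a, bn, b)
    else character()
  }
  msg <- c(msg,
    .chkSub(object@nNovelCosmic, object@nTotal, "nNovelCosmic", "nTotal"),
    .chkSub(object@nIcgcAmongNovel, object@nNovelCosmic,
            "nIcgcAmongNovel", "nNovelCosmic"),
    .chkSub(object@nSomaticAndPathogenic,
            min(object@nConfirmedSomatic, object@nPathogenic),
            "nSomaticAndPathogenic", "min(nConfirmedSomatic, nPathogenic)"),
    .chkSub(object@nPathogenicPriorTissue, object@nPathogenic,
            "nPathogenicPriorTissue", "nPathogenic"),
    .chkSub(object@nGermlineMafSupport, object@nGermlineBand,
            "nGermlineMafSupport", "nGermlineBand"),
    .chkSub(object@nGermlineBand, object@nTotal, "nGermlineBand", "nTotal"))
  # somatic/pathogenic live inside the COSMIC-present set
  inCosmic <- object@nTotal - object@nNovelCosmic
  union2 <- object@nConfirmedSomatic + object@nPathogenic -
    object@nSomaticAndPathogenic
  if (!is.na(union2) && !is.na(inCosmic) && union2 > inCosmic)
    msg <- c(msg, sprintf(
      "somatic+pathogenic union (%d) exceeds COSMIC-present variants (%d)",
      union2, inCosmic))
  if (!identical(sort(names(object@consequenceCounts)), sort(.CONSEQUENCES)))
    msg <- c(msg, "consequenceCounts must be named over the consequence enum")
  else if (sum(object@consequenceCounts) != object@nConfirmedSomatic)
    msg <- c(msg, "consequenceCounts must sum to nConfirmedSomatic")
  nMissense <- object@consequenceCounts[["missense"]]
  if (object@nSiftDeleterious + object@nSiftTolerated > nMissense)
    msg <- c(msg, "SIFT categories exceed somatic missense count")
  if (object@nPolyphenProbably + object@nPolyphenPossibly +
      object@nPolyphenBenign > nMissense)
    msg <- c(msg, "PolyPhen categories exceed somatic missense count")
  if (length(msg)) msg else TRUE
})

#' Construct a cascade composition
#'
#' Defaults reproduce the published cohort-level cascade: 4256 working
#' variants, 483 absent from COSMIC of which 17 appear in ICGC (466 novel
#' against both), 561 confirmed somatic, 299 pathogenic (taken as a subset of
#' the somatic set), 125 pathogenic variants with a prior large-intestine
#' report (so 174 are first-time in that tissue), 69 variants with a carrier
#' VAF in a germline band of which 45 have cohort-MAF support, 240/247
#' synonymous/missense consequences among the somatic set, 130/111 SIFT
#' deleterious/tolerated and 143 PolyPhen-benign (104 damaging) among somatic
#' missense.
#'
#' @param nTotal,nNovelCosmic,nIcgcAmongNovel,nConfirmedSomatic,nPathogenic
#'   cascade node counts, see slot documentation
#' @param nSomaticAndPathogenic,nPathogenicPriorTissue,nGermlineBand
#'   cascade node counts, see slot documentation
#' @param nGermlineMafSupport,nEnsemblCommon cascade node counts
#' @param nSiftDeleterious,nSiftTolerated SIFT tallies among somatic missense
#' @param nPolyphenProbably,nPolyphenPossibly,nPolyphenBenign PolyPhen tallies
#' @param consequenceCounts named integer vector over
#'   synonymous/missense/stop_gained/frameshift/splice/other summing to
#'   `nConfirmedSomatic`
#' @return a validated [CascadeComposition-class] object
#' @examples
#' comp <- CascadeComposition()
#' novelVsBoth(comp)   # 466
#' @export
CascadeComposition <- function(nTotal = 4256L,
                               nNovelCosmic = 483L,
                               nIcgcAmongNovel = 17L,
                               nConfirmedSomatic = 561L,
                               nPathogenic = 299L,
                               nSomaticAndPathogenic = 299L,
                               nPathogenicPriorTissue = 125L,
                               nGermlineBand = 69L,
                               nGermlineMafSupport = 45L,
                               nEnsemblCommon = 0L,
                               nSiftDeleterious = 130L,
                               nSiftTolerated = 111L,
                               nPolyphenProbably = 70L,
                               nPolyphenPossibly = 34L,
                               nPolyphenBenign = 143L,
                               consequenceCounts = c(
                                 synonymous = 240L, missense = 247L,
                                 stop_gained = 20L, frameshift = 24L,
                                 splice = 10L, other = 20L)) {
  new("CascadeComposition",
      nTotal = as.integer(nTotal),
      nNovelCosmic = as.integer(nNovelCosmic),
      nIcgcAmongNovel = as.integer(nIcgcAmongNovel),
      nConfirmedSomatic = as.integer(nConfirmedSomatic),
      nPathogenic = as.integer(nPathogenic),
      nSomaticAndPathogenic = as.integer(nSomaticAndPathogenic),
      nPathogenicPriorTissue = as.integer(nPathogenicPriorTissue),
      nGermlineBand = as.integer(nGermlineBand),
      nGermlineMafSupport = as.integer(nGermlineMafSupport),
      nEnsemblCommon = as.integer(nEnsemblCommon),
      nSiftDeleterious = as.integer(nSiftDeleterious),
      nSiftTolerated = as.integer(nSiftTolerated),
      nPolyphenProbably = as.integer(nPolyphenProbably),
      nPolyphenPossibly = as.integer(nPolyphenPossibly),
      nPolyphenBenign = as.integer(nPolyphenBenign),
      consequenceCounts =
        setNames(as.integer(consequenceCounts), names(consequenceCounts)))
}

setMethod("show", "CascadeComposition", function(object) {
  cat("CascadeComposition\n")
  cat(sprintf("  total variants:            %d\n", object@nTotal))
  cat(sprintf("  absent from COSMIC:        %d\n", object@nNovelCosmic))
  cat(sprintf("    of those in ICGC:        %d\n", object@nIcgcAmongNovel))
  cat(sprintf("    novel vs both:           %d\n",
              object@nNovelCosmic - object@nIcgcAmongNovel))
  cat(sprintf("  confirmed somatic:         %d\n", object@nConfirmedSomatic))
  cat(sprintf("  pathogenic:                %d (intersection with somatic: %d)\n",
              object@nPathogenic, object@nSomaticAndPathogenic))
  cat(sprintf("    prior target-tissue:     %d\n",
              object@nPathogenicPriorTissue))
  cat(sprintf("    novel in target tissue:  %d\n",
              object@nPathogenic - object@nPathogenicPriorTissue))
  cat(sprintf("  germline-band VAF:         %d (MAF-supported: %d)\n",
              object@nGermlineBand, object@nGermlineMafSupport))
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# CohortConfig
# ---------------------------------------------------------------------------

#' Configuration of the synthetic cohort generator
#'
#' Bundles the cohort size, gene panel, target cascade composition,
#' variant-allele-fraction model and clinicopathological marginal
#' distributions from which a synthetic tumor-only panel cohort is drawn.
#' Defaults emulate the study conditions of a 90-patient colorectal cohort
#' sequenced on a 409-gene comprehensive cancer panel at deep coverage.
#'
#' @slot nPatients number of patients
#' @slot panelGenes character vector of panel gene symbols
#' @slot variantsPerPatient mean number of variant calls per patient; controls
#'   the carrier-multiplicity of shared variants
#' @slot vafShape1,vafShape2 Beta shape parameters of the somatic VAF spread
#' @slot vafMin,vafMax somatic VAF support on the percent scale
#' @slot germlineBands 2x2 matrix of closed VAF intervals (percent) treated as
#'   germline-suspect
#' @slot composition a [CascadeComposition-class] realized count-exactly
#' @slot clinicopath named list of category weight tables for gender, stage,
#'   t/n/m stage and site plus ageMean/ageSD
#' @slot nFailQuality number of extra calls generated below the quality gate
#' @slot seed integer seed; identical config implies byte-identical output
#' @export
setClass("CohortConfig",
  representation(
    nPatients = "integer",
    panelGenes = "character",
    variantsPerPatient = "numeric",
    vafShape1 = "numeric",
    vafShape2 = "numeric",
    vafMin = "numeric",
    vafMax = "numeric",
    germlineBands = "matrix",
    composition = "CascadeComposition",
    clinicopath = "list",
    nFailQuality = "integer",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nPatients < 0L) msg <- c(msg, "nPatients must be >= 0")
  if (object@variantsPerPatient < 0) msg <- c(msg, "variantsPerPatient >= 0")
  if (object@vafMin <= 0 || object@vafMax > 100 ||
      object@vafMin >= object@vafMax)
    msg <- c(msg, "somatic VAF support must satisfy 0 < vafMin < vafMax <= 100")
  b <- object@germlineBands
  if (!is.numeric(b) || ncol(b) != 2L || any(b < 0) || any(b > 100) ||
      any(b[, 1] > b[, 2]))
    msg <- c(msg, "germlineBands must be rows of closed intervals in [0,100]")
  need <- c("gender", "stage", "tStage", "nStage", "mStage", "site")
  if (!all(need %in% names(object@clinicopath)))
    msg <- c(msg, paste("clinicopath must contain:",
                        paste(need, collapse = ", ")))
  for (nm in intersect(need, names(object@clinicopath))) {
    w <- object@clinicopath[[nm]]
    if (any(w < 0) || sum(w) <= 0)
      msg <- c(msg, sprintf("clinicopath$%s must be non-negative weights", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a cohort generator configuration
#'
#' @param nPatients cohort size (default 90, the analyzed study cohort)
#' @param panelGenes panel gene symbols; default 409 synthetic symbols
#'   `G001..G409` standing in for the comprehensive cancer panel
#' @param variantsPerPatient mean calls per patient (default 70)
#' @param vafShape1,vafShape2 Beta shapes of the somatic VAF spread
#'   (default Beta(2,3) scaled onto (5,95)\%, a plausible FFPE tumor-only
#'   spread)
#' @param vafMin,vafMax somatic VAF support, percent
#' @param germlineBands matrix of closed percent intervals flagged as
#'   germline-suspect (default `[49,51]` and `[99,100]`)
#' @param composition target [CascadeComposition-class]
#' @param clinicopath named list of marginal weights; defaults follow the
#'   published cohort-table marginals (58/37 male/female; stages 17/32/37/8;
#'   T 2/18/61/13; N 55/33/6; M 90/4; site 47/30/13 left/right/rectum;
#'   age mean 62, SD 14)
#' @param nFailQuality number of additional sub-threshold calls (default 0)
#' @param seed integer seed
#' @return a validated [CohortConfig-class]
#' @export
CohortConfig <- function(nPatients = 90L,
                         panelGenes = sprintf("G%03d", seq_len(409L)),
                         variantsPerPatient = 70,
                         vafShape1 = 2, vafShape2 = 3,
                         vafMin = 5, vafMax = 95,
                         germlineBands = rbind(c(49, 51), c(99, 100)),
                         composition = CascadeComposition(),
                         clinicopath = defaultClinicopath(),
                         nFailQuality = 0L,
                         seed = 1L) {
  new("CohortConfig",
      nPatients = as.integer(nPatients),
      panelGenes = as.character(panelGenes),
      variantsPerPatient = as.numeric(variantsPerPatient),
      vafShape1 = vafShape1, vafShape2 = vafShape2,
      vafMin = vafMin, vafMax = vafMax,
      germlineBands = germlineBands,
      composition = composition,
      clinicopath = clinicopath,
      nFailQuality = as.integer(nFailQuality),
      seed = as.integer(seed))
}

#' Default clinicopathological marginal distributions
#'
#' Category weights follow the published cohort table: counts are used as
#' sampling weights with field-specific denominators, and the joint
#' distribution is independent across fields (only marginals are published).
#'
#' @return named list of weight tables plus `ageMean` and `ageSD`
#' @export
defaultClinicopath <- function() {
  list(
    gender = c(male = 58, female = 37),
    stage = c(I = 17, II = 32, III = 37, IV = 8),
    tStage = c(T1 = 2, T2 = 18, T3 = 61, T4 = 13),
    nStage = c(N0 = 55, N1 = 33, N2 = 6),
    mStage = c(M0 = 90, M1 = 4),
    site = c(left_colon = 47, right_colon = 30, rectum = 13),
    ageMean = 62, ageSD = 14
  )
}

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig\n")
  cat(sprintf("  patients: %d   panel genes: %d   seed: %d\n",
              object@nPatients, length(object@panelGenes), object@seed))
  cat(sprintf("  somatic VAF: Beta(%g,%g) on (%g,%g)%%\n",
              object@vafShape1, object@vafShape2, object@vafMin,
              object@vafMax))
  cat(sprintf("  composition total: %d variants\n",
              object@composition@nTotal))
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# VariantCohort
# ---------------------------------------------------------------------------

#' A tumor-only panel cohort: patients, variant calls and annotations
#'
#' Container tying together the three tables the pipeline consumes: one row
#' per patient (clinicopathological features), one row per variant call per
#' sample (locus, alleles, depths, QUAL, VAF), and one row per distinct
#' variant (database and functional annotations).
#'
#' @slot patients data.frame of patient records
#' @slot calls data.frame of per-sample variant calls
#' @slot annotations data.frame of per-variant annotations
#' @slot config the generating [CohortConfig-class], or NULL for cohorts read
#'   from disk
#' @export
setClass("VariantCohort",
  representation(
    patients = "data.frame",
    calls = "data.frame",
    annotations = "data.frame",
    config = "ANY"
  )
)

setValidity("VariantCohort", function(object) {
  msg <- character()
  needC <- c("sample_id", "chrom", "pos", "ref", "alt", "qual", "depth",
             "alt_depth", "vaf_percent")
  if (!all(needC %in% names(object@calls)))
    msg <- c(msg, "calls must carry the VariantCall columns")
  needA <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
             "in_cosmic", "cosmic_confirmed_somatic", "cosmic_pathogenic",
             "cosmic_tissues", "in_icgc", "ensembl_known", "population_af",
             "sift", "polyphen")
  if (!all(needA %in% names(object@annotations)))
    msg <- c(msg, "annotations must carry the VariantAnnotation columns")
  if (length(msg)) msg else TRUE
})

setMethod("show", "VariantCohort", function(object) {
  cat("VariantCohort\n")
  cat(sprintf("  %d patients, %d calls, %d annotated variants\n",
              nrow(object@patients), nrow(object@calls),
              nrow(object@annotations)))
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# FilterConfig
# ---------------------------------------------------------------------------

#' Configuration of the filtration cascade
#'
#' @slot minCoverage coverage gate; calls require depth strictly greater
#'   (default 300, "more than 300X")
#' @slot minQuality site QUAL gate, strictly greater (default 50)
#' @slot germlineBands closed VAF intervals (percent) flagging possible
#'   germline origin (default `[49,51]` and `[99,100]`)
#' @slot germlineMafThreshold cohort minor-allele-frequency support threshold,
#'   exclusive (default 0.01)
#' @slot targetTissue COSMIC tissue of interest (default "large_intestine")
#' @slot popAfThreshold optional population-AF override for common-variant
#'   exclusion; NA (default) disables it
#' @export
setClass("FilterConfig",
  representation(
    minCoverage = "numeric",
    minQuality = "numeric",
    germlineBands = "matrix",
    germlineMafThreshold = "numeric",
    targetTissue = "character",
    popAfThreshold = "numeric"
  )
)

setValidity("FilterConfig", function(object) {
  msg <- character()
  if (object@minCoverage <= 0 || object@minQuality <= 0)
    msg <- c(msg, "thresholds must be positive")
  b <- object@germlineBands
  if (ncol(b) != 2L || any(b < 0) || any(b > 100) || any(b[, 1] > b[, 2]))
    msg <- c(msg, "germlineBands must be closed intervals within [0,100]")
  if (nrow(b) > 1L) {
    o <- order(b[, 1])
    bs <- b[o, , drop = FALSE]
    if (any(bs[-1L, 1] <= bs[-nrow(bs), 2]))
      msg <- c(msg, "germlineBands must be disjoint")
  }
  if (object@germlineMafThreshold <= 0)
    msg <- c(msg, "germlineMafThreshold must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a filtration configuration
#'
#' @param minCoverage,minQuality strict (exclusive) quality gates
#' @param germlineBands matrix of closed VAF intervals, percent scale
#' @param germlineMafThreshold exclusive cohort-MAF support threshold
#' @param targetTissue tissue name matched against COSMIC tissue-of-report
#' @param popAfThreshold optional population-AF common-variant override
#' @return a validated [FilterConfig-class]
#' @export
FilterConfig <- function(minCoverage = 300, minQuality = 50,
                         germlineBands = rbind(c(49, 51), c(99, 100)),
                         germlineMafThreshold = 0.01,
                         targetTissue = "large_intestine",
                         popAfThreshold = NA_real_) {
  new("FilterConfig", minCoverage = minCoverage, minQuality = minQuality,
      germlineBands = germlineBands,
      germlineMafThreshold = germlineMafThreshold,
      targetTissue = targetTissue, popAfThreshold = popAfThreshold)
}

setMethod("show", "FilterConfig", function(object) {
  cat(sprintf(
    "FilterConfig: depth > %g, QUAL > %g, germline MAF > %g, tissue '%s'\n",
    object@minCoverage, object@minQuality, object@germlineMafThreshold,
    object@targetTissue))
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# GeneSampleMatrix
# ---------------------------------------------------------------------------

#' Binary gene-by-sample incidence matrix
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose single assay `"incidence"` holds 0/1 cells: `cell[g, s] = 1` iff
#' sample `s` carries at least one variant in gene `g` meeting the matrix
#' criterion (one of `any`, `somatic`, `pathogenic`,
#' `tissue_specific_pathogenic`). The criterion is stored in `metadata()`.
#'
#' @export
setClass("GeneSampleMatrix", contains = "SummarizedExperiment")

setValidity("GeneSampleMatrix", function(object) {
  msg <- character()
  a <- SummarizedExperiment::assays(object)
  if (!"incidence" %in% names(a))
    return("assay 'incidence' is required")
  x <- a[["incidence"]]
  if (length(x) && !all(x %in% c(0L, 1L)))
    msg <- c(msg, "incidence cells must be 0/1")
  if (anyDuplicated(rownames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "gene and sample labels must be unique")
  crit <- S4Vectors::metadata(object)$criterion
  if (is.null(crit) || !crit %in% .CRITERIA)
    msg <- c(msg, "metadata criterion must be one of the known criteria")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# SKAT classes
# ---------------------------------------------------------------------------

#' Null trait model for score-based rare-variant tests
#'
#' @slot traitType "binary" or "quantitative"
#' @slot fitted per-individual expected trait under the null
#' @slot residuals trait minus fitted mean
#' @slot dispersion residual variance (quantitative traits; 1 for binary)
#' @slot design model matrix of the null fit (intercept plus covariates)
#' @export
setClass("SkatNullModel",
  representation(
    traitType = "character",
    fitted = "numeric",
    residuals = "numeric",
    dispersion = "numeric",
    design = "matrix"
  )
)

setValidity("SkatNullModel", function(object) {
  msg <- character()
  if (!object@traitType %in% c("binary", "quantitative"))
    msg <- c(msg, "traitType must be binary or quantitative")
  if (length(object@fitted) != length(object@residuals))
    msg <- c(msg, "fitted and residuals must align")
  if (abs(sum(object@residuals)) > 1e-6 * max(1, length(object@residuals)))
    msg <- c(msg, "residuals must sum to ~0 under an intercept model")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SkatNullModel", function(object) {
  cat(sprintf("SkatNullModel (%s trait, n = %d, %d design column%s)\n",
              object@traitType, length(object@fitted), ncol(object@design),
              if (ncol(object@design) == 1L) "" else "s"))
  invisible(NULL)
})

#' Gene-level SKAT-O result
#'
#' @slot gene gene symbol (set id)
#' @slot pValue combined SKAT-O p-value over the rho grid
#' @slot perRhoP named vector of per-rho p-values
#' @slot bestRho rho attaining the minimum per-rho p
#' @slot nMarkerAll,nMarkerTest variant counts in the gene / entering the test
#' @slot mac total minor allele count
#' @slot mCarriers individuals carrying at least one minor allele
#' @slot methodLabel which numerical path produced the p-value
#' @export
setClass("SkatOResult",
  representation(
    gene = "character",
    pValue = "numeric",
    perRhoP = "numeric",
    bestRho = "numeric",
    nMarkerAll = "integer",
    nMarkerTest = "integer",
    mac = "numeric",
    mCarriers = "integer",
    methodLabel = "character"
  )
)

setMethod("show", "SkatOResult", function(object) {
  cat(sprintf(
    "SkatOResult %s: p = %.4g (best rho %.2f), markers %d/%d, MAC %g, m %d [%s]\n",
    object@gene, object@pValue, object@bestRho, object@nMarkerTest,
    object@nMarkerAll, object@mac, object@mCarriers, object@methodLabel))
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# CorrelationMatrix
# ---------------------------------------------------------------------------

#' Pairwise co-occurrence correlation of gene mutation status
#'
#' Pearson correlation on 0/1 incidence vectors (equivalently the phi
#' coefficient of the 2x2 cross-table), with two-sided p-values from the
#' t transform on n-2 degrees of freedom.
#'
#' @slot genes genes entering the matrix (non-constant incidence)
#' @slot r symmetric correlation matrix, unit diagonal
#' @slot p symmetric p-value matrix (diagonal NA)
#' @slot n number of samples
#' @slot excluded genes dropped for zero variance
#' @slot starLevels significance thresholds used for star annotation
#' @export
setClass("CorrelationMatrix",
  representation(
    genes = "character",
    r = "matrix",
    p = "matrix",
    n = "integer",
    excluded = "character",
    starLevels = "numeric"
  )
)

setValidity("CorrelationMatrix", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@r, t(object@r), tolerance = 1e-8)))
    msg <- c(msg, "r must be symmetric")
  if (length(object@genes) && any(abs(diag(object@r) - 1) > 1e-8))
    msg <- c(msg, "diagonal of r must be 1")
  if (any(abs(object@r) > 1 + 1e-8))
    msg <- c(msg, "|r| must not exceed 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf(
    "CorrelationMatrix: %d genes, n = %d samples (%d excluded as constant)\n",
    length(object@genes), object@n, length(object@excluded)))
  invisible(NULL)
})
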