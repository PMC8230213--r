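#' Accessors for cohort and result containers
#'
#' Accessor generics: `patients()`, `variantCalls()` and `annotations()`
#' extract the three tables of a [VariantCohort-class]; `incidence()` and
#' `criterion()` extract the 0/1 matrix and selection criterion of a
#' [GeneSampleMatrix-class]; `novelVsBoth()` returns the derived
#' novel-against-both-databases tally of a [CascadeComposition-class];
#' `compositionCounts()` flattens a composition to a named integer vector.
#'
#' @param x the object
#' @return the extracted component
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("patients", function(x) standardGeneric("patients"))

#' @rdname accessors
#' @export
setGeneric("variantCalls", function(x) standardGeneric("variantCalls"))

#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname accessors
#' @export
setGeneric("incidence", function(x) standardGeneric("incidence"))

#' @rdname accessors
#' @export
setGeneric("criterion", function(x) standardGeneric("criterion"))

#' @rdname accessors
#' @export
setGeneric("novelVsBoth", function(x) standardGeneric("novelVsBoth"))

#' @rdname accessors
#' @export
setGeneric("compositionCounts", function(x)
  standardGeneric("compositionCounts"))

#' @rdname accessors
#' @export
setMethod("patients", "VariantCohort", function(x) x@patients)

#' @rdname accessors
#' @export
setMethod("variantCalls", "VariantCohort", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("annotations", "VariantCohort", function(x) x@annotations)

#' @rdname accessors
#' @export
setMethod("incidence", "GeneSampleMatrix", function(x)
  SummarizedExperiment::assay(x, "incidence"))

#' @rdname accessors
#' @export
setMethod("criterion", "GeneSampleMatrix", function(x)
  S4Vectors::metadata(x)$criterion)

#' @rdname accessors
#' @export
setMethod("novelVsBoth", "CascadeComposition", function(x)
  x@nNovelCosmic - x@nIcgcAmongNovel)

#' @rdname accessors
#' @export
setMethod("compositionCounts", "CascadeComposition", function(x) {
  c(n_total = x@nTotal,
    n_absent_cosmic = x@nNovelCosmic,
    n_of_those_in_icgc = x@nIcgcAmongNovel,
    n_novel_vs_both = x@nNovelCosmic - x@nIcgcAmongNovel,
    n_confirmed_somatic = x@nConfirmedSomatic,
    n_pathogenic = x@nPathogenic,
    n_somatic_and_pathogenic = x@nSomaticAndPathogenic,
    n_pathogenic_prior_tissue = x@nPathogenicPriorTissue,
    n_pathogenic_novel_tissue = x@nPathogenic - x@nPathogenicPriorTissue,
    n_germline_band = x@nGermlineBand,
    n_germline_maf_support = x@nGermlineMafSupport,
    n_ensembl_common = x@nEnsemblCommon,
    n_sift_deleterious = x@nSiftDeleterious,
    n_sift_tolerated = x@nSiftTolerated,
    n_polyphen_probably = x@nPolyphenProbably,
    n_polyphen_possibly = x@nPolyphenPossibly,
    n_polyphen_benign = x@nPolyphenBenign,
    setNames(x@consequenceCounts,
             paste0("n_consequence_", names(x@consequenceCounts))))
})
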