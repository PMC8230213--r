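# The filtration/classification cascade.
#
# Quality gates are strict inequalities ("more than 300X", "more than 50"),
# with the site-level QUAL taken as the read-quality field. Common-variant
# exclusion removes Ensembl-known variants unless rescued by COSMIC
# confirmed-somatic or pathogenic status. Per-variant flags are cohort-level:
# a variant is one row keyed by (chrom,pos,ref,alt), with carrier VAFs
# aggregated across samples.

#' Quality-gate variant calls
#'
#' Keeps exactly the calls with coverage strictly above `minCoverage` and
#' site QUAL strictly above `minQuality`. Calls with missing depth or QUAL
#' fail the gate. Idempotent; never errors on content.
#'
#' @param calls calls data.frame (see [readVcfCalls()])
#' @param config a [FilterConfig-class]
#' @return the surviving subset of `calls`
#' @examples
#' cfg <- FilterConfig()
#' df <- data.frame(sample_id = "S1", chrom = "chr1", pos = 1:2,
#'   ref = "A", alt = "G", qual = c(51, 50.1), depth = c(300L, 301L),
#'   alt_depth = c(30L, 40L), vaf_percent = c(10, 13.3))
#' nrow(qualityFilter(df, cfg))  # 1: depth 300 fails "more than 300X"
#' @export
qualityFilter <- function(calls, config = FilterConfig()) {
  stopifnot(is(config, "FilterConfig"))
  keep <- !is.na(calls$depth) & !is.na(calls$qual) &
    calls$depth > config@minCoverage & calls$qual > config@minQuality
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify variants through the filtration cascade
#'
#' Resolves every cascade flag for each distinct variant carried by the
#' cohort: COSMIC/ICGC novelty, common-variant exclusion,
#' somatic/pathogenic status, target-tissue specificity, VAF-band germline
#' suspicion with cohort-MAF support, and SIFT/PolyPhen damaging inclusion.
#'
#' Cohort MAF counts each carrier as one minor allele over `2 * nSamples`
#' chromosomes -- a stated convention for tumor-only data, which has no true
#' genotypes.
#'
#' @param calls calls data.frame (normally after [qualityFilter()])
#' @param annotations annotations data.frame; every call must have a row
#' @param config a [FilterConfig-class]
#' @param nSamples cohort size for the MAF denominator; defaults to the
#'   number of distinct samples in `calls`
#' @return data.frame, one row per variant key, with the cascade flags,
#'   gene, consequence and carrier count
#' @export
classifyVariants <- function(calls, annotations, config = FilterConfig(),
                             nSamples = NULL) {
  stopifnot(is(config, "FilterConfig"))
  if (is.null(nSamples)) nSamples <- length(unique(calls$sample_id))
  callKey <- variantKey(calls)
  annKey <- variantKey(annotations)
  orphan <- setdiff(unique(callKey), annKey)
  if (length(orphan))
    stop(sprintf("calls without an annotation row: %s",
                 paste(orphan, collapse = ", ")), call. = FALSE)

  keys <- intersect(annKey, unique(callKey))   # variants actually carried
  ann <- annotations[match(keys, annKey), , drop = FALSE]

  grp <- split(seq_along(callKey), callKey)[keys]
  nCarriers <- vapply(grp, function(i)
    length(unique(calls$sample_id[i])), integer(1))
  bands <- config@germlineBands
  vafInBand <- vapply(grp, function(i) {
    v <- calls$vaf_percent[i]
    any(.inBand(v[!is.na(v)], bands))
  }, logical(1))

  tissueList <- strsplit(ann$cosmic_tissues, ",", fixed = TRUE)
  hasTarget <- vapply(tissueList, function(tt)
    config@targetTissue %in% trimws(tt), logical(1))

  passedQuality <- vapply(grp, function(i) {
    d <- calls$depth[i]; q <- calls$qual[i]
    any(!is.na(d) & !is.na(q) & d > config@minCoverage &
          q > config@minQuality)
  }, logical(1))

  rescued <- ann$cosmic_confirmed_somatic | ann$cosmic_pathogenic
  excludedCommon <- ann$ensembl_known & !rescued
  if (!is.na(config@popAfThreshold))
    excludedCommon <- excludedCommon |
      (!is.na(ann$population_af) &
         ann$population_af > config@popAfThreshold & !rescued)

  novelCosmic <- !ann$in_cosmic
  novelBoth <- novelCosmic & !ann$in_icgc
  pathogenic <- ann$cosmic_pathogenic
  tissueSpecific <- pathogenic & hasTarget
  novelInTissue <- pathogenic & !hasTarget
  germVaf <- vafInBand
  cohortMaf <- nCarriers / (2 * max(nSamples, 1L))
  germMaf <- germVaf & cohortMaf > config@germlineMafThreshold
  damaging <- ann$sift == "deleterious" |
    ann$polyphen %in% c("probably_damaging", "possibly_damaging")

  out <- data.frame(
    variant_key = keys,
    chrom = ann$chrom, pos = ann$pos, ref = ann$ref, alt = ann$alt,
    gene = ann$gene,
    consequence = ann$consequence,
    passed_quality = passedQuality,
    excluded_common = excludedCommon,
    novel_vs_cosmic = novelCosmic,
    in_icgc = ann$in_icgc,
    novel_vs_both = novelBoth,
    confirmed_somatic = ann$cosmic_confirmed_somatic,
    pathogenic = pathogenic,
    tissue_specific_pathogenic = tissueSpecific,
    novel_in_target_tissue = novelInTissue,
    germline_suspect_vaf = germVaf,
    germline_suspect_maf_support = germMaf,
    damaging_included = damaging,
    sift = ann$sift,
    polyphen = ann$polyphen,
    n_carriers = nCarriers,
    cohort_maf = cohortMaf,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Tally the cascade nodes of a classified variant set
#'
#' Counts every node of the cascade (total, COSMIC novelty, ICGC overlap,
#' novel-against-both, confirmed somatic, pathogenic and their intersection,
#' tissue specificity, germline suspicion, common-variant exclusion) plus
#' the consequence and SIFT/PolyPhen category tallies among the
#' confirmed-somatic subset.
#'
#' @param classified data.frame from [classifyVariants()]
#' @param postQualityOnly restrict to variants with at least one gate-passing
#'   call (default TRUE); set FALSE to tally the pre-gate set
#' @return a [CascadeComposition-class]
#' @export
cascadeCounts <- function(classified, postQualityOnly = TRUE) {
  cl <- if (postQualityOnly && nrow(classified))
    classified[classified$passed_quality, , drop = FALSE] else classified
  som <- cl$confirmed_somatic
  mis <- som & cl$consequence %in% "missense"
  consRaw <- cl$consequence[som]
  consRaw[is.na(consRaw)] <- "other"
  cons <- setNames(integer(length(.CONSEQUENCES)), .CONSEQUENCES)
  tb <- table(factor(consRaw, levels = .CONSEQUENCES))
  cons[names(tb)] <- as.integer(tb)
  CascadeComposition(
    nTotal = nrow(cl),
    nNovelCosmic = sum(cl$novel_vs_cosmic),
    nIcgcAmongNovel = sum(cl$novel_vs_cosmic & cl$in_icgc),
    nConfirmedSomatic = sum(som),
    nPathogenic = sum(cl$pathogenic),
    nSomaticAndPathogenic = sum(som & cl$pathogenic),
    nPathogenicPriorTissue = sum(cl$tissue_specific_pathogenic),
    nGermlineBand = sum(cl$germline_suspect_vaf),
    nGermlineMafSupport = sum(cl$germline_suspect_maf_support),
    nEnsemblCommon = sum(cl$excluded_common),
    nSiftDeleterious = sum(mis & cl$sift %in% "deleterious"),
    nSiftTolerated = sum(mis & cl$sift %in% "tolerated"),
    nPolyphenProbably = sum(mis & cl$polyphen %in% "probably_damaging"),
    nPolyphenPossibly = sum(mis & cl$polyphen %in% "possibly_damaging"),
    nPolyphenBenign = sum(mis & cl$polyphen %in% "benign"),
    consequenceCounts = cons)
}
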