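# Gene x sample incidence matrices and cohort descriptives.

.criterionKeys <- function(classified, criterion) {
  sel <- switch(criterion,
    any = rep(TRUE, nrow(classified)),
    somatic = classified$confirmed_somatic,
    pathogenic = classified$pathogenic,
    tissue_specific_pathogenic = classified$tissue_specific_pathogenic,
    stop(sprintf("unknown criterion '%s'", criterion), call. = FALSE))
  classified$variant_key[sel]
}

#' Build a binary gene-by-sample incidence matrix
#'
#' `cell[g, s] = 1` iff sample `s` carries at least one variant in gene `g`
#' satisfying the criterion. Duplicated identical call records do not change
#' the matrix (set semantics).
#'
#' @param classified data.frame from [classifyVariants()]
#' @param calls the calls data.frame the classification was built from
#' @param criterion one of `"any"`, `"somatic"`, `"pathogenic"`,
#'   `"tissue_specific_pathogenic"`
#' @param samples sample universe (default: distinct samples in `calls`)
#' @param genes gene universe (default: genes in `classified`)
#' @return a [GeneSampleMatrix-class]
#' @export
geneSampleMatrix <- function(classified, calls,
                             criterion = c("any", "somatic", "pathogenic",
                                           "tissue_specific_pathogenic"),
                             samples = NULL, genes = NULL) {
  if (length(criterion) != 1L || !criterion %in% .CRITERIA)
    stop(sprintf("unknown criterion '%s'",
                 paste(criterion, collapse = ",")), call. = FALSE)
  keys <- .criterionKeys(classified, criterion)
  if (is.null(samples)) samples <- sort(unique(calls$sample_id))
  if (is.null(genes)) genes <- sort(unique(classified$gene))
  mat <- matrix(0L, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  if (length(keys) && nrow(calls)) {
    ck <- variantKey(calls)
    hit <- calls[ck %in% keys, , drop = FALSE]
    if (nrow(hit)) {
      hk <- variantKey(hit)
      gene <- classified$gene[match(hk, classified$variant_key)]
      pairs <- unique(data.frame(gene = gene, sample = hit$sample_id,
                                 stringsAsFactors = FALSE))
      pairs <- pairs[pairs$gene %in% genes & pairs$sample %in% samples, ,
                     drop = FALSE]
      mat[cbind(pairs$gene, pairs$sample)] <- 1L
    }
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(incidence = mat),
    metadata = list(criterion = criterion))
  new("GeneSampleMatrix", se)
}

#' Per-gene variant and sample-frequency summary
#'
#' One row per gene: variant counts (total, novel against COSMIC, somatic,
#' pathogenic, tissue-specific pathogenic), functional categories (PolyPhen
#' damaging, SIFT deleterious, non-synonymous), and the fraction of samples
#' carrying at least one pathogenic (all-tissue), tissue-specific
#' pathogenic, or somatic variant in the gene. Rows are ordered by the
#' all-tissue pathogenic sample fraction (descending), ties broken by the
#' somatic fraction then alphabetically.
#'
#' @param classified data.frame from [classifyVariants()]
#' @param calls the underlying calls
#' @param samples sample universe (default: distinct samples in `calls`)
#' @param top optionally keep only the first `top` rows
#' @return ordered data.frame of gene summary rows
#' @export
geneSummary <- function(classified, calls, samples = NULL, top = NULL) {
  if (is.null(samples)) samples <- sort(unique(calls$sample_id))
  nS <- length(samples)
  genes <- sort(unique(classified$gene))
  sp <- split(seq_len(nrow(classified)), classified$gene)[genes]

  mPath <- incidence(geneSampleMatrix(classified, calls, "pathogenic",
                                      samples = samples, genes = genes))
  mTis <- incidence(geneSampleMatrix(classified, calls,
                                     "tissue_specific_pathogenic",
                                     samples = samples, genes = genes))
  mSom <- incidence(geneSampleMatrix(classified, calls, "somatic",
                                     samples = samples, genes = genes))
  cnt <- function(i, flag) sum(flag[i])
  out <- data.frame(
    gene = genes,
    total_variants = vapply(sp, length, integer(1)),
    novel_variants = vapply(sp, cnt, numeric(1),
                            flag = classified$novel_vs_cosmic),
    somatic_variants = vapply(sp, cnt, numeric(1),
                              flag = classified$confirmed_somatic),
    pathogenic_variants = vapply(sp, cnt, numeric(1),
                                 flag = classified$pathogenic),
    tissue_specific_variants = vapply(sp, cnt, numeric(1),
      flag = classified$tissue_specific_pathogenic),
    polyphen_damaging = vapply(sp, cnt, numeric(1),
      flag = classified$polyphen %in% c("probably_damaging",
                                        "possibly_damaging")),
    sift_deleterious = vapply(sp, cnt, numeric(1),
      flag = classified$sift %in% "deleterious"),
    non_synonymous = vapply(sp, cnt, numeric(1),
      flag = !classified$consequence %in% "synonymous"),
    pct_samples_pathogenic = if (nS) rowSums(mPath) / nS else 0,
    pct_samples_tissue_specific = if (nS) rowSums(mTis) / nS else 0,
    pct_samples_somatic = if (nS) rowSums(mSom) / nS else 0,
    stringsAsFactors = FALSE)
  ord <- order(-out$pct_samples_pathogenic, -out$pct_samples_somatic,
               out$gene)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top)) out <- out[seq_len(min(top, nrow(out))), , drop = FALSE]
  out
}

#' Select recurrently mutated genes
#'
#' Genes whose incidence row sum reaches `minPatients` -- e.g. genes with at
#' least one tissue-specific confirmed pathogenic variant in at least three
#' patients.
#'
#' @param gsm a [GeneSampleMatrix-class]
#' @param minPatients minimum number of carrying patients (default 3)
#' @return character vector of gene symbols
#' @export
selectRecurrentGenes <- function(gsm, minPatients = 3L) {
  rs <- rowSums(incidence(gsm))
  names(rs)[rs >= minPatients]
}

.strata <- function(patients, axis) {
  switch(axis,
    gender = factor(patients$gender, levels = c("male", "female")),
    age_group = factor(ifelse(patients$age_years < 50, "young", "old"),
                       levels = c("young", "old")),
    stage_group = factor(
      ifelse(patients$overall_stage %in% c("I", "II"), "early", "late"),
      levels = c("early", "late")),
    site = factor(
      ifelse(patients$site == "left_colon", "left",
             ifelse(patients$site == "right_colon", "right", "other")),
      levels = c("left", "right", "other")),
    lymph_node = factor(
      ifelse(patients$n_stage == "N0", "node_negative", "node_positive"),
      levels = c("node_negative", "node_positive")),
    metastasis = factor(patients$m_stage, levels = c("M0", "M1")),
    stop(sprintf("unknown stratification axis '%s'", axis), call. = FALSE))
}

#' Dichotomize a clinicopathological axis
#'
#' Encodes the contrast the association analyses use: female vs male, young
#' (< 50 years) vs old, late (stage III--IV) vs early (I--II), left vs right
#' colon (rectum/other are NA for this contrast), node-positive vs N0, and
#' M1 vs M0. The first-named group is coded 1.
#'
#' @param patients patients data.frame
#' @param axis one of gender, age_group, stage_group, site, lymph_node,
#'   metastasis
#' @return integer 0/1 vector aligned with `patients` rows (NA where the
#'   contrast does not apply)
#' @export
dichotomizeTrait <- function(patients, axis) {
  axis <- match.arg(axis, .AXES)
  s <- .strata(patients, axis)
  switch(axis,
    gender = ifelse(s == "female", 1L, 0L),
    age_group = ifelse(s == "young", 1L, 0L),
    stage_group = ifelse(s == "late", 1L, 0L),
    site = ifelse(s == "left", 1L, ifelse(s == "right", 0L, NA_integer_)),
    lymph_node = ifelse(s == "node_positive", 1L, 0L),
    metastasis = ifelse(s == "M1", 1L, 0L))
}

#' Stratify gene incidence by a clinicopathological axis
#'
#' Per-gene counts of carrying samples in each stratum. Strata partition the
#' samples, so stratum counts sum to the unstratified row sums. Boundaries:
#' age 49.9 is young, 50.0 is old; stage II is early, III late.
#'
#' @param gsm a [GeneSampleMatrix-class]
#' @param patients patients data.frame covering every matrix sample
#' @param axis stratification axis (see [dichotomizeTrait()])
#' @return data.frame: gene, one count column per stratum, and `total`
#' @export
stratifyMatrix <- function(gsm, patients, axis) {
  axis <- match.arg(axis, .AXES)
  mat <- incidence(gsm)
  missing <- setdiff(colnames(mat), patients$patient_id)
  if (length(missing))
    stop(sprintf("samples without a patient record: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  p <- patients[match(colnames(mat), patients$patient_id), , drop = FALSE]
  s <- .strata(p, axis)
  out <- data.frame(gene = rownames(mat), stringsAsFactors = FALSE)
  for (lev in levels(s))
    out[[lev]] <- as.integer(rowSums(mat[, which(s == lev), drop = FALSE]))
  out$total <- as.integer(rowSums(mat))
  out
}

#' Cohort clinicopathological summary
#'
#' Counts and integer percentages per category for each clinicopathological
#' field, each with its own non-missing denominator (printed alongside, since
#' field denominators can legitimately differ), plus median/SD rows for age.
#' A field with no non-missing values is reported as a note row.
#'
#' @param patients patients data.frame
#' @return data.frame: field, category, n, denominator, pct, note
#' @examples
#' p <- data.frame(patient_id = sprintf("P%02d", 1:4), age_years = 60,
#'   gender = c("male", "male", "male", "female"),
#'   t_stage = "T3", n_stage = "N0", m_stage = "M0",
#'   overall_stage = c("I", "II", "III", "IV"),
#'   site = c("left_colon", "left_colon", "right_colon", "rectum"))
#' cohortSummary(p)
#' @export
cohortSummary <- function(patients) {
  if (nrow(patients) == 0L)
    stop("cohortSummary requires a nonempty patient table", call. = FALSE)
  rows <- list()
  addCat <- function(field, values, levels) {
    known <- values[!is.na(values)]
    denom <- length(known)
    if (denom == 0L) {
      rows[[length(rows) + 1L]] <<- data.frame(
        field = field, category = NA_character_, n = NA_integer_,
        denominator = 0L, pct = NA_real_,
        note = "all values missing; field omitted",
        stringsAsFactors = FALSE)
      return(invisible())
    }
    tb <- table(factor(known, levels = levels))
    rows[[length(rows) + 1L]] <<- data.frame(
      field = field, category = names(tb), n = as.integer(tb),
      denominator = denom, pct = round(100 * as.integer(tb) / denom),
      note = NA_character_, stringsAsFactors = FALSE)
  }
  age <- patients$age_years
  ageKnown <- age[!is.na(age)]
  rows[[1L]] <- data.frame(
    field = "age_years",
    category = c("median", "sd"),
    n = c(if (length(ageKnown)) median(ageKnown) else NA_real_,
          if (length(ageKnown) > 1L) sd(ageKnown) else NA_real_),
    denominator = length(ageKnown), pct = NA_real_, note = NA_character_,
    stringsAsFactors = FALSE)
  addCat("gender", patients$gender, c("male", "female"))
  addCat("overall_stage", patients$overall_stage, .STAGES)
  addCat("t_stage", patients$t_stage, paste0("T", 1:4))
  addCat("n_stage", patients$n_stage, paste0("N", 0:2))
  addCat("m_stage", patients$m_stage, paste0("M", 0:1))
  addCat("site", patients$site, .SITES)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
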