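# Synthetic cohort generation.
#
# The generator is count-exact: cascade category sizes in the target
# CascadeComposition are realized exactly by partitioning a shuffled index
# vector, never by independent Bernoulli draws, so downstream cascade
# regression tests are deterministic. Stochastic parts (VAF draws, carrier
# assignment, clinicopathological features) are fully reproducible under the
# config seed.

.emptyPatients <- function() {
  data.frame(patient_id = character(), age_years = numeric(),
             gender = character(), t_stage = character(),
             n_stage = character(), m_stage = character(),
             overall_stage = character(), site = character(),
             stringsAsFactors = FALSE)
}

.emptyCalls <- function() {
  data.frame(sample_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), qual = numeric(),
             depth = integer(), alt_depth = integer(),
             vaf_percent = numeric(), stringsAsFactors = FALSE)
}

.emptyAnnotations <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), gene = character(), exon = character(),
             hgvs_c = character(), hgvs_p = character(),
             consequence = character(), in_cosmic = logical(),
             cosmic_confirmed_somatic = logical(),
             cosmic_pathogenic = logical(), cosmic_tissues = character(),
             in_icgc = logical(), ensembl_known = logical(),
             population_af = numeric(), sift = character(),
             polyphen = character(), stringsAsFactors = FALSE)
}

#' Variant identity key
#'
#' Canonical `(chrom, pos, ref, alt)` join key used to match calls to
#' annotations after multi-allelic splitting.
#'
#' @param x data.frame with chrom/pos/ref/alt columns
#' @return character vector of keys
#' @export
variantKey <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

.withSeed <- function(seed, expr) {
  # run expr under a private RNG state, restoring the caller's stream
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.samplePatients <- function(n, cp) {
  pick <- function(w, k) sample(names(w), k, replace = TRUE, prob = w / sum(w))
  age <- round(pmin(pmax(rnorm(n, cp$ageMean, cp$ageSD), 25), 92))
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age_years = age,
    gender = pick(cp$gender, n),
    t_stage = pick(cp$tStage, n),
    n_stage = pick(cp$nStage, n),
    m_stage = pick(cp$mStage, n),
    overall_stage = pick(cp$stage, n),
    site = pick(cp$site, n),
    stringsAsFactors = FALSE)
}

.inBand <- function(v, bands) {
  hit <- rep(FALSE, length(v))
  for (i in seq_len(nrow(bands)))
    hit <- hit | (v >= bands[i, 1] & v <= bands[i, 2])
  hit
}

.drawSomaticVaf <- function(n, config) {
  # rejection-sample outside the germline bands (with a 0.2pp safety margin
  # absorbing alt-depth rounding) so band membership stays count-exact
  bands <- config@germlineBands
  bandsPad <- cbind(pmax(bands[, 1] - 0.2, 0), pmin(bands[, 2] + 0.2, 100))
  v <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- config@vafMin + (config@vafMax - config@vafMin) *
      rbeta(length(todo), config@vafShape1, config@vafShape2)
    ok <- !.inBand(draw, bandsPad)
    v[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  v
}

.drawBandVaf <- function(n, bands) {
  # 0.2pp inner margin keeps rounded VAFs inside the closed band
  i <- sample.int(nrow(bands), n, replace = TRUE,
                  prob = rev(seq_len(nrow(bands))))  # lower band favored
  lo <- bands[i, 1] + 0.2
  hi <- bands[i, 2] - ifelse(bands[i, 2] >= 100, 0, 0.2)
  runif(n, lo, pmin(hi, 100))
}

.takeIdx <- function(pool, k, what) {
  if (k > length(pool))
    stop(sprintf("composition inconsistency: %s needs %d variants but only %d remain",
                 what, k, length(pool)), call. = FALSE)
  pool[seq_len(k)]
}

#' Generate a synthetic tumor-only panel cohort
#'
#' Draws a patient table, per-sample variant calls and a per-variant
#' annotation table whose cascade category tallies exactly equal the target
#' [CascadeComposition-class]. Germline-band variants are preferentially
#' drawn from the COSMIC-absent ("novel") set, mirroring the tumor-only
#' germline screen being applied to novel variants; MAF-supported ones
#' receive enough carriers to push the cohort minor-allele frequency above
#' 1\%, the rest exactly one carrier.
#'
#' @param config a [CohortConfig-class]
#' @return a [VariantCohort-class]; `nPatients = 0` yields empty tables with
#'   valid headers
#' @examples
#' cfg <- CohortConfig(nPatients = 20,
#'   composition = CascadeComposition(nTotal = 100, nNovelCosmic = 20,
#'     nIcgcAmongNovel = 2, nConfirmedSomatic = 40, nPathogenic = 25,
#'     nSomaticAndPathogenic = 25, nPathogenicPriorTissue = 10,
#'     nGermlineBand = 5, nGermlineMafSupport = 5,
#'     nSiftDeleterious = 10, nSiftTolerated = 8, nPolyphenProbably = 5,
#'     nPolyphenPossibly = 3, nPolyphenBenign = 10,
#'     consequenceCounts = c(synonymous = 15, missense = 20,
#'       stop_gained = 2, frameshift = 2, splice = 1, other = 0)))
#' coh <- generateCohort(cfg)
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  comp <- config@composition
  validObject(comp)
  if (config@nPatients == 0L)
    return(new("VariantCohort", patients = .emptyPatients(),
               calls = .emptyCalls(), annotations = .emptyAnnotations(),
               config = config))

  .withSeed(config@seed, {
    pts <- .samplePatients(config@nPatients, config@clinicopath)

    nT <- comp@nTotal
    genes <- sample(config@panelGenes, nT, replace = TRUE)
    gi <- match(genes, config@panelGenes)
    chrom <- sprintf("chr%d", ((gi - 1L) %% 22L) + 1L)
    # unique loci: per-gene megabase blocks with a within-gene counter
    cnt <- stats::ave(seq_len(nT), gi, FUN = seq_along)
    pos <- gi * 1000000L + cnt * 7L + 11L
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nT, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

    # --- count-exact flag realization over a shuffled index vector -------
    idx <- sample.int(nT)
    novelIdx <- .takeIdx(idx, comp@nNovelCosmic, "nNovelCosmic")
    cosmicIdx <- setdiff(idx, novelIdx)
    icgcIdx <- .takeIdx(novelIdx, comp@nIcgcAmongNovel, "nIcgcAmongNovel")
    somaticIdx <- .takeIdx(cosmicIdx, comp@nConfirmedSomatic,
                           "nConfirmedSomatic")
    pathOverlap <- .takeIdx(somaticIdx, comp@nSomaticAndPathogenic,
                            "nSomaticAndPathogenic")
    pathOnlyPool <- setdiff(cosmicIdx, somaticIdx)
    pathOnly <- .takeIdx(pathOnlyPool,
                         comp@nPathogenic - comp@nSomaticAndPathogenic,
                         "nPathogenic beyond the somatic overlap")
    pathIdx <- c(pathOverlap, pathOnly)
    priorIdx <- .takeIdx(sample(pathIdx), comp@nPathogenicPriorTissue,
                         "nPathogenicPriorTissue")
    commonPool <- setdiff(cosmicIdx, union(somaticIdx, pathIdx))
    commonIdx <- .takeIdx(sample(commonPool), comp@nEnsemblCommon,
                          "nEnsemblCommon")

    inCosmic <- seq_len(nT) %in% cosmicIdx
    somatic <- seq_len(nT) %in% somaticIdx
    pathogenic <- seq_len(nT) %in% pathIdx
    prior <- seq_len(nT) %in% priorIdx
    icgc <- seq_len(nT) %in% icgcIdx
    ensembl <- seq_len(nT) %in% commonIdx

    # tissues: pathogenic with a prior target-tissue report include it;
    # other COSMIC variants get non-target tissues
    otherTissues <- c("lung", "breast", "liver", "skin", "stomach")
    tissues <- character(nT)
    for (i in which(inCosmic)) {
      tt <- sample(otherTissues, sample.int(2L, 1L))
      if (prior[i]) tt <- c("large_intestine", tt[seq_len(length(tt) - 1L)])
      tissues[i] <- paste(unique(tt), collapse = ",")
    }

    # consequences: exact counts on the confirmed-somatic subset (the set
    # the published category figures classify); others from a fixed mixture
    consequence <- character(nT)
    somShuffle <- sample(somaticIdx)
    consequence[somShuffle] <- rep(names(comp@consequenceCounts),
                                   comp@consequenceCounts)
    nonSom <- setdiff(seq_len(nT), somaticIdx)
    consequence[nonSom] <- sample(.CONSEQUENCES, length(nonSom),
                                  replace = TRUE,
                                  prob = c(.42, .42, .04, .05, .03, .04))

    sift <- rep("missing", nT)
    polyphen <- rep("missing", nT)
    somMis <- sample(intersect(somaticIdx, which(consequence == "missense")))
    sift[.takeIdx(somMis, comp@nSiftDeleterious,
                  "nSiftDeleterious")] <- "deleterious"
    remaining <- somMis[sift[somMis] == "missing"]
    sift[.takeIdx(remaining, comp@nSiftTolerated,
                  "nSiftTolerated")] <- "tolerated"
    ppAssign <- rep(c("probably_damaging", "possibly_damaging", "benign"),
                    c(comp@nPolyphenProbably, comp@nPolyphenPossibly,
                      comp@nPolyphenBenign))
    polyphen[somMis[seq_along(ppAssign)]] <- ppAssign

    # germline-band designation: from the novel set first (the germline
    # screen is applied to novel variants), overflowing if it must
    glPool <- c(sample(novelIdx), sample(setdiff(seq_len(nT), novelIdx)))
    glIdx <- .takeIdx(glPool, comp@nGermlineBand, "nGermlineBand")
    glMafIdx <- .takeIdx(glIdx, comp@nGermlineMafSupport,
                         "nGermlineMafSupport")
    isGl <- seq_len(nT) %in% glIdx
    isGlMaf <- seq_len(nT) %in% glMafIdx

    popAf <- rep(NA_real_, nT)
    popAf[ensembl] <- runif(sum(ensembl), 0.011, 0.3)
    rare <- sample(which(!ensembl), floor(0.3 * sum(!ensembl)))
    popAf[rare] <- runif(length(rare), 0, 0.005)

    ann <- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt, gene = genes,
      exon = NA_character_, hgvs_c = NA_character_, hgvs_p = NA_character_,
      consequence = consequence, in_cosmic = inCosmic,
      cosmic_confirmed_somatic = somatic, cosmic_pathogenic = pathogenic,
      cosmic_tissues = tissues, in_icgc = icgc, ensembl_known = ensembl,
      population_af = popAf, sift = sift, polyphen = polyphen,
      stringsAsFactors = FALSE)

    # --- carriers -------------------------------------------------------
    nP <- config@nPatients
    twoN <- 2L * nP
    mafCarrierMin <- floor(0.01 * twoN) + 1L  # strictly exceeds 1% MAF
    if (comp@nGermlineBand > comp@nGermlineMafSupport &&
        floor(0.01 * twoN) < 1L)
      stop("cohort too small to realize germline-band variants without MAF support",
           call. = FALSE)
    lambda <- max(nP * config@variantsPerPatient / max(nT, 1L) - 1, 0.05)
    nCar <- pmin(1L + rpois(nT, lambda), nP)
    nCar[isGlMaf] <- pmin(mafCarrierMin + rpois(sum(isGlMaf), 1), nP)
    nCar[isGl & !isGlMaf] <- max(1L, floor(0.01 * twoN))

    carrier <- lapply(nCar, function(k) sample.int(nP, k))
    vidx <- rep(seq_len(nT), nCar)
    sidx <- unlist(carrier)
    nCalls <- length(vidx)

    depth <- sample(301:1500, nCalls, replace = TRUE)
    qual <- round(runif(nCalls, 50.5, 150), 1)
    vaf <- numeric(nCalls)
    glCall <- isGl[vidx]
    vaf[!glCall] <- .drawSomaticVaf(sum(!glCall), config)
    vaf[glCall] <- .drawBandVaf(sum(glCall), config@germlineBands)
    altDepth <- pmax(1L, as.integer(round(vaf / 100 * depth)))
    altDepth <- pmin(altDepth, depth)
    # clamp band calls so the rounded VAF stays inside the closed band
    if (any(glCall)) {
      bands <- config@germlineBands
      for (j in which(glCall)) {
        b <- bands[which(.inBand(vaf[j], bands))[1L], ]
        lo <- as.integer(ceiling(b[1] * depth[j] / 100))
        hi <- as.integer(floor(b[2] * depth[j] / 100))
        altDepth[j] <- min(max(altDepth[j], lo), hi)
      }
    }
    vafOut <- round(100 * altDepth / depth, 4)

    calls <- data.frame(
      sample_id = pts$patient_id[sidx],
      chrom = chrom[vidx], pos = pos[vidx], ref = ref[vidx],
      alt = alt[vidx], qual = qual, depth = depth, alt_depth = altDepth,
      vaf_percent = vafOut, stringsAsFactors = FALSE)

    if (config@nFailQuality > 0L) {
      k <- config@nFailQuality
      fi <- sample.int(nT, k, replace = TRUE)
      fs <- sample.int(nP, k, replace = TRUE)
      fdepth <- sample(50:300, k, replace = TRUE)
      falt <- pmax(1L, as.integer(round(runif(k, 10, 40) / 100 * fdepth)))
      fails <- data.frame(
        sample_id = pts$patient_id[fs],
        chrom = chrom[fi], pos = pos[fi], ref = ref[fi], alt = alt[fi],
        qual = round(runif(k, 5, 50), 1), depth = fdepth, alt_depth = falt,
        vaf_percent = round(100 * falt / fdepth, 4),
        stringsAsFactors = FALSE)
      calls <- rbind(calls, fails)
    }
    calls <- calls[order(calls$sample_id, calls$chrom, calls$pos,
                         calls$alt), , drop = FALSE]
    rownames(calls) <- NULL

    new("VariantCohort", patients = pts, calls = calls, annotations = ann,
        config = config)
  })
}

#' Simulate null genotype/trait data for rare-variant test calibration
#'
#' Draws a genotype matrix of independent variants in Hardy-Weinberg
#' proportions and a trait that is independent of the genotypes (the global
#' null), for Monte-Carlo calibration of the SKAT-O family.
#'
#' @param nIndividuals number of individuals (at least 10)
#' @param nVariantsPerGene variants in the simulated gene
#' @param mafSpectrum minor-allele-frequency spectrum: a single number (point
#'   mass), a length-2 range (uniform draw), a vector of per-variant MAFs, or
#'   a function of the variant count
#' @param trait `"binary"` (balanced Bernoulli) or `"quantitative"`
#'   (standard normal)
#' @param seed integer seed
#' @return list with elements `genotypes` (individuals x variants matrix of
#'   0/1/2 allele counts), `trait`, and `mafs`
#' @export
generateSkatNull <- function(nIndividuals, nVariantsPerGene,
                             mafSpectrum = c(0.01, 0.4),
                             trait = c("binary", "quantitative"),
                             seed = 1L) {
  trait <- match.arg(trait)
  if (nIndividuals < 10L)
    stop("nIndividuals must be at least 10", call. = FALSE)
  .withSeed(seed, {
    m <- as.integer(nVariantsPerGene)
    mafs <- if (is.function(mafSpectrum)) {
      mafSpectrum(m)
    } else if (length(mafSpectrum) == 1L) {
      rep(mafSpectrum, m)
    } else if (length(mafSpectrum) == 2L) {
      runif(m, mafSpectrum[1], mafSpectrum[2])
    } else {
      rep_len(mafSpectrum, m)
    }
    if (all(mafs <= 0))
      stop("degenerate mafSpectrum: all minor-allele frequencies are zero",
           call. = FALSE)
    G <- vapply(mafs, function(p) rbinom(nIndividuals, 2L, p),
                integer(nIndividuals))
    y <- if (trait == "binary") rbinom(nIndividuals, 1L, 0.5)
         else rnorm(nIndividuals)
    list(genotypes = G, trait = y, mafs = mafs)
  })
}

#' Inject a gene-trait association into a synthetic cohort
#'
#' Resamples which patients carry a pathogenic variant in one gene so that
#' the population log-odds of carriage against a dichotomized
#' clinicopathological trait equals `log(oddsRatio)`, while preserving the
#' overall carriage prevalence. Used for power and recovery testing of the
#' downstream association stages.
#'
#' @param cohort a [VariantCohort-class]
#' @param gene panel gene symbol receiving the association
#' @param trait stratification axis (see [stratifyMatrix()]):
#'   one of gender, age_group, stage_group, site, lymph_node, metastasis
#' @param oddsRatio positive odds ratio; 1 preserves the null
#' @param seed integer seed
#' @return the modified [VariantCohort-class]
#' @export
injectGeneAssociation <- function(cohort, gene, trait, oddsRatio, seed = 1L) {
  stopifnot(is(cohort, "VariantCohort"))
  if (!is.numeric(oddsRatio) || oddsRatio <= 0)
    stop("oddsRatio must be a positive real", call. = FALSE)
  ann <- cohort@annotations
  panel <- if (is(cohort@config, "CohortConfig"))
    cohort@config@panelGenes else unique(ann$gene)
  if (!gene %in% panel && !gene %in% ann$gene)
    stop(sprintf("gene '%s' is not in the cohort panel", gene),
         call. = FALSE)
  z <- dichotomizeTrait(cohort@patients, trait)
  ok <- !is.na(z)
  if (length(unique(z[ok])) < 2L)
    stop(sprintf("trait '%s' is constant in this cohort and cannot carry an association",
                 trait), call. = FALSE)

  .withSeed(seed, {
    pathRows <- which(ann$gene == gene & ann$cosmic_pathogenic)
    if (!length(pathRows)) {
      # create one pathogenic target-tissue variant to carry the signal
      src <- which(ann$gene == gene)
      tmpl <- ann[if (length(src)) src[1L] else 1L, , drop = FALSE]
      tmpl$gene <- gene
      tmpl$pos <- max(ann$pos) + 1L
      tmpl$ref <- "A"; tmpl$alt <- "G"
      tmpl$in_cosmic <- TRUE
      tmpl$cosmic_confirmed_somatic <- TRUE
      tmpl$cosmic_pathogenic <- TRUE
      tmpl$cosmic_tissues <- "large_intestine"
      tmpl$in_icgc <- FALSE; tmpl$ensembl_known <- FALSE
      tmpl$consequence <- "missense"
      ann <- rbind(ann, tmpl)
      pathRows <- nrow(ann)
    }
    pathKeys <- variantKey(ann[pathRows, , drop = FALSE])
    carrierVar <- ann[pathRows[1L], , drop = FALSE]

    calls <- cohort@calls
    isGeneCall <- variantKey(calls) %in% pathKeys
    present <- cohort@patients$patient_id %in%
      unique(calls$sample_id[isGeneCall])
    pbar <- mean(present[ok])
    if (pbar <= 0 || pbar >= 1) pbar <- 0.3  # degenerate baseline: reset

    n1 <- sum(z[ok] == 1); n0 <- sum(z[ok] == 0)
    f <- function(p0) {
      p1 <- oddsRatio * p0 / (1 - p0 + oddsRatio * p0)
      (n1 * p1 + n0 * p0) / (n1 + n0) - pbar
    }
    p0 <- stats::uniroot(f, c(1e-9, 1 - 1e-9))$root
    p1 <- oddsRatio * p0 / (1 - p0 + oddsRatio * p0)

    prob <- ifelse(is.na(z), pbar, ifelse(z == 1, p1, p0))
    carry <- rbinom(length(prob), 1L, prob) == 1L

    # drop existing calls to this gene's pathogenic variants, re-add for the
    # resampled carriers
    calls <- calls[!isGeneCall, , drop = FALSE]
    carriers <- cohort@patients$patient_id[carry]
    if (length(carriers)) {
      depth <- sample(301:1500, length(carriers), replace = TRUE)
      vaf <- .drawSomaticVaf(length(carriers),
               if (is(cohort@config, "CohortConfig")) cohort@config
               else CohortConfig(nPatients = nrow(cohort@patients)))
      altDepth <- pmax(1L, as.integer(round(vaf / 100 * depth)))
      add <- data.frame(
        sample_id = carriers,
        chrom = carrierVar$chrom, pos = carrierVar$pos,
        ref = carrierVar$ref, alt = carrierVar$alt,
        qual = round(runif(length(carriers), 50.5, 150), 1),
        depth = depth, alt_depth = altDepth,
        vaf_percent = round(100 * altDepth / depth, 4),
        stringsAsFactors = FALSE)
      calls <- rbind(calls, add)
    }
    calls <- calls[order(calls$sample_id, calls$chrom, calls$pos,
                         calls$alt), , drop = FALSE]
    rownames(calls) <- NULL
    new("VariantCohort", patients = cohort@patients, calls = calls,
        annotations = ann, config = cohort@config)
  })
}
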