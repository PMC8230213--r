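mkCalls <- function(depth, qual) {
  n <- length(depth)
  data.frame(sample_id = "S1", chrom = "chr1", pos = seq_len(n),
             ref = "A", alt = "G", qual = qual, depth = depth,
             alt_depth = pmax(1L, depth %/% 4L),
             vaf_percent = 25, stringsAsFactors = FALSE)
}

test_that("quality gates are strict inequalities", {
  cfg <- FilterConfig()
  calls <- mkCalls(depth = c(300L, 301L, 301L, NA),
                   qual = c(51, 50, 50.1, 80))
  kept <- qualityFilter(calls, cfg)
  expect_equal(kept$pos, 3L)   # only depth 301 & qual 50.1 passes
})

test_that("quality filtering is idempotent on random call sets", {
  set.seed(42)
  for (i in 1:5) {
    calls <- mkCalls(depth = sample(250:350, 60, TRUE),
                     qual = runif(60, 30, 70))
    once <- qualityFilter(calls)
    twice <- qualityFilter(once)
    expect_identical(once, twice)
  }
})

mkAnn <- function(n, ...) {
  base <- data.frame(
    chrom = "chr1", pos = seq_len(n), ref = "A", alt = "G",
    gene = "G001", exon = NA_character_, hgvs_c = NA_character_,
    hgvs_p = NA_character_, consequence = "missense",
    in_cosmic = TRUE, cosmic_confirmed_somatic = FALSE,
    cosmic_pathogenic = FALSE, cosmic_tissues = "lung",
    in_icgc = FALSE, ensembl_known = FALSE, population_af = NA_real_,
    sift = "missing", polyphen = "missing", stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

oneCall <- function(pos, vaf = 30, sample = "S1") {
  data.frame(sample_id = sample, chrom = "chr1", pos = pos, ref = "A",
             alt = "G", qual = 80, depth = 400L,
             alt_depth = as.integer(round(vaf * 4)), vaf_percent = vaf,
             stringsAsFactors = FALSE)
}

test_that("cascade flags follow their definitions", {
  # pathogenic, reported only in lung -> novel in the target tissue
  ann <- mkAnn(1, cosmic_pathogenic = TRUE)
  cl <- classifyVariants(oneCall(1), ann, nSamples = 10)
  expect_true(cl$novel_in_target_tissue)
  expect_false(cl$tissue_specific_pathogenic)

  # prior large-intestine report -> tissue-specific
  ann2 <- mkAnn(1, cosmic_pathogenic = TRUE,
                cosmic_tissues = "large_intestine,lung")
  cl2 <- classifyVariants(oneCall(1), ann2, nSamples = 10)
  expect_true(cl2$tissue_specific_pathogenic)
  expect_false(cl2$novel_in_target_tissue)

  # absent from COSMIC but present in ICGC: novel vs COSMIC only
  ann3 <- mkAnn(1, in_cosmic = FALSE, cosmic_tissues = "", in_icgc = TRUE)
  cl3 <- classifyVariants(oneCall(1), ann3, nSamples = 10)
  expect_true(cl3$novel_vs_cosmic)
  expect_false(cl3$novel_vs_both)

  # Ensembl-known is excluded as common unless rescued by COSMIC status
  ann4 <- mkAnn(1, ensembl_known = TRUE)
  expect_true(classifyVariants(oneCall(1), ann4,
                               nSamples = 10)$excluded_common)
  ann5 <- mkAnn(1, ensembl_known = TRUE, cosmic_confirmed_somatic = TRUE)
  expect_false(classifyVariants(oneCall(1), ann5,
                                nSamples = 10)$excluded_common)

  # damaging inclusion from SIFT or PolyPhen
  ann6 <- mkAnn(1, sift = "deleterious")
  expect_true(classifyVariants(oneCall(1), ann6,
                               nSamples = 10)$damaging_included)
  ann7 <- mkAnn(1, polyphen = "possibly_damaging")
  expect_true(classifyVariants(oneCall(1), ann7,
                               nSamples = 10)$damaging_included)
})

test_that("germline VAF bands are closed and MAF support is exclusive", {
  ann <- mkAnn(1)
  expect_true(classifyVariants(oneCall(1, vaf = 50.0), ann,
                               nSamples = 100)$germline_suspect_vaf)
  expect_true(classifyVariants(oneCall(1, vaf = 49.0), ann,
                               nSamples = 100)$germline_suspect_vaf)
  expect_false(classifyVariants(oneCall(1, vaf = 48.9), ann,
                                nSamples = 100)$germline_suspect_vaf)
  # single carrier in 100 samples: MAF = 0.005, not > 1%
  one <- classifyVariants(oneCall(1, vaf = 50), ann, nSamples = 100)
  expect_false(one$germline_suspect_maf_support)
  # three carriers of 100: MAF = 0.015 > 1%
  calls3 <- rbind(oneCall(1, 50, "S1"), oneCall(1, 50.5, "S2"),
                  oneCall(1, 49.5, "S3"))
  three <- classifyVariants(calls3, ann, nSamples = 100)
  expect_true(three$germline_suspect_maf_support)
  expect_equal(three$n_carriers, 3L)
})

test_that("calls without annotations raise an error listing orphan keys", {
  ann <- mkAnn(1)
  calls <- rbind(oneCall(1), oneCall(2))
  expect_error(classifyVariants(calls, ann, nSamples = 5), "chr1:2:A:G",
               fixed = TRUE)
})

test_that("cascade counts equal brute-force per-flag tallies", {
  coh <- smallCohort(seed = 19L)
  cl <- classifySmall(coh)
  cc <- cascadeCounts(cl)
  expect_equal(cc@nTotal, nrow(cl))
  expect_equal(cc@nNovelCosmic, sum(cl$novel_vs_cosmic))
  expect_equal(novelVsBoth(cc), sum(cl$novel_vs_cosmic & !cl$in_icgc))
  expect_equal(cc@nPathogenic, sum(cl$pathogenic))
  expect_equal(cc@nPathogenic - cc@nPathogenicPriorTissue,
               sum(cl$novel_in_target_tissue))
  # conservation: novel vs both = novel vs COSMIC - ICGC overlap
  expect_equal(novelVsBoth(cc),
               cc@nNovelCosmic - cc@nIcgcAmongNovel)
  # nesting: tissue-specific <= pathogenic <= somatic-or-pathogenic <= total
  somOrPath <- cc@nConfirmedSomatic + cc@nPathogenic -
    cc@nSomaticAndPathogenic
  expect_lte(cc@nPathogenicPriorTissue, cc@nPathogenic)
  expect_lte(cc@nPathogenic, somOrPath)
  expect_lte(somOrPath, cc@nTotal)
})

test_that("classification is invariant to record order", {
  coh <- smallCohort(seed = 23L)
  calls <- qualityFilter(variantCalls(coh))
  cl1 <- classifyVariants(calls, annotations(coh), nSamples = 30)
  set.seed(2)
  cl2 <- classifyVariants(calls[sample(nrow(calls)), ],
                          annotations(coh)[sample(nrow(annotations(coh))), ],
                          nSamples = 30)
  cl2 <- cl2[match(cl1$variant_key, cl2$variant_key), ]
  rownames(cl2) <- NULL
  expect_equal(cl1, cl2)
})

test_that("empty classified input tallies to zero", {
  coh <- smallCohort(seed = 2L)
  cl <- classifySmall(coh)[0, ]
  cc <- cascadeCounts(cl)
  expect_equal(cc@nTotal, 0L)
  expect_equal(sum(compositionCounts(cc)), 0L)
})
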