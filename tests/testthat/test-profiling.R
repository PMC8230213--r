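test_that("incidence cells reflect carriage under the criterion", {
  coh <- smallCohort(seed = 31L)
  cl <- classifySmall(coh)
  calls <- qualityFilter(variantCalls(coh))
  for (crit in c("any", "somatic", "pathogenic",
                 "tissue_specific_pathogenic")) {
    gsm <- geneSampleMatrix(cl, calls, crit,
                            samples = patients(coh)$patient_id)
    expect_s4_class(gsm, "GeneSampleMatrix")
    expect_equal(criterion(gsm), crit)
    mat <- incidence(gsm)
    # brute-force recount from raw calls
    sel <- switch(crit, any = rep(TRUE, nrow(cl)),
                  somatic = cl$confirmed_somatic,
                  pathogenic = cl$pathogenic,
                  tissue_specific_pathogenic =
                    cl$tissue_specific_pathogenic)
    keys <- cl$variant_key[sel]
    for (g in sample(rownames(mat), 5)) {
      gk <- intersect(keys, cl$variant_key[cl$gene == g])
      carriers <- unique(calls$sample_id[variantKey(calls) %in% gk])
      expect_equal(sum(mat[g, ]), length(carriers))
    }
  }
  expect_error(geneSampleMatrix(cl, calls, "bogus"), "criterion")
})

test_that("duplicated identical call records do not change the matrix", {
  coh <- smallCohort(seed = 8L)
  cl <- classifySmall(coh)
  calls <- qualityFilter(variantCalls(coh))
  m1 <- incidence(geneSampleMatrix(cl, calls, "pathogenic"))
  m2 <- incidence(geneSampleMatrix(cl, rbind(calls, calls), "pathogenic"))
  expect_identical(m1, m2)
})

test_that("tissue-specific criterion excludes first-time-in-tissue variants", {
  coh <- smallCohort(seed = 15L)
  cl <- classifySmall(coh)
  calls <- qualityFilter(variantCalls(coh))
  gsm <- geneSampleMatrix(cl, calls, "tissue_specific_pathogenic")
  novelKeys <- cl$variant_key[cl$novel_in_target_tissue &
                                !cl$tissue_specific_pathogenic]
  onlyNovelGenes <- setdiff(
    cl$gene[cl$variant_key %in% novelKeys],
    cl$gene[cl$tissue_specific_pathogenic])
  if (length(onlyNovelGenes))
    expect_true(all(rowSums(incidence(gsm))[onlyNovelGenes] == 0))
  expect_gt(length(novelKeys), 0)
})

test_that("gene summary reproduces a known per-gene composition", {
  # one gene carrying 38 variants: 5 novel, 23 somatic of which 15
  # pathogenic, 12 of those with a prior large-intestine report
  n <- 38
  ann <- data.frame(
    chrom = "chr1", pos = 1:n, ref = "A", alt = "G", gene = "APC",
    exon = NA_character_, hgvs_c = NA_character_, hgvs_p = NA_character_,
    consequence = "missense",
    in_cosmic = c(rep(FALSE, 5), rep(TRUE, 33)),
    cosmic_confirmed_somatic = c(rep(FALSE, 5), rep(TRUE, 23),
                                 rep(FALSE, 10)),
    cosmic_pathogenic = c(rep(FALSE, 5), rep(TRUE, 15), rep(FALSE, 18)),
    cosmic_tissues = c(rep("", 5), rep("large_intestine", 12),
                       rep("lung", 21)),
    in_icgc = FALSE, ensembl_known = FALSE, population_af = NA_real_,
    sift = "missing", polyphen = "missing", stringsAsFactors = FALSE)
  calls <- data.frame(
    sample_id = "S1", chrom = "chr1", pos = 1:n, ref = "A", alt = "G",
    qual = 80, depth = 400L, alt_depth = 100L, vaf_percent = 25,
    stringsAsFactors = FALSE)
  cl <- classifyVariants(calls, ann, nSamples = 1)
  gs <- geneSummary(cl, calls)
  expect_equal(gs$gene, "APC")
  expect_equal(gs$total_variants, 38)
  expect_equal(gs$novel_variants, 5)
  expect_equal(gs$pathogenic_variants, 15)
  expect_equal(gs$somatic_variants, 23)
  expect_equal(gs$tissue_specific_variants, 12)
  expect_equal(gs$pct_samples_pathogenic, 1.0)
})

test_that("gene summary ordering is stable under input permutation", {
  coh <- smallCohort(seed = 17L)
  cl <- classifySmall(coh)
  calls <- qualityFilter(variantCalls(coh))
  g1 <- geneSummary(cl, calls)
  set.seed(5)
  g2 <- geneSummary(cl[sample(nrow(cl)), ], calls[sample(nrow(calls)), ])
  expect_equal(g1, g2)
  # the most prevalent pathogenic gene leads
  expect_true(all(diff(g1$pct_samples_pathogenic) <= 0))
})

test_that("recurrent gene selection is a simple threshold scan", {
  mat <- matrix(0L, 3, 5, dimnames = list(c("A", "B", "C"),
                                          paste0("S", 1:5)))
  mat["A", 1:2] <- 1L; mat["B", 1:3] <- 1L; mat["C", 1:4] <- 1L
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(incidence = mat),
    metadata = list(criterion = "tissue_specific_pathogenic"))
  gsm <- new("GeneSampleMatrix", se)
  expect_setequal(selectRecurrentGenes(gsm, 3), c("B", "C"))
  expect_setequal(selectRecurrentGenes(gsm, 1), c("A", "B", "C"))
  # oracle: brute-force threshold scan
  expect_setequal(selectRecurrentGenes(gsm, 3),
                  names(which(rowSums(mat) >= 3)))
})

test_that("stratification boundaries and conservation hold", {
  coh <- smallCohort(seed = 12L)
  pts <- patients(coh)
  pts$age_years[1] <- 49.9
  pts$age_years[2] <- 50.0
  z <- dichotomizeTrait(pts, "age_group")
  expect_equal(z[1:2], c(1L, 0L))   # young strictly below 50
  pts$overall_stage[3] <- "II"; pts$overall_stage[4] <- "III"
  zs <- dichotomizeTrait(pts, "stage_group")
  expect_equal(zs[3:4], c(0L, 1L))  # II early, III late
  cl <- classifySmall(coh)
  gsm <- geneSampleMatrix(cl, qualityFilter(variantCalls(coh)), "any",
                          samples = pts$patient_id)
  for (ax in c("gender", "age_group", "stage_group", "site",
               "lymph_node", "metastasis")) {
    st <- stratifyMatrix(gsm, pts, ax)
    strata <- setdiff(names(st), c("gene", "total"))
    expect_equal(rowSums(st[, strata, drop = FALSE]), st$total,
                 ignore_attr = TRUE)
  }
  expect_error(stratifyMatrix(gsm, pts[-1, ], "gender"),
               pts$patient_id[1])
})

test_that("cohort summary uses field-specific denominators", {
  pts <- table1Patients()
  cs <- cohortSummary(pts)
  male <- cs[cs$field == "gender" & cs$category == "male", ]
  expect_equal(male$n, 58L)
  expect_equal(male$denominator, 95L)
  expect_equal(male$pct, 61)
  left <- cs[cs$field == "site" & cs$category == "left_colon", ]
  expect_equal(left$n, 47L)
  expect_equal(left$denominator, 90L)
  expect_equal(left$pct, 52)
  stage3 <- cs[cs$field == "overall_stage" & cs$category == "III", ]
  expect_equal(stage3$pct, 39)
  # numerators never exceed denominators
  catRows <- cs[!is.na(cs$pct), ]
  expect_true(all(catRows$n <= catRows$denominator))
})

test_that("an all-missing field is reported as a note row", {
  pts <- table1Patients()
  pts$site <- NA_character_
  cs <- cohortSummary(pts)
  note <- cs[cs$field == "site", ]
  expect_equal(nrow(note), 1L)
  expect_match(note$note, "missing")
  expect_error(cohortSummary(pts[0, ]), "nonempty")
})
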