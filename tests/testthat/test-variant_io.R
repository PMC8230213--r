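test_that("VAF arithmetic and multi-allelic splitting on a crafted VCF", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    "chr1\t100\t.\tA\tG\t72\t.\t.\tGT:DP:AD\t0/1:400:300,100",
    "chr1\t200\t.\tC\tG,T\t60\t.\t.\tGT:DP:AD\t0/1:500:300,120,80"),
    path)
  calls <- readVcfCalls(path)
  expect_equal(nrow(calls), 3L)
  expect_equal(calls$vaf_percent[1], 25.0)
  two <- calls[calls$pos == 200, ]
  expect_equal(two$alt, c("G", "T"))
  expect_equal(two$ref, c("C", "C"))
  expect_equal(two$vaf_percent, c(24, 16))
})

test_that("malformed headers fail with a line number", {
  bad <- tempfile(fileext = ".vcf")
  writeLines(c("not-a-vcf", "chr1\t1\t.\tA\tG\t50\t.\t."), bad)
  expect_error(readVcfCalls(bad), "line 1")
  bad2 <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "chr1\t1\t.\tA\tG\t50\t.\t."), bad2)
  expect_error(readVcfCalls(bad2), "line 2")
})

test_that("records without depth or fraction keep a missing VAF, with warning", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    "chr1\t100\t.\tA\tG\t72\t.\t.\tGT\t0/1"),
    path)
  expect_warning(calls <- readVcfCalls(path), "missing")
  expect_true(is.na(calls$vaf_percent[1]))
  expect_equal(nrow(calls), 1L)
})

test_that("a written cohort round-trips through VCF to the same call set", {
  coh <- smallCohort(seed = 13L)
  dir <- tempfile()
  writeCohortVcfs(coh, dir)
  back <- readVcfDir(dir)
  canon <- function(df) {
    df <- df[order(df$sample_id, df$chrom, df$pos, df$alt), ,
             drop = FALSE]
    rownames(df) <- NULL
    df
  }
  orig <- canon(variantCalls(coh))
  got <- canon(back)
  expect_equal(got$sample_id, orig$sample_id)
  expect_equal(got$pos, orig$pos)
  expect_equal(got$depth, orig$depth)
  expect_equal(got$alt_depth, orig$alt_depth)
  expect_equal(got$vaf_percent, orig$vaf_percent, tolerance = 1e-8)
  expect_equal(got$qual, orig$qual, tolerance = 1e-8)
})

test_that("annotation and patient TSVs round-trip and normalize enums", {
  coh <- smallCohort(seed = 4L)
  fA <- tempfile(fileext = ".tsv"); fP <- tempfile(fileext = ".tsv")
  writeTable(annotations(coh), fA)
  writeTable(patients(coh), fP)
  annBack <- readAnnotations(fA)
  expect_equal(annBack$gene, annotations(coh)$gene)
  expect_equal(annBack$population_af, annotations(coh)$population_af,
               tolerance = 1e-12)
  expect_identical(annBack$cosmic_pathogenic,
                   annotations(coh)$cosmic_pathogenic)
  ptsBack <- readPatients(fP)
  expect_identical(ptsBack$gender, patients(coh)$gender)
  expect_identical(ptsBack$overall_stage, patients(coh)$overall_stage)

  # case-insensitive enum parsing
  ann <- annotations(coh)[1:2, ]
  ann$polyphen <- c("Probably Damaging", "probably_damaging")
  ann$sift <- c("Deleterious", "TOLERATED")
  f2 <- tempfile(fileext = ".tsv")
  writeTable(ann, f2)
  back <- readAnnotations(f2)
  expect_equal(back$polyphen,
               c("probably_damaging", "probably_damaging"))
  expect_equal(back$sift, c("deleterious", "tolerated"))
})

test_that("header-only tables read as empty sets without error", {
  f <- tempfile(fileext = ".tsv")
  writeTable(annotations(smallCohort(seed = 1L))[0, ], f)
  expect_equal(nrow(readAnnotations(f)), 0L)
  f2 <- tempfile(fileext = ".tsv")
  writeTable(patients(smallCohort(seed = 1L))[0, ], f2)
  expect_equal(nrow(readPatients(f2)), 0L)
})

test_that("annotation invariant violations name the offending keys", {
  ann <- annotations(smallCohort(seed = 6L))
  i <- which(!ann$in_cosmic)[1]
  ann$cosmic_tissues[i] <- "lung"
  key <- variantKey(ann[i, , drop = FALSE])
  expect_error(validateAnnotations(ann), key, fixed = TRUE)
})

test_that("reading is insensitive to input line order", {
  coh <- smallCohort(seed = 9L)
  ann <- annotations(coh)
  f1 <- tempfile(); f2 <- tempfile()
  writeTable(ann, f1)
  set.seed(1)
  writeTable(ann[sample(nrow(ann)), ], f2)
  a1 <- readAnnotations(f1); a2 <- readAnnotations(f2)
  k1 <- variantKey(a1); k2 <- variantKey(a2)
  expect_setequal(k1, k2)
  a2 <- a2[match(k1, k2), ]
  rownames(a2) <- NULL
  expect_equal(a1$cosmic_pathogenic, a2$cosmic_pathogenic)
  expect_equal(a1$gene, a2$gene)
})
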