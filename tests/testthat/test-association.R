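test_that("Fisher two-sided p matches closed forms and symmetry", {
  res <- fisherExact2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisherExact2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  # empty margin
  deg <- fisherExact2x2(matrix(c(0, 0, 3, 4), 2))
  expect_equal(deg$p_value, 1)
  expect_true(is.na(deg$odds_ratio) || !is.finite(deg$odds_ratio))
  expect_error(fisherExact2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("Fisher p equals enumeration oracle and stats::fisher.test on random tables", {
  set.seed(101)
  for (i in 1:200) {
    repeat {
      tb <- matrix(rpois(4, sample(1:8, 1)), 2)
      if (sum(tb) <= 40) break
    }
    p <- fisherExact2x2(tb)$p_value
    expect_equal(p, fisherEnumOracle(tb), tolerance = 1e-9)
    if (all(rowSums(tb) > 0) && all(colSums(tb) > 0))
      expect_equal(p, stats::fisher.test(tb)$p.value, tolerance = 1e-7)
  }
})

test_that("chi-square 2x2 matches the uncorrected base test", {
  set.seed(7)
  for (i in 1:20) {
    tb <- matrix(rpois(4, 10) + 1L, 2)
    ours <- chisq2x2(tb)
    ref <- suppressWarnings(stats::chisq.test(tb, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

mkGsm <- function(mat, crit = "tissue_specific_pathogenic") {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(incidence = mat), metadata = list(criterion = crit))
  new("GeneSampleMatrix", se)
}

test_that("binary Pearson correlation equals phi and its chi-square identity", {
  set.seed(21)
  for (rep in 1:10) {
    n <- 40
    mat <- matrix(rbinom(5 * n, 1, runif(1, 0.2, 0.8)), nrow = 5,
                  dimnames = list(paste0("g", 1:5), paste0("s", 1:n)))
    v <- apply(mat, 1, function(x) length(unique(x)) > 1)
    if (sum(v) < 2) next
    cm <- suppressMessages(pearsonBinaryCorrelation(mkGsm(mat)))
    for (i in 1:(length(cm@genes) - 1)) for (j in (i + 1):length(cm@genes)) {
      x <- mat[cm@genes[i], ]; y <- mat[cm@genes[j], ]
      tb <- table(factor(x, 0:1), factor(y, 0:1))
      phi <- (tb[2, 2] * tb[1, 1] - tb[2, 1] * tb[1, 2]) /
        sqrt(prod(rowSums(tb)) * prod(colSums(tb)))
      expect_equal(cm@r[i, j], unname(phi), tolerance = 1e-10)
      # n * r^2 equals the uncorrected chi-square statistic
      chi <- suppressWarnings(
        stats::chisq.test(tb, correct = FALSE)$statistic)
      expect_equal(n * cm@r[i, j]^2, unname(chi), tolerance = 1e-8)
    }
  }
})

test_that("perfectly aligned and opposed genes give r of +-1", {
  mat <- rbind(a = c(1, 1, 0, 0, 1), b = c(1, 1, 0, 0, 1),
               c = c(0, 0, 1, 1, 0))
  colnames(mat) <- paste0("s", 1:5)
  cm <- pearsonBinaryCorrelation(mkGsm(mat))
  expect_equal(cm@r["a", "b"], 1)
  expect_equal(cm@r["a", "c"], -1)
})

test_that("constant genes are excluded with notice", {
  mat <- rbind(a = c(1, 0, 1, 0), b = c(1, 1, 1, 1))
  colnames(mat) <- paste0("s", 1:4)
  expect_message(cm <- pearsonBinaryCorrelation(mkGsm(mat)), "constant")
  expect_equal(cm@excluded, "b")
  expect_equal(cm@genes, "a")
  expect_error(pearsonBinaryCorrelation(mkGsm(mat[, 1:2])), "3 samples")
})

test_that("MAF and exact HWE match enumeration and symmetry", {
  expect_equal(mafAndHwe(rep(0, 20)), list(maf = 0, hwe_p = 1))
  expect_equal(mafAndHwe(c(NA, NA)), list(maf = NA_real_,
                                          hwe_p = NA_real_))
  # 50 hets among 100 with equal allele counts
  g <- c(rep(1, 50), rep(0, 25), rep(2, 25))
  res <- mafAndHwe(g)
  expect_equal(res$maf, 0.5)
  expect_equal(res$hwe_p, hweEnumOracle(50, 100, 100), tolerance = 1e-10)
  set.seed(33)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    g <- sample(0:2, n, TRUE, prob = c(0.5, 0.3, 0.2))
    res <- mafAndHwe(g)
    nMinor <- min(sum(g), 2 * n - sum(g))
    # allele-label swap leaves both outputs unchanged
    res2 <- mafAndHwe(2 - g)
    expect_equal(res$maf, res2$maf)
    expect_equal(res$hwe_p, res2$hwe_p, tolerance = 1e-12)
    if (nMinor > 0) {
      nHet <- sum(g == 1)
      expect_equal(res$hwe_p, hweEnumOracle(nHet, nMinor, n),
                   tolerance = 1e-10)
    }
  }
  expect_error(mafAndHwe(c(0, 3)), "0, 1 or 2")
})

test_that("tumor-only MAF/HWE summary encodes carriers as heterozygotes", {
  coh <- smallCohort(seed = 3L)
  cl <- classifySmall(coh)
  mh <- variantMafHwe(cl, nSamples = 30)
  expect_equal(nrow(mh), nrow(cl))
  i <- which(cl$n_carriers == max(cl$n_carriers))[1]
  expect_equal(mh$maf[i], cl$n_carriers[i] / 60)
})

test_that("Bonferroni threshold is alpha over m", {
  expect_equal(bonferroniThreshold(0.05, 409), 0.05 / 409)
  expect_equal(signif(bonferroniThreshold(0.05, 409), 1), 1e-4)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.05, 5), 0.01)
  expect_error(bonferroniThreshold(0.05, 0), "positive")
  expect_error(bonferroniThreshold(1.2, 10), "alpha")
})

test_that("Fisher screen under an independent null is not anti-conservative", {
  set.seed(55)
  n <- 80
  reps <- 150
  hits <- 0
  for (i in 1:reps) {
    x <- rbinom(n, 1, 0.3); z <- rbinom(n, 1, 0.5)
    tb <- matrix(c(sum(x & z), sum(x & !z), sum(!x & z), sum(!x & !z)),
                 2, byrow = TRUE)
    if (fisherExact2x2(tb)$p_value < 0.05) hits <- hits + 1
  }
  # conservatism of the exact test allowed: at most the binomial 99% upper CI
  expect_lte(hits / reps, 0.05 + 2.58 * sqrt(0.05 * 0.95 / reps))
})
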