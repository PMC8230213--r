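# Cohort association statistics, authored from first principles:
# probability-ordering two-sided Fisher exact test, phi/Pearson binary
# co-occurrence correlation with t-transform p-values, exact conditional
# Hardy-Weinberg test, minor allele frequency, Bonferroni thresholding.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities, over
#' all tables with the observed margins, that do not exceed the probability
#' of the observed table (probability-ordering convention, with a 1e-7
#' relative tolerance absorbing floating-point ties). The reported odds
#' ratio is the sample cross-product ratio `ad/bc` (not the conditional
#' MLE); an empty margin yields p = 1 with a missing odds ratio.
#'
#' @param tbl 2x2 matrix of non-negative integer counts
#' @return list with `odds_ratio` and `p_value`
#' @examples
#' fisherExact2x2(matrix(c(10, 0, 0, 10), 2))$p_value  # 2 / choose(20, 10)
#' @export
fisherExact2x2 <- function(tbl) {
  tbl <- as.matrix(tbl)
  stopifnot(identical(dim(tbl), c(2L, 2L)))
  if (any(tbl < 0) || any(tbl != round(tbl)))
    stop("table must contain non-negative integer counts", call. = FALSE)
  a <- tbl[1, 1]; b <- tbl[1, 2]; c <- tbl[2, 1]; d <- tbl[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  orat <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else a * d / (b * c)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n)
    return(list(odds_ratio = orat, p_value = 1))
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  pObs <- dhyper(a, c1, n - c1, r1)
  p <- sum(probs[probs <= pObs * (1 + 1e-7)])
  list(odds_ratio = orat, p_value = min(p, 1))
}

#' Pearson chi-square test for a 2x2 table, without continuity correction
#'
#' @param tbl 2x2 count matrix
#' @return list with `statistic` and `p_value`
#' @export
chisq2x2 <- function(tbl) {
  tbl <- as.matrix(tbl)
  n <- sum(tbl)
  rs <- rowSums(tbl); cs <- colSums(tbl)
  if (n == 0 || any(rs == 0) || any(cs == 0))
    return(list(statistic = NA_real_, p_value = 1))
  expd <- outer(rs, cs) / n
  stat <- sum((tbl - expd)^2 / expd)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Gene-by-trait association screen
#'
#' For every gene in the incidence matrix, cross-tabulates mutation carriage
#' against the dichotomized clinicopathological axis and applies Fisher's
#' exact test (default) or the uncorrected chi-square test.
#'
#' @param gsm a [GeneSampleMatrix-class]
#' @param patients patients data.frame covering the matrix samples
#' @param axis contrast axis (see [dichotomizeTrait()])
#' @param test `"fisher"` or `"chisq"`
#' @return data.frame: gene, the four table cells (carrier/non-carrier by
#'   trait), odds ratio, p-value, test label; ordered by p
#' @export
associationScreen <- function(gsm, patients, axis,
                              test = c("fisher", "chisq")) {
  test <- match.arg(test)
  mat <- incidence(gsm)
  missing <- setdiff(colnames(mat), patients$patient_id)
  if (length(missing))
    stop(sprintf("samples without a patient record: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  p <- patients[match(colnames(mat), patients$patient_id), , drop = FALSE]
  z <- dichotomizeTrait(p, axis)
  keep <- !is.na(z)
  rows <- lapply(rownames(mat), function(g) {
    x <- mat[g, keep]
    tbl <- matrix(c(sum(x == 1 & z[keep] == 1), sum(x == 1 & z[keep] == 0),
                    sum(x == 0 & z[keep] == 1), sum(x == 0 & z[keep] == 0)),
                  nrow = 2, byrow = TRUE)
    res <- if (test == "fisher") fisherExact2x2(tbl)
           else c(list(odds_ratio = NA_real_), chisq2x2(tbl))
    data.frame(gene = g, axis = axis,
               carrier_trait1 = tbl[1, 1], carrier_trait0 = tbl[1, 2],
               noncarrier_trait1 = tbl[2, 1], noncarrier_trait0 = tbl[2, 2],
               odds_ratio = res$odds_ratio, p_value = res$p_value,
               test = test, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise co-occurrence correlation of binary gene incidence
#'
#' Pearson correlation between 0/1 incidence vectors, which equals the phi
#' coefficient of the pairwise 2x2 cross-table; two-sided p-values from
#' `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom. Genes with
#' zero variance are excluded and listed in the result.
#'
#' @param gsm a [GeneSampleMatrix-class] with at least 3 samples
#' @param starLevels significance thresholds for star annotation
#' @return a [CorrelationMatrix-class]
#' @export
pearsonBinaryCorrelation <- function(gsm,
                                     starLevels = c(0.05, 0.01, 0.001)) {
  mat <- incidence(gsm)
  n <- ncol(mat)
  if (n < 3L)
    stop("correlation requires at least 3 samples", call. = FALSE)
  v <- apply(mat, 1L, function(x) length(unique(x)) > 1L)
  excluded <- rownames(mat)[!v]
  if (length(excluded))
    message("excluding constant gene(s): ", paste(excluded, collapse = ", "))
  mat <- mat[v, , drop = FALSE]
  genes <- rownames(mat)
  r <- cor(t(mat))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0  # perfectly aligned columns
  diag(r) <- 1
  diag(p) <- NA_real_
  new("CorrelationMatrix", genes = genes, r = r, p = p, n = as.integer(n),
      excluded = excluded, starLevels = starLevels)
}

#' Significance stars for a correlation matrix
#'
#' @param corMat a [CorrelationMatrix-class]
#' @return character matrix of `""`, `"*"`, `"**"`, `"***"` per star level
#' @export
significanceStars <- function(corMat) {
  lv <- sort(corMat@starLevels, decreasing = TRUE)
  s <- matrix("", nrow = nrow(corMat@p), ncol = ncol(corMat@p),
              dimnames = dimnames(corMat@p))
  for (k in seq_along(lv))
    s[!is.na(corMat@p) & corMat@p < lv[k]] <- strrep("*", k)
  s
}

#' Minor allele frequency and exact Hardy-Weinberg test
#'
#' `maf` is `min(p, 1-p)` of the sample allele frequency. The HWE p-value is
#' the exact conditional test: all heterozygote counts compatible with the
#' observed allele counts are enumerated, and the probabilities not
#' exceeding that of the observed configuration are summed.
#'
#' @param genotypes vector of per-sample minor-allele copy counts in
#'   `{0, 1, 2}` (NA allowed)
#' @return list with `maf` and `hwe_p` (both NA when all genotypes missing)
#' @export
mafAndHwe <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  if (!length(g)) return(list(maf = NA_real_, hwe_p = NA_real_))
  if (any(!g %in% 0:2))
    stop("genotypes must be 0, 1 or 2 copies", call. = FALSE)
  n <- length(g)
  nHet <- sum(g == 1L)
  nA <- sum(g)               # minor allele count
  af <- nA / (2 * n)
  maf <- min(af, 1 - af)
  nMinor <- min(nA, 2L * n - nA)
  if (nMinor == 0L) return(list(maf = maf, hwe_p = 1))
  hets <- seq(nMinor %% 2L, nMinor, by = 2L)
  logProb <- vapply(hets, function(h) {
    homMinor <- (nMinor - h) / 2
    homMajor <- n - h - homMinor
    h * log(2) + lgamma(n + 1) -
      (lgamma(homMinor + 1) + lgamma(h + 1) + lgamma(homMajor + 1)) +
      lgamma(nMinor + 1) + lgamma(2 * n - nMinor + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logProb - max(logProb))
  prob <- prob / sum(prob)
  pObs <- prob[match(nHet, hets)]
  p <- sum(prob[prob <= pObs * (1 + 1e-9)])
  list(maf = maf, hwe_p = min(p, 1))
}

#' Per-variant MAF/HWE summary under the tumor-only carrier convention
#'
#' Tumor-only data has no true genotypes; each carrier is encoded as
#' heterozygous (one minor-allele copy) and non-carriers as zero, mirroring
#' what a PLINK-style run on presence/absence calls would see. This is a
#' convention, not a claim about the underlying germline genotypes.
#'
#' @param classified data.frame from [classifyVariants()]
#' @param nSamples cohort size (carriers beyond it are impossible)
#' @return data.frame: variant_key, gene, maf, hwe_p
#' @export
variantMafHwe <- function(classified, nSamples) {
  rows <- lapply(seq_len(nrow(classified)), function(i) {
    k <- classified$n_carriers[i]
    g <- c(rep(1L, k), rep(0L, nSamples - k))
    res <- mafAndHwe(g)
    data.frame(variant_key = classified$variant_key[i],
               gene = classified$gene[i], maf = res$maf, hwe_p = res$hwe_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise level in (0,1)
#' @param m number of tests (>= 1)
#' @return `alpha / m` (0.05 over 409 genes gives 1.22e-4, i.e. 0.0001 at
#'   one significant figure)
#' @export
bonferroniThreshold <- function(alpha = 0.05, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0,1)", call. = FALSE)
  if (missing(m) || !is.numeric(m) || m < 1)
    stop("m must be a positive test count", call. = FALSE)
  alpha / m
}
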