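# Shared fixtures, built in code at test time.

smallComposition <- function() {
  CascadeComposition(
    nTotal = 100L, nNovelCosmic = 20L, nIcgcAmongNovel = 2L,
    nConfirmedSomatic = 40L, nPathogenic = 25L,
    nSomaticAndPathogenic = 25L, nPathogenicPriorTissue = 10L,
    nGermlineBand = 5L, nGermlineMafSupport = 5L, nEnsemblCommon = 3L,
    nSiftDeleterious = 10L, nSiftTolerated = 8L,
    nPolyphenProbably = 5L, nPolyphenPossibly = 3L, nPolyphenBenign = 10L,
    consequenceCounts = c(synonymous = 15L, missense = 20L,
                          stop_gained = 2L, frameshift = 2L,
                          splice = 1L, other = 0L))
}

smallConfig <- function(nPatients = 30L, seed = 11L, ...) {
  CohortConfig(nPatients = nPatients,
               panelGenes = sprintf("G%03d", 1:40),
               variantsPerPatient = 8,
               composition = smallComposition(), seed = seed, ...)
}

smallCohort <- function(seed = 11L, nPatients = 30L, ...) {
  generateCohort(smallConfig(nPatients = nPatients, seed = seed, ...))
}

classifySmall <- function(cohort, config = FilterConfig()) {
  classifyVariants(qualityFilter(cohort@calls, config),
                   cohort@annotations, config,
                   nSamples = nrow(cohort@patients))
}

# the published cohort table, reconstructed from its printed counts:
# 95 patients with clinicopathological records; stage/T/N/M known for 94,
# site known for 90
table1Patients <- function() {
  fill <- function(counts, labels, n = 95L) {
    v <- rep(labels, counts)
    c(v, rep(NA_character_, n - length(v)))
  }
  data.frame(
    patient_id = sprintf("P%03d", 1:95),
    age_years = rep(62, 95),
    gender = fill(c(58, 37), c("male", "female")),
    t_stage = fill(c(2, 18, 61, 13), paste0("T", 1:4)),
    n_stage = fill(c(55, 33, 6), paste0("N", 0:2)),
    m_stage = fill(c(90, 4), paste0("M", 0:1)),
    overall_stage = fill(c(17, 32, 37, 8), c("I", "II", "III", "IV")),
    site = fill(c(47, 30, 13), c("left_colon", "right_colon", "rectum")),
    stringsAsFactors = FALSE)
}

# independent brute-force two-sided Fisher p: enumerate every table with the
# observed margins, computing each probability from factorials directly
fisherEnumOracle <- function(tbl) {
  a <- tbl[1, 1]; b <- tbl[1, 2]; c <- tbl[2, 1]; d <- tbl[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; n <- sum(tbl)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  logP <- function(aa) {
    bb <- r1 - aa; cc <- c1 - aa; dd <- r2 - cc
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
      lfactorial(n) - lfactorial(aa) - lfactorial(bb) - lfactorial(cc) -
      lfactorial(dd)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  lp <- vapply(support, logP, numeric(1))
  pObs <- lp[match(a, support)]
  sum(exp(lp[lp <= pObs + 1e-7]))
}

# independent exact HWE oracle: enumerate heterozygote counts, probability
# of each configuration from combinatorial counting
hweEnumOracle <- function(nHet, nMinor, n) {
  hets <- seq(nMinor %% 2L, nMinor, by = 2L)
  count <- vapply(hets, function(h) {
    homMinor <- (nMinor - h) / 2
    homMajor <- n - h - homMinor
    lfactorial(n) - lfactorial(homMinor) - lfactorial(h) -
      lfactorial(homMajor) + h * log(2)
  }, numeric(1))
  prob <- exp(count - max(count))
  prob <- prob / sum(prob)
  pObs <- prob[match(nHet, hets)]
  sum(prob[prob <= pObs * (1 + 1e-9)])
}
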