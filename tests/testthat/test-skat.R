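test_that("chi-square mixture tail matches exact and Monte-Carlo references", {
  # equal eigenvalues collapse to a plain chi-square
  expect_equal(pQuadForm(12, rep(2, 4))$p,
               pchisq(6, df = 4, lower.tail = FALSE), tolerance = 1e-8)
  set.seed(77)
  for (i in 1:4) {
    lam <- sort(runif(sample(3:8, 1), 0.05, 4), decreasing = TRUE)
    q <- sum(lam) * runif(1, 0.5, 2.5)
    draws <- colSums(lam * matrix(rchisq(length(lam) * 1e5, 1),
                                  length(lam)))
    mc <- mean(draws > q)
    se <- sqrt(mc * (1 - mc) / 1e5)
    expect_lt(abs(pQuadForm(q, lam)$p - mc), 3 * se + 1e-6)
  }
})

test_that("beta weights are monotone decreasing and match the density", {
  w <- betaWeights(c(0.001, 0.05, 0.4))
  expect_true(all(diff(w) < 0))
  expect_equal(betaWeights(c(0.1, 0.3), 1, 1), c(1, 1))
  mafs <- c(0.01, 0.1, 0.25)
  expect_equal(betaWeights(mafs, 1, 25), dbeta(mafs, 1, 25))
  expect_error(betaWeights(c(0.1, 1.2)), "\\[0,1\\]")
})

test_that("null model fits match closed forms and a numeric optimizer", {
  y <- c(rep(1, 30), rep(0, 70))
  nm <- fitNull(y, "binary")
  expect_equal(unname(nm@fitted), rep(0.3, 100), tolerance = 1e-8)
  expect_lt(abs(sum(nm@residuals)), 1e-8)
  yq <- rnorm(50, 3)
  nq <- fitNull(yq, "quantitative")
  expect_equal(nq@residuals, yq - mean(yq), tolerance = 1e-10)
  # logistic with a covariate against brute-force likelihood maximization
  set.seed(4)
  x <- rnorm(20)
  yb <- rbinom(20, 1, plogis(0.4 + 0.8 * x))
  if (length(unique(yb)) == 2) {
    nmc <- fitNull(yb, "binary", covariates = cbind(x = x))
    nll <- function(b) -sum(yb * (b[1] + b[2] * x) -
                              log1p(exp(b[1] + b[2] * x)))
    opt <- optim(c(0, 0), nll, method = "BFGS")
    muOpt <- plogis(opt$par[1] + opt$par[2] * x)
    expect_equal(unname(nmc@fitted), muOpt, tolerance = 1e-4)
  }
  expect_error(fitNull(rep(1, 20), "binary"), "single class")
  expect_error(fitNull(rbinom(5, 1, 0.5), "binary"), "at least 10")
})

test_that("a single-variant gene reduces to the per-variant score test", {
  sim <- generateSkatNull(150, 1, mafSpectrum = 0.2, seed = 6L)
  null <- fitNull(sim$trait, "binary")
  r <- skatOTest(sim$genotypes, null)
  expect_true(all(abs(r@perRhoP - r@perRhoP[1]) < 1e-12))
  expect_equal(r@pValue, unname(r@perRhoP[1]))
  # independent score test: U^2 / Var(U) ~ chi2_1
  g <- sim$genotypes[, 1]
  w <- betaWeights(min(mean(g) / 2, 1 - mean(g) / 2))
  u <- sum(w * g * null@residuals)
  mu <- null@fitted
  v <- mu * (1 - mu)
  gw <- w * g
  varU <- sum(v * gw^2) - sum(v * gw)^2 / sum(v)
  expect_equal(r@pValue, pchisq(u^2 / varU, 1, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("rho = 1 reduces to an independently computed burden test", {
  sim <- generateSkatNull(200, 8, seed = 9L)
  null <- fitNull(sim$trait, "binary")
  r <- skatOTest(sim$genotypes, null)
  af <- colMeans(sim$genotypes) / 2
  w <- betaWeights(pmin(af, 1 - af))
  b <- as.vector(sim$genotypes %*% w)   # collapsed burden score
  u <- sum(b * null@residuals)
  mu <- null@fitted; v <- mu * (1 - mu)
  varU <- sum(v * b^2) - sum(v * b)^2 / sum(v)
  expect_equal(unname(r@perRhoP["1.00"]),
               pchisq(u^2 / varU, 1, lower.tail = FALSE),
               tolerance = 1e-7)
})

test_that("rho = 0 reduces to a standalone SKAT built from first pieces", {
  sim <- generateSkatNull(180, 7, seed = 14L)
  null <- fitNull(sim$trait, "binary")
  r <- skatOTest(sim$genotypes, null)
  # independent route: dense projection matrix and raw eigen-decomposition
  af <- colMeans(sim$genotypes) / 2
  w <- betaWeights(pmin(af, 1 - af))
  A <- sweep(sim$genotypes, 2, w, `*`)
  mu <- null@fitted; v <- mu * (1 - mu)
  X <- null@design
  P <- diag(v) - (v %o% v) / sum(v)       # intercept-only projection
  K <- t(A) %*% P %*% A
  lam <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > max(lam) * 1e-10]
  Q <- sum(as.vector(crossprod(A, null@residuals))^2)
  pRef <- pQuadForm(Q, lam)$p
  expect_equal(unname(r@perRhoP["0.00"]), pRef, tolerance = 1e-6)
})

test_that("p-values are invariant to a consistent permutation of individuals", {
  sim <- generateSkatNull(120, 6, seed = 22L)
  null <- fitNull(sim$trait, "binary")
  r1 <- skatOTest(sim$genotypes, null)
  set.seed(1); perm <- sample(120)
  null2 <- fitNull(sim$trait[perm], "binary")
  r2 <- skatOTest(sim$genotypes[perm, ], null2)
  expect_equal(r1@pValue, r2@pValue, tolerance = 1e-9)
  expect_equal(r1@perRhoP, r2@perRhoP, tolerance = 1e-9)
})

test_that("degenerate inputs are handled", {
  sim <- generateSkatNull(50, 3, seed = 2L)
  null <- fitNull(sim$trait, "binary")
  expect_warning(r <- skatOTest(matrix(0L, 50, 3), null), "all-zero")
  expect_equal(r@pValue, 1)
  expect_equal(r@mac, 0)
  expect_error(skatOTest(sim$genotypes[1:10, ], null), "match")
})

test_that("result bookkeeping: MAC, carriers and the min-p bound", {
  sim <- generateSkatNull(100, 5, seed = 31L)
  null <- fitNull(sim$trait, "binary")
  r <- skatOTest(sim$genotypes, null)
  expect_equal(r@mac, sum(sim$genotypes))
  expect_equal(r@mCarriers, sum(rowSums(sim$genotypes) > 0))
  expect_gte(r@pValue, min(r@perRhoP) * 0.1)
  expect_lte(r@pValue, 1)
})

test_that("the panel screen reports the conventional per-gene columns and ranks by p", {
  coh <- smallCohort(seed = 41L, nPatients = 60L)
  cl <- classifySmall(coh)
  scr <- skatOScreen(cl, qualityFilter(variantCalls(coh)),
                     patients(coh), "gender")
  expect_true(all(c("SetID", "p.value", "N.Marker.All", "N.Marker.Test",
                    "MAC", "m", "method") %in% names(scr)))
  # no variants are excluded, only down-weighted
  expect_equal(scr$N.Marker.All, scr$N.Marker.Test)
  expect_true(!is.unsorted(scr$p.value))
  expect_true(all(scr$p.value > 0 & scr$p.value <= 1))
})

test_that("an injected strong association is recovered at the top of the screen", {
  hits <- 0L
  for (i in 1:8) {
    coh <- smallCohort(seed = 600 + i, nPatients = 80L)
    ci <- injectGeneAssociation(coh, "G005", "gender", oddsRatio = 15,
                                seed = 700 + i)
    cl <- classifySmall(ci)
    scr <- skatOScreen(cl, qualityFilter(variantCalls(ci)),
                       patients(ci), "gender")
    if (scr$SetID[1] == "G005") hits <- hits + 1L
  }
  expect_gte(hits, 6L)
})
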