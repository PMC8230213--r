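# Gene-based rare-variant association: burden, SKAT and the optimal unified
# SKAT-O test, built from the score-statistic formulas.
#
# With genotype matrix G (n x m), diagonal weights W, null residuals r and
# null variance V, the family of statistics is
#   Q_rho = (1 - rho) * Q_SKAT + rho * Q_burden
#         = r' (GW) R_rho (GW)' r,   R_rho = (1-rho) I + rho 11',
# whose null distribution is the mixture of chi-squares with eigenvalues of
# S_rho B S_rho, where B = (GW)' P (GW) is the score covariance under the
# null (P the variance of residuals after projecting out the design) and
# S_rho the symmetric square root of R_rho. rho = 0 is SKAT, rho = 1 the
# weighted burden test. The combined p-value for the minimum over a rho grid
# follows the one-dimensional integration of the optimal-test construction.

#' Fit the null trait model
#'
#' Binary traits are fit by logistic regression (iteratively reweighted
#' least squares, convergence tolerance 1e-10); quantitative traits by
#' ordinary least squares, with the residual variance as dispersion.
#' Intercept-only by default.
#'
#' @param trait numeric trait vector (0/1 for binary)
#' @param traitType `"binary"` or `"quantitative"`
#' @param covariates optional numeric matrix of covariate columns
#' @param traitName label used in error messages
#' @return a [SkatNullModel-class]
#' @export
fitNull <- function(trait, traitType = c("binary", "quantitative"),
                    covariates = NULL, traitName = "trait") {
  traitType <- match.arg(traitType)
  y <- as.numeric(trait)
  if (anyNA(y)) stop("trait must not contain NA; subset first",
                     call. = FALSE)
  n <- length(y)
  if (n < 10L) stop("null model requires at least 10 individuals",
                    call. = FALSE)
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  if (traitType == "binary") {
    if (!all(y %in% c(0, 1)))
      stop(sprintf("binary trait '%s' must be 0/1", traitName),
           call. = FALSE)
    if (length(unique(y)) < 2L)
      stop(sprintf("binary trait '%s' has a single class", traitName),
           call. = FALSE)
    fit <- glm.fit(X, y, family = binomial(),
                   control = list(epsilon = 1e-10, maxit = 100))
    mu <- fit$fitted.values
    if (!fit$converged || any(mu < 1e-10) || any(mu > 1 - 1e-10))
      stop(sprintf(
        "logistic null model for trait '%s' failed (separation or non-convergence)",
        traitName), call. = FALSE)
    new("SkatNullModel", traitType = "binary", fitted = mu,
        residuals = y - mu, dispersion = 1, design = X)
  } else {
    fit <- lm.fit(X, y)
    res <- fit$residuals
    disp <- sum(res^2) / max(n - ncol(X), 1L)
    new("SkatNullModel", traitType = "quantitative",
        fitted = y - res, residuals = res, dispersion = disp, design = X)
  }
}

#' Beta-density allele-frequency weights
#'
#' `weight_j = dbeta(maf_j, a, b)`: with the default `Beta(1, 25)` the
#' weight is strictly decreasing in MAF, so rare variants receive higher
#' weight than common ones. `a = b = 1` gives the unweighted test.
#'
#' @param mafs per-variant minor allele frequencies in `[0, 1]`
#' @param a,b Beta shape parameters (defaults 1 and 25)
#' @return non-negative weight vector
#' @export
betaWeights <- function(mafs, a = 1, b = 25) {
  if (any(is.na(mafs)) || any(mafs < 0) || any(mafs > 1))
    stop("mafs must lie in [0,1]", call. = FALSE)
  dbeta(mafs, a, b)
}

.rhoSqrt <- function(m, rho) {
  # symmetric square root of R_rho = (1-rho) I + rho 11'
  s1 <- sqrt(1 - rho)
  s2 <- (sqrt(1 - rho + m * rho) - s1) / m
  diag(s1, m) + matrix(s2, m, m)
}

.scoreCov <- function(A, null) {
  V <- if (null@traitType == "binary")
    null@fitted * (1 - null@fitted) else rep(null@dispersion,
                                             length(null@fitted))
  X <- null@design
  VA <- A * V
  XtVX <- crossprod(X, X * V)
  C1 <- crossprod(A, X * V)
  B <- crossprod(A, VA) - C1 %*% solve(XtVX, t(C1))
  (B + t(B)) / 2
}

.skatOParam <- function(B) {
  m <- ncol(B)
  one <- rep(1, m)
  Bone <- as.vector(B %*% one)
  sbar <- sum(Bone) / m^2                 # ||z_mean||^2
  cof1 <- (Bone / m) / sbar
  D2 <- B - sbar * tcrossprod(cof1)
  lambda <- eigen(D2, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > max(lambda, 0) * 1e-10 & lambda > 0]
  W33 <- 4 * sbar * drop(crossprod(cof1, D2 %*% cof1))
  list(lambda = lambda, MuQ = sum(lambda),
       VarQ = 2 * sum(lambda^2) + W33, VarRemain = W33,
       sbar = sbar, sumCof2 = sum(cof1^2), m = m)
}

.skatOCombinedP <- function(pmin, qmin, param, rhoGrid) {
  rhoAdj <- pmin(rhoGrid, 0.999)
  tau <- (param$m^2 * rhoGrid + (1 - rhoGrid) * param$sumCof2) * param$sbar
  sd1 <- if (param$VarQ > 0)
    sqrt(max(param$VarQ - param$VarRemain, 0)) / sqrt(param$VarQ) else 1
  stOf <- function(xi) {
    tmin <- min((qmin - tau * xi) / (1 - rhoAdj))
    (tmin - param$MuQ) * sd1 + param$MuQ
  }
  # lower-tail CDF of the residual mixture; for moderate pmin a monotone
  # spline over the st range replaces per-point inversions
  lowTail <- function(st) {
    if (st <= 0) return(0)
    if (st > sum(param$lambda) * 1e4) return(1)
    1 - pQuadForm(st, param$lambda)$p
  }
  if (pmin > 1e-4) {
    stRange <- vapply(c(0, 40), stOf, numeric(1))
    grid <- seq(max(min(stRange), 1e-8), max(stRange, 1), length.out = 48L)
    up <- .pQuadFormImhofMulti(grid, param$lambda, absTol = 1e-6)
    if (anyNA(up)) up <- vapply(grid, function(g)
      .pQuadFormLiu(g, param$lambda), numeric(1))
    vals <- pmin(pmax(1 - up, 0), 1)
    vals <- cummax(vals)                      # enforce monotone CDF
    spl <- stats::splinefun(grid, vals, method = "hyman")
    lowTail <- function(st) {
      if (st <= grid[1L]) return(if (st <= 0) 0 else vals[1L])
      if (st >= grid[48L]) return(vals[48L])
      min(max(spl(st), 0), 1)
    }
  }
  integrand <- function(x) {
    vapply(x, function(xi)
      lowTail(stOf(xi)) * dchisq(xi, df = 1), numeric(1))
  }
  # the integrand vanishes once any per-rho constraint drives st below 0;
  # restrict the quadrature to the support so the mass near x = 0 (where
  # the near-burden constraints bind) is never missed
  thr <- if (sd1 > 0) param$MuQ * (1 - 1 / sd1) else 0
  xcut <- min((qmin - (1 - rhoAdj) * thr) / tau)
  upper <- min(max(xcut, 0), 40)
  val <- if (upper <= 0) 0 else tryCatch(
    integrate(integrand, lower = 0, upper = upper, subdivisions = 2000L,
              abs.tol = 1e-10)$value,
    error = function(e) NA_real_)
  p <- if (is.na(val)) pmin * length(rhoGrid) else 1 - val
  # the min-p statistic bounds: pmin <= p <= Bonferroni over the grid
  min(max(p, pmin), min(pmin * length(rhoGrid), 1))
}

#' SKAT-O test for one gene
#'
#' Computes the per-rho statistics `Q_rho`, their tail probabilities from
#' the induced chi-square mixtures, and the combined optimal-test p-value
#' over the rho grid. `rhoGrid = 0` reduces exactly to SKAT and
#' `rhoGrid = 1` to the weighted burden score test. A single-variant gene
#' collapses to the score test for that variant under every rho.
#'
#' @param genotypes individuals-by-variants matrix of allele counts (0/1/2)
#' @param null a [SkatNullModel-class] from [fitNull()]
#' @param weights per-variant weights; default [betaWeights()] on `mafs`
#' @param mafs per-variant minor allele frequencies; default estimated from
#'   the genotype column means (folded)
#' @param rhoGrid grid of SKAT/burden mixing weights (standard 8 points)
#' @param weightsBeta Beta shape parameters when weights are derived
#' @param gene gene label carried into the result
#' @param usePermutation add a residual-permutation p-value as a
#'   small-sample safeguard (method label records it)
#' @param nPermutations permutation count when enabled (default 2000)
#' @param seed seed for the permutation draw
#' @return a [SkatOResult-class]
#' @export
skatOTest <- function(genotypes, null, weights = NULL, mafs = NULL,
                      rhoGrid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1),
                      weightsBeta = c(1, 25), gene = "gene",
                      usePermutation = FALSE, nPermutations = 2000L,
                      seed = 1L) {
  G <- as.matrix(genotypes)
  stopifnot(is(null, "SkatNullModel"))
  n <- length(null@residuals)
  if (nrow(G) != n)
    stop("genotype rows must match the null model individuals",
         call. = FALSE)
  m <- ncol(G)
  if (m < 1L) stop("at least one variant is required", call. = FALSE)
  if (is.null(mafs)) {
    af <- colMeans(G) / 2
    mafs <- pmin(af, 1 - af)
  }
  if (is.null(weights))
    weights <- betaWeights(mafs, weightsBeta[1], weightsBeta[2])
  mac <- sum(G)
  mCar <- sum(rowSums(G) > 0)

  if (all(G == 0)) {
    warning("all-zero genotype matrix; p = 1", call. = FALSE)
    return(new("SkatOResult", gene = gene, pValue = 1,
               perRhoP = setNames(rep(1, length(rhoGrid)),
                                  format(rhoGrid)),
               bestRho = rhoGrid[1], nMarkerAll = m, nMarkerTest = m,
               mac = 0, mCarriers = 0L, methodLabel = "degenerate"))
  }

  A <- sweep(G, 2L, weights, `*`)
  s <- drop(crossprod(A, null@residuals))
  Qs <- (1 - rhoGrid) * sum(s^2) + rhoGrid * sum(s)^2
  B <- .scoreCov(A, null)

  methods <- character(length(rhoGrid))
  perRho <- numeric(length(rhoGrid))
  lambdas <- vector("list", length(rhoGrid))
  for (i in seq_along(rhoGrid)) {
    rho <- rhoGrid[i]
    if (m == 1L) {
      lam <- as.vector(B)
    } else {
      S <- .rhoSqrt(m, rho)
      lam <- eigen(S %*% B %*% S, symmetric = TRUE,
                   only.values = TRUE)$values
      lam <- lam[lam > max(lam, 0) * 1e-10 & lam > 0]
    }
    lambdas[[i]] <- lam
    res <- pQuadForm(Qs[i], lam)
    perRho[i] <- res$p
    methods[i] <- res$method
  }
  names(perRho) <- format(rhoGrid)
  best <- which.min(perRho)
  pmin <- perRho[best]

  if (length(rhoGrid) == 1L || m == 1L) {
    pOut <- unname(if (m == 1L) perRho[1] else pmin)
    label <- paste(unique(methods), collapse = "+")
    if (m == 1L) label <- "single-variant"
  } else {
    qmin <- vapply(seq_along(rhoGrid), function(i)
      .qQuadFormLiu(pmin, lambdas[[i]]), numeric(1))
    param <- .skatOParam(B)
    pOut <- .skatOCombinedP(pmin, qmin, param, rhoGrid)
    label <- if (any(methods == "liu")) "skat-o:liu-fallback" else "skat-o"
  }

  if (usePermutation) {
    permP <- .withSeed(seed, {
      obsMin <- min(vapply(seq_along(rhoGrid), function(i)
        .pQuadFormLiu(Qs[i], lambdas[[i]]), numeric(1)))
      hits <- 0L
      for (b in seq_len(nPermutations)) {
        rp <- sample(null@residuals)
        sp <- drop(crossprod(A, rp))
        Qp <- (1 - rhoGrid) * sum(sp^2) + rhoGrid * sum(sp)^2
        pm <- min(vapply(seq_along(rhoGrid), function(i)
          .pQuadFormLiu(Qp[i], lambdas[[i]]), numeric(1)))
        if (pm <= obsMin) hits <- hits + 1L
      }
      (hits + 1) / (nPermutations + 1)
    })
    pOut <- permP
    label <- sprintf("permutation(%d)", nPermutations)
  }

  new("SkatOResult", gene = gene, pValue = unname(pOut), perRhoP = perRho,
      bestRho = rhoGrid[best], nMarkerAll = m, nMarkerTest = m,
      mac = mac, mCarriers = as.integer(mCar), methodLabel = label)
}

#' Build per-gene carrier genotype matrices from classified calls
#'
#' Tumor-only carrier encoding: genotype 1 if the sample carries the
#' variant, 0 otherwise.
#'
#' @param classified data.frame from [classifyVariants()]
#' @param calls underlying calls
#' @param samples sample universe
#' @param genes genes to build (default: all in `classified`)
#' @return named list of samples-by-variants 0/1 matrices
#' @export
geneGenotypeMatrices <- function(classified, calls, samples,
                                 genes = NULL) {
  if (is.null(genes)) genes <- sort(unique(classified$gene))
  ck <- variantKey(calls)
  out <- list()
  for (g in genes) {
    keys <- classified$variant_key[classified$gene == g]
    if (!length(keys)) next
    Gm <- matrix(0L, nrow = length(samples), ncol = length(keys),
                 dimnames = list(samples, keys))
    hit <- calls[ck %in% keys, , drop = FALSE]
    hit <- hit[hit$sample_id %in% samples, , drop = FALSE]
    if (nrow(hit))
      Gm[cbind(hit$sample_id, variantKey(hit))] <- 1L
    out[[g]] <- Gm
  }
  out
}

#' Gene-level SKAT-O screen across the panel
#'
#' Runs [skatOTest()] for every gene against a dichotomized
#' clinicopathological trait, ranking results by p-value. Output columns
#' mirror the conventional per-gene report: SetID, p.value, N.Marker.All,
#' N.Marker.Test, MAC (total minor allele count), m (individuals with at
#' least one minor allele) and the method label. No variants are excluded
#' (common variants simply receive lower weight), so N.Marker.Test equals
#' N.Marker.All. Significance is flagged at the Bonferroni threshold
#' `0.05 / bonferroniM`.
#'
#' @param classified data.frame from [classifyVariants()]
#' @param calls underlying calls
#' @param patients patients table
#' @param trait contrast axis (see [dichotomizeTrait()])
#' @param genes genes to screen (default: all classified genes)
#' @param rhoGrid,weightsBeta passed to [skatOTest()]
#' @param bonferroniM test count for the significance flag (default 409,
#'   the panel size)
#' @param usePermutation,nPermutations,seed passed to [skatOTest()]
#' @return data.frame ranked by p.value
#' @export
skatOScreen <- function(classified, calls, patients, trait,
                        genes = NULL,
                        rhoGrid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1),
                        weightsBeta = c(1, 25), bonferroniM = 409L,
                        usePermutation = FALSE, nPermutations = 2000L,
                        seed = 1L) {
  z <- dichotomizeTrait(patients, trait)
  keep <- !is.na(z)
  ids <- patients$patient_id[keep]
  null <- fitNull(z[keep], "binary", traitName = trait)
  mats <- geneGenotypeMatrices(classified, calls, ids, genes = genes)
  rows <- lapply(names(mats), function(g) {
    res <- suppressWarnings(
      skatOTest(mats[[g]], null, rhoGrid = rhoGrid,
                weightsBeta = weightsBeta, gene = g,
                usePermutation = usePermutation,
                nPermutations = nPermutations, seed = seed))
    data.frame(SetID = g, p.value = res@pValue,
               N.Marker.All = res@nMarkerAll,
               N.Marker.Test = res@nMarkerTest, MAC = res@mac,
               m = res@mCarriers, best_rho = res@bestRho,
               method = res@methodLabel, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p.value, out$SetID), , drop = FALSE]
  out$significant <- out$p.value < bonferroniThreshold(0.05, bonferroniM)
  rownames(out) <- NULL
  out
}
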