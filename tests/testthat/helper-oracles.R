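# Independent oracle implementations used to cross-check the package's
# estimators. Deliberately written in plain scalar/loop style, from the
# primary formulas, sharing no code with the implementations they check.

# Weir & Cockerham (1984) theta: per-locus a, b, c assembled population by
# population from genotype vectors (dosage lists, one per population)
oracleWcTheta <- function(popDosages) {
  L <- length(popDosages[[1]][1, ])
  sumA <- sumT <- 0
  perLocus <- numeric(L)
  for (l in seq_len(L)) {
    ns <- ps <- hs <- c()
    for (pop in popDosages) {
      g <- pop[, l]
      g <- g[!is.na(g)]
      if (length(g) == 0) next
      ns <- c(ns, length(g))
      ps <- c(ps, sum(g) / (2 * length(g)))
      hs <- c(hs, mean(g == 1))
    }
    r <- length(ns)
    if (r < 2 || mean(ns) <= 1) { perLocus[l] <- NA; next }
    nbar <- mean(ns)
    nc <- (sum(ns) - sum(ns^2) / sum(ns)) / (r - 1)
    pbar <- sum(ns * ps) / sum(ns)
    s2 <- sum(ns * (ps - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ns * hs) / sum(ns)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    perLocus[l] <- a / (a + b + cc)
    sumA <- sumA + a
    sumT <- sumT + a + b + cc
  }
  list(global = sumA / sumT, perLocus = perLocus)
}

# exact Hardy-Weinberg test by direct enumeration of the conditional
# distribution of heterozygote counts (probabilities from first principles)
oracleHweP <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  nB <- 2 * n - nA
  if (nA == 0 || nB == 0) return(1)
  hs <- seq(nA %% 2, min(nA, nB), by = 2)
  pr <- sapply(hs, function(h) {
    naa2 <- (nA - h) / 2
    nbb2 <- (nB - h) / 2
    exp(lgamma(n + 1) - lgamma(naa2 + 1) - lgamma(h + 1) - lgamma(nbb2 + 1) +
          h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1))
  })
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[hs == nAa] * (1 + 1e-9)])
}

# redundancy analysis by explicit normal equations and PCA of fitted values
oracleRda <- function(Y, X) {
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  B <- solve(t(Xc) %*% Xc) %*% t(Xc) %*% Yc
  Yhat <- Xc %*% B
  eig <- eigen(t(Yhat) %*% Yhat / (nrow(Y) - 1), symmetric = TRUE)$values
  eig <- eig[eig > 1e-10]
  list(eigenvalues = eig,
       R2 = sum(Yhat^2) / sum(Yc^2),
       eigSum = sum(Yhat^2) / (nrow(Y) - 1))
}

# random small genotype panel for estimator cross-checks; sharedFreqs = TRUE
# draws one frequency vector for all populations (a true null panel)
randomPanel <- function(nPops, nInd, nLoci, missingRate = 0, seed = 1,
                        sharedFreqs = FALSE) {
  set.seed(seed)
  d <- matrix(NA_real_, nLoci, nPops * nInd)
  pShared <- runif(nLoci, 0.05, 0.95)
  for (k in seq_len(nPops)) {
    p <- if (sharedFreqs) pShared else runif(nLoci, 0.05, 0.95)
    cols <- (k - 1) * nInd + seq_len(nInd)
    d[, cols] <- matrix(rbinom(nLoci * nInd, 2, rep(p, nInd)), nLoci, nInd)
  }
  if (missingRate > 0) d[runif(length(d)) < missingRate] <- NA
  genotypePanel(d, rep(sprintf("P%02d", seq_len(nPops)), each = nInd))
}
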