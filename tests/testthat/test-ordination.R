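test_that("AEM of a chain matches the brute-force construction", {
  P <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  P["A", "B"] <- P["B", "C"] <- P["C", "D"] <- 1
  aem <- buildAem(P)
  expect_equal(nrow(aemEdges(aem)), 3)
  expect_equal(ncol(aemVectors(aem)), 3)
  # brute force: site-by-edge incidence of the chain, centred SVD
  E <- rbind(A = c(0, 0, 0), B = c(1, 0, 0), C = c(1, 1, 0), D = c(1, 1, 1))
  sv <- svd(scale(E, center = TRUE, scale = FALSE))
  keep <- sv$d > 1e-8
  expect_equal(aem@values, sv$d[keep], tolerance = 1e-10)
  for (k in which(keep)) {
    got <- aemVectors(aem)[, k]
    want <- sv$u[, k]
    expect_equal(abs(sum(got * want)), 1, tolerance = 1e-10)  # up to sign
  }
  a1 <- aemVectors(aem)[, 1]
  expect_true(all(diff(a1) > 0) || all(diff(a1) < 0))  # monotone along chain
})

test_that("AEM retention keeps the stronger direction and breaks cycles", {
  P <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  P["A", "B"] <- 0.6; P["B", "A"] <- 0.2
  aem <- buildAem(P)
  e <- aemEdges(aem)
  expect_equal(nrow(e), 1)
  expect_equal(e$from, "A"); expect_equal(e$to, "B")
  expect_equal(ncol(aemVectors(aem)), 1)
  # a 3-cycle of one-way links: weakest edge dropped to reach a DAG
  P3 <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  P3["A", "B"] <- 0.5; P3["B", "C"] <- 0.4; P3["C", "A"] <- 0.1
  aem3 <- buildAem(P3)
  e3 <- aemEdges(aem3)
  expect_equal(nrow(e3), 2)
  expect_false(any(e3$from == "C" & e3$to == "A"))
  g <- crossprod(aemVectors(aem3))
  expect_lt(max(abs(g - diag(ncol(g)))), 1e-8)   # orthonormal
})

test_that("AEM count is n - 1 for a connected path-rich directed graph", {
  n <- 8
  P <- matrix(0, n, n, dimnames = list(paste0("S", 1:n), paste0("S", 1:n)))
  for (i in 1:(n - 1)) P[i, i + 1] <- runif(1, 0.2, 0.8)
  P[1, 3] <- 0.15
  aem <- buildAem(P)
  expect_equal(ncol(aemVectors(aem)), n - 1)
})

test_that("dbMEM eigenvectors behave like Moran eigenvector maps on a transect", {
  xy <- cbind(seq(0, 900, by = 100), 0)
  D <- as.matrix(dist(xy))
  mem <- buildDbmem(D)
  expect_lte(ncol(mem$vectors), 9)
  signChanges <- function(v) sum(diff(sign(v)) != 0)
  pos <- which(mem$moran == "positive")
  expect_equal(signChanges(mem$vectors[, pos[1]]), 1)
  expect_gt(signChanges(mem$vectors[, pos[3]]), signChanges(mem$vectors[, pos[1]]))
  expect_lt(max(abs(crossprod(mem$vectors) - diag(ncol(mem$vectors)))), 1e-8)
  # positive-eigenvalue half agrees with the classical PCNM construction
  pcnm <- vegan::pcnm(as.dist(D), threshold = mem$truncation)
  expect_equal(sum(mem$values > 1e-8), ncol(pcnm$vectors))
  expect_error(buildDbmem(D[1:2, 1:2]), ">= 3")
  # three equidistant collinear sites: at most 2 eigenvectors
  D3 <- as.matrix(dist(cbind(c(0, 100, 200), 0)))
  expect_lte(ncol(buildDbmem(D3)$vectors), 2)
})

test_that("Hellinger transform produces unit-norm rows and preserves zeros", {
  expect_equal(as.vector(hellingerTransform(matrix(c(1, 3), 1))),
               c(0.5, sqrt(3) / 2), tolerance = 1e-12)
  set.seed(2)
  M <- matrix(rpois(60, 3), 6)
  M[2, 4] <- 0
  H <- hellingerTransform(M)
  expect_equal(unname(apply(H, 1, function(r) sum(r^2))), rep(1, 6))
  expect_equal(H[2, 4], 0)
  expect_error(hellingerTransform(rbind(c(1, 2), c(0, 0))), "all-zero")
  expect_error(hellingerTransform(matrix(c(-1, 2), 1)), "nonnegative")
})

test_that("rdaFit matches the normal-equations oracle and vegan", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    Y <- matrix(rnorm(n * sample(3:6, 1)), n)
    X <- matrix(rnorm(n * sample(1:3, 1)), n)
    m <- rdaFit(Y, X)
    o <- oracleRda(Y, X)
    expect_equal(sum(m@eigenvalues), o$eigSum, tolerance = 1e-10)
    expect_equal(m@eigenvalues, o$eigenvalues, tolerance = 1e-10)
    expect_equal(m@R2, o$R2, tolerance = 1e-10)
  }
  Y <- matrix(rnorm(24), 6); X <- matrix(rnorm(12), 6)
  v <- vegan::rda(Y ~ X)
  m <- rdaFit(Y, X)
  expect_equal(unname(m@eigenvalues), unname(v$CCA$eig), tolerance = 1e-10)
  expect_equal(m@R2adj, vegan::RsquareAdj(v)$adj.r.squared, tolerance = 1e-10)
})

test_that("rdaFit handles exact, orthogonal and collinear designs", {
  set.seed(7)
  X <- matrix(rnorm(16), 8)
  Y <- X %*% matrix(c(1, 2, -1, 0.5), 2) + 5
  m <- rdaFit(Y, X)
  expect_equal(m@R2, 1, tolerance = 1e-12)
  expect_equal(m@R2adj, 1, tolerance = 1e-12)
  x <- rnorm(8)
  Yorth <- cbind(residuals(lm(rnorm(8) ~ x)), residuals(lm(rnorm(8) ~ x)))
  expect_lt(rdaFit(Yorth, cbind(x))@R2, 1e-10)
  Xcol <- cbind(a = x, b = 2 * x)
  expect_warning(mc <- rdaFit(Y, Xcol), "aliased")
  expect_equal(ncol(mc@X), 1)
  expect_error(rdaFit(Y, matrix(rnorm(40), 10)), "same number of rows")
})

test_that("RDA permutation p-values are calibrated, bounded and powerful", {
  set.seed(13)
  rej <- logical(150)
  for (s in seq_along(rej)) {
    Y <- matrix(rnorm(10 * 4), 10)
    X <- matrix(rnorm(10 * 2), 10)
    pt <- rdaPermutationTest(rdaFit(Y, X), nPerm = 59, seed = s)
    rej[s] <- pt$p <= 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.05)
  Y <- matrix(rnorm(20 * 3), 20)
  X <- cbind(Y[, 1] + rnorm(20, 0, 0.15))
  strong <- rdaPermutationTest(rdaFit(Y, X), nPerm = 999, seed = 1)
  expect_equal(strong$p, 0.001)
  expect_error(rdaPermutationTest(rdaFit(Y, X), nPerm = 9), "19")
  ax <- rdaPermutationTest(rdaFit(Y, cbind(X, rnorm(20))), nPerm = 99,
                           by = "axis", seed = 2)
  expect_true(all(ax$p >= 1 / 100))
})

test_that("backward selection keeps true predictors and drops noise", {
  set.seed(3)
  kept <- noise <- 0
  for (s in 1:20) {
    n <- 50
    x1 <- rnorm(n)
    Y <- cbind(x1 + rnorm(n, 0, 0.4), -x1 + rnorm(n, 0, 0.4), rnorm(n))
    X <- cbind(X1 = x1, X2 = rnorm(n), X3 = rnorm(n), X4 = rnorm(n),
               X5 = rnorm(n))
    sel <- backwardSelect(Y, X, nPerm = 199, seed = s)
    kept <- kept + ("X1" %in% sel$selected)
    noise <- noise + length(setdiff(sel$selected, "X1"))
  }
  expect_gte(kept / 20, 0.9)
  expect_lte(noise / (20 * 4), 0.15)
  # single perfect predictor: retained at the smallest attainable p
  x <- rnorm(12)
  selP <- backwardSelect(cbind(x, 2 * x), cbind(P = x), nPerm = 199, seed = 1)
  expect_equal(selP$selected, "P")
  expect_equal(unname(rdaPermutationTest(selP$model, nPerm = 199,
                                         by = "margin", seed = 1)$p), 1 / 200)
})

test_that("vector fitting matches axes and rejects constants", {
  set.seed(21)
  scores <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("RDA1", "RDA2")))
  env <- data.frame(ax = scores[, 1], junk = rnorm(10))
  ef <- envfitVectors(scores, env, nPerm = 199, seed = 1)
  expect_equal(ef$r2[ef$variable == "ax"], 1, tolerance = 1e-10)
  expect_true(all(ef$r2 >= 0 & ef$r2 <= 1))
  expect_error(envfitVectors(scores, data.frame(k = rep(1, 10))), "constant")
})

test_that("DAPC separates distinct clusters and returns coherent objects", {
  cfg <- metapopConfig(nDemes = 3, demeSizes = 80, migrationRate = 0.005,
                       nNeutralLoci = 250, nSelectedLoci = 0,
                       nGenerations = 300, sampleSizes = 15,
                       missingRate = 0.02)
  G <- simulateMetapopulation(cfg, seed = 61)
  m <- dapc(G, nRep = 20, seed = 2)
  expect_gte(mean(m@assign == populations(G)), 0.95)
  expect_equal(unname(rowSums(m@posterior)), rep(1, ncol(G)),
               tolerance = 1e-9)
  expect_lte(m@nPca, ncol(G) - 1)
  expect_equal(ncol(m@scores), 2)          # groups - 1 discriminants
  expect_true(all(c("n_pca", "rep", "error") %in% names(m@xval)))
  expect_error(dapc(G, groups = rep("one", ncol(G))), "2 groups")
})
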