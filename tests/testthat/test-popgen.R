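test_that("diversity reproduces Nei's unbiased expected heterozygosity", {
  d <- matrix(c(rep(0, 2), rep(1, 5), rep(2, 3)), nrow = 1)
  G <- genotypePanel(d, rep("A", 10))
  dv <- diversity(G)
  expect_equal(dv$Ho, 0.5)
  expect_equal(dv$He, 2 * 0.45 * 0.55 * 20 / 19, tolerance = 1e-12)
  expect_equal(dv$FIS, 1 - 0.5 / (2 * 0.45 * 0.55 * 20 / 19), tolerance = 1e-12)
  allHet <- genotypePanel(matrix(1, 1, 8), rep("A", 8))
  dvH <- diversity(allHet)
  expect_equal(dvH$Ho, 1)
  expect_lt(dvH$FIS, 0)
  mono <- genotypePanel(matrix(0, 1, 8), rep("A", 8))
  expect_true(is.na(diversity(mono)$FIS))
})

test_that("wcFst handles the boundary cases", {
  fixed <- genotypePanel(cbind(matrix(0, 3, 10), matrix(2, 3, 10)),
                         rep(c("A", "B"), each = 10))
  expect_equal(wcFst(fixed), 1)
  same <- matrix(rbinom(30, 2, 0.5), 3, 10)
  ident <- genotypePanel(cbind(same, same), rep(c("A", "B"), each = 10))
  expect_lte(wcFst(ident), 0.001)
  expect_error(wcFst(genotypePanel(matrix(0:2, 3, 4), rep("A", 4))),
               ">= 2 populations")
})

test_that("wcFst equals the independent variance-component oracle", {
  # a hand-checkable two-population pair plus random panels with and without missingness
  d <- matrix(c(rep(0, 6), rep(1, 3), 2, 0, rep(1, 3), rep(2, 6)), nrow = 1)
  G <- genotypePanel(d, rep(c("A", "B"), each = 10))
  o <- oracleWcTheta(list(t(dosage(G)[, 1:10, drop = FALSE]),
                          t(dosage(G)[, 11:20, drop = FALSE])))
  expect_equal(wcFst(G), o$global, tolerance = 1e-12)
  for (s in 1:20) {
    G2 <- randomPanel(nPops = 2 + s %% 3, nInd = 8 + s %% 5, nLoci = 15,
                      missingRate = ifelse(s %% 2, 0.1, 0), seed = 200 + s)
    pops <- populations(G2)
    popD <- lapply(unique(pops), function(p) t(dosage(G2)[, pops == p]))
    o2 <- oracleWcTheta(popD)
    expect_equal(wcFst(G2), o2$global, tolerance = 1e-12)
    expect_equal(unname(wcFst(G2, "per_locus")), o2$perLocus,
                 tolerance = 1e-12)
  }
})

test_that("pairwise FST is symmetric with coherent inference columns", {
  G <- randomPanel(3, 10, 40, seed = 17)
  fst <- pairwiseFst(G, nPerm = 49, nBoot = 99, seed = 2)
  pw <- fst@pairwise
  expect_equal(pw, t(pw))
  expect_equal(unname(diag(pw)), rep(0, 3))
  up <- upper.tri(pw)
  expect_true(all(fst@p[up] >= 1 / 50))
  expect_true(all(fst@pAdj[up] >= fst@p[up]))           # BH never lowers
  ordRaw <- order(fst@p[up]); adj <- fst@pAdj[up][ordRaw]
  expect_true(all(diff(cummax(adj)) >= 0))              # order-preserving
  expect_true(all(fst@ciLower[up] <= pw[up] + 1e-9))
  expect_true(all(fst@ciUpper[up] >= pw[up] - 1e-9))
})

test_that("pairwise permutation p-values are calibrated under the null", {
  rej <- logical(120)
  for (s in seq_along(rej)) {
    G <- randomPanel(2, 12, 30, seed = 4000 + s, sharedFreqs = TRUE)
    fst <- pairwiseFst(G, nPerm = 39, nBoot = 0, seed = s)
    rej[s] <- fst@p[1, 2] <= 0.05
  }
  # alpha = 0.05 at 39 perms means p = 1/40 or 2/40; binomial check
  expect_lt(mean(rej), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 120))
  expect_gt(mean(rej), 0.001)
})

test_that("amova decomposes variance coherently and detects planted groups", {
  M <- matrix(0, 4, 4); M[1, 2] <- M[2, 1] <- M[3, 4] <- M[4, 3] <- 0.2
  diag(M) <- 0.8
  cfg <- metapopConfig(nDemes = 4, demeSizes = 100, migrationMatrix = M,
                       nNeutralLoci = 200, nSelectedLoci = 0,
                       nGenerations = 120, sampleSizes = 15,
                       missingRate = 0.02)
  G <- simulateMetapopulation(cfg, seed = 5)
  grp <- setNames(c("g1", "g1", "g2", "g2"), paste0("P0", 1:4))
  a <- amova(G, grp, nPerm = 199, scheme = "individual", seed = 1)
  expect_gt(a@phi["FCT"], 0.1)
  expect_lte(a@p, 0.005 + 1e-9)
  expect_equal(sum(a@percent), 100)
  expect_equal(unname(a@phi["FCT"]),
               unname(a@components["amongGroups"] / sum(a@components)))
  # panmictic null
  cfgN <- metapopConfig(nDemes = 4, demeSizes = 300, migrationRate = 0.5,
                        nNeutralLoci = 150, nSelectedLoci = 0,
                        nGenerations = 40, sampleSizes = 15, missingRate = 0)
  GN <- simulateMetapopulation(cfgN, seed = 6)
  aN <- amova(GN, grp, nPerm = 199, scheme = "individual", seed = 1)
  expect_lt(abs(aN@phi["FCT"]), 0.02)
  expect_gt(aN@p, 0.05)
  expect_error(amova(G, setNames(rep("g", 4), paste0("P0", 1:4))), "2 groups")
})

test_that("Mantel IBD recovers a perfect monotone relation and stays bounded", {
  geo <- as.matrix(dist(cbind(c(0, 100, 250, 500, 900), 0)))
  fstM <- log(geo + 1) / 50
  fstM <- fstM / (1 + fstM)     # any increasing transform of log distance
  diag(fstM) <- 0
  res <- mantelIbd(fstM, geo, nPerm = 199, seed = 1)
  expect_equal(res$r, 1, tolerance = 1e-6)
  expect_true(res$r >= -1 && res$r <= 1)
  expect_error(mantelIbd(matrix(0.1, 5, 5) - diag(0.1, 5), geo * 0 + 1),
               "constant")
})

test_that("LD-Ne returns Inf below the sampling floor and recovers truth", {
  # frequency-engine data carry no pedigree LD: estimate must be huge/Inf
  cfg <- metapopConfig(nDemes = 1, demeSizes = 500,
                       migrationMatrix = matrix(1, 1, 1),
                       nNeutralLoci = 120, nSelectedLoci = 0,
                       nGenerations = 5, sampleSizes = 40, missingRate = 0)
  G <- simulateMetapopulation(cfg, seed = 31)
  ne0 <- neLd(G)
  expect_gt(ne0@estimate, 300)
  # pedigree engine, true Ne = 50
  cfg1 <- metapopConfig(nDemes = 1, demeSizes = 50,
                        migrationMatrix = matrix(1, 1, 1),
                        nNeutralLoci = 300, nSelectedLoci = 0,
                        nGenerations = 60, sampleSizes = 50, missingRate = 0)
  G1 <- simulateMetapopulation(cfg1, seed = 32, engine = "individual")
  ne1 <- neLd(G1)
  expect_true(ne1@estimate > 20 && ne1@estimate < 120)
  expect_lte(ne1@ciLower, ne1@estimate)
  expect_gte(ne1@ciUpper, ne1@estimate)
  expect_error(neLd(G1[1, ]), "2 usable loci")
})

test_that("relative migration normalises to 1 and resolves planted asymmetry", {
  set.seed(44)
  d <- matrix(rbinom(60 * 20, 2, rep(runif(60, 0.2, 0.8), 20)), 60, 20)
  Gsame <- genotypePanel(cbind(d, d), rep(c("A", "B"), each = 20))
  rm0 <- relativeMigration(Gsame, nBoot = 20, seed = 1)
  expect_equal(unname(rm0@m[1, 2]), 1)
  expect_equal(unname(rm0@m[2, 1]), 1)
  expect_error(relativeMigration(genotypePanel(matrix(1, 2, 4),
                                               c("A", "A", "B", "B"))),
               ">= 3")
  # strong one-way migration A -> B: B resembles the migrant pool
  wins <- 0
  for (s in 1:10) {
    M <- matrix(c(0.99, 0.01, 0.1, 0.9), 2, 2, byrow = TRUE)
    cfg <- metapopConfig(nDemes = 2, demeSizes = 150, migrationMatrix = M,
                         nNeutralLoci = 200, nSelectedLoci = 0,
                         nGenerations = 150, sampleSizes = 20, missingRate = 0)
    G <- simulateMetapopulation(cfg, seed = 500 + s)
    rmA <- relativeMigration(G, nBoot = 0, seed = s)
    if (rmA@m["P01", "P02"] > rmA@m["P02", "P01"]) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("directionality is poorly resolved in high gene-flow systems", {
  sig <- 0
  for (s in 1:6) {
    M <- matrix(c(1 - 0.02, 0.02, 0.2, 0.8), 2, 2, byrow = TRUE)
    cfg <- metapopConfig(nDemes = 2, demeSizes = 400, migrationMatrix = M,
                         nNeutralLoci = 150, nSelectedLoci = 0,
                         nGenerations = 80, sampleSizes = 18, missingRate = 0)
    G <- simulateMetapopulation(cfg, seed = 700 + s)
    rmB <- relativeMigration(G, nBoot = 60, seed = s)
    if (rmB@significant["P01", "P02"] || rmB@significant["P02", "P01"])
      sig <- sig + 1
  }
  expect_lte(sig / 6, 0.5)
})
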