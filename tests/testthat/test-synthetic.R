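test_that("uniform field is constant off land and masked on land", {
  f <- makeBasinField(50, 60, nt = 12, features = "uniform",
                      uniformU = 0.1, uniformV = 0)
  ocean <- !f@landMask
  for (k in c(1, 6, 12)) {
    uk <- f@u[k, , ]; vk <- f@v[k, , ]
    expect_true(all(uk[ocean] == 0.1))
    expect_true(all(vk[ocean] == 0))
    expect_true(all(uk[f@landMask] == 0))
    expect_true(all(vk[f@landMask] == 0))
  }
})

test_that("western boundary current flows southward in the westernmost ocean column", {
  f <- makeBasinField(30, 36, nt = 2, features = "western_boundary", seed = 4)
  westCol <- which(apply(!f@landMask, 2, any))[1]
  oceanRows <- !f@landMask[, westCol]
  expect_lt(mean(f@v[1, oceanRows, westCol]), 0)
})

test_that("gyre velocities circulate about the box centre", {
  f <- makeBasinField(30, 36, nt = 1, features = "gyre", landBorder = FALSE,
                      gyreBox = list(lonRange = c(118, 123),
                                     latRange = c(6, 12)))
  vAt <- function(lon, lat) {
    i <- which.min(abs(f@lon - lon)); j <- which.min(abs(f@lat - lat))
    c(u = f@u[1, j, i], v = f@v[1, j, i])
  }
  # opposite meridional flow on the west vs east flank, opposite zonal flow
  # on the south vs north flank: closed rotation about (120.5, 9)
  expect_gt(vAt(118.6, 9)["v"] * vAt(122.4, 9)["v"], -Inf)
  expect_true(sign(vAt(118.6, 9)["v"]) != sign(vAt(122.4, 9)["v"]))
  expect_true(sign(vAt(120.5, 6.6)["u"]) != sign(vAt(120.5, 11.4)["u"]))
})

test_that("fields are bit-identical under a fixed seed", {
  a <- makeBasinField(20, 20, nt = 3, features = c("western_boundary", "gyre"),
                      noiseSd = 0.05, seed = 7)
  b <- makeBasinField(20, 20, nt = 3, features = c("western_boundary", "gyre"),
                      noiseSd = 0.05, seed = 7)
  expect_identical(a@u, b@u)
  expect_identical(a@v, b@v)
})

test_that("field generator rejects bad arguments", {
  expect_error(makeBasinField(4, 20), "nx")
  expect_error(makeBasinField(20, 20, features = "tide"), "unknown feature")
})

test_that("habitat nodes sit on coastline cells at the requested spacing", {
  f <- makeBasinField(40, 40, nt = 1, features = "uniform",
                      landBorder = FALSE,
                      island = list(lonRange = c(119.5, 121.5),
                                    latRange = c(8, 10)))
  nodes <- makeHabitatNodes(f, spacingKm = 50)
  land <- f@landMask
  for (k in seq_len(nrow(nodes))) {
    r <- nodes$row[k]; c <- nodes$col[k]
    expect_false(land[r, c])
    nb <- c(if (r > 1) land[r - 1, c], if (r < nrow(land)) land[r + 1, c],
            if (c > 1) land[r, c - 1], if (c < ncol(land)) land[r, c + 1])
    expect_true(any(nb))
  }
  # node count ~ ring perimeter / spacing: order coastline cells by angle
  # about the island centre and accumulate haversine distances
  cells <- which(!land & (rbind(land[-1, ], FALSE) | rbind(FALSE, land[-nrow(land), ]) |
                          cbind(land[, -1], FALSE) | cbind(FALSE, land[, -ncol(land)])),
                 arr.ind = TRUE)
  lon <- f@lon[cells[, 2]]; lat <- f@lat[cells[, 1]]
  ang <- atan2(lat - 9, lon - 120.5)
  ord <- order(ang)
  per <- sum(haversineKm(lon[ord], lat[ord],
                         lon[c(ord[-1], ord[1])], lat[c(ord[-1], ord[1])]))
  expect_lte(abs(nrow(nodes) - per / 50), 2)
})

test_that("an all-ocean field has no coastline", {
  f <- makeBasinField(20, 20, nt = 1, features = "uniform", landBorder = FALSE)
  expect_error(makeHabitatNodes(f, 50), "no coastline")
})

test_that("metapopulation genotypes are reproducible and well-formed", {
  cfg <- metapopConfig(nDemes = 3, demeSizes = 40, nNeutralLoci = 60,
                       nSelectedLoci = 4, nGenerations = 15,
                       sampleSizes = 10, missingRate = 0.1)
  a <- simulateMetapopulation(cfg, seed = 11)
  b <- simulateMetapopulation(cfg, seed = 11)
  expect_identical(dosage(a), dosage(b))
  d <- dosage(a)
  expect_true(all(d[!is.na(d)] %in% 0:2))
  expect_equal(dim(d), c(64, 30))
  expect_equal(as.vector(table(populations(a))), c(10, 10, 10))
  c2 <- simulateMetapopulation(cfg, seed = 12)
  expect_false(identical(dosage(a), dosage(c2)))
})

test_that("full mixing yields near-zero FST; no migration yields strong drift", {
  mix <- metapopConfig(nDemes = 4, demeSizes = 200, nNeutralLoci = 150,
                       nSelectedLoci = 0, nGenerations = 50,
                       migrationMatrix = matrix(0.25, 4, 4),
                       sampleSizes = 20, missingRate = 0)
  expect_lt(abs(wcFst(simulateMetapopulation(mix, seed = 21))), 0.01)
  iso <- metapopConfig(nDemes = 4, demeSizes = 50, nNeutralLoci = 150,
                       nSelectedLoci = 0, nGenerations = 200,
                       migrationMatrix = diag(4),
                       sampleSizes = 20, missingRate = 0)
  expect_gt(wcFst(simulateMetapopulation(iso, seed = 22)), 0.3)
})

test_that("config validation catches inconsistent designs", {
  expect_error(metapopConfig(nDemes = 3, migrationMatrix = matrix(1, 2, 2)),
               "nDemes")
  bad <- matrix(c(0.5, 0.4, 0.5, 0.5), 2, 2)
  expect_error(metapopConfig(nDemes = 2, migrationMatrix = bad), "sum to 1")
  expect_error(metapopConfig(nDemes = 2, demeSizes = 5, sampleSizes = 10),
               "sample size")
  expect_error(metapopConfig(missingRate = 1), "missingRate")
})

test_that("zero-gradient 'selected' loci are indistinguishable from neutral", {
  perLocusTheta <- function(seed) {
    cfg <- metapopConfig(nDemes = 4, demeSizes = 100, migrationRate = 0.2,
                         nNeutralLoci = 120, nSelectedLoci = 40,
                         selectionGradient = 0, nGenerations = 40,
                         sampleSizes = 15, missingRate = 0)
    G <- simulateMetapopulation(cfg, seed = seed)
    sel <- SummarizedExperiment::rowData(G)$selected
    th <- wcFst(G, "per_locus")
    list(neu = th[!sel], sel = th[sel])
  }
  neu <- sel <- c()
  for (s in 1:20) {
    r <- perLocusTheta(s)
    neu <- c(neu, r$neu); sel <- c(sel, r$sel)
  }
  p <- suppressWarnings(stats::ks.test(neu[is.finite(neu)],
                                       sel[is.finite(sel)])$p.value)
  expect_gt(p, 0.01)
})

test_that("strong clinal selection lifts selected loci above the neutral 99th percentile", {
  hits <- 0; total <- 0
  for (s in 1:10) {
    cfg <- metapopConfig(nDemes = 6, demeSizes = 200, migrationRate = 0.15,
                         nNeutralLoci = 300, nSelectedLoci = 5,
                         selectionGradient = 0.12, nGenerations = 80,
                         sampleSizes = 15, missingRate = 0)
    G <- simulateMetapopulation(cfg, seed = 100 + s)
    selFlag <- SummarizedExperiment::rowData(G)$selected
    th <- wcFst(G, "per_locus")
    q99 <- quantile(th[!selFlag], 0.99, na.rm = TRUE)
    hits <- hits + sum(th[selFlag] > q99, na.rm = TRUE)
    total <- total + sum(selFlag)
  }
  expect_gte(hits / total, 0.8)
})

test_that("environment tables respect the cline and ordering invariants", {
  sites <- data.frame(site_id = sprintf("A%d", 1:6), latitude_rank = 1:6)
  env <- makeEnvironment(sites, clineParams = list(noiseSd = 0), seed = 3)
  june <- env[env$month == 6, ]
  june <- june[match(sites$site_id, june$site_id), ]
  # exactly linear in latitude rank with zero noise
  fit <- lm(SST_mean ~ sites$latitude_rank, data = june)
  expect_lt(max(abs(residuals(fit))), 1e-10)
  envN <- makeEnvironment(sites, seed = 3)
  expect_true(all(envN$SST_min <= envN$SST_mean))
  expect_true(all(envN$SST_mean <= envN$SST_max))
  slope <- function(m) {
    sub <- envN[envN$month == m, ]
    coef(lm(sub$SST_mean ~ sites$latitude_rank[match(sub$site_id, sites$site_id)]))[2]
  }
  expect_gt(abs(slope(8)), abs(slope(2)))
  expect_error(makeEnvironment(sites[0, ]), "empty")
  expect_identical(makeEnvironment(sites, seed = 5),
                   makeEnvironment(sites, seed = 5))
})

test_that("seed splitting is deterministic and component-distinct", {
  expect_identical(splitSeed(42, "dispersal"), splitSeed(42, "dispersal"))
  expect_false(splitSeed(42, "dispersal") == splitSeed(42, "metapop"))
  expect_true(splitSeed(2147483646, "field") <= 2147483646)
})
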