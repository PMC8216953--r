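uniformField <- function(u = 0.1, v = 0)
  makeBasinField(30, 30, nt = 1, features = "uniform", uniformU = u,
                 uniformV = v, landBorder = FALSE)

test_that("uniform-current displacement matches u * t to 0.1%", {
  f <- uniformField(0.1, 0)
  pos <- c(120, 9)
  for (k in 1:24) pos <- advectParticle(f, pos, (k - 1) / 24, 1 / 24)$position
  dist <- haversineKm(120, 9, pos[1], pos[2])
  expect_lt(abs(dist - 8.64) / 8.64, 0.001)
  expect_gt(pos[1], 120)            # eastward
  expect_equal(pos[2], 9, tolerance = 1e-6)
})

test_that("zero field leaves particles in place; dt must be positive", {
  f <- uniformField(0, 0)
  st <- advectParticle(f, c(119, 8), 0, 0.5)
  expect_equal(st$position, c(119, 8))
  expect_identical(st$status, "ok")
  expect_error(advectParticle(f, c(119, 8), 0, -1), "dt")
})

test_that("solid-body rotation closes within 1% of the start radius per period", {
  period <- 10
  f <- makeBasinField(40, 40, nt = 1, features = "solid_body",
                      solidBodyPeriodDays = period, landBorder = FALSE)
  centre <- c(mean(f@lon), mean(f@lat))
  start <- centre + c(0.6, 0)
  pos <- start
  for (k in seq_len(period * 24))
    pos <- advectParticle(f, pos, (k - 1) / 24, 1 / 24)$position
  r0 <- haversineKm(centre[1], centre[2], start[1], start[2])
  r1 <- haversineKm(centre[1], centre[2], pos[1], pos[2])
  expect_lt(abs(r1 - r0) / r0, 0.01)
  expect_lt(haversineKm(start[1], start[2], pos[1], pos[2]) / r0, 0.02)
})

test_that("halving the step changes smooth-field endpoints by < 0.5%", {
  f <- makeBasinField(40, 40, nt = 1, features = "solid_body",
                      solidBodyPeriodDays = 8, landBorder = FALSE)
  run <- function(dtH) {
    pos <- c(mean(f@lon) + 0.5, mean(f@lat) + 0.2)
    steps <- 5 * 24 / dtH
    for (k in seq_len(steps))
      pos <- advectParticle(f, pos, (k - 1) * dtH / 24, dtH / 24)$position
    pos
  }
  a <- run(2); b <- run(1)
  travelled <- 2 * pi * haversineKm(mean(f@lon), mean(f@lat),
                                    mean(f@lon) + 0.5, mean(f@lat) + 0.2) * 5 / 8
  expect_lt(haversineKm(a[1], a[2], b[1], b[2]) / travelled, 0.005)
})

test_that("particles entering land are reflected and flagged; leaving the grid is lost", {
  f <- makeBasinField(20, 20, nt = 1, features = "uniform",
                      uniformU = 1.5, uniformV = 0)   # fast eastward
  # start just west of the eastern land ring and walk into the coast
  iOcean <- which(apply(!f@landMask, 2, any))
  lonNearCoast <- f@lon[iOcean[length(iOcean)]]
  latMid <- f@lat[10]
  pos <- c(lonNearCoast, latMid)
  status <- "ok"
  for (k in 1:48) {
    st <- advectParticle(f, pos, (k - 1) / 12, 1 / 12)
    if (st$status != "ok") { status <- st$status; break }
    pos <- st$position
  }
  expect_identical(status, "stranded")
  expect_equal(st$position, pos)   # reflected back to last ocean position
  fNoLand <- uniformField(3, 0)
  st2 <- advectParticle(fNoLand, c(max(fNoLand@lon) - 0.01, latMid), 0, 2)
  expect_identical(st2$status, "lost")
})

test_that("deterministic thinning halves the cohort exactly at the mortality day", {
  f <- uniformField(0, 0)
  sites <- data.frame(site_id = "A", lon = 120, lat = 9)
  sched <- releaseSchedule(sites, particlesPerRelease = 1000,
                           intervalDays = 7, durationDays = 1)
  traits <- particleTraits(settlementRadiusKm = 5)
  nodes <- data.frame(node_id = "N1", lon = 123, lat = 12)  # out of reach
  fates <- runDispersal(f, sched, traits, nodes, seed = 1, dtHours = 6,
                        thinning = "deterministic")
  expect_equal(sum(fates$fate == "dead"), 500)
  expect_true(all(fates$day[fates$fate == "dead"] == 4))
  expect_equal(sum(fates$fate == "expired"), 500)
  expect_equal(nrow(fates), 1000)
})

test_that("competency gates settlement: none before day 20, survivors settle on day 20", {
  f <- uniformField(0, 0)
  sites <- data.frame(site_id = "A", lon = 120, lat = 9)
  sched <- releaseSchedule(sites, particlesPerRelease = 400,
                           intervalDays = 7, durationDays = 1)
  traits <- particleTraits(settlementRadiusKm = 10)
  nodes <- data.frame(node_id = "N1", lon = 120, lat = 9)  # on release point
  fates <- runDispersal(f, sched, traits, nodes, seed = 2, dtHours = 6,
                        thinning = "deterministic")
  settled <- fates[fates$fate == "settled", ]
  expect_equal(nrow(settled), 200)           # all post-mortality survivors
  expect_true(all(settled$day == 20))
  expect_true(all(settled$node == "N1"))
})

test_that("fates always conserve the released count", {
  f <- makeBasinField(25, 25, nt = 2, features = c("western_boundary"),
                      noiseSd = 0.02, seed = 5)
  sites <- data.frame(site_id = c("A", "B"),
                      lon = c(f@lon[3], f@lon[3]),
                      lat = c(f@lat[18], f@lat[8]))
  sched <- releaseSchedule(sites, particlesPerRelease = 150,
                           intervalDays = 10, durationDays = 20)
  traits <- particleTraits(settlementRadiusKm = 25)
  nodes <- makeHabitatNodes(f, 80)
  fates <- runDispersal(f, sched, traits, nodes, seed = 3, dtHours = 4)
  expect_equal(nrow(fates), 2 * 2 * 150)
  expect_true(all(fates$fate %in% c("settled", "dead", "lost", "expired")))
  counts <- table(fates$source)
  expect_true(all(counts == 300))
})

test_that("a pure southward current yields strictly asymmetric connectivity", {
  f <- makeBasinField(20, 40, nt = 1, features = "uniform",
                      uniformU = 0, uniformV = -0.25)
  # N and S sites on the same meridian, ~480 km apart: 20 days at 21.6 km/day
  north <- c(120.5, 11); south <- c(120.5, 6.7)
  sites <- data.frame(site_id = c("N", "S"), lon = c(north[1], south[1]),
                      lat = c(north[2], south[2]))
  nodes <- data.frame(node_id = c("nN", "nS"), lon = sites$lon, lat = sites$lat)
  sched <- releaseSchedule(sites, particlesPerRelease = 60,
                           intervalDays = 7, durationDays = 1)
  traits <- particleTraits(settlementRadiusKm = 60)
  fates <- runDispersal(f, sched, traits, nodes, seed = 4, dtHours = 6)
  C <- buildConnectivity(fates, nodes, sites, poolingRadiusKm = 75)
  expect_gt(connProb(C)["N", "S"], 0)
  expect_equal(connProb(C)["S", "N"], 0)
})

test_that("connectivity arithmetic, pooling and normalisation follow the contracts", {
  nodes <- data.frame(node_id = c("X", "Y", "Z"),
                      lon = c(120, 120.1, 122.8), lat = c(9, 9.05, 10.8))
  sites <- data.frame(site_id = c("P1", "P2"), lon = c(120, 122.8),
                      lat = c(9, 10.8))
  fates <- data.frame(
    source = "P1", release_day = 0, particle = 1:1000,
    fate = c(rep("settled", 450), rep("dead", 550)),
    node = c(rep("X", 300), rep("Y", 100), rep("Z", 50), rep(NA, 550)),
    day = 21, stranded = FALSE)
  C <- buildConnectivity(fates, nodes, sites, poolingRadiusKm = 75)
  expect_equal(connProb(C)["P1", "P1"], 0.40)
  expect_equal(connProb(C)["P1", "P2"], 0.05)
  expect_equal(unname(connReleased(C)["P1"]), 1000)
  Cs <- buildConnectivity(fates, nodes, sites, poolingRadiusKm = 75,
                          normalize = "settled")
  expect_equal(connProb(Cs)["P1", "P1"], 400 / 450)
  badFates <- fates; badFates$node[1] <- "QQ"
  expect_error(buildConnectivity(badFates, nodes, sites), "unknown node")
  noneFates <- fates; noneFates$fate <- "dead"; noneFates$node <- NA
  C0 <- buildConnectivity(noneFates, nodes, sites)
  expect_true(all(connProb(C0) == 0))
  expect_equal(unname(connReleased(C0)["P1"]), 1000)
})

test_that("isolated site shows complete self-recruitment on settled-normalised output", {
  nodes <- data.frame(node_id = "home", lon = 120, lat = 9)
  sites <- data.frame(site_id = "TW", lon = 120, lat = 9)
  fates <- data.frame(source = "TW", release_day = 0, particle = 1:100,
                      fate = c(rep("settled", 30), rep("dead", 70)),
                      node = c(rep("home", 30), rep(NA, 70)),
                      day = 22, stranded = FALSE)
  C <- buildConnectivity(fates, nodes, sites, normalize = "settled")
  expect_equal(unname(selfRecruitment(C)["TW"]), 1.0)
})

test_that("schedules and traits validate their invariants", {
  sites <- data.frame(site_id = "A", lon = 120, lat = 9)
  expect_error(releaseSchedule(sites, intervalDays = 0), "intervalDays")
  expect_error(releaseSchedule(sites, offshoreOffsetKm = 20), "12")
  expect_error(particleTraits(mortalityDay = 25), "mortalityDay")
  expect_error(particleTraits(mortalitySurvivalFraction = 0), "Fraction")
  f <- uniformField(0, 0)
  sched <- releaseSchedule(sites, particlesPerRelease = 10,
                           intervalDays = 7, durationDays = 1)
  expect_error(runDispersal(f, sched, particleTraits(), NULL, seed = 1),
               "empty node")
})
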