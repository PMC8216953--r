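#' Larval particle traits
#'
#' Biological behaviour of simulated larvae: competency window, one-time
#' early mortality, and radius-based settlement detection.
#'
#' @param competencyStartDay age (days) at which larvae become competent to
#'   settle.
#' @param maxPldDay maximum pelagic larval duration (days).
#' @param mortalityDay age at which the cohort is thinned once.
#' @param mortalitySurvivalFraction fraction surviving the thinning.
#' @param settlementRadiusKm settlement detection radius around a node.
#' @return list of class `ParticleTraits`.
#' @export
particleTraits <- function(competencyStartDay = 20, maxPldDay = 30,
                           mortalityDay = 4, mortalitySurvivalFraction = 0.5,
                           settlementRadiusKm = 10) {
  if (!(0 < mortalityDay && mortalityDay < competencyStartDay &&
        competencyStartDay <= maxPldDay))
    stop("need 0 < mortalityDay < competencyStartDay <= maxPldDay")
  if (mortalitySurvivalFraction <= 0 || mortalitySurvivalFraction > 1)
    stop("mortalitySurvivalFraction must be in (0, 1]")
  if (settlementRadiusKm <= 0) stop("settlementRadiusKm must be > 0")
  structure(list(competencyStartDay = competencyStartDay,
                 maxPldDay = maxPldDay, mortalityDay = mortalityDay,
                 mortalitySurvivalFraction = mortalitySurvivalFraction,
                 settlementRadiusKm = settlementRadiusKm),
            class = "ParticleTraits")
}

#' Particle release schedule
#'
#' @param sites data.frame with `site_id`, `lon`, `lat` release sites.
#' @param particlesPerRelease particles per site per release event.
#' @param intervalDays days between release events (releases happen on days
#'   0, `intervalDays`, ... strictly below `durationDays`).
#' @param durationDays release window length.
#' @param offshoreOffsetKm maximum offshore adjustment of release points
#'   (release points are moved to the nearest ocean cell within this range).
#' @return list of class `ReleaseSchedule`.
#' @export
releaseSchedule <- function(sites, particlesPerRelease = 50000,
                            intervalDays = 7, durationDays = 365,
                            offshoreOffsetKm = 12) {
  if (intervalDays <= 0) stop("intervalDays must be > 0")
  if (offshoreOffsetKm > 12) stop("offshoreOffsetKm must be <= 12")
  stopifnot(all(c("site_id", "lon", "lat") %in% names(sites)))
  structure(list(sites = sites, particlesPerRelease = particlesPerRelease,
                 intervalDays = intervalDays, durationDays = durationDays,
                 offshoreOffsetKm = offshoreOffsetKm),
            class = "ReleaseSchedule")
}

# bilinear space / linear time interpolation of (u, v) at particle positions;
# NA for positions outside the grid
fieldVelocity <- function(field, lon, lat, t) {
  nx <- length(field@lon); ny <- length(field@lat); nt <- length(field@time)
  out <- list(u = rep(NA_real_, length(lon)), v = rep(NA_real_, length(lon)))
  inside <- !is.na(lon) & !is.na(lat) &
            lon >= field@lon[1] & lon <= field@lon[nx] &
            lat >= field@lat[1] & lat <= field@lat[ny]
  if (!any(inside)) return(out)
  lo <- lon[inside]; la <- lat[inside]
  i0 <- pmin(pmax(findInterval(lo, field@lon), 1L), nx - 1L)
  j0 <- pmin(pmax(findInterval(la, field@lat), 1L), ny - 1L)
  fx <- (lo - field@lon[i0]) / (field@lon[i0 + 1] - field@lon[i0])
  fy <- (la - field@lat[j0]) / (field@lat[j0 + 1] - field@lat[j0])
  tc <- min(max(t, field@time[1]), field@time[nt])
  k0 <- if (nt == 1) 1L else pmin(pmax(findInterval(tc, field@time), 1L), nt - 1L)
  ft <- if (nt == 1) 0 else (tc - field@time[k0]) / (field@time[k0 + 1] - field@time[k0])
  bil <- function(a, k) {
    v00 <- a[cbind(k, j0, i0)];     v01 <- a[cbind(k, j0, i0 + 1L)]
    v10 <- a[cbind(k, j0 + 1L, i0)]; v11 <- a[cbind(k, j0 + 1L, i0 + 1L)]
    (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
  }
  u <- bil(field@u, k0); v <- bil(field@v, k0)
  if (nt > 1 && any(ft > 0)) {
    u <- (1 - ft) * u + ft * bil(field@u, k0 + 1L)
    v <- (1 - ft) * v + ft * bil(field@v, k0 + 1L)
  }
  out$u[inside] <- u; out$v[inside] <- v
  out
}

# vectorised RK4 step; returns new positions plus per-particle status:
# 0 ok, 1 lost (left grid), 2 stranded (entered land; reverted)
advectStep <- function(field, lon, lat, t, dtSec) {
  degRate <- function(lo, la, tt) {
    vel <- fieldVelocity(field, lo, la, tt)
    list(dlon = vel$u / (EARTH_M_PER_DEG_LON_EQ * cos(la * pi / 180)),
         dlat = vel$v / EARTH_M_PER_DEG_LAT)
  }
  tDay <- dtSec / 86400
  k1 <- degRate(lon, lat, t)
  k2 <- degRate(lon + k1$dlon * dtSec / 2, lat + k1$dlat * dtSec / 2, t + tDay / 2)
  k3 <- degRate(lon + k2$dlon * dtSec / 2, lat + k2$dlat * dtSec / 2, t + tDay / 2)
  k4 <- degRate(lon + k3$dlon * dtSec, lat + k3$dlat * dtSec, t + tDay)
  newLon <- lon + dtSec / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon)
  newLat <- lat + dtSec / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat)
  status <- integer(length(lon))
  ci <- cellIndex(field@lon, newLon)
  cj <- cellIndex(field@lat, newLat)
  lost <- is.na(ci) | is.na(cj) | is.na(newLon) | is.na(newLat)
  status[lost] <- 1L
  onLand <- rep(FALSE, length(lon))
  idx <- which(!lost)
  if (length(idx))
    onLand[idx] <- field@landMask[cbind(cj[idx], ci[idx])]
  status[onLand] <- 2L
  newLon[onLand] <- lon[onLand]   # reflect to last ocean position
  newLat[onLand] <- lat[onLand]
  list(lon = newLon, lat = newLat, status = status)
}

#' Advect a single particle one time step
#'
#' Fourth-order Runge-Kutta integration of the interpolated velocity field
#' (bilinear in space, linear in time), with metres-to-degrees conversion
#' using the local cosine-of-latitude correction. A particle stepping onto
#' land is reflected back to its last ocean position and flagged
#' `"stranded"`; one leaving the grid is flagged `"lost"`.
#'
#' @param field a [VelocityField-class].
#' @param position numeric `c(lon, lat)` inside the grid.
#' @param t time (days since field start).
#' @param dt step in days (> 0).
#' @return list with `position` (lon, lat) and `status` one of `"ok"`,
#'   `"lost"`, `"stranded"`.
#' @export
advectParticle <- function(field, position, t, dt) {
  if (dt <= 0) stop("dt must be > 0")
  st <- advectStep(field, position[1], position[2], t, dt * 86400)
  list(position = c(st$lon, st$lat),
       status = c("ok", "lost", "stranded")[st$status + 1L])
}

# move release sites to the nearest ocean cell centre within offsetKm
adjustReleasePoints <- function(field, sites, offsetKm) {
  ocean <- which(!field@landMask, arr.ind = TRUE)
  oLon <- field@lon[ocean[, "col"]]
  oLat <- field@lat[ocean[, "row"]]
  lon <- numeric(nrow(sites)); lat <- numeric(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    dd <- haversineKm(sites$lon[i], sites$lat[i], oLon, oLat)
    j <- which.min(dd)
    if (dd[j] > max(offsetKm, 1e-9)) {
      ci <- cellIndex(field@lon, sites$lon[i])
      cj <- cellIndex(field@lat, sites$lat[i])
      onOcean <- !is.na(ci) && !is.na(cj) && !field@landMask[cj, ci]
      if (!onOcean)
        stop("schedule site ", sites$site_id[i], " is on land and no ocean ",
             "cell lies within the offshore offset")
      lon[i] <- sites$lon[i]; lat[i] <- sites$lat[i]
    } else {
      lon[i] <- oLon[j]; lat[i] <- oLat[j]
    }
  }
  data.frame(site_id = sites$site_id, lon = lon, lat = lat,
             stringsAsFactors = FALSE)
}

#' Run the Lagrangian dispersal simulation
#'
#' Releases particle cohorts per the schedule, advects them with RK4 over
#' the velocity field, applies a one-time mortality thinning at
#' `mortalityDay`, and settles competent particles (age within the
#' competency window) at the first settlement node encountered within
#' `settlementRadiusKm`. Every particle ends in exactly one fate:
#' `settled`, `dead`, `lost`, or `expired`, so fates sum to releases.
#'
#' @param field a [VelocityField-class].
#' @param schedule a [releaseSchedule()].
#' @param traits a [particleTraits()].
#' @param nodes data.frame from [makeHabitatNodes()] (needs `node_id`,
#'   `lon`, `lat`).
#' @param seed integer seed.
#' @param dtHours integration step in hours.
#' @param thinning `"bernoulli"` (each particle survives independently) or
#'   `"deterministic"` (exactly `round(n * fraction)` survivors, lowest
#'   particle indices kept).
#' @return data.frame with one row per particle: `source`, `release_day`,
#'   `particle`, `fate`, `node` (NA unless settled), `day` (age at
#'   settlement/death/loss/expiry), `stranded` (ever touched land).
#' @export
runDispersal <- function(field, schedule, traits, nodes, seed = 1,
                         dtHours = 1, thinning = c("bernoulli", "deterministic")) {
  thinning <- match.arg(thinning)
  if (is.null(nodes) || nrow(nodes) == 0) stop("empty node list")
  release <- adjustReleasePoints(field, schedule$sites,
                                 schedule$offshoreOffsetKm)
  relDays <- seq(0, schedule$durationDays, by = schedule$intervalDays)
  relDays <- relDays[relDays < schedule$durationDays]
  stepsPerDay <- max(1L, round(24 / dtHours))
  dtSec <- 86400 / stepsPerDay
  res <- vector("list", nrow(release) * length(relDays))
  ri <- 0L
  withSeed(splitSeed(seed, "dispersal"), {
    for (s in seq_len(nrow(release))) for (rd in relDays) {
      n <- schedule$particlesPerRelease
      lon <- rep(release$lon[s], n); lat <- rep(release$lat[s], n)
      fate <- rep(NA_character_, n)
      node <- rep(NA_character_, n)
      fateDay <- rep(NA_real_, n)
      stranded <- rep(FALSE, n)
      active <- rep(TRUE, n)
      mortalityDone <- FALSE
      totalSteps <- traits$maxPldDay * stepsPerDay
      for (st in seq_len(totalSteps)) {
        age <- st / stepsPerDay           # age after this step, days
        idx <- which(active)
        if (!length(idx)) break
        stp <- advectStep(field, lon[idx], lat[idx],
                          rd + (st - 1) / stepsPerDay, dtSec)
        lon[idx] <- stp$lon; lat[idx] <- stp$lat
        lostNow <- idx[stp$status == 1L]
        if (length(lostNow)) {
          fate[lostNow] <- "lost"; fateDay[lostNow] <- age
          active[lostNow] <- FALSE
        }
        stranded[idx[stp$status == 2L]] <- TRUE
        if (!mortalityDone && age >= traits$mortalityDay) {
          alive <- which(active)
          frac <- traits$mortalitySurvivalFraction
          die <- if (thinning == "deterministic") {
            nKeep <- round(length(alive) * frac)
            if (nKeep < length(alive)) alive[-seq_len(nKeep)] else integer(0)
          } else alive[runif(length(alive)) >= frac]
          if (length(die)) {
            fate[die] <- "dead"; fateDay[die] <- age
            active[die] <- FALSE
          }
          mortalityDone <- TRUE
        }
        if (age >= traits$competencyStartDay) {
          cand <- which(active)
          if (length(cand)) {
            dmat <- crossDistKm(lon[cand], lat[cand], nodes$lon, nodes$lat)
            nearest <- max.col(-dmat, ties.method = "first")
            hit <- dmat[cbind(seq_along(cand), nearest)] <= traits$settlementRadiusKm
            if (any(hit)) {
              who <- cand[hit]
              fate[who] <- "settled"
              node[who] <- nodes$node_id[nearest[hit]]
              fateDay[who] <- age
              active[who] <- FALSE
            }
          }
        }
      }
      still <- which(active)
      if (length(still)) {
        fate[still] <- "expired"; fateDay[still] <- traits$maxPldDay
      }
      ri <- ri + 1L
      res[[ri]] <- data.frame(source = release$site_id[s], release_day = rd,
                              particle = seq_len(n), fate = fate, node = node,
                              day = fateDay, stranded = stranded,
                              stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, res[seq_len(ri)])
}

#' Build a directed connectivity matrix from particle fates
#'
#' Pools settlement nodes to the nearest release/sampling site within
#' `poolingRadiusKm`; nodes farther than that from every site are aggregated
#' into an `"other"` sink column. Entry (source, pool) is the number of
#' particles from `source` that settled in `pool`, divided by the number of
#' particles released from `source` (default) or by the number settled
#' (survivor-normalised alternative).
#'
#' @param fates fate table from [runDispersal()].
#' @param nodes node table used in the run.
#' @param sites data.frame with `site_id`, `lon`, `lat` (pooling targets).
#' @param poolingRadiusKm node-to-site pooling radius.
#' @param normalize `"released"` (default) or `"settled"`.
#' @return A [ConnectivityMatrix-class].
#' @export
buildConnectivity <- function(fates, nodes, sites, poolingRadiusKm = 75,
                              normalize = c("released", "settled")) {
  normalize <- match.arg(normalize)
  settledTab <- fates[fates$fate == "settled", , drop = FALSE]
  if (nrow(settledTab) &&
      !all(settledTab$node %in% nodes$node_id))
    stop("unknown node id in fate table")
  dmat <- crossDistKm(nodes$lon, nodes$lat, sites$lon, sites$lat)
  nearest <- max.col(-dmat, ties.method = "first")
  pool <- ifelse(dmat[cbind(seq_len(nrow(nodes)), nearest)] <= poolingRadiusKm,
                 sites$site_id[nearest], "other")
  names(pool) <- nodes$node_id
  sources <- unique(fates$source)
  pools <- c(sites$site_id, if (any(pool == "other")) "other")
  released <- setNames(as.numeric(table(fates$source)[sources]), sources)
  settled <- matrix(0, length(sources), length(pools),
                    dimnames = list(sources, pools))
  if (nrow(settledTab)) {
    tab <- table(settledTab$source, pool[settledTab$node])
    settled[rownames(tab), colnames(tab)] <- tab
  }
  denom <- if (normalize == "released") released
           else pmax(rowSums(settled), 1)
  prob <- sweep(settled, 1, denom, "/")
  new("ConnectivityMatrix", prob = prob, released = released,
      settled = settled)
}
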