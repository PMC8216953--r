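#' Generate a synthetic basin circulation field
#'
#' Builds a [VelocityField-class] emulating the surface circulation of a
#' semi-enclosed tropical basin: a southward western-boundary throughflow, a
#' closed cyclonic gyre in the southern half, optional uniform flow and
#' solid-body rotation (the latter two mainly exercise the particle tracker).
#' Velocities are set to zero on land; an optional random perturbation is
#' deterministic for a fixed seed.
#'
#' @param nx,ny grid cells in longitude/latitude (each >= 8).
#' @param nt number of time slices spanning `durationDays`.
#' @param features character vector, any of `"western_boundary"`, `"gyre"`,
#'   `"uniform"`, `"solid_body"`.
#' @param lonRange,latRange basin bounding box, decimal degrees.
#' @param landBorder enclose the basin with a one-cell land ring.
#' @param island optional `list(lonRange=, latRange=)` rectangular land block.
#' @param uniformU,uniformV m/s for the `"uniform"` feature.
#' @param wbcSpeed peak southward speed (m/s) of the western-boundary current.
#' @param gyreSpeed peak speed (m/s) of the southern gyre.
#' @param gyreBox optional `list(lonRange=, latRange=)` for the gyre; default
#'   is the southern half of the ocean interior.
#' @param solidBodyPeriodDays rotation period for `"solid_body"`.
#' @param seasonalAmplitude relative seasonal modulation of all currents
#'   (annual cosine; 0 disables).
#' @param noiseSd standard deviation (m/s) of added Gaussian perturbation.
#' @param durationDays time span covered by the `nt` slices.
#' @param seed integer seed for the perturbation.
#' @return A [VelocityField-class].
#' @examples
#' f <- makeBasinField(20, 24, nt = 2, features = "western_boundary")
#' f
#' @export
makeBasinField <- function(nx, ny, nt = 12,
                           features = c("western_boundary", "gyre"),
                           lonRange = c(117, 124), latRange = c(5, 13),
                           landBorder = TRUE, island = NULL,
                           uniformU = 0.1, uniformV = 0,
                           wbcSpeed = 0.3, gyreSpeed = 0.25, gyreBox = NULL,
                           solidBodyPeriodDays = 30,
                           seasonalAmplitude = 0, noiseSd = 0,
                           durationDays = 365, seed = 1) {
  if (nx < 8 || ny < 8) stop("nx and ny must be >= 8")
  if (nt < 1) stop("nt must be >= 1")
  known <- c("western_boundary", "gyre", "uniform", "solid_body")
  bad <- setdiff(features, known)
  if (length(bad)) stop("unknown feature: ", paste(bad, collapse = ", "))

  lon <- seq(lonRange[1], lonRange[2], length.out = nx)
  lat <- seq(latRange[1], latRange[2], length.out = ny)
  tgrid <- if (nt == 1) 0 else seq(0, durationDays, length.out = nt)

  land <- matrix(FALSE, ny, nx)
  if (landBorder) {
    land[c(1, ny), ] <- TRUE
    land[, c(1, nx)] <- TRUE
  }
  if (!is.null(island)) {
    ii <- lat >= island$latRange[1] & lat <= island$latRange[2]
    jj <- lon >= island$lonRange[1] & lon <= island$lonRange[2]
    land[ii, jj] <- TRUE
  }

  lonM <- matrix(lon, ny, nx, byrow = TRUE)
  latM <- matrix(lat, ny, nx)
  u0 <- matrix(0, ny, nx)
  v0 <- matrix(0, ny, nx)

  if ("uniform" %in% features) {
    u0 <- u0 + uniformU
    v0 <- v0 + uniformV
  }
  if ("western_boundary" %in% features) {
    # Stommel-style single-gyre streamfunction with western intensification:
    # psi = -C sin(pi Y) g(X), g(X) = (1 - exp(-X/delta)) (1 - X); no normal
    # flow at the basin walls, southward jet of peak wbcSpeed at the western
    # boundary, weak interior return flow
    oceanCols <- which(apply(!land, 2, any))
    oceanRows <- which(apply(!land, 1, any))
    lonW <- lon[oceanCols[1]]; lonE <- lon[oceanCols[length(oceanCols)]]
    latS <- lat[oceanRows[1]]; latN <- lat[oceanRows[length(oceanRows)]]
    X <- pmin(pmax((lonM - lonW) / (lonE - lonW), 0), 1)
    Y <- pmin(pmax((latM - latS) / (latN - latS), 0), 1)
    delta <- 0.08
    Lx <- (lonE - lonW) * EARTH_M_PER_DEG_LON_EQ * cos(mean(latRange) * pi / 180)
    Ly <- (latN - latS) * EARTH_M_PER_DEG_LAT
    gX <- (1 - exp(-X / delta)) * (1 - X)
    gpX <- exp(-X / delta) / delta * (1 - X) - (1 - exp(-X / delta))
    Cpsi <- wbcSpeed * Lx * delta
    u0 <- u0 + (Cpsi * pi / Ly) * cos(pi * Y) * gX
    v0 <- v0 - (Cpsi / Lx) * sin(pi * Y) * gpX
  }
  if ("gyre" %in% features) {
    if (identical(gyreBox, "basin")) {
      oceanCols <- which(apply(!land, 2, any))
      oceanRows <- which(apply(!land, 1, any))
      gyreBox <- list(lonRange = range(lon[oceanCols]),
                      latRange = range(lat[oceanRows]))
    }
    if (is.null(gyreBox)) {
      dlon <- diff(lon[1:2]); dlat <- diff(lat[1:2])
      gyreBox <- list(lonRange = c(lonRange[1] + dlon, lonRange[2] - dlon),
                      latRange = c(latRange[1] + dlat,
                                   latRange[1] + diff(latRange) / 2))
    }
    X <- (lonM - gyreBox$lonRange[1]) / diff(gyreBox$lonRange)
    Y <- (latM - gyreBox$latRange[1]) / diff(gyreBox$latRange)
    inside <- X >= 0 & X <= 1 & Y >= 0 & Y <= 1
    # streamfunction ~ sin(pi X) sin(pi Y): closed streamlines about the
    # box centre; cyclonic sense for positive gyreSpeed
    gu <- -gyreSpeed * sin(pi * X) * cos(pi * Y)
    gv <- gyreSpeed * cos(pi * X) * sin(pi * Y)
    u0 <- u0 + ifelse(inside, gu, 0)
    v0 <- v0 + ifelse(inside, gv, 0)
  }
  if ("solid_body" %in% features) {
    omega <- 2 * pi / (solidBodyPeriodDays * 86400)
    lonC <- mean(lonRange); latC <- mean(latRange)
    xm <- (lonM - lonC) * EARTH_M_PER_DEG_LON_EQ * cos(latC * pi / 180)
    ym <- (latM - latC) * EARTH_M_PER_DEG_LAT
    u0 <- u0 - omega * ym
    v0 <- v0 + omega * xm
  }

  u <- array(0, c(nt, ny, nx))
  v <- array(0, c(nt, ny, nx))
  withSeed(splitSeed(seed, "field"), {
    for (k in seq_len(nt)) {
      fac <- 1 + seasonalAmplitude * cos(2 * pi * tgrid[k] / 365)
      uk <- u0 * fac
      vk <- v0 * fac
      if (noiseSd > 0) {
        uk <- uk + matrix(rnorm(ny * nx, 0, noiseSd), ny, nx)
        vk <- vk + matrix(rnorm(ny * nx, 0, noiseSd), ny, nx)
      }
      uk[land] <- 0
      vk[land] <- 0
      u[k, , ] <- uk
      v[k, , ] <- vk
    }
  })
  new("VelocityField", lon = lon, lat = lat, time = tgrid,
      u = u, v = v, landMask = land)
}

# coastline = ocean cells with at least one land 4-neighbour
coastlineCells <- function(field) {
  land <- field@landMask
  ny <- nrow(land); nx <- ncol(land)
  pad <- function(m, di, dj) {
    out <- matrix(TRUE, ny, nx)  # outside the grid counts as non-land
    out[] <- FALSE
    ri <- seq_len(ny) + di; cj <- seq_len(nx) + dj
    ok_i <- ri >= 1 & ri <= ny; ok_j <- cj >= 1 & cj <= nx
    out[ok_i, ok_j] <- m[ri[ok_i], cj[ok_j]]
    out
  }
  nb <- pad(land, 1, 0) | pad(land, -1, 0) | pad(land, 0, 1) | pad(land, 0, -1)
  which(!land & nb, arr.ind = TRUE)
}

#' Place larval settlement nodes along the coastline
#'
#' Settlement nodes are placed on ocean cells adjacent to land
#' (4-neighbourhood), approximately `spacingKm` apart along each coastline
#' component. The node set discretises suitable settlement habitat the way a
#' basin-scale habitat map would.
#'
#' @param field a [VelocityField-class].
#' @param spacingKm target along-coast spacing (> 0).
#' @return data.frame with `node_id`, `lon`, `lat`, `row`, `col`.
#' @examples
#' f <- makeBasinField(20, 24, nt = 1, features = "uniform")
#' nodes <- makeHabitatNodes(f, spacingKm = 120)
#' @export
makeHabitatNodes <- function(field, spacingKm) {
  if (spacingKm <= 0) stop("spacingKm must be > 0")
  cells <- coastlineCells(field)
  if (nrow(cells) == 0) stop("no coastline in field")
  lon <- field@lon[cells[, "col"]]
  lat <- field@lat[cells[, "row"]]

  # order cells into chains by nearest-neighbour traversal; a jump larger
  # than ~3 cells starts a new coastline component
  dCell <- haversineKm(field@lon[1], field@lat[1], field@lon[2], field@lat[1])
  jump <- 3.5 * max(dCell, haversineKm(field@lon[1], field@lat[1],
                                       field@lon[1], field@lat[2]))
  n <- nrow(cells)
  visited <- logical(n)
  keep <- integer(0)
  while (!all(visited)) {
    cur <- which(!visited)[1]
    visited[cur] <- TRUE
    keep <- c(keep, cur)           # first cell of a component is a node
    acc <- 0
    repeat {
      open <- which(!visited)
      if (!length(open)) break
      dd <- haversineKm(lon[cur], lat[cur], lon[open], lat[open])
      nxt <- open[which.min(dd)]
      if (min(dd) > jump) break    # next component
      visited[nxt] <- TRUE
      acc <- acc + min(dd)
      if (acc >= spacingKm) {
        keep <- c(keep, nxt)
        acc <- acc - spacingKm   # carry the remainder: mean spacing stays true
      }
      cur <- nxt
    }
  }
  data.frame(node_id = sprintf("N%03d", seq_along(keep)),
             lon = lon[keep], lat = lat[keep],
             row = cells[keep, "row"], col = cells[keep, "col"],
             stringsAsFactors = FALSE)
}

# order coastline cells into chains by nearest-neighbour traversal;
# returns a list of data.frames (lon, lat, arc = cumulative km)
coastChains <- function(field) {
  cells <- coastlineCells(field)
  if (nrow(cells) == 0) stop("no coastline in field")
  lon <- field@lon[cells[, "col"]]
  lat <- field@lat[cells[, "row"]]
  dCell <- max(haversineKm(field@lon[1], field@lat[1],
                           field@lon[2], field@lat[1]),
               haversineKm(field@lon[1], field@lat[1],
                           field@lon[1], field@lat[2]))
  jump <- 3.5 * dCell
  n <- length(lon)
  visited <- logical(n)
  chains <- list()
  while (!all(visited)) {
    cur <- which(!visited)[1]
    visited[cur] <- TRUE
    chain <- data.frame(lon = lon[cur], lat = lat[cur], arc = 0)
    repeat {
      open <- which(!visited)
      if (!length(open)) break
      dd <- haversineKm(lon[cur], lat[cur], lon[open], lat[open])
      if (min(dd) > jump) break
      nxt <- open[which.min(dd)]
      visited[nxt] <- TRUE
      chain <- rbind(chain, data.frame(
        lon = lon[nxt], lat = lat[nxt],
        arc = chain$arc[nrow(chain)] + min(dd)))
      cur <- nxt
    }
    chains[[length(chains) + 1]] <- chain
  }
  chains
}

#' Pick sampling sites along the basin coastline
#'
#' Convenience generator for a site table emulating a sampling design:
#' `n` positions evenly spaced along the longest coastline chain (so sites
#' line the basin's shores the way sampling localities do), with unique
#' codes, a pool label (one pool per site) and an integer `latitude_rank`
#' (1 = southernmost).
#'
#' @param field a [VelocityField-class].
#' @param n number of sites.
#' @param seed integer seed (rotates the placement phase along the coast).
#' @return data.frame with `site_id`, `lon`, `lat`, `pool_id`,
#'   `latitude_rank`.
#' @export
makeSiteTable <- function(field, n = 8, seed = 1) {
  chains <- coastChains(field)
  chain <- chains[[which.max(vapply(chains, function(ch)
    ch$arc[nrow(ch)], numeric(1)))]]
  if (nrow(chain) < n) stop("not enough coastline cells for ", n, " sites")
  total <- chain$arc[nrow(chain)]
  phase <- withSeed(splitSeed(seed, "nodes"), runif(1)) * total / n
  targets <- (phase + (seq_len(n) - 1) * total / n) %% total
  idx <- vapply(targets, function(a) which.min(abs(chain$arc - a)), integer(1))
  idx <- unique(idx)
  if (length(idx) < n) stop("coastline too short to separate ", n, " sites")
  ord <- idx[order(chain$lat[idx])]
  data.frame(site_id = sprintf("S%02d", seq_len(n)),
             lon = chain$lon[ord], lat = chain$lat[ord],
             pool_id = sprintf("S%02d", seq_len(n)),
             latitude_rank = seq_len(n),
             stringsAsFactors = FALSE)
}
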