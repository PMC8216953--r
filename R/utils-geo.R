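# geographic helpers shared by the field generator and the particle tracker

EARTH_M_PER_DEG_LAT <- 110574
EARTH_M_PER_DEG_LON_EQ <- 111320

#' Great-circle distances in kilometres
#'
#' Haversine distance between paired coordinates (vectorised).
#'
#' @param lon1,lat1,lon2,lat2 decimal degrees, recycled to common length.
#' @return Numeric vector of distances in km.
#' @export
haversineKm <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lon2))
  geosphere::distHaversine(cbind(rep_len(lon1, n), rep_len(lat1, n)),
                           cbind(rep_len(lon2, n), rep_len(lat2, n))) / 1000
}

# sites x sites (or points x nodes) cross-distance matrix in km
crossDistKm <- function(lon1, lat1, lon2, lat2) {
  out <- matrix(0, length(lon1), length(lon2))
  for (j in seq_along(lon2))
    out[, j] <- haversineKm(lon1, lat1, lon2[j], lat2[j])
  out
}

# cell index of a lon/lat position on a regular ascending grid; NA outside
# the outer cell edges
cellIndex <- function(grid, x) {
  half <- diff(grid[1:2]) / 2
  i <- findInterval(x, c(grid - half, grid[length(grid)] + half))
  i[i < 1 | i > length(grid)] <- NA_integer_
  i
}
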