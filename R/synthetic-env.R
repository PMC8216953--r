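#' Generate monthly SST and rainfall tables with a latitudinal cline
#'
#' Emulates the statistical structure of basin-scale environmental data:
#' monthly sea-surface-temperature summaries (mean, min, max, degrees C) and
#' rainfall (mm/day), with SST decreasing linearly in expectation with the
#' site's `latitude_rank` and the steepest thermal cline during the wet
#' season (June-November). `SST_min <= SST_mean <= SST_max` is enforced at
#' every site-month.
#'
#' @param sites data.frame with `site_id` and `latitude_rank` (integer; rank
#'   1 = southernmost).
#' @param clineParams optional list overriding any of: `sstBase` (deg C at
#'   rank 0), `slope` (12 monthly deg C per rank step; negative = cooler
#'   northwards), `spread` (12 monthly half-widths between mean and min/max),
#'   `noiseSd` (deg C), `rainBase` (mm/day), `rainSeason` (12 monthly
#'   offsets), `rainSlope` (12 monthly mm/day per rank), `rainNoiseSd`.
#' @param seed integer seed.
#' @return data.frame (long format): `site_id`, `month` (1-12), `SST_mean`,
#'   `SST_min`, `SST_max`, `rainfall`.
#' @examples
#' sites <- data.frame(site_id = c("A", "B"), latitude_rank = 1:2)
#' env <- makeEnvironment(sites, seed = 2)
#' head(env)
#' @export
makeEnvironment <- function(sites, clineParams = list(), seed = 1) {
  if (nrow(sites) == 0) stop("empty site table")
  if (is.null(sites$latitude_rank))
    stop("sites must carry a latitude_rank column")
  wet <- 6:11  # June-November
  p <- list(
    sstBase = 29.5,
    # steepest (most negative) latitudinal slope in the wet season
    slope = ifelse(seq_len(12) %in% wet, -0.35, -0.12),
    spread = rep(1.2, 12),
    noiseSd = 0.15,
    rainBase = 5,
    rainSeason = ifelse(seq_len(12) %in% wet, 6, 0),
    rainSlope = ifelse(seq_len(12) %in% wet, -0.6, -0.1),
    rainNoiseSd = 0.8)
  p[names(clineParams)] <- clineParams

  out <- expand.grid(site_id = sites$site_id, month = seq_len(12),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rank <- sites$latitude_rank[match(out$site_id, sites$site_id)]
  m <- out$month
  withSeed(splitSeed(seed, "environment"), {
    eps <- rnorm(nrow(out), 0, p$noiseSd)
    sstMean <- p$sstBase + p$slope[m] * rank + eps
    lo <- abs(rnorm(nrow(out), 0, p$noiseSd))
    hi <- abs(rnorm(nrow(out), 0, p$noiseSd))
    out$SST_mean <- sstMean
    out$SST_min <- sstMean - p$spread[m] - lo
    out$SST_max <- sstMean + p$spread[m] + hi
    rain <- p$rainBase + p$rainSeason[m] + p$rainSlope[m] * rank +
      rnorm(nrow(out), 0, p$rainNoiseSd)
    out$rainfall <- pmax(rain, 0)
  })
  out[order(out$site_id, out$month), ]
}

#' Reshape an environment table to site-by-month predictor matrices
#'
#' @param env long-format table from [makeEnvironment()].
#' @param variable one of `"SST_mean"`, `"SST_min"`, `"SST_max"`,
#'   `"rainfall"`.
#' @return numeric matrix, sites x 12 months (columns `JAN`..`DEC`).
#' @export
envPredictors <- function(env, variable = "SST_mean") {
  stopifnot(variable %in% names(env))
  sites <- unique(env$site_id)
  out <- matrix(NA_real_, length(sites), 12,
                dimnames = list(sites, toupper(month.abb)))
  for (i in seq_along(sites)) {
    sub <- env[env$site_id == sites[i], ]
    out[i, sub$month] <- sub[[variable]]
  }
  out
}
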