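# per-locus inputs shared by the outlier scans: corrected theta (WC84),
# an uncorrected differentiation ratio used for the chi-square null fit,
# and pooled expected heterozygosity
outlierLocusStats <- function(G) {
  pp <- perPopStats(G)
  wc <- wcComponents(pp$n, pp$p, pp$h)
  theta <- wc$a / (wc$a + wc$b + wc$c)
  pq <- wc$pbar * (1 - wc$pbar)
  # uncorrected ratio: between-population variance over total, no
  # finite-sample correction (the null-fit statistic; its scale and df are
  # inferred from the data rather than assumed)
  fnc <- wc$s2 / (pq + wc$s2 / wc$r)
  data.frame(locus = rownames(pp$n), He = 2 * pq, theta = theta,
             thetaNoCorr = fnc, r = wc$r, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Trimmed chi-square FST-outlier scan
#'
#' Infers the distribution of neutral differentiation by fitting a scaled
#' chi-square to the central body of the per-locus FST distribution
#' (left/right tails trimmed), then flags loci in the right tail of the
#' fitted null. Both the degrees of freedom and the mean of the neutral
#' distribution are estimated by maximum likelihood on the trimmed
#' (truncated) sample; low-heterozygosity loci are excluded from fitting
#' and flagging because their FST estimates are unstable.
#'
#' @param G a [GenotypePanel-class] (>= 2 populations; >= 50 loci
#'   recommended).
#' @param leftTrim,rightTrim trimming fractions for the null fit.
#' @param hMin minimum pooled expected heterozygosity.
#' @param qThreshold FDR threshold for flagging.
#' @return An [OutlierScan-class]; `stats` columns: `locus`, `He`, `theta`
#'   (corrected per-locus WC estimate), `thetaNoCorr` (uncorrected ratio
#'   used in the fit), `p` (right-tail), `q`, `flag`.
#' @export
trimmedChisqScan <- function(G, leftTrim = 0.05, rightTrim = 0.05,
                             hMin = 0.1, qThreshold = 0.05) {
  st <- outlierLocusStats(G)
  r <- max(st$r, na.rm = TRUE)
  usable <- !is.na(st$thetaNoCorr) & st$He >= hMin & st$thetaNoCorr > 0
  f <- st$thetaNoCorr[usable]
  qlo <- quantile(f, leftTrim, names = FALSE)
  qhi <- quantile(f, 1 - rightTrim, names = FALSE)
  core <- f[f >= qlo & f <= qhi]
  if (length(core) < 10) stop("trimming leaves fewer than 10 loci")
  nll <- function(par) {
    df <- par[1]; fbar <- par[2]
    sc <- df / fbar
    z <- pchisq(qhi * sc, df) - pchisq(qlo * sc, df)
    if (!is.finite(z) || z <= 0) return(1e10)
    -sum(dchisq(core * sc, df, log = TRUE) + log(sc)) + length(core) * log(z)
  }
  fit <- optim(c(df = r - 1, fbar = mean(core)), nll, method = "L-BFGS-B",
               lower = c(1, 1e-8), upper = c(10 * (r - 1), 10 * max(f)))
  df <- fit$par[1]; fbar <- fit$par[2]
  p <- rep(NA_real_, nrow(st))
  p[usable] <- pchisq(st$thetaNoCorr[usable] * df / fbar, df,
                      lower.tail = FALSE)
  q <- rep(NA_real_, nrow(st))
  q[usable] <- p.adjust(p[usable], "BH")
  st$p <- p
  st$q <- q
  st$flag <- !is.na(q) & q < qThreshold
  new("OutlierScan", stats = st, method = "trimmed_chisq",
      params = list(leftTrim = leftTrim, rightTrim = rightTrim, hMin = hMin,
                    qThreshold = qThreshold, df = unname(df),
                    fbar = unname(fbar)))
}

#' Island-model envelope FST-outlier scan
#'
#' Simulates neutral loci under a hierarchical island model (two-level
#' Balding-Nichols allele-frequency sampling: ancestral frequency, then
#' group frequencies, then deme frequencies, then binomial genotype
#' sampling at the observed sample sizes), calibrated so the simulated
#' global differentiation matches the observed global theta. Observed loci
#' falling outside the central `ci` quantile envelope of simulated theta,
#' conditional on heterozygosity, are flagged; the diversifying (upper)
#' tail is what feeds the consensus rule.
#'
#' @param G a [GenotypePanel-class].
#' @param nSim simulated neutral loci for the envelope.
#' @param groups,demesPerGroup hierarchical structure of the simulated
#'   metapopulation; sampled demes are spread round-robin across groups.
#' @param ci central envelope coverage (0.99 flags ~1% of neutral loci).
#' @param seed integer seed.
#' @return An [OutlierScan-class]; `stats` columns as in
#'   [trimmedChisqScan()] plus `tail` (`"high"`/`"low"`).
#' @export
fdistEnvelopeScan <- function(G, nSim = 20000, groups = 10,
                              demesPerGroup = 100, ci = 0.99, seed = 1) {
  st <- outlierLocusStats(G)
  obsTheta <- wcFst(G)
  if (!is.finite(obsTheta) || obsTheta <= 0)
    stop("calibration fails: observed global theta is not positive")
  pp <- perPopStats(G)
  nInd <- round(colMeans(pp$n))
  r <- length(nInd)
  grpOf <- rep(seq_len(groups), length.out = r)

  simulateLoci <- function(L, F) {
    fct <- F / 2; fsc <- F / 2
    p0 <- runif(L, 0.02, 0.98)
    bn <- function(p, F) {
      shape <- (1 - F) / F
      rbeta(length(p), p * shape, (1 - p) * shape)
    }
    pg <- matrix(bn(rep(p0, groups), fct), L, groups)
    n <- matrix(rep(nInd, each = L), L, r)
    pHat <- hHat <- matrix(0, L, r)
    for (k in seq_len(r)) {
      pd <- bn(pg[, grpOf[k]], fsc)
      # sample nInd[k] diploids: sufficient statistics via binomial draws
      het <- rbinom(L, nInd[k], 2 * pd * (1 - pd))
      altHom <- rbinom(L, nInd[k] - het, pmin(pd^2 / (1 - 2 * pd * (1 - pd)), 1))
      pHat[, k] <- (het + 2 * altHom) / (2 * nInd[k])
      hHat[, k] <- het / nInd[k]
    }
    wc <- wcComponents(n, pHat, hHat)
    theta <- wc$a / (wc$a + wc$b + wc$c)
    data.frame(He = 2 * wc$pbar * (1 - wc$pbar), theta = theta,
               a = wc$a, tot = wc$a + wc$b + wc$c)
  }

  res <- withSeed(splitSeed(seed, "outliers"), {
    F <- max(obsTheta, 1e-4)
    for (it in seq_len(10)) {
      sim <- simulateLoci(2000, F)
      simGlobal <- sum(sim$a, na.rm = TRUE) / sum(sim$tot, na.rm = TRUE)
      if (simGlobal <= 0) { F <- F * 2; next }
      ratio <- obsTheta / simGlobal
      if (abs(ratio - 1) < 0.05) break
      F <- min(max(F * ratio, 1e-6), 0.9)
    }
    sim <- simulateLoci(nSim, F)
    sim <- sim[is.finite(sim$theta) & is.finite(sim$He), ]
    simGlobal <- sum(sim$a) / sum(sim$tot)
    if (abs(simGlobal - obsTheta) > 0.1 * max(obsTheta, 0.01))
      stop("calibration fails to bracket the observed global theta")
    list(sim = sim, F = F, simGlobal = simGlobal)
  })
  sim <- res$sim
  nBins <- max(20, min(40, floor(nrow(sim) / 200)))
  edges <- unique(quantile(sim$He, seq(0, 1, length.out = nBins + 1)))
  bin <- cut(sim$He, edges, include.lowest = TRUE)
  obsBin <- cut(pmin(pmax(st$He, min(sim$He)), max(sim$He)), edges,
                include.lowest = TRUE)
  alpha <- (1 - ci) / 2
  p <- rep(NA_real_, nrow(st))
  tail <- rep(NA_character_, nrow(st))
  flag <- rep(FALSE, nrow(st))
  for (b in levels(bin)) {
    simTheta <- sim$theta[bin == b]
    if (length(simTheta) < 20) next
    idx <- which(obsBin == b & is.finite(st$theta))
    if (!length(idx)) next
    n <- length(simTheta)
    qs <- quantile(simTheta, c(alpha, 1 - alpha), names = FALSE, type = 7)
    for (i in idx) {
      pHigh <- (sum(simTheta >= st$theta[i]) + 1) / (n + 1)
      pLow <- (sum(simTheta <= st$theta[i]) + 1) / (n + 1)
      p[i] <- min(pHigh, pLow)   # one-sided tail probability
      tail[i] <- if (pHigh <= pLow) "high" else "low"
      flag[i] <- st$theta[i] > qs[2] || st$theta[i] < qs[1]
    }
  }
  st$p <- p
  st$q <- p.adjust(p, "BH")
  st$flag <- flag
  st$tail <- tail
  new("OutlierScan", stats = st, method = "fdist_envelope",
      params = list(nSim = nSim, groups = groups,
                    demesPerGroup = demesPerGroup, ci = ci,
                    calibratedF = res$F, simGlobalTheta = res$simGlobal))
}

#' Consensus of outlier scans
#'
#' Loci flagged by at least `k` methods. Scans may be
#' [OutlierScan-class] objects (whose locus universes must agree) or plain
#' character vectors of flagged locus ids (so externally computed flag
#' sets, e.g. from a Bayesian method, can be plugged in).
#'
#' @param scans list of scans or flag sets (>= 2).
#' @param k minimum number of methods flagging a locus.
#' @return Character vector of consensus locus ids (sorted).
#' @export
consensusOutliers <- function(scans, k = 2) {
  if (length(scans) < 2) stop("need >= 2 scans")
  universes <- lapply(scans, function(s)
    if (is(s, "OutlierScan")) sort(s@stats$locus) else NULL)
  universes <- universes[!vapply(universes, is.null, logical(1))]
  if (length(universes) > 1 &&
      !all(vapply(universes, identical, logical(1), y = universes[[1]])))
    stop("inconsistent locus universes across scans")
  flagSets <- lapply(scans, function(s)
    if (is(s, "OutlierScan")) flaggedLoci(s) else as.character(s))
  counts <- table(unlist(lapply(flagSets, unique)))
  sort(names(counts)[counts >= k])
}
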