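# Weir & Cockerham (1984) variance components per locus from per-population
# summaries: n (individuals), p (alt freq), h (het fraction), loci in rows.
# Returns a, b, c; loci with < 2 informative populations get NA.
wcComponents <- function(n, p, h) {
  r <- rowSums(n > 0)
  nTot <- rowSums(n)
  nbar <- nTot / r
  ok <- r >= 2 & nbar > 1
  nc <- (nTot - rowSums(n^2) / nTot) / (r - 1)
  pbar <- rowSums(n * p, na.rm = TRUE) / nTot
  s2 <- rowSums(n * (p - pbar)^2, na.rm = TRUE) / ((r - 1) * nbar)
  hbar <- rowSums(n * h, na.rm = TRUE) / nTot
  pq <- pbar * (1 - pbar)
  a <- nbar / nc *
    (s2 - (pq - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pq - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!ok] <- NA; b[!ok] <- NA; cc[!ok] <- NA
  list(a = a, b = b, c = cc, pbar = pbar, s2 = s2, r = r)
}

# fast two-or-more-group component computation from a dosage matrix and a
# group indicator matrix Z (individuals x groups, 0/1); used by the
# permutation engine
wcComponentsFromDosage <- function(d, Z) {
  notNA <- !is.na(d)
  d0 <- d; d0[!notNA] <- 0
  n <- notNA %*% Z
  p <- (d0 %*% Z) / (2 * n)
  h <- ((d == 1 & notNA) %*% Z) / n
  p[n == 0] <- NA; h[n == 0] <- NA
  wcComponents(n, p, h)
}

#' Weir-Cockerham FST
#'
#' The theta estimator of Weir & Cockerham (1984): per-locus variance
#' components a (among populations), b (among individuals within
#' populations) and c (within individuals), combined across loci as a ratio
#' of sums (`sum(a) / sum(a + b + c)`). Handles missing data by using
#' per-locus per-population non-missing counts; theta can be slightly
#' negative for undifferentiated populations.
#'
#' @param G a [GenotypePanel-class] with >= 2 populations of >= 2
#'   individuals.
#' @param scope `"global"` (multi-locus scalar) or `"per_locus"`.
#' @return Numeric scalar or per-locus named vector.
#' @examples
#' d <- cbind(matrix(0, 2, 10), matrix(2, 2, 10))  # fixed difference
#' G <- genotypePanel(d, rep(c("A", "B"), each = 10))
#' wcFst(G)  # 1
#' @export
wcFst <- function(G, scope = c("global", "per_locus")) {
  scope <- match.arg(scope)
  pp <- perPopStats(G)
  if (length(pp$pops) < 2) stop("need >= 2 populations")
  wc <- wcComponents(pp$n, pp$p, pp$h)
  if (scope == "global") {
    sum(wc$a, na.rm = TRUE) /
      sum(wc$a + wc$b + wc$c, na.rm = TRUE)
  } else {
    theta <- wc$a / (wc$a + wc$b + wc$c)
    names(theta) <- rownames(dosage(G))
    theta
  }
}

#' Pairwise FST with permutation significance and bootstrap CIs
#'
#' For every population pair: multi-locus theta; an empirical p-value from
#' permuting individuals between the two populations
#' (`p = (#perm >= obs + 1) / (nPerm + 1)`); a percentile confidence
#' interval from bootstrapping loci; and Benjamini-Hochberg adjustment of
#' p-values across pairs.
#'
#' @param G a [GenotypePanel-class].
#' @param nPerm permutations per pair.
#' @param nBoot bootstrap replicates over loci for the CIs.
#' @param seed integer seed.
#' @return An [FstResult-class].
#' @export
pairwiseFst <- function(G, nPerm = 999, nBoot = 10000, seed = 1) {
  pp <- perPopStats(G)
  pops <- pp$pops
  if (length(pops) < 2) stop("need >= 2 populations")
  d <- dosage(G)
  lab <- populations(G)
  k <- length(pops)
  theta <- pmat <- lo <- hi <- matrix(NA_real_, k, k,
                                      dimnames = list(pops, pops))
  diag(theta) <- 0
  globalTheta <- wcFst(G)
  perLocus <- wcFst(G, "per_locus")
  withSeed(splitSeed(seed, "popgen"), {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      cols <- which(lab %in% pops[c(i, j)])
      sub <- d[, cols, drop = FALSE]
      grp <- lab[cols] == pops[j]
      if (sum(!grp) < 2 || sum(grp) < 2)
        stop("pair ", pops[i], "-", pops[j], " needs >= 2 individuals each")
      Z <- cbind(!grp, grp) + 0
      wc <- wcComponentsFromDosage(sub, Z)
      A <- wc$a; Tt <- wc$a + wc$b + wc$c
      obs <- sum(A, na.rm = TRUE) / sum(Tt, na.rm = TRUE)
      theta[i, j] <- theta[j, i] <- obs
      ge <- 0
      for (b in seq_len(nPerm)) {
        Zp <- Z[sample.int(nrow(Z)), , drop = FALSE]
        wcp <- wcComponentsFromDosage(sub, Zp)
        tp <- sum(wcp$a, na.rm = TRUE) /
          sum(wcp$a + wcp$b + wcp$c, na.rm = TRUE)
        if (tp >= obs) ge <- ge + 1
      }
      pmat[i, j] <- pmat[j, i] <- (ge + 1) / (nPerm + 1)
      if (nBoot > 0) {
        keep <- which(!is.na(A))
        bt <- vapply(seq_len(nBoot), function(b) {
          idx <- sample(keep, length(keep), replace = TRUE)
          sum(A[idx]) / sum(Tt[idx])
        }, numeric(1))
        qs <- quantile(bt, c(0.025, 0.975), names = FALSE)
        lo[i, j] <- lo[j, i] <- qs[1]
        hi[i, j] <- hi[j, i] <- qs[2]
      }
    }
  })
  up <- upper.tri(pmat)
  padj <- pmat
  padj[up] <- p.adjust(pmat[up], "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  new("FstResult", global = globalTheta, perLocus = perLocus,
      pairwise = theta, p = pmat, pAdj = padj, ciLower = lo, ciUpper = hi)
}

#' Per-population diversity summaries
#'
#' Observed heterozygosity, Nei's unbiased expected heterozygosity
#' (`2pq * 2n/(2n - 1)` per locus, averaged over loci) and the inbreeding
#' coefficient `FIS = 1 - Ho/He` (NA for monomorphic populations).
#'
#' @param G a [GenotypePanel-class].
#' @return data.frame: `population`, `n`, `Ho`, `He`, `FIS`.
#' @export
diversity <- function(G) {
  pp <- perPopStats(G)
  out <- data.frame(population = pp$pops,
                    n = colMeans(pp$n),
                    Ho = NA_real_, He = NA_real_, FIS = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(pp$pops)) {
    ok <- pp$n[, k] > 0
    ho <- mean(pp$h[ok, k])
    he <- mean(2 * pp$p[ok, k] * (1 - pp$p[ok, k]) *
                 2 * pp$n[ok, k] / (2 * pp$n[ok, k] - 1))
    out$Ho[k] <- ho
    out$He[k] <- he
    out$FIS[k] <- if (he > 0) 1 - ho / he else NA_real_
  }
  out
}
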