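#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Three-level decomposition of genetic variance on allele dosages:
#' among groups, among populations within groups, and within populations.
#' Sums of squares use Euclidean distances on (mean-imputed within
#' population) dosage vectors; variance components come from the standard
#' unequal-sample-size expected mean squares, and Phi-statistics from the
#' component ratios. Significance of the among-group component (`FCT`) is
#' tested by permutation: `scheme = "population"` (classical) permutes
#' whole populations among groups, which with few populations has coarse
#' p-value resolution; `scheme = "individual"` permutes individuals among
#' groups and resolves small p-values at the cost of ignoring the
#' population level under the null.
#'
#' @param G a [GenotypePanel-class].
#' @param groups named character vector mapping population label to group.
#' @param nPerm permutations for the FCT test.
#' @param scheme permutation unit for the FCT test.
#' @param seed integer seed.
#' @return An [AmovaResult-class].
#' @export
amova <- function(G, groups, nPerm = 1000,
                  scheme = c("population", "individual"), seed = 1) {
  scheme <- match.arg(scheme)
  pops <- populations(G)
  popLv <- unique(pops)
  if (!all(popLv %in% names(groups)))
    stop("groups must name every population")
  grpOfPop <- groups[popLv]
  if (length(unique(grpOfPop)) < 2) stop("need >= 2 groups")
  if (any(table(grpOfPop) == length(popLv)))
    stop("a group cannot contain all populations")
  X <- t(dosage(imputeMissing(G, "mean_dosage")))
  decompose <- function(grpOfPop, pops) {
    popLv <- unique(pops)
    N <- nrow(X); P <- length(popLv); Gn <- length(unique(grpOfPop))
    grandMean <- colMeans(X)
    ssWP <- 0; ssAP <- 0; ssAG <- 0
    for (p in popLv) {
      rows <- pops == p
      pm <- colMeans(X[rows, , drop = FALSE])
      ssWP <- ssWP + sum(sweep(X[rows, , drop = FALSE], 2, pm)^2)
    }
    for (g in unique(grpOfPop)) {
      popsIn <- popLv[grpOfPop == g]
      rows <- pops %in% popsIn
      gm <- colMeans(X[rows, , drop = FALSE])
      for (p in popsIn) {
        pm <- colMeans(X[pops == p, , drop = FALSE])
        ssAP <- ssAP + sum(pops == p) * sum((pm - gm)^2)
      }
      ssAG <- ssAG + sum(rows) * sum((gm - grandMean)^2)
    }
    dfAG <- Gn - 1; dfAP <- P - Gn; dfWP <- N - P
    nPerPop <- vapply(popLv, function(p) sum(pops == p), numeric(1))
    nPerGrp <- vapply(unique(grpOfPop), function(g)
      sum(nPerPop[grpOfPop == g]), numeric(1))
    sumn2ByGrp <- vapply(unique(grpOfPop), function(g)
      sum(nPerPop[grpOfPop == g]^2), numeric(1))
    nPrime <- (N - sum(sumn2ByGrp / nPerGrp)) / dfAP
    nDoublePrime <- (sum(sumn2ByGrp / nPerGrp) - sum(nPerPop^2) / N) / dfAG
    nTriplePrime <- (N - sum(nPerGrp^2) / N) / dfAG
    msWP <- ssWP / dfWP
    msAP <- ssAP / dfAP
    msAG <- ssAG / dfAG
    sigC <- msWP
    sigB <- (msAP - sigC) / nPrime
    sigA <- (msAG - sigC - nDoublePrime * sigB) / nTriplePrime
    c(a = sigA, b = sigB, c = sigC)
  }
  comp <- decompose(grpOfPop, pops)
  tot <- sum(comp)
  phi <- c(FCT = comp["a"] / tot,
           FSC = comp["b"] / (comp["b"] + comp["c"]),
           FST = (comp["a"] + comp["b"]) / tot)
  names(phi) <- c("FCT", "FSC", "FST")
  obs <- phi["FCT"]
  ge <- 0
  withSeed(splitSeed(seed, "popgen"), {
    for (b in seq_len(nPerm)) {
      perm <- if (scheme == "population")
        decompose(setNames(sample(grpOfPop), popLv), pops)
      else {
        # shuffle individuals among groups: relabel individuals with
        # permuted population labels, keeping the pop-to-group map
        decompose(grpOfPop, sample(pops))
      }
      if (perm["a"] / sum(perm) >= obs) ge <- ge + 1
    }
  })
  comps <- setNames(as.numeric(comp),
                    c("amongGroups", "amongPopsWithinGroups", "withinPops"))
  new("AmovaResult", components = comps,
      percent = 100 * comps / sum(comps), phi = phi,
      p = (ge + 1) / (nPerm + 1))
}

#' Mantel test of isolation by distance
#'
#' Correlates linearised genetic distance `FST / (1 - FST)` with
#' log-geographic distance by a Mantel permutation test.
#'
#' @param fst symmetric pairwise FST matrix.
#' @param geoKm symmetric geographic distance matrix (km), same dimension.
#' @param nPerm Mantel permutations.
#' @param seed integer seed.
#' @return list with `r` and `p`.
#' @export
mantelIbd <- function(fst, geoKm, nPerm = 9999, seed = 1) {
  stopifnot(identical(dim(fst), dim(geoKm)))
  gen <- fst / (1 - fst)
  geo <- log(geoKm)
  diag(gen) <- 0; diag(geo) <- 0
  if (sd(gen[upper.tri(gen)]) == 0 || sd(geo[upper.tri(geo)]) == 0)
    stop("constant distance matrix: Mantel r undefined")
  res <- withSeed(splitSeed(seed, "popgen"),
                  vegan::mantel(as.dist(geo), as.dist(gen),
                                permutations = nPerm))
  list(r = unname(res$statistic), p = res$signif)
}

#' Effective population size from linkage disequilibrium
#'
#' Mean squared composite (Burrows) correlation between all locus pairs
#' within one population, corrected for the sampling expectation
#' `E[r2 | S]` and inverted to Ne under random mating (the drift
#' expectation `E[r2] ~ 1/(3Ne)` for unlinked loci, with the small-sample
#' second-order correction). Negative adjusted r-squared yields
#' `Ne = Inf`. The parametric confidence interval treats the number of
#' locus pairs as independent chi-square draws.
#'
#' @param G a [GenotypePanel-class]; all individuals are treated as one
#'   population (subset first for per-population estimates).
#' @param mafCutoff loci with minor allele frequency below this are
#'   excluded.
#' @return An [NeEstimate-class].
#' @export
neLd <- function(G, mafCutoff = 0.05) {
  d <- dosage(G)
  st <- locusStats(G)
  keep <- !is.na(st$maf) & st$maf >= mafCutoff
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 2) stop("fewer than 2 usable loci after the MAF cutoff")
  r2 <- ldMatrix(d)
  up <- upper.tri(r2)
  vals <- r2[up]
  # per-pair overlapping sample sizes for the harmonic mean
  notNA <- (!is.na(d)) + 0
  Smat <- notNA %*% t(notNA)
  Ss <- Smat[up]
  ok <- !is.na(vals) & Ss >= 2
  vals <- vals[ok]; Ss <- Ss[ok]
  if (!length(vals)) stop("no usable locus pairs")
  S <- length(Ss) / sum(1 / Ss)
  r2bar <- mean(vals)
  J <- length(vals)
  # expectation of a squared Pearson correlation between independent
  # variables over S observations; matches the dosage-correlation statistic
  # used here (verified by sampling theory: E[r2] = 1/(S-1))
  expS <- 1 / (S - 1)
  toNe <- function(r2m) {
    adj <- r2m - expS
    if (is.na(adj) || adj <= 0) return(Inf)
    # second-order drift correction of the 1/(3*adj) inversion
    ne <- (1 / 3 + sqrt(pmax(1 / 9 - 2.76 * adj, 0))) / (2 * adj)
    if (ne <= 0) Inf else ne
  }
  # effective number of independent comparisons: locus pairs sharing a locus
  # are correlated, so the raw pair count overstates the information; a
  # delete-one-locus jackknife of the mean r2 estimates its true variance
  # and Var(mean of n independent chi2_1 scaled draws) = 2*mean^2/n gives n
  r2full <- r2
  diag(r2full) <- NA
  L <- nrow(r2full)
  rowSumsR2 <- rowSums(r2full, na.rm = TRUE)
  rowNs <- rowSums(!is.na(r2full))
  totalSum <- sum(vals)
  jackMeans <- (totalSum - rowSumsR2) / pmax(J - rowNs, 1)
  varJack <- (L - 1) / L * sum((jackMeans - mean(jackMeans))^2)
  Jeff <- if (varJack > 0) max(2, min(J, 2 * r2bar^2 / varJack)) else J
  r2lo <- r2bar * Jeff / qchisq(0.975, Jeff)
  r2hi <- r2bar * Jeff / qchisq(0.025, Jeff)
  new("NeEstimate", estimate = toNe(r2bar),
      ciLower = toNe(r2hi), ciUpper = toNe(r2lo),
      S = S, r2Mean = r2bar, r2Adjusted = r2bar - expS,
      nPairs = as.integer(J), mafCutoff = mafCutoff)
}

# Nei's GST between two sets of allele frequencies (ratio of sums over loci)
neiGstPair <- function(p1, p2) {
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  pb <- (p1 + p2) / 2
  ht <- 2 * pb * (1 - pb)
  ok <- !is.na(hs) & !is.na(ht)
  1 - sum(hs[ok]) / max(sum(ht[ok]), .Machine$double.eps)
}

#' Directional relative migration between population pools
#'
#' For each pair of pools a hypothetical pool of migrants (the mean of the
#' two allele-frequency profiles) is constructed; the genetic
#' differentiation (Nei's GST) between each pool and the migrant pool is
#' inverted to a directional number-of-migrants estimate
#' (`Nm = (1/GST - 1)/4`), and the full directed matrix is normalised to a
#' maximum of 1. Asymmetry significance is assessed by bootstrapping
#' individuals within pools: an ordered pair is flagged when the 95%
#' bootstrap interval of `m[a,b] - m[b,a]` excludes zero. In high gene-flow
#' systems (FST near zero) both pools resemble the migrant pool and
#' directionality is expected to be poorly resolved.
#'
#' @param G a [GenotypePanel-class].
#' @param pools optional named vector mapping population to pool (default:
#'   populations are the pools). Each pool needs >= 3 individuals.
#' @param nBoot bootstrap replicates.
#' @param seed integer seed.
#' @return A [RelativeMigration-class].
#' @export
relativeMigration <- function(G, pools = NULL, nBoot = 1000, seed = 1) {
  pops <- populations(G)
  pool <- if (is.null(pools)) pops else unname(pools[pops])
  lv <- unique(pool)
  if (length(lv) < 2) stop("need >= 2 pools")
  if (any(table(pool) < 3)) stop("every pool needs >= 3 individuals")
  d <- dosage(G)
  freqOf <- function(cols) {
    sub <- d[, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    ifelse(n > 0, rowSums(sub, na.rm = TRUE) / (2 * n), NA)
  }
  mFrom <- function(colList) {
    k <- length(lv)
    fr <- lapply(colList, freqOf)
    m <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      pPool <- (fr[[i]] + fr[[j]]) / 2
      gI <- max(neiGstPair(fr[[i]], pPool), 1e-12)
      gJ <- max(neiGstPair(fr[[j]], pPool), 1e-12)
      m[i, j] <- (1 / gJ - 1) / 4   # migration i -> j: j close to pool
      m[j, i] <- (1 / gI - 1) / 4
    }
    m / max(m, na.rm = TRUE)
  }
  colsOf <- lapply(lv, function(g) which(pool == g))
  names(colsOf) <- lv
  mObs <- mFrom(colsOf)
  diffBoot <- array(NA_real_, c(length(lv), length(lv), nBoot))
  withSeed(splitSeed(seed, "popgen"), {
    for (b in seq_len(nBoot)) {
      bootCols <- lapply(colsOf, function(cc)
        sample(cc, length(cc), replace = TRUE))
      mb <- mFrom(bootCols)
      diffBoot[, , b] <- mb - t(mb)
    }
  })
  signif <- matrix(FALSE, length(lv), length(lv), dimnames = list(lv, lv))
  if (nBoot > 0) {
    for (i in seq_along(lv)) for (j in seq_along(lv)) {
      if (i == j) next
      qs <- quantile(diffBoot[i, j, ], c(0.025, 0.975), na.rm = TRUE)
      signif[i, j] <- qs[1] > 0 | qs[2] < 0
    }
  }
  new("RelativeMigration", m = mObs, significant = signif)
}
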