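# per-population per-locus summaries used across the genetic stages:
# n (non-missing individuals), p (alt-allele freq), h (observed het fraction)
perPopStats <- function(G) {
  d <- dosage(G)
  pops <- populations(G)
  lv <- unique(pops)
  L <- nrow(d)
  n <- p <- h <- matrix(0, L, length(lv), dimnames = list(rownames(d), lv))
  for (k in seq_along(lv)) {
    sub <- d[, pops == lv[k], drop = FALSE]
    nk <- rowSums(!is.na(sub))
    n[, k] <- nk
    p[, k] <- ifelse(nk > 0, rowSums(sub, na.rm = TRUE) / (2 * nk), NA)
    h[, k] <- ifelse(nk > 0, rowSums(sub == 1, na.rm = TRUE) / nk, NA)
  }
  list(n = n, p = p, h = h, pops = lv)
}

#' Per-locus summary statistics
#'
#' Missingness, minor allele frequency (computed over all non-missing calls
#' pooled across sites), observed heterozygosity and pooled expected
#' heterozygosity. Loci with zero non-missing calls are flagged undefined.
#'
#' @param G a [GenotypePanel-class] with at least one locus.
#' @return data.frame: `locus`, `n`, `missing_fraction`, `maf`, `Ho`, `He`,
#'   `defined`.
#' @examples
#' d <- matrix(c(rep(0, 4), rep(1, 5), 2), nrow = 1)
#' G <- genotypePanel(d, rep("A", 10))
#' locusStats(G)  # MAF 0.35, Ho 0.5
#' @export
locusStats <- function(G) {
  if (nrow(G) < 1) stop("need at least one locus")
  d <- dosage(G)
  n <- rowSums(!is.na(d))
  p <- ifelse(n > 0, rowSums(d, na.rm = TRUE) / (2 * n), NA)
  data.frame(locus = rownames(d), n = n,
             missing_fraction = 1 - n / ncol(d),
             maf = pmin(p, 1 - p),
             Ho = ifelse(n > 0, rowSums(d == 1, na.rm = TRUE) / n, NA),
             He = 2 * p * (1 - p),
             defined = n > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Exact conditional test: enumerates all heterozygote counts compatible
#' with the observed allele counts and sums the probabilities of outcomes no
#' more probable than the observed one (two-sided by probability ordering).
#' Suitable for the small per-site samples (12-22 individuals) where the
#' chi-square approximation is unreliable.
#'
#' @param nAA,nAa,naa genotype counts (non-negative).
#' @return p-value in (0, 1].
#' @examples
#' hweExactTest(25, 50, 25)   # ~1: perfect HW proportions
#' hweExactTest(50, 0, 50)    # << 1e-6: no heterozygotes
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  if (any(c(nAA, nAa, naa) < 0)) stop("negative genotype counts")
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  nB <- 2 * n - nA
  if (nA == 0 || nB == 0) return(1)   # monomorphic
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  logp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((nB - hets) / 2) + hets * log(2) +
    lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(nAa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

#' Composite linkage disequilibrium r-squared between two loci
#'
#' Squared Pearson correlation of the dosage vectors over pairwise-complete
#' individuals (the Burrows composite measure for unphased diploid data).
#'
#' @param G a [GenotypePanel-class].
#' @param locusI,locusJ locus ids or indices.
#' @return r-squared, or `NA` if fewer than 2 complete pairs or either locus
#'   has zero variance (treated as not linked).
#' @export
ldR2 <- function(G, locusI, locusJ) {
  d <- dosage(G)
  x <- d[locusI, ]; y <- d[locusJ, ]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])^2
}

# full pairwise r^2 matrix (pairwise-complete); NA for undefined pairs
ldMatrix <- function(d) {
  suppressWarnings(cor(t(d), use = "pairwise.complete.obs"))^2
}

#' Construct a filter report
#'
#' @param steps data.frame with `name`, `n_removed`, `n_retained`.
#' @return A [FilterReport-class] (validity enforces count reconciliation).
#' @export
filterReport <- function(steps) new("FilterReport", steps = steps)

#' Post-assembly SNP filter cascade
#'
#' Applies, in order: (1) locus missingness, (2) minor allele frequency /
#' informativeness, (3) Hardy-Weinberg exact tests per population with
#' within-population FDR adjustment, excluding loci out of HWE in at least
#' half the populations, (4) linkage-disequilibrium pruning (one locus
#' removed per linked pair; the earlier locus id is kept), and (5) an
#' observed-heterozygosity ceiling that removes likely paralog-collapse
#' artefacts. Bookkeeping mirrors the removed/retained table convention of
#' RADseq SNP-panel reports.
#'
#' @param G a [GenotypePanel-class].
#' @param thresholds list overriding any of `missing` (0.30: loci with
#'   *more* missingness removed), `maf` (0.05: loci *below* removed),
#'   `hweAlpha` (0.05 on FDR-adjusted p), `hwePopFraction` (0.5),
#'   `ldR2` (0.8: pairs *above* pruned), `hoMax` (0.6: loci *above*
#'   removed).
#' @return list with `panel` (filtered [GenotypePanel-class]) and `report`
#'   (a [FilterReport-class]).
#' @export
filterCascade <- function(G, thresholds = list()) {
  th <- list(missing = 0.30, maf = 0.05, hweAlpha = 0.05,
             hwePopFraction = 0.5, ldR2 = 0.8, hoMax = 0.6)
  th[names(thresholds)] <- thresholds
  steps <- data.frame(name = "initial", n_removed = 0L,
                      n_retained = nrow(G), stringsAsFactors = FALSE)
  record <- function(name, keep) {
    steps <<- rbind(steps, data.frame(
      name = name, n_removed = sum(!keep),
      n_retained = steps$n_retained[nrow(steps)] - sum(!keep)))
    keep
  }
  cur <- G
  st <- locusStats(cur)
  cur <- cur[record("missing > 30%", st$missing_fraction <= th$missing), ]
  st <- locusStats(cur)
  informative <- !is.na(st$maf) & st$maf >= th$maf & st$maf > 0
  cur <- cur[record("MAF < 0.05, informative loci", informative), ]

  pp <- perPopStats(cur)
  d <- dosage(cur); pops <- populations(cur)
  nPops <- length(pp$pops)
  sig <- matrix(FALSE, nrow(cur), nPops)
  for (k in seq_len(nPops)) {
    sub <- d[, pops == pp$pops[k], drop = FALSE]
    pv <- vapply(seq_len(nrow(sub)), function(l) {
      g <- sub[l, ]; g <- g[!is.na(g)]
      hweExactTest(sum(g == 0), sum(g == 1), sum(g == 2))
    }, numeric(1))
    sig[, k] <- p.adjust(pv, "BH") < th$hweAlpha
  }
  keepHwe <- rowSums(sig) < th$hwePopFraction * nPops
  cur <- cur[record("HWE per population", keepHwe), ]

  if (nrow(cur) > 1) {
    r2 <- ldMatrix(dosage(cur))
    drop <- logical(nrow(cur))
    linked <- which(upper.tri(r2) & !is.na(r2) & r2 > th$ldR2, arr.ind = TRUE)
    linked <- linked[order(linked[, 1], linked[, 2]), , drop = FALSE]
    for (k in seq_len(nrow(linked))) {
      i <- linked[k, 1]; j <- linked[k, 2]
      if (!drop[i] && !drop[j]) drop[j] <- TRUE  # keep the earlier locus
    }
    cur <- cur[record("LD (r2 > 0.8)", !drop), ]
  } else {
    record("LD (r2 > 0.8)", rep(TRUE, nrow(cur)))
  }
  st <- locusStats(cur)
  cur <- cur[record("observed heterozygosity > 0.6", st$Ho <= th$hoMax), ]
  if (nrow(cur) == 0)
    warning("no loci survive the cascade; downstream analyses will fail")
  list(panel = cur, report = filterReport(steps))
}

#' Impute missing genotypes from population allele frequencies
#'
#' `mean_dosage` replaces each missing call with the population's expected
#' dosage (`2p`); `sample_from_pop_freq` draws a genotype from
#' Binomial(2, p). Populations with no calls at a locus fall back to the
#' global frequency (0.5 if the locus has no calls anywhere).
#'
#' @param G a [GenotypePanel-class].
#' @param mode `"mean_dosage"` or `"sample_from_pop_freq"`.
#' @param seed integer seed (sample mode).
#' @return A [GenotypePanel-class] without missing values.
#' @export
imputeMissing <- function(G, mode = c("mean_dosage", "sample_from_pop_freq"),
                          seed = 1) {
  mode <- match.arg(mode)
  d <- dosage(G)
  if (!anyNA(d)) return(G)
  pops <- populations(G)
  pp <- perPopStats(G)
  nGlob <- rowSums(pp$n)
  pGlob <- ifelse(nGlob > 0,
                  rowSums(pp$p * pp$n, na.rm = TRUE) / nGlob, 0.5)
  withSeed(splitSeed(seed, "filtering"), {
    for (k in seq_along(pp$pops)) {
      cols <- which(pops == pp$pops[k])
      pk <- ifelse(pp$n[, k] > 0, pp$p[, k], pGlob)
      sub <- d[, cols, drop = FALSE]
      miss <- which(is.na(sub), arr.ind = TRUE)
      if (nrow(miss) == 0) next
      pmiss <- pk[miss[, 1]]
      sub[miss] <- if (mode == "mean_dosage") 2 * pmiss
                   else rbinom(nrow(miss), 2, pmiss)
      d[, cols] <- sub
    }
  })
  out <- G
  SummarizedExperiment::assay(out, "dosage") <- d
  out
}
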