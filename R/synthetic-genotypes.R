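#' Metapopulation simulation configuration
#'
#' Bundles and validates the parameters of the forward Wright-Fisher
#' metapopulation simulator. Defaults emulate the study design the package's
#' synthetic data are built around: 8 sites of 12-22 diploid individuals,
#' ~1,600 biallelic SNPs with weak neutral structure (global FST about
#' 0.005) and a handful of strongly differentiated loci under latitudinal
#' clinal selection.
#'
#' @param nDemes number of demes.
#' @param demeSizes diploid individuals per deme (recycled).
#' @param migrationMatrix row-stochastic backward migration matrix
#'   (`m[i, j]` = probability a gene in deme i came from deme j); default is
#'   an island model with total emigration `migrationRate`.
#' @param migrationRate total per-generation migration used to build the
#'   default island-model matrix.
#' @param nNeutralLoci,nSelectedLoci locus counts.
#' @param selectionGradient selection coefficient per unit of
#'   `latitudeRank`; deme-specific coefficient is
#'   `selectionGradient * (latitudeRank - mean(latitudeRank))`, so selection
#'   favours the alternate allele at high ranks and disfavours it at low
#'   ranks (a latitudinal cline).
#' @param latitudeRank integer rank per deme (default `1:nDemes`).
#' @param nGenerations forward generations simulated.
#' @param sampleSizes individuals sampled per deme (recycled; must not
#'   exceed the deme size).
#' @param missingRate genotype-level missingness applied uniformly at random.
#' @return A validated list of class `MetapopConfig`.
#' @examples
#' cfg <- metapopConfig(nDemes = 4, demeSizes = 50, nNeutralLoci = 100)
#' @export
metapopConfig <- function(nDemes = 8,
                          demeSizes = 400,
                          migrationMatrix = NULL,
                          migrationRate = 0.10,
                          nNeutralLoci = 1588,
                          nSelectedLoci = 12,
                          selectionGradient = 0.07,
                          latitudeRank = seq_len(nDemes),
                          nGenerations = 150,
                          sampleSizes = c(14, 13, 15, 12, 22, 13, 15, 12),
                          missingRate = 0.05) {
  demeSizes <- rep_len(demeSizes, nDemes)
  sampleSizes <- rep_len(sampleSizes, nDemes)
  if (is.null(migrationMatrix)) {
    m <- migrationRate / (nDemes - 1)
    migrationMatrix <- matrix(m, nDemes, nDemes)
    diag(migrationMatrix) <- 1 - migrationRate
  }
  cfg <- list(nDemes = nDemes, demeSizes = demeSizes,
              migrationMatrix = migrationMatrix,
              nNeutralLoci = nNeutralLoci, nSelectedLoci = nSelectedLoci,
              selectionGradient = selectionGradient,
              latitudeRank = rep_len(latitudeRank, nDemes),
              nGenerations = nGenerations, sampleSizes = sampleSizes,
              missingRate = missingRate)
  class(cfg) <- "MetapopConfig"
  validateMetapopConfig(cfg)
  cfg
}

validateMetapopConfig <- function(cfg) {
  M <- cfg$migrationMatrix
  if (!is.matrix(M) || nrow(M) != cfg$nDemes || ncol(M) != cfg$nDemes)
    stop("migrationMatrix must be nDemes x nDemes")
  if (any(M < 0) || any(abs(rowSums(M) - 1) > 1e-8))
    stop("migration matrix rows must be nonnegative and sum to 1")
  if (any(cfg$demeSizes < 2)) stop("demeSizes must be >= 2")
  if (cfg$missingRate < 0 || cfg$missingRate >= 1)
    stop("missingRate must be in [0, 1)")
  if (any(cfg$sampleSizes > cfg$demeSizes))
    stop("sample size cannot exceed deme size")
  invisible(cfg)
}

#' Simulate metapopulation SNP genotypes
#'
#' Forward-in-time Wright-Fisher simulation with backward migration and
#' deme-specific viability selection on the planted non-neutral loci, then
#' sampling of diploid individuals with uniform missingness. Two engines:
#'
#' * `"frequency"` (default): deme allele frequencies migrate
#'   deterministically (`p <- M p`), selection reweights frequencies
#'   (`p(1+s) / (1 + ps)`), and drift is binomial sampling of `2N` gene
#'   copies per deme. Loci evolve independently; fast, and sufficient for
#'   any FST-level target.
#' * `"individual"`: a pedigree-based engine in which each offspring draws
#'   two parents (deme of origin from the backward-migration row, parents
#'   weighted by viability fitness) and one gamete per parent per locus.
#'   Shared pedigrees generate the background linkage disequilibrium that
#'   the LD-based effective-size estimator measures; use this engine when
#'   LD itself is the quantity of interest.
#'
#' @param config a [metapopConfig()] object.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param engine `"frequency"` or `"individual"`.
#' @param initFreq initial alternate-allele frequencies (recycled over loci;
#'   default draws from U(0.1, 0.9)).
#' @return A [GenotypePanel-class]; `rowData(G)$selected` marks planted
#'   selected loci, `rowData(G)$sel_coef` the per-rank coefficient.
#' @examples
#' cfg <- metapopConfig(nDemes = 3, demeSizes = 30, nNeutralLoci = 50,
#'                      nSelectedLoci = 0, nGenerations = 20,
#'                      sampleSizes = 10)
#' G <- simulateMetapopulation(cfg, seed = 1)
#' @export
simulateMetapopulation <- function(config, seed = 1,
                                   engine = c("frequency", "individual"),
                                   initFreq = NULL) {
  validateMetapopConfig(config)
  engine <- match.arg(engine)
  d <- config$nDemes
  L <- config$nNeutralLoci + config$nSelectedLoci
  selected <- c(rep(FALSE, config$nNeutralLoci), rep(TRUE, config$nSelectedLoci))
  rankC <- config$latitudeRank - mean(config$latitudeRank)
  sDeme <- outer(rankC, as.numeric(selected) * config$selectionGradient) # d x L
  N <- config$demeSizes
  M <- config$migrationMatrix

  withSeed(splitSeed(seed, "metapop"), {
    p0 <- if (is.null(initFreq)) runif(L, 0.1, 0.9) else rep_len(initFreq, L)
    if (engine == "frequency") {
      p <- matrix(rep(p0, each = d), d, L)
      for (g in seq_len(config$nGenerations)) {
        p <- M %*% p
        if (config$nSelectedLoci > 0) {
          w <- 1 + sDeme
          p <- p * w / (1 + p * sDeme)
        }
        p <- pmin(pmax(p, 0), 1)  # guard rounding from the matrix product
        p <- matrix(rbinom(d * L, 2 * N, p), d, L) / (2 * N)
      }
      dos <- sampleGenotypes(p, config$sampleSizes)
    } else {
      # individuals in rows, loci in columns, per deme
      demes <- lapply(seq_len(d), function(k)
        matrix(rbinom(N[k] * L, 2, rep(p0, each = N[k])), N[k], L))
      for (g in seq_len(config$nGenerations)) {
        fitness <- lapply(seq_len(d), function(k) {
          if (config$nSelectedLoci == 0) rep(1, N[k])
          else exp(demes[[k]][, selected, drop = FALSE] %*%
                     log1p(pmax(sDeme[k, selected], -0.99)))
        })
        newDemes <- vector("list", d)
        for (k in seq_len(d)) {
          srcA <- sample.int(d, N[k], replace = TRUE, prob = M[k, ])
          srcB <- sample.int(d, N[k], replace = TRUE, prob = M[k, ])
          child <- matrix(0L, N[k], L)
          for (src in unique(c(srcA, srcB))) {
            ia <- which(srcA == src)
            if (length(ia)) {
              par <- sample.int(N[src], length(ia), replace = TRUE,
                                prob = fitness[[src]])
              g1 <- matrix(rbinom(length(ia) * L, 1,
                                  demes[[src]][par, , drop = FALSE] / 2),
                           length(ia), L)
              child[ia, ] <- child[ia, ] + g1
            }
            ib <- which(srcB == src)
            if (length(ib)) {
              par <- sample.int(N[src], length(ib), replace = TRUE,
                                prob = fitness[[src]])
              g2 <- matrix(rbinom(length(ib) * L, 1,
                                  demes[[src]][par, , drop = FALSE] / 2),
                           length(ib), L)
              child[ib, ] <- child[ib, ] + g2
            }
          }
          newDemes[[k]] <- child
        }
        demes <- newDemes
      }
      dos <- do.call(cbind, lapply(seq_len(d), function(k)
        t(demes[[k]][sample.int(N[k], config$sampleSizes[k]), , drop = FALSE])))
    }
    if (config$missingRate > 0) {
      miss <- runif(length(dos)) < config$missingRate
      dos[miss] <- NA
    }
  })
  popLabels <- rep(sprintf("P%02d", seq_len(d)), config$sampleSizes)
  rownames(dos) <- sprintf("L%04d", seq_len(L))
  colnames(dos) <- sprintf("%s_i%02d", popLabels,
                           unlist(lapply(config$sampleSizes, seq_len)))
  genotypePanel(dos, popLabels,
                lociData = S4Vectors::DataFrame(
                  selected = selected,
                  sel_coef = as.numeric(selected) * config$selectionGradient))
}

# sample diploid genotypes from deme allele frequencies:
# returns loci x individuals dosage matrix
sampleGenotypes <- function(p, sampleSizes) {
  d <- nrow(p); L <- ncol(p)
  cols <- vector("list", d)
  for (k in seq_len(d)) {
    n <- sampleSizes[k]
    cols[[k]] <- matrix(rbinom(n * L, 2, rep(p[k, ], each = n)), L, n,
                        byrow = TRUE)
  }
  do.call(cbind, cols)
}
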