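#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats cor dist optim p.adjust pchisq dchisq qchisq quantile
#'   rbinom rbeta rnorm runif sd var prcomp setNames predict aggregate as.dist
#' @importFrom utils head read.csv write.csv write.table read.table
NULL

#' GenotypePanel: diploid biallelic SNP dosages with population labels
#'
#' The hub object of all genetic stages. Extends
#' [SummarizedExperiment::SummarizedExperiment] with a single `"dosage"` assay
#' holding alternate-allele dosages (loci in rows, individuals in columns;
#' values 0, 1, 2 or `NA` for missing) and a mandatory `population` column in
#' `colData`.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [genotypePanel()], [dosage()], [populations()]
#' @export
setClass("GenotypePanel", contains = "SummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  msg <- NULL
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- d[!is.na(d)]
    # raw calls are 0/1/2; mean-imputed panels carry expected dosages in [0, 2]
    if (length(bad) && (any(bad < 0) || any(bad > 2)))
      msg <- c(msg, "dosages must lie in [0, 2] or be NA")
  }
  if (!"population" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData column 'population' is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "locus ids (rownames) must be unique")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypePanel
#'
#' @param dosage numeric/integer matrix, loci x individuals, entries 0/1/2/NA.
#' @param populations character or factor of length `ncol(dosage)`.
#' @param lociData optional `DataFrame`/data.frame of per-locus annotation
#'   (e.g. a logical `selected` column for planted non-neutral loci).
#' @return A [GenotypePanel-class] object.
#' @examples
#' d <- matrix(c(0, 1, 2, 1, 0, 2), nrow = 2,
#'             dimnames = list(c("L1", "L2"), c("i1", "i2", "i3")))
#' g <- genotypePanel(d, populations = c("A", "A", "B"))
#' dosage(g)
#' @export
genotypePanel <- function(dosage, populations, lociData = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("L%04d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("ind%03d", seq_len(ncol(dosage)))
  if (length(populations) != ncol(dosage))
    stop("length(populations) must equal the number of individuals")
  cd <- S4Vectors::DataFrame(population = as.character(populations),
                             row.names = colnames(dosage))
  rd <- if (is.null(lociData)) S4Vectors::DataFrame(row.names = rownames(dosage))
        else S4Vectors::DataFrame(lociData, row.names = rownames(dosage))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage), colData = cd, rowData = rd)
  new("GenotypePanel", se)
}

#' VelocityField: gridded surface-velocity field on a regular lon/lat grid
#'
#' Stand-in for ocean-model surface currents: `u` (eastward) and `v`
#' (northward) velocities in m/s on a (time, lat, lon) grid, with a land mask.
#' Velocities are identically zero on land cells.
#'
#' @slot lon,lat strictly ascending 1-D grids (decimal degrees).
#' @slot time 1-D grid, days since simulation start.
#' @slot u,v numeric arrays dim (time, lat, lon), m/s.
#' @slot landMask logical matrix dim (lat, lon); `TRUE` = land.
#' @export
setClass("VelocityField",
  representation(lon = "numeric", lat = "numeric", time = "numeric",
                 u = "array", v = "array", landMask = "matrix"))

setValidity("VelocityField", function(object) {
  msg <- NULL
  dims <- c(length(object@time), length(object@lat), length(object@lon))
  if (!identical(dim(object@u), dims) || !identical(dim(object@v), dims))
    msg <- c(msg, "u and v must have dim (time, lat, lon)")
  if (any(diff(object@lon) <= 0) || any(diff(object@lat) <= 0))
    msg <- c(msg, "grid spacing must be strictly positive")
  if (!all(is.finite(object@u)) || !all(is.finite(object@v)))
    msg <- c(msg, "u and v must be finite everywhere")
  if (!identical(dim(object@landMask), dims[2:3]))
    msg <- c(msg, "landMask must have dim (lat, lon)")
  if (length(msg) == 0) {
    land <- which(object@landMask, arr.ind = TRUE)
    if (nrow(land)) {
      for (k in seq_len(length(object@time))) {
        uk <- object@u[k, , ]; vk <- object@v[k, , ]
        if (any(uk[land] != 0) || any(vk[land] != 0)) {
          msg <- c(msg, "u and v must be zero on land cells"); break
        }
      }
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' ConnectivityMatrix: directed source-to-sink settlement proportions
#'
#' Rows are particle source sites, columns settlement pools. Entry (s, p) is
#' the proportion of particles released from `s` that settled in pool `p`
#' (denominator = particles released, so rows need not sum to 1: mortality and
#' loss stay visible). The diagonal (matching labels) is self-recruitment.
#'
#' @slot prob numeric matrix of settlement proportions in \[0, 1\].
#' @slot released named numeric, particles released per source row.
#' @slot settled numeric matrix of raw settlement counts.
#' @export
setClass("ConnectivityMatrix",
  representation(prob = "matrix", released = "numeric", settled = "matrix"))

setValidity("ConnectivityMatrix", function(object) {
  msg <- NULL
  if (any(object@prob < 0) || any(object@prob > 1))
    msg <- c(msg, "proportions must lie in [0, 1]")
  if (any(rowSums(object@prob) > 1 + 1e-9))
    msg <- c(msg, "row sums cannot exceed 1")
  if (length(object@released) != nrow(object@prob))
    msg <- c(msg, "one released count per source row required")
  if (is.null(msg)) TRUE else msg
})

#' AEMBasis: asymmetric eigenvector maps from a directed connectivity graph
#'
#' Spatial eigenfunctions encoding directional processes (here, ocean-current
#' mediated dispersal) for use as ordination predictors. Built from the
#' site-by-edge incidence of the direction-retained connectivity graph.
#'
#' @slot vectors sites x eigenfunction matrix (orthonormal columns, named
#'   `AEM1`, `AEM2`, ...).
#' @slot values singular values of the centred, weight-scaled incidence matrix.
#' @slot edges data.frame with `from`, `to`, `weight` for retained edges.
#' @export
setClass("AEMBasis",
  representation(vectors = "matrix", values = "numeric", edges = "data.frame"))

setValidity("AEMBasis", function(object) {
  msg <- NULL
  if (ncol(object@vectors) != length(object@values))
    msg <- c(msg, "one singular value per eigenfunction required")
  if (ncol(object@vectors) > 0) {
    g <- crossprod(object@vectors)
    if (max(abs(g - diag(ncol(g)))) > 1e-8)
      msg <- c(msg, "eigenfunctions must be orthonormal")
  }
  if (is.null(msg)) TRUE else msg
})

#' RDAModel: redundancy-analysis fit
#'
#' Constrained ordination: PCA of the fitted values of the multivariate
#' regression of a (column-centred) response on predictors.
#'
#' @slot Y,X centred response and predictor matrices used in the fit.
#' @slot eigenvalues canonical eigenvalues (variances of fitted-value PCs).
#' @slot siteScores site scores on the canonical axes.
#' @slot R2,R2adj coefficient of determination and its adjusted form.
#' @slot rank number of canonical axes.
#' @slot pseudoF global pseudo-F statistic.
#' @export
setClass("RDAModel",
  representation(Y = "matrix", X = "matrix", eigenvalues = "numeric",
                 siteScores = "matrix", R2 = "numeric", R2adj = "numeric",
                 rank = "integer", pseudoF = "numeric"))

#' OutlierScan: per-locus FST-outlier scan result
#'
#' @slot stats data.frame with per-locus `locus`, `He`, `theta`, `p`, `q`,
#'   `flag` columns (columns may be NA for methods that do not produce them).
#' @slot method scan method label.
#' @slot params list of method parameters.
#' @export
setClass("OutlierScan",
  representation(stats = "data.frame", method = "character", params = "list"))

#' FilterReport: per-step bookkeeping of the SNP filter cascade
#'
#' @slot steps data.frame with `name`, `n_removed`, `n_retained`, one row per
#'   cascade step; counts reconcile (`retained[k] = retained[k-1] - removed[k]`).
#' @export
setClass("FilterReport", representation(steps = "data.frame"))

setValidity("FilterReport", function(object) {
  s <- object@steps
  if (!all(c("name", "n_removed", "n_retained") %in% names(s)))
    return("steps needs columns name, n_removed, n_retained")
  if (nrow(s) > 1) {
    ok <- all(s$n_retained[-1] == s$n_retained[-nrow(s)] - s$n_removed[-1])
    if (!ok) return("retained counts do not reconcile with removals")
  }
  TRUE
})

#' FstResult: Weir-Cockerham differentiation estimates with inference
#'
#' @slot global multi-locus global theta (ratio of sums).
#' @slot perLocus per-locus theta.
#' @slot pairwise symmetric matrix of pairwise theta.
#' @slot p,pAdj raw and FDR-adjusted permutation p-values (pairwise).
#' @slot ciLower,ciUpper bootstrap-over-loci confidence bounds (pairwise).
#' @export
setClass("FstResult",
  representation(global = "numeric", perLocus = "numeric", pairwise = "matrix",
                 p = "matrix", pAdj = "matrix", ciLower = "matrix",
                 ciUpper = "matrix"))

#' AmovaResult: hierarchical analysis of molecular variance
#'
#' @slot components named variance components (amongGroups,
#'   amongPopsWithinGroups, withinPops).
#' @slot percent components as percent of total.
#' @slot phi named Phi-statistics (FCT, FSC, FST).
#' @slot p permutation p-value for FCT (populations permuted among groups).
#' @export
setClass("AmovaResult",
  representation(components = "numeric", percent = "numeric",
                 phi = "numeric", p = "numeric"))

#' NeEstimate: linkage-disequilibrium effective population size
#'
#' @slot estimate point estimate (diploid individuals; `Inf` when the adjusted
#'   mean r-squared is at or below its sampling expectation).
#' @slot ciLower,ciUpper parametric 95 percent confidence bounds.
#' @slot S harmonic-mean sample size over locus pairs.
#' @slot r2Mean,r2Adjusted mean composite r-squared before/after removing the
#'   sampling expectation.
#' @slot nPairs number of locus pairs used.
#' @slot mafCutoff minor-allele-frequency cutoff applied.
#' @export
setClass("NeEstimate",
  representation(estimate = "numeric", ciLower = "numeric", ciUpper = "numeric",
                 S = "numeric", r2Mean = "numeric", r2Adjusted = "numeric",
                 nPairs = "integer", mafCutoff = "numeric"))

#' RelativeMigration: directional relative migration between pools
#'
#' @slot m directed matrix of relative migration, normalised so max = 1;
#'   `m[a, b]` is migration from a into b. Diagonal is NA.
#' @slot significant logical matrix: bootstrap support for asymmetry of the
#'   (a, b) vs (b, a) pair.
#' @export
setClass("RelativeMigration",
  representation(m = "matrix", significant = "matrix"))

#' DAPCModel: discriminant analysis of principal components
#'
#' @slot nPca retained principal components.
#' @slot loadings discriminant-function loadings in PC space.
#' @slot scores per-individual discriminant scores.
#' @slot posterior per-individual group membership probabilities (rows sum 1).
#' @slot assign predicted group per individual.
#' @slot xval data.frame cross-validation curve: `n_pca`, `error` per replicate.
#' @export
setClass("DAPCModel",
  representation(nPca = "integer", loadings = "matrix", scores = "matrix",
                 posterior = "matrix", assign = "character",
                 xval = "data.frame"))
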