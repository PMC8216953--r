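#' Accessors for seagen classes
#'
#' Small accessor layer so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @describeIn accessors dosage matrix (loci x individuals) of a
#'   [GenotypePanel-class].
#' @export
dosage <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @describeIn accessors population label per individual.
#' @export
populations <- function(x) SummarizedExperiment::colData(x)$population

#' @describeIn accessors number of loci.
#' @export
nLoci <- function(x) nrow(x)

#' @describeIn accessors unique population labels, in order of appearance.
#' @export
popLevels <- function(x) unique(populations(x))

#' @describeIn accessors settlement-proportion matrix of a
#'   [ConnectivityMatrix-class].
#' @export
connProb <- function(x) x@prob

#' @describeIn accessors particles released per source.
#' @export
connReleased <- function(x) x@released

#' @describeIn accessors self-recruitment diagonal (sources that are also
#'   sinks), released-normalised.
#' @export
selfRecruitment <- function(x) {
  common <- intersect(rownames(x@prob), colnames(x@prob))
  setNames(x@prob[cbind(common, common)], common)
}

#' @describeIn accessors eigenfunction matrix of an [AEMBasis-class].
#' @export
aemVectors <- function(x) x@vectors

#' @describeIn accessors retained directed edges of an [AEMBasis-class].
#' @export
aemEdges <- function(x) x@edges

#' @describeIn accessors per-step bookkeeping table of a
#'   [FilterReport-class].
#' @export
filterSteps <- function(x) x@steps

#' @describeIn accessors per-locus statistics of an [OutlierScan-class].
#' @export
scanStats <- function(x) x@stats

#' @describeIn accessors locus ids flagged by an [OutlierScan-class].
#' @export
flaggedLoci <- function(x) x@stats$locus[which(x@stats$flag)]

setMethod("show", "GenotypePanel", function(object) {
  pops <- table(populations(object))
  cat("GenotypePanel:", nrow(object), "loci x", ncol(object), "individuals\n")
  cat(" populations:", paste0(names(pops), "(", pops, ")", collapse = " "), "\n")
  d <- dosage(object)
  cat(sprintf(" missing: %.1f%%\n", 100 * mean(is.na(d))))
})

setMethod("show", "VelocityField", function(object) {
  cat("VelocityField:", length(object@lon), "lon x", length(object@lat),
      "lat x", length(object@time), "time\n")
  cat(sprintf(" lon [%.2f, %.2f]  lat [%.2f, %.2f]  land %.0f%%\n",
      min(object@lon), max(object@lon), min(object@lat), max(object@lat),
      100 * mean(object@landMask)))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat("ConnectivityMatrix:", nrow(object@prob), "sources x",
      ncol(object@prob), "sinks\n")
  cat(sprintf(" mean settlement %.3f; self-recruitment %s\n",
      mean(rowSums(object@prob)),
      paste(sprintf("%.2f", selfRecruitment(object)), collapse = " ")))
})

setMethod("show", "AEMBasis", function(object) {
  cat("AEMBasis:", ncol(object@vectors), "eigenfunctions over",
      nrow(object@vectors), "sites;", nrow(object@edges), "edges\n")
})

setMethod("show", "RDAModel", function(object) {
  cat("RDAModel:", nrow(object@Y), "sites,", ncol(object@X), "predictors,",
      object@rank, "canonical axes\n")
  cat(sprintf(" R2 = %.4f  R2adj = %.4f  pseudo-F = %.3f\n",
      object@R2, object@R2adj, object@pseudoF))
})

setMethod("show", "OutlierScan", function(object) {
  cat("OutlierScan [", object@method, "]: ", nrow(object@stats), " loci, ",
      sum(object@stats$flag, na.rm = TRUE), " flagged\n", sep = "")
})

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport:\n")
  print(object@steps, row.names = FALSE)
})

setMethod("show", "FstResult", function(object) {
  cat(sprintf("FstResult: global theta = %.4f over %d loci; %d populations\n",
      object@global, length(object@perLocus), nrow(object@pairwise)))
})

setMethod("show", "AmovaResult", function(object) {
  cat("AmovaResult:\n")
  print(round(rbind(component = object@components,
                    percent = object@percent), 4))
  cat(sprintf(" FCT = %.4f (p = %.4g)  FSC = %.4f  FST = %.4f\n",
      object@phi["FCT"], object@p, object@phi["FSC"], object@phi["FST"]))
})

setMethod("show", "NeEstimate", function(object) {
  cat(sprintf(
    "NeEstimate (LD): Ne = %.1f [%.1f, %.1f]; S = %.1f, %d pairs, MAF >= %.2f\n",
    object@estimate, object@ciLower, object@ciUpper, object@S,
    object@nPairs, object@mafCutoff))
})

setMethod("show", "RelativeMigration", function(object) {
  cat("RelativeMigration over", nrow(object@m), "pools (max-normalised)\n")
  print(round(object@m, 3))
})

setMethod("show", "DAPCModel", function(object) {
  cat("DAPCModel:", object@nPca, "PCs retained,", ncol(object@scores),
      "discriminant functions\n")
})
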