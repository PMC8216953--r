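#' Write a GenotypePanel in genepop format
#'
#' Two-digit allele coding: dosage 0 = `0101`, 1 = `0102`, 2 = `0202`,
#' missing = `0000`.
#'
#' @param G a [GenotypePanel-class].
#' @param file output path.
#' @param title first (comment) line of the file.
#' @export
writeGenepop <- function(G, file, title = "seagen genotype export") {
  d <- dosage(G)
  pops <- populations(G)
  code <- c("0101", "0102", "0202")
  lines <- c(title, rownames(d))
  for (p in unique(pops)) {
    lines <- c(lines, "Pop")
    for (i in which(pops == p)) {
      g <- d[, i]
      gc <- ifelse(is.na(g), "0000", code[g + 1])
      lines <- c(lines, paste0(colnames(d)[i], " ,  ", paste(gc, collapse = " ")))
    }
  }
  writeLines(lines, file)
  invisible(file)
}

#' Read a genepop file into a GenotypePanel
#'
#' Accepts 2- or 3-digit allele coding; `0000`/`000000` is missing. Dosage
#' is the count of the numerically larger allele observed at the locus.
#'
#' @param file genepop path.
#' @return A [GenotypePanel-class]; populations are labelled `P01`, `P02`,
#'   ... in file order.
#' @export
readGenepop <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  popIdx <- grep("^pop$", lines, ignore.case = TRUE)
  if (!length(popIdx)) stop("no 'Pop' lines found; not a genepop file")
  header <- lines[2:(popIdx[1] - 1)]
  loci <- unlist(strsplit(paste(header, collapse = ","), ","))
  loci <- trimws(loci)
  nL <- length(loci)
  inds <- list(); pops <- character(0)
  popNo <- 0L
  for (i in seq_along(lines)) {
    if (grepl("^pop$", lines[i], ignore.case = TRUE)) { popNo <- popNo + 1L; next }
    if (i <= popIdx[1] - 1 || popNo == 0L) next
    parts <- strsplit(lines[i], ",")[[1]]
    name <- trimws(parts[1])
    gtxt <- strsplit(trimws(paste(parts[-1], collapse = " ")), "[[:space:]]+")[[1]]
    if (length(gtxt) != nL) stop("individual ", name, ": expected ", nL,
                                 " genotypes, got ", length(gtxt))
    w <- nchar(gtxt[1]) / 2
    a1 <- as.integer(substr(gtxt, 1, w))
    a2 <- as.integer(substr(gtxt, w + 1, 2 * w))
    dos <- ifelse(a1 == 0 | a2 == 0, NA_integer_,
                  (a1 == 2) + (a2 == 2))
    inds[[length(inds) + 1L]] <- dos
    pops <- c(pops, sprintf("P%02d", popNo))
    names(inds)[length(inds)] <- name
  }
  d <- do.call(cbind, inds)
  rownames(d) <- loci
  genotypePanel(d, pops)
}

#' Write a GenotypePanel as VCF (plus a population map)
#'
#' Loci become rows of a minimal VCF (GT field only; missing = `./.`).
#' Population labels cannot live in a VCF, so a two-column population map
#' CSV is written alongside.
#'
#' @param G a [GenotypePanel-class].
#' @param file output path; vcfR gzips, so use a `.vcf.gz` name.
#' @param popmapFile optional path for the individual-to-population map.
#' @importClassesFrom vcfR vcfR
#' @export
writeVcfPanel <- function(G, file, popmapFile = NULL) {
  d <- dosage(G)
  gtCode <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(d), ncol(d), dimnames = dimnames(d))
  ok <- !is.na(d)
  gt[ok] <- gtCode[d[ok] + 1]
  fix <- cbind(CHROM = "1", POS = as.character(seq_len(nrow(d))),
               ID = rownames(d), REF = "A", ALT = "T", QUAL = ".",
               FILTER = "PASS", INFO = ".")
  gt2 <- cbind(FORMAT = "GT", gt)
  obj <- new("vcfR",
             meta = c("##fileformat=VCFv4.2",
                      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             fix = fix, gt = gt2)
  vcfR::write.vcf(obj, file)
  if (!is.null(popmapFile))
    write.csv(data.frame(individual = colnames(d),
                         population = populations(G)),
              popmapFile, row.names = FALSE)
  invisible(file)
}

#' Read a biallelic VCF into a GenotypePanel
#'
#' @param file VCF path (plain or gzipped).
#' @param popmap optional data.frame (`individual`, `population`) or path to
#'   such a CSV; without it, every individual goes into population `"P01"`.
#' @return A [GenotypePanel-class] of alternate-allele dosages.
#' @export
readVcfPanel <- function(file, popmap = NULL) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt1 <- substr(gt, 1, 1); alt2 <- substr(gt, 3, 3)
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  ok <- !is.na(gt) & alt1 %in% c("0", "1") & alt2 %in% c("0", "1")
  d[ok] <- as.integer(alt1[ok]) + as.integer(alt2[ok])
  if (is.character(popmap)) popmap <- read.csv(popmap)
  pops <- if (is.null(popmap)) rep("P01", ncol(d))
          else popmap$population[match(colnames(d), popmap$individual)]
  ids <- vcfR::getID(v)
  if (!any(is.na(ids)) && !anyDuplicated(ids)) rownames(d) <- ids
  genotypePanel(d, pops)
}

#' Write a velocity field as plain-text files
#'
#' Writes `header.json` (grids, dimensions) and `uv.csv` (long format:
#' `time_index`, `lat_index`, `lon_index`, `u`, `v`, `land`) into `dir`.
#'
#' @param field a [VelocityField-class].
#' @param dir output directory (created if absent).
#' @export
writeVelocityField <- function(field, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(lon = field@lon, lat = field@lat,
                            time = field@time),
                       file.path(dir, "header.json"), digits = NA)
  nt <- length(field@time); ny <- length(field@lat); nx <- length(field@lon)
  idx <- expand.grid(time_index = seq_len(nt), lat_index = seq_len(ny),
                     lon_index = seq_len(nx), KEEP.OUT.ATTRS = FALSE)
  idx$u <- field@u[as.matrix(idx[, 1:3])]
  idx$v <- field@v[as.matrix(idx[, 1:3])]
  idx$land <- as.integer(field@landMask[as.matrix(idx[, 2:3])])
  write.csv(idx, file.path(dir, "uv.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a velocity field written by [writeVelocityField()]
#'
#' @param dir directory with `header.json` and `uv.csv`.
#' @return A [VelocityField-class].
#' @export
readVelocityField <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "header.json"), simplifyVector = TRUE)
  uv <- read.csv(file.path(dir, "uv.csv"))
  nt <- length(hdr$time); ny <- length(hdr$lat); nx <- length(hdr$lon)
  u <- array(0, c(nt, ny, nx)); v <- array(0, c(nt, ny, nx))
  land <- matrix(FALSE, ny, nx)
  u[as.matrix(uv[, 1:3])] <- uv$u
  v[as.matrix(uv[, 1:3])] <- uv$v
  land[as.matrix(uv[, 2:3])] <- uv$land == 1
  new("VelocityField", lon = hdr$lon, lat = hdr$lat, time = hdr$time,
      u = u, v = v, landMask = land)
}

#' Write a connectivity matrix as labelled CSV
#'
#' Sources in rows; a `released` column records the denominators.
#'
#' @param C a [ConnectivityMatrix-class].
#' @param file output path.
#' @export
writeConnectivity <- function(C, file) {
  df <- data.frame(source = rownames(C@prob), released = C@released,
                   C@prob, check.names = FALSE)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
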