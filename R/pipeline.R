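#' Scenario configuration for the end-to-end pipeline
#'
#' Assembles (and validates) all stage parameters with study-style
#' defaults, scaled so a desk-size run completes in minutes. Every source
#' of randomness derives from the single `seed` via [splitSeed()].
#'
#' @param outDir output directory.
#' @param seed global integer seed.
#' @param field list of [makeBasinField()] arguments.
#' @param nSites number of sampling sites.
#' @param nodeSpacingKm coastline node spacing.
#' @param dispersal list: `particlesPerRelease`, `intervalDays`,
#'   `durationDays`, `dtHours`, `settlementRadiusKm`, `poolingRadiusKm`.
#' @param metapop list of [metapopConfig()] overrides (`migrationRate` is
#'   replaced by connectivity-derived migration when `coupleMigration`).
#' @param coupleMigration derive the backward migration matrix from the
#'   simulated connectivity matrix.
#' @param totalMigration total migration rate used when coupling.
#' @param inference list: `nPerm` (pairwise FST / AMOVA / RDA), `nBoot`,
#'   `outlierSims`.
#' @param stages character subset of
#'   `c("dispersal", "genetics", "outliers", "ordination")`.
#' @return list of class `ScenarioConfig`.
#' @export
scenarioConfig <- function(outDir = tempfile("seagen_run_"), seed = 1,
                           field = list(nx = 40, ny = 48, nt = 13,
                             features = c("western_boundary", "gyre"),
                             wbcSpeed = 0.45, gyreSpeed = 0.35,
                             gyreBox = "basin", seasonalAmplitude = 1.2,
                             noiseSd = 0.05, durationDays = 180),
                           nSites = 8, nodeSpacingKm = 60,
                           dispersal = list(), metapop = list(),
                           coupleMigration = TRUE, totalMigration = 0.2,
                           baselineMigration = 0.03,
                           inference = list(), stages = c("dispersal",
                             "genetics", "outliers", "ordination")) {
  disp <- list(particlesPerRelease = 300, intervalDays = 14,
               durationDays = 180, dtHours = 2, settlementRadiusKm = 35,
               poolingRadiusKm = 200)
  disp[names(dispersal)] <- dispersal
  inf <- list(nPerm = 199, nBoot = 200, outlierSims = 8000)
  inf[names(inference)] <- inference
  cfg <- list(outDir = outDir, seed = seed, field = field, nSites = nSites,
              nodeSpacingKm = nodeSpacingKm, dispersal = disp,
              metapop = metapop, coupleMigration = coupleMigration,
              totalMigration = totalMigration,
              baselineMigration = baselineMigration, inference = inf,
              stages = stages)
  class(cfg) <- "ScenarioConfig"
  cfg
}

#' Backward migration matrix from a connectivity matrix
#'
#' Converts forward settlement proportions into a row-stochastic backward
#' migration matrix: the probability that a gene in deme i immigrated from
#' deme j is proportional to the settlement flow j -> i, scaled to a total
#' immigrant fraction of `totalMigration` per deme (demes receiving no
#' flow keep their residents).
#'
#' @param C a [ConnectivityMatrix-class] or square probability matrix.
#' @param totalMigration per-generation immigrant fraction along links.
#' @param baseline uniform background mixing blended into the matrix
#'   (processes the larval model does not capture: adult movement, rare
#'   long-distance transport); 0 disables.
#' @return row-stochastic matrix (receiving deme in rows).
#' @export
migrationFromConnectivity <- function(C, totalMigration = 0.35,
                                      baseline = 0.05) {
  P <- if (is(C, "ConnectivityMatrix")) connProb(C) else as.matrix(C)
  sites <- intersect(rownames(P), setdiff(colnames(P), "other"))
  P <- P[sites, sites]
  Minc <- t(P)  # M[i, j]: flow into i from j
  diag(Minc) <- 0
  M <- matrix(0, nrow(Minc), ncol(Minc), dimnames = dimnames(Minc))
  for (i in seq_len(nrow(Minc))) {
    tot <- sum(Minc[i, ])
    if (tot > 0) M[i, ] <- totalMigration * Minc[i, ] / tot
    M[i, i] <- 1 - sum(M[i, -i])
  }
  if (baseline > 0) {
    d <- nrow(M)
    M <- (1 - baseline) * M + baseline / d
  }
  M
}

# stable short hash of the configuration for artifact stamping
configHash <- function(cfg) {
  s <- paste(deparse(cfg[setdiff(names(cfg), "outDir")]), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Run a full seascape-genomics scenario
#'
#' Orchestrates synthetic field -> larval dispersal -> connectivity ->
#' metapopulation genotypes (with migration optionally coupled to the
#' simulated connectivity) -> SNP filter cascade -> diversity / FST /
#' AMOVA-free summary statistics -> outlier scans and consensus -> AEM /
#' dbMEM construction and RDA against current- and environment-derived
#' predictors -> DAPC. All artifacts are written under `config$outDir`,
#' stamped with the seed and a parameter hash; a rerun with the same
#' config is bit-identical.
#'
#' @param config a [scenarioConfig()].
#' @return Invisible list of stage results (also written to disk).
#' @export
runScenario <- function(config) {
  stopifnot(inherits(config, "ScenarioConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config, hash = configHash(config))
  stage <- function(name) name %in% config$stages

  fieldArgs <- config$field
  fieldArgs$seed <- config$seed
  field <- do.call(makeBasinField, fieldArgs)
  sites <- makeSiteTable(field, config$nSites, seed = config$seed)
  nodes <- makeHabitatNodes(field, config$nodeSpacingKm)
  res$field <- field; res$sites <- sites; res$nodes <- nodes
  write.csv(sites, file.path(config$outDir, "sites.csv"), row.names = FALSE)

  if (stage("dispersal")) {
    d <- config$dispersal
    sched <- releaseSchedule(sites, particlesPerRelease = d$particlesPerRelease,
                             intervalDays = d$intervalDays,
                             durationDays = d$durationDays)
    traits <- particleTraits(settlementRadiusKm = d$settlementRadiusKm)
    fates <- runDispersal(field, sched, traits, nodes, seed = config$seed,
                          dtHours = d$dtHours)
    C <- buildConnectivity(fates, nodes, sites,
                           poolingRadiusKm = d$poolingRadiusKm)
    res$fates <- fates; res$connectivity <- C
    writeConnectivity(C, file.path(config$outDir, "connectivity.csv"))
  }

  if (stage("genetics")) {
    mp <- config$metapop
    mp$nDemes <- config$nSites
    if (config$coupleMigration && !is.null(res$connectivity)) {
      M <- migrationFromConnectivity(res$connectivity, config$totalMigration,
                                     config$baselineMigration)
      if (identical(rownames(M), sites$site_id) && nrow(M) == config$nSites)
        mp$migrationMatrix <- unname(M)
    }
    cfg <- do.call(metapopConfig, mp)
    G <- simulateMetapopulation(cfg, seed = config$seed)
    fc <- filterCascade(G)
    res$genotypes <- G
    res$filterReport <- fc$report
    panel <- fc$panel
    res$panel <- panel
    res$diversity <- diversity(panel)
    inf <- config$inference
    res$fst <- pairwiseFst(panel, nPerm = inf$nPerm, nBoot = inf$nBoot,
                           seed = config$seed)
    geo <- crossDistKm(sites$lon, sites$lat, sites$lon, sites$lat)
    dimnames(geo) <- list(sites$site_id, sites$site_id)
    pops <- popLevels(panel)
    if (length(pops) == nrow(geo)) {
      res$ibd <- mantelIbd(res$fst@pairwise, geo,
                           nPerm = min(inf$nPerm * 10 + 9, 9999),
                           seed = config$seed)
    }
    res$ne <- lapply(setNames(pops, pops), function(p)
      tryCatch(neLd(panel[, populations(panel) == p]), error = function(e) NULL))
    write.table(filterSteps(res$filterReport),
                file.path(config$outDir, "filter_report.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(res$diversity, file.path(config$outDir, "diversity.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.csv(res$fst@pairwise, file.path(config$outDir, "pairwise_fst.csv"))
  }

  if (stage("outliers") && !is.null(res$panel)) {
    inf <- config$inference
    s1 <- trimmedChisqScan(res$panel)
    s2 <- fdistEnvelopeScan(res$panel, nSim = inf$outlierSims,
                            seed = config$seed)
    cons <- consensusOutliers(list(s1, s2))
    res$scans <- list(trimmed_chisq = s1, fdist_envelope = s2)
    res$consensus <- cons
    neutralIds <- setdiff(rownames(res$panel), cons)
    res$neutralPanel <- res$panel[neutralIds, ]
    res$outlierPanel <- if (length(cons) >= 1) res$panel[cons, ] else NULL
    write.table(scanStats(s1),
                file.path(config$outDir, "outlier_scan_trimmed.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(scanStats(s2),
                file.path(config$outDir, "outlier_scan_envelope.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(cons, file.path(config$outDir, "consensus_outliers.txt"))
  }

  if (stage("ordination") && !is.null(res$connectivity) &&
      !is.null(res$panel)) {
    inf <- config$inference
    neutral <- if (!is.null(res$neutralPanel)) res$neutralPanel else res$panel
    aem <- buildAem(res$connectivity)
    res$aem <- aem
    Yn <- hellingerTransform(alleleFreqResponse(neutral))
    sel <- backwardSelect(Yn, aemVectors(aem), nPerm = inf$nPerm,
                          seed = config$seed)
    res$rdaAem <- sel
    if (!is.null(sel$model))
      res$rdaAemTest <- rdaPermutationTest(sel$model, nPerm = inf$nPerm,
                                           seed = config$seed)
    env <- makeEnvironment(sites, seed = config$seed)
    res$environment <- env
    write.csv(env, file.path(config$outDir, "environment.csv"),
              row.names = FALSE)
    if (!is.null(res$outlierPanel) && nrow(res$outlierPanel) >= 2) {
      Yo <- hellingerTransform(alleleFreqResponse(res$outlierPanel))
      sst <- envPredictors(env, "SST_mean")
      selEnv <- backwardSelect(Yo, sst, nPerm = inf$nPerm,
                               seed = config$seed)
      res$rdaSst <- selEnv
      if (!is.null(selEnv$model) && length(selEnv$selected)) {
        res$rdaSstTest <- rdaPermutationTest(selEnv$model, nPerm = inf$nPerm,
                                             seed = config$seed)
        nAxes <- min(2, selEnv$model@rank)
        res$envfit <- envfitVectors(
          selEnv$model@siteScores[, seq_len(nAxes), drop = FALSE],
          sst[, selEnv$selected, drop = FALSE], nPerm = inf$nPerm,
          seed = config$seed)
      }
    }
    geo <- crossDistKm(sites$lon, sites$lat, sites$lon, sites$lat)
    dimnames(geo) <- list(sites$site_id, sites$site_id)
    res$dbmem <- buildDbmem(geo)
    if (ncol(res$panel) >= 3 * config$nSites / 2)
      res$dapc <- tryCatch(dapc(res$panel, nRep = 30, seed = config$seed),
                           error = function(e) NULL)
  }
  writeReport(res, file.path(config$outDir, "report.md"))
  jsonlite::write_json(
    list(seed = config$seed, hash = res$hash,
         stages = config$stages),
    file.path(config$outDir, "run_info.json"), auto_unbox = TRUE)
  invisible(res)
}

#' Write a human-readable scenario report
#'
#' Markdown summary mirroring the classic report tables of a seascape
#' genomics study: per-site diversity, the filter cascade bookkeeping,
#' pairwise differentiation, outlier consensus, and the constrained
#' ordination summary.
#'
#' @param results list from [runScenario()] (>= 1 stage result).
#' @param file output path.
#' @return Invisible path.
#' @export
writeReport <- function(results, file) {
  if (is.null(results) || !length(results)) stop("no stage results")
  ln <- c("# Scenario report", "",
          paste0("seed: ", results$config$seed, "  |  parameter hash: ",
                 results$hash), "")
  fmtTable <- function(df) {
    df[] <- lapply(df, function(x) if (is.numeric(x)) signif(x, 4) else x)
    c(paste(names(df), collapse = "\t"),
      apply(df, 1, paste, collapse = "\t"))
  }
  if (!is.null(results$connectivity)) {
    sr <- selfRecruitment(results$connectivity)
    ln <- c(ln, "## Dispersal", "",
            paste0("sources: ", nrow(connProb(results$connectivity)),
                   "; mean settlement ",
                   signif(mean(rowSums(connProb(results$connectivity))), 3),
                   "; mean self-recruitment ", signif(mean(sr), 3)),
            "", "see connectivity.csv", "")
  }
  if (!is.null(results$filterReport))
    ln <- c(ln, "## SNP filter cascade", "",
            fmtTable(filterSteps(results$filterReport)), "")
  if (!is.null(results$diversity))
    ln <- c(ln, "## Genetic diversity by site", "",
            fmtTable(results$diversity), "")
  if (!is.null(results$fst))
    ln <- c(ln, "## Differentiation", "",
            paste0("global Weir-Cockerham theta = ",
                   signif(results$fst@global, 4)),
            "see pairwise_fst.csv", "")
  if (!is.null(results$consensus))
    ln <- c(ln, "## Outlier loci", "",
            paste0(length(results$consensus), " consensus loci (>= 2 methods)"),
            if (length(results$consensus))
              paste(results$consensus, collapse = ", ") else NULL, "")
  if (!is.null(results$rdaAem)) {
    m <- results$rdaAem$model
    ln <- c(ln, "## Current-driven structure (AEM RDA, neutral loci)", "",
            if (is.null(m)) "no AEM retained by backward selection"
            else paste0("selected: ",
                        paste(results$rdaAem$selected, collapse = ", "),
                        "; Radj2 = ", signif(m@R2adj, 4),
                        if (!is.null(results$rdaAemTest))
                          paste0("; p = ", signif(results$rdaAemTest$p, 4))),
            "")
  }
  if (!is.null(results$rdaSst)) {
    m <- results$rdaSst$model
    ln <- c(ln, "## Thermal association (SST RDA, outlier loci)", "",
            if (is.null(m) || !length(results$rdaSst$selected))
              "no SST month retained by backward selection"
            else paste0("selected: ",
                        paste(results$rdaSst$selected, collapse = ", "),
                        "; Radj2 = ", signif(m@R2adj, 4),
                        if (!is.null(results$rdaSstTest))
                          paste0("; p = ", signif(results$rdaSstTest$p, 4))),
            "")
  }
  files <- list.files(dirname(file))
  ln <- c(ln, "## Artifacts", "", paste0("- ", sort(files)))
  writeLines(ln, file)
  invisible(file)
}
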