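#' Asymmetric eigenvector maps from a directed connectivity matrix
#'
#' Encodes directional connectivity as spatial eigenfunctions. For every
#' ordered site pair with positive dispersal probability an edge is
#' created; when both directions are positive only the direction with the
#' higher probability is retained, and any remaining cycles are broken by
#' dropping the weakest edge until the graph is acyclic. Each site's row of
#' the site-by-edge matrix marks the edges lying on directed paths into
#' that site; columns are scaled by edge weight (dispersal probability, or
#' 1 for a binary basis), the matrix is column-centred, and the
#' eigenfunctions are the left singular vectors with positive singular
#' value. Sites with no upstream edges act as origins of their component.
#'
#' @param C a [ConnectivityMatrix-class] (or plain square matrix of
#'   probabilities with identical row/column names; an `"other"` column is
#'   ignored).
#' @param weights `"probability"` (default) or `"binary"`.
#' @return An [AEMBasis-class]. For a connected directed graph over n sites
#'   with enough independent paths the basis has n - 1 eigenfunctions.
#' @export
buildAem <- function(C, weights = c("probability", "binary")) {
  weights <- match.arg(weights)
  P <- if (is(C, "ConnectivityMatrix")) connProb(C) else as.matrix(C)
  sites <- intersect(rownames(P), setdiff(colnames(P), "other"))
  if (length(sites) < 2) stop("need >= 2 sites")
  P <- P[sites, sites]
  edges <- NULL
  for (i in seq_along(sites)) for (j in seq_along(sites)) {
    if (i == j || P[i, j] <= 0) next
    if (P[j, i] > 0) {
      # bidirectional: retain only the direction with higher probability
      if (P[i, j] < P[j, i] || (P[i, j] == P[j, i] && i > j)) next
    }
    edges <- rbind(edges, data.frame(from = sites[i], to = sites[j],
                                     weight = P[i, j],
                                     stringsAsFactors = FALSE))
  }
  if (is.null(edges) || nrow(edges) == 0) stop("no positive-probability edges")
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = sites)
  while (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- which(comp$csize > 1)[1]
    inCyc <- names(comp$membership)[comp$membership == cyc]
    el <- igraph::as_data_frame(g)
    cand <- which(el$from %in% inCyc & el$to %in% inCyc)
    drop <- cand[which.min(el$weight[cand])]
    g <- igraph::delete_edges(g, drop)
  }
  el <- igraph::as_data_frame(g)
  names(el) <- c("from", "to", "weight")
  if (igraph::components(g, mode = "weak")$no > 1)
    warning("connectivity graph is disconnected; ",
            "each component gets its own origin")
  # reach[v, s]: is s reachable from v along directed edges
  dm <- igraph::distances(g, mode = "out")
  E <- matrix(0, length(sites), nrow(el),
              dimnames = list(sites,
                              paste0(el$from, ">", el$to)))
  for (e in seq_len(nrow(el)))
    E[, e] <- as.numeric(is.finite(dm[el$to[e], sites]))
  w <- if (weights == "probability") el$weight else rep(1, nrow(el))
  Ew <- sweep(E, 2, w, "*")
  Ec <- scale(Ew, center = TRUE, scale = FALSE)
  sv <- svd(Ec)
  keep <- sv$d > max(sv$d) * 1e-8
  vectors <- sv$u[, keep, drop = FALSE]
  dimnames(vectors) <- list(sites, paste0("AEM", seq_len(sum(keep))))
  new("AEMBasis", vectors = vectors, values = sv$d[keep], edges = el)
}

#' Distance-based Moran eigenvector maps (dbMEM)
#'
#' Symmetric spatial eigenfunctions from a truncated geographic distance
#' matrix: distances above the truncation threshold (default: the largest
#' edge of the minimum spanning tree, which keeps the graph connected) are
#' replaced by four times the threshold, the matrix is Gower-centred and
#' eigen-decomposed, and eigenvectors with non-negligible eigenvalue are
#' returned. Positive eigenvalues correspond to positive spatial
#' autocorrelation.
#'
#' @param geoKm symmetric distance matrix (km).
#' @param truncation threshold; `NULL` for the spanning-tree default.
#' @param tol relative eigenvalue tolerance.
#' @return list with `vectors` (orthonormal columns `MEM1`, ...), `values`
#'   (eigenvalues), `moran` (sign labels `"positive"`/`"negative"`),
#'   `truncation`.
#' @export
buildDbmem <- function(geoKm, truncation = NULL, tol = 1e-8) {
  geoKm <- as.matrix(geoKm)
  n <- nrow(geoKm)
  if (n < 3) stop("need >= 3 sites")
  if (max(abs(geoKm - t(geoKm))) > 1e-8) stop("distance matrix must be symmetric")
  if (is.null(truncation)) {
    st <- vegan::spantree(as.dist(geoKm))
    truncation <- max(st$dist)
  }
  W <- geoKm
  W[W > truncation] <- 4 * truncation
  diag(W) <- 0
  A <- -0.5 * W^2
  H <- diag(n) - matrix(1 / n, n, n)
  B <- H %*% A %*% H
  ev <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep <- abs(ev$values) > tol * max(abs(ev$values))
  # drop the trivial ~zero eigenvalue of the centring
  vectors <- ev$vectors[, keep, drop = FALSE]
  values <- ev$values[keep]
  ord <- order(values, decreasing = TRUE)
  vectors <- vectors[, ord, drop = FALSE]
  values <- values[ord]
  colnames(vectors) <- paste0("MEM", seq_along(values))
  rownames(vectors) <- rownames(geoKm)
  list(vectors = vectors, values = values,
       moran = ifelse(values > 0, "positive", "negative"),
       truncation = truncation)
}

#' Hellinger transformation
#'
#' Rows are divided by their sums and square-rooted, giving unit-norm rows;
#' makes composition-like data (here site-by-locus allele frequencies)
#' suitable for Euclidean ordination.
#'
#' @param M nonnegative matrix with no all-zero rows.
#' @return Transformed matrix.
#' @examples
#' hellingerTransform(matrix(c(1, 3), 1))  # 0.5, 0.866
#' @export
hellingerTransform <- function(M) {
  M <- as.matrix(M)
  if (any(M < 0)) stop("entries must be nonnegative")
  if (any(rowSums(M) == 0)) stop("all-zero row")
  out <- vegan::decostand(M, method = "hellinger")
  attr(out, "parameters") <- NULL
  attr(out, "decostand") <- NULL
  out
}

#' Site-by-locus allele-frequency response matrix
#'
#' Per-population alternate-allele frequencies (populations in rows), the
#' response construction used for constrained ordination of genetic data.
#' A population with no calls at a locus receives the across-population
#' mean frequency for that locus.
#'
#' @param G a [GenotypePanel-class].
#' @return populations x loci frequency matrix.
#' @export
alleleFreqResponse <- function(G) {
  pp <- perPopStats(G)
  fr <- t(pp$p)
  if (anyNA(fr)) {
    mu <- colMeans(fr, na.rm = TRUE)
    idx <- which(is.na(fr), arr.ind = TRUE)
    fr[idx] <- mu[idx[, 2]]
  }
  fr
}

#' Redundancy analysis (RDA)
#'
#' Constrained ordination: the response is column-centred, regressed on the
#' (column-centred) predictors by least squares, and the canonical axes are
#' the principal components of the fitted values. Collinear predictors are
#' dropped with a warning.
#'
#' @param Y response matrix (sites x variables).
#' @param X predictor matrix (sites x predictors); `n > ncol(X) + 1`
#'   required.
#' @return An [RDAModel-class].
#' @export
rdaFit <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (nrow(Y) != nrow(X)) stop("Y and X need the same number of rows")
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qx <- qr(Xc)
  if (qx$rank < ncol(Xc)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    warning("dropping aliased predictors: ",
            paste(colnames(Xc)[-keep], collapse = ", "))
    Xc <- Xc[, keep, drop = FALSE]
    qx <- qr(Xc)
  }
  m <- qx$rank
  if (n <= m + 1) stop("need n > number of (independent) predictors + 1")
  Yhat <- qr.fitted(qx, Yc)
  sv <- svd(Yhat)
  keep <- sv$d > max(sv$d, 1e-300) * 1e-8
  rank <- sum(keep)
  eig <- (sv$d[keep]^2) / (n - 1)
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], rank)
  dimnames(scores) <- list(rownames(Y), paste0("RDA", seq_len(rank)))
  ssY <- sum(Yc^2); ssFit <- sum(Yhat^2)
  R2 <- if (ssY > 0) ssFit / ssY else 0
  R2adj <- 1 - (1 - R2) * (n - 1) / (n - m - 1)
  ssRes <- ssY - ssFit
  pseudoF <- (ssFit / m) / (ssRes / (n - m - 1))
  new("RDAModel", Y = Yc, X = Xc, eigenvalues = eig, siteScores = scores,
      R2 = R2, R2adj = R2adj, rank = as.integer(rank), pseudoF = pseudoF)
}

# pseudo-F of Y on X (both centred), used by the permutation engines
rdaPseudoF <- function(Yc, qx, n, m) {
  ssFit <- sum(qr.fitted(qx, Yc)^2)
  ssRes <- max(sum(Yc^2) - ssFit, 0)
  if (ssRes == 0) return(Inf)   # saturated fit: strongest possible statistic
  (ssFit / m) / (ssRes / (n - m - 1))
}

#' Permutation tests for an RDA model
#'
#' Unrestricted permutation of response rows with recomputation of the
#' pseudo-F statistic; `p = (#perm >= obs + 1) / (nPerm + 1)`.
#' `by = "global"` tests the whole model, `"margin"` each predictor's
#' marginal (drop-one) contribution, `"axis"` each canonical axis
#' (sequentially, against the full-model residual).
#'
#' @param model an [RDAModel-class].
#' @param nPerm number of permutations (>= 19).
#' @param by `"global"`, `"margin"` or `"axis"`.
#' @param seed integer seed.
#' @return list with `statistic` and `p` (scalars for global, named
#'   vectors otherwise).
#' @export
rdaPermutationTest <- function(model, nPerm = 999,
                               by = c("global", "margin", "axis"), seed = 1) {
  by <- match.arg(by)
  if (nPerm < 19) stop("nPerm must be >= 19")
  Yc <- model@Y; Xc <- model@X
  n <- nrow(Yc); m <- ncol(Xc)
  qx <- qr(Xc)
  withSeed(splitSeed(seed, "ordination"), {
    if (by == "global") {
      obs <- rdaPseudoF(Yc, qx, n, m)
      ge <- 0
      for (b in seq_len(nPerm)) {
        Fp <- rdaPseudoF(Yc[sample.int(n), , drop = FALSE], qx, n, m)
        if (Fp >= obs) ge <- ge + 1
      }
      list(statistic = obs, p = (ge + 1) / (nPerm + 1))
    } else if (by == "margin") {
      ssRes <- sum(qr.resid(qx, Yc)^2)
      stat <- p <- setNames(numeric(m), colnames(Xc))
      for (j in seq_len(m)) {
        qxj <- qr(Xc[, -j, drop = FALSE])
        dfj <- m - qxj$rank
        marginF <- function(Ym) {
          ssFull <- sum(qr.fitted(qx, Ym)^2)
          ssWo <- if (ncol(Xc) > 1) sum(qr.fitted(qxj, Ym)^2) else 0
          ssRes <- max(sum(Ym^2) - ssFull, 0)
          if (ssRes == 0) return(Inf)
          ((ssFull - ssWo) / dfj) / (ssRes / (n - m - 1))
        }
        obs <- marginF(Yc)
        ge <- 0
        for (b in seq_len(nPerm))
          if (marginF(Yc[sample.int(n), , drop = FALSE]) >= obs) ge <- ge + 1
        stat[j] <- obs
        p[j] <- (ge + 1) / (nPerm + 1)
      }
      list(statistic = stat, p = p)
    } else {
      k <- model@rank
      ssRes <- sum(Yc^2) - sum(qr.fitted(qx, Yc)^2)
      obs <- model@eigenvalues * (n - 1) / (ssRes / (n - m - 1))
      ge <- numeric(k)
      for (b in seq_len(nPerm)) {
        Yp <- Yc[sample.int(n), , drop = FALSE]
        Yhat <- qr.fitted(qx, Yp)
        d2 <- svd(Yhat, nu = 0, nv = 0)$d^2
        ssResP <- sum(Yp^2) - sum(Yhat^2)
        Fp <- d2[seq_len(k)] / (ssResP / (n - m - 1))
        ge <- ge + (ifelse(is.na(Fp), -Inf, Fp) >= obs)
      }
      p <- (ge + 1) / (nPerm + 1)
      names(p) <- names(obs) <- paste0("RDA", seq_len(k))
      list(statistic = obs, p = p)
    }
  })
}

#' Backward selection of RDA predictors
#'
#' Iteratively removes the least significant predictor (largest marginal
#' permutation p-value) while that p-value exceeds `alpha`. Deterministic
#' under a fixed seed.
#'
#' @param Y response matrix.
#' @param X predictor matrix (>= 1 column).
#' @param alpha retention threshold.
#' @param nPerm permutations per marginal test.
#' @param seed integer seed.
#' @return list with `selected` (character, possibly empty), `trace`
#'   (data.frame of per-step drops) and `model` (the final
#'   [RDAModel-class], or NULL if nothing was retained).
#' @export
backwardSelect <- function(Y, X, alpha = 0.05, nPerm = 999, seed = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  current <- colnames(X)
  trace <- data.frame(step = integer(0), dropped = character(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  n <- nrow(as.matrix(Y))
  if (length(current) > n - 2) {
    # saturated model: screen by single-predictor fit and keep the best
    # n - 2 so marginal tests retain residual degrees of freedom
    r2 <- vapply(current, function(v)
      rdaFit(Y, X[, v, drop = FALSE])@R2, numeric(1))
    dropped <- current[order(r2)][seq_len(length(current) - (n - 2))]
    trace <- rbind(trace, data.frame(step = 0L, dropped = dropped,
                                     p = NA_real_))
    current <- setdiff(current, dropped)
  }
  step <- 0L
  seedStep <- seed
  while (length(current) > 0) {
    model <- rdaFit(Y, X[, current, drop = FALSE])
    mt <- rdaPermutationTest(model, nPerm = nPerm, by = "margin",
                             seed = seedStep)
    worst <- which.max(mt$p)
    if (mt$p[worst] <= alpha) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step,
                                     dropped = names(mt$p)[worst],
                                     p = unname(mt$p[worst])))
    current <- setdiff(current, names(mt$p)[worst])
    seedStep <- seedStep + 1L
  }
  model <- if (length(current)) rdaFit(Y, X[, current, drop = FALSE]) else NULL
  list(selected = current, trace = trace, model = model)
}

#' Fit environmental vectors onto an ordination
#'
#' Least-squares fit of each variable onto the site scores, with
#' permutation p-values (wraps the standard vector-fitting procedure).
#'
#' @param scores site-score matrix (e.g. `model@siteScores[, 1:2]`).
#' @param env matrix/data.frame of environmental variables (no constants).
#' @param nPerm permutations.
#' @param seed integer seed.
#' @return data.frame: `variable`, per-axis direction cosines, `r2`, `p`.
#' @export
envfitVectors <- function(scores, env, nPerm = 999, seed = 1) {
  env <- as.data.frame(env)
  sds <- vapply(env, sd, numeric(1))
  if (any(sds == 0)) stop("constant variable: ",
                          paste(names(env)[sds == 0], collapse = ", "))
  fit <- withSeed(splitSeed(seed, "ordination"),
                  vegan::envfit(as.matrix(scores), env,
                                permutations = nPerm))
  arr <- fit$vectors$arrows
  data.frame(variable = rownames(arr), arr,
             r2 = fit$vectors$r, p = fit$vectors$pvals,
             row.names = NULL, check.names = FALSE)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' PCA of the (mean-imputed, centred) dosage matrix followed by linear
#' discriminant analysis on the retained components. The number of
#' components is chosen by stratified hold-out cross-validation (lowest
#' mean assignment error over `nRep` replicates) unless given.
#'
#' @param G a [GenotypePanel-class] (>= 2 groups, each >= 3 individuals).
#' @param groups grouping vector (default: populations).
#' @param nPca number of PCs; `NULL` for cross-validated choice.
#' @param nRep cross-validation replicates.
#' @param holdout hold-out fraction per replicate.
#' @param seed integer seed.
#' @return A [DAPCModel-class].
#' @export
dapc <- function(G, groups = NULL, nPca = NULL, nRep = 100, holdout = 0.1,
                 seed = 1) {
  if (is.null(groups)) groups <- populations(G)
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab < 3)) stop("every group needs >= 3 individuals")
  if (any(floor(tab * (1 - holdout)) < 2))
    stop("a group is smaller than the hold-out fraction allows")
  X <- t(dosage(imputeMissing(G, "mean_dosage")))
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  maxPca <- min(nrow(X) - length(tab) - 1, sum(pc$sdev > 1e-8))
  scoresAll <- pc$x
  xval <- data.frame(n_pca = integer(0), rep = integer(0), error = numeric(0))
  withSeed(splitSeed(seed, "ordination"), {
    if (is.null(nPca)) {
      grid <- unique(pmax(2, round(seq(2, maxPca, length.out = min(6, maxPca - 1)))))
      for (np in grid) for (r in seq_len(nRep)) {
        test <- unlist(lapply(names(tab), function(g) {
          idx <- which(groups == g)
          sample(idx, max(1, round(length(idx) * holdout)))
        }))
        train <- setdiff(seq_len(nrow(X)), test)
        ld <- suppressWarnings(
          MASS::lda(scoresAll[train, seq_len(np), drop = FALSE],
                    grouping = groups[train]))
        pred <- predict(ld, scoresAll[test, seq_len(np), drop = FALSE])$class
        xval <- rbind(xval, data.frame(n_pca = np, rep = r,
                                       error = mean(pred != groups[test])))
      }
      mu <- aggregate(error ~ n_pca, xval, mean)
      nPca <- mu$n_pca[which.min(mu$error)]
    }
    nPca <- min(nPca, maxPca)
    ld <- suppressWarnings(
      MASS::lda(scoresAll[, seq_len(nPca), drop = FALSE], grouping = groups))
    pr <- predict(ld)
    model <- list(ld = ld, pr = pr, nPca = nPca)
  })
  new("DAPCModel", nPca = as.integer(model$nPca), loadings = model$ld$scaling,
      scores = model$pr$x, posterior = model$pr$posterior,
      assign = as.character(model$pr$class), xval = xval)
}
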