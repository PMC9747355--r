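#' Co-clustering frequency under subsampling
#'
#' Repeatedly clusters random cell subsets and records how often each pair
#' of cells lands in the same cluster. For each repetition a uniform random
#' \code{frac} fraction of cells is drawn without replacement, the
#' k-nearest-neighbor graph is rebuilt on the subset's PC embedding and
#' Louvain clustering is run at the given resolution. The co-clustering
#' frequency of a pair is its co-cluster count divided by its co-sample
#' count; pairs never co-sampled are \code{NA}.
#'
#' @param sce output of \code{\link{pcaNeighbors}}.
#' @param resolution Louvain resolution.
#' @param nReps number of repetitions (>= 2).
#' @param frac subsample fraction.
#' @param seed base seed; repetition r uses \code{seed + r}.
#' @return object of class \code{CoClusterMatrix}: list with
#'   \code{frequency} (cells x cells, in [0,1] or NA) and \code{nPairs}
#'   (co-sample counts)
#' @export
coClustering <- function(sce, resolution, nReps = 5, frac = 0.8, seed = 0) {
    if (nReps < 2) stop("nReps must be at least 2")
    coords <- SingleCellExperiment::reducedDim(sce, "PCA")
    k <- S4Vectors::metadata(sce)$pca$k
    if (is.null(k)) k <- 15
    n <- nrow(coords)
    M <- matrix(0, n, n)
    C <- matrix(0, n, n)
    m <- max(1L, floor(frac * n))
    for (r in seq_len(nReps)) {
        repSeed <- .deriveSeed(seed, r)
        set.seed(repSeed)
        idx <- sort(sample.int(n, m, replace = FALSE))
        adj <- .knnGraph(coords[idx, , drop = FALSE], k)
        lab <- .louvainLabels(adj, resolution, repSeed)
        C[idx, idx] <- C[idx, idx] + 1
        M[idx, idx] <- M[idx, idx] + outer(lab, lab, "==")
    }
    freq <- ifelse(C > 0, M / pmax(C, 1), NA_real_)
    dimnames(freq) <- dimnames(C) <- list(colnames(sce), colnames(sce))
    structure(list(frequency = freq, nPairs = C), class = "CoClusterMatrix")
}

#' Robustness score of a clustering resolution
#'
#' Mean silhouette width of the full-data cluster labels under the
#' dissimilarity \code{1 - co-clustering frequency}. A resolution whose
#' clusters always re-form under subsampling scores 1; one whose cluster
#' assignments are arbitrary scores near 0. Pairs never co-sampled are
#' excluded from the silhouette terms rather than imputed.
#'
#' @param cocluster a \code{CoClusterMatrix}.
#' @param labels full-data cluster labels (one per cell), or a clustered
#'   \code{SingleCellExperiment}.
#' @return list with \code{score} (mean silhouette, in [-1,1]) and
#'   \code{nClusters}
#' @export
robustnessScore <- function(cocluster, labels) {
    if (methods::is(labels, "SingleCellExperiment")) labels <- labels$cluster
    freq <- cocluster$frequency
    stopifnot(length(labels) == nrow(freq))
    nClusters <- length(unique(labels))
    if (nClusters < 2L) {
        warning("single cluster: silhouette undefined, score set to 0")
        return(list(score = 0, nClusters = nClusters))
    }
    D <- 1 - freq
    diag(D) <- 0
    s <- .silhouetteWidths(D, labels)
    list(score = mean(s, na.rm = TRUE), nClusters = nClusters)
}

#' Automatic clustering-resolution selection
#'
#' Scores each candidate resolution by subsampling-based robustness
#' (\code{\link{coClustering}} + \code{\link{robustnessScore}}, with
#' \code{nReps} random \code{frac} subsets per resolution) and returns the
#' resolution with the highest mean silhouette score; ties go to the
#' smallest resolution (the coarsest equally stable solution).
#'
#' @param sce output of \code{\link{pcaNeighbors}}.
#' @param grid candidate resolutions.
#' @param nReps,frac subsampling settings.
#' @param seed master seed; grid index g (0-based) uses base seed
#'   \code{seed + 1000 g}, its full-data clustering \code{+0} and
#'   repetition r \code{+r}.
#' @return list with \code{bestResolution} and a \code{scores} data.frame
#'   (resolution, score, n_clusters)
#' @export
chooseResolution <- function(sce, grid = seq(0.4, 1.4, by = 0.2),
                             nReps = 5, frac = 0.8, seed = 0) {
    if (!length(grid)) stop("resolution grid is empty")
    grid <- sort(grid)
    rows <- lapply(seq_along(grid), function(g) {
        res <- grid[g]
        base <- .deriveSeed(seed, 1000 * (g - 1))
        labels <- .louvainLabels(S4Vectors::metadata(sce)$neighbor_graph,
                                 res, base)
        cc <- coClustering(sce, res, nReps = nReps, frac = frac, seed = base)
        sc <- robustnessScore(cc, labels)
        data.frame(resolution = res, score = sc$score,
                   n_clusters = sc$nClusters)
    })
    scores <- do.call(rbind, rows)
    best <- min(scores$resolution[scores$score == max(scores$score)])
    list(bestResolution = best, scores = scores)
}
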