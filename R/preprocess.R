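#' Quality filtering of cells and genes
#'
#' Removes low-complexity cells, cells dominated by mitochondrial reads, and
#' rarely detected genes. Cell filters are evaluated first on the raw counts;
#' the gene filter is then evaluated on the surviving cells, so a gene's
#' support is counted only among cells that passed QC.
#'
#' @param sce \code{SingleCellExperiment} with a \code{counts} assay.
#' @param minGenesPerCell keep cells expressing at least this many genes.
#' @param minCellsPerGene keep genes detected in at least this many
#'   surviving cells.
#' @param maxMitoFrac keep cells whose mitochondrial count fraction is
#'   strictly below this value.
#' @param mitoPrefix gene-symbol prefix identifying mitochondrial genes
#'   (human convention "MT-").
#' @return the filtered \code{SingleCellExperiment}
#' @export
filterCellsGenes <- function(sce, minGenesPerCell = 200, minCellsPerGene = 3,
                             maxMitoFrac = 0.30, mitoPrefix = "MT-") {
    counts <- SummarizedExperiment::assay(sce, "counts")
    nGenes <- Matrix::colSums(counts > 0)
    mito <- startsWith(rownames(counts), mitoPrefix)
    tot <- Matrix::colSums(counts)
    mitoFrac <- if (any(mito))
        Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(tot, 1)
    else rep(0, ncol(counts))
    keepCells <- nGenes >= minGenesPerCell & mitoFrac < maxMitoFrac
    if (!any(keepCells)) stop("all cells removed by filtering")
    counts <- counts[, keepCells, drop = FALSE]
    keepGenes <- Matrix::rowSums(counts > 0) >= minCellsPerGene
    if (!any(keepGenes)) stop("all genes removed by filtering")
    out <- sce[keepGenes, keepCells]
    S4Vectors::metadata(out)$qc <- list(
        minGenesPerCell = minGenesPerCell, minCellsPerGene = minCellsPerGene,
        maxMitoFrac = maxMitoFrac, mitoPrefix = mitoPrefix,
        nCellsRemoved = sum(!keepCells), nGenesRemoved = sum(!keepGenes))
    out
}

#' Depth normalization and log transformation
#'
#' Scales each cell to \code{targetSum} total counts and applies
#' \code{log1p}, storing the result as the \code{logcounts} assay.
#'
#' @param sce filtered \code{SingleCellExperiment}.
#' @param targetSum per-cell total after normalization.
#' @return \code{sce} with a \code{logcounts} assay added
#' @export
normalizeLog <- function(sce, targetSum = 10000) {
    counts <- SummarizedExperiment::assay(sce, "counts")
    tot <- Matrix::colSums(counts)
    if (any(tot == 0))
        stop("cell(s) with zero total counts: ",
             paste(colnames(counts)[tot == 0], collapse = ", "))
    norm <- counts %*% Matrix::Diagonal(x = targetSum / tot)
    dimnames(norm) <- dimnames(counts)
    SummarizedExperiment::assay(sce, "logcounts") <- log1p(norm)
    S4Vectors::metadata(sce)$normalization <-
        list(targetSum = targetSum, log = "natural")
    sce
}

#' Highly variable gene selection and scaling
#'
#' Selects highly variable genes by dispersion-based binning on the
#' de-logged normalized values (per-gene dispersion = variance/mean on the
#' de-logged scale, log-dispersion z-scored within 20 equal-width bins of
#' log1p mean expression), then centers each selected
#' gene to mean zero and unit variance on the log scale, clipping scaled
#' values at \code{± clip} to bound outlier leverage.
#'
#' @param sce \code{SingleCellExperiment} with \code{logcounts}.
#' @param minMean,maxMean mean-expression window (on de-logged values) for
#'   the dispersion thresholding mode.
#' @param minDisp minimum normalized dispersion.
#' @param nTop if given, take the top \code{nTop} genes by normalized
#'   dispersion instead of thresholding.
#' @param clip absolute bound on scaled values.
#' @return \code{sce} with \code{rowData()$highly_variable} set and the
#'   scaled HVG x cells matrix in \code{metadata()$scaled}
#' @export
selectHvgScale <- function(sce, minMean = 0.0125, maxMean = 3, minDisp = 0.5,
                           nTop = NULL, clip = 10) {
    lc <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
    x <- expm1(lc)
    mu <- rowMeans(x)
    v <- apply(x, 1L, stats::var)
    disp <- ifelse(mu > 0, v / mu, 0)
    ldisp <- ifelse(disp > 0, log(disp), -Inf)
    bin <- cut(log1p(mu), breaks = 20L, include.lowest = TRUE)
    ok <- is.finite(ldisp)
    bmean <- tapply(ldisp[ok], bin[ok], mean)
    bsd <- tapply(ldisp[ok], bin[ok], stats::sd)
    bsd[is.na(bsd) | bsd == 0] <- 1
    z <- (ldisp - bmean[as.character(bin)]) / bsd[as.character(bin)]
    z[!ok | is.na(z)] <- -Inf
    hvg <- if (!is.null(nTop)) {
        rank(-z, ties.method = "first") <= nTop & v > 0
    } else {
        mu > minMean & mu < maxMean & z >= minDisp & v > 0
    }
    hvg[is.na(hvg)] <- FALSE
    if (sum(hvg) < 2L)
        stop("fewer than 2 highly variable genes; relax thresholds")
    SummarizedExperiment::rowData(sce)$highly_variable <- hvg
    sub <- lc[hvg, , drop = FALSE]
    m <- rowMeans(sub)
    s <- apply(sub, 1L, stats::sd)
    keep <- s > 0
    sub <- (sub[keep, , drop = FALSE] - m[keep]) / s[keep]
    sub[sub > clip] <- clip
    sub[sub < -clip] <- -clip
    S4Vectors::metadata(sce)$scaled <- sub
    S4Vectors::metadata(sce)$hvg <- list(
        n = sum(keep), minMean = minMean, maxMean = maxMean,
        minDisp = minDisp, nTop = nTop, clip = clip)
    sce
}

#' Principal components and nearest-neighbor graph
#'
#' Computes the top principal components of the scaled HVG matrix and an
#' undirected k-nearest-neighbor graph (Euclidean distance in PC space,
#' union-symmetrized, unit edge weights, no self loops).
#'
#' @param sce output of \code{\link{selectHvgScale}}.
#' @param nPcs number of principal components (reduced with a warning if it
#'   exceeds the matrix rank).
#' @param kNeighbors neighbors per cell.
#' @return \code{sce} with a \code{"PCA"} reduced dimension and the sparse
#'   adjacency matrix in \code{metadata()$neighbor_graph}
#' @export
pcaNeighbors <- function(sce, nPcs = 20, kNeighbors = 15) {
    scaled <- S4Vectors::metadata(sce)$scaled
    if (is.null(scaled)) stop("run selectHvgScale() first")
    X <- t(scaled)
    maxRank <- min(nrow(X) - 1L, ncol(X))
    if (nPcs > maxRank) {
        warning("nPcs reduced from ", nPcs, " to ", maxRank)
        nPcs <- maxRank
    }
    pr <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = nPcs)
    coords <- pr$x
    rownames(coords) <- colnames(sce)
    SingleCellExperiment::reducedDim(sce, "PCA") <- coords
    S4Vectors::metadata(sce)$neighbor_graph <-
        .knnGraph(coords, kNeighbors)
    S4Vectors::metadata(sce)$pca <- list(
        nPcs = nPcs, k = kNeighbors,
        sdev = pr$sdev[seq_len(nPcs)])
    sce
}

## kNN adjacency (union-symmetrized, weight 1) from an embedding.
.knnGraph <- function(coords, k) {
    n <- nrow(coords)
    k <- min(k, n - 1L)
    D <- as.matrix(stats::dist(coords))
    ii <- integer(0); jj <- integer(0)
    for (i in seq_len(n)) {
        ord <- order(D[i, ])
        nb <- setdiff(ord, i)[seq_len(k)]
        ii <- c(ii, rep.int(i, k)); jj <- c(jj, nb)
    }
    adj <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n),
                                dimnames = list(rownames(coords),
                                                rownames(coords)))
    adj <- adj + Matrix::t(adj)
    adj@x[] <- 1
    Matrix::diag(adj) <- 0
    Matrix::drop0(adj)
}

#' Louvain community detection on the neighbor graph
#'
#' @param sce output of \code{\link{pcaNeighbors}}, or any
#'   \code{SingleCellExperiment} with \code{metadata()$neighbor_graph}.
#' @param resolution modularity resolution parameter.
#' @param seed RNG seed; identical seeds give identical labels.
#' @return \code{sce} with integer cluster labels (0-based, ordered by
#'   descending cluster size) in \code{colData()$cluster}
#' @export
clusterLouvain <- function(sce, resolution = 1.0, seed = 0) {
    adj <- S4Vectors::metadata(sce)$neighbor_graph
    if (is.null(adj)) stop("run pcaNeighbors() first")
    if (nrow(adj) == 0) stop("empty neighbor graph")
    labels <- .louvainLabels(adj, resolution, seed)
    sce$cluster <- labels
    S4Vectors::metadata(sce)$clustering <-
        list(resolution = resolution, seed = seed,
             nClusters = length(unique(labels)))
    sce
}

.louvainLabels <- function(adj, resolution, seed) {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             weighted = TRUE)
    set.seed(.deriveSeed(seed, 0))
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    .canonicalLabels(igraph::membership(cl))
}

#' Re-run the clustering chain on selected clusters
#'
#' Restricts the analysis to cells of the selected clusters and repeats the
#' whole chain on that subset: normalization, HVG selection, scaling, PCA,
#' neighbor graph and Louvain clustering are all recomputed, so substructure
#' hidden inside a cluster can surface.
#'
#' @param sce a clustered \code{SingleCellExperiment}.
#' @param clusterIds cluster labels to keep.
#' @param ... parameters forwarded to \code{\link{runClustering}} (e.g.
#'   \code{resolution}, \code{autoResolution}, \code{nPcs}).
#' @return a new clustered \code{SingleCellExperiment} over the selected
#'   cells
#' @export
subcluster <- function(sce, clusterIds, ...) {
    if (is.null(sce$cluster)) stop("sce has no clustering")
    missing <- setdiff(clusterIds, unique(sce$cluster))
    if (length(missing))
        stop("unknown cluster id(s): ", paste(missing, collapse = ", "))
    keep <- sce$cluster %in% clusterIds
    if (!any(keep)) stop("empty cluster selection")
    counts <- SummarizedExperiment::assay(sce, "counts")[, keep, drop = FALSE]
    runClustering(asCountsExperiment(counts), ...)
}

#' One-call clustering workflow
#'
#' Runs filtering, normalization, HVG selection/scaling, PCA, neighbor graph
#' and Louvain clustering in sequence. With \code{autoResolution = TRUE} the
#' resolution is chosen by subsampling-based robustness scoring
#' (\code{\link{chooseResolution}}); otherwise \code{resolution} is used
#' directly.
#'
#' @param sce \code{SingleCellExperiment} with raw counts (or a counts
#'   matrix, which is wrapped).
#' @param minGenesPerCell,minCellsPerGene,maxMitoFrac,mitoPrefix QC
#'   thresholds, see \code{\link{filterCellsGenes}}.
#' @param targetSum normalization target, see \code{\link{normalizeLog}}.
#' @param nTop optional HVG count cap, see \code{\link{selectHvgScale}}.
#' @param nPcs,kNeighbors embedding/graph parameters.
#' @param resolution Louvain resolution when \code{autoResolution} is FALSE.
#' @param autoResolution choose the resolution automatically.
#' @param grid,nReps,frac auto-resolution settings, see
#'   \code{\link{chooseResolution}}.
#' @param seed RNG seed.
#' @return a clustered \code{SingleCellExperiment}; with auto-resolution the
#'   per-resolution scores are kept in \code{metadata()$resolution_scores}
#' @export
runClustering <- function(sce, minGenesPerCell = 200, minCellsPerGene = 3,
                          maxMitoFrac = 0.30, mitoPrefix = "MT-",
                          targetSum = 10000, nTop = NULL, nPcs = 20,
                          kNeighbors = 15, resolution = 1.0,
                          autoResolution = FALSE,
                          grid = seq(0.4, 1.4, by = 0.2), nReps = 5,
                          frac = 0.8, seed = 0) {
    if (!methods::is(sce, "SingleCellExperiment"))
        sce <- asCountsExperiment(sce)
    sce <- filterCellsGenes(sce, minGenesPerCell, minCellsPerGene,
                            maxMitoFrac, mitoPrefix)
    sce <- normalizeLog(sce, targetSum)
    sce <- selectHvgScale(sce, nTop = nTop)
    sce <- pcaNeighbors(sce, nPcs = nPcs, kNeighbors = kNeighbors)
    if (autoResolution) {
        cr <- chooseResolution(sce, grid = grid, nReps = nReps, frac = frac,
                               seed = seed)
        resolution <- cr$bestResolution
        sce <- clusterLouvain(sce, resolution = resolution,
                              seed = .deriveSeed(seed, 1000 *
                                  (match(resolution, cr$scores$resolution) - 1)))
        S4Vectors::metadata(sce)$resolution_scores <- cr$scores
    } else {
        sce <- clusterLouvain(sce, resolution = resolution, seed = seed)
    }
    sce
}
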