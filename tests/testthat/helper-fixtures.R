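## Fixture builders and independent oracles shared across test files.

## SCE with a planted 2D embedding of well-separated blobs; enough scaffolding
## (dummy logcounts, PCA, neighbor graph) to run clustering and co-clustering.
blobSCE <- function(sizes = c(20, 20), sep = 30, k = 10, seed = 42) {
    set.seed(seed)
    coords <- do.call(rbind, lapply(seq_along(sizes), function(b)
        cbind(rnorm(sizes[b], sep * b), rnorm(sizes[b], 0))))
    n <- nrow(coords)
    rownames(coords) <- sprintf("c%03d", seq_len(n))
    lc <- matrix(0, 2, n, dimnames = list(c("g1", "g2"), rownames(coords)))
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(logcounts = lc))
    SingleCellExperiment::reducedDim(sce, "PCA") <- coords
    S4Vectors::metadata(sce)$neighbor_graph <- scRepurpose:::.knnGraph(coords, k)
    S4Vectors::metadata(sce)$pca <- list(nPcs = 2, k = k)
    sce$blob <- rep(seq_along(sizes) - 1L, sizes)
    sce
}

## Small SCE straight from a counts matrix with logcounts and clusters set.
miniSCE <- function(counts, clusters = NULL, targetSum = 100) {
    sce <- asCountsExperiment(counts)
    sce <- normalizeLog(sce, targetSum = targetSum)
    if (!is.null(clusters)) sce$cluster <- clusters
    sce
}

## Brute-force silhouette on a dissimilarity matrix with NA exclusions;
## written as plain loops, independent of the package implementation.
silhouetteOracle <- function(D, labels) {
    n <- length(labels)
    vals <- c()
    for (i in seq_len(n)) {
        own <- which(labels == labels[i])
        own <- own[own != i]
        if (!length(own)) { vals <- c(vals, 0); next }
        a <- mean(D[i, own], na.rm = TRUE)
        b <- Inf
        for (l in setdiff(unique(labels), labels[i])) {
            m <- mean(D[i, which(labels == l)], na.rm = TRUE)
            if (is.finite(m) && m < b) b <- m
        }
        if (!is.finite(a) || !is.finite(b)) next
        s <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
        vals <- c(vals, s)
    }
    mean(vals)
}

## Hand-rolled two-group log-rank: observed minus expected event counts and
## their variance accumulated over distinct event times.
logrankOracle <- function(time, event, group) {
    g1 <- group == levels(factor(group))[1]
    O1 <- 0; E1 <- 0; V <- 0
    for (t in sort(unique(time[event == 1]))) {
        atRisk <- time >= t
        n <- sum(atRisk); n1 <- sum(atRisk & g1)
        d <- sum(event == 1 & time == t)
        d1 <- sum(event == 1 & time == t & g1)
        O1 <- O1 + d1
        E1 <- E1 + d * n1 / n
        if (n > 1)
            V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    list(O1 = O1, E1 = E1, V = V, chisq = (O1 - E1)^2 / V)
}

## Exact hypergeometric upper-tail by explicit summation.
hyperTailOracle <- function(overlap, termSize, querySize, universe) {
    hi <- min(termSize, querySize)
    if (overlap > hi) return(0)
    sum(sapply(overlap:hi, function(j)
        choose(termSize, j) * choose(universe - termSize, querySize - j))) /
        choose(universe, querySize)
}

## Three-cluster expression fixture with planted per-cluster markers.
markerSCE <- function(cellsPerCluster = 30, nGenes = 60, nMarkers = 5,
                      effect = 3, seed = 7) {
    set.seed(seed)
    k <- 3
    n <- k * cellsPerCluster
    labels <- rep(0:(k - 1), each = cellsPerCluster)
    counts <- matrix(rpois(nGenes * n, 5), nGenes, n)
    markers <- split(seq_len(k * nMarkers), rep(1:k, each = nMarkers))
    for (cl in 1:k)
        counts[markers[[cl]], labels == cl - 1] <-
            rpois(nMarkers * cellsPerCluster, 5 * effect)
    dimnames(counts) <- list(sprintf("G%03d", seq_len(nGenes)),
                             sprintf("c%03d", seq_len(n)))
    sce <- miniSCE(counts, clusters = labels, targetSum = 1000)
    attr(sce, "markers") <- lapply(markers, function(i) rownames(counts)[i])
    sce
}

## A DrugResponseModel whose training-set predictions are exactly `pred`
## (lines x drugs), built by solving the kernel system; used to test the
## drug-filtering quartile rule against engineered coefficients.
modelWithPredictions <- function(pred, seed = 3) {
    set.seed(seed)
    nLines <- nrow(pred); nDrugs <- ncol(pred)
    fc <- matrix(rnorm(nLines * (nLines + 2)), nLines,
                 dimnames = list(rownames(pred),
                                 sprintf("G%02d", seq_len(nLines + 2))))
    X <- cor(t(fc), t(fc))
    f <- nDrugs
    W <- solve(X, pred)          # X %*% W = pred, one latent per drug
    Q <- diag(nDrugs)
    methods::new("DrugResponseModel",
        W = W, Q = Q, b = setNames(rep(0, nDrugs), colnames(pred)),
        mu = 0, f = as.integer(f), lambda = 0,
        featureGenes = colnames(fc), trainFC = fc,
        fcReference = setNames(rep(0, ncol(fc)), colnames(fc)),
        responseScale = "gdsc", lossTrace = 0,
        config = list())
}

## Adjusted Rand index (independent of the implementation under test).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
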