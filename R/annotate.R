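#' Per-cluster differential expression
#'
#' One-vs-rest test per gene per cluster on log-normalized expression.
#' Default is a Welch two-sample t-test; a Wilcoxon rank-sum alternative is
#' available. The log2 fold change compares de-logged cluster and rest
#' means; p-values are Benjamini-Hochberg adjusted within each cluster and
#' genes are ranked by test score (descending).
#'
#' @param sce clustered \code{SingleCellExperiment} with \code{logcounts}.
#' @param method "t" (Welch) or "wilcoxon".
#' @return data.frame with columns cluster, gene, score, log2_fold_change,
#'   p_value, adj_p_value, rank
#' @export
rankDEGs <- function(sce, method = c("t", "wilcoxon")) {
    method <- match.arg(method)
    labels <- sce$cluster
    if (is.null(labels)) stop("sce has no clustering")
    if (length(unique(labels)) < 2L) stop("need at least 2 clusters")
    lc <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
    out <- list()
    for (cl in sort(unique(labels))) {
        inC <- labels == cl
        n1 <- sum(inC); n2 <- sum(!inC)
        if (n1 < 2L) {
            warning("cluster ", cl, " has fewer than 2 cells; skipped")
            next
        }
        x1 <- lc[, inC, drop = FALSE]; x2 <- lc[, !inC, drop = FALSE]
        m1 <- rowMeans(x1); m2 <- rowMeans(x2)
        if (method == "t") {
            v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
            v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
            se2 <- v1 / n1 + v2 / n2
            score <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
            df <- ifelse(se2 > 0,
                se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))),
                1)
            p <- 2 * stats::pt(-abs(score), df)
        } else {
            res <- apply(lc, 1L, function(g) {
                w <- stats::wilcox.test(g[inC], g[!inC], exact = FALSE)
                c(w$statistic, w$p.value)
            })
            expU <- n1 * n2 / 2
            sdU <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
            score <- (res[1, ] - expU) / sdU
            p <- res[2, ]
        }
        p[!is.finite(p)] <- 1
        lfc <- log2((rowMeans(expm1(x1)) + 1e-9) /
                    (rowMeans(expm1(x2)) + 1e-9))
        ord <- order(-score)
        out[[length(out) + 1L]] <- data.frame(
            cluster = cl, gene = rownames(lc), score = score,
            log2_fold_change = lfc, p_value = p, adj_p_value = .bh(p),
            rank = NA_integer_, row.names = NULL)[ord, ]
        out[[length(out)]]$rank <- seq_len(nrow(lc))
    }
    if (!length(out)) stop("no testable cluster")
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Per-cluster mean expression profiles
#'
#' The gene expression profile (GEP) of a cluster is the arithmetic mean of
#' its cells' log-normalized expression.
#'
#' @param sce clustered \code{SingleCellExperiment} with \code{logcounts}.
#' @return clusters x genes matrix; row names are cluster ids
#' @export
clusterGEP <- function(sce) {
    labels <- sce$cluster
    if (is.null(labels)) stop("sce has no clustering")
    lc <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
    geps <- t(vapply(sort(unique(labels)), function(cl)
        rowMeans(lc[, labels == cl, drop = FALSE]),
        numeric(nrow(lc))))
    rownames(geps) <- sort(unique(labels))
    colnames(geps) <- rownames(lc)
    geps
}

#' Correlation-based cell-type annotation
#'
#' Assigns each cluster the reference profile with the highest rank
#' (Spearman) correlation to its GEP over the shared genes. Rank correlation
#' makes the assignment invariant to monotone transformations of either
#' side, so query and reference need not share a normalization.
#'
#' @param gep clusters x genes matrix (\code{\link{clusterGEP}} output).
#' @param reference genes x reference-profiles matrix with profile names as
#'   column names.
#' @param method "spearman" (default) or "pearson".
#' @return data.frame with columns cluster, cell_type, correlation
#' @export
annotateCellTypes <- function(gep, reference,
                              method = c("spearman", "pearson")) {
    method <- match.arg(method)
    shared <- intersect(colnames(gep), rownames(reference))
    if (!length(shared)) stop("no shared genes between query and reference")
    if (length(shared) < 50)
        warning("only ", length(shared), " shared genes; annotation may be ",
                "unreliable")
    cc <- stats::cor(t(gep[, shared, drop = FALSE]),
                     reference[shared, , drop = FALSE], method = method)
    best <- max.col(cc, ties.method = "first")
    data.frame(cluster = rownames(gep),
               cell_type = colnames(reference)[best],
               correlation = cc[cbind(seq_len(nrow(cc)), best)],
               row.names = NULL)
}

#' Gene-set over-representation of cluster DEG lists
#'
#' For each cluster, the query is the set of DEGs passing all three
#' thresholds (log2 fold change strictly above \code{lfcMin}, raw and
#' adjusted p strictly below \code{pMax}/\code{adjPMax}); each gene set is
#' tested by the hypergeometric tail against the background universe, and
#' p-values are Benjamini-Hochberg adjusted within the cluster.
#'
#' @param degTable output of \code{\link{rankDEGs}}.
#' @param gmt named list of gene sets (\code{\link{readGMT}} output).
#' @param lfcMin,pMax,adjPMax DEG thresholds.
#' @param background character vector of background genes; defaults to all
#'   genes in \code{degTable}.
#' @return data.frame with columns cluster, term, overlap_count, term_size,
#'   query_size, p_value, adj_p_value
#' @export
enrichClusters <- function(degTable, gmt, lfcMin = 2, pMax = 0.01,
                           adjPMax = 0.01, background = NULL) {
    if (is.null(background)) background <- unique(degTable$gene)
    N <- length(background)
    gmt <- lapply(gmt, intersect, background)
    out <- list()
    for (cl in unique(degTable$cluster)) {
        sub <- degTable[degTable$cluster == cl, ]
        query <- sub$gene[sub$log2_fold_change > lfcMin &
                          sub$p_value < pMax & sub$adj_p_value < adjPMax]
        query <- intersect(query, background)
        if (!length(query)) {
            warning("cluster ", cl, ": no DEGs pass thresholds")
            next
        }
        k <- length(query)
        p <- vapply(gmt, function(set) {
            K <- length(set)
            ov <- length(intersect(query, set))
            stats::phyper(ov - 1, K, N - K, k, lower.tail = FALSE)
        }, numeric(1))
        ov <- vapply(gmt, function(set)
            length(intersect(query, set)), integer(1))
        out[[length(out) + 1L]] <- data.frame(
            cluster = cl, term = names(gmt), overlap_count = ov,
            term_size = lengths(gmt), query_size = k, p_value = p,
            adj_p_value = .bh(p), row.names = NULL)
    }
    if (!length(out))
        return(data.frame(cluster = character(), term = character(),
                          overlap_count = integer(), term_size = integer(),
                          query_size = integer(), p_value = numeric(),
                          adj_p_value = numeric()))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Tumor-cluster selection from cell-origin labels
#'
#' A cluster is called a tumor cluster when tumor-origin cells are more than
#' \code{ratioThreshold} times over-represented in it relative to
#' normal-origin cells. Representation is measured as the within-cluster
#' fraction of each origin's total cells, so overall tumor/normal imbalance
#' in the dataset does not bias the call; the inequality is strict.
#'
#' @param sce clustered \code{SingleCellExperiment}.
#' @param origin character vector over cells with values "tumor"/"normal"
#'   (named by cell or in \code{colnames(sce)} order).
#' @param ratioThreshold over-representation ratio required.
#' @return integer vector of selected cluster ids
#' @export
selectTumorClusters <- function(sce, origin, ratioThreshold = 2) {
    labels <- sce$cluster
    if (is.null(labels)) stop("sce has no clustering")
    if (!is.null(names(origin))) origin <- origin[colnames(sce)]
    if (length(origin) != ncol(sce) || anyNA(origin))
        stop("every cell needs a tumor/normal origin label")
    if (!all(origin %in% c("tumor", "normal")))
        stop("origin labels must be 'tumor' or 'normal'")
    nT <- sum(origin == "tumor"); nN <- sum(origin == "normal")
    if (nT == 0 || nN == 0) stop("both origins must be present")
    sel <- vapply(sort(unique(labels)), function(cl) {
        inC <- labels == cl
        fT <- sum(origin[inC] == "tumor") / nT
        fN <- sum(origin[inC] == "normal") / nN
        fT > ratioThreshold * fN
    }, logical(1))
    sort(unique(labels))[sel]
}
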