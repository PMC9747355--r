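## Internal helpers shared across modules.

.assertMatrixLike <- function(x, what = "matrix") {
    if (!(is.matrix(x) || methods::is(x, "Matrix")))
        stop(what, " must be a matrix", call. = FALSE)
    invisible(TRUE)
}

## Silhouette widths from a dissimilarity matrix with possible missing
## entries (NA = pair never observed). Cells in singleton clusters get 0,
## the usual convention. Unobserved pairs are simply dropped from the
## within/between means; a cell with no usable neighbour terms is dropped
## from the average.
.silhouetteWidths <- function(D, labels) {
    n <- length(labels)
    stopifnot(nrow(D) == n, ncol(D) == n)
    labs <- unique(labels)
    if (length(labs) < 2L)
        stop("silhouette undefined for a single cluster")
    idxByLab <- split(seq_len(n), labels)
    sizes <- lengths(idxByLab)
    s <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        li <- as.character(labels[i])
        if (sizes[[li]] == 1L) { s[i] <- 0; next }
        own <- setdiff(idxByLab[[li]], i)
        a <- mean(D[i, own], na.rm = TRUE)
        bs <- vapply(setdiff(names(idxByLab), li), function(l)
            mean(D[i, idxByLab[[l]]], na.rm = TRUE), numeric(1))
        bs <- bs[is.finite(bs)]
        if (!is.finite(a) || !length(bs)) next
        b <- min(bs)
        s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }
    s
}

## Pearson correlation of each column of A against each column of B.
## Plain cor() but centralized so degenerate columns error with context.
.corColumns <- function(A, B, method = "pearson") {
    sdA <- apply(A, 2L, stats::sd)
    if (any(sdA == 0 | !is.finite(sdA)))
        stop("zero-variance profile for sample(s): ",
             paste(colnames(A)[sdA == 0 | !is.finite(sdA)], collapse = ", "),
             call. = FALSE)
    stats::cor(A, B, method = method)
}

## Relabel cluster ids to consecutive integers 0..K-1 ordered by
## descending cluster size (ties by first appearance) for stability.
.canonicalLabels <- function(labels) {
    tab <- sort(table(labels), decreasing = TRUE)
    map <- stats::setNames(seq_along(tab) - 1L, names(tab))
    unname(map[as.character(labels)])
}

## Spearman correlation that returns NA instead of erroring on constant
## input (used for per-drug prediction quality).
.spearman <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) return(NA_real_)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok], method = "spearman")
}

## Benjamini-Hochberg wrapper preserving names.
.bh <- function(p) stats::p.adjust(p, method = "BH")

## Seed guard: all internal seeds derived from a master seed stay below
## .Machine$integer.max.
.deriveSeed <- function(master, offset) {
    as.integer((as.numeric(master) + as.numeric(offset)) %% 2147483647)
}
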