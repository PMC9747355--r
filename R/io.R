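#' Read a 10x-style Matrix Market triplet into a SingleCellExperiment
#'
#' Expects \code{matrix.mtx}, \code{barcodes.tsv} and \code{features.tsv}
#' (or \code{genes.tsv}) in \code{dir}, optionally gzipped. Features files
#' may have one column (gene id) or the usual id/symbol/type columns; gene
#' symbols are used as row names when present so mitochondrial genes can be
#' recognized by symbol prefix.
#'
#' @param dir directory holding the triplet.
#' @return a \code{SingleCellExperiment} with a \code{counts} assay
#'   (genes x cells).
#' @export
readCounts10x <- function(dir) {
    find <- function(base) {
        for (f in c(file.path(dir, base), file.path(dir, paste0(base, ".gz"))))
            if (file.exists(f)) return(f)
        NULL
    }
    mtx <- find("matrix.mtx")
    bcs <- find("barcodes.tsv")
    fts <- find("features.tsv")
    if (is.null(fts)) fts <- find("genes.tsv")
    if (is.null(mtx) || is.null(bcs) || is.null(fts))
        stop("expected matrix.mtx, barcodes.tsv and features.tsv under ", dir)
    m <- as(Matrix::readMM(mtx), "CsparseMatrix")
    barcodes <- readLines(bcs)
    feats <- utils::read.delim(fts, header = FALSE, stringsAsFactors = FALSE)
    sym <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
    sym <- make.unique(as.character(sym))
    if (length(sym) != nrow(m) || length(barcodes) != ncol(m))
        stop("matrix dimensions do not match barcodes/features files")
    dimnames(m) <- list(sym, make.unique(barcodes))
    SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

#' Read a dense genes x cells count table
#'
#' @param path TSV with gene ids in the first column and one column per cell.
#' @return a \code{SingleCellExperiment} with a \code{counts} assay.
#' @export
readCountsTSV <- function(path) {
    tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
    m <- as(as.matrix(tab), "CsparseMatrix")
    SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

#' Build a SingleCellExperiment from a count matrix
#'
#' @param counts genes x cells matrix of non-negative integer counts with
#'   unique dimnames.
#' @return a \code{SingleCellExperiment}
#' @export
asCountsExperiment <- function(counts) {
    .assertMatrixLike(counts, "counts")
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must carry gene and cell identifiers as dimnames")
    if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
        stop("gene and cell identifiers must be unique")
    if (any(counts < 0) || any(!is.finite(as.vector(counts[seq_len(min(100, length(counts)))]))))
        stop("counts must be finite and non-negative")
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = as(counts, "CsparseMatrix")))
}

#' Read a GMT gene-set library
#'
#' @param path GMT file: term, description, then member genes, tab-separated.
#' @return named list of character vectors (term -> genes).
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- lapply(lines, function(l) {
        parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
        unique(parts[-(1:2)])
    })
    names(sets) <- vapply(lines, function(l)
        strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
    sets
}

#' Read a drug-screen training panel
#'
#' @param exprPath lines x genes expression table (TSV/CSV by extension),
#'   cell-line ids in the first column.
#' @param respPath lines x drugs response table; missing responses may be
#'   empty/NA and are masked during training.
#' @param responseScale "gdsc" (-log IC50 values) or "prism" (1-AUC values).
#' @return list with \code{expression} (lines x genes), \code{response}
#'   (lines x drugs) and \code{responseScale}.
#' @export
readDrugPanel <- function(exprPath, respPath,
                          responseScale = c("gdsc", "prism")) {
    responseScale <- match.arg(responseScale)
    rd <- function(p) {
        sep <- if (grepl("\\.csv$", p)) "," else "\t"
        as.matrix(utils::read.delim(p, row.names = 1, sep = sep,
                                    check.names = FALSE))
    }
    expr <- rd(exprPath); resp <- rd(respPath)
    common <- intersect(rownames(expr), rownames(resp))
    if (!length(common)) stop("no shared cell lines between tables")
    list(expression = expr[common, , drop = FALSE],
         response = resp[common, , drop = FALSE],
         responseScale = responseScale)
}

#' Read a bulk survival cohort
#'
#' @param exprPath genes x patients expression TSV.
#' @param clinicalPath TSV with columns patient, time, event.
#' @return list with \code{expression} (patients x genes), \code{time},
#'   \code{event}.
#' @export
readCohort <- function(exprPath, clinicalPath) {
    expr <- t(as.matrix(utils::read.delim(exprPath, row.names = 1,
                                          check.names = FALSE)))
    clin <- utils::read.delim(clinicalPath, check.names = FALSE)
    need <- c("patient", "time", "event")
    if (!all(need %in% names(clin)))
        stop("clinical table must have columns: patient, time, event")
    common <- intersect(rownames(expr), clin$patient)
    if (!length(common)) stop("no shared patients between tables")
    clin <- clin[match(common, clin$patient), ]
    if (any(clin$time <= 0)) stop("survival times must be positive")
    list(expression = expr[common, , drop = FALSE],
         time = clin$time, event = as.integer(clin$event))
}

#' Read a perturbation screen from metadata + GEP tables
#'
#' @param metaPath long-format TSV: experiment_id, compound, concentration,
#'   unit, is_control.
#' @param gepPath genes x experiments profile TSV (anti-log scale).
#' @param referenceLine optional reference cell-line name.
#' @return a \code{PerturbationScreen}
#' @export
readScreen <- function(metaPath, gepPath, referenceLine = NA_character_) {
    meta <- utils::read.delim(metaPath, check.names = FALSE)
    gep <- as.matrix(utils::read.delim(gepPath, row.names = 1,
                                       check.names = FALSE))
    PerturbationScreen(gep, meta, referenceLine)
}

#' Write a cell-to-cluster assignment table
#'
#' @param sce a clustered \code{SingleCellExperiment}.
#' @param path output TSV path.
#' @export
writeClusteringTSV <- function(sce, path) {
    stopifnot("cluster" %in% names(SummarizedExperiment::colData(sce)))
    utils::write.table(
        data.frame(cell_id = colnames(sce), cluster = sce$cluster),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.writeTSV <- function(df, path, rowNames = FALSE) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = rowNames,
                       col.names = if (rowNames) NA else TRUE)
    invisible(path)
}
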