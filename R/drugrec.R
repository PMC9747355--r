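#' Affine scaling of 1-AUC drug responses
#'
#' PRISM-style screens report the area under the dose-response curve; the
#' model trains on an affinely rescaled 1-AUC, \eqn{D' = 240 D - 120},
#' which widens the narrow [0,1] range onto a scale comparable to -log IC50
#' values. \code{unscalePrism} is the exact inverse.
#'
#' @param D unscaled 1-AUC values (any numeric shape).
#' @return rescaled values of the same shape
#' @export
scalePrism <- function(D) 240 * D - 120

#' @rdname scalePrism
#' @param Dprime scaled values.
#' @export
unscalePrism <- function(Dprime) (Dprime + 120) / 240

#' Response-correlated feature genes
#'
#' Selects genes whose expression across training lines correlates with the
#' per-line mean drug response at \code{|r| >= minAbsCorr} (Pearson).
#' Constant genes have undefined correlation and are excluded.
#'
#' @param expression lines x genes matrix.
#' @param response lines x drugs matrix (NA = unobserved).
#' @param minAbsCorr absolute correlation threshold.
#' @return character vector of selected genes
#' @export
selectFeatureGenes <- function(expression, response, minAbsCorr = 0.2) {
    if (nrow(expression) < 3) stop("need at least 3 cell lines")
    target <- rowMeans(response, na.rm = TRUE)
    r <- suppressWarnings(stats::cor(expression, target))
    sel <- !is.na(r) & abs(r) >= minAbsCorr
    if (!any(sel))
        stop("no gene passes |r| >= ", minAbsCorr,
             "; lower the threshold")
    colnames(expression)[sel]
}

#' Kernel features of expression profiles
#'
#' Represents each sample by its Pearson correlations to the training cell
#' lines, computed on log2 fold-change profiles over the feature genes.
#' Fold changes are taken against the panel's per-gene mean expression, so
#' a training line's own kernel row has a 1 at itself.
#'
#' @param queryExpression samples x genes matrix on the same log scale as
#'   the panel expression.
#' @param panel drug panel list (\code{expression}, \code{response}) or a
#'   fitted \code{DrugResponseModel}.
#' @param featureGenes genes to use; defaults to the panel's/model's.
#' @return list with \code{x} (samples x training-lines kernel matrix) and
#'   \code{fcReference} (per-gene panel mean)
#' @export
kernelFeatures <- function(queryExpression, panel, featureGenes = NULL) {
    if (methods::is(panel, "DrugResponseModel")) {
        fg <- if (is.null(featureGenes)) panel@featureGenes else featureGenes
        ref <- panel@fcReference[fg]
        trainFC <- panel@trainFC[, fg, drop = FALSE]
    } else {
        fg <- if (is.null(featureGenes)) colnames(panel$expression)
              else featureGenes
        ref <- colMeans(panel$expression[, fg, drop = FALSE])
        trainFC <- sweep(panel$expression[, fg, drop = FALSE], 2L, ref)
    }
    miss <- setdiff(fg, colnames(queryExpression))
    if (length(miss))
        stop("feature gene(s) absent from query: ",
             paste(utils::head(miss, 5), collapse = ", "))
    fcQ <- sweep(queryExpression[, fg, drop = FALSE], 2L, ref)
    x <- .corColumns(t(fcQ), t(trainFC))
    list(x = x, fcReference = ref)
}

## Predictions on the model scale from a kernel-feature matrix.
.predictFromKernel <- function(model, x) {
    p <- x %*% model@W
    s <- p %*% t(model@Q) + rep(model@b, each = nrow(x))
    dimnames(s) <- list(rownames(x), rownames(model@Q))
    s
}

#' Train the latent-factor drug-response model
#'
#' Minimizes the masked squared-error objective
#' \deqn{L = \frac{1}{2K}\sum_{i,u} m_{iu}(s_{iu}-\hat{s}_{iu})^2
#'       + \lambda\lVert W\rVert^2 + \lambda\lVert Q\rVert^2,\qquad
#'       \hat{s}_{iu} = b_i + q_i\cdot(x_u W)}
#' over the projection \code{W}, drug factors \code{Q} and per-drug biases,
#' where \eqn{K} counts the observed drug-line pairs and \eqn{x_u} are
#' kernel features. Optimization is first-order gradient descent with an
#' adaptive step ("bold driver": a step that increases the objective is
#' rejected and the rate halved, an accepted step grows it 5\%), so the
#' recorded loss trace is non-increasing by construction. Training stops at
#' \code{maxEpochs} or when the relative loss change over 100 accepted
#' epochs falls below 1e-8. PRISM-style panels (1-AUC responses) are put on
#' the model scale with \code{\link{scalePrism}} before fitting.
#'
#' @param panel list with \code{expression} (lines x genes), \code{response}
#'   (lines x drugs, NA allowed) and optionally \code{responseScale}
#'   ("gdsc"/"prism", default "gdsc").
#' @param f latent dimension (capped at the number of lines).
#' @param lambda L2 regularization weight.
#' @param learningRate initial gradient step.
#' @param maxEpochs epoch cap.
#' @param seed RNG seed for the parameter initialization.
#' @param featureGenes feature genes; NULL uses all non-constant genes.
#' @return a \code{DrugResponseModel}
#' @export
trainDrugModel <- function(panel, f = 10, lambda = 0.01,
                           learningRate = 0.01, maxEpochs = 100000,
                           seed = 0, featureGenes = NULL) {
    expr <- panel$expression
    scaleTag <- if (is.null(panel$responseScale)) "gdsc"
                else panel$responseScale
    S <- panel$response
    if (scaleTag == "prism") S <- scalePrism(S)
    if (is.null(featureGenes)) {
        sdv <- apply(expr, 2L, stats::sd)
        featureGenes <- colnames(expr)[sdv > 0]
    }
    f <- as.integer(min(f, nrow(expr)))
    ref <- colMeans(expr[, featureGenes, drop = FALSE])
    trainFC <- sweep(expr[, featureGenes, drop = FALSE], 2L, ref)
    X <- .corColumns(t(trainFC), t(trainFC))
    d <- ncol(X); nDrugs <- ncol(S)
    mask <- !is.na(S)
    K <- sum(mask)
    if (K == 0) stop("no observed drug-line responses")
    Sz <- S; Sz[!mask] <- 0

    set.seed(.deriveSeed(seed, 0))
    W <- matrix(stats::rnorm(d * f, 0, 0.01), d, f)
    Q <- matrix(stats::rnorm(nDrugs * f, 0, 0.01), nDrugs, f)
    b <- colMeans(S, na.rm = TRUE)
    b[is.na(b)] <- 0

    lossOf <- function(W, Q, b) {
        E <- (X %*% W) %*% t(Q) + rep(b, each = nrow(X)) - Sz
        E[!mask] <- 0
        sum(E^2) / (2 * K) + lambda * (sum(W^2) + sum(Q^2))
    }
    lr <- learningRate
    loss <- lossOf(W, Q, b)
    trace <- loss
    stale <- 0L
    for (epoch in seq_len(maxEpochs)) {
        P <- X %*% W
        E <- P %*% t(Q) + rep(b, each = nrow(X)) - Sz
        E[!mask] <- 0
        gb <- colSums(E) / K
        gQ <- crossprod(E, P) / K + 2 * lambda * Q
        gW <- crossprod(X, E %*% Q) / K + 2 * lambda * W
        W2 <- W - lr * gW; Q2 <- Q - lr * gQ; b2 <- b - lr * gb
        newLoss <- lossOf(W2, Q2, b2)
        if (!is.finite(newLoss)) {
            if (lr < 1e-12)
                stop("training diverged; use a smaller learning rate")
            lr <- lr / 2
            next
        }
        if (newLoss <= loss) {
            rel <- (loss - newLoss) / max(loss, .Machine$double.eps)
            W <- W2; Q <- Q2; b <- b2
            loss <- newLoss
            trace <- c(trace, loss)
            lr <- lr * 1.05
            stale <- if (rel < 1e-8) stale + 1L else 0L
            if (stale >= 100L) break
        } else {
            lr <- lr / 2
            if (lr < 1e-14) break
        }
    }
    rownames(W) <- rownames(X)
    rownames(Q) <- colnames(S)
    methods::new("DrugResponseModel",
        W = W, Q = Q, b = stats::setNames(b, colnames(S)),
        mu = mean(S[mask]), f = f, lambda = lambda,
        featureGenes = featureGenes, trainFC = trainFC,
        fcReference = ref, responseScale = scaleTag,
        lossTrace = trace,
        config = list(learningRate = learningRate, maxEpochs = maxEpochs,
                      seed = seed, epochsRun = length(trace) - 1L))
}

#' Predict drug responses for expression profiles
#'
#' @param model a \code{DrugResponseModel}.
#' @param expression samples x genes matrix on the panel's log scale.
#' @return samples x drugs matrix of predictions on the model scale
#' @export
predictResponse <- function(model, expression) {
    kf <- kernelFeatures(expression, model)
    .predictFromKernel(model, kf$x)
}

#' Per-cluster drug-response prediction from single cells
#'
#' Two prediction modes: \code{per_cell_mean} builds kernel features per
#' cell (fold change against the panel reference), predicts each cell and
#' averages predictions within a cluster; \code{cluster_wise} builds one
#' fold-change profile per cluster against the mean of all other clusters
#' (against the panel reference when there is a single cluster) and
#' predicts each cluster directly. For PRISM-scale models the sensitivity
#' matrix is reported as predicted 1-AUC (higher = more sensitive); for
#' GDSC-scale models it is the predicted -log IC50 itself.
#'
#' @param model a \code{DrugResponseModel}.
#' @param sce clustered \code{SingleCellExperiment} with \code{logcounts}.
#' @param mode prediction mode.
#' @return list with \code{prediction} (clusters x drugs, model scale),
#'   \code{sensitivity} (clusters x drugs, reporting scale) and \code{mode}
#' @export
predictCells <- function(model, sce,
                         mode = c("per_cell_mean", "cluster_wise")) {
    mode <- match.arg(mode)
    labels <- sce$cluster
    if (is.null(labels)) stop("sce has no clustering")
    clusters <- sort(unique(labels))
    if (mode == "per_cell_mean") {
        expr <- t(as.matrix(SummarizedExperiment::assay(sce, "logcounts")))
        perCell <- predictResponse(model, expr)
        pred <- t(vapply(clusters, function(cl) {
            rows <- which(labels == cl)
            if (!length(rows)) stop("cluster ", cl, " has no usable cells")
            colMeans(perCell[rows, , drop = FALSE])
        }, numeric(ncol(perCell))))
    } else {
        gep <- clusterGEP(sce)
        fg <- model@featureGenes
        miss <- setdiff(fg, colnames(gep))
        if (length(miss))
            stop("feature gene(s) absent from single-cell data: ",
                 paste(utils::head(miss, 5), collapse = ", "))
        fc <- t(vapply(seq_len(nrow(gep)), function(i) {
            if (nrow(gep) == 1L) gep[i, fg] - model@fcReference[fg]
            else gep[i, fg] - colMeans(gep[-i, fg, drop = FALSE])
        }, numeric(length(fg))))
        x <- .corColumns(t(fc), t(model@trainFC[, fg, drop = FALSE]))
        pred <- .predictFromKernel(model, x)
    }
    rownames(pred) <- clusters
    sens <- if (model@responseScale == "prism") unscalePrism(pred) else pred
    list(prediction = pred, sensitivity = sens, mode = mode)
}

#' Drop poorly modelled drugs
#'
#' Computes the per-drug Spearman correlation between predicted and
#' observed training responses and drops drugs whose coefficient falls
#' strictly below the first quartile (linear-interpolation percentile) of
#' the coefficient distribution.
#'
#' @param model a \code{DrugResponseModel}.
#' @param panel the training panel.
#' @return character vector of retained drug names, with the per-drug
#'   coefficients as attribute \code{"coefficients"}
#' @export
filterDrugs <- function(model, panel) {
    S <- panel$response
    if (!is.null(panel$responseScale) && panel$responseScale == "prism")
        S <- scalePrism(S)
    X <- .corColumns(t(model@trainFC), t(model@trainFC))
    pred <- .predictFromKernel(model, X)
    coefs <- vapply(seq_len(ncol(S)), function(j)
        .spearman(pred[, j], S[, j]), numeric(1))
    names(coefs) <- colnames(S)
    if (ncol(S) < 4) {
        warning("fewer than 4 drugs; no filtering applied")
        retained <- colnames(S)
    } else {
        q1 <- stats::quantile(coefs, 0.25, type = 7, na.rm = TRUE,
                              names = FALSE)
        retained <- colnames(S)[!is.na(coefs) & coefs >= q1]
    }
    attr(retained, "coefficients") <- coefs
    retained
}

#' Held-out evaluation of the drug-response model
#'
#' Splits off \code{nHoldout} cell lines, trains on the remainder, predicts
#' the held-out lines through their kernel features against the training
#' lines, and reports the median absolute error and Pearson correlation
#' between actual and predicted responses, plus per-drug Spearman
#' correlations.
#'
#' @param panel the drug panel.
#' @param nHoldout number of validation lines.
#' @param f,lambda,learningRate,maxEpochs,featureGenes training settings.
#' @param seed seed for the split and the fit.
#' @return list with \code{mae}, \code{pearson}, \code{perDrugSpearman},
#'   \code{holdoutLines} and the fitted \code{model}
#' @export
evaluateHoldout <- function(panel, nHoldout = 24, f = 10, lambda = 0.01,
                            learningRate = 0.01, maxEpochs = 100000,
                            featureGenes = NULL, seed = 0) {
    nLines <- nrow(panel$expression)
    if (nHoldout >= nLines)
        stop("nHoldout must be smaller than the number of lines")
    set.seed(.deriveSeed(seed, 99))
    hold <- sort(sample.int(nLines, nHoldout))
    sub <- list(expression = panel$expression[-hold, , drop = FALSE],
                response = panel$response[-hold, , drop = FALSE],
                responseScale = panel$responseScale)
    model <- trainDrugModel(sub, f = f, lambda = lambda,
                            learningRate = learningRate,
                            maxEpochs = maxEpochs, seed = seed,
                            featureGenes = featureGenes)
    obs <- panel$response[hold, , drop = FALSE]
    if (!is.null(panel$responseScale) && panel$responseScale == "prism")
        obs <- scalePrism(obs)
    pred <- predictResponse(model, panel$expression[hold, , drop = FALSE])
    ok <- !is.na(obs)
    perDrug <- vapply(seq_len(ncol(obs)), function(j)
        .spearman(pred[, j], obs[, j]), numeric(1))
    names(perDrug) <- colnames(obs)
    list(mae = stats::median(abs(pred[ok] - obs[ok])),
         pearson = stats::cor(pred[ok], obs[ok]),
         perDrugSpearman = perDrug,
         holdoutLines = rownames(panel$expression)[hold],
         model = model)
}
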