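test_that("response scaling is the stated affine map and inverts exactly", {
    expect_equal(scalePrism(0.5), 0)
    expect_equal(scalePrism(0), -120)
    expect_equal(scalePrism(1), 120)
    x <- seq(-0.2, 1.2, by = 0.01)
    expect_equal(unscalePrism(scalePrism(x)), x, tolerance = 1e-12)
})

test_that("feature-gene selection keys on response correlation", {
    set.seed(20)
    expr <- matrix(rnorm(50 * 10), 50, 10,
                   dimnames = list(sprintf("L%02d", 1:50),
                                   sprintf("G%02d", 1:10)))
    resp <- matrix(rnorm(50 * 4), 50, 4,
                   dimnames = list(rownames(expr), paste0("D", 1:4)))
    target <- rowMeans(resp)
    expr[, 1] <- target             # r = 1
    expr[, 2] <- 7                  # constant -> excluded
    fg <- selectFeatureGenes(expr, resp, minAbsCorr = 0.2)
    expect_true("G01" %in% fg)
    expect_false("G02" %in% fg)
    expect_error(selectFeatureGenes(expr[, 2, drop = FALSE], resp),
                 "threshold")

    ## planted response-linked genes are recalled at n = 200 lines
    set.seed(21)
    expr <- matrix(rnorm(200 * 300), 200, 300,
                   dimnames = list(sprintf("L%03d", 1:200),
                                   sprintf("G%03d", 1:300)))
    resp <- matrix(rnorm(200, sd = 1), 200, 5,
                   dimnames = list(rownames(expr), paste0("D", 1:5)))
    linked <- sprintf("G%03d", 1:30)
    for (g in linked) expr[, g] <- rowMeans(resp) + rnorm(200, 0, 1)
    fg <- selectFeatureGenes(expr, resp, minAbsCorr = 0.2)
    expect_gte(length(intersect(fg, linked)) / 30, 0.9)
})

test_that("kernel features equal brute-force pairwise Pearson", {
    set.seed(22)
    expr <- matrix(rnorm(12 * 30, 8), 12, 30,
                   dimnames = list(sprintf("L%02d", 1:12),
                                   sprintf("G%02d", 1:30)))
    panel <- list(expression = expr,
                  response = matrix(rnorm(12 * 3), 12, 3,
                                    dimnames = list(rownames(expr),
                                                    paste0("D", 1:3))))
    kf <- kernelFeatures(expr, panel)
    ref <- colMeans(expr)
    for (i in c(1, 5, 12)) for (j in c(2, 7)) {
        expect_equal(kf$x[i, j], cor(expr[i, ] - ref, expr[j, ] - ref),
                     tolerance = 1e-10)
    }
    ## training line against itself: exactly 1
    expect_equal(diag(kf$x), rep(1, 12), tolerance = 1e-12,
                 ignore_attr = TRUE)

    ## panel-mean query has a zero fold-change profile -> error names it
    flat <- matrix(ref, 1, 30, dimnames = list("meanq", colnames(expr)))
    expect_error(kernelFeatures(flat, panel), "meanq")
})

test_that("training descends monotonically and shrinks to drug means under
           heavy regularization", {
    sim <- simulateDrugPanel(nLines = 30, nDrugs = 8, nGenes = 100,
                             fTrue = 2, noiseSd = 0.1, seed = 4)
    m <- trainDrugModel(sim$panel, f = 2, seed = 4)
    expect_true(all(diff(lossTrace(m)) <= 0))
    expect_lt(tail(lossTrace(m), 1), lossTrace(m)[1])

    heavy <- trainDrugModel(sim$panel, f = 2, lambda = 1e6, seed = 4)
    expect_lt(max(abs(heavy@W)), 1e-3)
    expect_lt(max(abs(heavy@Q)), 1e-3)
    X <- diag(nrow(sim$panel$expression))
    pred <- heavy@b  # with W,Q ~ 0 predictions collapse to the drug biases
    expect_equal(unname(pred), unname(colMeans(sim$panel$response)),
                 tolerance = 1e-3)

    ## determinism: same seed, same fit
    m2 <- trainDrugModel(sim$panel, f = 2, seed = 4)
    expect_identical(m@W, m2@W)
    expect_identical(lossTrace(m), lossTrace(m2))
})

test_that("a noiseless model-generated panel is fit almost perfectly", {
    sim <- simulateDrugPanel(nLines = 60, nDrugs = 25, fTrue = 4,
                             noiseSd = 0, seed = 1)
    m <- trainDrugModel(sim$panel, f = 4, lambda = 1e-4, seed = 1)
    pred <- predictResponse(m, sim$panel$expression)
    sp <- vapply(1:25, function(j)
        cor(pred[, j], sim$panel$response[, j], method = "spearman"),
        numeric(1))
    expect_gte(min(sp), 0.99)
})

test_that("masked responses are ignored and gene order does not matter", {
    sim <- simulateDrugPanel(nLines = 30, nDrugs = 8, nGenes = 100,
                             fTrue = 2, noiseSd = 0.05, seed = 9)
    panel <- sim$panel
    panel$response[sample(length(panel$response), 40)] <- NA
    m <- trainDrugModel(panel, f = 2, seed = 9)
    expect_true(all(is.finite(lossTrace(m))))

    perm <- sample(ncol(panel$expression))
    panelP <- panel
    panelP$expression <- panel$expression[, perm]
    mP <- trainDrugModel(panelP, f = 2, seed = 9)
    q <- panel$expression[1:3, , drop = FALSE]
    expect_equal(predictResponse(m, q), predictResponse(mP, q),
                 tolerance = 1e-8)
})

test_that("per-cluster prediction modes agree on degenerate input and
           order clusters by known sensitivity", {
    sim <- simulateDrugPanel(nLines = 20, nDrugs = 6, nGenes = 80,
                             fTrue = 2, noiseSd = 0, seed = 5)
    m <- trainDrugModel(sim$panel, f = 2, lambda = 1e-4, seed = 5)

    ## all cells identical, single cluster: both modes coincide
    cellExpr <- matrix(rep(sim$panel$expression[3, ], 10), 10, byrow = TRUE,
                       dimnames = list(paste0("c", 1:10),
                                       colnames(sim$panel$expression)))
    lc <- t(cellExpr)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(logcounts = lc))
    sce$cluster <- rep(0L, 10)
    pcm <- predictCells(m, sce, mode = "per_cell_mean")
    pcw <- predictCells(m, sce, mode = "cluster_wise")
    expect_equal(pcm$prediction, pcw$prediction, tolerance = 1e-10)

    ## clusters built from two training lines preserve the panel's
    ## predicted drug ordering
    lines <- c(2, 11)
    cellExpr <- rbind(
        matrix(rep(sim$panel$expression[lines[1], ], 8), 8, byrow = TRUE),
        matrix(rep(sim$panel$expression[lines[2], ], 8), 8, byrow = TRUE))
    dimnames(cellExpr) <- list(paste0("c", 1:16),
                               colnames(sim$panel$expression))
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(logcounts = t(cellExpr)))
    sce$cluster <- rep(0:1, each = 8L)
    pred <- predictCells(m, sce, mode = "per_cell_mean")$prediction
    panelPred <- predictResponse(m, sim$panel$expression[lines, ])
    for (j in 1:6)
        expect_equal(pred[1, j] > pred[2, j],
                     panelPred[1, j] > panelPred[2, j])
})

test_that("drug filtering drops strictly-below-first-quartile performers", {
    ## engineered per-drug Spearman coefficients 0.1, 0.4, 0.6, 0.9
    pred <- matrix(rep(1:5, 4), 5, 4,
                   dimnames = list(paste0("L", 1:5), paste0("D", 1:4)))
    obs <- cbind(D1 = c(4, 2, 3, 1, 5), D2 = c(4, 1, 2, 3, 5),
                 D3 = c(3, 2, 1, 4, 5), D4 = c(1, 2, 3, 5, 4))
    rownames(obs) <- paste0("L", 1:5)
    model <- modelWithPredictions(pred)
    panel <- list(expression = NULL, response = obs)
    kept <- filterDrugs(model, panel)
    coefs <- attr(kept, "coefficients")
    expect_equal(unname(coefs), c(0.1, 0.4, 0.6, 0.9))
    ## Q1 (linear interpolation) = 0.325: only D1 is dropped
    expect_setequal(as.character(kept), c("D2", "D3", "D4"))
    ## exhaustive oracle re-application of the rule
    q1 <- quantile(coefs, 0.25, type = 7)
    expect_setequal(as.character(kept), names(coefs)[coefs >= q1])
    expect_gte(length(kept), ceiling(0.75 * 4))

    ## all-equal coefficients: nothing dropped
    obsEq <- matrix(rep(c(2, 1, 3, 4, 5), 4), 5, 4,
                    dimnames = dimnames(obs))
    keptEq <- filterDrugs(modelWithPredictions(pred),
                          list(expression = NULL, response = obsEq))
    expect_length(keptEq, 4)

    expect_warning(
        filterDrugs(modelWithPredictions(pred[, 1:3]),
                    list(expression = NULL, response = obs[, 1:3])),
        "fewer than 4")
})

test_that("held-out evaluation recovers noiseless panels and is
           deterministic", {
    sim <- simulateDrugPanel(nLines = 60, nDrugs = 25, fTrue = 4,
                             noiseSd = 0, seed = 2)
    ev <- evaluateHoldout(sim$panel, nHoldout = 24, f = 4, lambda = 1e-4,
                          seed = 2)
    expect_gte(ev$pearson, 0.95)
    ev2 <- evaluateHoldout(sim$panel, nHoldout = 24, f = 4, lambda = 1e-4,
                           seed = 2)
    expect_identical(ev$mae, ev2$mae)
    expect_identical(ev$pearson, ev2$pearson)
    expect_error(evaluateHoldout(sim$panel, nHoldout = 60), "smaller")
})

test_that("both screen-style configurations train without divergence", {
    gd <- simulateDrugPanel(nLines = 40, nDrugs = 12, fTrue = 3,
                            noiseSd = 0.2, seed = 6)
    mg <- trainDrugModel(gd$panel, f = 10, seed = 6)
    expect_true(all(is.finite(lossTrace(mg))))

    pr <- simulateDrugPanel(nLines = 40, nDrugs = 12, fTrue = 3,
                            noiseSd = 0.2, seed = 7)
    ## PRISM-style: responses are 1-AUC in [0,1], scaled before fitting
    pr$panel$response <- 1 / (1 + exp(-pr$panel$response / 2))
    pr$panel$responseScale <- "prism"
    mp <- trainDrugModel(pr$panel, f = 140, seed = 7)  # f capped at lines
    expect_equal(latentDim(mp), 40L)
    expect_true(all(is.finite(lossTrace(mp))))
    expect_equal(mp@responseScale, "prism")
})

test_that("degenerate latent structure reduces to drug means", {
    sim <- simulateDrugPanel(nLines = 25, nDrugs = 6, fTrue = 0,
                             noiseSd = 0, seed = 8)
    expect_equal(sim$panel$response,
                 matrix(rep(sim$truth$biases, each = 25), 25, 6,
                        dimnames = dimnames(sim$panel$response)),
                 tolerance = 1e-12)
    m <- trainDrugModel(sim$panel, f = 1, seed = 8)
    pred <- predictResponse(m, sim$panel$expression)
    expect_equal(unname(pred[1, ]), unname(sim$truth$biases),
                 tolerance = 1e-3)
})
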