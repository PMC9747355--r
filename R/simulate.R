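#' Simulate clustered single-cell counts
#'
#' Negative-binomial counts with k planted cell clusters. Baseline gene
#' means are log-normal; each cluster up-regulates its own disjoint marker
#' set by \code{markerEffect}; per-cell library sizes vary log-normally.
#' The defaults (dispersion 0.5, 4x marker shift, ~5000 counts/cell) give
#' clearly separated but noisy populations that a standard clustering chain
#' should recover essentially perfectly.
#'
#' @param nCells,nGenes matrix dimensions.
#' @param kClusters number of planted clusters (cells split evenly).
#' @param nMarkersPerCluster markers up-regulated per cluster (disjoint
#'   sets).
#' @param depth expected total counts per cell.
#' @param markerEffect multiplicative mean shift on marker genes.
#' @param dispersion negative-binomial dispersion (NB size = 1/dispersion).
#' @param librarySd sd of the log-normal library-size factor.
#' @param seed RNG seed.
#' @return list with \code{sce} (a \code{SingleCellExperiment}) and
#'   \code{truth} (labels, markers, parameters)
#' @export
simulateCounts <- function(nCells = 750, nGenes = 2000, kClusters = 5,
                           nMarkersPerCluster = 50, depth = 5000,
                           markerEffect = 4, dispersion = 0.5,
                           librarySd = 0.3, seed = 0) {
    if (kClusters < 1) stop("kClusters must be >= 1")
    if (kClusters * nMarkersPerCluster > nGenes)
        stop("marker sets exceed the number of genes")
    set.seed(.deriveSeed(seed, 0))
    labels <- rep(seq_len(kClusters) - 1L, length.out = nCells)
    labels <- sample(labels)
    baseMean <- stats::rlnorm(nGenes, meanlog = 0, sdlog = 1)
    markers <- if (nMarkersPerCluster > 0)
        split(seq_len(kClusters * nMarkersPerCluster),
              rep(seq_len(kClusters), each = nMarkersPerCluster))
    else rep(list(integer(0)), kClusters)
    names(markers) <- seq_len(kClusters) - 1L
    libSize <- stats::rlnorm(nCells, meanlog = 0, sdlog = librarySd)
    mu <- matrix(baseMean, nGenes, nCells)
    for (k in seq_len(kClusters)) {
        cells <- which(labels == k - 1L)
        mu[markers[[k]], cells] <- mu[markers[[k]], cells] * markerEffect
    }
    mu <- sweep(mu, 2L, depth * libSize / colSums(mu), "*")
    counts <- matrix(stats::rnbinom(nGenes * nCells, mu = mu,
                                    size = 1 / dispersion),
                     nGenes, nCells)
    rownames(counts) <- sprintf("GENE%04d", seq_len(nGenes))
    colnames(counts) <- sprintf("CELL%04d", seq_len(nCells))
    markerNames <- lapply(markers, function(i) rownames(counts)[i])
    sce <- asCountsExperiment(counts)
    truth <- list(generator = "simulateCounts", seed = seed,
                  labels = stats::setNames(labels, colnames(counts)),
                  markers = markerNames,
                  params = list(nCells = nCells, nGenes = nGenes,
                                kClusters = kClusters,
                                nMarkersPerCluster = nMarkersPerCluster,
                                depth = depth, markerEffect = markerEffect,
                                dispersion = dispersion,
                                librarySd = librarySd))
    list(sce = sce, truth = truth)
}

#' Simulate a drug-screen training panel
#'
#' A generative twin of the latent-factor response model. Cell lines get
#' low-rank expression (latent line factors times gene loadings plus gene
#' noise); sample latents are a planted linear projection of the panel's
#' own kernel features, exactly the functional form the model fits; and
#' responses are \eqn{s_{iu} = b_i + q_i \cdot p_u + \varepsilon} with
#' noise scaled relative to the sd of the noiseless responses.
#'
#' @param nLines,nDrugs,nGenes panel dimensions.
#' @param fTrue latent dimension of the generative model (0 = responses are
#'   pure drug biases).
#' @param noiseSd sd of the response noise as a fraction of the noiseless
#'   response sd.
#' @param exprNoiseSd sd of the per-gene expression noise.
#' @param seed RNG seed.
#' @return list with \code{panel} (expression, response, responseScale) and
#'   \code{truth} (latent factors, drug factors, biases)
#' @export
simulateDrugPanel <- function(nLines = 60, nDrugs = 25, nGenes = 300,
                              fTrue = 4, noiseSd = 0.1, exprNoiseSd = 0.1,
                              seed = 0) {
    if (fTrue > min(nLines, nDrugs))
        stop("fTrue must not exceed min(nLines, nDrugs)")
    set.seed(.deriveSeed(seed, 0))
    r <- max(fTrue, 1L)
    Z <- matrix(stats::rnorm(nLines * r), nLines, r)
    G <- matrix(stats::rnorm(r * nGenes), r, nGenes)
    expr <- 8 + Z %*% G / sqrt(r) +
        matrix(stats::rnorm(nLines * nGenes, 0, exprNoiseSd), nLines, nGenes)
    b <- stats::rnorm(nDrugs, 0, 1)
    fc <- sweep(expr, 2L, colMeans(expr))
    kern <- stats::cor(t(fc), t(fc))
    if (fTrue > 0) {
        Qt <- matrix(stats::rnorm(nDrugs * fTrue), nDrugs, fTrue)
        Wt <- matrix(stats::rnorm(nLines * fTrue), nLines, fTrue)
        P <- kern %*% Wt
        P <- scale(P)  # unit-variance latents keep the signal scale fixed
        clean <- P %*% t(Qt) + rep(b, each = nLines)
    } else {
        Qt <- matrix(0, nDrugs, 0)
        Wt <- matrix(0, nLines, 0)
        P <- matrix(0, nLines, 0)
        clean <- matrix(rep(b, each = nLines), nLines, nDrugs)
    }
    eps <- matrix(stats::rnorm(nLines * nDrugs, 0,
                               noiseSd * stats::sd(clean)),
                  nLines, nDrugs)
    resp <- clean + eps
    dimnames(expr) <- list(sprintf("LINE%03d", seq_len(nLines)),
                           sprintf("GENE%04d", seq_len(nGenes)))
    dimnames(resp) <- list(rownames(expr),
                           sprintf("DRUG%03d", seq_len(nDrugs)))
    list(panel = list(expression = expr, response = resp,
                      responseScale = "gdsc"),
         truth = list(generator = "simulateDrugPanel", seed = seed,
                      latent = P, drugFactors = Qt, projection = Wt,
                      biases = b,
                      cleanResponse = clean,
                      params = list(nLines = nLines, nDrugs = nDrugs,
                                    nGenes = nGenes, fTrue = fTrue,
                                    noiseSd = noiseSd,
                                    exprNoiseSd = exprNoiseSd)))
}

#' Simulate a perturbation screen with planted kill patterns
#'
#' Treated subpopulation proportions are the base proportions with the
#' planted per-dose reductions applied to the targeted subpopulations,
#' renormalized; bulk GEPs are the signature-weighted mixtures plus
#' Gaussian noise. Controls sit at the base proportions.
#'
#' @param signature genes x subpopulations matrix (anti-log scale).
#' @param baseProportions subpopulation proportions summing to 1.
#' @param killPatterns named list: compound -> list(targets = subpopulation
#'   names, reductions = one reduction in [0,1] per dose).
#' @param doses concentrations shared by all compounds.
#' @param unit concentration unit label.
#' @param nControls number of control experiments.
#' @param noiseSd sd of GEP noise as a fraction of the mean signal.
#' @param seed RNG seed.
#' @return list with \code{screen} (a \code{PerturbationScreen}) and
#'   \code{truth} (planted proportions and kill sets)
#' @export
simulatePerturbationScreen <- function(signature, baseProportions,
                                       killPatterns, doses = c(1, 10),
                                       unit = "uM", nControls = 2,
                                       noiseSd = 0, seed = 0) {
    stopifnot(abs(sum(baseProportions) - 1) < 1e-8)
    if (length(baseProportions) != ncol(signature))
        stop("one base proportion per subpopulation required")
    for (kp in killPatterns) {
        if (any(kp$reductions > 1)) stop("reductions must not exceed 1")
        if (length(kp$reductions) != length(doses))
            stop("one reduction per dose required")
    }
    set.seed(.deriveSeed(seed, 0))
    subpops <- colnames(signature)
    names(baseProportions) <- subpops
    meta <- list(); geps <- list(); trueProps <- list()
    for (i in seq_len(nControls)) {
        id <- sprintf("CTRL%02d", i)
        meta[[id]] <- data.frame(experiment_id = id, compound = "control",
                                 concentration = 0, unit = unit,
                                 is_control = TRUE)
        trueProps[[id]] <- baseProportions
    }
    for (cmp in names(killPatterns)) {
        kp <- killPatterns[[cmp]]
        for (di in seq_along(doses)) {
            id <- sprintf("%s_d%02d", cmp, di)
            p <- baseProportions
            p[kp$targets] <- p[kp$targets] * (1 - kp$reductions[di])
            p <- p / sum(p)
            meta[[id]] <- data.frame(experiment_id = id, compound = cmp,
                                     concentration = doses[di], unit = unit,
                                     is_control = FALSE)
            trueProps[[id]] <- p
        }
    }
    meta <- do.call(rbind, meta)
    props <- do.call(cbind, trueProps)
    gep <- signature %*% props
    if (noiseSd > 0)
        gep <- pmax(gep + matrix(stats::rnorm(length(gep), 0,
                                              noiseSd * mean(gep)),
                                 nrow(gep)), 0)
    colnames(gep) <- meta$experiment_id
    killSets <- lapply(killPatterns, function(kp)
        kp$targets[rep(TRUE, length(kp$targets))])
    list(screen = PerturbationScreen(gep, meta, "synthetic"),
         truth = list(generator = "simulatePerturbationScreen", seed = seed,
                      proportions = t(props), killPatterns = killPatterns,
                      baseProportions = baseProportions,
                      params = list(doses = doses, noiseSd = noiseSd,
                                    nControls = nControls)))
}

#' Simulate a bulk survival cohort tied to cluster signatures
#'
#' Each patient gets an independent latent activity level per cluster;
#' a cluster's signature genes track its latent level plus noise. Survival
#' times are exponential with hazard
#' \eqn{h_p = h_0 \cdot \mathrm{HR}^{z_p}} in the effect cluster's latent
#' \eqn{z_p} (constant hazard when no effect cluster is given). Censoring
#' is independent exponential, calibrated so roughly \code{censorRate} of
#' patients are censored at HR = 1.
#'
#' @param nPatients cohort size.
#' @param signatures named list cluster -> signature genes.
#' @param effectCluster cluster whose activity drives hazard (NULL = null
#'   cohort).
#' @param hazardRatio per-unit-latent hazard multiplier.
#' @param censorRate target censoring fraction.
#' @param exprNoiseSd sd of expression noise around the latent level.
#' @param baseHazard baseline event rate.
#' @param seed RNG seed.
#' @return list with \code{cohort} (expression, time, event) and
#'   \code{truth} (latents, parameters)
#' @export
simulateSurvivalCohort <- function(nPatients = 200, signatures,
                                   effectCluster = NULL, hazardRatio = 1,
                                   censorRate = 0.2, exprNoiseSd = 0.6,
                                   baseHazard = 0.1, seed = 0) {
    if (hazardRatio <= 0) stop("hazardRatio must be positive")
    set.seed(.deriveSeed(seed, 0))
    clusters <- names(signatures)
    genes <- unique(unlist(signatures))
    Z <- matrix(stats::rnorm(nPatients * length(clusters)), nPatients,
                length(clusters), dimnames = list(NULL, clusters))
    expr <- matrix(stats::rnorm(nPatients * length(genes), 0, exprNoiseSd),
                   nPatients, length(genes),
                   dimnames = list(sprintf("PT%03d", seq_len(nPatients)),
                                   genes))
    for (cl in clusters)
        expr[, signatures[[cl]]] <- expr[, signatures[[cl]]] + Z[, cl]
    z <- if (is.null(effectCluster)) rep(0, nPatients)
         else Z[, as.character(effectCluster)]
    hazard <- baseHazard * hazardRatio^z
    tEvent <- stats::rexp(nPatients, rate = hazard)
    if (censorRate > 0) {
        cRate <- baseHazard * censorRate / (1 - censorRate)
        tCens <- stats::rexp(nPatients, rate = cRate)
    } else tCens <- rep(Inf, nPatients)
    time <- pmin(tEvent, tCens)
    event <- as.integer(tEvent <= tCens)
    rownames(Z) <- rownames(expr)
    list(cohort = list(expression = expr, time = time, event = event),
         truth = list(generator = "simulateSurvivalCohort", seed = seed,
                      latents = Z, effectCluster = effectCluster,
                      params = list(nPatients = nPatients,
                                    hazardRatio = hazardRatio,
                                    censorRate = censorRate,
                                    exprNoiseSd = exprNoiseSd,
                                    baseHazard = baseHazard)))
}
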