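#' Default reference cell-line panel names
#'
#' Cell lines commonly profiled at scale in public perturbation screens,
#' used as the default candidate set when assigning a reference line.
#' @export
referenceLineNames <- c("A375", "A549", "HCC515", "HEPG2", "HT29", "MCF7",
                        "PC3", "YAPC")

#' Assign the best-matching reference cell line
#'
#' Correlates the pooled single-cell GEP against each candidate bulk
#' profile (Pearson, shared genes) and returns the best match. Ties go to
#' the first panel column in its stored order.
#'
#' @param scGEP named numeric vector: pooled mean expression over all cells.
#' @param referenceGEPs genes x lines matrix of bulk profiles.
#' @return list with \code{line} and \code{correlation} (all candidates'
#'   correlations as attribute)
#' @export
assignReferenceLine <- function(scGEP, referenceGEPs) {
    shared <- intersect(names(scGEP), rownames(referenceGEPs))
    if (!length(shared)) stop("no shared genes with the reference panel")
    r <- stats::cor(scGEP[shared], referenceGEPs[shared, , drop = FALSE])[1, ]
    best <- which.max(r)
    structure(list(line = colnames(referenceGEPs)[best],
                   correlation = unname(r[best])),
              all = r)
}

#' Signature matrix from cluster profiles
#'
#' Converts cluster GEPs (log scale) to the anti-log scale and restricts to
#' the screen's gene space, yielding the non-negative genes x subpopulations
#' signature matrix used for deconvolution.
#'
#' @param gep clusters x genes matrix from \code{\link{clusterGEP}}.
#' @param screenGenes genes measured in the perturbation screen (NULL = no
#'   restriction).
#' @return genes x clusters non-negative matrix
#' @export
signatureMatrix <- function(gep, screenGenes = NULL) {
    sig <- t(expm1(gep))
    if (!is.null(screenGenes)) {
        shared <- intersect(rownames(sig), screenGenes)
        if (length(shared) < ncol(sig))
            stop("need at least as many shared genes as subpopulations")
        sig <- sig[shared, , drop = FALSE]
    }
    sig
}

#' Deconvolve bulk profiles into subpopulation proportions
#'
#' Estimates, for every experiment, the non-negative mixture weights that
#' minimize the squared error between the bulk GEP and a weighted sum of
#' subpopulation signatures, then normalizes the weights to proportions
#' summing to one.
#'
#' @param screen a \code{PerturbationScreen}.
#' @param signature genes x subpopulations matrix
#'   (\code{\link{signatureMatrix}} output).
#' @return experiments x subpopulations matrix of proportions
#' @export
deconvolve <- function(screen, signature) {
    gep <- screenGEP(screen)
    shared <- intersect(rownames(gep), rownames(signature))
    if (length(shared) < ncol(signature))
        stop("need at least as many shared genes as subpopulations")
    A <- signature[shared, , drop = FALSE]
    if (qr(A)$rank < ncol(A))
        warning("rank-deficient signature matrix; proportions may not be ",
                "unique")
    props <- t(apply(gep[shared, , drop = FALSE], 2L, function(y) {
        w <- pracma::lsqnonneg(A, y)$x
        if (sum(w) == 0) w else w / sum(w)
    }))
    dimnames(props) <- list(colnames(gep), colnames(signature))
    props
}

#' Call killed subpopulations per perturbation
#'
#' The reduction of subpopulation s under an experiment is
#' \code{1 - p_treated / p_control}, with control proportions averaged over
#' all control experiments. A subpopulation is a kill candidate when its
#' reduction exceeds \code{killThreshold}; the call is confirmed only if
#' every experiment with the same compound at a strictly higher
#' concentration (same unit) also shows a reduction of at least
#' \code{consistencyThreshold} for that subpopulation (vacuously confirmed
#' when no higher dose exists). Subpopulations absent from the controls are
#' excluded with a warning.
#'
#' @param proportions experiments x subpopulations matrix from
#'   \code{\link{deconvolve}}.
#' @param screen the \code{PerturbationScreen}.
#' @param killThreshold reduction required to call a kill.
#' @param consistencyThreshold reduction required at higher doses.
#' @return data.frame (class \code{KillTable}) with one row per treated
#'   experiment x subpopulation: experiment_id, compound, concentration,
#'   unit, subpopulation, reduction, candidate, killed
#' @export
callKilled <- function(proportions, screen, killThreshold = 0.90,
                       consistencyThreshold = 0.75) {
    meta <- screenMeta(screen)
    ctrl <- proportions[meta$is_control, , drop = FALSE]
    pCtrl <- colMeans(ctrl)
    usable <- pCtrl > 0
    if (!all(usable))
        warning("subpopulation(s) with zero control proportion excluded: ",
                paste(colnames(proportions)[!usable], collapse = ", "))
    trtIdx <- which(!meta$is_control)
    red <- sweep(proportions[trtIdx, usable, drop = FALSE], 2L,
                 pCtrl[usable], "/")
    red <- 1 - red
    subpops <- colnames(proportions)[usable]
    rows <- expand.grid(i = seq_along(trtIdx), s = seq_along(subpops),
                        KEEP.OUT.ATTRS = FALSE)
    kt <- data.frame(
        experiment_id = meta$experiment_id[trtIdx][rows$i],
        compound = meta$compound[trtIdx][rows$i],
        concentration = meta$concentration[trtIdx][rows$i],
        unit = meta$unit[trtIdx][rows$i],
        subpopulation = subpops[rows$s],
        reduction = red[cbind(rows$i, rows$s)])
    kt$candidate <- kt$reduction > killThreshold
    kt$killed <- kt$candidate
    for (r in which(kt$candidate)) {
        higher <- kt$compound == kt$compound[r] &
            kt$subpopulation == kt$subpopulation[r] &
            kt$concentration > kt$concentration[r]
        sameUnit <- kt$unit[higher] == kt$unit[r]
        if (any(higher) && !all(sameUnit)) {
            warning("compound ", kt$compound[r],
                    ": mixed concentration units; consistency check ",
                    "restricted to matching units")
            higher <- higher & kt$unit == kt$unit[r]
        }
        if (any(higher))
            kt$killed[r] <- all(kt$reduction[higher] >= consistencyThreshold)
    }
    kt <- kt[order(kt$compound, kt$concentration, kt$subpopulation), ]
    rownames(kt) <- NULL
    class(kt) <- c("KillTable", "data.frame")
    kt
}

#' Greedy search for minimal drug combinations
#'
#' Iteratively adds the perturbation that kills the largest number of
#' not-yet-killed subpopulations; ties are broken by the greater total
#' efficacy (sum of that perturbation's reductions over all
#' subpopulations), and perturbations still tied on both criteria branch
#' into separate candidate plans. Killed subpopulations are removed after
#' each step and the search stops when no perturbation kills a new one.
#'
#' @param killTable output of \code{\link{callKilled}}.
#' @param maxPlans cap on the number of branched plans returned.
#' @param tol numeric tolerance for efficacy ties.
#' @return list of plans; each plan is a list with \code{steps} (data.frame:
#'   experiment_id, compound, concentration, newly_killed, efficacy),
#'   \code{killed} (cumulative killed set) and \code{totalEfficacy}
#' @export
greedyCombination <- function(killTable, maxPlans = 50, tol = 1e-9) {
    if (!nrow(killTable)) stop("empty kill table")
    ids <- unique(killTable$experiment_id)
    killSets <- lapply(ids, function(id)
        killTable$subpopulation[killTable$experiment_id == id &
                                killTable$killed])
    efficacy <- vapply(ids, function(id)
        sum(killTable$reduction[killTable$experiment_id == id]),
        numeric(1))
    info <- killTable[match(ids, killTable$experiment_id),
                      c("experiment_id", "compound", "concentration")]
    ord <- order(info$compound, info$concentration)
    ids <- ids[ord]; killSets <- killSets[ord]
    efficacy <- efficacy[ord]; info <- info[ord, ]

    expand <- function(steps, killed) {
        newly <- lapply(killSets, setdiff, killed)
        gain <- lengths(newly)
        if (max(gain) == 0L)
            return(list(list(steps = steps, killed = killed)))
        cand <- which(gain == max(gain))
        eff <- efficacy[cand]
        cand <- cand[eff >= max(eff) - tol]
        plans <- list()
        for (j in cand) {
            st <- rbind(steps, data.frame(
                experiment_id = ids[j], compound = info$compound[j],
                concentration = info$concentration[j],
                newly_killed = I(list(newly[[j]])),
                efficacy = efficacy[j]))
            plans <- c(plans,
                       expand(st, union(killed, killSets[[j]])))
            if (length(plans) >= maxPlans) break
        }
        plans
    }
    empty <- data.frame(experiment_id = character(),
                        compound = character(), concentration = numeric(),
                        newly_killed = I(list()), efficacy = numeric())
    plans <- expand(empty, character(0))
    plans <- plans[!duplicated(lapply(plans, function(p) p$steps$experiment_id))]
    if (length(plans) > maxPlans) plans <- plans[seq_len(maxPlans)]
    if (nrow(plans[[1]]$steps) == 0) {
        message("no perturbation kills any subpopulation")
        return(list())
    }
    lapply(plans, function(p)
        list(steps = p$steps, killed = sort(p$killed),
             totalEfficacy = sum(p$steps$efficacy)))
}
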