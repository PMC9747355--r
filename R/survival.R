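#' Cluster signature genes
#'
#' Takes each cluster's top-n DEGs (by DEG rank) as its gene signature,
#' restricted to genes measured in the bulk cohort. When a top gene is
#' absent from the cohort it is back-filled from the next DEG ranks so all
#' signatures keep the same length where possible; remaining shortfalls are
#' reported with a warning. Clusters with no usable gene are dropped.
#'
#' @param degTable output of \code{\link{rankDEGs}}.
#' @param cohortGenes genes measured in the cohort (NULL = no restriction).
#' @param n signature size.
#' @return named list cluster -> character vector of signature genes
#' @export
signatureGenes <- function(degTable, cohortGenes = NULL, n = 20) {
    sigs <- list()
    for (cl in unique(degTable$cluster)) {
        sub <- degTable[degTable$cluster == cl, ]
        sub <- sub[order(sub$rank), ]
        genes <- sub$gene
        if (!is.null(cohortGenes)) genes <- genes[genes %in% cohortGenes]
        if (!length(genes)) {
            warning("cluster ", cl, ": no signature gene present in cohort; ",
                    "cluster excluded")
            next
        }
        if (length(genes) < n)
            warning("cluster ", cl, ": only ", length(genes),
                    " usable signature genes (requested ", n, ")")
        sigs[[as.character(cl)]] <- utils::head(genes, n)
    }
    if (!length(sigs)) stop("no cluster has a usable signature")
    sigs
}

#' Signature activity scores in a bulk cohort
#'
#' For each patient and cluster, counts how many of the cluster's signature
#' genes the patient expresses strictly above the gene's cohort-wide
#' median. Ties at the median score 0, so the score of a patient sitting at
#' the median for every gene is 0.
#'
#' @param cohort list with \code{expression} (patients x genes), as from
#'   \code{\link{readCohort}} or \code{\link{simulateSurvivalCohort}}.
#' @param signatures named list cluster -> genes.
#' @return patients x clusters integer matrix with the signature list as
#'   attribute \code{"signatures"}
#' @export
activityScores <- function(cohort, signatures) {
    expr <- cohort$expression
    med <- apply(expr, 2L, stats::median)
    scores <- vapply(signatures, function(genes) {
        genes <- intersect(genes, colnames(expr))
        if (!length(genes)) return(rep(0L, nrow(expr)))
        as.integer(rowSums(expr[, genes, drop = FALSE] >
                           rep(med[genes], each = nrow(expr))))
    }, integer(nrow(expr)))
    scores <- matrix(scores, nrow = nrow(expr),
                     dimnames = list(rownames(expr), names(signatures)))
    attr(scores, "signatures") <- signatures
    scores
}

#' High/low stratification by activity score
#'
#' Patients in the top quartile of a cluster's activity scores form the
#' "high" group, the bottom quartile the "low" group, and the middle half
#' is excluded. Quartiles use the linear-interpolation percentile (type 7);
#' ties at a quartile are included in the extreme group. If the two
#' quartiles coincide without all scores being equal, strict comparisons
#' are used so the groups stay disjoint.
#'
#' @param scores numeric activity scores, one per patient.
#' @return factor with levels high/low/excluded, one per patient
#' @export
stratifyPatients <- function(scores) {
    if (length(scores) < 8) stop("need at least 8 patients")
    q <- stats::quantile(scores, c(0.25, 0.75), type = 7, names = FALSE)
    if (q[1] == q[2]) {
        if (all(scores == scores[1])) stop("no separation: all scores equal")
        grp <- ifelse(scores > q[2], "high",
                      ifelse(scores < q[1], "low", "excluded"))
    } else {
        grp <- ifelse(scores >= q[2], "high",
                      ifelse(scores <= q[1], "low", "excluded"))
    }
    factor(grp, levels = c("high", "low", "excluded"))
}

#' Kaplan-Meier curves and log-rank comparison
#'
#' Product-limit survival curves per group, the two-sample log-rank
#' chi-square statistic and p-value, and a hazard ratio estimated from the
#' log-rank observed/expected table as (O_high/E_high)/(O_low/E_low).
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @param groups factor from \code{\link{stratifyPatients}} (patients
#'   labelled \code{excluded} are dropped) or any two-level grouping.
#' @return list with \code{chisq}, \code{p_value}, \code{hazard_ratio},
#'   \code{n} (group sizes), \code{obs}, \code{exp} and \code{curves}
#'   (data.frame: group, time, surv)
#' @export
kmLogrank <- function(time, event, groups) {
    keep <- groups %in% c("high", "low")
    if (!any(keep)) keep <- !is.na(groups)
    time <- time[keep]; event <- event[keep]
    g <- droplevels(factor(groups[keep]))
    if (nlevels(g) != 2L) stop("need exactly two non-empty groups")
    if (sum(event) == 0) stop("no events observed")
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    lv <- levels(g)
    hiIdx <- if ("high" %in% lv) match("high", lv) else 1L
    loIdx <- if ("high" %in% lv) match("low", lv) else 2L
    rate <- function(i) {
        if (sd$exp[i] == 0) return(NA_real_)
        sd$obs[i] / sd$exp[i]
    }
    hr <- rate(hiIdx) / rate(loIdx)
    fit <- survival::survfit(survival::Surv(time, event) ~ g)
    strata <- rep(names(fit$strata), fit$strata)
    curves <- data.frame(group = sub("^g=", "", strata),
                         time = fit$time, surv = fit$surv)
    list(chisq = unname(sd$chisq), p_value = unname(p),
         hazard_ratio = unname(hr),
         n = stats::setNames(as.vector(table(g)), lv),
         obs = stats::setNames(sd$obs, lv), exp = stats::setNames(sd$exp, lv),
         curves = curves)
}

#' Per-cluster survival impact of signature activity
#'
#' Stratifies the cohort by each cluster's activity score and compares the
#' high and low groups by log-rank test.
#'
#' @param cohort list with \code{expression}, \code{time}, \code{event}.
#' @param activity patients x clusters matrix from
#'   \code{\link{activityScores}}.
#' @param adjust apply Benjamini-Hochberg across clusters (off by default;
#'   raw log-rank p-values are reported).
#' @return data.frame: cluster, p_value, adj_p_value (if requested),
#'   hazard_ratio, n_high, n_low
#' @export
clusterSurvival <- function(cohort, activity, adjust = FALSE) {
    rows <- lapply(colnames(activity), function(cl) {
        res <- tryCatch({
            grp <- stratifyPatients(activity[, cl])
            km <- kmLogrank(cohort$time, cohort$event, grp)
            data.frame(cluster = cl, p_value = km$p_value,
                       hazard_ratio = km$hazard_ratio,
                       n_high = unname(km$n["high"]),
                       n_low = unname(km$n["low"]))
        }, error = function(e) {
            warning("cluster ", cl, ": ", conditionMessage(e))
            NULL
        })
        res
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) stop("no cluster could be stratified")
    if (adjust) out$adj_p_value <- .bh(out$p_value)
    rownames(out) <- NULL
    out
}
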