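#' @import methods
#' @importFrom stats cor median p.adjust pchisq phyper prcomp pt quantile
#'   rbinom rexp rlnorm rnbinom rnorm runif sd var aggregate setNames
#' @importFrom utils head read.delim write.table
NULL

#' Latent-factor drug-response model
#'
#' A recommender-style bilinear model that places drugs and samples in a
#' shared f-dimensional latent space. Samples enter as kernel features: a
#' vector of Pearson correlations between the sample's expression
#' fold-change profile and the fold-change profile of each training cell
#' line. The prediction for drug \eqn{i} and sample \eqn{u} is
#' \deqn{\hat{s}_{iu} = b_i + q_i \cdot (x_u W)}
#' where \eqn{x_u} is the kernel feature vector, \eqn{W} projects it onto
#' the latent space, \eqn{q_i} is the drug's latent vector and \eqn{b_i} a
#' per-drug bias. The overall mean of the training responses is retained as
#' a diagnostic but deliberately excluded from prediction, as are per-sample
#' biases, so that the model transfers to samples unseen at training time.
#'
#' @slot W numeric matrix, training-lines x f projection of kernel features.
#' @slot Q numeric matrix, drugs x f latent drug factors.
#' @slot b numeric vector of per-drug biases.
#' @slot mu numeric(1), overall mean of observed training responses
#'   (diagnostic only; not used in prediction).
#' @slot f integer(1), latent dimension.
#' @slot lambda numeric(1), L2 regularization weight.
#' @slot featureGenes character, genes used to build fold-change profiles.
#' @slot trainFC numeric matrix, training-lines x featureGenes fold-change
#'   profiles the kernel is computed against.
#' @slot fcReference numeric, per-gene mean expression across training lines
#'   used as the fold-change reference.
#' @slot responseScale character(1), "gdsc" (-log IC50) or "prism"
#'   (scaled 1-AUC).
#' @slot lossTrace numeric, objective value at each accepted epoch.
#' @slot config list of training settings (learning rate, epochs, seed).
#' @export
setClass("DrugResponseModel",
    representation(
        W = "matrix", Q = "matrix", b = "numeric", mu = "numeric",
        f = "integer", lambda = "numeric",
        featureGenes = "character", trainFC = "matrix",
        fcReference = "numeric", responseScale = "character",
        lossTrace = "numeric", config = "list"
    )
)

setValidity("DrugResponseModel", function(object) {
    msg <- character()
    if (object@f < 1L) msg <- c(msg, "latent dimension f must be >= 1")
    if (ncol(object@W) != object@f || ncol(object@Q) != object@f)
        msg <- c(msg, "W and Q must have f columns")
    if (nrow(object@Q) != length(object@b))
        msg <- c(msg, "one bias per drug required")
    if (!all(is.finite(object@W)) || !all(is.finite(object@Q)) ||
        !all(is.finite(object@b)))
        msg <- c(msg, "model parameters must be finite")
    if (!object@responseScale %in% c("gdsc", "prism"))
        msg <- c(msg, "responseScale must be 'gdsc' or 'prism'")
    if (length(msg)) msg else TRUE
})

#' @describeIn DrugResponseModel compact description of a fitted model
#' @param object a \code{DrugResponseModel}
#' @export
setMethod("show", "DrugResponseModel", function(object) {
    cat("DrugResponseModel (", object@responseScale, " scale)\n", sep = "")
    cat("  drugs: ", nrow(object@Q), ", training lines: ", nrow(object@W),
        ", latent dim f = ", object@f, "\n", sep = "")
    cat("  lambda = ", object@lambda, ", feature genes = ",
        length(object@featureGenes), "\n", sep = "")
    cat("  final loss = ", signif(utils::tail(object@lossTrace, 1), 6),
        " after ", length(object@lossTrace), " epochs\n", sep = "")
})

#' @rdname DrugResponseModel
#' @aliases drugNames
#' @export
setGeneric("drugNames", function(object) standardGeneric("drugNames"))

#' @describeIn DrugResponseModel drug identifiers of the model
#' @export
setMethod("drugNames", "DrugResponseModel", function(object) rownames(object@Q))

#' @rdname DrugResponseModel
#' @aliases latentDim
#' @export
setGeneric("latentDim", function(object) standardGeneric("latentDim"))

#' @describeIn DrugResponseModel latent dimension f
#' @export
setMethod("latentDim", "DrugResponseModel", function(object) object@f)

#' @rdname DrugResponseModel
#' @aliases lossTrace
#' @export
setGeneric("lossTrace", function(object) standardGeneric("lossTrace"))

#' @describeIn DrugResponseModel per-epoch objective values
#' @export
setMethod("lossTrace", "DrugResponseModel", function(object) object@lossTrace)

#' Perturbation screen container
#'
#' Bulk gene-expression profiles of drug-perturbation experiments on one
#' reference cell line, with per-experiment compound, concentration and
#' control annotations. Profiles are kept on anti-log (linear) scale so they
#' can be modelled as non-negative mixtures of subpopulation signatures.
#'
#' @slot gep numeric matrix, genes x experiments, non-negative.
#' @slot meta data.frame with one row per experiment and columns
#'   \code{experiment_id}, \code{compound}, \code{concentration},
#'   \code{unit}, \code{is_control}.
#' @slot referenceLine character(1), name of the profiled cell line.
#' @export
setClass("PerturbationScreen",
    representation(gep = "matrix", meta = "data.frame",
                   referenceLine = "character")
)

setValidity("PerturbationScreen", function(object) {
    msg <- character()
    need <- c("experiment_id", "compound", "concentration", "unit",
              "is_control")
    if (!all(need %in% names(object@meta)))
        msg <- c(msg, paste("meta must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (ncol(object@gep) != nrow(object@meta))
            msg <- c(msg, "one meta row per GEP column required")
        if (!any(object@meta$is_control))
            msg <- c(msg, "at least one control experiment required")
        trt <- !object@meta$is_control
        if (any(trt) && any(object@meta$concentration[trt] <= 0))
            msg <- c(msg, "treated concentrations must be positive")
        if (anyDuplicated(object@meta$experiment_id))
            msg <- c(msg, "experiment ids must be unique")
    }
    if (any(object@gep < 0)) msg <- c(msg, "GEPs must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Construct a PerturbationScreen
#'
#' @param gep genes x experiments non-negative matrix (anti-log scale);
#'   column names must match \code{meta$experiment_id}.
#' @param meta data.frame of experiment annotations (see class docs).
#' @param referenceLine name of the reference cell line.
#' @return a \code{PerturbationScreen}
#' @export
PerturbationScreen <- function(gep, meta, referenceLine = NA_character_) {
    gep <- as.matrix(gep)
    meta$is_control <- as.logical(meta$is_control)
    if (!is.null(colnames(gep)))
        meta <- meta[match(colnames(gep), meta$experiment_id), , drop = FALSE]
    else colnames(gep) <- meta$experiment_id
    new("PerturbationScreen", gep = gep, meta = meta,
        referenceLine = as.character(referenceLine))
}

#' @describeIn PerturbationScreen compact summary
#' @param object a \code{PerturbationScreen}
#' @export
setMethod("show", "PerturbationScreen", function(object) {
    cat("PerturbationScreen on", object@referenceLine, "\n")
    cat(" ", nrow(object@gep), "genes x", ncol(object@gep), "experiments (",
        sum(object@meta$is_control), "controls,",
        length(unique(object@meta$compound[!object@meta$is_control])),
        "compounds )\n")
})

#' @rdname PerturbationScreen
#' @aliases screenGEP
#' @export
setGeneric("screenGEP", function(object) standardGeneric("screenGEP"))

#' @describeIn PerturbationScreen genes x experiments profile matrix
#' @export
setMethod("screenGEP", "PerturbationScreen", function(object) object@gep)

#' @rdname PerturbationScreen
#' @aliases screenMeta
#' @export
setGeneric("screenMeta", function(object) standardGeneric("screenMeta"))

#' @describeIn PerturbationScreen experiment annotation table
#' @export
setMethod("screenMeta", "PerturbationScreen", function(object) object@meta)
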