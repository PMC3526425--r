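#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' LigapDataset: a multi-condition expression time course
#'
#' An extension of \linkS4class{SummarizedExperiment} holding one assay
#' (\code{"exprs"}) of log2-scale expression values (genes x samples) and a
#' sample annotation (\code{colData}) with the columns \code{condition}
#' (character label), \code{time} (non-negative hours) and \code{replicate}
#' (positive integer). Missing observations are encoded as \code{NA} in the
#' assay.
#'
#' @slot .placeholder unused; all state lives in the SummarizedExperiment.
#' @seealso [LigapDataset()], [readLongTable()], [readWideMatrix()],
#'   [validateDataset()]
#' @exportClass LigapDataset
setClass("LigapDataset", contains = "SummarizedExperiment")

setValidity("LigapDataset", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    cd <- colData(object)
    need <- c("condition", "time", "replicate")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (!length(msg)) {
        if (!is.numeric(cd$time) || any(cd$time < 0))
            msg <- c(msg, "time must be numeric and non-negative (hours)")
        rep <- cd$replicate
        if (!is.numeric(rep) || any(rep != round(rep)) || any(rep < 1))
            msg <- c(msg, "replicate must be a positive integer")
        key <- paste(cd$condition, cd$time, rep, sep = "\r")
        if (anyDuplicated(key))
            msg <- c(msg, paste0("duplicated (condition, time, replicate): ",
                                 paste(unique(gsub("\r", ",", key[duplicated(key)])),
                                       collapse = "; ")))
        if (length(unique(cd$condition)) < 2L)
            msg <- c(msg, "at least 2 conditions are required")
        tcount <- vapply(split(cd$time, cd$condition),
                         function(t) length(unique(t)), integer(1))
        if (any(tcount < 2L))
            msg <- c(msg, paste0("each condition needs >= 2 distinct time ",
                                 "points; violated by: ",
                                 paste(names(tcount)[tcount < 2L],
                                       collapse = ", ")))
        if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
            msg <- c(msg, "sample ids (colnames) must be present and unique")
        if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
            msg <- c(msg, "gene ids (rownames) must be present and unique")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a LigapDataset
#'
#' @param exprs numeric matrix of log2 expression, genes in rows, samples in
#'   columns; \code{NA} marks missing observations.
#' @param condition character vector of condition labels, one per column.
#' @param time numeric vector of measurement times in hours, one per column.
#' @param replicate integer vector of replicate indices, one per column.
#' @param sample_id optional sample identifiers; defaults to
#'   \code{colnames(exprs)} or \code{condition_time_replicate}.
#' @return a validated [LigapDataset-class] object.
#' @examples
#' m <- matrix(rnorm(12), 2, 6,
#'             dimnames = list(c("g1", "g2"), NULL))
#' ds <- LigapDataset(m, condition = rep(c("A", "B"), each = 3),
#'                    time = rep(c(0, 12, 24), 2),
#'                    replicate = rep(1L, 6))
#' conditions(ds)
#' @export
LigapDataset <- function(exprs, condition, time, replicate,
                         sample_id = NULL) {
    exprs <- as.matrix(exprs)
    storage.mode(exprs) <- "double"
    if (is.null(sample_id)) {
        sample_id <- colnames(exprs)
        if (is.null(sample_id))
            sample_id <- paste(condition, time, replicate, sep = "_")
    }
    colnames(exprs) <- sample_id
    cd <- DataFrame(condition = as.character(condition),
                    time = as.numeric(time),
                    replicate = as.integer(replicate),
                    row.names = sample_id)
    se <- SummarizedExperiment(assays = list(exprs = exprs), colData = cd)
    new("LigapDataset", se)
}

#' @describeIn LigapDataset condition labels in order of first appearance.
#' @param object,x a \code{LigapDataset}.
#' @export
setGeneric("conditions", function(object, ...) standardGeneric("conditions"))

#' @rdname LigapDataset
#' @param ... unused.
#' @export
setMethod("conditions", "LigapDataset", function(object, ...) {
    unique(as.character(colData(object)$condition))
})

#' @describeIn LigapDataset measurement times (hours) per sample.
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))

#' @rdname LigapDataset
#' @export
setMethod("sampleTimes", "LigapDataset", function(object) {
    as.numeric(colData(object)$time)
})

setMethod("show", "LigapDataset", function(object) {
    cd <- colData(object)
    cat("LigapDataset:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("conditions:", paste(conditions(object), collapse = ", "), "\n")
    cat("time points (h):",
        paste(sort(unique(cd$time)), collapse = ", "), "\n")
    nmiss <- sum(is.na(assay(object, "exprs")))
    if (nmiss) cat("missing observations:", nmiss, "\n")
    invisible(NULL)
})

#' GPFit: one Gaussian-process regression fit
#'
#' Holds the data block, optimized hyperparameters (on the natural scale) and
#' the optimized log marginal likelihood of a single GP regression with the
#' non-stationary neural-network covariance. Targets are stored mean-centered;
#' \code{center} is added back by [posteriorPredict()].
#'
#' @slot times numeric, raw observation times in hours.
#' @slot y numeric, centered targets (same length as \code{times}).
#' @slot center numeric(1), the subtracted mean of the raw targets.
#' @slot tmax numeric(1), the time-scaling constant (times are divided by
#'   \code{tmax} before bias augmentation).
#' @slot hyper named numeric: \code{l_bias}, \code{l_time} (lengthscales),
#'   \code{sigma} (signal variance), \code{noise} (noise variance).
#' @slot logMarginal numeric(1), the maximal optimized log marginal likelihood.
#' @slot restartLogMarginals numeric, one optimized value per restart.
#' @exportClass GPFit
setClass("GPFit",
    representation(times = "numeric", y = "numeric", center = "numeric",
                   tmax = "numeric", hyper = "numeric",
                   logMarginal = "numeric", restartLogMarginals = "numeric"))

setValidity("GPFit", function(object) {
    msg <- character()
    if (length(object@times) != length(object@y))
        msg <- c(msg, "times and y must have equal length")
    if (length(object@restartLogMarginals) &&
        abs(object@logMarginal - max(object@restartLogMarginals)) > 1e-9)
        msg <- c(msg, "logMarginal must equal the best restart")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GPFit", function(object) {
    cat("GPFit:", length(object@y), "observations, log marginal likelihood",
        format(object@logMarginal, digits = 6), "\n")
    h <- object@hyper
    cat(sprintf("  l_bias=%.4g l_time=%.4g sigma=%.4g noise=%.4g\n",
                h[["l_bias"]], h[["l_time"]], h[["sigma"]], h[["noise"]]))
    invisible(NULL)
})

#' LigapResults: per-gene partition posteriors and scores
#'
#' Container returned by [runLigap()]. Matrices are genes x partitions or
#' genes x conditions; row order matches the analyzed dataset.
#'
#' @slot conditions character, condition labels in canonical order.
#' @slot partitions list of partitions; each is a list of character blocks.
#' @slot partitionLabels character, human-readable partition labels
#'   (blocks joined by \code{"|"}, members by \code{"+"}).
#' @slot logMarginals genes x partitions matrix of per-hypothesis log
#'   marginal likelihoods (NA for unanalyzable genes).
#' @slot posteriors genes x partitions matrix of posterior probabilities.
#' @slot scores genes x conditions matrix of differential-regulation scores.
#' @slot allDifferentScore numeric, posterior of the all-singletons partition.
#' @slot foldChangePass genes x conditions logical matrix.
#' @slot calls list of character vectors (called conditions, possibly
#'   \code{"all_different"}).
#' @slot analyzable logical, one flag per gene.
#' @slot settings the [ligapSettings()] list used for the run.
#' @exportClass LigapResults
setClass("LigapResults",
    representation(conditions = "character", partitions = "list",
                   partitionLabels = "character", logMarginals = "matrix",
                   posteriors = "matrix", scores = "matrix",
                   allDifferentScore = "numeric", foldChangePass = "matrix",
                   calls = "list", analyzable = "logical",
                   settings = "list"))

setValidity("LigapResults", function(object) {
    msg <- character()
    ng <- nrow(object@posteriors)
    if (ncol(object@posteriors) != length(object@partitions))
        msg <- c(msg, "posteriors must have one column per partition")
    ok <- object@analyzable
    if (length(ok) != ng) msg <- c(msg, "analyzable flag per gene required")
    if (ng && any(ok)) {
        s <- rowSums(object@posteriors[ok, , drop = FALSE])
        if (any(abs(s - 1) > 1e-10))
            msg <- c(msg, "posteriors of analyzable genes must sum to 1")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "LigapResults", function(object) {
    ng <- nrow(object@posteriors)
    cat("LigapResults:", ng, "genes,", length(object@partitions),
        "partitions of", length(object@conditions), "conditions\n")
    cat("partitions:", paste(object@partitionLabels, collapse = "  "), "\n")
    ncalled <- sum(lengths(object@calls) > 0)
    cat("genes with at least one call:", ncalled, "\n")
    invisible(NULL)
})

#' @describeIn LigapResults genes x partitions posterior probability matrix.
#' @param object,x a \code{LigapResults}.
#' @export
setGeneric("posteriors", function(object) standardGeneric("posteriors"))

#' @rdname LigapResults
#' @export
setMethod("posteriors", "LigapResults", function(object) object@posteriors)

#' @describeIn LigapResults genes x conditions differential-regulation scores.
#' @export
setGeneric("conditionScores",
           function(object) standardGeneric("conditionScores"))

#' @rdname LigapResults
#' @export
setMethod("conditionScores", "LigapResults",
          function(object) object@scores)

#' @describeIn LigapResults posterior of the all-singletons partition,
#'   per gene.
#' @export
setGeneric("allDifferentScores",
           function(object) standardGeneric("allDifferentScores"))

#' @rdname LigapResults
#' @export
setMethod("allDifferentScores", "LigapResults",
          function(object) object@allDifferentScore)

#' @describeIn LigapResults list of called condition labels per gene.
#' @export
setGeneric("ligapCalls", function(object) standardGeneric("ligapCalls"))

#' @rdname LigapResults
#' @export
setMethod("ligapCalls", "LigapResults", function(object) object@calls)

#' BindingPredictions: precomputed TF-binding p-values over a gene universe
#'
#' Wraps a table of (tf, gene, p_value) records together with the background
#' gene universe over which binding was scored. Binding predictions are
#' consumed, not computed, by this package.
#'
#' @slot records data.frame with columns \code{tf}, \code{gene},
#'   \code{p_value}.
#' @slot background character, the scored gene universe.
#' @seealso [readBindingPredictions()], [callTargets()], [enrichAll()]
#' @exportClass BindingPredictions
setClass("BindingPredictions",
    representation(records = "data.frame", background = "character"))

setValidity("BindingPredictions", function(object) {
    msg <- character()
    r <- object@records
    if (!all(c("tf", "gene", "p_value") %in% colnames(r)))
        msg <- c(msg, "records need columns tf, gene, p_value")
    else {
        if (any(r$p_value < 0 | r$p_value > 1, na.rm = TRUE))
            msg <- c(msg, "p_value must lie in [0, 1]")
        bad <- setdiff(unique(r$gene), object@background)
        if (length(bad))
            msg <- c(msg, paste0("record gene(s) absent from background: ",
                                 paste(utils::head(bad, 5), collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a BindingPredictions object
#'
#' @param records data.frame with columns \code{tf}, \code{gene},
#'   \code{p_value} (binding p-values in \code{[0,1]}).
#' @param background character vector of the scored gene universe; defaults
#'   to the genes present in \code{records}.
#' @return a [BindingPredictions-class] object.
#' @export
BindingPredictions <- function(records, background = NULL) {
    records <- as.data.frame(records)
    if (is.null(background)) background <- unique(records$gene)
    new("BindingPredictions", records = records,
        background = as.character(background))
}

setMethod("show", "BindingPredictions", function(object) {
    cat("BindingPredictions:", nrow(object@records), "records,",
        length(unique(object@records$tf)), "TFs,",
        length(object@background), "background genes\n")
    invisible(NULL)
})
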