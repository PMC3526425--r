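## The analysis engine: for every gene and every partition of the
## conditions, fit one GP prior (a single shared hyperparameter set) to the
## partition's blocks -- blocks are independent given the hyperparameters
## (block-diagonal covariance) -- and use the summed block log marginal
## likelihoods at the shared type-II ML optimum as the hypothesis evidence.
## Bayes' theorem converts evidences to posterior probabilities, which are
## summarized into per-condition differential-regulation scores. Sharing one
## hyperparameter set within a hypothesis keeps model complexity equal
## across hypotheses; all blocks of a gene share the gene-wide mean as the
## centering constant so every hypothesis sees the same (shifted) data.
## Sub-seeds derive from (gene, hypothesis, restart), so results are
## identical regardless of processing order.

#' Settings for a run
#'
#' @param nRestarts optimizer restarts per GP fit (default 10).
#' @param probCutoff posterior-probability threshold for calling a gene
#'   differentially regulated (default 0.9, the strong-evidence grade).
#' @param foldChangeLog2 minimum fitted-profile separation, in log2 units,
#'   between a called condition and every other condition at some time point
#'   (default 1.0, i.e. two-fold).
#' @param requireFoldChange apply the fold-change filter to condition calls
#'   (default \code{TRUE}).
#' @param priors per-partition prior probabilities (simplex); default uniform.
#' @param seed integer run seed; all randomness derives from it.
#' @return a validated settings list.
#' @export
ligapSettings <- function(nRestarts = 10, probCutoff = 0.9,
                          foldChangeLog2 = 1.0, requireFoldChange = TRUE,
                          priors = NULL, seed = 1) {
    stopifnot(nRestarts >= 1, probCutoff > 0, probCutoff < 1,
              foldChangeLog2 >= 0)
    if (!is.null(priors)) {
        if (any(priors < 0) || abs(sum(priors) - 1) > 1e-8)
            stop("priors must be non-negative and sum to 1")
    }
    list(nRestarts = as.integer(nRestarts), probCutoff = probCutoff,
         foldChangeLog2 = foldChangeLog2,
         requireFoldChange = isTRUE(requireFoldChange),
         priors = priors, seed = as.integer(seed))
}

## Stable integer id of a block within a condition ordering (bitmask), and
## the hypothesis-level sub-seed built from the sorted block ids (independent
## of gene processing order and of block order within the partition).
blockId <- function(block, conditions) {
    sum(2^(match(block, conditions) - 1))
}

hypothesisSeed <- function(settings, geneIndex, partition, conditions) {
    ids <- sort(vapply(partition, blockId, numeric(1),
                       conditions = conditions))
    deriveSeed(settings$seed, geneIndex, ids)
}

## Joint fit of one hypothesis for one gene; returns the fitJointGP() list
## with fits named by block.
fitHypothesis <- function(geneData, partition, tmax, settings, geneIndex) {
    conditions <- names(geneData)
    blockTimes <- lapply(partition, function(b)
        unlist(lapply(geneData[b], `[[`, "time"), use.names = FALSE))
    blockY <- lapply(partition, function(b)
        unlist(lapply(geneData[b], `[[`, "value"), use.names = FALSE))
    gm <- mean(unlist(lapply(geneData, `[[`, "value"), use.names = FALSE))
    jf <- fitJointGP(blockTimes, blockY, nRestarts = settings$nRestarts,
                     seed = hypothesisSeed(settings, geneIndex, partition,
                                           conditions),
                     tmax = tmax, centerValue = gm)
    names(jf$fits) <- vapply(partition, paste, character(1), collapse = "+")
    jf
}

#' Log marginal likelihood of one partition hypothesis for one gene
#'
#' The evidence of a partition is the product over its blocks of the block
#' marginal likelihoods; each block pools the observations of its
#' conditions. One shared hyperparameter set per hypothesis is optimized by
#' type-II maximum likelihood to maximize the summed block log marginal
#' likelihoods (blocks are independent GPs given the hyperparameters), and
#' all blocks are centered by the gene-wide mean, so evidences are
#' comparable across hypotheses.
#'
#' @param geneData named list, one element per condition, each a list with
#'   numeric \code{time} and \code{value} (missing values already dropped).
#' @param partition one partition from [enumeratePartitions()].
#' @param settings a [ligapSettings()] list.
#' @param tmax time-scaling constant (default: max time in \code{geneData}).
#' @param geneIndex integer used in sub-seed derivation (default 1).
#' @return the summed block log marginal likelihoods at the shared optimum.
#' @export
hypothesisLogMarginal <- function(geneData, partition, settings = ligapSettings(),
                                  tmax = NULL, geneIndex = 1L) {
    if (is.null(tmax))
        tmax <- max(unlist(lapply(geneData, `[[`, "time")))
    fitHypothesis(geneData, partition, tmax, settings, geneIndex)$logMarginal
}

#' Posterior probabilities of the partition hypotheses
#'
#' Bayes' theorem on per-partition log marginal likelihoods, computed with
#' max-shifted exponentiation (log-sum-exp) for numerical safety:
#' \code{P(H_j | D) = P(D | H_j) P(H_j) / sum_k P(D | H_k) P(H_k)}.
#'
#' @param logMarginals numeric, one log marginal likelihood per partition.
#' @param priors prior simplex over partitions; default uniform.
#' @return a probability vector summing to 1.
#' @export
posteriorProbabilities <- function(logMarginals, priors = NULL) {
    if (any(!is.finite(logMarginals)))
        stop("non-finite log marginal likelihood")
    k <- length(logMarginals)
    if (is.null(priors)) priors <- rep(1 / k, k)
    stopifnot(length(priors) == k, all(priors >= 0),
              abs(sum(priors) - 1) < 1e-8)
    lp <- logMarginals + log(priors)
    w <- exp(lp - max(lp))
    w / sum(w)
}

#' Differential-regulation score of one condition
#'
#' The posterior probability that the condition's temporal profile differs
#' from every other condition's: the summed posterior of all partitions in
#' which the condition is a singleton block (for three conditions A, B, C the
#' score of C is \code{P(H_2 | D) + P(H_5 | D)} in the canonical numbering).
#'
#' @param posteriors probability vector, one entry per partition.
#' @param partitions the matching list from [enumeratePartitions()].
#' @param condition a condition label.
#' @return a scalar in \code{[0, 1]}.
#' @export
conditionScore <- function(posteriors, partitions, condition) {
    stopifnot(length(posteriors) == length(partitions))
    sel <- singletonPartitions(partitions, condition)
    idx <- vapply(sel, attr, integer(1), which = "index")
    if (!length(idx)) return(0)
    sum(posteriors[idx])
}

#' Fold-change filter on fitted profiles
#'
#' A condition passes when there exists a time point on the evaluation grid
#' at which its posterior-mean profile differs from the profiles of all
#' other conditions simultaneously by at least \code{thresholdLog2}
#' (\code{>=} at the boundary).
#'
#' @param fits named list of per-condition [GPFit-class] objects.
#' @param times numeric evaluation grid (typically the union of observed
#'   time points).
#' @param thresholdLog2 minimum absolute log2 difference (default 1 =
#'   two-fold).
#' @return named logical vector, one flag per condition.
#' @export
foldChangeFilter <- function(fits, times, thresholdLog2 = 1.0) {
    stopifnot(length(fits) >= 1, length(times) >= 1)
    mu <- vapply(fits, function(f) posteriorPredict(f, times)$mean,
                 numeric(length(times)))
    mu <- matrix(mu, nrow = length(times),
                 dimnames = list(NULL, names(fits)))
    out <- vapply(colnames(mu), function(cc) {
        others <- setdiff(colnames(mu), cc)
        if (!length(others)) return(TRUE)
        d <- abs(mu[, others, drop = FALSE] - mu[, cc])
        any(apply(d >= thresholdLog2, 1, all))
    }, logical(1))
    names(out) <- colnames(mu)
    out
}

## Direction of regulation of a condition relative to the others, from fitted
## profiles: sign of the largest-magnitude difference that clears the filter
## grid. Used by downstream up/down stratification.
foldChangeDirection <- function(fits, times) {
    mu <- vapply(fits, function(f) posteriorPredict(f, times)$mean,
                 numeric(length(times)))
    mu <- matrix(mu, nrow = length(times),
                 dimnames = list(NULL, names(fits)))
    vapply(colnames(mu), function(cc) {
        others <- setdiff(colnames(mu), cc)
        if (!length(others)) return(0)
        d <- mu[, cc] - rowMeans(mu[, others, drop = FALSE])
        sign(d[which.max(abs(d))])
    }, numeric(1))
}

## Split one gene's row into per-condition (time, value) lists, dropping NAs.
splitGeneData <- function(values, cd, conditions) {
    out <- lapply(conditions, function(cc) {
        sel <- cd$condition == cc & !is.na(values)
        list(time = as.numeric(cd$time[sel]), value = as.numeric(values[sel]))
    })
    names(out) <- conditions
    out
}

#' Run the full partition-comparison analysis
#'
#' For each gene: fits one GP per unique block over all partitions of the
#' conditions, converts per-partition evidences into posterior probabilities,
#' derives per-condition scores and the all-different score, applies the
#' fold-change filter on fitted profiles, and calls conditions whose score
#' exceeds \code{probCutoff} (and pass the filter, when required). Genes with
#' fewer than 2 non-missing observations in any condition are flagged
#' unanalyzable and excluded from calls.
#'
#' @param ds a [LigapDataset-class].
#' @param settings a [ligapSettings()] list.
#' @param verbose print per-gene progress (default \code{FALSE}).
#' @return a [LigapResults-class] object.
#' @export
runLigap <- function(ds, settings = ligapSettings(), verbose = FALSE) {
    stopifnot(is(ds, "LigapDataset"))
    vr <- validateDataset(ds)
    if (length(vr$errors))
        stop("invalid dataset: ", paste(vr$errors, collapse = "; "))
    conds <- conditions(ds)
    parts <- enumeratePartitions(conds)
    labels <- vapply(parts, partitionLabel, character(1))
    npart <- length(parts)
    priors <- settings$priors
    if (!is.null(priors) && length(priors) != npart)
        stop("priors must have one entry per partition (", npart, ")")
    cd <- as.data.frame(colData(ds))
    X <- assay(ds, "exprs")
    genes <- rownames(ds)
    tmax <- max(cd$time)
    grid <- sort(unique(cd$time))
        lm <- matrix(NA_real_, nrow(X), npart, dimnames = list(genes, labels))
    post <- lm
    scores <- matrix(NA_real_, nrow(X), length(conds),
                     dimnames = list(genes, conds))
    fcpass <- matrix(NA, nrow(X), length(conds),
                     dimnames = list(genes, conds))
    fcdir <- scores
    alldiff <- rep(NA_real_, nrow(X))
    calls <- vector("list", nrow(X))
    analyzable <- !genes %in% vr$unanalyzable$gene

    for (i in seq_len(nrow(X))) {
        if (!analyzable[i]) { calls[[i]] <- character(0); next }
        gd <- splitGeneData(X[i, ], cd, conds)
        singles <- NULL
        for (j in seq_len(npart)) {
            jf <- fitHypothesis(gd, parts[[j]], tmax, settings, i)
            lm[i, j] <- jf$logMarginal
            if (j == npart) singles <- jf$fits   # all-singletons blocks are
        }                                        # the per-condition fits
        names(singles) <- conds
        post[i, ] <- posteriorProbabilities(lm[i, ], priors)
        scores[i, ] <- vapply(conds, function(cc)
            conditionScore(post[i, ], parts, cc), numeric(1))
        alldiff[i] <- post[i, npart]   # all-singletons is last in order
        fcpass[i, ] <- foldChangeFilter(singles, grid,
                                        settings$foldChangeLog2)
        fcdir[i, ] <- foldChangeDirection(singles, grid)
        called <- conds[scores[i, ] > settings$probCutoff &
                        (!settings$requireFoldChange | fcpass[i, ])]
        if (alldiff[i] > settings$probCutoff)
            called <- c(called, "all_different")
        calls[[i]] <- called
        if (verbose)
            message("gene ", genes[i], ": ",
                    if (length(called)) paste(called, collapse = ",")
                    else "no call")
    }
    if (!any(analyzable)) stop("no analyzable genes in the dataset")
    res <- new("LigapResults", conditions = conds, partitions = parts,
               partitionLabels = labels, logMarginals = lm,
               posteriors = post, scores = scores,
               allDifferentScore = alldiff, foldChangePass = fcpass,
               calls = calls, analyzable = analyzable, settings = settings)
    attr(res@scores, "direction") <- fcdir
    res
}

#' Refit the per-condition GPs of one gene
#'
#' Convenience accessor for plotting and clustering: returns the per-block
#' fits of the all-singletons hypothesis (one GP per condition, sharing one
#' hyperparameter set), using the same seeding scheme as [runLigap()], so the
#' fits agree with those used in a run with identical settings.
#'
#' @param ds a [LigapDataset-class].
#' @param gene a gene identifier (rowname of \code{ds}).
#' @param settings a [ligapSettings()] list.
#' @return named list of [GPFit-class], one per condition.
#' @export
fitConditionGPs <- function(ds, gene, settings = ligapSettings()) {
    stopifnot(is(ds, "LigapDataset"))
    i <- match(gene, rownames(ds))
    if (is.na(i)) stop("unknown gene: ", gene)
    cd <- as.data.frame(colData(ds))
    conds <- conditions(ds)
    gd <- splitGeneData(assay(ds, "exprs")[i, ], cd, conds)
    parts <- enumeratePartitions(conds)
    jf <- fitHypothesis(gd, parts[[length(parts)]], max(cd$time),
                        settings, i)
    fits <- jf$fits
    names(fits) <- conds
    fits
}
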