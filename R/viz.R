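## Figure surface. Every plotting function also writes the numbers behind the
## figure to a companion TSV next to the image, so rendered quantities are
## testable without parsing images.

#' @importFrom ggplot2 ggplot aes geom_line geom_ribbon geom_point labs
#'   theme_bw scale_fill_manual scale_colour_manual ggsave
NULL

companionPath <- function(out) paste0(tools::file_path_sans_ext(out), ".tsv")

#' Plot per-condition expression profiles of one gene with 95% bands
#'
#' Draws, per condition, the GP posterior-mean curve on a dense grid with a
#' shaded 95 percent credible band (mean +/- 1.96 posterior standard
#' deviations of the latent function) and the raw observations as points.
#' The plotted numbers are written to \code{<out>.tsv}.
#'
#' @param gene gene identifier (for the title).
#' @param fits named list of per-condition [GPFit-class] (see
#'   [fitConditionGPs()]).
#' @param grid_size number of evaluation points (default 100).
#' @param out output figure path (extension selects the device, e.g.
#'   \code{.png} or \code{.pdf}).
#' @return invisibly, the plot-data data.frame (columns condition, time,
#'   mean, lower, upper).
#' @export
plotProfiles <- function(gene, fits, grid_size = 100, out) {
    stopifnot(length(fits) >= 1, grid_size >= 2)
    tmin <- min(vapply(fits, function(f) min(f@times), numeric(1)))
    tmax <- max(vapply(fits, function(f) max(f@times), numeric(1)))
    grid <- seq(tmin, tmax, length.out = grid_size)
    pd <- do.call(rbind, lapply(names(fits), function(cc) {
        pp <- posteriorPredict(fits[[cc]], grid)
        data.frame(condition = cc, time = pp$time, mean = pp$mean,
                   lower = pp$mean - 1.96 * sqrt(pp$variance),
                   upper = pp$mean + 1.96 * sqrt(pp$variance),
                   stringsAsFactors = FALSE)
    }))
    obs <- do.call(rbind, lapply(names(fits), function(cc) {
        f <- fits[[cc]]
        data.frame(condition = cc, time = f@times, value = f@y + f@center,
                   stringsAsFactors = FALSE)
    }))
    g <- ggplot(pd, aes(x = time, y = mean,
                        colour = condition, fill = condition)) +
        geom_ribbon(aes(ymin = lower, ymax = upper),
                    alpha = 0.2, colour = NA) +
        geom_line(linewidth = 0.8) +
        geom_point(data = obs, aes(y = value), size = 1.6) +
        labs(title = gene, x = "time (h)", y = "log2 expression") +
        theme_bw()
    ggsave(out, g, width = 6, height = 4)
    utils::write.table(pd, companionPath(out), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(pd)
}

#' Build the gene x score matrix for PCA
#'
#' Features are the per-condition differential-regulation scores followed by
#' the all-different score (four features for three conditions); only
#' analyzable genes are kept.
#'
#' @param results a [LigapResults-class].
#' @return a numeric matrix, genes x (conditions + 1).
#' @export
scoreMatrix <- function(results) {
    stopifnot(is(results, "LigapResults"))
    m <- cbind(results@scores, all_different = results@allDifferentScore)
    m[results@analyzable, , drop = FALSE]
}

#' PCA of differential-regulation score vectors
#'
#' Projects the per-gene score vectors onto their first two principal
#' components (column-centered, unscaled: all features already live on
#' \code{[0, 1]}). Loadings are sign-fixed so the largest-magnitude entry of
#' each loading is positive, making coordinates reproducible bit-for-bit.
#'
#' @param scores numeric matrix from [scoreMatrix()] (>= 3 genes).
#' @return a list with \code{coordinates} (genes x 2), \code{loadings}
#'   (features x 2) and \code{explained} (variance fraction per component,
#'   all components).
#' @export
pcaScores <- function(scores) {
    scores <- as.matrix(scores)
    if (nrow(scores) < 3) stop("PCA needs at least 3 genes")
    pc <- stats::prcomp(scores, center = TRUE, scale. = FALSE)
    k <- min(2, ncol(pc$rotation))
    rot <- pc$rotation[, seq_len(k), drop = FALSE]
    flip <- vapply(seq_len(k), function(j) {
        v <- rot[, j]
        if (v[which.max(abs(v))] < 0) -1 else 1
    }, numeric(1))
    rot <- sweep(rot, 2, flip, `*`)
    coords <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
    ev <- pc$sdev^2
    list(coordinates = coords, loadings = rot, explained = ev / sum(ev))
}

#' Clustered heat map of standardized fitted profiles
#'
#' Each selected gene's feature vector is the concatenation of its
#' per-condition GP posterior-mean profiles on the shared grid of observed
#' time points, standardized per gene to mean 0 / sd 1 across all time points
#' and conditions. Genes are clustered by complete-linkage hierarchical
#' clustering on Euclidean distances and the tree is cut into \code{k}
#' clusters. The heat map is written to \code{out}; the standardized matrix
#' and assignments go to companion TSVs.
#'
#' @param ds a [LigapDataset-class].
#' @param genes character subset of rownames to cluster.
#' @param k number of clusters (\code{<=} number of genes).
#' @param out figure path (written via pheatmap) or \code{NULL} to skip the
#'   figure.
#' @param settings a [ligapSettings()] list (controls the GP fits).
#' @return a list with \code{assignments} (named integer vector),
#'   \code{hclust} (the tree) and \code{matrix} (standardized features).
#' @export
clusterHeatmap <- function(ds, genes, k, out = NULL,
                           settings = ligapSettings()) {
    stopifnot(is(ds, "LigapDataset"), length(genes) >= 1)
    if (k > length(genes)) stop("k exceeds the number of genes")
    grid <- sort(unique(sampleTimes(ds)))
    conds <- conditions(ds)
    feat <- t(vapply(genes, function(g) {
        fits <- fitConditionGPs(ds, g, settings)
        unlist(lapply(conds, function(cc)
            posteriorPredict(fits[[cc]], grid)$mean), use.names = FALSE)
    }, numeric(length(grid) * length(conds))))
    colnames(feat) <- paste(rep(conds, each = length(grid)),
                            rep(grid, length(conds)), sep = "_")
    rownames(feat) <- genes
    mu <- rowMeans(feat)
    sd <- apply(feat, 1, stats::sd)
    sd[sd == 0] <- 1
    z <- (feat - mu) / sd
    hc <- stats::hclust(stats::dist(z, method = "euclidean"),
                        method = "complete")
    assignments <- stats::cutree(hc, k = k)
    if (!is.null(out)) {
        lim <- max(abs(z))
        pheatmap::pheatmap(
            z[hc$order, , drop = FALSE], cluster_rows = FALSE,
            cluster_cols = FALSE,
            breaks = seq(-lim, lim, length.out = 101),
            filename = out, silent = TRUE)
        utils::write.table(
            data.frame(gene = names(assignments), cluster = assignments),
            companionPath(out), sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(assignments = assignments, hclust = hc, matrix = z)
}
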