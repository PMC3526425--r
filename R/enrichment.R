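## TF-binding-site enrichment. Targets of a TF are the genes whose binding
## p-value falls strictly below the binding cutoff (default 0.01); the
## over-representation of targets in a query gene set relative to the scored
## background is tested with a one-sided Fisher's exact test, which for a
## 2x2 table is the hypergeometric upper tail.

#' Predicted targets of one transcription factor
#'
#' @param bp a [BindingPredictions-class].
#' @param tf a TF identifier present in the records.
#' @param p_cutoff binding p-value cutoff; strictly-less-than comparison
#'   (default 0.01).
#' @return character vector of target genes (possibly empty).
#' @export
callTargets <- function(bp, tf, p_cutoff = 0.01) {
    stopifnot(is(bp, "BindingPredictions"))
    r <- bp@records
    if (!tf %in% r$tf) stop("unknown TF: ", tf)
    unique(r$gene[r$tf == tf & r$p_value < p_cutoff])
}

#' One-sided Fisher's exact test for gene-set over-representation
#'
#' Builds the 2x2 table (target and query, target only, query only, neither)
#' over the background and returns the probability of observing at least the
#' attained overlap under random draws from the background (hypergeometric
#' upper tail).
#'
#' @param targets,query,background character gene sets; \code{targets} and
#'   \code{query} must be subsets of \code{background}.
#' @return a list with \code{a}, \code{b}, \code{c}, \code{d} (the table),
#'   \code{p_value} and \code{overlap} (the intersection).
#' @export
fisherEnrichment <- function(targets, query, background) {
    background <- unique(background)
    targets <- unique(targets); query <- unique(query)
    if (length(background) < 2) stop("background must have >= 2 genes")
    off <- c(setdiff(targets, background), setdiff(query, background))
    if (length(off))
        stop("gene(s) outside the background: ",
             paste(utils::head(off, 10), collapse = ", "))
    a <- length(intersect(targets, query))
    b <- length(targets) - a
    cc <- length(query) - a
    d <- length(background) - a - b - cc
    ## P(X >= a), X ~ Hypergeom(#targets, #non-targets, #query)
    p <- stats::phyper(a - 1, a + b, cc + d, a + cc, lower.tail = FALSE)
    list(a = a, b = b, c = cc, d = d,
         p_value = min(max(p, .Machine$double.xmin), 1),
         overlap = sort(intersect(targets, query)))
}

#' Enrichment of every TF in every query gene set
#'
#' Targets are called per TF at \code{binding_cutoff} (optionally after
#' pooling motifs into families via \code{aliases}); each (TF, set) pair is
#' tested with [fisherEnrichment()] and raw p-values are
#' Benjamini-Hochberg-adjusted within the run. Empty query sets yield
#' \code{p = 1} with a warning.
#'
#' @param bp a [BindingPredictions-class].
#' @param gene_sets named list of character gene sets (e.g. up/down per
#'   condition); all genes must lie in the background.
#' @param binding_cutoff binding p-value cutoff for target calling
#'   (default 0.01, strict \code{<}).
#' @param report_cutoff rows with raw \code{p < report_cutoff} are flagged
#'   \code{significant} (default 0.01).
#' @param aliases optional data.frame with columns \code{motif},
#'   \code{family}: motifs sharing a family have their targets pooled and are
#'   reported under the family name.
#' @return a data.frame with columns tf, set, a, b, c, d, p_value,
#'   adjusted_p, significant.
#' @export
enrichAll <- function(bp, gene_sets, binding_cutoff = 0.01,
                      report_cutoff = 0.01, aliases = NULL) {
    stopifnot(is(bp, "BindingPredictions"), length(gene_sets) >= 1)
    if (is.null(names(gene_sets)) || any(names(gene_sets) == ""))
        stop("gene_sets must be a named list")
    bg <- bp@background
    tfs <- unique(bp@records$tf)
    targetSets <- lapply(tfs, function(tf) callTargets(bp, tf, binding_cutoff))
    names(targetSets) <- tfs
    if (!is.null(aliases)) {
        requireColumns(aliases, c("motif", "family"), "alias map")
        fam <- aliases$family[match(tfs, aliases$motif)]
        fam[is.na(fam)] <- tfs[is.na(fam)]
        targetSets <- lapply(split(tfs, fam), function(members)
            unique(unlist(targetSets[members], use.names = FALSE)))
    }
    rows <- list()
    for (tf in names(targetSets)) {
        for (set in names(gene_sets)) {
            q <- unique(gene_sets[[set]])
            if (!length(q)) {
                warning("empty query set '", set, "'")
                rows[[length(rows) + 1]] <- data.frame(
                    tf = tf, set = set, a = 0L, b = length(targetSets[[tf]]),
                    c = 0L, d = length(bg) - length(targetSets[[tf]]),
                    p_value = 1, stringsAsFactors = FALSE)
                next
            }
            fe <- fisherEnrichment(targetSets[[tf]], q, bg)
            rows[[length(rows) + 1]] <- data.frame(
                tf = tf, set = set, a = fe$a, b = fe$b, c = fe$c, d = fe$d,
                p_value = fe$p_value, stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_value < report_cutoff
    out[order(out$p_value), , drop = FALSE]
}

#' Overlap between predicted and experimentally observed target sets
#'
#' Reports the intersection of two gene sets over a common background with a
#' one-sided hypergeometric over-representation p-value (the probability of
#' at least the observed overlap if the predicted set were drawn at random
#' from the background).
#'
#' @param predicted,observed,background character gene sets; both sets must
#'   lie in the background.
#' @return a list with \code{overlap} (character) and \code{p_value}.
#' @export
overlapReport <- function(predicted, observed, background) {
    fe <- fisherEnrichment(predicted, observed, background)
    list(overlap = fe$overlap, p_value = fe$p_value)
}

#' Up/down-stratified gene sets from a results object
#'
#' For each condition, splits the called genes by the direction of their
#' fitted-profile deviation from the other conditions, yielding sets named
#' \code{<condition>_up} and \code{<condition>_down} (plus
#' \code{all_different} when called).
#'
#' @param results a [LigapResults-class] from [runLigap()].
#' @return a named list of character gene sets (empty sets dropped).
#' @export
callGeneSets <- function(results) {
    stopifnot(is(results, "LigapResults"))
    genes <- rownames(results@posteriors)
    dir <- attr(results@scores, "direction")
    sets <- list()
    for (cc in results@conditions) {
        called <- vapply(results@calls, function(x) cc %in% x, logical(1))
        if (!any(called)) next
        up <- called & !is.na(dir[, cc]) & dir[, cc] > 0
        dn <- called & !is.na(dir[, cc]) & dir[, cc] < 0
        if (any(up)) sets[[paste0(cc, "_up")]] <- genes[up]
        if (any(dn)) sets[[paste0(cc, "_down")]] <- genes[dn]
    }
    ad <- vapply(results@calls, function(x) "all_different" %in% x,
                 logical(1))
    if (any(ad)) sets[["all_different"]] <- genes[ad]
    sets
}
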