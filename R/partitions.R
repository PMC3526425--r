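## The hypothesis space: all set partitions of the condition labels.
## Conditions in one block share a latent trajectory; the number of
## partitions of N labels is the Bell number B_N (B_1 = 1, B_2 = 2, B_3 = 5,
## B_4 = 15, ...). Partitions are enumerated through restricted-growth
## strings and ordered canonically by (number of blocks ascending, then
## lexicographic growth string), which for three conditions (A, B, C) yields
## the familiar sequence: all-together; C alone; B alone; A alone;
## all-singletons.

#' Bell number
#'
#' The number of set partitions of \code{n} labels, computed exactly with the
#' Bell triangle recurrence.
#'
#' @param n positive integer.
#' @return the Bell number \code{B_n} as a numeric (exact for \code{n <= 22}).
#' @examples
#' bellNumber(3)  # 5
#' bellNumber(4)  # 15
#' @export
bellNumber <- function(n) {
    if (length(n) != 1 || !is.finite(n) || n < 1 || n != round(n))
        stop("n must be a positive integer")
    row <- 1
    for (i in seq_len(n - 1)) {
        nxt <- numeric(i + 1)
        nxt[1] <- row[i]
        for (j in seq_len(i)) nxt[j + 1] <- nxt[j] + row[j]
        row <- nxt
    }
    row[length(row)]
}

## All restricted-growth strings of length n (first element 0; each element
## at most 1 + running maximum), in lexicographic order.
growthStrings <- function(n) {
    out <- list()
    rec <- function(prefix, mx) {
        if (length(prefix) == n) {
            out[[length(out) + 1]] <<- prefix
            return(invisible(NULL))
        }
        for (v in 0:(mx + 1)) rec(c(prefix, v), max(mx, v))
    }
    rec(0L, 0L)
    out
}

#' Enumerate all set partitions of the condition labels
#'
#' @param conditions character vector of distinct condition labels (order
#'   fixes the canonical partition numbering).
#' @param warn_above integer; emit a warning when the hypothesis space gets
#'   large (default 5 conditions), since a run costs one GP fit per block per
#'   gene. Hard cap at 8 conditions.
#' @return an ordered list of partitions; each partition is a list of
#'   character vectors (the blocks) with attributes \code{index} (canonical
#'   position) and \code{label} (see [partitionLabel()]).
#' @examples
#' p <- enumeratePartitions(c("Th0", "Th1", "Th2"))
#' length(p)             # 5
#' partitionLabel(p[[2]])  # "Th0+Th1|Th2"
#' @export
enumeratePartitions <- function(conditions, warn_above = 5) {
    conditions <- as.character(conditions)
    if (length(conditions) < 1) stop("at least one condition label required")
    if (anyDuplicated(conditions)) stop("condition labels must be distinct")
    n <- length(conditions)
    if (n > 8)
        stop("more than 8 conditions: the hypothesis space (Bell number) is ",
             "impractically large")
    if (n > warn_above)
        warning("enumerating ", bellNumber(n), " partitions of ", n,
                " conditions; runs will be slow")
    gs <- growthStrings(n)
    nblocks <- vapply(gs, max, integer(1)) + 1L
    ord <- order(nblocks, vapply(gs, paste, character(1), collapse = ","))
    gs <- gs[ord]
    lapply(seq_along(gs), function(i) {
        g <- gs[[i]]
        blocks <- lapply(sort(unique(g)), function(b) conditions[g == b])
        attr(blocks, "index") <- i
        attr(blocks, "label") <- paste(
            vapply(blocks, paste, character(1), collapse = "+"),
            collapse = "|")
        blocks
    })
}

#' Human-readable partition label
#'
#' Blocks are joined with \code{"|"}, members within a block with \code{"+"}
#' (for example \code{"Th0+Th1|Th2"}).
#'
#' @param partition one element of [enumeratePartitions()].
#' @return a character scalar.
#' @export
partitionLabel <- function(partition) {
    lbl <- attr(partition, "label")
    if (!is.null(lbl)) return(lbl)
    paste(vapply(partition, paste, character(1), collapse = "+"),
          collapse = "|")
}

#' Partitions in which a condition is a singleton block
#'
#' These are the partitions that model the named condition as behaving
#' distinctly from every other condition; their summed posterior is the
#' condition's differential-regulation score.
#'
#' @param partitions the list from [enumeratePartitions()].
#' @param condition a condition label present in every partition.
#' @return the subset of \code{partitions} where \code{list(condition)} is a
#'   block by itself.
#' @export
singletonPartitions <- function(partitions, condition) {
    labels <- unique(unlist(partitions[[1]]))
    if (!condition %in% labels)
        stop("unknown condition: ", condition)
    if (length(labels) == 1) return(list())
    keep <- vapply(partitions, function(p)
        any(vapply(p, function(b) length(b) == 1 && b == condition,
                   logical(1))), logical(1))
    partitions[keep]
}
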