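## Reading and writing: long-format tables, wide matrix + design, binding
## predictions and results tables. All formats are delimited text (tab by
## default); missing observations are "NA" (case-insensitive) or an empty
## field on read, written back as "NA".

readDelim <- function(path, delimiter) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.table(path, sep = delimiter, header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      na.strings = c("NA", "na", "Na", "nA", ""),
                      quote = "\"", comment.char = "")
}

requireColumns <- function(df, cols, what) {
    miss <- setdiff(cols, colnames(df))
    if (length(miss))
        stop(what, " is missing required column(s): ",
             paste(miss, collapse = ", "))
}

checkNumericColumn <- function(raw, parsed, column) {
    bad <- which(!is.na(raw) & raw != "" & is.na(parsed))
    if (length(bad))
        stop("non-numeric '", column, "' value at data line ",
             bad[1], ": '", raw[bad[1]], "'")
}

#' Read an expression time course from a long-format table
#'
#' Expects a delimited text file with a header and columns \code{gene},
#' \code{condition}, \code{time}, \code{replicate}, \code{value} (log2
#' expression; \code{NA} or empty = missing). Each (gene, condition, time,
#' replicate) combination must occur at most once.
#'
#' @param path file path.
#' @param delimiter field delimiter (default tab).
#' @return a [LigapDataset-class].
#' @export
readLongTable <- function(path, delimiter = "\t") {
    raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             colClasses = "character", quote = "\"",
                             comment.char = "")
    requireColumns(raw, c("gene", "condition", "time", "replicate", "value"),
                   "long table")
    time <- suppressWarnings(as.numeric(raw$time))
    checkNumericColumn(raw$time, time, "time")
    isMissing <- is.na(raw$value) | raw$value == "" |
        tolower(raw$value) == "na"
    value <- suppressWarnings(as.numeric(raw$value))
    value[isMissing] <- NA_real_
    checkNumericColumn(ifelse(isMissing, NA, raw$value), value, "value")
    replicate <- suppressWarnings(as.integer(raw$replicate))
    checkNumericColumn(raw$replicate, replicate, "replicate")
    key <- paste(raw$gene, raw$condition, time, replicate, sep = ",")
    if (anyDuplicated(key))
        stop("duplicated (gene, condition, time, replicate) row(s): ",
             paste(unique(key[duplicated(key)]), collapse = "; "))
    genes <- unique(raw$gene)
    sampleKey <- paste(raw$condition, time, replicate, sep = "_")
    samples <- unique(data.frame(sample_id = sampleKey,
                                 condition = raw$condition,
                                 time = time, replicate = replicate,
                                 stringsAsFactors = FALSE))
    m <- matrix(NA_real_, length(genes), nrow(samples),
                dimnames = list(genes, samples$sample_id))
    m[cbind(match(raw$gene, genes), match(sampleKey, samples$sample_id))] <-
        value
    LigapDataset(m, condition = samples$condition, time = samples$time,
                 replicate = samples$replicate,
                 sample_id = samples$sample_id)
}

#' Read an expression time course from a wide matrix plus a design table
#'
#' The matrix file has genes in rows (first column = gene id) and sample ids
#' as the remaining column names; the design file maps each sample id to
#' columns \code{condition}, \code{time}, \code{replicate}.
#'
#' @param matrix_path path of the gene x sample matrix file.
#' @param design_path path of the design file (columns \code{sample_id},
#'   \code{condition}, \code{time}, \code{replicate}).
#' @param delimiter field delimiter (default tab).
#' @return a [LigapDataset-class], element-wise equal to the equivalent
#'   long-table read.
#' @export
readWideMatrix <- function(matrix_path, design_path, delimiter = "\t") {
    mdf <- readDelim(matrix_path, delimiter)
    if (ncol(mdf) < 2) stop("matrix file needs a gene column plus samples")
    design <- readDelim(design_path, delimiter)
    requireColumns(design, c("sample_id", "condition", "time", "replicate"),
                   "design file")
    genes <- as.character(mdf[[1]])
    m <- as.matrix(mdf[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
    absent <- setdiff(colnames(m), design$sample_id)
    if (length(absent))
        stop("sample id(s) in matrix absent from design: ",
             paste(absent, collapse = ", "))
    design <- design[match(colnames(m), design$sample_id), ]
    LigapDataset(m, condition = design$condition, time = design$time,
                 replicate = design$replicate, sample_id = design$sample_id)
}

#' Read a TF binding-prediction table
#'
#' Delimited text with columns \code{tf}, \code{gene}, \code{p_value}
#' (binding p-values in \code{[0, 1]}). The background universe defaults to
#' the genes present in the table.
#'
#' @param path file path.
#' @param delimiter field delimiter (default tab).
#' @param background optional explicit gene universe.
#' @return a [BindingPredictions-class].
#' @export
readBindingPredictions <- function(path, delimiter = "\t",
                                   background = NULL) {
    df <- readDelim(path, delimiter)
    requireColumns(df, c("tf", "gene", "p_value"), "binding predictions")
    df$p_value <- as.numeric(df$p_value)
    BindingPredictions(df, background)
}

#' Validate a dataset against the analysis requirements
#'
#' Checks the design invariants (>= 2 conditions, >= 2 distinct time points
#' per condition, unique sample keys) and flags genes that retain fewer than
#' 2 non-missing observations in some condition (unanalyzable there, not
#' fatal). Pure: never mutates its input.
#'
#' @param ds a [LigapDataset-class].
#' @return a list with \code{errors} (character), \code{warnings}
#'   (character) and \code{unanalyzable} (data.frame of gene, condition).
#' @export
validateDataset <- function(ds) {
    errors <- character()
    warnings <- character()
    cd <- as.data.frame(colData(ds))
    if (length(unique(cd$condition)) < 2)
        errors <- c(errors, "at least 2 conditions are required")
    tc <- vapply(split(cd$time, cd$condition),
                 function(t) length(unique(t)), integer(1))
    if (any(tc < 2))
        errors <- c(errors,
                    paste0("condition(s) with < 2 distinct time points: ",
                           paste(names(tc)[tc < 2], collapse = ", ")))
    X <- assay(ds, "exprs")
    conds <- unique(cd$condition)
    nObs <- vapply(conds, function(cc)
        rowSums(!is.na(X[, cd$condition == cc, drop = FALSE])),
        numeric(nrow(X)))
    nObs <- matrix(nObs, nrow = nrow(X), dimnames = list(rownames(X), conds))
    bad <- which(nObs < 2, arr.ind = TRUE)
    unanalyzable <- data.frame(
        gene = rownames(X)[bad[, 1]],
        condition = conds[bad[, 2]],
        stringsAsFactors = FALSE)
    if (nrow(unanalyzable))
        warnings <- c(warnings,
                      paste0(nrow(unanalyzable), " (gene, condition) pairs ",
                             "have < 2 non-missing observations"))
    list(errors = errors, warnings = warnings, unanalyzable = unanalyzable)
}

#' Convert results to a per-gene table
#'
#' One row per gene: per-partition posteriors, per-condition scores, the
#' all-different score, fold-change flags and the final calls
#' (semicolon-separated). Column order is stable:
#' gene, analyzable, \code{P.<partition>} ..., \code{score.<condition>} ...,
#' all_different, \code{fold2.<condition>} ..., calls.
#'
#' @param results a [LigapResults-class].
#' @return a data.frame.
#' @export
resultsTable <- function(results) {
    stopifnot(is(results, "LigapResults"))
    post <- results@posteriors
    df <- data.frame(gene = rownames(post),
                     analyzable = results@analyzable,
                     stringsAsFactors = FALSE)
    p <- as.data.frame(post)
    colnames(p) <- paste0("P.", results@partitionLabels)
    s <- as.data.frame(results@scores)
    colnames(s) <- paste0("score.", results@conditions)
    f <- as.data.frame(results@foldChangePass)
    colnames(f) <- paste0("fold2.", results@conditions)
    cbind(df, p, s,
          data.frame(all_different = results@allDifferentScore), f,
          data.frame(calls = vapply(results@calls, paste, character(1),
                                    collapse = ";")))
}

#' Write results to a delimited text file
#'
#' @param results a [LigapResults-class] (non-empty).
#' @param path output file path.
#' @param delimiter field delimiter (default tab).
#' @return invisibly, the written data.frame.
#' @export
writeResults <- function(results, path, delimiter = "\t") {
    df <- resultsTable(results)
    if (!nrow(df)) stop("empty results: nothing to write")
    ok <- tryCatch({
        utils::write.table(df, path, sep = delimiter, quote = FALSE,
                           row.names = FALSE, na = "NA")
        TRUE
    }, error = function(e) stop("cannot write results to '", path, "': ",
                                conditionMessage(e)))
    invisible(df)
}

#' Write a dataset in wide-matrix + design form
#'
#' Inverse of [readWideMatrix()]: finite values are written with full
#' precision (\code{format = "%.17g"} via default numeric formatting),
#' missing as \code{NA}.
#'
#' @param ds a [LigapDataset-class].
#' @param matrix_path,design_path output paths.
#' @param delimiter field delimiter (default tab).
#' @return invisibly \code{NULL}.
#' @export
writeWideMatrix <- function(ds, matrix_path, design_path, delimiter = "\t") {
    X <- assay(ds, "exprs")
    df <- data.frame(gene = rownames(X), X, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, matrix_path, sep = delimiter, quote = FALSE,
                       row.names = FALSE, na = "NA")
    cd <- as.data.frame(colData(ds))
    design <- data.frame(sample_id = rownames(cd),
                         condition = cd$condition, time = cd$time,
                         replicate = cd$replicate)
    utils::write.table(design, design_path, sep = delimiter, quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(NULL)
}
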