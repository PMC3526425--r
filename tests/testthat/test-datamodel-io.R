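test_that("long-table reads keep counts, catch duplicates and bad fields", {
    df <- makeLongDf()
    ds <- readLongTable(writeLongFile(df))
    expect_s4_class(ds, "LigapDataset")
    expect_equal(dim(ds), c(2L, 15L))          # 2 genes, 3 x 5 x 1 samples
    expect_setequal(conditions(ds), c("Th0", "Th1", "Th2"))

    dup <- rbind(df, df[df$gene == "g1" & df$condition == "Th1" &
                        df$time == 12, ])
    expect_error(readLongTable(writeLongFile(dup)),
                 "duplicated.*g1,Th1,12,1")

    noCol <- df; noCol$replicate <- NULL
    expect_error(readLongTable(writeLongFile(noCol)),
                 "missing required column.*replicate")

    bad <- df; bad$time <- as.character(bad$time); bad$time[3] <- "noon"
    expect_error(readLongTable(writeLongFile(bad)), "non-numeric 'time'.*3")
})

test_that("the reference design shape gives 14 samples per condition", {
    sim <- simulateDataset(simulationConfig(n_genes = 2, seed = 4))
    path <- tempfile(fileext = ".tsv")
    cd <- as.data.frame(SummarizedExperiment::colData(sim$dataset))
    X <- SummarizedExperiment::assay(sim$dataset, "exprs")
    long <- do.call(rbind, lapply(rownames(X), function(g)
        data.frame(gene = g, condition = cd$condition, time = cd$time,
                   replicate = cd$replicate, value = X[g, ])))
    write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
    ds <- readLongTable(path)
    perCond <- table(SummarizedExperiment::colData(ds)$condition)
    expect_true(all(perCond == 14))            # 4 x 3 + 2 per condition
})

test_that("wide-matrix reads round-trip with the long form", {
    df <- makeLongDf()
    long <- readLongTable(writeLongFile(df))
    mp <- tempfile(fileext = ".tsv"); dp <- tempfile(fileext = ".tsv")
    writeWideMatrix(long, mp, dp)
    wide <- readWideMatrix(mp, dp)
    expect_identical(SummarizedExperiment::assay(wide, "exprs"),
                     SummarizedExperiment::assay(long, "exprs"))
    expect_identical(
        as.data.frame(SummarizedExperiment::colData(wide)),
        as.data.frame(SummarizedExperiment::colData(long)))

    # missing cell marker -> NA observation
    m <- read.table(mp, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character")
    m[1, 2] <- "NA"
    write.table(m, mp, sep = "\t", quote = FALSE, row.names = FALSE)
    wide2 <- readWideMatrix(mp, dp)
    expect_true(is.na(SummarizedExperiment::assay(wide2, "exprs")[1, 1]))

    # matrix sample absent from design -> error listing the id
    d <- read.table(dp, sep = "\t", header = TRUE)
    write.table(d[-1, ], dp, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readWideMatrix(mp, dp), "absent from design")
})

test_that("validation reports unanalyzable genes without mutating input", {
    ds <- readLongTable(writeLongFile(makeLongDf()))
    before <- SummarizedExperiment::assay(ds, "exprs")
    rep0 <- validateDataset(ds)
    expect_length(rep0$errors, 0)
    expect_equal(nrow(rep0$unanalyzable), 0)
    expect_identical(SummarizedExperiment::assay(ds, "exprs"), before)

    X <- SummarizedExperiment::assay(ds, "exprs")
    cd <- SummarizedExperiment::colData(ds)
    X["g1", cd$condition == "Th1"] <- NA
    ds2 <- LigapDataset(X, condition = cd$condition, time = cd$time,
                        replicate = cd$replicate)
    rep1 <- validateDataset(ds2)
    expect_length(rep1$errors, 0)
    expect_identical(rep1$unanalyzable,
                     data.frame(gene = "g1", condition = "Th1",
                                stringsAsFactors = FALSE))
    # a one-condition design is rejected at construction
    expect_error(LigapDataset(X[, cd$condition == "Th0"],
                              condition = rep("Th0", 5),
                              time = c(0, 12, 24, 48, 72),
                              replicate = rep(1L, 5)),
                 "at least 2 conditions")
})

test_that("results tables carry one posterior column per partition", {
    set.seed(1)
    post3 <- matrix(rexp(5 * 5), 5, 5)
    post3 <- post3 / rowSums(post3)
    res3 <- fakeResults(post3)
    tab <- resultsTable(res3)
    expect_equal(nrow(tab), 5)
    expect_equal(sum(startsWith(colnames(tab), "P.")), 5)   # B_3 = 5

    post4 <- matrix(rexp(3 * 15), 3, 15)
    post4 <- post4 / rowSums(post4)
    res4 <- fakeResults(post4, conds = c("Th0", "Th1", "Th2", "Th17"))
    tab4 <- resultsTable(res4)
    expect_equal(sum(startsWith(colnames(tab4), "P.")), 15)  # B_4 = 15

    out <- tempfile(fileext = ".tsv")
    writeResults(res3, out)
    back <- read.table(out, sep = "\t", header = TRUE, check.names = FALSE)
    expect_equal(nrow(back), 5)
    expect_error(
        suppressWarnings(writeResults(res3,
                                      file.path(tempdir(),
                                                "no/such/dir/x.tsv"))),
        "cannot write")
})
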