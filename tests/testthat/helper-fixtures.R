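# Fixtures are built in code at test time.

# A small complete long-format table: 2 genes x 3 conditions x 5 times x 1 rep.
makeLongDf <- function() {
    grid <- expand.grid(gene = c("g1", "g2"),
                        condition = c("Th0", "Th1", "Th2"),
                        time = c(0, 12, 24, 48, 72),
                        replicate = 1L, stringsAsFactors = FALSE)
    grid$value <- round(6 + as.numeric(factor(grid$gene)) +
                        0.01 * grid$time, 4)
    grid
}

writeLongFile <- function(df, path = tempfile(fileext = ".tsv")) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

# Dataset with the reference design shape: 3 conditions, times 0-48 h in
# three replicates and 72 h in two (14 samples per condition).
makeDesignDataset <- function(n_genes = 3, seed = 1) {
    sim <- simulateDataset(simulationConfig(n_genes = n_genes, seed = seed))
    sim$dataset
}

# A GPFit on constant data has an exactly flat posterior mean, handy for
# constructing profiles at known log2 levels.
flatFit <- function(level, times = c(0, 12, 24, 48, 72)) {
    fitGP(times, rep(level, length(times)), nRestarts = 1, seed = 1)
}

# Exhaustive one-sided hypergeometric tail by explicit combinatorics:
# P(overlap >= a) for draws of size nq from a background with nt targets.
hyperTailOracle <- function(a, nt, nq, nbg) {
    ks <- a:min(nt, nq)
    sum(choose(nt, ks) * choose(nbg - nt, nq - ks)) / choose(nbg, nq)
}

# A minimal valid LigapResults built by hand (3 conditions, 5 partitions).
fakeResults <- function(post, conds = c("Th0", "Th1", "Th2")) {
    parts <- enumeratePartitions(conds)
    labels <- vapply(parts, partitionLabel, character(1))
    ng <- nrow(post)
    genes <- sprintf("g%03d", seq_len(ng))
    dimnames(post) <- list(genes, labels)
    scores <- vapply(conds, function(cc)
        apply(post, 1, function(p) conditionScore(p, parts, cc)),
        numeric(ng))
    scores <- matrix(scores, nrow = ng, dimnames = list(genes, conds))
    fc <- matrix(TRUE, ng, length(conds), dimnames = list(genes, conds))
    new("LigapResults", conditions = conds, partitions = parts,
        partitionLabels = labels, logMarginals = log(post),
        posteriors = post, scores = scores,
        allDifferentScore = post[, length(parts)], foldChangePass = fc,
        calls = replicate(ng, character(0), simplify = FALSE),
        analyzable = rep(TRUE, ng), settings = ligapSettings())
}
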