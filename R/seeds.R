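## Counter-based derivation of sub-seeds. Every stochastic step (a restart of
## a block fit, a simulated gene) draws its seed from the run seed plus its
## own coordinates, so results do not depend on the order in which genes or
## hypotheses are processed. All arithmetic stays below 2^53, results below
## 2^31 - 1.

MOD31 <- 2147483647

deriveSeed <- function(seed, ...) {
    s <- as.numeric(seed) %% MOD31
    for (k in as.numeric(c(...))) {
        s <- (s * 69069 + k + 1) %% MOD31
        s <- (s * 69069 + 12345) %% MOD31
    }
    as.integer(s)
}
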