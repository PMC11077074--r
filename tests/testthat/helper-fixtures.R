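# Shared fixtures and independent oracles, built in code at test time.

fixtureGenome <- function(length = 20000L, seed = 7L) {
    buildGenome(ToyGenomeSpec("toy1", length, toyOpposingGenes(length),
                              seed = seed))
}

fixtureComplexSV <- function(length = 20000L) {
    # inversion with adjacent deletion scaled into the intergenic region
    s <- as.integer(round(length * 0.40))
    e <- as.integer(round(length * 0.55))
    d <- as.integer(round(length * 0.61))
    SVSpec("cx1", "COMPLEX_INV_DEL", rbind(c(s, e), c(e, d)),
           c("geneA", "geneB"))
}

# Independent semi-global edit-distance oracle: minimum full edit distance
# (base R adist) between the pattern and every substring of the text with a
# length achievable at distance <= k, over both strands.
oracleMinEdit <- function(query, read, k) {
    m <- nchar(query)
    best <- Inf
    for (txt in c(read, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(read))))) {
        n <- nchar(txt)
        for (w in max(1, m - k):min(n, m + k)) {
            if (w > n) next
            subs <- substring(txt, seq_len(n - w + 1L),
                              seq_len(n - w + 1L) + w - 1L)
            best <- min(best, min(utils::adist(query, subs)))
        }
    }
    best
}

randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutateBases <- function(seq, positions) {
    for (p in positions) {
        cur <- substr(seq, p, p)
        substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
    seq
}

# One simulated sample ready for signature extraction.
simulateSample <- function(genome, sv, genotype, coverage = 30,
                           seed = 1L, errorRate = 0.001) {
    alt <- applySV(genome, sv)
    cfg <- ReadSimConfig(100L, 350, 50, coverage, errorRate, seed = seed)
    simulateWgs(refHaplotype(genome), alt, genotype, cfg,
                contig = contigName(genome))
}
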