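test_that("fuzzyMatch finds exact, mismatched and reverse-complement hits", {
    set.seed(101)
    q <- randomDna(20)
    read <- paste0(randomDna(15), q, randomDna(15))
    m <- fuzzyMatch(q, c(r1 = read), 0)
    expect_equal(m$read_id, "r1")
    expect_equal(m$edit_distance, 0L)
    expect_equal(m$strand, "+")

    # two substitutions: invisible at k=1, found at k=2
    read2 <- paste0(randomDna(10), mutateBases(q, c(5, 12)), randomDna(10))
    expect_equal(nrow(fuzzyMatch(q, c(x = read2), 1)), 0L)
    m2 <- fuzzyMatch(q, c(x = read2), 2)
    expect_equal(m2$edit_distance, 2L)

    # reverse-complement containment reports the minus strand
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
    m3 <- fuzzyMatch(q, c(y = paste0("AAAA", rc, "GGGG")), 0)
    expect_equal(m3$strand, "-")
    expect_equal(m3$edit_distance, 0L)

    expect_error(fuzzyMatch("ACGTN", c(r = "ACGTACGT"), 0), "non-ACGT")
})

test_that("fuzzyMatch agrees with the exhaustive edit-distance oracle", {
    set.seed(202)
    for (i in 1:100) {
        m <- sample(12:25, 1)
        q <- randomDna(m)
        k <- sample(0:3, 1)
        type <- sample(c("random", "plant", "mutate", "revcomp"), 1)
        read <- switch(type,
            random = randomDna(sample(30:60, 1)),
            plant = paste0(randomDna(8), q, randomDna(8)),
            mutate = paste0(randomDna(8),
                            mutateBases(q, sample(m, min(m, sample(1:3, 1)))),
                            randomDna(8)),
            revcomp = paste0(randomDna(8), as.character(
                Biostrings::reverseComplement(Biostrings::DNAString(q))),
                randomDna(8)))
        got <- fuzzyMatch(q, c(r = read), k)
        want <- oracleMinEdit(q, read, k)
        if (want <= k) {
            expect_equal(nrow(got), 1L,
                         info = sprintf("i=%d q=%s read=%s k=%d", i, q, read, k))
            expect_equal(got$edit_distance, as.integer(want),
                         info = sprintf("i=%d q=%s read=%s k=%d", i, q, read, k))
        } else {
            expect_equal(nrow(got), 0L,
                         info = sprintf("i=%d q=%s read=%s k=%d", i, q, read, k))
        }
    }
})

test_that("increasing the edit budget never shrinks the candidate set", {
    set.seed(303)
    q <- randomDna(18)
    reads <- vapply(1:60, function(i) {
        if (i %% 3 == 0) paste0(randomDna(5),
                                mutateBases(q, sample(18, i %% 4)),
                                randomDna(5))
        else randomDna(40)
    }, character(1))
    names(reads) <- paste0("r", seq_along(reads))
    prev <- character()
    for (k in 0:3) {
        cur <- fuzzyMatch(q, reads, k)$read_id
        expect_true(all(prev %in% cur))
        prev <- cur
    }
})

test_that("remapClassify separates on-target, decoy and ambiguous reads", {
    set.seed(404)
    ref <- randomDna(30000)
    # plant a decoy: copy 600 bp from the locus to a distant position
    locus <- substr(ref, 10000, 10599)
    ref <- paste0(substr(ref, 1, 24999), locus, substr(ref, 25600, 30000))
    win <- c(8000, 13000)

    onTarget <- substr(ref, 9000, 9099)        # unique to the window
    decoyRead <- substr(ref, 27000, 27099)     # unique, outside the window
    ambiguous <- substr(ref, 10100, 10199)     # present at both copies
    garbage <- randomDna(100)                  # aligns nowhere

    cl <- remapClassify(c(a = onTarget, b = decoyRead, c = ambiguous,
                          d = garbage), ref, win)
    expect_equal(cl$classification,
                 c("TRUE_POSITIVE", "FALSE_POSITIVE", "UNCERTAIN", "DROPPED"))

    # reverse-complemented reads classify identically
    rc <- function(x) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(x)))
    cl2 <- remapClassify(c(a = rc(onTarget), b = rc(decoyRead),
                           c = rc(ambiguous)), ref, win)
    expect_equal(cl2$classification,
                 c("TRUE_POSITIVE", "FALSE_POSITIVE", "UNCERTAIN"))
})

test_that("callGenotype implements the boolean presence rule", {
    rule <- GenotypeRule("CTRL & JUNCTION & !DEL_INTERNAL")
    expect_equal(callGenotype(c(CTRL = 3L, JUNCTION = 2L, DEL_INTERNAL = 0L),
                              rule)$call, "POSITIVE")
    expect_equal(callGenotype(c(CTRL = 3L, JUNCTION = 0L, DEL_INTERNAL = 5L),
                              rule)$call, "NEGATIVE")
    expect_equal(callGenotype(c(CTRL = 0L, JUNCTION = 0L, DEL_INTERNAL = 0L),
                              rule)$call, "NO_CALL")
    expect_error(callGenotype(c(CTRL = 1L), rule), "unknown")
    expect_error(GenotypeRule("CTRL &&& JUNCTION"), "parse")

    # presence threshold is configurable
    rule2 <- GenotypeRule("JUNCTION", minReadsPresent = 3L)
    expect_equal(callGenotype(c(JUNCTION = 2L), rule2)$call, "NEGATIVE")
    expect_equal(callGenotype(c(JUNCTION = 3L), rule2)$call, "POSITIVE")
})

test_that("genotype calls are invariant under reverse-complementing every read", {
    g <- fixtureGenome(20000L)
    sv <- fixtureComplexSV(20000L)
    alt <- applySV(g, sv)
    q <- designBreakpointQueries(g, sv, alt)
    rule <- GenotypeRule("CTRL & JUNCTION")
    mani <- data.frame(sample_id = "s1", population = "P")
    sim <- simulateSample(g, sv, 1, coverage = 30, seed = 51L)
    reads <- setNames(sim$reads$seq,
                      paste0(sim$reads$read_id, "/", sim$reads$mate))
    rcReads <- setNames(as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads))), names(reads))
    res1 <- genotypeCohort(list(s1 = reads), mani, q, rule, refSequence(g))
    res2 <- genotypeCohort(list(s1 = rcReads), mani, q, rule, refSequence(g))
    expect_equal(res1$calls$call, "POSITIVE")
    expect_equal(res1$calls$call, res2$calls$call)
    expect_equal(res1$calls$JUNCTION, res2$calls$JUNCTION)
})

test_that("query design yields windows and junction queries with the stated invariants", {
    g <- fixtureGenome(20000L)
    sv <- fixtureComplexSV(20000L)
    alt <- applySV(g, sv)
    q <- designBreakpointQueries(g, sv, alt)
    expect_setequal(unique(q$role), c("JUNCTION", "DEL_INTERNAL", "CTRL"))
    expect_true(all(q$window_end - q$window_start > 2 * nchar(q$sequence)))
    expect_false(any(grepl("[^ACGT]", q$sequence)))
    expect_error(validateQueries(transform(q, sequence = tolower(sequence))),
                 "ACGT")
})

test_that("genotypeCohort reads FASTQ input and reports missing files as NO_CALL", {
    g <- fixtureGenome(20000L)
    sv <- fixtureComplexSV(20000L)
    alt <- applySV(g, sv)
    q <- designBreakpointQueries(g, sv, alt)
    rule <- GenotypeRule("CTRL & JUNCTION")
    sim <- simulateSample(g, sv, 2, coverage = 20, seed = 61L)
    prefix <- file.path(tempdir(), "gt_s1")
    paths <- writeFastqPair(sim, prefix)
    mani <- data.frame(sample_id = c("s1", "s2"), population = "P")
    files <- data.frame(sample_id = c("s1", "s2"),
                        fastq1 = c(paths[1], "/nonexistent_1.fastq"),
                        fastq2 = c(paths[2], "/nonexistent_2.fastq"),
                        stringsAsFactors = FALSE)
    res <- genotypeCohort(files, mani, q, rule, refSequence(g))
    expect_equal(res$calls$call[res$calls$sample_id == "s1"], "POSITIVE")
    expect_equal(res$calls$call[res$calls$sample_id == "s2"], "NO_CALL")
    expect_equal(res$calls$reason[res$calls$sample_id == "s2"],
                 "missing FASTQ")
    unlink(paths)
})

test_that("FASTQ quality filtering drops low-quality and N-rich reads", {
    fq <- file.path(tempdir(), "qf.fastq")
    writeLines(c("@good", strrep("ACGT", 25), "+", strrep("I", 100),
                 "@lowq", strrep("ACGT", 25), "+", strrep("#", 100),
                 "@enns", paste0(strrep("N", 15), strrep("A", 85)), "+",
                 strrep("I", 100)), fq)
    kept <- readFilteredFastq(fq)
    expect_equal(names(kept), "good")
    unlink(fq)
})
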