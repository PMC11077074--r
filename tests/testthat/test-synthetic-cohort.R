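test_that("buildGenome conserves length, is deterministic and validates bounds", {
    spec <- ToyGenomeSpec("toy1", 50000L, toyOpposingGenes(50000L), seed = 3L)
    g1 <- buildGenome(spec)
    g2 <- buildGenome(spec)
    expect_equal(length(refSequence(g1)), 50000L)
    expect_identical(as.character(refSequence(g1)),
                     as.character(refSequence(g2)))
    # different seed -> different sequence
    g3 <- buildGenome(ToyGenomeSpec("toy1", 50000L, toyOpposingGenes(50000L),
                                    seed = 4L))
    expect_false(identical(as.character(refSequence(g1)),
                           as.character(refSequence(g3))))
    expect_error(ToyGenomeSpec("toy1", 1000L,
                               data.frame(gene = "g", strand = "+",
                                          start = 900L, end = 1100L)),
                 "bounds")
    expect_error(ToyGenomeSpec("toy1", 1000L,
                               data.frame(gene = "g", strand = "+",
                                          start = c(10L, 50L),
                                          end = c(100L, 120L))),
                 "overlap")
})

test_that("applySV arithmetic: deletion, duplication, inversion involution", {
    g <- fixtureGenome(10000L)
    rs <- as.character(refSequence(g))

    del <- applySV(g, SVSpec("d", "DEL", c(2000L, 5228L)))
    expect_equal(length(hapSequence(del)), 10000L - 3228L)

    inv <- SVSpec("i", "INV", c(1500L, 2600L))
    once <- applySV(g, inv)
    twice <- applySV(hapSequence(once), inv)
    expect_identical(as.character(hapSequence(twice)), rs)

    # tandem duplication of [100, 200): the window across the new junction
    # is ref[130,200) followed by ref[100,170)  (direct string construction)
    dup <- applySV(g, SVSpec("u", "DUP", c(100L, 200L)))
    altc <- as.character(hapSequence(dup))
    expect_equal(nchar(altc), 10100L)
    expect_identical(substr(altc, 131, 270),
                     paste0(substr(rs, 131, 200), substr(rs, 101, 170)))

    expect_error(applySV(g, SVSpec("x", "DEL", c(9000L, 12000L))), "outside")
})

test_that("junction records occur verbatim in the alternate haplotype and not the reference", {
    g <- fixtureGenome(20000L)
    rs <- as.character(refSequence(g))
    rc <- as.character(Biostrings::reverseComplement(refSequence(g)))
    svs <- list(SVSpec("d", "DEL", c(8000L, 11228L)),
                SVSpec("u", "DUP", c(8000L, 12000L)),
                SVSpec("i", "INV", c(8000L, 15000L)),
                fixtureComplexSV(20000L))
    for (sv in svs) {
        alt <- applySV(g, sv)
        jn <- junctionRecords(alt)
        expect_gt(nrow(jn), 0L)
        altc <- as.character(hapSequence(alt))
        for (s in jn$seq) {
            expect_true(grepl(s, altc, fixed = TRUE))
            expect_false(grepl(s, rs, fixed = TRUE) ||
                         grepl(s, rc, fixed = TRUE),
                         info = sprintf("junction of %s found in reference",
                                        svType(sv)))
        }
    }
})

test_that("liftover round-trips to identity outside the SV intervals", {
    g <- fixtureGenome(20000L)
    for (sv in list(SVSpec("d", "DEL", c(8000L, 11000L)),
                    SVSpec("i", "INV", c(8000L, 15000L)),
                    fixtureComplexSV(20000L))) {
        alt <- applySV(g, sv)
        bp <- svBreakpoints(sv)
        outside <- c(0L, 500L, min(bp) - 1L, max(bp), 19999L)
        fwd <- refToAlt(alt, outside)
        expect_false(anyNA(fwd))
        back <- altToRef(alt, fwd)
        expect_equal(back$ref_pos, outside)
        expect_true(all(back$strand == "+"))
        # positions inside a deletion are absent from the haplotype
        if (svType(sv) == "DEL")
            expect_true(is.na(refToAlt(alt, min(bp) + 5L)))
    }
})

test_that("sampleCohort draws Hardy-Weinberg genotypes reproducibly", {
    pops <- data.frame(label = c("A", "B"), allele_frequency = c(0, 1),
                       n = c(50L, 40L))
    coh <- sampleCohort(pops, seed = 5L)
    expect_true(all(coh$genotype[coh$population == "A"] == 0L))
    expect_true(all(coh$genotype[coh$population == "B"] == 2L))
    expect_identical(coh, sampleCohort(pops, seed = 5L))

    big <- sampleCohort(data.frame(label = "C", allele_frequency = 0.5,
                                   n = 10000L), seed = 6L)
    props <- as.numeric(table(factor(big$genotype, 0:2)) / 10000)
    se <- sqrt(c(0.25 * 0.75, 0.5 * 0.5, 0.25 * 0.75) / 10000)
    expect_true(all(abs(props - c(0.25, 0.5, 0.25)) <= 3 * se))
})

test_that("simulated reads respect genotype: junction support and coverage holes", {
    g <- fixtureGenome(20000L)
    sv <- SVSpec("d", "DEL", c(8000L, 11228L))
    alt <- applySV(g, sv)
    jseq <- junctionRecords(alt)$seq[1]

    # genotype 0: no read supports the novel junction
    sim0 <- simulateSample(g, sv, 0, coverage = 30, seed = 21L)
    core <- substr(jseq, nchar(jseq) / 2 - 14, nchar(jseq) / 2 + 15)
    hits0 <- fuzzyMatch(core, setNames(sim0$reads$seq,
                                       seq_len(nrow(sim0$reads))), 0)
    expect_equal(nrow(hits0), 0L)

    # genotype 2 deletion: zero reference coverage inside the deleted region
    sim2 <- simulateSample(g, sv, 2, coverage = 30, seed = 22L)
    cov <- coverageProfile(sim2$pairs, c(0, 20000))
    expect_true(all(cov[8501:10500] == 0))

    # mean coverage within 15% of target
    tot <- sum(nchar(sim2$reads$seq))
    expect_lt(abs(tot / (20000 - 3228) - 30) / 30, 0.15)
})

test_that("a heterozygous inversion yields FF and RR pairs at both breakpoints", {
    g <- fixtureGenome(20000L)
    sv <- SVSpec("i", "INV", c(8000L, 15000L))
    sim <- simulateSample(g, sv, 1, coverage = 30, seed = 23L)
    sig <- extractSignatures(sim$pairs, list(mean = 350, sd = 50))
    cl <- sig$clusters
    ff <- cl[cl$signature == "FF", ]
    rr <- cl[cl$signature == "RR", ]
    expect_equal(nrow(ff), 1L)
    expect_equal(nrow(rr), 1L)
    # FF left mates end near the upstream breakpoint, right mates near the
    # downstream one; RR mirrored
    expect_lt(abs(ff$left_hi - 8000), 350)
    expect_lt(abs(ff$right_hi - 15000), 350)
    expect_lt(abs(rr$left_lo - 8000), 350)
    expect_lt(abs(rr$right_lo - 15000), 350)
})

test_that("chimera table generation follows carrier and background probabilities", {
    coh <- sampleCohort(data.frame(label = "P", allele_frequency = 0.3,
                                   n = 200L), seed = 31L)
    samp <- addTissueSamples(coh, paste0("t", 1:5), 5L, seed = 32L)
    carriers <- coh$individual_id[coh$genotype > 0]

    chim <- data.frame(chimera_id = "f1", gene5 = "geneA", gene3 = "geneB",
                       sv_id = "v", carrier_prob = 1, background_prob = 0,
                       stringsAsFactors = FALSE)
    occ <- simulateChimeraTable(samp, coh, chim, seed = 33L)
    expect_setequal(unique(occ$individual_id), carriers)
    expect_equal(nrow(occ), sum(samp$individual_id %in% carriers))

    chim$carrier_prob <- 0
    expect_equal(nrow(simulateChimeraTable(samp, coh, chim, seed = 33L)), 0L)

    # background-only: ~ binomial(n_noncarrier_samples, p)
    chim2 <- data.frame(chimera_id = "bg", gene5 = "a", gene3 = "b",
                        sv_id = NA_character_, carrier_prob = 0,
                        background_prob = 0.005, stringsAsFactors = FALSE)
    occ2 <- simulateChimeraTable(samp, coh, chim2, seed = 34L)
    n <- nrow(samp)
    expect_lt(abs(nrow(occ2) - n * 0.005), 3 * sqrt(n * 0.005 * 0.995) + 1)
})

test_that("phenotype simulation respects prevalence and planted effects", {
    coh <- sampleCohort(data.frame(label = "P", allele_frequency = 0.2,
                                   n = 2000L), seed = 41L)
    ph <- simulatePhenotypes(coh, c("c1", "c2", "c3"),
                             baselinePrevalence = c(0.1, 0, 0.1),
                             planted = list(code = "c3", odds_ratio = 12.1),
                             model = "dominant", seed = 42L)
    expect_false("c2" %in% ph$phenotypes$code)
    expect_true(all(c("age", "sex", paste0("PC", 1:5)) %in%
                    names(ph$covariates)))
    carriers <- coh$individual_id[coh$genotype > 0]
    prevIn <- function(code, ids)
        mean(ids %in% ph$phenotypes$individual_id[ph$phenotypes$code == code])
    expect_gt(prevIn("c3", carriers),
              3 * prevIn("c3", setdiff(coh$individual_id, carriers)))
    expect_lt(abs(prevIn("c1", carriers) -
                  prevIn("c1", setdiff(coh$individual_id, carriers))), 0.08)
})
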