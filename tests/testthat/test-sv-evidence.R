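mkPair <- function(pos1, strand1, pos2, strand2, rl = 100L) {
    data.frame(read_id = sprintf("p%06d", seq_along(pos1)), chrom = "toy1",
               pos1 = pos1, end1 = pos1 + rl, strand1 = strand1,
               split1 = FALSE, pos2 = pos2, end2 = pos2 + rl,
               strand2 = strand2, split2 = FALSE, stringsAsFactors = FALSE)
}

im <- list(mean = 350, sd = 50)

test_that("pair orientation and insert thresholds drive signature classes", {
    # insert = right end - left start = pos2 - pos1 + 100
    pairs <- rbind(
        mkPair(1000L, "+", 1250L, "-"),              # insert = mean
        mkPair(2000L, "+", 2350L, "-"),              # mean + 2 sd: concordant
        mkPair(3000L, "+", 3450L, "-"),              # mean + 4 sd: long
        mkPair(4000L, "-", 4250L, "+"),              # RF
        mkPair(5000L, "+", 5250L, "+"),              # FF
        mkPair(6000L, "-", 6250L, "-"))              # RR
    sig <- extractSignatures(pairs, im, minSupport = 1L)
    expect_equal(sig$pairs$signature,
                 c("CONCORDANT", "CONCORDANT", "FR_LONG", "RF", "FF", "RR"))
    # concordant pairs never reach clusters
    expect_false("CONCORDANT" %in% sig$clusters$signature)
})

test_that("support counts are invariant under read-order shuffling", {
    g <- fixtureGenome(20000L)
    sim <- simulateSample(g, SVSpec("i", "INV", c(8000L, 15000L)), 1,
                          seed = 71L)
    sig1 <- extractSignatures(sim$pairs, im)
    set.seed(1)
    shuffled <- sim$pairs[sample(nrow(sim$pairs)), ]
    sig2 <- extractSignatures(shuffled, im)
    o <- function(cl) cl[order(cl$signature, cl$left_lo), ]
    expect_equal(o(sig1$clusters), o(sig2$clusters), ignore_attr = TRUE)
})

test_that("classifySv decision rules on constructed clusters and coverage", {
    region <- c(0, 20000)
    flat <- rep(30L, 20000)
    clusters <- function(...) list(clusters = rbind(...), pairs = NULL)
    row <- function(sig, n, l0, l1, r0, r1)
        data.frame(signature = sig, n = n, left_lo = l0, left_hi = l1,
                   right_lo = r0, right_hi = r1, left_med = (l0 + l1) / 2,
                   left_end_med = l1, right_med = (r0 + r1) / 2,
                   stringsAsFactors = FALSE)

    # FF + RR with flat coverage -> inversion
    callInv <- classifySv(clusters(row("FF", 10, 7700, 8000, 14700, 15000),
                                   row("RR", 9, 8000, 8300, 15000, 15300)),
                          flat, region, im)
    expect_equal(callInv$sv_type, "INV")
    expect_lt(abs(callInv$breakpoints[1, 1] - 8000), im$mean)

    # RF cluster + doubled coverage inside -> duplication
    gain <- flat; gain[8000:12000] <- 60L
    callDup <- classifySv(clusters(row("RF", 8, 8000, 8300, 11700, 12000)),
                          gain, region, im)
    expect_equal(callDup$sv_type, "DUP")
    expect_gt(callDup$coverage_ratio, 1.3)

    # same RF cluster with flat coverage stays NONE
    expect_equal(classifySv(clusters(row("RF", 8, 8000, 8300, 11700, 12000)),
                            flat, region, im)$sv_type, "NONE")

    # long-insert FR + halved coverage -> deletion
    loss <- flat; loss[9000:11500] <- 14L
    callDel <- classifySv(clusters(row("FR_LONG", 7, 8700, 9000, 11500, 11800)),
                          loss, region, im)
    expect_equal(callDel$sv_type, "DEL")
    expect_lt(callDel$coverage_ratio, 0.7)

    # inversion signature + adjacent depleted interval -> complex call
    lossAdj <- flat; lossAdj[11000:12200] <- 0L
    callCx <- classifySv(clusters(row("FF", 10, 7700, 8000, 10700, 11000),
                                  row("RR", 9, 8000, 8300, 12200, 12500)),
                         lossAdj, region, im)
    expect_equal(callCx$sv_type, "COMPLEX_INV_DEL")
    expect_equal(nrow(callCx$breakpoints), 2L)

    # below min_support everything is NONE
    expect_equal(classifySv(clusters(row("FF", 2, 7700, 8000, 14700, 15000),
                                     row("RR", 2, 8000, 8300, 15000, 15300)),
                            flat, region, im)$sv_type, "NONE")
})

test_that("planted SVs of every type are recovered from simulated reads", {
    g <- fixtureGenome(50000L)
    region <- c(0, 50000)
    svs <- list(DEL = SVSpec("v", "DEL", c(20000L, 23228L)),
                DUP = SVSpec("v", "DUP", c(20000L, 24000L)),
                INV = SVSpec("v", "INV", c(20000L, 30000L)),
                COMPLEX_INV_DEL = SVSpec("v", "COMPLEX_INV_DEL",
                                         rbind(c(20000L, 30000L),
                                               c(30000L, 33228L))))
    for (tp in names(svs)) {
        sim <- simulateSample(g, svs[[tp]], 1, coverage = 30,
                              seed = 80L + match(tp, names(svs)))
        call <- classifySv(extractSignatures(sim$pairs, im),
                           coverageProfile(sim$pairs, region), region, im)
        expect_equal(call$sv_type, tp)
        # breakpoint localisation within one insert mean
        truth <- sort(unique(as.vector(svBreakpoints(svs[[tp]]))))
        est <- sort(unique(as.vector(call$breakpoints)))
        expect_true(all(vapply(truth, function(b)
            min(abs(est - b)) <= im$mean, logical(1))))
    }
    # genotype 0 gives NONE
    sim0 <- simulateSample(g, svs$INV, 0, coverage = 30, seed = 90L)
    expect_equal(classifySv(extractSignatures(sim0$pairs, im),
                            coverageProfile(sim0$pairs, region),
                            region, im)$sv_type, "NONE")
})

test_that("SV calls are matched to chimera gene pairs by distance and geometry", {
    del <- list(sv_type = "DEL", breakpoints = rbind(c(10500, 30200)))
    sameStrand <- data.frame(gene = c("gA", "gB"), chrom = "chr6",
                             start = c(4000, 30000), end = c(11000, 37600),
                             strand = c("+", "+"), stringsAsFactors = FALSE)
    expect_equal(matchSvToChimera(del, sameStrand)$status, "DIRECT_EVIDENCE")

    inv <- list(sv_type = "INV", breakpoints = rbind(c(10500, 30200)))
    opp <- transform(sameStrand, strand = c("+", "-"))
    expect_equal(matchSvToChimera(inv, opp)$status, "DIRECT_EVIDENCE")
    # an inversion cannot fuse same-strand genes head-to-tail
    expect_equal(matchSvToChimera(inv, sameStrand)$status, "NO_EVIDENCE")

    interchrom <- transform(opp, chrom = c("chr6", "chr15"))
    res <- matchSvToChimera(inv, interchrom)
    expect_equal(res$status, "NO_EVIDENCE")
    expect_match(res$reason, "interchromosomal")

    far <- list(sv_type = "DEL", breakpoints = rbind(c(500000, 520000)))
    expect_equal(matchSvToChimera(far, sameStrand)$status, "NO_EVIDENCE")
    none <- list(sv_type = "NONE", breakpoints = NULL)
    expect_equal(matchSvToChimera(none, sameStrand)$status, "NO_EVIDENCE")
})

test_that("truth SAM round-trips through the SAM reader", {
    g <- fixtureGenome(20000L)
    sim <- simulateSample(g, fixtureComplexSV(20000L), 1, coverage = 5,
                          seed = 95L)
    sam <- file.path(tempdir(), "truth.sam")
    writeTruthSam(sim, sam, 20000L)
    pairs <- readPairsFromSam(sam)
    expect_equal(nrow(pairs), nrow(sim$pairs))
    i <- match(sim$pairs$read_id, pairs$read_id)
    expect_equal(pairs$pos1[i], sim$pairs$pos1)
    expect_equal(pairs$strand2[i], sim$pairs$strand2)
    # signature extraction agrees between in-memory truth and the SAM file
    s1 <- extractSignatures(sim$pairs, im)
    s2 <- extractSignatures(sam, im)
    expect_equal(sort(s1$pairs$signature), sort(s2$pairs$signature))
    unlink(sam)
})
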