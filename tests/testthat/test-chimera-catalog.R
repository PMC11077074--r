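occRow <- function(score = 0.8, identity = 0.5, pos5 = 4400L, pos3 = 16000L,
                   gene5 = "geneA", gene3 = "geneB", strand5 = "+",
                   strand3 = "-", id = "c1", sample = "s1", ind = "i1",
                   tissue = "t1") {
    data.frame(chimera_id = id, gene5 = gene5, gene3 = gene3,
               chrom5 = "toy1", pos5 = pos5, strand5 = strand5,
               chrom3 = "toy1", pos3 = pos3, strand3 = strand3,
               score = score, identity = identity, sample_id = sample,
               individual_id = ind, tissue = tissue,
               stringsAsFactors = FALSE)
}

test_that("confidence filter applies the score and identity boundaries strictly", {
    occ <- rbind(occRow(score = 0.59, id = "low"),
                 occRow(score = 0.60, id = "edge"),
                 occRow(score = 0.95, identity = 0.91, id = "similar"),
                 occRow(score = 0.95, identity = 0.90, id = "ok"),
                 occRow(score = 0.95, pos5 = NA, id = "nopos"))
    res <- confidenceFilter(occ)
    expect_setequal(res$occurrences$chimera_id, c("edge", "ok"))
    expect_equal(unname(res$removed), c(1L, 1L, 1L))
    expect_equal(sum(res$removed), nrow(occ) - nrow(res$occurrences))

    empty <- confidenceFilter(occ[0, ])
    expect_equal(nrow(empty$occurrences), 0L)
    expect_equal(sum(empty$removed), 0L)

    expect_error(confidenceFilter(data.frame(pos5 = 1, pos3 = 2)), "score")
})

test_that("confidence filter is monotone in its thresholds", {
    set.seed(8)
    occ <- do.call(rbind, lapply(1:200, function(i)
        occRow(score = runif(1), identity = runif(1), id = paste0("c", i))))
    kept <- function(ms, mi)
        confidenceFilter(occ, ms, mi)$occurrences$chimera_id
    for (ms in c(0.2, 0.5, 0.8)) {
        expect_true(all(kept(ms + 0.1, 0.9) %in% kept(ms, 0.9)))
        expect_true(all(kept(ms, 0.7) %in% kept(ms, 0.9)))
    }
})

test_that("junction classification matches exon edges within +/- 2 bp, strand-aware", {
    g <- fixtureGenome(20000L)
    ex <- exonRanges(g)
    gA <- g@spec@genes[g@spec@genes$gene == "geneA", ]
    gB <- g@spec@genes[g@spec@genes$gene == "geneB", ]
    donorEdge <- gA$end[2]        # geneA is '+': donor edge = exon end
    accEdge <- gB$end[2]          # geneB is '-': acceptor edge = exon end

    cls <- function(p5, p3) classifyJunction(occRow(pos5 = p5, pos3 = p3), ex)
    expect_equal(cls(donorEdge, accEdge), "E_E")
    expect_equal(cls(donorEdge + 2L, accEdge), "E_E")
    expect_equal(cls(donorEdge + 3L, accEdge), "M_E")
    expect_equal(cls(donorEdge, accEdge - 40L), "E_M")
    expect_equal(cls(donorEdge - 50L, accEdge - 40L), "M_M")

    expect_warning(out <- classifyJunction(occRow(gene5 = "nope"), ex),
                   "absent")
    expect_match(out, "^M_")
})

test_that("junction classification is invariant under coordinate translation", {
    for (shift in c(0L, 1234L)) {
        genes <- toyOpposingGenes(20000L)
        genes$start <- genes$start + shift
        genes$end <- genes$end + shift
        genes$cds_start <- genes$cds_start + shift
        genes$cds_end <- genes$cds_end + shift
        g <- buildGenome(ToyGenomeSpec("toy1", 30000L, genes, seed = 2L))
        donorEdge <- genes$end[2]
        accEdge <- genes$end[6]
        expect_equal(classifyJunction(occRow(pos5 = donorEdge + 1L,
                                             pos3 = accEdge - 7L),
                                      exonRanges(g)), "E_M")
    }
})

test_that("frame prediction follows cumulative CDS length mod 3", {
    # geneA '+': CDS starts at start[1]+100; exon1 CDS width 300
    genes <- data.frame(gene = c("gA", "gA", "gB", "gB"),
                        strand = "+",
                        start = c(1000L, 2000L, 6000L, 7000L),
                        end = c(1400L, 2400L, 6400L, 7400L),
                        cds_start = c(1100L, 2000L, 6100L, 7000L),
                        cds_end = c(1400L, 2400L, 6400L, 7400L))
    g <- buildGenome(ToyGenomeSpec("toy1", 10000L, genes, seed = 1L))
    cds <- cdsRanges(g)
    # donor at end of exon1 contributes 300 CDS nt; acceptor at gB CDS start
    # has phase 0
    frameAt <- function(p5, p3)
        predictFrame(occRow(gene5 = "gA", gene3 = "gB", pos5 = p5, pos3 = p3,
                            strand3 = "+"), cds)
    expect_equal(frameAt(1400L, 6100L), "IN_FRAME")     # 300 %% 3 == 0
    expect_equal(frameAt(2001L, 6100L), "FRAMESHIFT")   # 301 %% 3 == 1
    expect_equal(frameAt(2002L, 6100L), "FRAMESHIFT")   # 302 %% 3 == 2
    expect_equal(frameAt(2003L, 6100L), "IN_FRAME")     # 303 %% 3 == 0
    expect_equal(frameAt(1400L, 6103L), "IN_FRAME")     # phases 0 == 0
    expect_equal(frameAt(1400L, 6104L), "FRAMESHIFT")   # phase 3' = 1
    # 5' junction in the 5'UTR: no CDS contributed
    expect_equal(frameAt(1050L, 6100L), "NON_CODING")
    # 3' junction beyond the CDS end: nothing left to translate
    expect_equal(frameAt(1400L, 7400L), "NON_CODING")
})

test_that("polymorphic filter reproduces the stated aggregation arithmetic", {
    manifest <- data.frame(
        sample_id = paste0("s", 1:30),
        individual_id = rep(c("i1", "i2", "i3"), each = 10),
        tissue = rep(paste0("t", 1:10), 3), stringsAsFactors = FALSE)
    mkocc <- function(ind, k, tissues) {
        sel <- manifest[manifest$individual_id == ind, ][seq_len(k), ]
        sel$tissue <- tissues[seq_len(k)]
        do.call(rbind, lapply(seq_len(nrow(sel)), function(j)
            occRow(id = "x", sample = sel$sample_id[j], ind = ind,
                   tissue = sel$tissue[j])))
    }
    # fractions (1.0, 1.0, 0.1); tissue counts (7, 7, 1):
    # mean fraction 0.7 > 2/3 but mean tissues 5 is not > 5 -> excluded
    occ <- rbind(mkocc("i1", 10, paste0("t", c(1:7, 1:3))),
                 mkocc("i2", 10, paste0("t", c(1:7, 5:7))),
                 mkocc("i3", 1, "t1"))
    res <- polymorphicFilter(occ, manifest, maxIndividuals = 250L)
    expect_equal(res$metrics$mean_sample_fraction, 0.7)
    expect_equal(res$metrics$mean_tissue_count, 5)
    expect_false(res$metrics$selected)

    # raise the third individual's spread (4 samples, 4 tissues):
    # mean fraction (1 + 1 + 0.4)/3 = 0.8 and mean tissues 6 > 5 -> selected
    occ2 <- rbind(mkocc("i1", 10, paste0("t", c(1:7, 1:3))),
                  mkocc("i2", 10, paste0("t", c(1:7, 5:7))),
                  mkocc("i3", 4, paste0("t", 1:4)))
    res2 <- polymorphicFilter(occ2, manifest)
    expect_equal(res2$metrics$mean_tissue_count, 6)
    expect_true(res2$metrics$selected)

    # per_individual_all: i3's fraction 0.4 < 2/3 fails the strict variant
    res3 <- polymorphicFilter(occ2, manifest,
                              aggregation = "per_individual_all")
    expect_false(res3$metrics$selected)

    # an occurrence naming an unknown sample is an error
    bad <- occRow(id = "x", sample = "s99", ind = "i9")
    expect_error(polymorphicFilter(rbind(occ, bad), manifest), "absent")
})

test_that("polymorphic filter excludes chimeras at or above the individual cap", {
    n <- 250L
    manifest <- data.frame(sample_id = paste0("s", 1:n),
                           individual_id = paste0("i", 1:n),
                           tissue = "t1", stringsAsFactors = FALSE)
    occ <- do.call(rbind, lapply(1:n, function(i)
        occRow(id = "wide", sample = paste0("s", i), ind = paste0("i", i),
               tissue = "t1")))
    res <- polymorphicFilter(occ, manifest, minTissues = 0.5,
                             minSampleFraction = 0.5)
    expect_equal(res$metrics$n_individuals, n)
    expect_false(res$metrics$selected)      # strict "< 250"
})
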