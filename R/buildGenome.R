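#' Default two-gene toy locus layout
#'
#' A compact locus with two genes in opposing orientations separated by an
#' intergenic spacer, mirroring the geometry in which a pseudogene and a
#' neighbouring gene on opposite strands can be fused by an inversion plus
#' adjacent deletion.  Useful as the `genes` argument of [ToyGenomeSpec()].
#'
#' @param length Contig length; genes are scaled into the middle of it.
#' @return Exon-level data.frame.
#' @export
toyOpposingGenes <- function(length = 50000L) {
    # geneA: forward strand, 4 exons; geneB: reverse strand, 4 exons,
    # downstream of geneA with a spacer in between.
    scale <- length / 50000
    ex <- function(s, e) as.integer(round(c(s, e) * scale))
    a <- rbind(ex(4000, 4400), ex(6000, 6300), ex(8000, 8350), ex(10500, 11000))
    b <- rbind(ex(30000, 30500), ex(32500, 32800), ex(34500, 34800), ex(37000, 37600))
    genes <- data.frame(
        gene = c(rep("geneA", 4), rep("geneB", 4)),
        strand = c(rep("+", 4), rep("-", 4)),
        start = c(a[, 1], b[, 1]), end = c(a[, 2], b[, 2]),
        stringsAsFactors = FALSE)
    # CDS: all but scaled UTR stubs on the terminal exons
    utr <- max(1L, as.integer(round(100 * scale)))
    genes$cds_start <- genes$start
    genes$cds_end <- genes$end
    genes$cds_start[1] <- genes$start[1] + utr       # geneA 5'UTR
    genes$cds_end[4] <- genes$end[4] - utr           # geneA 3'UTR
    genes$cds_end[8] <- genes$end[8] - utr           # geneB 5'UTR (reverse strand)
    genes$cds_start[5] <- genes$start[5] + utr       # geneB 3'UTR
    genes
}

#' Build a toy genome from a specification
#'
#' Draws a random background sequence (uniform base composition) of exactly
#' `spec@length` bases and materialises the exon/CDS annotation as
#' `GRanges`.  Deterministic for a given seed.
#'
#' @param spec A [ToyGenomeSpec-class].
#' @return A [ToyGenome-class].
#' @export
buildGenome <- function(spec) {
    validObject(spec)
    seq <- withSeed(spec@seed, {
        Biostrings::DNAString(paste(sample(c("A", "C", "G", "T"),
                                           spec@length, replace = TRUE),
                                    collapse = ""))
    })
    g <- spec@genes
    if (nrow(g)) {
        exons <- GenomicRanges::GRanges(
            seqnames = spec@contigName,
            ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
            strand = g$strand, gene = g$gene)
        has <- !is.na(g$cds_start)
        cds <- GenomicRanges::GRanges(
            seqnames = spec@contigName,
            ranges = IRanges::IRanges(start = g$cds_start[has] + 1L,
                                      end = g$cds_end[has]),
            strand = g$strand[has], gene = g$gene[has])
    } else {
        exons <- GenomicRanges::GRanges()
        cds <- GenomicRanges::GRanges()
    }
    new("ToyGenome", spec = spec, sequence = seq, exons = exons, cds = cds)
}

#' Write a genome (or any named sequences) as FASTA
#'
#' @param genome A [ToyGenome-class], or a named list/`DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
    if (is(genome, "ToyGenome")) {
        seqs <- Biostrings::DNAStringSet(list(genome@sequence))
        names(seqs) <- genome@spec@contigName
    } else if (is(genome, "DNAStringSet")) {
        seqs <- genome
    } else {
        seqs <- Biostrings::DNAStringSet(lapply(genome, Biostrings::DNAString))
    }
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}

#' Write exon annotation as BED6
#'
#' One record per exon, 0-based half-open per the BED convention, named
#' `gene:rank`.
#'
#' @param genome A [ToyGenome-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAnnotationBed <- function(genome, path) {
    g <- genome@spec@genes
    if (!nrow(g)) {
        writeLines(character(), path)
        return(invisible(path))
    }
    rank <- stats::ave(seq_len(nrow(g)), g$gene, FUN = seq_along)
    bed <- data.frame(chrom = genome@spec@contigName,
                      start = g$start, end = g$end,
                      name = paste0(g$gene, ":", rank),
                      score = 0L, strand = g$strand)
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}
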