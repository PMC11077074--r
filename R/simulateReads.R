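#' Simulate paired-end whole-genome reads from a genotype
#'
#' Draws fragments from the two haplotypes in proportion to allele dosage
#' (genotype 0 = two reference haplotypes, 1 = one of each, 2 = two
#' alternate haplotypes), with Normal insert sizes truncated at the read
#' length and uniform fragment starts.  Pairs are FR-oriented on their
#' haplotype of origin; uniform substitution errors are applied at
#' `config@baseErrorRate`.  Truth alignments are computed through the
#' haplotype-to-reference block map, so reads crossing a novel adjacency
#' become discordant and/or split in reference space.
#'
#' @param refHap Reference haplotype ([refHaplotype()]).
#' @param altHap Alternate haplotype ([applySV()]).
#' @param genotype 0, 1 or 2 copies of the alternate allele.
#' @param config A [ReadSimConfig-class].
#' @param contig Contig name recorded in truth alignments.
#' @return A list with elements `reads` (data.frame: `read_id`, `mate`,
#'   `seq`), `pairs` (pair-level truth: reference positions, strands and
#'   split flags of both mates, 0-based half-open), `n_fragments`, and the
#'   echoed `config`.
#' @export
simulateWgs <- function(refHap, altHap, genotype, config,
                        contig = "toy1") {
    stopifnot(genotype %in% 0:2)
    validObject(config)
    haps <- list(refHap, altHap)
    lens <- vapply(haps, function(h) length(h@sequence), integer(1))
    used <- unique(c(1L, 2L)[c(genotype < 2, genotype > 0)])
    if (config@insertMean >= min(lens[used]))
        stop("insertMean must be smaller than the haplotype length", call. = FALSE)
    rl <- config@readLength
    # fragment count targets the dosage-weighted mean haplotype length so
    # realised coverage tracks the configured value for any genotype
    effLen <- ((2 - genotype) * lens[1] + genotype * lens[2]) / 2
    nFrag <- as.integer(round(config@coverage * effLen / (2 * rl)))
    withSeed(config@seed, {
        alleleAlt <- rbinom(nFrag, 1L, genotype / 2) == 1L
        hapIdx <- ifelse(alleleAlt, 2L, 1L)
        hapLen <- lens[hapIdx]
        insert <- pmax(rl, as.integer(round(rnorm(nFrag, config@insertMean,
                                                  config@insertSd))))
        insert <- pmin(insert, hapLen)
        start <- as.integer(floor(runif(nFrag) * (hapLen - insert + 1)))

        hapStr <- vapply(haps, function(h) as.character(h@sequence), character(1))
        s1 <- start; e1 <- start + rl
        s2 <- start + insert - rl; e2 <- start + insert
        seq1 <- substring(hapStr[hapIdx], s1 + 1L, e1)
        seq2raw <- substring(hapStr[hapIdx], s2 + 1L, e2)
        seq2 <- revComp(seq2raw)
        seq1 <- injectErrors(seq1, config@baseErrorRate)
        seq2 <- injectErrors(seq2, config@baseErrorRate)

        ids <- sprintf("frag%07d", seq_len(nFrag))
        m1 <- liftReads(haps, hapIdx, s1, e1, "+")
        m2 <- liftReads(haps, hapIdx, s2, e2, "-")
        pairs <- data.frame(read_id = ids, chrom = contig,
                            pos1 = m1$pos, end1 = m1$end, strand1 = m1$strand,
                            split1 = m1$split,
                            pos2 = m2$pos, end2 = m2$end, strand2 = m2$strand,
                            split2 = m2$split,
                            allele = ifelse(alleleAlt, "alt", "ref"),
                            stringsAsFactors = FALSE)
        reads <- data.frame(read_id = rep(ids, 2L),
                            mate = rep(c(1L, 2L), each = nFrag),
                            seq = c(seq1, seq2), stringsAsFactors = FALSE)
        list(reads = reads, pairs = pairs, n_fragments = nFrag,
             contig = contig, config = config)
    })
}

# Uniform substitution errors; vectorised over reads.
injectErrors <- function(seqs, rate) {
    if (rate <= 0 || !length(seqs)) return(seqs)
    rl <- nchar(seqs)
    nerr <- rbinom(length(seqs), rl, rate)
    hit <- which(nerr > 0L)
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
        pos <- sample.int(rl[i], nerr[i])
        for (p in pos) {
            cur <- substr(seqs[i], p, p)
            substr(seqs[i], p, p) <- sample(setdiff(bases, cur), 1L)
        }
    }
    seqs
}

# Lift read intervals [s, e) on their haplotype to reference space via the
# majority-overlap segment.  Returns 0-based leftmost-aligned position,
# aligned end, reference strand and a split flag for reads crossing a block
# boundary.
liftReads <- function(haps, hapIdx, s, e, hapStrand) {
    n <- length(s)
    pos <- integer(n); end <- integer(n)
    strand <- character(n); split <- logical(n)
    for (h in unique(hapIdx)) {
        sel <- which(hapIdx == h)
        seg <- haps[[h]]@segments
        ov_best <- rep(-1L, length(sel))
        for (i in seq_len(nrow(seg))) {
            ov_a <- pmax(s[sel], seg$alt_start[i])
            ov_b <- pmin(e[sel], seg$alt_end[i])
            w <- ov_b - ov_a
            better <- w > ov_best
            if (!any(better)) next
            bsel <- better
            if (seg$strand[i] == "+") {
                pos[sel[bsel]] <- seg$ref_start[i] + (ov_a[bsel] - seg$alt_start[i])
                end[sel[bsel]] <- pos[sel[bsel]] + w[bsel]
                strand[sel[bsel]] <- hapStrand
            } else {
                end[sel[bsel]] <- seg$ref_end[i] - (ov_a[bsel] - seg$alt_start[i])
                pos[sel[bsel]] <- end[sel[bsel]] - w[bsel]
                strand[sel[bsel]] <- if (hapStrand == "+") "-" else "+"
            }
            split[sel[bsel]] <- w[bsel] < (e[sel[bsel]] - s[sel[bsel]])
            ov_best[bsel] <- w[bsel]
        }
    }
    list(pos = pos, end = end, strand = strand, split = split)
}

#' Write simulated reads as a paired FASTQ
#'
#' Mates are written to `<prefix>_1.fastq` and `<prefix>_2.fastq` with
#' constant Phred-40 qualities (the simulator models substitution errors,
#' not quality decay).
#'
#' @param sim Output of [simulateWgs()].
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
writeFastqPair <- function(sim, prefix) {
    paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
    for (m in 1:2) {
        rd <- sim$reads[sim$reads$mate == m, ]
        seqs <- Biostrings::DNAStringSet(rd$seq)
        names(seqs) <- paste0(rd$read_id, "/", m)
        quals <- Biostrings::BStringSet(strrep("I", nchar(rd$seq)))
        Biostrings::writeXStringSet(seqs, paths[m], format = "fastq",
                                    qualities = quals)
    }
    invisible(paths)
}

#' Write truth alignments as a coordinate-sorted SAM file
#'
#' Emits one record per mate with proper paired-end flags (paired, mate
#' strand, first/last in pair), 1-based positions and soft-clipped CIGARs
#' for reads crossing novel adjacencies.
#'
#' @param sim Output of [simulateWgs()].
#' @param path Output path (`.sam`).
#' @param contigLength Reference contig length for the `@SQ` header.
#' @return `path`, invisibly.
#' @export
writeTruthSam <- function(sim, path, contigLength) {
    p <- sim$pairs
    rl <- sim$config@readLength
    rec <- function(mate) {
        pos <- p[[paste0("pos", mate)]]; end <- p[[paste0("end", mate)]]
        str <- p[[paste0("strand", mate)]]; spl <- p[[paste0("split", mate)]]
        ostr <- p[[paste0("strand", 3 - mate)]]
        opos <- p[[paste0("pos", 3 - mate)]]
        flag <- 1L +
            ifelse(str == "-", 16L, 0L) +
            ifelse(ostr == "-", 32L, 0L) +
            if (mate == 1L) 64L else 128L
        w <- end - pos
        cigar <- ifelse(spl, sprintf("%dM%dS", w, rl - w), sprintf("%dM", rl))
        seq <- sim$reads$seq[sim$reads$mate == mate]
        # SEQ is stored on the forward reference strand
        seq <- ifelse(str == "-", revComp(seq), seq)
        tlen <- pmax(end, p[[paste0("end", 3 - mate)]]) -
            pmin(pos, opos)
        tlen <- ifelse(pos <= opos, tlen, -tlen)
        data.frame(qname = p$read_id, flag = flag, rname = p$chrom,
                   pos = pos + 1L, mapq = 60L, cigar = cigar, rnext = "=",
                   pnext = opos + 1L, tlen = tlen, seq = seq,
                   qual = strrep("I", nchar(seq)), stringsAsFactors = FALSE)
    }
    recs <- rbind(rec(1L), rec(2L))
    recs <- recs[order(recs$pos, recs$qname), ]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("@HD\tVN:1.6\tSO:coordinate",
                 sprintf("@SQ\tSN:%s\tLN:%d", sim$contig, contigLength)), con)
    write.table(recs, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read paired alignments from a SAM/BAM file
#'
#' Converts SAM to BAM via Rsamtools when needed, then assembles one row
#' per read pair with 0-based half-open mate coordinates, strands and a
#' split flag (any soft/hard clip).  Input must be coordinate-sorted.
#'
#' @param path SAM or BAM path.
#' @return data.frame in the pair format used by [extractSignatures()].
#' @export
readPairsFromSam <- function(path) {
    if (grepl("\\.sam$", path)) {
        dest <- tempfile()
        bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                                indexDestination = FALSE)
    } else {
        bam <- path
    }
    res <- Rsamtools::scanBam(bam,
        param = Rsamtools::ScanBamParam(
            what = c("qname", "flag", "rname", "pos", "qwidth", "cigar",
                     "strand")))[[1]]
    if (length(res$pos) > 1L && is.unsorted(res$pos, na.rm = TRUE))
        stop("alignments are not coordinate-sorted", call. = FALSE)
    aligned <- vapply(strsplit(gsub("([0-9]+)([MIDNSHP=X])", "\\1.\\2,",
                                    res$cigar), ","), function(ops) {
        sum(as.integer(sub("\\..*", "", ops[grepl("\\.(M|=|X|D)", ops)])))
    }, integer(1))
    df <- data.frame(qname = res$qname,
                     mate = ifelse(bitwAnd(res$flag, 64L) > 0L, 1L, 2L),
                     chrom = as.character(res$rname), pos = res$pos - 1L,
                     end = res$pos - 1L + aligned,
                     strand = as.character(res$strand),
                     split = grepl("[SH]", res$cigar),
                     stringsAsFactors = FALSE)
    m1 <- df[df$mate == 1L, ]; m2 <- df[df$mate == 2L, ]
    i <- match(m1$qname, m2$qname)
    ok <- !is.na(i)
    m1 <- m1[ok, ]; m2 <- m2[i[ok], ]
    data.frame(read_id = m1$qname, chrom = m1$chrom,
               pos1 = m1$pos, end1 = m1$end, strand1 = m1$strand,
               split1 = m1$split,
               pos2 = m2$pos, end2 = m2$end, strand2 = m2$strand,
               split2 = m2$split, stringsAsFactors = FALSE)
}
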