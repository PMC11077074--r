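#' Classify and cluster discordant read-pair signatures
#'
#' Pairs are oriented by their leftmost-aligned mate: `FR` (forward then
#' reverse) is the concordant geometry; `FF`/`RR` ("left-left"/
#' "right-right" in browser colouring) signal inversion breakpoints; `RF`
#' (outward-facing, "right-left") signals a tandem duplication.  An FR pair
#' is concordant when its insert lies within `multiplier` standard
#' deviations of the insert mean; FR pairs with longer inserts form the
#' `FR_LONG` deletion signature.  Discordant pairs are clustered per class
#' by proximity (gap <= insert mean between successive left positions).
#'
#' @param pairs Pair table ([simulateWgs()] truth, or
#'   [readPairsFromSam()]), or a SAM/BAM path.
#' @param insertModel list with `mean`, `sd` and optional `multiplier`
#'   (default 3).
#' @param region Optional numeric length-2 vector restricting analysis to
#'   pairs whose leftmost position falls in the 0-based half-open interval.
#' @param minSupport Clusters below this size are dropped (default 3).
#' @return list with `clusters` (class, n, left/right position ranges and
#'   medians) and `pairs` (annotated pair table with `orientation`,
#'   `insert`, `signature`).
#' @export
extractSignatures <- function(pairs, insertModel, region = NULL,
                              minSupport = 3L) {
    if (is.character(pairs)) pairs <- readPairsFromSam(pairs)
    checkColumns(pairs, c("pos1", "end1", "strand1", "pos2", "end2",
                          "strand2"), "pairs")
    mult <- insertModel$multiplier %||% 3
    swap <- pairs$pos2 < pairs$pos1
    left_pos <- ifelse(swap, pairs$pos2, pairs$pos1)
    left_end <- ifelse(swap, pairs$end2, pairs$end1)
    left_str <- ifelse(swap, pairs$strand2, pairs$strand1)
    right_pos <- ifelse(swap, pairs$pos1, pairs$pos2)
    right_end <- ifelse(swap, pairs$end1, pairs$end2)
    right_str <- ifelse(swap, pairs$strand1, pairs$strand2)
    orientation <- paste0(ifelse(left_str == "+", "F", "R"),
                          ifelse(right_str == "+", "F", "R"))
    insert <- pmax(right_end, left_end) - left_pos
    signature <- rep("CONCORDANT", nrow(pairs))
    lo <- insertModel$mean - mult * insertModel$sd
    hi <- insertModel$mean + mult * insertModel$sd
    signature[orientation == "FR" & insert > hi] <- "FR_LONG"
    signature[orientation == "FR" & insert < lo] <- "FR_SHORT"
    signature[orientation == "RF"] <- "RF"
    signature[orientation == "FF"] <- "FF"
    signature[orientation == "RR"] <- "RR"
    ann <- data.frame(left_pos = left_pos, left_end = left_end,
                      right_pos = right_pos, right_end = right_end,
                      orientation = orientation, insert = insert,
                      signature = signature, stringsAsFactors = FALSE)
    if ("split1" %in% names(pairs))
        ann$split <- pairs$split1 | pairs$split2
    if (!is.null(region)) {
        keep <- ann$left_pos >= region[1] & ann$left_pos < region[2]
        ann <- ann[keep, , drop = FALSE]
    }
    ann <- ann[order(ann$left_pos), , drop = FALSE]
    disc <- ann[!ann$signature %in% c("CONCORDANT", "FR_SHORT"), , drop = FALSE]
    clusters <- do.call(rbind, lapply(split(disc, disc$signature), function(d) {
        gap <- c(0, diff(d$left_pos))
        cid <- cumsum(gap > insertModel$mean)
        do.call(rbind, lapply(split(d, cid), function(cl) {
            data.frame(signature = cl$signature[1], n = nrow(cl),
                       left_lo = min(cl$left_pos), left_hi = max(cl$left_end),
                       right_lo = min(cl$right_pos),
                       right_hi = max(cl$right_end),
                       left_med = median(cl$left_pos),
                       left_end_med = median(cl$left_end),
                       right_med = median(cl$right_pos),
                       stringsAsFactors = FALSE)
        }))
    }))
    if (is.null(clusters)) {
        clusters <- data.frame(signature = character(), n = integer(),
                               left_lo = integer(), left_hi = integer(),
                               right_lo = integer(), right_hi = integer(),
                               left_med = numeric(), right_med = numeric(),
                               stringsAsFactors = FALSE)
    } else {
        clusters <- clusters[clusters$n >= minSupport, , drop = FALSE]
        rownames(clusters) <- NULL
    }
    list(clusters = clusters, pairs = ann)
}

#' Per-base coverage profile from a pair table
#'
#' @param pairs Pair table (see [extractSignatures()]).
#' @param region Numeric length-2 vector, 0-based half-open.
#' @return Integer vector of per-base read coverage over the region.
#' @export
coverageProfile <- function(pairs, region) {
    L <- as.integer(region[2] - region[1])
    s <- c(pairs$pos1, pairs$pos2) - region[1]
    e <- c(pairs$end1, pairs$end2) - region[1]
    s <- pmax(as.integer(s), 0L); e <- pmin(as.integer(e), L)
    ok <- e > s
    delta <- tabulate(s[ok] + 1L, nbins = L + 1L) -
        tabulate(e[ok] + 1L, nbins = L + 1L)
    cumsum(delta)[seq_len(L)]
}

# Running-mean smoothing (centred window), used before thresholding so that
# per-base sampling noise does not fragment depleted runs.
smoothCoverage <- function(coverage, window = 101L) {
    n <- length(coverage)
    if (n < window) return(coverage)
    cs <- cumsum(c(0, coverage))
    half <- window %/% 2L
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Mean coverage inside [lo, hi) relative to the median coverage of the rest
# of the region (the candidate interval, padded, is excluded from the
# baseline).
coverageRatio <- function(coverage, region, lo, hi) {
    n <- length(coverage)
    i0 <- max(1L, as.integer(lo - region[1]) + 1L)
    i1 <- min(n, as.integer(hi - region[1]))
    if (i1 <= i0) return(NA_real_)
    inside <- mean(coverage[i0:i1])
    pad <- min(i1 - i0 + 1L, 500L)
    keep <- setdiff(seq_len(n), seq(max(1L, i0 - pad), min(n, i1 + pad)))
    if (!length(keep)) return(NA_real_)
    base <- median(coverage[keep])
    if (is.na(base) || base == 0) return(NA_real_)
    inside / base
}

# Longest contiguous depleted run (smoothed coverage < frac * baseline)
# inside a search interval; returns NULL or c(lo, hi) in region coordinates.
findDepletedRun <- function(coverage, region, searchLo, searchHi,
                            frac = 0.7, minLen = 200L) {
    i0 <- max(1L, as.integer(searchLo - region[1]) + 1L)
    i1 <- min(length(coverage), as.integer(searchHi - region[1]))
    if (i1 <= i0) return(NULL)
    sm <- smoothCoverage(coverage)
    base <- median(sm[sm > 0])
    if (!length(base) || is.na(base) || base == 0) return(NULL)
    dep <- sm[i0:i1] < frac * base
    r <- rle(dep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= minLen)
    if (!length(runs)) return(NULL)
    k <- runs[which.max(r$lengths[runs])]
    c(region[1] + i0 - 1L + starts[k] - 1L,
      region[1] + i0 - 1L + ends[k])
}

#' Classify the structural-variant type from signature clusters and coverage
#'
#' Decision rules (all supporting clusters need >= `minSupport` pairs):
#' inversion when FF and RR clusters are both present; if an adjacent
#' depleted interval (coverage below `lossThreshold` of baseline) is also
#' found the call is the complex inversion-plus-deletion; duplication when
#' an outward RF cluster coincides with a coverage gain above
#' `gainThreshold`; deletion when a long-insert FR cluster coincides with
#' a coverage loss below `lossThreshold`; `NONE` otherwise.
#'
#' @param signatures Output of [extractSignatures()].
#' @param coverage Output of [coverageProfile()] over `region`.
#' @param region Numeric length-2 vector (0-based half-open).
#' @param insertModel list with `mean`, `sd`.
#' @param minSupport Minimum pairs per supporting cluster (default 3).
#' @param gainThreshold Coverage ratio above which a gain is called
#'   (default 1.3).
#' @param lossThreshold Coverage ratio below which a loss is called
#'   (default 0.7).
#' @return list with `sv_type`, `breakpoints` (matrix of 0-based half-open
#'   intervals), `support` (named cluster sizes), `coverage_ratio`.
#' @export
classifySv <- function(signatures, coverage, region, insertModel,
                       minSupport = 3L, gainThreshold = 1.3,
                       lossThreshold = 0.7) {
    cl <- signatures$clusters
    cl <- cl[cl$n >= minSupport, , drop = FALSE]
    pick <- function(sig) {
        d <- cl[cl$signature == sig, , drop = FALSE]
        if (!nrow(d)) NULL else d[which.max(d$n), ]
    }
    ff <- pick("FF"); rr <- pick("RR"); rf <- pick("RF"); frl <- pick("FR_LONG")
    support <- c(FF = if (is.null(ff)) 0L else ff$n,
                 RR = if (is.null(rr)) 0L else rr$n,
                 RF = if (is.null(rf)) 0L else rf$n,
                 FR_LONG = if (is.null(frl)) 0L else frl$n)
    none <- list(sv_type = "NONE", breakpoints = NULL, support = support,
                 coverage_ratio = NA_real_)
    if (!is.null(ff) && !is.null(rr)) {
        # FF pairs straddle the upstream breakpoint / inverted copy of it;
        # RR pairs straddle the inverted copy / downstream continuation.
        s_est <- round((ff$left_hi + rr$left_lo) / 2)
        e_inv <- ff$right_hi                 # inversion end
        e_next <- rr$right_lo                # where the reference resumes
        dep <- findDepletedRun(coverage, region, e_inv - insertModel$mean,
                               rr$right_hi + insertModel$mean,
                               frac = lossThreshold,
                               minLen = max(200L, as.integer(insertModel$sd)))
        if (!is.null(dep)) {
            delIv <- c(min(e_inv, dep[1]), max(e_next, dep[2]))
            ratio <- coverageRatio(coverage, region, delIv[1], delIv[2])
            return(list(sv_type = "COMPLEX_INV_DEL",
                        breakpoints = rbind(inversion = c(s_est, delIv[1]),
                                            deletion = delIv),
                        support = support, coverage_ratio = ratio))
        }
        e_est <- round((e_inv + rr$right_hi) / 2)
        ratio <- coverageRatio(coverage, region, s_est, e_est)
        return(list(sv_type = "INV",
                    breakpoints = rbind(inversion = c(s_est, e_est)),
                    support = support, coverage_ratio = ratio))
    }
    if (!is.null(rf)) {
        lo <- rf$left_lo; hi <- rf$right_hi
        ratio <- coverageRatio(coverage, region, lo, hi)
        if (!is.na(ratio) && ratio > gainThreshold)
            return(list(sv_type = "DUP",
                        breakpoints = rbind(duplication = c(lo, hi)),
                        support = support, coverage_ratio = ratio))
    }
    if (!is.null(frl)) {
        # median inner bounds localise the deletion robustly: stray
        # long-insert pairs away from the event cannot drag the interval
        lo <- round(frl$left_end_med); hi <- round(frl$right_med)
        dep <- findDepletedRun(coverage, region, lo - insertModel$mean,
                               hi + insertModel$mean, frac = lossThreshold,
                               minLen = max(200L, as.integer(insertModel$sd)))
        ratio <- if (!is.null(dep))
            coverageRatio(coverage, region, max(lo, dep[1]), min(hi, dep[2]))
        else coverageRatio(coverage, region, lo, hi)
        if (!is.na(ratio) && ratio < lossThreshold)
            return(list(sv_type = "DEL",
                        breakpoints = rbind(deletion = c(lo, hi)),
                        support = support, coverage_ratio = ratio))
    }
    none
}

#' Match an SV call to a chimera's parental-gene loci
#'
#' `DIRECT_EVIDENCE` requires a non-`NONE` call whose breakpoints each lie
#' within `maxDistance` of the respective parental gene and whose geometry
#' can place the two genes in a transcribable 5'-to-3' adjacency on one
#' resulting strand: deletions and duplications can fuse same-strand
#' neighbours, while inversions (simple or complex) fuse opposite-strand
#' neighbours by flipping one partner.  Interchromosomal gene pairs are
#' always `NO_EVIDENCE` from this intrachromosomal detector.
#'
#' @param svcall Output of [classifySv()].
#' @param geneLoci data.frame with one row per parental gene (5' first):
#'   `gene`, `chrom`, `start`, `end`, `strand` (0-based half-open).
#' @param maxDistance Maximum breakpoint-to-gene distance (default 100 kb).
#' @return list with `status` (`DIRECT_EVIDENCE` / `NO_EVIDENCE`) and
#'   `reason`.
#' @export
matchSvToChimera <- function(svcall, geneLoci, maxDistance = 1e5) {
    stopifnot(nrow(geneLoci) == 2L)
    if (length(unique(geneLoci$chrom)) > 1L)
        return(list(status = "NO_EVIDENCE",
                    reason = "interchromosomal gene pair"))
    if (svcall$sv_type == "NONE")
        return(list(status = "NO_EVIDENCE", reason = "no SV call"))
    bp <- svcall$breakpoints
    dist <- function(pos, g)
        max(0, geneLoci$start[g] - pos, pos - geneLoci$end[g])
    near <- (dist(min(bp), 1) <= maxDistance || dist(min(bp), 2) <= maxDistance) &&
            (dist(max(bp), 1) <= maxDistance || dist(max(bp), 2) <= maxDistance)
    if (!near)
        return(list(status = "NO_EVIDENCE",
                    reason = "breakpoints too distant from parental genes"))
    sameStrand <- geneLoci$strand[1] == geneLoci$strand[2]
    geomOk <- switch(svcall$sv_type,
                     DEL = sameStrand, DUP = sameStrand,
                     INV = !sameStrand, COMPLEX_INV_DEL = !sameStrand,
                     FALSE)
    if (!geomOk)
        return(list(status = "NO_EVIDENCE",
                    reason = "SV geometry cannot place the genes in a transcribable adjacency"))
    list(status = "DIRECT_EVIDENCE", reason = "")
}
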