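#' Confidence filtering of chimeric-RNA predictions
#'
#' Removes low-confidence rows: prediction score below `minScore`
#' (predictions scoring < 0.6 are dropped, i.e. rows with score >= 0.6 are
#' retained), undefined junction positions, and predictions highly similar
#' to annotated transcripts (identity above `maxIdentity`).  Rules are
#' applied in that order and each row is counted against the first rule it
#' violates, so the removal counts sum to the number of rows dropped.
#'
#' @param occurrences ChimeraOccurrence data.frame (requires `score`,
#'   `pos5`, `pos3`; `identity` optional).
#' @param minScore Minimum retained prediction score (default 0.6).
#' @param maxIdentity Maximum identity to annotated transcripts
#'   (default 0.9).
#' @return list with `occurrences` (retained rows) and `removed` (named
#'   counts: `low_score`, `undefined_junction`, `high_identity`).
#' @export
confidenceFilter <- function(occurrences, minScore = 0.6, maxIdentity = 0.9) {
    stopifnot(minScore >= 0, minScore <= 1, maxIdentity >= 0, maxIdentity <= 1)
    if (!"score" %in% names(occurrences))
        stop("prediction table lacks a 'score' column", call. = FALSE)
    lowScore <- is.na(occurrences$score) | occurrences$score < minScore
    undef <- !lowScore & (is.na(occurrences$pos5) | is.na(occurrences$pos3))
    ident <- occurrences$identity %||% rep(0, nrow(occurrences))
    highIdent <- !lowScore & !undef & !is.na(ident) & ident > maxIdentity
    keep <- !(lowScore | undef | highIdent)
    list(occurrences = occurrences[keep, , drop = FALSE],
         removed = c(low_score = sum(lowScore),
                     undefined_junction = sum(undef),
                     high_identity = sum(highIdent)))
}

# Strand-aware annotated edges for one side of a junction, in 0-based
# coordinates.  The donor (5') side must coincide with an exon 3' edge and
# the acceptor (3') side with an exon 5' edge for an E designation.
exonEdges <- function(exons, gene, side, strand) {
    sel <- exons[S4Vectors::mcols(exons)$gene == gene]
    if (!length(sel)) return(integer())
    starts0 <- GenomicRanges::start(sel) - 1L
    ends0 <- GenomicRanges::end(sel)
    if (side == "donor") {
        if (strand == "+") ends0 else starts0
    } else {
        if (strand == "+") starts0 else ends0
    }
}

#' Classify a chimeric junction against exon annotation
#'
#' Each side is labelled `E` (end-of-exon) when the junction position falls
#' within `toleranceBp` of the appropriate annotated exon edge (donor side:
#' exon 3' edge; acceptor side: exon 5' edge; both strand-aware), and `M`
#' (middle-of-exon) otherwise.  Junctions on genes or contigs absent from
#' the annotation are labelled `M` on that side with a warning.
#'
#' @param occurrences ChimeraOccurrence data.frame.
#' @param exons `GRanges` of exons with a `gene` metadata column (e.g.
#'   [exonRanges()]).
#' @param toleranceBp Matching tolerance in bp (default 2).
#' @return Character vector of junction classes (`E_E`, `E_M`, `M_E`,
#'   `M_M`), one per row.
#' @export
classifyJunction <- function(occurrences, exons, toleranceBp = 2L) {
    vapply(seq_len(nrow(occurrences)), function(i) {
        o <- occurrences[i, ]
        sideClass <- function(gene, pos, strand, side) {
            edges <- exonEdges(exons, gene, side, strand)
            if (!length(edges)) {
                warning(sprintf("gene %s absent from annotation; side labelled M",
                                gene), call. = FALSE)
                return("M")
            }
            if (min(abs(edges - pos)) <= toleranceBp) "E" else "M"
        }
        paste(sideClass(o$gene5, o$pos5, o$strand5, "donor"),
              sideClass(o$gene3, o$pos3, o$strand3, "acceptor"), sep = "_")
    }, character(1))
}

# Coding bases of `gene` upstream of 0-based position `pos` in transcription
# order, plus whether any CDS remains downstream.
cdsUpstream <- function(cds, gene, pos, strand) {
    sel <- cds[S4Vectors::mcols(cds)$gene == gene]
    if (!length(sel)) return(list(upstream = NA_integer_, downstream = NA_integer_))
    s0 <- GenomicRanges::start(sel) - 1L
    e0 <- GenomicRanges::end(sel)
    if (strand == "+") {
        up <- sum(pmax(0L, pmin(e0, pos) - s0))
        down <- sum(pmax(0L, e0 - pmax(s0, pos)))
    } else {
        up <- sum(pmax(0L, e0 - pmax(s0, pos)))
        down <- sum(pmax(0L, pmin(e0, pos) - s0))
    }
    list(upstream = up, downstream = down)
}

#' Predict the reading frame of a fusion transcript
#'
#' `IN_FRAME` when the cumulative CDS length contributed by the 5' partner
#' up to the junction is congruent (mod 3) with the CDS phase of the 3'
#' partner at its junction; `FRAMESHIFT` otherwise; `NON_CODING` when
#' either partner contributes no CDS at the junction (5' junction upstream
#' of the CDS, or 3' junction downstream of it).
#'
#' @param occurrences ChimeraOccurrence data.frame.
#' @param cds `GRanges` of CDS intervals with a `gene` metadata column
#'   (e.g. [cdsRanges()]).
#' @return Character vector (`IN_FRAME`, `FRAMESHIFT`, `NON_CODING`).
#' @export
predictFrame <- function(occurrences, cds) {
    vapply(seq_len(nrow(occurrences)), function(i) {
        o <- occurrences[i, ]
        don <- cdsUpstream(cds, o$gene5, o$pos5, o$strand5)
        acc <- cdsUpstream(cds, o$gene3, o$pos3, o$strand3)
        if (is.na(don$upstream) || is.na(acc$upstream)) return("NON_CODING")
        if (don$upstream == 0L || acc$downstream == 0L) return("NON_CODING")
        if (don$upstream %% 3L == acc$upstream %% 3L) "IN_FRAME" else "FRAMESHIFT"
    }, character(1))
}

#' Polymorphic-pattern filter for chimeric RNAs
#'
#' Selects chimeras detected in fewer than `maxIndividuals` unique
#' individuals that are nonetheless broadly expressed within each carrier:
#' under the default `"mean"` aggregation, the mean (over expressing
#' individuals) per-individual sample fraction must exceed
#' `minSampleFraction` and the mean unique-tissue count must exceed
#' `minTissues`; under `"per_individual_all"` every expressing individual
#' must satisfy both thresholds itself.  All inequalities are strict.
#'
#' @param occurrences ChimeraOccurrence data.frame.
#' @param manifest Sample manifest (all samples per individual: columns
#'   `sample_id`, `individual_id`, `tissue`); the denominator for sample
#'   fractions.
#' @param maxIndividuals Selection requires n_individuals < this
#'   (default 250).
#' @param minTissues Selection requires tissue count > this (default 5).
#' @param minSampleFraction Selection requires sample fraction > this
#'   (default 2/3).
#' @param aggregation `"mean"` or `"per_individual_all"`.
#' @return list with `selected` (chimera ids) and `metrics` (per-chimera
#'   `n_individuals`, `mean_sample_fraction`, `mean_tissue_count`,
#'   `selected`).
#' @export
polymorphicFilter <- function(occurrences, manifest, maxIndividuals = 250L,
                              minTissues = 5L, minSampleFraction = 2/3,
                              aggregation = c("mean", "per_individual_all")) {
    aggregation <- match.arg(aggregation)
    stopifnot(maxIndividuals > 0, minTissues > 0,
              minSampleFraction > 0, minSampleFraction <= 1)
    checkColumns(manifest, c("sample_id", "individual_id", "tissue"), "manifest")
    unknown <- setdiff(occurrences$sample_id, manifest$sample_id)
    if (length(unknown))
        stop(sprintf("occurrence references sample(s) absent from manifest: %s",
                     paste(head(unknown, 3), collapse = ", ")), call. = FALSE)
    denom <- table(manifest$individual_id)
    # per (chimera, individual): unique expressing samples and tissues
    key <- paste(occurrences$chimera_id, occurrences$individual_id, sep = "\r")
    sampCnt <- vapply(split(occurrences$sample_id, key),
                      function(x) length(unique(x)), integer(1))
    tisCnt <- vapply(split(occurrences$tissue, key),
                     function(x) length(unique(x)), integer(1))
    parts <- strsplit(names(sampCnt), "\r", fixed = TRUE)
    chim <- vapply(parts, `[[`, character(1), 1L)
    ind <- vapply(parts, `[[`, character(1), 2L)
    frac <- as.numeric(sampCnt) / as.numeric(denom[ind])
    nInd <- tapply(ind, chim, length)
    meanFrac <- tapply(frac, chim, mean)
    meanTis <- tapply(as.numeric(tisCnt), chim, mean)
    ok <- if (aggregation == "mean") {
        meanFrac > minSampleFraction & meanTis > minTissues
    } else {
        tapply(frac > minSampleFraction, chim, all) &
            tapply(tisCnt > minTissues, chim, all)
    }
    metrics <- data.frame(chimera_id = names(nInd),
                          n_individuals = as.integer(nInd),
                          mean_sample_fraction = as.numeric(meanFrac),
                          mean_tissue_count = as.numeric(meanTis),
                          selected = as.integer(nInd) < maxIndividuals &
                              as.logical(ok),
                          stringsAsFactors = FALSE, row.names = NULL)
    list(selected = metrics$chimera_id[metrics$selected], metrics = metrics)
}
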