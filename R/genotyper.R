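#' Validate a breakpoint-query table
#'
#' @param queries data.frame with `query_id`, `role` (`CTRL`,
#'   `DEL_INTERNAL`, `JUNCTION`), `sequence` (uppercase ACGT), `contig`,
#'   `window_start`, `window_end` (0-based half-open target window).
#' @return The validated data.frame, invisibly.
#' @export
validateQueries <- function(queries) {
    checkColumns(queries, c("query_id", "role", "sequence", "contig",
                            "window_start", "window_end"), "queries")
    if (!all(queries$role %in% c("CTRL", "DEL_INTERNAL", "JUNCTION")))
        stop("query role must be CTRL, DEL_INTERNAL or JUNCTION", call. = FALSE)
    if (any(grepl("[^ACGT]", queries$sequence)))
        stop("query sequences must be uppercase ACGT", call. = FALSE)
    w <- queries$window_end - queries$window_start
    if (any(w <= 2L * nchar(queries$sequence)))
        stop("target window must be wider than twice the query length",
             call. = FALSE)
    invisible(queries)
}

#' Approximate matching of a breakpoint query against reads
#'
#' Returns every read containing a substring within Levenshtein distance
#' `maxEdits` of the query on either strand; the reported edit distance is
#' the minimum over positions and strands.  `maxEdits = 0` is an exact
#' (agrep-default) substring search.  Ambiguous bases (`N`) in reads count
#' as mismatches.
#'
#' @param query Query sequence (character scalar, uppercase ACGT) or a
#'   one-row query table (see [validateQueries()]).
#' @param reads Character vector or `DNAStringSet` of read sequences;
#'   names (or indices) become read identifiers.
#' @param maxEdits Maximum edit distance (default 0).
#' @return data.frame with `read_id`, `strand`, `edit_distance`.
#' @export
fuzzyMatch <- function(query, reads, maxEdits = 0L) {
    if (is.data.frame(query)) query <- query$sequence[1]
    if (grepl("[^ACGT]", query))
        stop("query contains non-ACGT symbols", call. = FALSE)
    stopifnot(maxEdits >= 0)
    ids <- names(reads) %||% as.character(seq_along(reads))
    if (is.null(names(reads))) names(reads) <- ids
    seqs <- as.character(reads)
    hit <- cpp_fuzzy_match(query, unname(seqs), as.integer(maxEdits))
    data.frame(read_id = ids[hit$index], strand = hit$strand,
               edit_distance = hit$edit_distance, stringsAsFactors = FALSE)
}

#' Re-map matched reads and classify them by locus
#'
#' Local alignments of each read to the reference are computed by k-mer
#' seeding plus banded Smith-Waterman extension (match +1, mismatch -1,
#' gap -2).  Alignments with score >= `minScore`, identity >= `minIdentity`
#' and score within 1\% of the read's best are retained.  A read is
#' `TRUE_POSITIVE` when all retained loci lie inside the target window,
#' `FALSE_POSITIVE` when none do, and `UNCERTAIN` when both on- and
#' off-target loci are retained.  Reads with no retained alignment are
#' labelled `DROPPED` and excluded from evidence counts.
#'
#' @param reads Character vector / `DNAStringSet` of read sequences (named).
#' @param reference Reference sequence (`DNAString` or character).
#' @param targetWindow Numeric length-2 vector, 0-based half-open window
#'   around the locus of interest (default width 100 kb in query design).
#' @param minScore Minimum alignment score (default 90).
#' @param minIdentity Minimum identity, matches / alignment columns
#'   (default 0.90).
#' @param seedK Seed k-mer size (default 11).
#' @param band Alignment band half-width (default 16).
#' @param chainGap Sub-alignments of one read lying within this distance on
#'   the reference are chained into a single locus alignment (score and
#'   matches summed), so breakpoint-spanning reads whose halves align as
#'   split pieces at one locus still clear `minScore` — the behaviour of
#'   BLAT-style chained alignments (default 20 kb).
#' @return data.frame with `read_id`, `classification`, `n_loci`,
#'   `best_score`, `best_identity`.
#' @export
remapClassify <- function(reads, reference, targetWindow, minScore = 90,
                          minIdentity = 0.90, seedK = 11L, band = 16L,
                          chainGap = 2e4) {
    ids <- names(reads) %||% as.character(seq_along(reads))
    refChar <- as.character(reference)
    hits <- cpp_remap(unname(as.character(reads)), refChar,
                      as.integer(seedK), as.integer(band))
    out <- data.frame(read_id = ids,
                      classification = "DROPPED",
                      n_loci = 0L, best_score = NA_real_,
                      best_identity = NA_real_, stringsAsFactors = FALSE)
    if (!nrow(hits)) return(out)
    for (r in unique(hits$read)) {
        h <- hits[hits$read == r, , drop = FALSE]
        if (!nrow(h)) next
        # Alignments clearing minScore on their own are distinct candidate
        # loci.  Sub-threshold pieces at one locus (a read split across a
        # breakpoint) are chained into a single alignment, with the score
        # and identity thresholds applied to the chain.
        strong <- h$score >= minScore
        chains <- data.frame(score = h$score[strong],
                             identity = h$identity[strong],
                             mid = (h$ref_start[strong] +
                                    h$ref_end[strong]) / 2)
        w <- h[!strong, , drop = FALSE]
        if (nrow(w)) {
            w <- w[order(w$ref_start), , drop = FALSE]
            chainId <- cumsum(c(1, diff(w$ref_start) > chainGap))
            chains <- rbind(chains, do.call(rbind,
                lapply(split(w, chainId), function(p) {
                    data.frame(score = sum(p$score),
                               identity = sum(p$identity * p$score) /
                                   sum(p$score),
                               mid = mean((p$ref_start + p$ref_end) / 2))
                })))
        }
        chains <- chains[chains$score >= minScore &
                         chains$identity >= minIdentity, , drop = FALSE]
        if (!nrow(chains)) next
        best <- max(chains$score)
        chains <- chains[chains$score >= 0.99 * best, , drop = FALSE]
        inWin <- chains$mid >= targetWindow[1] & chains$mid < targetWindow[2]
        cls <- if (all(inWin)) "TRUE_POSITIVE"
               else if (!any(inWin)) "FALSE_POSITIVE"
               else "UNCERTAIN"
        out$classification[r] <- cls
        out$n_loci[r] <- nrow(chains)
        out$best_score[r] <- best
        out$best_identity[r] <- max(chains$identity)
    }
    out
}

#' Apply a boolean genotype rule to per-query evidence counts
#'
#' A query is *present* when its on-target read count reaches the rule's
#' `minReadsPresent`.  The call is `POSITIVE` when the rule expression
#' evaluates true, `NEGATIVE` otherwise, and `NO_CALL` when there is no
#' evidence at all (zero reads across every query).
#'
#' @param counts Named integer vector of TRUE_POSITIVE read counts per
#'   query (names must cover every query referenced by the rule).
#' @param rule A [GenotypeRule-class].
#' @return list with `call`, `present` (named logical) and `counts`.
#' @export
callGenotype <- function(counts, rule) {
    validObject(rule)
    vars <- ruleQueries(rule)
    missing <- setdiff(vars, names(counts))
    if (length(missing))
        stop(sprintf("rule references unknown query/queries: %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
    present <- counts >= rule@minReadsPresent
    call <- if (sum(counts) == 0L) {
        "NO_CALL"
    } else {
        ok <- eval(str2lang(rule@expression), envir = as.list(present))
        if (isTRUE(ok)) "POSITIVE" else "NEGATIVE"
    }
    list(call = call, present = present, counts = counts)
}

#' Design breakpoint-spanning genotyping queries for an SV
#'
#' Builds the query set used by the in-silico genotyping pipeline:
#' one `JUNCTION` query per novel adjacency of the alternate haplotype
#' (centred on the junction), a `DEL_INTERNAL` query inside each deleted
#' interval (present only while a reference allele remains), and a `CTRL`
#' query from unrearranged reference sequence within the target window.
#'
#' @param genome A [ToyGenome-class] (or `DNAString`).
#' @param sv The [SVSpec-class].
#' @param altHap The matching [AltHaplotype-class] from [applySV()].
#' @param width Query width in bp (default 70).
#' @param windowWidth Target-window width centred on the locus
#'   (default 100 kb, clipped to the contig).
#' @return Query data.frame (see [validateQueries()]).
#' @export
designBreakpointQueries <- function(genome, sv, altHap, width = 70L,
                                    windowWidth = 1e5) {
    refSeq <- if (is(genome, "ToyGenome")) genome@sequence else genome
    contig <- if (is(genome, "ToyGenome")) genome@spec@contigName else "ref"
    L <- length(refSeq)
    b <- sv@breakpoints
    centre <- mean(range(b))
    win <- c(max(0, centre - windowWidth / 2), min(L, centre + windowWidth / 2))
    refChar <- as.character(refSeq)
    grab <- function(centre0) {
        lo <- max(0L, as.integer(centre0) - width %/% 2L)
        substr(refChar, lo + 1L, min(L, lo + width))
    }
    rows <- list()
    jn <- altHap@junctions
    for (i in seq_len(nrow(jn))) {
        altChar <- as.character(altHap@sequence)
        lo <- max(0L, jn$alt_pos[i] - width %/% 2L)
        rows[[length(rows) + 1L]] <- data.frame(
            query_id = sprintf("%s_JUNCTION_%d", sv@svId, i), role = "JUNCTION",
            sequence = substr(altChar, lo + 1L,
                              min(length(altHap@sequence), lo + width)),
            stringsAsFactors = FALSE)
    }
    if (sv@svType %in% c("DEL", "COMPLEX_INV_DEL")) {
        del <- if (sv@svType == "DEL") b[1, ] else b[2, ]
        rows[[length(rows) + 1L]] <- data.frame(
            query_id = sprintf("%s_DEL_INTERNAL", sv@svId), role = "DEL_INTERNAL",
            sequence = grab(mean(del)), stringsAsFactors = FALSE)
    }
    # control: reference sequence well clear of every SV interval but inside
    # the window
    margin <- 5L * width
    ctrlPos <- if (min(b) - win[1] > 2 * margin) min(b) - margin
               else max(b) + margin
    rows[[length(rows) + 1L]] <- data.frame(
        query_id = sprintf("%s_CTRL", sv@svId), role = "CTRL",
        sequence = grab(ctrlPos), stringsAsFactors = FALSE)
    q <- do.call(rbind, rows)
    q$contig <- contig
    q$window_start <- as.integer(win[1])
    q$window_end <- as.integer(win[2])
    validateQueries(q)
    q
}

#' Genotype a cohort of read sets
#'
#' Runs the full in-silico genotyping pipeline per sample: approximate
#' query matching against the reads, re-mapping validation of matched
#' reads against the reference, per-query TRUE_POSITIVE counting, and the
#' boolean genotype rule.  A per-population detection summary in the style
#' of a cohort occurrence table is attached.
#'
#' @param readSets Named list (one element per sample) of read sequences
#'   (character vector or `DNAStringSet`), or a manifest data.frame with
#'   columns `sample_id`, `fastq1`, `fastq2` pointing at FASTQ files.
#' @param manifest data.frame with `sample_id`, `population`.
#' @param queries Query table ([validateQueries()]).
#' @param rule A [GenotypeRule-class].
#' @param reference Reference sequence.
#' @param maxEdits Maximum edit distance for query matching (default 0).
#' @param minScore,minIdentity Re-mapping retention thresholds.
#' @param minMeanQuality,maxNFraction Read quality filters applied when
#'   reading FASTQ input (mean Phred and N fraction).
#' @return list with `calls` (per-sample data.frame: call plus per-query
#'   counts) and `summary` (per-population detection rows).
#' @export
genotypeCohort <- function(readSets, manifest, queries, rule, reference,
                           maxEdits = 0L, minScore = 90, minIdentity = 0.90,
                           minMeanQuality = 20, maxNFraction = 0.10) {
    validateQueries(queries)
    checkColumns(manifest, c("sample_id", "population"), "manifest")
    fromFiles <- is.data.frame(readSets)
    sampleIds <- if (fromFiles) readSets$sample_id else names(readSets)
    refChar <- as.character(reference)
    calls <- lapply(seq_along(sampleIds), function(si) {
        sid <- sampleIds[si]
        counts <- setNames(integer(nrow(queries)), queries$query_id)
        missingInput <- FALSE
        reads <- if (fromFiles) {
            paths <- unlist(readSets[si, c("fastq1", "fastq2")])
            if (!all(file.exists(paths))) {
                missingInput <- TRUE
                character()
            } else readFilteredFastq(paths, minMeanQuality, maxNFraction)
        } else readSets[[si]]
        if (missingInput) {
            rolled <- rollupRoles(counts, queries)
            return(cbind(data.frame(sample_id = sid, call = "NO_CALL",
                                    reason = "missing FASTQ",
                                    stringsAsFactors = FALSE),
                         as.data.frame(as.list(rolled))))
        }
        if (is.null(names(reads)))
            names(reads) <- as.character(seq_along(reads))
        for (qi in seq_len(nrow(queries))) {
            m <- fuzzyMatch(queries$sequence[qi], reads, maxEdits)
            if (!nrow(m)) next
            cl <- remapClassify(reads[m$read_id],
                                refChar,
                                c(queries$window_start[qi],
                                  queries$window_end[qi]),
                                minScore = minScore, minIdentity = minIdentity)
            counts[qi] <- sum(cl$classification == "TRUE_POSITIVE")
        }
        rolled <- rollupRoles(counts, queries)
        res <- callGenotype(rolled, rule)
        cbind(data.frame(sample_id = sid, call = res$call, reason = "",
                         stringsAsFactors = FALSE),
              as.data.frame(as.list(rolled)))
    })
    calls <- do.call(rbind, calls)
    det <- merge(manifest, calls[, c("sample_id", "call")], by = "sample_id")
    det$detected <- det$call == "POSITIVE"
    list(calls = calls,
         summary = detectionSummary(det))
}

# Sum per-query counts up to role level so rules can reference roles
# (CTRL, JUNCTION, DEL_INTERNAL) as well as individual query ids.
rollupRoles <- function(counts, queries) {
    roles <- vapply(split(counts, queries$role), sum, integer(1))
    c(counts, roles[setdiff(names(roles), names(counts))])
}

#' Read and quality-filter FASTQ files
#'
#' Drops reads with mean Phred quality below `minMeanQuality` or more than
#' `maxNFraction` ambiguous bases.
#'
#' @param paths FASTQ paths (all are pooled).
#' @param minMeanQuality Minimum mean Phred score (default 20).
#' @param maxNFraction Maximum fraction of N bases (default 0.10).
#' @return Named character vector of read sequences.
#' @export
readFilteredFastq <- function(paths, minMeanQuality = 20, maxNFraction = 0.10) {
    sets <- lapply(paths, Biostrings::readQualityScaledDNAStringSet)
    out <- lapply(sets, function(s) {
        q <- methods::as(Biostrings::quality(s), "IntegerList")
        meanQ <- vapply(q, mean, numeric(1))
        nFrac <- Biostrings::letterFrequency(Biostrings::DNAStringSet(s),
                                             "N")[, 1] / Biostrings::width(s)
        keep <- meanQ >= minMeanQuality & nFrac <= maxNFraction
        setNames(as.character(s)[keep], names(s)[keep])
    })
    unlist(out)
}
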