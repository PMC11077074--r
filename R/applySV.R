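#' Apply a structural variant to a reference sequence
#'
#' Produces the alternate haplotype, the block map relating haplotype to
#' reference coordinates, and one junction record per novel adjacency (the
#' junction-spanning sequence with up to `flank` bases either side).
#'
#' * `DEL` removes the interval.
#' * `DUP` inserts a tandem copy of the interval.
#' * `INV` reverse-complements the interval in place.
#' * `COMPLEX_INV_DEL` applies the inversion, then removes the adjacent
#'   deletion interval.
#'
#' @param reference A `DNAString` (or [ToyGenome-class]).
#' @param sv An [SVSpec-class]; intervals must lie within the reference.
#' @param flank Flank width for junction records (default 70, matching the
#'   width of breakpoint-spanning genotyping queries).
#' @return An [AltHaplotype-class].
#' @export
applySV <- function(reference, sv, flank = 70L) {
    if (is(reference, "ToyGenome")) reference <- reference@sequence
    validObject(sv)
    L <- length(reference)
    b <- sv@breakpoints
    if (any(b > L)) stop("SV interval outside the reference", call. = FALSE)
    seg <- function(s, e, strand = "+") {
        data.frame(ref_start = s, ref_end = e, strand = strand,
                   stringsAsFactors = FALSE)
    }
    segments <- switch(sv@svType,
        DEL = rbind(seg(0L, b[1, 1]), seg(b[1, 2], L)),
        DUP = rbind(seg(0L, b[1, 2]), seg(b[1, 1], L)),
        INV = rbind(seg(0L, b[1, 1]), seg(b[1, 1], b[1, 2], "-"), seg(b[1, 2], L)),
        COMPLEX_INV_DEL = {
            inv <- b[1, ]; del <- b[2, ]
            rbind(seg(0L, inv[1]), seg(inv[1], inv[2], "-"), seg(del[2], L))
        })
    segments <- segments[segments$ref_end > segments$ref_start, , drop = FALSE]
    widths <- segments$ref_end - segments$ref_start
    segments$alt_start <- cumsum(c(0L, widths[-length(widths)]))
    segments$alt_end <- segments$alt_start + widths
    rownames(segments) <- NULL

    pieces <- lapply(seq_len(nrow(segments)), function(i) {
        piece <- Biostrings::subseq(reference, segments$ref_start[i] + 1L,
                                    segments$ref_end[i])
        if (segments$strand[i] == "-") piece <- Biostrings::reverseComplement(piece)
        piece
    })
    alt <- Reduce(Biostrings::xscat, pieces)

    # Novel adjacencies: any inter-segment boundary that is not a trivial
    # forward/forward continuation of the reference.
    jn <- list()
    for (i in seq_len(nrow(segments) - 1L)) {
        a <- segments[i, ]; z <- segments[i + 1L, ]
        trivial <- a$strand == "+" && z$strand == "+" && a$ref_end == z$ref_start
        if (trivial) next
        pos <- a$alt_end
        lo <- max(0L, pos - flank); hi <- min(length(alt), pos + flank)
        jn[[length(jn) + 1L]] <- data.frame(
            junction_id = sprintf("%s_j%d", sv@svId, length(jn) + 1L),
            alt_pos = pos,
            ref_left = if (a$strand == "+") a$ref_end else a$ref_start,
            ref_right = if (z$strand == "+") z$ref_start else z$ref_end,
            seq = as.character(Biostrings::subseq(alt, lo + 1L, hi)),
            stringsAsFactors = FALSE)
    }
    junctions <- if (length(jn)) do.call(rbind, jn) else
        data.frame(junction_id = character(), alt_pos = integer(),
                   ref_left = integer(), ref_right = integer(),
                   seq = character(), stringsAsFactors = FALSE)
    new("AltHaplotype", svId = sv@svId, sequence = alt,
        segments = segments, junctions = junctions)
}

#' Reference haplotype (identity block map)
#'
#' @param reference A `DNAString` (or [ToyGenome-class]).
#' @return An [AltHaplotype-class] with a single forward segment and no
#'   junctions.
#' @export
refHaplotype <- function(reference) {
    if (is(reference, "ToyGenome")) reference <- reference@sequence
    L <- length(reference)
    new("AltHaplotype", svId = "ref", sequence = reference,
        segments = data.frame(ref_start = 0L, ref_end = L, strand = "+",
                              alt_start = 0L, alt_end = L,
                              stringsAsFactors = FALSE),
        junctions = data.frame(junction_id = character(), alt_pos = integer(),
                               ref_left = integer(), ref_right = integer(),
                               seq = character(), stringsAsFactors = FALSE))
}

#' Lift haplotype coordinates to reference coordinates
#'
#' Maps 0-based haplotype positions through the block map.  For positions in
#' inverted blocks the returned strand is `-` and the coordinate is that of
#' the aligned reference base.
#'
#' @param hap An [AltHaplotype-class].
#' @param pos Integer vector of 0-based haplotype positions.
#' @return data.frame with `ref_pos`, `strand`, `segment`.
#' @export
altToRef <- function(hap, pos) {
    s <- hap@segments
    idx <- findInterval(pos, s$alt_start)
    idx[pos < 0 | pos >= max(s$alt_end)] <- NA_integer_
    ref <- ifelse(s$strand[idx] == "+",
                  s$ref_start[idx] + (pos - s$alt_start[idx]),
                  s$ref_end[idx] - 1L - (pos - s$alt_start[idx]))
    data.frame(ref_pos = as.integer(ref), strand = s$strand[idx],
               segment = idx)
}

#' Lift reference coordinates to haplotype coordinates
#'
#' Positions that fall in blocks retained on the haplotype are mapped
#' (inverted blocks map through the reverse complement); deleted positions
#' return `NA`.  Duplicated positions map to their first copy.
#'
#' @param hap An [AltHaplotype-class].
#' @param pos Integer vector of 0-based reference positions.
#' @return Integer vector of 0-based haplotype positions (NA where absent).
#' @export
refToAlt <- function(hap, pos) {
    s <- hap@segments
    out <- rep(NA_integer_, length(pos))
    for (i in seq_len(nrow(s))) {
        hit <- which(is.na(out) & pos >= s$ref_start[i] & pos < s$ref_end[i])
        if (!length(hit)) next
        out[hit] <- if (s$strand[i] == "+")
            s$alt_start[i] + (pos[hit] - s$ref_start[i])
        else
            s$alt_start[i] + (s$ref_end[i] - 1L - pos[hit])
    }
    out
}
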