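#' @import methods
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Toy genome specification
#'
#' Describes a single-contig toy genome: contig name, length, the gene
#' models laid out on it and the seed used to draw the random sequence.
#' Coordinates are 0-based half-open throughout the package; 1-based
#' coordinates appear only in SAM/BED-style emissions.
#'
#' @slot contigName Contig name.
#' @slot length Contig length in bp.
#' @slot genes data.frame with one row per exon: `gene`, `strand` (`+`/`-`),
#'   `start`, `end` (0-based half-open), `cds_start`, `cds_end` (NA for
#'   non-coding exons; must lie within the exon).
#' @slot seed Integer seed for the random background sequence.
#' @export
setClass("ToyGenomeSpec",
         representation(contigName = "character", length = "integer",
                        genes = "data.frame", seed = "integer"))

setValidity("ToyGenomeSpec", function(object) {
    g <- object@genes
    msg <- character()
    if (length(object@length) != 1L || object@length <= 0L)
        msg <- c(msg, "contig length must be a positive integer")
    need <- c("gene", "strand", "start", "end")
    if (nrow(g) && !all(need %in% names(g)))
        msg <- c(msg, paste("genes must have columns", paste(need, collapse = ", ")))
    if (!length(msg) && nrow(g)) {
        if (!all(g$strand %in% c("+", "-")))
            msg <- c(msg, "gene strand must be '+' or '-'")
        if (any(g$start < 0L) || any(g$end > object@length) || any(g$end <= g$start))
            msg <- c(msg, "exon interval outside contig bounds or empty")
        for (gn in unique(g$gene)) {
            e <- g[g$gene == gn, , drop = FALSE]
            if (is.unsorted(e$start, strictly = TRUE))
                msg <- c(msg, sprintf("exons of gene %s are not sorted", gn))
            if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)]))
                msg <- c(msg, sprintf("exons of gene %s overlap", gn))
        }
        if (all(c("cds_start", "cds_end") %in% names(g))) {
            has <- !is.na(g$cds_start)
            if (any(has & (g$cds_start < g$start | g$cds_end > g$end |
                           g$cds_end <= g$cds_start)))
                msg <- c(msg, "CDS intervals must lie within their exon")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ToyGenomeSpec
#'
#' @param contigName Contig name.
#' @param length Contig length (bp).
#' @param genes Exon-level data.frame (see [ToyGenomeSpec-class]).
#' @param seed Seed for the random background sequence.
#' @return A `ToyGenomeSpec`.
#' @export
ToyGenomeSpec <- function(contigName = "toy1", length = 50000L,
                          genes = data.frame(), seed = 1L) {
    if (nrow(genes) && !"cds_start" %in% names(genes)) {
        genes$cds_start <- NA_integer_
        genes$cds_end <- NA_integer_
    }
    new("ToyGenomeSpec", contigName = contigName, length = as.integer(length),
        genes = genes, seed = as.integer(seed))
}

setMethod("show", "ToyGenomeSpec", function(object) {
    cat(sprintf("ToyGenomeSpec: %s (%d bp), %d gene(s), seed %d\n",
                object@contigName, object@length,
                length(unique(object@genes$gene)), object@seed))
})

#' Toy genome: sequence plus annotation
#'
#' @slot spec The generating [ToyGenomeSpec-class].
#' @slot sequence `DNAString` of length `spec@length`.
#' @slot exons `GRanges` of exons with `gene` metadata column.
#' @slot cds `GRanges` of CDS intervals with `gene` metadata column.
#' @export
setClass("ToyGenome",
         representation(spec = "ToyGenomeSpec", sequence = "DNAString",
                        exons = "GRanges", cds = "GRanges"))

setValidity("ToyGenome", function(object) {
    if (length(object@sequence) != object@spec@length)
        "sequence length does not match the specification" else TRUE
})

setMethod("show", "ToyGenome", function(object) {
    cat(sprintf("ToyGenome: %s (%d bp), %d exon(s), %d CDS segment(s)\n",
                object@spec@contigName, length(object@sequence),
                length(object@exons), length(object@cds)))
})

#' @describeIn ToyGenome-class reference sequence accessor
#' @param x A `ToyGenome`.
#' @export
refSequence <- function(x) x@sequence

#' @describeIn ToyGenome-class contig name accessor
#' @export
contigName <- function(x) {
    if (is(x, "ToyGenome")) x@spec@contigName else x@contigName
}

#' @describeIn ToyGenome-class exon annotation accessor
#' @export
exonRanges <- function(x) x@exons

#' @describeIn ToyGenome-class CDS annotation accessor
#' @export
cdsRanges <- function(x) x@cds

#' Structural-variant specification
#'
#' @slot svId Variant identifier.
#' @slot svType One of `DEL`, `DUP`, `INV`, `COMPLEX_INV_DEL`.
#' @slot breakpoints Integer matrix with columns `start`, `end`
#'   (0-based half-open intervals, sorted).  `COMPLEX_INV_DEL` carries
#'   exactly two rows: the inversion interval and the adjacent deletion
#'   interval.
#' @slot expectedFusion Character vector of length two (5' gene, 3' gene)
#'   or length zero.
#' @export
setClass("SVSpec",
         representation(svId = "character", svType = "character",
                        breakpoints = "matrix", expectedFusion = "character"))

setValidity("SVSpec", function(object) {
    msg <- character()
    b <- object@breakpoints
    if (!object@svType %in% c("DEL", "DUP", "INV", "COMPLEX_INV_DEL"))
        msg <- c(msg, "unknown svType")
    if (ncol(b) != 2L || any(b < 0) || any(b[, 2] <= b[, 1]))
        msg <- c(msg, "breakpoints must be non-empty intervals with start < end")
    if (nrow(b) > 1L && is.unsorted(b[, 1], strictly = TRUE))
        msg <- c(msg, "breakpoint intervals must be sorted")
    if (object@svType == "COMPLEX_INV_DEL") {
        if (nrow(b) != 2L) {
            msg <- c(msg, "COMPLEX_INV_DEL needs exactly one inversion and one deletion interval")
        } else if (b[1, 2] != b[2, 1]) {
            msg <- c(msg, "the deletion interval must be adjacent to the inversion interval")
        }
    } else if (nrow(b) != 1L) {
        msg <- c(msg, "simple SV types carry exactly one interval")
    }
    if (!length(object@expectedFusion) %in% c(0L, 2L))
        msg <- c(msg, "expectedFusion must name two genes or be empty")
    if (length(msg)) msg else TRUE
})

#' Construct an SVSpec
#'
#' @param svId Variant identifier.
#' @param svType `DEL`, `DUP`, `INV` or `COMPLEX_INV_DEL`.
#' @param breakpoints Two-column matrix (or length-2 vector) of 0-based
#'   half-open intervals.  For `COMPLEX_INV_DEL` the first row is the
#'   inversion, the second the adjacent deletion.
#' @param expectedFusion Optional ordered gene pair.
#' @return An `SVSpec`.
#' @export
SVSpec <- function(svId, svType, breakpoints, expectedFusion = character()) {
    if (is.null(dim(breakpoints)))
        breakpoints <- matrix(as.integer(breakpoints), ncol = 2, byrow = TRUE)
    storage.mode(breakpoints) <- "integer"
    colnames(breakpoints) <- c("start", "end")
    new("SVSpec", svId = svId, svType = svType, breakpoints = breakpoints,
        expectedFusion = as.character(expectedFusion))
}

setMethod("show", "SVSpec", function(object) {
    iv <- apply(object@breakpoints, 1L, function(r)
        sprintf("[%d,%d)", r[1], r[2]))
    cat(sprintf("SVSpec %s: %s %s%s\n", object@svId, object@svType,
                paste(iv, collapse = " + "),
                if (length(object@expectedFusion))
                    paste0(" -> ", paste(object@expectedFusion, collapse = "-"))
                else ""))
})

#' @describeIn SVSpec-class variant type accessor
#' @param x An `SVSpec`.
#' @export
svType <- function(x) x@svType

#' @describeIn SVSpec-class breakpoint interval accessor
#' @export
svBreakpoints <- function(x) x@breakpoints

#' Alternate haplotype produced by applying an SV
#'
#' @slot svId Identifier of the applied variant (`"ref"` for the trivial
#'   reference haplotype).
#' @slot sequence Haplotype sequence.
#' @slot segments data.frame mapping haplotype to reference space, one row
#'   per colinear block: `ref_start`, `ref_end`, `strand`, `alt_start`,
#'   `alt_end` (all 0-based half-open).
#' @slot junctions data.frame of novel adjacencies: `junction_id`,
#'   `alt_pos` (0-based position of the junction on the haplotype),
#'   `ref_left`, `ref_right` (reference coordinates flanking the junction)
#'   and `seq` (the junction-spanning sequence, +/- 70 bp flanks).
#' @export
setClass("AltHaplotype",
         representation(svId = "character", sequence = "DNAString",
                        segments = "data.frame", junctions = "data.frame"))

setValidity("AltHaplotype", function(object) {
    s <- object@segments
    if (!nrow(s)) return("haplotype needs at least one segment")
    if (sum(s$alt_end - s$alt_start) != length(object@sequence))
        return("segment lengths do not sum to the haplotype length")
    TRUE
})

setMethod("show", "AltHaplotype", function(object) {
    cat(sprintf("AltHaplotype [%s]: %d bp, %d segment(s), %d novel junction(s)\n",
                object@svId, length(object@sequence), nrow(object@segments),
                nrow(object@junctions)))
})

#' @describeIn AltHaplotype-class haplotype sequence accessor
#' @param x An `AltHaplotype`.
#' @export
hapSequence <- function(x) x@sequence

#' @describeIn AltHaplotype-class junction record accessor
#' @export
junctionRecords <- function(x) x@junctions

#' @describeIn AltHaplotype-class reference-segment map accessor
#' @export
hapSegments <- function(x) x@segments

#' Paired-end read-simulation configuration
#'
#' @slot readLength Read length (bp).
#' @slot insertMean Mean insert (fragment) size (bp); must exceed the read
#'   length.
#' @slot insertSd Insert-size standard deviation (bp).
#' @slot coverage Target mean fold coverage.
#' @slot baseErrorRate Per-base substitution error probability (< 0.1).
#' @slot seed Integer seed.
#' @export
setClass("ReadSimConfig",
         representation(readLength = "integer", insertMean = "numeric",
                        insertSd = "numeric", coverage = "numeric",
                        baseErrorRate = "numeric", seed = "integer"))

setValidity("ReadSimConfig", function(object) {
    msg <- character()
    if (object@insertMean <= object@readLength)
        msg <- c(msg, "insertMean must exceed readLength")
    if (object@baseErrorRate < 0 || object@baseErrorRate >= 0.1)
        msg <- c(msg, "baseErrorRate must be in [0, 0.1)")
    if (object@coverage <= 0) msg <- c(msg, "coverage must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a ReadSimConfig
#'
#' @param readLength,insertMean,insertSd,coverage,baseErrorRate,seed See
#'   [ReadSimConfig-class].
#' @return A `ReadSimConfig`.
#' @export
ReadSimConfig <- function(readLength = 100L, insertMean = 350, insertSd = 50,
                          coverage = 30, baseErrorRate = 0.001, seed = 1L) {
    new("ReadSimConfig", readLength = as.integer(readLength),
        insertMean = insertMean, insertSd = insertSd, coverage = coverage,
        baseErrorRate = baseErrorRate, seed = as.integer(seed))
}

setMethod("show", "ReadSimConfig", function(object) {
    cat(sprintf("ReadSimConfig: %dbp reads, insert %g+/-%g, %gx, err %g, seed %d\n",
                object@readLength, object@insertMean, object@insertSd,
                object@coverage, object@baseErrorRate, object@seed))
})

#' Boolean genotype-calling rule
#'
#' A boolean expression over query identifiers/roles with presence
#' predicates, e.g. `"CTRL & JUNCTION & !DEL_INTERNAL"`.  A query is
#' *present* when its on-target (TRUE_POSITIVE) read count reaches
#' `minReadsPresent`.
#'
#' @slot expression The boolean expression (R syntax over query names).
#' @slot minReadsPresent Reads required for presence (default 1).
#' @export
setClass("GenotypeRule",
         representation(expression = "character", minReadsPresent = "integer"))

setValidity("GenotypeRule", function(object) {
    msg <- character()
    if (!isSingleString(object@expression))
        msg <- c(msg, "expression must be a single string")
    if (object@minReadsPresent < 1L)
        msg <- c(msg, "minReadsPresent must be >= 1")
    parsed <- tryCatch(str2lang(object@expression), error = function(e) NULL)
    if (is.null(parsed)) msg <- c(msg, "expression does not parse")
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypeRule
#'
#' @param expression Boolean expression over query names (R syntax:
#'   `&`, `|`, `!`, parentheses).
#' @param minReadsPresent On-target reads required to count a query as
#'   present.
#' @return A `GenotypeRule`.
#' @export
GenotypeRule <- function(expression, minReadsPresent = 1L) {
    new("GenotypeRule", expression = expression,
        minReadsPresent = as.integer(minReadsPresent))
}

setMethod("show", "GenotypeRule", function(object) {
    cat(sprintf("GenotypeRule: %s (present >= %d read(s))\n",
                object@expression, object@minReadsPresent))
})

ruleQueries <- function(rule) all.vars(str2lang(rule@expression))
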