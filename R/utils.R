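#' @importFrom stats rbinom rnorm runif median setNames complete.cases
#'   pchisq glm binomial coef glm.control lm pnorm quantile
#' @importFrom utils head tail write.table read.delim
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores whatever state was in place before.  All generators in the
#' package route their randomness through this helper so that every
#' simulation is a pure function of its configuration plus seed.
#'
#' @param seed Integer scalar seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    code
}

# Round half away from zero, the convention used for printed percentages
# (base round() rounds half to even).
roundHalfUp <- function(x, digits = 1) {
    m <- 10^digits
    sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive a stream-specific child seed from a master seed, kept within the
# 32-bit integer range.
childSeed <- function(seed, stream) {
    as.integer((as.numeric(seed) * 1103515245 + stream * 12345) %% .Machine$integer.max)
}

isSingleString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

checkColumns <- function(df, required, what = "table") {
    missing <- setdiff(required, names(df))
    if (length(missing)) {
        stop(sprintf("%s is missing required column(s): %s",
                     what, paste(missing, collapse = ", ")), call. = FALSE)
    }
    invisible(df)
}

# Reverse-complement for plain character vectors.
revComp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write a TSV with a provenance header line
#'
#' The first line is a `#`-prefixed provenance record echoing the producing
#' stage and its parameters, so every table is self-describing.  Content is
#' deterministic for fixed inputs (no timestamps).
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param stage Stage name recorded in the header.
#' @param params Named list echoed into the header.
#' @return `path`, invisibly.
#' @export
writeProvTsv <- function(df, path, stage = "polyfusion", params = list()) {
    hdr <- sprintf("#polyfusion\tstage=%s%s", stage,
                   if (length(params)) {
                       paste0("\t", paste(names(params),
                                          vapply(params, function(p)
                                              paste(format(p, trim = TRUE), collapse = ","),
                                              character(1)),
                                          sep = "=", collapse = "\t"))
                   } else "")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE, col.names = TRUE))
    invisible(path)
}

#' Read a provenance-headed TSV
#'
#' @param path Input path.
#' @param required Character vector of required column names.
#' @return data.frame.
#' @export
readProvTsv <- function(path, required = NULL) {
    df <- read.delim(path, comment.char = "#", sep = "\t",
                     stringsAsFactors = FALSE, check.names = FALSE)
    if (!is.null(required)) checkColumns(df, required, what = basename(path))
    df
}
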