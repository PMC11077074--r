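#' Alternate-allele frequency from genotype counts
#'
#' @param counts Numeric vector `c(n0, n1, n2)` of genotype counts
#'   (reference homozygote, heterozygote, alternate homozygote).
#' @return `(n1 + 2 n2) / (2 N)`, or `NA` when `N = 0`.
#' @export
alleleFrequency <- function(counts) {
    stopifnot(length(counts) == 3L, all(counts >= 0))
    n <- sum(counts)
    if (n == 0) return(NA_real_)
    unname((counts[2] + 2 * counts[3]) / (2 * n))
}

#' Hardy-Weinberg equilibrium test
#'
#' Chi-square goodness-of-fit of observed genotype counts against the
#' Hardy-Weinberg expectation `(p^2, 2pq, q^2) * N` with the allele
#' frequency estimated from the data (1 degree of freedom), without
#' continuity correction.  An exact test (conditional on the observed
#' allele counts, summing the probabilities of heterozygote counts no more
#' probable than the observed one) is available for small samples.
#'
#' @param counts `c(n0, n1, n2)` genotype counts.
#' @param exact Use the exact test instead of chi-square (default FALSE).
#' @return list with `chi_square`, `df`, `p_value`, `expected`, `method`.
#' @export
hweTest <- function(counts, exact = FALSE) {
    stopifnot(length(counts) == 3L, all(counts >= 0))
    n <- sum(counts)
    if (n == 0) stop("no individuals", call. = FALSE)
    q <- alleleFrequency(counts)   # alternate-allele frequency
    p <- 1 - q
    expected <- n * c(p^2, 2 * p * q, q^2)
    if (q %in% c(0, 1)) {
        return(list(chi_square = 0, df = 1L, p_value = 1,
                    expected = expected, method = "chisq"))
    }
    if (exact) {
        pval <- hweExactP(counts)
        chi <- sum((counts - expected)^2 / expected)
        return(list(chi_square = chi, df = 1L, p_value = pval,
                    expected = expected, method = "exact"))
    }
    chi <- sum((counts - expected)^2 / expected)
    list(chi_square = chi, df = 1L,
         p_value = stats::pchisq(chi, df = 1L, lower.tail = FALSE),
         expected = expected, method = "chisq")
}

# Exact HWE p-value: enumerate heterozygote counts compatible with the
# observed allele counts and sum the probabilities of outcomes no more
# likely than the observed one.
hweExactP <- function(counts) {
    n <- sum(counts)
    nAlt <- counts[2] + 2 * counts[3]
    nHetObs <- counts[2]
    hets <- seq(nAlt %% 2, min(nAlt, 2 * n - nAlt), by = 2)
    logProb <- vapply(hets, function(h) {
        homAlt <- (nAlt - h) / 2
        homRef <- n - h - homAlt
        lgamma(n + 1) - lgamma(homRef + 1) - lgamma(h + 1) -
            lgamma(homAlt + 1) + h * log(2) +
            lgamma(nAlt + 1) + lgamma(2 * n - nAlt + 1) - lgamma(2 * n + 1)
    }, numeric(1))
    prob <- exp(logProb - max(logProb))
    prob <- prob / sum(prob)
    min(1, sum(prob[prob <= prob[match(nHetObs, hets)] + 1e-12]))
}

#' Per-population detection summary
#'
#' Produces occurrence-table rows (population, detected, total, percentage
#' to one decimal, rounded half-up) from per-sample detection flags.
#'
#' @param detections data.frame with `population` and logical `detected`;
#'   optional `description` per population.
#' @return data.frame with `population`, `description`, `detected`,
#'   `total`, `percentage`.
#' @export
detectionSummary <- function(detections) {
    checkColumns(detections, c("population", "detected"), "detections")
    desc <- if ("description" %in% names(detections)) {
        tapply(detections$description, detections$population, function(x) x[1])
    } else NULL
    pops <- unique(detections$population)
    if (!length(pops)) {
        return(data.frame(population = character(),
                          description = character(), detected = integer(),
                          total = integer(), percentage = numeric(),
                          stringsAsFactors = FALSE))
    }
    rows <- lapply(pops, function(p) {
        d <- detections[detections$population == p, ]
        tot <- nrow(d)
        det <- sum(d$detected)
        data.frame(population = p,
                   description = if (is.null(desc)) p else unname(desc[p]),
                   detected = det, total = tot,
                   percentage = if (tot == 0) NA_real_
                                else roundHalfUp(100 * det / tot, 1),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
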