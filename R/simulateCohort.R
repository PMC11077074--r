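#' Sample a Hardy-Weinberg cohort
#'
#' Draws each individual's genotype as Binomial(2, allele frequency) within
#' its population, i.e. exact Hardy-Weinberg sampling.
#'
#' @param populations data.frame with columns `label`, `allele_frequency`
#'   (in \[0,1\]) and `n` (>= 0 individuals).
#' @param seed Integer seed.
#' @return data.frame with `individual_id`, `population`, `genotype`.
#' @export
sampleCohort <- function(populations, seed = 1L) {
    checkColumns(populations, c("label", "allele_frequency", "n"), "populations")
    stopifnot(all(populations$allele_frequency >= 0),
              all(populations$allele_frequency <= 1),
              all(populations$n >= 0))
    withSeed(seed, {
        rows <- lapply(seq_len(nrow(populations)), function(i) {
            p <- populations[i, ]
            if (p$n == 0) return(NULL)
            data.frame(
                individual_id = sprintf("%s_ind%04d", p$label, seq_len(p$n)),
                population = p$label,
                genotype = rbinom(p$n, 2L, p$allele_frequency),
                stringsAsFactors = FALSE)
        })
        do.call(rbind, rows)
    })
}

#' Attach multi-tissue samples to a cohort
#'
#' Emulates a donor/tissue design: each individual contributes one sample
#' per drawn tissue.
#'
#' @param cohort Output of [sampleCohort()].
#' @param tissues Character vector of tissue labels.
#' @param samplesPerDonor Samples per individual (default: one per tissue).
#' @param seed Integer seed.
#' @return data.frame with `sample_id`, `individual_id`, `tissue`.
#' @export
addTissueSamples <- function(cohort, tissues, samplesPerDonor = length(tissues),
                             seed = 1L) {
    withSeed(seed, {
        rows <- lapply(seq_len(nrow(cohort)), function(i) {
            tt <- if (samplesPerDonor <= length(tissues))
                sample(tissues, samplesPerDonor)
            else sample(tissues, samplesPerDonor, replace = TRUE)
            data.frame(
                sample_id = sprintf("%s_s%02d", cohort$individual_id[i],
                                    seq_along(tt)),
                individual_id = cohort$individual_id[i], tissue = tt,
                stringsAsFactors = FALSE)
        })
        do.call(rbind, rows)
    })
}

#' Simulate a chimeric-RNA prediction table
#'
#' For every sample and chimera, an occurrence row is emitted with the
#' carrier expression probability when the sample's donor carries the
#' linked variant (genotype > 0), and with the genotype-independent
#' background ("trans-splicing") probability otherwise.  Chimeras without a
#' linked variant (`sv_id` NA) are pure-background decoys.  Each row
#' carries donor, tissue, junction coordinates and a confidence score.
#'
#' @param samples Output of [addTissueSamples()].
#' @param cohort Output of [sampleCohort()] (supplies genotypes).
#' @param chimeras data.frame with columns `chimera_id`, `gene5`, `gene3`,
#'   `sv_id` (NA for genotype-independent chimeras), `carrier_prob`,
#'   `background_prob`; optional `chrom5`, `pos5`, `strand5`, `chrom3`,
#'   `pos3`, `strand3`, `score_shape1`, `score_shape2`.
#' @param seed Integer seed.
#' @return ChimeraOccurrence data.frame (one row per detected occurrence).
#' @export
simulateChimeraTable <- function(samples, cohort, chimeras, seed = 1L) {
    checkColumns(chimeras, c("chimera_id", "gene5", "gene3", "sv_id",
                             "carrier_prob", "background_prob"), "chimeras")
    stopifnot(all(chimeras$carrier_prob >= 0 & chimeras$carrier_prob <= 1),
              all(chimeras$background_prob >= 0 & chimeras$background_prob <= 1))
    geno <- setNames(cohort$genotype, cohort$individual_id)
    withSeed(seed, {
        out <- lapply(seq_len(nrow(chimeras)), function(i) {
            ch <- chimeras[i, ]
            carrier <- if (is.na(ch$sv_id)) rep(FALSE, nrow(samples))
                       else geno[samples$individual_id] > 0L
            p <- ifelse(carrier, ch$carrier_prob, ch$background_prob)
            hit <- runif(nrow(samples)) < p
            if (!any(hit)) return(NULL)
            n <- sum(hit)
            a <- ch$score_shape1 %||% 8; b <- ch$score_shape2 %||% 2
            if (is.na(a)) a <- 8
            if (is.na(b)) b <- 2
            data.frame(
                chimera_id = ch$chimera_id,
                gene5 = ch$gene5, gene3 = ch$gene3,
                chrom5 = ch$chrom5 %||% "toy1", pos5 = ch$pos5 %||% 0L,
                strand5 = ch$strand5 %||% "+",
                chrom3 = ch$chrom3 %||% "toy1", pos3 = ch$pos3 %||% 0L,
                strand3 = ch$strand3 %||% "+",
                score = stats::rbeta(n, a, b),
                identity = runif(n, 0.3, 0.88),
                sample_id = samples$sample_id[hit],
                individual_id = samples$individual_id[hit],
                tissue = samples$tissue[hit],
                stringsAsFactors = FALSE)
        })
        out <- out[!vapply(out, is.null, logical(1))]
        if (!length(out)) {
            return(data.frame(chimera_id = character(), gene5 = character(),
                              gene3 = character(), chrom5 = character(),
                              pos5 = integer(), strand5 = character(),
                              chrom3 = character(), pos3 = integer(),
                              strand3 = character(), score = numeric(),
                              identity = numeric(), sample_id = character(),
                              individual_id = character(), tissue = character(),
                              stringsAsFactors = FALSE))
        }
        do.call(rbind, out)
    })
}

#' Simulate phenotype codes and covariates
#'
#' Code presence is drawn per individual from a logistic model
#' `logit(p) = logit(prevalence) + log(OR) * g`, with `g` the genotype
#' under the chosen disease model.  Covariates (age, sex at birth and five
#' ancestry principal components with population-specific mean shifts) are
#' generated alongside; their effects default to zero so the planted
#' genotype effect is the only structured signal.
#'
#' @param cohort Output of [sampleCohort()].
#' @param codes Character vector of code identifiers.
#' @param baselinePrevalence Named (or recycled) per-code baseline
#'   prevalence.
#' @param planted Optional list with `code` and `odds_ratio` (> 0); all
#'   other codes behave as OR = 1.
#' @param model `"dominant"` (g = carrier 0/1) or `"additive"`
#'   (g = allele count 0/1/2).
#' @param seed Integer seed.
#' @return list with `phenotypes` (rows `individual_id`, `code` for present
#'   codes), `covariates` (age, sex, PC1..PC5 per individual) and `truth`.
#' @export
simulatePhenotypes <- function(cohort, codes, baselinePrevalence = 0.05,
                               planted = NULL, model = c("dominant", "additive"),
                               seed = 1L) {
    model <- match.arg(model)
    if (!is.null(planted)) stopifnot(planted$odds_ratio > 0)
    prev <- rep_len(baselinePrevalence, length(codes))
    names(prev) <- codes
    n <- nrow(cohort)
    g <- if (model == "dominant") as.numeric(cohort$genotype > 0)
         else as.numeric(cohort$genotype)
    withSeed(seed, {
        popIdx <- as.integer(factor(cohort$population))
        covariates <- data.frame(
            individual_id = cohort$individual_id,
            age = round(runif(n, 20, 80)),
            sex = sample(c("M", "F"), n, replace = TRUE),
            stringsAsFactors = FALSE)
        for (k in 1:5) {
            shift <- if (k <= 2) (popIdx - mean(popIdx)) * (3 - k) else 0
            covariates[[paste0("PC", k)]] <- rnorm(n) + shift
        }
        rows <- lapply(codes, function(cd) {
            if (prev[cd] <= 0) return(NULL)
            beta <- if (!is.null(planted) && cd == planted$code)
                log(planted$odds_ratio) else 0
            eta <- stats::qlogis(prev[cd]) + beta * g
            hit <- runif(n) < stats::plogis(eta)
            if (!any(hit)) return(NULL)
            data.frame(individual_id = cohort$individual_id[hit], code = cd,
                       stringsAsFactors = FALSE)
        })
        rows <- rows[!vapply(rows, is.null, logical(1))]
        phen <- if (length(rows)) do.call(rbind, rows) else
            data.frame(individual_id = character(), code = character(),
                       stringsAsFactors = FALSE)
        list(phenotypes = phen, covariates = covariates,
             truth = list(planted = planted, model = model,
                          baseline_prevalence = prev))
    })
}
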