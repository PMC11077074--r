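#' Filter clinical codes for association testing
#'
#' Retains codes with at least `minTotal` total instances (unique donors
#' carrying the code) including at least `minInExperimental` instances in
#' the experimental (carrier) group.  The number of retained codes is the
#' multiple-testing burden `m`.
#'
#' @param phenotypes data.frame of present codes (`individual_id`, `code`).
#' @param carriers Character vector of carrier individual ids (the
#'   experimental group).
#' @param minTotal Minimum total instances (default 20).
#' @param minInExperimental Minimum carrier instances (default 1).
#' @return Character vector of eligible codes.
#' @export
filterCodes <- function(phenotypes, carriers, minTotal = 20L,
                        minInExperimental = 1L) {
    checkColumns(phenotypes, c("individual_id", "code"), "phenotypes")
    phen <- unique(phenotypes[, c("individual_id", "code")])
    tot <- table(phen$code)
    inExp <- table(phen$code[phen$individual_id %in% carriers])
    codes <- names(tot)[tot >= minTotal]
    codes[codes %in% names(inExp)[inExp >= minInExperimental]]
}

#' Covariate-adjusted logistic association of one code with genotype
#'
#' Maximum-likelihood logistic regression (IRLS, tolerance 1e-8, up to 100
#' iterations) of code presence on the coded genotype plus covariates,
#' with a Wald test on the genotype coefficient and the odds ratio as the
#' natural exponent of the log-odds coefficient.  Perfect separation is
#' flagged and no Wald p-value is reported for it.
#'
#' @param code Code identifier (for labelling).
#' @param y Logical/0-1 outcome per individual.
#' @param g Genotype coding per individual (0/1 dominant or 0/1/2
#'   additive).
#' @param covariates Optional data.frame of covariates (rows aligned with
#'   `y`); collinear columns are dropped with a warning.
#' @param family `"logistic"` (default) or `"linear"` (ordinary least
#'   squares on the binary outcome, as in additive-model phenome scans).
#' @return One-row data.frame: `code`, `model`, `beta`, `odds_ratio`,
#'   `p_value`, `n_cases`, `n_total`, `separation`.
#' @export
fitCodeAssociation <- function(code, y, g, covariates = NULL,
                               family = c("logistic", "linear")) {
    family <- match.arg(family)
    y <- as.numeric(y)
    if (length(unique(g)) < 2L)
        stop("genotype column is constant; degenerate design", call. = FALSE)
    if (sum(y) == 0 || sum(y) == length(y))
        stop("need at least one case and one control", call. = FALSE)
    dat <- data.frame(y = y, g = as.numeric(g))
    if (!is.null(covariates)) {
        covariates <- as.data.frame(covariates)
        for (nm in names(covariates)) {
            v <- covariates[[nm]]
            if (is.character(v)) v <- factor(v)
            dat[[nm]] <- v
        }
        # drop collinear / constant covariates
        for (nm in names(covariates)) {
            if (length(unique(dat[[nm]])) < 2L) {
                warning(sprintf("covariate %s is constant; dropped", nm),
                        call. = FALSE)
                dat[[nm]] <- NULL
            }
        }
        X <- stats::model.matrix(~ ., dat[, -1, drop = FALSE])
        qrX <- qr(X)
        if (qrX$rank < ncol(X)) {
            bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
            badCov <- unique(unlist(lapply(names(covariates), function(nm)
                if (any(startsWith(bad, nm))) nm else NULL)))
            for (nm in badCov) {
                warning(sprintf("covariate %s is collinear; dropped", nm),
                        call. = FALSE)
                dat[[nm]] <- NULL
            }
        }
    }
    if (family == "logistic") {
        fit <- suppressWarnings(
            glm(y ~ ., data = dat, family = binomial(),
                control = glm.control(epsilon = 1e-8, maxit = 100)))
        beta <- coef(fit)[["g"]]
        mu <- fit$fitted.values
        separated <- !fit$converged || any(mu < 1e-8 | mu > 1 - 1e-8) &&
            abs(beta) > 10
        se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))[["g"]]
        p <- if (separated) NA_real_ else
            2 * pnorm(-abs(beta / se))
        or <- exp(beta)
    } else {
        fit <- lm(y ~ ., data = dat)
        sm <- summary(fit)$coefficients
        beta <- sm["g", "Estimate"]
        p <- sm["g", "Pr(>|t|)"]
        or <- NA_real_
        separated <- FALSE
    }
    data.frame(code = code,
               model = if (family == "logistic") "dominant_logistic"
                       else "additive_linear",
               beta = beta, odds_ratio = or, p_value = p,
               n_cases = sum(y), n_total = length(y),
               separation = separated, stringsAsFactors = FALSE)
}

#' Phenome-wide association scan
#'
#' Tests one variant against every eligible code under a dominant model
#' (carrier indicator, logistic regression) or an additive model (allele
#' count; ordinary linear regression on the binary outcome by default, the
#' convention of standard phenome-scan tooling, with a logistic option),
#' adjusting for the supplied covariates (typically age, sex and five
#' ancestry principal components).  Bonferroni correction is applied over
#' the tested set.
#'
#' @param phenotypes data.frame of present codes (`individual_id`, `code`).
#' @param genotypes data.frame with `individual_id`, `genotype` (0/1/2).
#' @param covariates data.frame with `individual_id` plus covariate
#'   columns.
#' @param model `"dominant"` or `"additive"`.
#' @param additiveFamily `"linear"` (default) or `"logistic"` for the
#'   additive model.
#' @param minTotal,minInExperimental Code-eligibility thresholds (see
#'   [filterCodes()]).
#' @param alpha Significance level for the `significant` flag
#'   (Bonferroni-adjusted; default 0.05).
#' @return data.frame of association results sorted by p-value, with
#'   `p_bonferroni = min(1, m * p)` and `neg_log10_p` for rank plots.
#' @export
phewas <- function(phenotypes, genotypes, covariates = NULL,
                   model = c("dominant", "additive"),
                   additiveFamily = c("linear", "logistic"),
                   minTotal = 20L, minInExperimental = 1L, alpha = 0.05) {
    model <- match.arg(model)
    additiveFamily <- match.arg(additiveFamily)
    checkColumns(genotypes, c("individual_id", "genotype"), "genotypes")
    ids <- genotypes$individual_id
    g <- if (model == "dominant") as.numeric(genotypes$genotype > 0)
         else as.numeric(genotypes$genotype)
    if (length(unique(g)) < 2L) {
        warning("genotype has no variation; no tests run", call. = FALSE)
        return(data.frame())
    }
    covs <- NULL
    if (!is.null(covariates)) {
        covs <- covariates[match(ids, covariates$individual_id),
                           setdiff(names(covariates), "individual_id"),
                           drop = FALSE]
    }
    carriers <- ids[genotypes$genotype > 0]
    codes <- filterCodes(phenotypes, carriers, minTotal, minInExperimental)
    m <- length(codes)
    fam <- if (model == "dominant") "logistic" else additiveFamily
    res <- lapply(codes, function(cd) {
        y <- ids %in% phenotypes$individual_id[phenotypes$code == cd]
        r <- tryCatch(fitCodeAssociation(cd, y, g, covs, family = fam),
                      error = function(e) NULL)
        if (is.null(r)) {
            warning(sprintf("code %s: degenerate fit; skipped", cd),
                    call. = FALSE)
        }
        r
    })
    res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
    if (is.null(res) || !nrow(res)) return(data.frame())
    res$m_tests <- m
    res$p_bonferroni <- pmin(1, res$p_value * m)
    res$significant <- !is.na(res$p_bonferroni) & res$p_bonferroni < alpha
    res$neg_log10_p <- -log10(res$p_value)
    res[order(res$p_value), ]
}
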