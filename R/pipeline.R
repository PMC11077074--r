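#' Default demonstration pipeline configuration
#'
#' A compact end-to-end configuration: a 20-kb two-gene locus, one complex
#' inversion-plus-deletion allele segregating at different frequencies in
#' three populations, multi-tissue chimera expression, paired-end reads
#' and phenotype codes.
#'
#' @param outdir Output directory.
#' @param seed Global seed; stage seeds are derived from it.
#' @return Nested configuration list accepted by [runPipeline()].
#' @export
demoConfig <- function(outdir = tempfile("polyfusion_run_"), seed = 42L) {
    list(
        seed = seed,
        outdir = outdir,
        genome = list(contig_name = "toy1", length = 20000L),
        sv = list(sv_id = "cx1", sv_type = "COMPLEX_INV_DEL",
                  breakpoints = list(c(8000L, 11000L), c(11000L, 12200L)),
                  expected_fusion = c("geneA", "geneB")),
        cohort = list(populations = data.frame(
            label = c("POPA", "POPB", "POPC"),
            allele_frequency = c(0.10, 0.0, 0.02),
            n = c(30L, 30L, 30L))),
        tissues = list(labels = paste0("tissue", 1:8), samples_per_donor = 8L),
        chimera = list(carrier_prob = 0.9, background_prob = 0.005,
                       n_decoys = 10L, decoy_prob = 0.08),
        reads = list(read_length = 100L, insert_mean = 350, insert_sd = 50,
                     coverage = 15, base_error_rate = 0.001,
                     n_wgs_samples = 12L),
        catalog = list(min_score = 0.6, max_identity = 0.9,
                       max_individuals = 250L, min_tissues = 5L,
                       min_sample_fraction = 2 / 3, aggregation = "mean"),
        genotype = list(max_edits = 0L, min_score = 90, min_identity = 0.90,
                        rule = "CTRL & JUNCTION"),
        sv_evidence = list(min_support = 3L, gain_threshold = 1.3,
                           loss_threshold = 0.7),
        phenotypes = list(codes = sprintf("code%03d", 1:30),
                          baseline_prevalence = 0.08,
                          planted = NULL, model = "dominant"),
        association = list(min_total = 10L, min_in_experimental = 1L)
    )
}

requireKeys <- function(config, keys, where) {
    missing <- keys[!vapply(keys, function(k) !is.null(config[[k]]), logical(1))]
    if (length(missing))
        stop(sprintf("configuration is missing key(s) under %s: %s", where,
                     paste(missing, collapse = ", ")), call. = FALSE)
}

#' Run the polymorphic-fusion pipeline end to end
#'
#' Executes the stages in dependency order — simulate (genome, SV allele,
#' cohort, reads, chimera and phenotype tables), catalog (confidence +
#' polymorphic filters, junction classes, frames), genotype (breakpoint
#' queries against each sample's reads), sv-evidence (discordant-pair
#' classification on one carrier and one non-carrier), popgen (allele
#' frequency, Hardy-Weinberg, detection summary) and associate (code
#' screen) — writing provenance-headed TSVs plus a JSON run manifest.
#' A stage failure halts downstream stages.  Outputs are byte-identical
#' for a fixed configuration and seed.
#'
#' @param config Configuration list (see [demoConfig()]) or a YAML path.
#' @param stages Character vector of stages to run (default all).
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json` in `outdir`.
#' @export
runPipeline <- function(config, stages = c("simulate", "catalog", "genotype",
                                           "sv_evidence", "popgen",
                                           "associate")) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    requireKeys(config, c("seed", "outdir", "genome", "sv", "cohort",
                          "reads", "genotype"), "top level")
    requireKeys(config$genome, c("contig_name", "length"), "genome")
    requireKeys(config$sv, c("sv_id", "sv_type", "breakpoints"), "sv")
    outdir <- config$outdir
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(config$seed)
    manifest <- list(stages = list(), seed = seed, outdir = outdir)
    note <- function(stage, status, outputs = character()) {
        manifest$stages[[stage]] <<- list(
            status = status, outputs = outputs,
            output_md5 = as.list(unname(tools::md5sum(
                outputs[file.exists(outputs)]))))
        message(sprintf("[polyfusion] stage=%s seed=%d status=%s", stage,
                        seed, status))
    }

    env <- new.env(parent = emptyenv())
    runStage <- function(stage, fun) {
        if (!stage %in% stages) return(invisible())
        ok <- tryCatch({ fun(); TRUE },
                       error = function(e) {
                           note(stage, paste("FAILED:", conditionMessage(e)))
                           FALSE
                       })
        if (!ok) {
            manifest$status <<- "failed"
            writeManifest(manifest, outdir)
            stop(sprintf("stage %s failed; downstream stages halted", stage),
                 call. = FALSE)
        }
    }

    runStage("simulate", function() {
        gcfg <- config$genome
        genes <- gcfg$genes %||% toyOpposingGenes(gcfg$length)
        spec <- ToyGenomeSpec(gcfg$contig_name, gcfg$length, genes,
                              seed = childSeed(seed, 1))
        env$genome <- buildGenome(spec)
        bp <- do.call(rbind, lapply(config$sv$breakpoints, function(x)
            as.integer(x)))
        env$sv <- SVSpec(config$sv$sv_id, config$sv$sv_type, bp,
                         config$sv$expected_fusion %||% character())
        env$alt <- applySV(env$genome, env$sv)
        env$refHap <- refHaplotype(env$genome)
        env$cohort <- sampleCohort(as.data.frame(config$cohort$populations),
                                   seed = childSeed(seed, 2))
        tis <- config$tissues %||% list(labels = paste0("tissue", 1:8),
                                        samples_per_donor = 8L)
        env$samples <- addTissueSamples(env$cohort, tis$labels,
                                        tis$samples_per_donor,
                                        seed = childSeed(seed, 3))
        ch <- config$chimera %||% list(carrier_prob = 0.9,
                                       background_prob = 0.005,
                                       n_decoys = 10L, decoy_prob = 0.08)
        nd <- ch$n_decoys %||% 10L
        chim <- rbind(
            data.frame(chimera_id = paste0(config$sv$sv_id, "_fusion"),
                       gene5 = (config$sv$expected_fusion %||% c("geneA", "geneB"))[1],
                       gene3 = (config$sv$expected_fusion %||% c("geneA", "geneB"))[2],
                       sv_id = config$sv$sv_id,
                       carrier_prob = ch$carrier_prob,
                       background_prob = ch$background_prob,
                       stringsAsFactors = FALSE),
            if (nd > 0) data.frame(
                chimera_id = sprintf("decoy%02d", seq_len(nd)),
                gene5 = "geneA", gene3 = "geneB", sv_id = NA_character_,
                carrier_prob = 0, background_prob = ch$decoy_prob,
                stringsAsFactors = FALSE))
        env$chimeras <- simulateChimeraTable(env$samples, env$cohort, chim,
                                             seed = childSeed(seed, 4))
        # junction coordinates of the planted fusion: exon edges of the
        # parental genes
        rcfg <- config$reads
        env$readCfgBase <- rcfg
        nW <- min(rcfg$n_wgs_samples %||% nrow(env$cohort), nrow(env$cohort))
        # WGS for a genotype-stratified subset: carriers first
        ord <- order(-env$cohort$genotype)
        env$wgsIdx <- sort(ord[seq_len(nW)])
        env$readSets <- lapply(env$wgsIdx, function(i) {
            cfgi <- ReadSimConfig(rcfg$read_length, rcfg$insert_mean,
                                  rcfg$insert_sd, rcfg$coverage,
                                  rcfg$base_error_rate,
                                  seed = childSeed(seed, 100 + i))
            simulateWgs(env$refHap, env$alt, env$cohort$genotype[i], cfgi,
                        contig = gcfg$contig_name)
        })
        names(env$readSets) <- env$cohort$individual_id[env$wgsIdx]
        ph <- config$phenotypes %||% list(codes = sprintf("code%03d", 1:30),
                                          baseline_prevalence = 0.08,
                                          planted = NULL, model = "dominant")
        env$phen <- simulatePhenotypes(env$cohort, ph$codes,
                                       ph$baseline_prevalence,
                                       planted = ph$planted,
                                       model = ph$model %||% "dominant",
                                       seed = childSeed(seed, 5))
        writeGenomeFasta(env$genome, file.path(outdir, "reference.fasta"))
        writeGenomeFasta(list(alt = env$alt@sequence),
                         file.path(outdir, "haplotype_alt.fasta"))
        writeAnnotationBed(env$genome, file.path(outdir, "annotation.bed"))
        writeProvTsv(env$cohort, file.path(outdir, "cohort_truth.tsv"),
                     "simulate", list(seed = seed))
        writeProvTsv(env$samples, file.path(outdir, "sample_manifest.tsv"),
                     "simulate", list(seed = seed))
        writeProvTsv(env$chimeras, file.path(outdir, "chimera_predictions.tsv"),
                     "simulate", list(seed = seed))
        writeProvTsv(env$phen$phenotypes, file.path(outdir, "phenotypes.tsv"),
                     "simulate", list(seed = seed))
        writeProvTsv(env$phen$covariates, file.path(outdir, "covariates.tsv"),
                     "simulate", list(seed = seed))
        first <- env$readSets[[1]]
        writeFastqPair(first, file.path(outdir, paste0("sample_",
                                                       names(env$readSets)[1])))
        writeTruthSam(first, file.path(outdir, "sample1_truth.sam"),
                      gcfg$length)
        note("simulate", "OK",
             file.path(outdir, c("reference.fasta", "annotation.bed",
                                 "cohort_truth.tsv", "sample_manifest.tsv",
                                 "chimera_predictions.tsv", "phenotypes.tsv",
                                 "covariates.tsv", "sample1_truth.sam")))
    })

    runStage("catalog", function() {
        cc <- config$catalog %||% list()
        occ <- env$chimeras
        occ$pos5 <- occ$pos5 %||% 0L
        filt <- confidenceFilter(occ, cc$min_score %||% 0.6,
                                 cc$max_identity %||% 0.9)
        pf <- polymorphicFilter(filt$occurrences, env$samples,
                                cc$max_individuals %||% 250L,
                                cc$min_tissues %||% 5L,
                                cc$min_sample_fraction %||% 2 / 3,
                                cc$aggregation %||% "mean")
        env$selected <- pf$selected
        out <- file.path(outdir, "polymorphic_chimeras.tsv")
        writeProvTsv(pf$metrics, out, "catalog",
                     c(cc, list(seed = seed)))
        note("catalog", "OK", out)
    })

    runStage("genotype", function() {
        gt <- config$genotype
        env$queries <- designBreakpointQueries(env$genome, env$sv, env$alt,
                                               windowWidth = gt$window_width %||% 1e5)
        rule <- GenotypeRule(gt$rule %||% "CTRL & JUNCTION",
                             gt$min_reads_present %||% 1L)
        readVecs <- lapply(env$readSets, function(s)
            setNames(s$reads$seq, paste0(s$reads$read_id, "/", s$reads$mate)))
        mani <- data.frame(sample_id = names(readVecs),
                           population = env$cohort$population[env$wgsIdx],
                           stringsAsFactors = FALSE)
        env$calls <- genotypeCohort(readVecs, mani, env$queries, rule,
                                    env$genome@sequence,
                                    maxEdits = gt$max_edits %||% 0L,
                                    minScore = gt$min_score %||% 90,
                                    minIdentity = gt$min_identity %||% 0.90)
        out <- file.path(outdir, c("genotype_calls.tsv",
                                   "detection_summary.tsv",
                                   "queries.tsv"))
        writeProvTsv(env$calls$calls, out[1], "genotype", list(seed = seed))
        writeProvTsv(env$calls$summary, out[2], "genotype", list(seed = seed))
        writeProvTsv(env$queries, out[3], "genotype", list(seed = seed))
        note("genotype", "OK", out)
    })

    runStage("sv_evidence", function() {
        sv <- config$sv_evidence %||% list()
        rcfg <- env$readCfgBase
        im <- list(mean = rcfg$insert_mean, sd = rcfg$insert_sd)
        region <- c(0, config$genome$length)
        genos <- env$cohort$genotype[env$wgsIdx]
        chosen <- c(carrier = which(genos > 0)[1],
                    noncarrier = which(genos == 0)[1])
        rows <- lapply(names(chosen), function(nm) {
            i <- chosen[[nm]]
            if (is.na(i)) return(NULL)
            sig <- extractSignatures(env$readSets[[i]]$pairs, im, region,
                                     sv$min_support %||% 3L)
            cov <- coverageProfile(env$readSets[[i]]$pairs, region)
            call <- classifySv(sig, cov, region, im,
                               sv$min_support %||% 3L,
                               sv$gain_threshold %||% 1.3,
                               sv$loss_threshold %||% 0.7)
            bp <- call$breakpoints
            data.frame(sample = names(env$readSets)[i], role = nm,
                       sv_type = call$sv_type,
                       breakpoints = if (is.null(bp)) "" else
                           paste(apply(bp, 1, function(r)
                               sprintf("%d-%d", r[1] + 1L, r[2])),
                               collapse = ";"),
                       support = paste(names(call$support), call$support,
                                       sep = ":", collapse = ","),
                       coverage_ratio = call$coverage_ratio,
                       stringsAsFactors = FALSE)
        })
        out <- file.path(outdir, "sv_calls.tsv")
        writeProvTsv(do.call(rbind, rows), out, "sv_evidence", list(seed = seed))
        note("sv_evidence", "OK", out)
    })

    runStage("popgen", function() {
        rows <- do.call(rbind, lapply(split(env$cohort, env$cohort$population),
                                      function(p) {
            cnt <- c(sum(p$genotype == 0), sum(p$genotype == 1),
                     sum(p$genotype == 2))
            hw <- hweTest(cnt)
            data.frame(population = p$population[1], n0 = cnt[1], n1 = cnt[2],
                       n2 = cnt[3], allele_frequency = alleleFrequency(cnt),
                       hwe_chi_square = hw$chi_square, hwe_p = hw$p_value,
                       stringsAsFactors = FALSE)
        }))
        out <- file.path(outdir, "popgen.tsv")
        writeProvTsv(rows, out, "popgen", list(seed = seed))
        note("popgen", "OK", out)
    })

    runStage("associate", function() {
        ac <- config$association %||% list()
        geno <- env$cohort[, c("individual_id", "genotype")]
        res <- phewas(env$phen$phenotypes, geno, env$phen$covariates,
                      model = config$phenotypes$model %||% "dominant",
                      minTotal = ac$min_total %||% 20L,
                      minInExperimental = ac$min_in_experimental %||% 1L)
        out <- file.path(outdir, "associations.tsv")
        writeProvTsv(res, out, "associate", list(seed = seed))
        note("associate", "OK", out)
    })

    manifest$status <- manifest$status %||% "ok"
    writeManifest(manifest, outdir)
    invisible(manifest)
}

# Manifest written atomically: temp file then rename.
writeManifest <- function(manifest, outdir) {
    tmp <- file.path(outdir, ".manifest.json.tmp")
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                         null = "null")
    file.rename(tmp, file.path(outdir, "manifest.json"))
}

#' Validate bundled file formats
#'
#' Light well-formedness checks for the formats the pipeline reads and
#' writes: FASTA, FASTQ (sequence/quality length agreement), SAM (column
#' count, numeric positions), BED and TSV (required columns).
#'
#' @param paths Character vector of paths.
#' @param tsvColumns Optional named list: required columns per TSV path.
#' @return data.frame report (`path`, `ok`, `message`, `line`); zero
#'   problem rows means all files validate.
#' @export
validateFormats <- function(paths, tsvColumns = NULL) {
    rows <- lapply(paths, function(p) {
        ext <- tolower(tools::file_ext(p))
        if (!file.exists(p))
            return(data.frame(path = p, ok = FALSE, message = "missing file",
                              line = NA_integer_, stringsAsFactors = FALSE))
        res <- tryCatch(switch(ext,
            fa = , fasta = {
                Biostrings::readDNAStringSet(p); NULL
            },
            fq = , fastq = validateFastq(p),
            sam = validateSam(p),
            bed = validateBed(p),
            tsv = {
                req <- tsvColumns[[p]]
                df <- readProvTsv(p)
                miss <- setdiff(req %||% character(), names(df))
                if (length(miss))
                    list(message = paste("missing column(s):",
                                         paste(miss, collapse = ", ")),
                         line = 1L)
                else NULL
            },
            NULL),
            error = function(e) list(message = conditionMessage(e),
                                     line = NA_integer_))
        if (is.null(res))
            data.frame(path = p, ok = TRUE, message = "", line = NA_integer_,
                       stringsAsFactors = FALSE)
        else
            data.frame(path = p, ok = FALSE, message = res$message,
                       line = res$line, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

validateFastq <- function(p) {
    ln <- readLines(p)
    if (length(ln) %% 4 != 0)
        return(list(message = "truncated FASTQ record", line = length(ln)))
    for (i in seq(1, length(ln), by = 4)) {
        if (!startsWith(ln[i], "@"))
            return(list(message = "record does not start with @", line = i))
        if (nchar(ln[i + 1]) != nchar(ln[i + 3]))
            return(list(message = "sequence/quality length mismatch",
                        line = i))
    }
    NULL
}

validateSam <- function(p) {
    ln <- readLines(p)
    body <- which(!startsWith(ln, "@"))
    for (i in body) {
        f <- strsplit(ln[i], "\t")[[1]]
        if (length(f) < 11)
            return(list(message = "fewer than 11 SAM columns", line = i))
        if (is.na(suppressWarnings(as.integer(f[4]))))
            return(list(message = "non-numeric POS", line = i))
    }
    NULL
}

validateBed <- function(p) {
    ln <- readLines(p)
    for (i in seq_along(ln)) {
        f <- strsplit(ln[i], "\t")[[1]]
        if (length(f) < 3 ||
            is.na(suppressWarnings(as.integer(f[2]))) ||
            is.na(suppressWarnings(as.integer(f[3]))))
            return(list(message = "malformed BED record", line = i))
    }
    NULL
}
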