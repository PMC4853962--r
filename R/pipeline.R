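#' Run the full pathway-association pipeline
#'
#' Orchestrates the whole analysis on one configuration: obtain data
#' (either simulate a synthetic panel or load genotype/annotation/
#' phenotype files), apply per-trait preprocessing, filter markers, fit
#' the genomic mixed model per trait, back-solve marker effects, run the
#' circular-permutation SNP-set test, test cross-trait overlap of
#' sub-threshold sets, and partition variance within sub-threshold sets.
#' All stage outputs are written to \code{outDir} as plain-text tables
#' plus a JSON manifest with md5 checksums; given fixed seeds a rerun
#' reproduces the outputs byte for byte.
#'
#' @param config a named list or path to a YAML file. Recognized keys:
#'   \describe{
#'     \item{sim}{arguments for \code{\link{simConfig}} (synthetic
#'       mode), or absent when \code{input} is given.}
#'     \item{input}{list of paths: geno (TSV), genes (BED), go (TSV),
#'       pheno (CSV).}
#'     \item{traits}{named list; per trait: \code{h2}, optional
#'       \code{causalSets}, optional \code{transform} (none /
#'       arcsine_sqrt / plate_equalize) and \code{plateColumn}. In input
#'       mode, names must match the pheno \code{trait} column.}
#'     \item{mafMin, windowBp, minGenes, minMarkers}{filter settings
#'       (defaults 0.05, 5000, 11, 200).}
#'     \item{nPerm, nBoot}{permutation / bootstrap sizes (bootstrap
#'       skipped when \code{nBoot} = 0).}
#'     \item{thresholds}{list(significance = 0.005, overlap = 0.05).}
#'     \item{seed}{base RNG seed.}
#'   }
#' @param outDir output directory (created).
#' @return the manifest, invisibly (list with per-stage file paths,
#'   checksums, and the headline numbers).
#' @export
runPipeline <- function(config, outDir) {
    if (is.character(config) && length(config) == 1L) {
        if (!file.exists(config))
            stop("config file not found: ", config)
        config <- yaml::read_yaml(config)
    }
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    cfg <- utils::modifyList(
        list(mafMin = 0.05, windowBp = 5000L, minGenes = 11L,
             minMarkers = 200L, nPerm = 1000L, nBoot = 0L,
             thresholds = list(significance = 0.005, overlap = 0.05),
             seed = 1L),
        config)
    log <- function(stage, ...) message("[", stage, "] ", ...)

    ## ---- data stage -------------------------------------------------
    truth <- NULL
    if (!is.null(cfg$sim)) {
        log("simulate", "generating synthetic panel")
        traits <- cfg$traits
        if (is.null(traits)) traits <- list(trait1 = list(h2 = 0.5))
        pheno <- NULL; truth <- list()
        simBase <- do.call(simConfig, utils::modifyList(
            cfg$sim, list(seed = cfg$seed)))
        geno <- simulateGenotypes(simBase)
        annot <- simulateAnnotation(simBase)
        for (k in seq_along(traits)) {
            tr <- traits[[k]]
            scfg <- do.call(simConfig, utils::modifyList(cfg$sim, list(
                seed = cfg$seed + 1000L * k,
                h2Target = if (is.null(tr$h2)) 0.5 else tr$h2,
                causalSets = if (is.null(tr$causalSets)) character()
                             else tr$causalSets)))
            st <- simulateTrait(geno, annot, scfg,
                                windowBp = cfg$windowBp)
            st$pheno$trait <- names(traits)[k]
            pheno <- rbind(pheno, st$pheno)
            truth[[names(traits)[k]]] <- st$truth
        }
        genes <- annot$genes
        go <- annot$go
    } else {
        if (is.null(cfg$input))
            stop("config needs either 'sim' or 'input'")
        for (f in unlist(cfg$input))
            if (!file.exists(f)) stop("input file not found: ", f)
        log("load", "reading inputs")
        geno <- readGenotypes(cfg$input$geno, format = "tsv")
        genes <- readGenes(cfg$input$genes, format = "bed")
        go <- readGoTable(cfg$input$go)
        pheno <- readPhenotypes(cfg$input$pheno)
        if (is.null(cfg$traits)) {
            cfg$traits <- stats::setNames(
                rep(list(list()), length(unique(pheno$trait))),
                unique(pheno$trait))
        }
    }
    writeGenotypes(geno, file.path(outDir, "genotypes.tsv"))
    writeGenesBed(genes, file.path(outDir, "genes.bed"))
    writeGoTable(go, file.path(outDir, "go.tsv"))
    writePhenotypes(pheno, file.path(outDir, "phenotypes.csv"))

    ## ---- preprocessing + marker filtering ---------------------------
    for (tn in names(cfg$traits)) {
        tr <- cfg$traits[[tn]]
        sel <- pheno$trait == tn
        if (!is.null(tr$transform) && tr$transform == "arcsine_sqrt")
            pheno$value[sel] <- arcsineSqrt(pheno$value[sel])
        if (!is.null(tr$transform) && tr$transform == "plate_equalize") {
            pc <- if (is.null(tr$plateColumn)) "block" else tr$plateColumn
            pheno$value[sel] <- plateEqualize(pheno$value[sel],
                                              pheno[[pc]][sel])
        }
    }
    geno <- filterMarkers(geno, mafMin = cfg$mafMin, verbose = FALSE)
    log("filter", ncol(genoCounts(geno)), " markers retained")
    scaled <- scaleGenotypes(geno)
    grm <- computeGRM(scaled)
    G <- grm$G
    dimnames(G) <- list(lineIds(geno), lineIds(geno))
    geneMap <- mapSnpsToGenes(geno, genes, windowBp = cfg$windowBp)
    catalog <- suppressMessages(buildSnpSets(
        geneMap, go, nMarkersTotal = scaled$m,
        minGenes = cfg$minGenes, minMarkers = cfg$minMarkers))
    log("sets", length(setIds(catalog)), " SNP-sets retained")

    ## ---- per-trait model fit, effects, pathway test -----------------
    covars <- intersect(c("wolbachia", paste0("inv", 1:5), "block"),
                        names(pheno))
    fits <- list(); results <- list(); summaries <- list()
    for (tn in names(cfg$traits)) {
        log("fit", tn)
        ph <- pheno[pheno$trait == tn, , drop = FALSE]
        fit <- suppressMessages(remlFit(ph, G, covariates = covars))
        fits[[tn]] <- fit
        sm <- list(trait = tn, h2 = heritability(fit),
                   sigmaG = fit@sigmaG, sigmaE = fit@sigmaE,
                   logLik = fit@logLik, beta = as.list(fit@beta))
        if (cfg$nBoot >= 100L) {
            ci <- bootstrapCI(ph, G, covariates = covars,
                              nBoot = cfg$nBoot, seed = cfg$seed)
            sm$ci <- c(ci$lower, ci$upper)
        }
        jsonlite::write_json(sm, file.path(outDir,
                                           paste0("fit_", tn, ".json")),
                             auto_unbox = TRUE, digits = NA)
        bs <- backsolveEffects(scaled, lineBLUP(fit)[lineIds(geno)])
        rr <- markerRanges(geno)
        eff <- data.frame(
            chrom = as.character(GenomicRanges::seqnames(rr)),
            pos = GenomicRanges::start(rr),
            marker_id = markerIds(geno), s_hat = bs$s)
        write.table(eff,
                    file.path(outDir, paste0("effects_", tn, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        res <- pathwayTest(bs$s, catalog, nPerm = cfg$nPerm,
                           seed = cfg$seed + 7L)
        write.table(res,
                    file.path(outDir, paste0("results_", tn, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        results[[tn]] <- res
        summaries[[tn]] <- sm
    }

    ## ---- overlap + variance partitioning ----------------------------
    ovPath <- NULL
    if (length(results) >= 2L) {
        inc <- buildIncidence(results,
                              threshold = cfg$thresholds$overlap)
        ov <- suppressMessages(overlapTest(inc, nPerm = cfg$nPerm,
                                           seed = cfg$seed + 11L))
        ovPath <- file.path(outDir, "overlap.tsv")
        write.table(ov, ovPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    vpAll <- NULL
    for (tn in names(results)) {
        hits <- results[[tn]]$go_id[results[[tn]]$p <
                                    cfg$thresholds$overlap]
        if (length(hits) == 0L) next
        bs <- backsolveEffects(scaled,
                               lineBLUP(fits[[tn]])[lineIds(geno)])
        vp <- partitionSets(scaled, bs$s, geneMap, catalog,
                            goIds = hits)
        vpAll <- rbind(vpAll, cbind(trait = tn, vp))
    }
    if (!is.null(vpAll))
        write.table(vpAll, file.path(outDir, "varpart.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)

    ## ---- manifest ---------------------------------------------------
    outFiles <- sort(list.files(outDir, full.names = TRUE))
    outFiles <- outFiles[!basename(outFiles) %in% "manifest.json"]
    manifest <- list(
        package = "pathBLUP",
        version = as.character(packageVersion("pathBLUP")),
        seed = cfg$seed,
        settings = cfg[c("mafMin", "windowBp", "minGenes", "minMarkers",
                         "nPerm", "nBoot", "thresholds")],
        traits = summaries,
        nSets = length(setIds(catalog)),
        expected = lapply(split(setIds(catalog), setClasses(catalog)),
                          function(ids) expectedCounts(
                              length(ids),
                              cfg$thresholds$overlap)[c("expected_fp",
                                                "expected_overlap")]),
        files = stats::setNames(as.list(unname(tools::md5sum(outFiles))),
                                basename(outFiles)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$truth <- truth
    manifest$results <- results
    manifest$fits <- fits
    invisible(manifest)
}
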