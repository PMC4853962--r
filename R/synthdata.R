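#' Simulation configuration for a synthetic inbred-line panel
#'
#' Builds the configuration object consumed by
#' \code{\link{simulateGenotypes}}, \code{\link{simulateAnnotation}} and
#' \code{\link{simulateTrait}}. Defaults emulate a small subset of a
#' fully inbred, genome-sequenced reference panel: 20-30 lines, genotypes
#' in \{0, 2\}, blockwise linkage disequilibrium, markers with minor
#' allele frequency above 0.05, genes laid consecutively on chromosome
#' arms, and GO terms of heterogeneous size in three classes.
#'
#' @param nLines number of inbred lines (>= 2).
#' @param nMarkersPerChrom integer vector, markers per chromosome arm;
#'   recycled to \code{length(chromNames)}.
#' @param chromNames chromosome arm labels, in concatenation order.
#' @param ldBlockLen markers per LD block (1 = no LD).
#' @param mafRange length-2 numeric in (0, 0.5], target range of sample
#'   minor allele frequencies.
#' @param mutProb per line-per marker probability of deviating from the
#'   copied block haplotype (keeps within-block correlation just below 1).
#' @param inbreeding fraction of calls rendered heterozygous; 0 gives
#'   fully inbred genotypes in \{0, 2\}.
#' @param nGenes number of genes laid across the arms.
#' @param geneLen,intergenicLen gene and spacer lengths in bp.
#' @param nGoSets integer vector of GO-set counts, named BP/MF/CC.
#' @param goSizeRange length-2 integer, genes per GO set (uniform draw).
#' @param causalSets character, GO ids whose member markers carry true
#'   effects (resolved against the generated annotation).
#' @param h2Target target SNP heritability in [0, 1].
#' @param nRepsPerLine replicate observations per line.
#' @param fixedEffectSizes named numeric: effect of Wolbachia infection,
#'   common effect size of the five inversion factors, and of the
#'   experimental block, on the phenotype scale.
#' @param seed RNG seed.
#' @return A list of class \code{"SimConfig"}.
#' @examples
#' cfg <- simConfig(nLines = 25, seed = 1)
#' gd <- simulateGenotypes(cfg)
#' @export
simConfig <- function(nLines = 25L,
                      nMarkersPerChrom = 500L,
                      chromNames = defaultChromOrder(),
                      ldBlockLen = 10L,
                      mafRange = c(0.05, 0.5),
                      mutProb = 0.02,
                      inbreeding = 0,
                      nGenes = 120L,
                      geneLen = 1000L,
                      intergenicLen = 1000L,
                      nGoSets = c(BP = 20L, MF = 8L, CC = 6L),
                      goSizeRange = c(5L, 30L),
                      causalSets = character(),
                      h2Target = 0.5,
                      nRepsPerLine = 5L,
                      fixedEffectSizes = c(wolbachia = 0.5,
                                           inversion = 0.25,
                                           block = 0.25),
                      seed = 1L) {
    cfg <- list(nLines = as.integer(nLines),
                nMarkersPerChrom = rep_len(as.integer(nMarkersPerChrom),
                                           length(chromNames)),
                chromNames = as.character(chromNames),
                ldBlockLen = as.integer(ldBlockLen),
                mafRange = as.numeric(mafRange),
                mutProb = as.numeric(mutProb),
                inbreeding = as.numeric(inbreeding),
                nGenes = as.integer(nGenes),
                geneLen = as.integer(geneLen),
                intergenicLen = as.integer(intergenicLen),
                nGoSets = {
                    v <- vapply(nGoSets, as.integer, integer(1))
                    if (is.null(names(v)) || !all(nzchar(names(v)))) {
                        if (length(v) > 3L)
                            stop("nGoSets must be named when longer ",
                                 "than the three GO classes")
                        names(v) <- c("BP", "MF", "CC")[seq_along(v)]
                    }
                    v
                },
                goSizeRange = as.integer(goSizeRange),
                causalSets = as.character(causalSets),
                h2Target = as.numeric(h2Target),
                nRepsPerLine = as.integer(nRepsPerLine),
                fixedEffectSizes = fixedEffectSizes,
                seed = as.integer(seed))
    if (cfg$nLines < 2L)
        stop("nLines must be at least 2")
    if (cfg$ldBlockLen < 1L)
        stop("ldBlockLen must be >= 1")
    if (cfg$h2Target < 0 || cfg$h2Target > 1)
        stop("h2Target must lie in [0, 1]")
    if (any(cfg$nMarkersPerChrom < 1L) || cfg$nGenes < 1L ||
        cfg$nRepsPerLine < 1L)
        stop("all counts must be positive")
    if (cfg$mafRange[1] <= 0 || cfg$mafRange[2] > 0.5 ||
        cfg$mafRange[1] > cfg$mafRange[2])
        stop("mafRange must satisfy 0 < min <= max <= 0.5")
    class(cfg) <- "SimConfig"
    cfg
}

## marker spacing (bp) on the simulated arms
.MARKER_SPACING <- 100L

#' Simulate genotypes with blockwise LD
#'
#' Markers are laid on the configured chromosome arms at a fixed spacing
#' and generated block by block: each LD block has two ancestral
#' haplotypes (minor allele present on one of them), every line copies
#' one of the two for the whole block, and each call deviates from the
#' copied haplotype with probability \code{mutProb}. This yields high
#' within-block genotype correlation and (asymptotically) none between
#' blocks. The number of lines carrying the minor haplotype is drawn so
#' the block's allele frequency falls inside \code{mafRange}; any marker
#' whose post-mutation sample MAF escapes the range has its mutations
#' reverted, so every generated marker satisfies the range.
#'
#' @param cfg a \code{\link{simConfig}} object.
#' @return A \linkS4class{GenotypeData}; deterministic given
#'   \code{cfg$seed}.
#' @export
simulateGenotypes <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed)
    n <- cfg$nLines
    freqOK <- function(cnt) {
        f <- cnt / (2 * n)
        f <- pmin(f, 1 - f)
        f >= cfg$mafRange[1] & f <= cfg$mafRange[2]
    }
    ## admissible minor-haplotype line counts for block assignment
    kAll <- seq_len(n - 1L)
    kOK <- kAll[freqOK(2 * kAll)]
    if (length(kOK) == 0L)
        stop("mafRange admits no line count at nLines = ", n)
    chromList <- vector("list", length(cfg$chromNames))
    for (ci in seq_along(cfg$chromNames)) {
        m <- cfg$nMarkersPerChrom[ci]
        geno <- matrix(0L, n, m)
        start <- 1L
        while (start <= m) {
            len <- min(cfg$ldBlockLen, m - start + 1L)
            k <- if (length(kOK) == 1L) kOK else sample(kOK, 1L)
            carriers <- sample.int(n, k)
            block <- matrix(0L, n, len)
            block[carriers, ] <- 2L
            if (cfg$mutProb > 0) {
                flip <- matrix(runif(n * len) < cfg$mutProb, n, len)
                mutated <- block
                mutated[flip] <- 2L - mutated[flip]
                ## revert mutations on markers pushed out of the MAF range
                bad <- !freqOK(colSums(mutated))
                mutated[, bad] <- block[, bad]
                block <- mutated
            }
            geno[, start:(start + len - 1L)] <- block
            start <- start + len
        }
        chromList[[ci]] <- geno
    }
    counts <- do.call(cbind, chromList)
    if (cfg$inbreeding > 0) {
        het <- matrix(runif(length(counts)) < cfg$inbreeding,
                      nrow(counts), ncol(counts))
        counts[het] <- 1L
    }
    chrom <- rep(cfg$chromNames, cfg$nMarkersPerChrom)
    pos <- unlist(lapply(cfg$nMarkersPerChrom,
                         function(m) seq_len(m) * .MARKER_SPACING))
    rownames(counts) <- sprintf("line_%03d", seq_len(n))
    colnames(counts) <- paste0(chrom, "_", pos)
    GenotypeData(counts, chrom = chrom, pos = pos,
                 chromOrder = cfg$chromNames)
}

#' Simulate gene and GO annotation
#'
#' Genes are placed consecutively (round-robin across arms) as
#' non-overlapping intervals of \code{geneLen} bp separated by
#' \code{intergenicLen} bp. GO sets draw member genes uniformly without
#' replacement, with sizes uniform on \code{goSizeRange}, labelled
#' BP/MF/CC per \code{nGoSets}.
#'
#' @param cfg a \code{\link{simConfig}} object.
#' @return A list with \code{genes} (a \code{GRanges} with
#'   \code{gene_id}) and \code{go} (data.frame: gene_id, go_id, class);
#'   deterministic given \code{cfg$seed}.
#' @export
simulateAnnotation <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed + 1L)
    chromLen <- cfg$nMarkersPerChrom * .MARKER_SPACING
    pitch <- cfg$geneLen + cfg$intergenicLen
    capacity <- pmax(0L, (chromLen - cfg$intergenicLen) %/% pitch + 1L)
    capacity[chromLen < cfg$geneLen] <- 0L
    if (sum(capacity) < cfg$nGenes)
        stop("nGenes = ", cfg$nGenes, " genes of ", cfg$geneLen,
             " bp (+", cfg$intergenicLen, " bp spacers) exceed the ",
             "simulated chromosome span (capacity ", sum(capacity), ")")
    ## round-robin assignment of genes to arms, respecting capacity
    slot <- integer(length(cfg$chromNames))
    chromOf <- integer(cfg$nGenes)
    slotOf <- integer(cfg$nGenes)
    ci <- 1L
    for (g in seq_len(cfg$nGenes)) {
        while (slot[ci] >= capacity[ci])
            ci <- ci %% length(capacity) + 1L
        slot[ci] <- slot[ci] + 1L
        chromOf[g] <- ci
        slotOf[g] <- slot[ci]
        ci <- ci %% length(capacity) + 1L
    }
    start <- (slotOf - 1L) * pitch + cfg$intergenicLen %/% 2L + 1L
    genes <- GenomicRanges::GRanges(
        seqnames = factor(cfg$chromNames[chromOf],
                          levels = cfg$chromNames),
        ranges = IRanges::IRanges(start = start,
                                  width = cfg$geneLen),
        gene_id = sprintf("gene_%04d", seq_len(cfg$nGenes)))
    genes <- GenomicRanges::sort(genes)
    genes$gene_id <- sprintf("gene_%04d", seq_along(genes))
    classes <- rep(names(cfg$nGoSets), cfg$nGoSets)
    nSets <- length(classes)
    sizeChoices <- cfg$goSizeRange[1]:cfg$goSizeRange[2]
    sizes <- if (length(sizeChoices) == 1L) rep(sizeChoices, nSets)
             else sample(sizeChoices, nSets, replace = TRUE)
    sizes <- pmin(sizes, cfg$nGenes)
    go <- do.call(rbind, lapply(seq_len(nSets), function(i) {
        data.frame(
            gene_id = sort(sample(genes$gene_id, sizes[i])),
            go_id = sprintf("GO:%07d", i),
            class = classes[i])
    }))
    rownames(go) <- NULL
    list(genes = genes, go = go)
}

#' Simulate a replicated trait with known genetic architecture
#'
#' True marker effects are drawn iid N(0, 1) for markers belonging to the
#' configured causal GO sets (via the +/- 5 kb gene window) and are zero
#' elsewhere. Line genomic values are g = W s on the centred and scaled
#' genotype matrix, and the residual standard deviation is chosen so the
#' realized heritability Var(Zg) / (Var(Zg) + Var(e)) matches
#' \code{h2Target} up to sampling noise in the realized residuals.
#' Covariates: Wolbachia ~ Bernoulli(0.5) per line, five biallelic
#' inversion factors per line, experimental block assigned round-robin
#' over replicates.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param annot annotation list from \code{\link{simulateAnnotation}}.
#' @param cfg a \code{\link{simConfig}} object. If \code{cfg$causalSets}
#'   is empty and \code{h2Target > 0}, 10\% of markers genome-wide are
#'   causal instead of set-restricted markers.
#' @param windowBp gene window used to resolve causal sets to markers.
#' @return A list with \code{pheno} (data.frame: line_id, rep, trait,
#'   value, wolbachia, inv1..inv5, block) and \code{truth} (list:
#'   true_s, true_g, true_h2 realized, causal_set_ids, covariates).
#' @export
simulateTrait <- function(geno, annot, cfg, windowBp = 5000L) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed + 2L)
    n <- nrow(genoCounts(geno))
    m <- ncol(genoCounts(geno))
    W <- scaleGenotypes(geno)$W
    causalIdx <- integer(0)
    if (cfg$h2Target > 0) {
        if (length(cfg$causalSets)) {
            missing <- setdiff(cfg$causalSets, unique(annot$go$go_id))
            if (length(missing))
                stop("causal sets not in annotation: ",
                     paste(missing, collapse = ", "))
            g2m <- mapSnpsToGenes(geno, annot$genes, windowBp = windowBp)
            genesIn <- annot$go$gene_id[annot$go$go_id %in% cfg$causalSets]
            causalIdx <- sort(unique(unlist(g2m[intersect(names(g2m),
                                                          genesIn)])))
        } else {
            causalIdx <- sort(sample.int(m, max(1L, round(0.1 * m))))
        }
    }
    s <- numeric(m)
    if (length(causalIdx))
        s[causalIdx] <- rnorm(length(causalIdx))
    g <- as.numeric(W %*% s)
    if (cfg$h2Target == 1 && cfg$nRepsPerLine > 1L)
        warning("h2Target = 1 with replicates: residual variance is ",
                "exactly zero (degenerate)")
    ## covariates per line / per replicate
    wol <- rbinom(n, 1L, 0.5)
    inv <- matrix(rbinom(n * 5L, 1L, 0.5), n, 5L,
                  dimnames = list(NULL, paste0("inv", 1:5)))
    reps <- cfg$nRepsPerLine
    block <- rep_len(seq_len(min(3L, reps)), reps)  # round-robin
    varG <- if (n > 1) var(rep(g, each = reps)) else 0
    sigmaE <- if (cfg$h2Target >= 1) 0
              else if (cfg$h2Target == 0) 1
              else sqrt(varG * (1 - cfg$h2Target) / cfg$h2Target)
    fx <- cfg$fixedEffectSizes
    lineFix <- fx[["wolbachia"]] * wol +
        inv %*% rep(fx[["inversion"]], 5L)
    pheno <- data.frame(
        line_id = rep(lineIds(geno), each = reps),
        rep = rep(seq_len(reps), times = n),
        trait = "sim_trait",
        value = NA_real_,
        wolbachia = rep(wol, each = reps),
        inv[rep(seq_len(n), each = reps), , drop = FALSE],
        block = rep(block, times = n))
    eps <- rnorm(n * reps, sd = sigmaE)
    pheno$value <- rep(as.numeric(lineFix), each = reps) +
        fx[["block"]] * (pheno$block - mean(block)) +
        rep(g, each = reps) + eps
    varE <- var(eps)
    trueH2 <- if (varG + varE > 0) varG / (varG + varE) else 0
    list(pheno = pheno,
         truth = list(true_s = s, true_g = g, true_h2 = trueH2,
                      causal_set_ids = cfg$causalSets,
                      causal_markers = causalIdx,
                      covariates = data.frame(line_id = lineIds(geno),
                                              wolbachia = wol, inv)))
}
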