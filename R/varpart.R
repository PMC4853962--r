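#' Per-gene genetic effect vectors within a SNP-set
#'
#' For every member gene of a set, the gene-level genetic value of each
#' line is f_hat = W_gene s_gene, summing marker effect times scaled
#' genotype over the gene's markers (restricted to markers that are in
#' the set). When the member genes partition the set's markers the gene
#' vectors sum exactly to the set-level effect vector W_set s_set;
#' markers shared by several member genes contribute to each of them.
#'
#' @param scaled result of \code{\link{scaleGenotypes}} (or W matrix).
#' @param effects genome-ordered marker effects (vector or
#'   \code{\link{backsolveEffects}} result).
#' @param geneMap gene -> marker index list from
#'   \code{\link{mapSnpsToGenes}}.
#' @param setIdx integer marker indices of the set.
#' @param genes character, member gene ids (genes with no marker inside
#'   the set are excluded with a message).
#' @return named list of per-line numeric vectors, one per retained
#'   gene; marker counts attached as \code{attr(, "m_gene")}.
#' @export
geneEffects <- function(scaled, effects, geneMap, setIdx, genes) {
    W <- if (is.list(scaled)) scaled$W else scaled
    if (is.list(effects) && !is.null(effects$s)) effects <- effects$s
    out <- list(); mg <- integer(0)
    skipped <- character(0)
    for (g in genes) {
        ix <- intersect(geneMap[[g]], setIdx)
        if (length(ix) == 0L) {
            skipped <- c(skipped, g)
            next
        }
        out[[g]] <- as.numeric(W[, ix, drop = FALSE] %*% effects[ix])
        mg[g] <- length(ix)
    }
    if (length(skipped))
        message(length(skipped),
                " gene(s) without markers in the set excluded")
    if (length(out) == 0L)
        stop("no member gene has markers inside the set")
    attr(out, "m_gene") <- mg
    out
}

#' Partition within-set genetic variance to genes
#'
#' For each gene, VarF is the sample variance (n - 1 denominator) across
#' lines of its genetic effect vector, adjusted for gene size by
#' dividing by the gene's marker count. Shares are VarF normalized to
#' sum to one within the set; genes whose share strictly exceeds
#' \code{flagShare} (default 20\%) are flagged as the set's main
#' contributors. Shares are invariant to rescaling all marker effects by
#' a nonzero constant.
#'
#' @param fhat named list of per-line gene effect vectors from
#'   \code{\link{geneEffects}} (with its \code{m_gene} attribute), or a
#'   named list plus an explicit \code{mGene}.
#' @param mGene optional named integer, markers per gene.
#' @param flagShare share threshold for flagging (strict >).
#' @return data.frame: gene_id, m_gene, varF, share, flagged; sorted by
#'   decreasing share.
#' @export
varianceShares <- function(fhat, mGene = NULL, flagShare = 0.20) {
    if (is.null(mGene)) mGene <- attr(fhat, "m_gene")
    if (is.null(mGene))
        stop("marker counts per gene (mGene) are required")
    nLines <- length(fhat[[1]])
    if (nLines < 2L) stop("variance requires at least 2 lines")
    varF <- vapply(names(fhat),
                   function(g) var(fhat[[g]]) / mGene[[g]], numeric(1))
    tot <- sum(varF)
    if (tot <= 0)
        stop("all per-gene variances are zero; shares undefined")
    share <- varF / tot
    out <- data.frame(gene_id = names(fhat),
                      m_gene = as.integer(mGene[names(fhat)]),
                      varF = unname(varF), share = unname(share),
                      flagged = unname(share > flagShare),
                      row.names = NULL)
    out[order(-out$share), ]
}

#' Variance partitioning for catalog sets
#'
#' Convenience wrapper running \code{\link{geneEffects}} and
#' \code{\link{varianceShares}} for one or more sets of a
#' \linkS4class{SnpSetCatalog}.
#'
#' @inheritParams geneEffects
#' @param catalog a \linkS4class{SnpSetCatalog}.
#' @param goIds sets to partition (default: all).
#' @param flagShare share threshold for flagging.
#' @return data.frame with a go_id column stacked over sets.
#' @export
partitionSets <- function(scaled, effects, geneMap, catalog,
                          goIds = setIds(catalog), flagShare = 0.20) {
    mk <- setMarkers(catalog); gn <- setGenes(catalog)
    res <- lapply(goIds, function(id) {
        f <- suppressMessages(
            geneEffects(scaled, effects, geneMap, mk[[id]], gn[[id]]))
        cbind(go_id = id, varianceShares(f, flagShare = flagShare))
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}
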