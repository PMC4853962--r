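#' @import methods
#' @importFrom stats var sd cor optimize pnorm pt quantile rbinom rnorm runif
#' @importFrom utils read.delim write.table write.csv read.csv head
#'   packageVersion modifyList combn
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importMethodsFrom SummarizedExperiment assay assayNames rowRanges
NULL

#' GenotypeData: allele counts for a panel of lines
#'
#' A \linkS4class{RangedSummarizedExperiment} holding minor-allele counts
#' for biallelic markers on a panel of (typically fully inbred) lines.
#' Rows are markers with genomic coordinates (1-based), columns are lines.
#' The single assay \code{"counts"} contains values in \{0, 1, 2\}, counting
#' copies of the minor allele as observed in the loaded sample.
#'
#' Use \code{\link{genoCounts}} for the lines x markers orientation used by
#' the mixed model, \code{\link{markerMAF}} for per-marker minor allele
#' frequencies, and \code{\link{filterMarkers}} to drop monomorphic and
#' rare markers.
#'
#' @aliases GenotypeData-class
#' @exportClass GenotypeData
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
    msg <- NULL
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        a <- SummarizedExperiment::assay(object, "counts")
        if (any(!is.finite(a)) || any(a < 0 | a > 2))
            msg <- c(msg, "allele counts must lie in [0, 2]")
    }
    if (is.null(msg)) TRUE else msg
})

#' SnpSetCatalog: GO term to marker-index sets
#'
#' Holds, for each retained gene-ontology term, its class (BP/MF/CC), the
#' member gene ids, and the deduplicated genome-ordered marker indices
#' (positions into the marker ordering of the \linkS4class{GenotypeData}
#' the catalog was built from).
#'
#' @slot setIds character, GO identifiers.
#' @slot setClass character, one of "BP", "MF", "CC" per set.
#' @slot genes list of character vectors, member gene ids per set.
#' @slot markers list of integer vectors, strictly increasing marker
#'   indices per set.
#' @slot nMarkersTotal integer, number of markers in the source genotype
#'   matrix (the modulus used by circular rotation).
#' @slot provenance list recording the filters applied.
#'
#' @aliases SnpSetCatalog-class
#' @exportClass SnpSetCatalog
setClass("SnpSetCatalog",
    representation(
        setIds = "character",
        setClass = "character",
        genes = "list",
        markers = "list",
        nMarkersTotal = "integer",
        provenance = "list"
    )
)

setValidity("SnpSetCatalog", function(object) {
    msg <- NULL
    n <- length(object@setIds)
    if (length(object@setClass) != n || length(object@genes) != n ||
        length(object@markers) != n)
        msg <- c(msg, "slot lengths disagree")
    if (anyDuplicated(object@setIds))
        msg <- c(msg, "duplicated set ids")
    if (n > 0 && !all(object@setClass %in% c("BP", "MF", "CC")))
        msg <- c(msg, "setClass must be BP, MF or CC")
    for (ix in object@markers) {
        if (length(ix) == 0L || is.unsorted(ix, strictly = TRUE) ||
            ix[1L] < 1L || ix[length(ix)] > object@nMarkersTotal) {
            msg <- c(msg, "marker indices must be unique, sorted, in range")
            break
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' GblupFit: a fitted genomic mixed model
#'
#' Result of \code{\link{remlFit}} for the model
#' y = Xb + Zg + e with g ~ N(0, G sigma_g^2), e ~ N(0, I sigma_e^2).
#'
#' @slot beta named numeric, fixed-effect estimates.
#' @slot gblup named numeric, per-line genomic BLUPs.
#' @slot sigmaG numeric(1), genomic variance component.
#' @slot sigmaE numeric(1), residual variance component.
#' @slot logLik numeric(1), REML log-likelihood at the optimum.
#' @slot converged logical(1).
#' @slot boundary logical(1), TRUE if a variance component is at zero.
#' @slot identifiable logical(1), FALSE when sigma_g^2 and sigma_e^2 are
#'   jointly unidentifiable (e.g. G = I with one observation per line).
#' @slot droppedColumns character, collinear design columns pruned from X.
#' @slot lineIds character, line ordering of \code{gblup} (matches G).
#'
#' @aliases GblupFit-class
#' @exportClass GblupFit
setClass("GblupFit",
    representation(
        beta = "numeric",
        gblup = "numeric",
        sigmaG = "numeric",
        sigmaE = "numeric",
        logLik = "numeric",
        converged = "logical",
        boundary = "logical",
        identifiable = "logical",
        droppedColumns = "character",
        lineIds = "character"
    )
)

setValidity("GblupFit", function(object) {
    msg <- NULL
    if (object@sigmaG < 0 || object@sigmaE < 0)
        msg <- c(msg, "variance components must be nonnegative")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "GenotypeData", function(object) {
    cat("GenotypeData:", ncol(object), "lines x", nrow(object), "markers\n")
    p <- markerMAF(object)
    cat(sprintf("  MAF range: [%.3f, %.3f]; chromosomes: %s\n",
        min(p), max(p),
        paste(GenomeInfoDb::seqlevels(SummarizedExperiment::rowRanges(object)),
              collapse = ", ")))
})

setMethod("show", "SnpSetCatalog", function(object) {
    cat("SnpSetCatalog with", length(object@setIds), "SNP-sets (",
        paste(sprintf("%s: %d", names(table(object@setClass)),
                      as.integer(table(object@setClass))), collapse = ", "),
        ")\n")
    cat("  markers per set:",
        paste(range(lengths(object@markers)), collapse = "-"),
        "; modulus m =", object@nMarkersTotal, "\n")
})

setMethod("show", "GblupFit", function(object) {
    cat("GblupFit:", length(object@gblup), "lines\n")
    cat(sprintf("  sigma_g^2 = %.4g, sigma_e^2 = %.4g, h2_SNP = %.3f\n",
        object@sigmaG, object@sigmaE, heritability(object)))
    cat(sprintf("  REML logLik = %.4f; converged: %s%s%s\n",
        object@logLik, object@converged,
        if (object@boundary) "; boundary estimate" else "",
        if (!object@identifiable) "; variance components unidentifiable"
        else ""))
})
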