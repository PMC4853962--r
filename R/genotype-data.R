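#' Default chromosome-arm ordering
#'
#' The fixed order in which chromosome arms are concatenated into the
#' genome-wide marker vector (Drosophila arm naming). Any analysis that
#' relies on genome order (marker-effect rotation in particular) uses this
#' ordering unless the loaded data name different chromosomes, in which
#' case the order of first appearance is kept.
#'
#' @export
defaultChromOrder <- function() c("2L", "2R", "3L", "3R", "X", "4")

.orderChromLevels <- function(chrom, chromOrder = defaultChromOrder()) {
    seen <- unique(as.character(chrom))
    known <- chromOrder[chromOrder %in% seen]
    c(known, setdiff(seen, known))
}

#' Construct a GenotypeData object
#'
#' @param counts numeric matrix of minor-allele counts, lines x markers,
#'   values in \{0, 1, 2\}. Row names are line ids, column names marker ids
#'   (generated when absent).
#' @param chrom character, chromosome per marker.
#' @param pos integer, 1-based position per marker.
#' @param chromOrder character, chromosome concatenation order; chromosomes
#'   not listed are appended in order of first appearance.
#' @return A \linkS4class{GenotypeData} with markers sorted by
#'   (chromosome order, position) and counts oriented to the sample minor
#'   allele.
#' @examples
#' a <- matrix(c(0, 2, 2, 0, 2, 2), nrow = 3,
#'             dimnames = list(paste0("L", 1:3), c("m1", "m2")))
#' gd <- GenotypeData(a, chrom = c("2L", "2L"), pos = c(100L, 200L))
#' markerMAF(gd)
#' @export
GenotypeData <- function(counts, chrom, pos,
                         chromOrder = defaultChromOrder()) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (length(chrom) != ncol(counts) || length(pos) != ncol(counts))
        stop("chrom/pos must have one entry per marker (column of counts)")
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("line_", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0(chrom, "_", pos)
    lev <- .orderChromLevels(chrom, chromOrder)
    o <- order(match(chrom, lev), pos)
    if (is.unsorted(o)) {
        counts <- counts[, o, drop = FALSE]
        chrom <- chrom[o]
        pos <- pos[o]
    }
    ## orient to the sample minor allele
    f <- colMeans(counts) / 2
    flip <- f > 0.5
    if (any(flip))
        counts[, flip] <- 2L - counts[, flip, drop = FALSE]
    rr <- GenomicRanges::GRanges(
        seqnames = factor(chrom, levels = lev),
        ranges = IRanges::IRanges(start = as.integer(pos), width = 1L),
        flipped = flip
    )
    names(rr) <- colnames(counts)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = t(counts)), rowRanges = rr)
    methods::new("GenotypeData", se)
}

#' Accessors for GenotypeData
#'
#' \code{genoCounts} returns the allele-count matrix in the lines x markers
#' orientation used by the mixed model; \code{markerMAF} the per-marker
#' sample minor allele frequency; \code{lineIds} and \code{markerIds} the
#' dimension names; \code{markerRanges} the marker coordinates as a
#' \code{GRanges}.
#'
#' @param x a \linkS4class{GenotypeData}.
#' @return See description.
#' @rdname genotype-accessors
#' @export
genoCounts <- function(x) t(SummarizedExperiment::assay(x, "counts"))

#' @rdname genotype-accessors
#' @export
markerMAF <- function(x) {
    a <- SummarizedExperiment::assay(x, "counts")
    unname(rowMeans(a) / 2)
}

#' @rdname genotype-accessors
#' @export
lineIds <- function(x) colnames(x)

#' @rdname genotype-accessors
#' @export
markerIds <- function(x) rownames(x)

#' @rdname genotype-accessors
#' @export
markerRanges <- function(x) SummarizedExperiment::rowRanges(x)

#' Subset lines of a GenotypeData object
#'
#' Keeps the given lines and re-orients counts to the minor allele of the
#' subset (allele frequencies are sample quantities, so subsetting lines
#' can flip orientation or create monomorphic markers; run
#' \code{\link{filterMarkers}} afterwards).
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param lines character or integer index of lines to keep.
#' @return A \linkS4class{GenotypeData}.
#' @export
subsetLines <- function(x, lines) {
    a <- genoCounts(x)[lines, , drop = FALSE]
    rr <- markerRanges(x)
    GenotypeData(a, chrom = as.character(GenomicRanges::seqnames(rr)),
                 pos = GenomicRanges::start(rr),
                 chromOrder = GenomeInfoDb::seqlevels(rr))
}

#' Remove monomorphic and low-frequency markers
#'
#' Monomorphic markers (zero variance in the analyzed sample) are always
#' removed; markers whose sample minor allele frequency is at or below
#' \code{mafMin} are removed as well. Frequencies are recomputed on the
#' analyzed line subset, so the filter should be re-applied after any
#' subsetting of lines.
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param mafMin frequency threshold; markers with MAF <= mafMin are
#'   dropped (default 0.05). \code{mafMin = 0} drops only monomorphic
#'   markers.
#' @param verbose report the number of removed markers.
#' @return Filtered \linkS4class{GenotypeData}.
#' @export
filterMarkers <- function(x, mafMin = 0.05, verbose = TRUE) {
    a <- SummarizedExperiment::assay(x, "counts")
    mono <- apply(a, 1L, function(v) all(v == v[1L]))
    p <- markerMAF(x)
    keep <- !mono & p > mafMin
    if (!any(keep))
        stop("all markers removed by the MAF filter (mafMin = ",
             mafMin, ")")
    if (verbose && any(!keep))
        message(sum(mono), " monomorphic and ", sum(!keep & !mono),
                " low-MAF markers removed (", sum(keep), " retained)")
    x[keep, ]
}
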