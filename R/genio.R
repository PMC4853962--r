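#' Read genotypes from TSV or VCF
#'
#' Two plain-text formats are supported. \code{format = "tsv"}: a
#' lines x markers matrix with a header of marker ids, a first column of
#' line ids, and a sidecar marker map \code{<path>.markers.tsv}
#' (marker_id, chrom, pos). \code{format = "vcf"}: a VCF whose GT field
#' carries the calls; only biallelic SNP records are used (multiallelic
#' records are skipped with a warning). In both cases allele counts are
#' re-oriented so they count the minor allele of the loaded sample, and
#' markers are sorted along the genome.
#'
#' @param path input file.
#' @param format "tsv" or "vcf".
#' @param chromOrder chromosome concatenation order.
#' @return A \linkS4class{GenotypeData}.
#' @export
readGenotypes <- function(path, format = c("tsv", "vcf"),
                          chromOrder = defaultChromOrder()) {
    format <- match.arg(format)
    if (format == "tsv") {
        tab <- read.delim(path, check.names = FALSE)
        counts <- as.matrix(tab[, -1, drop = FALSE])
        rownames(counts) <- as.character(tab[[1]])
        map <- read.delim(paste0(path, ".markers.tsv"))
        map <- map[match(colnames(counts), map$marker_id), ]
        GenotypeData(counts, chrom = as.character(map$chrom),
                     pos = as.integer(map$pos), chromOrder = chromOrder)
    } else {
        .readGenotypesVcf(path, chromOrder)
    }
}

.readGenotypesVcf <- function(path, chromOrder) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
        stop("reading VCF requires the VariantAnnotation package")
    vcf <- VariantAnnotation::readVcf(path)
    nAlt <- lengths(VariantAnnotation::alt(vcf))
    if (any(nAlt > 1L)) {
        warning(sum(nAlt > 1L), " multiallelic records skipped")
        vcf <- vcf[nAlt <= 1L, ]
    }
    gt <- VariantAnnotation::geno(vcf)$GT
    counts <- t(apply(gt, c(1L, 2L), function(g) {
        al <- strsplit(g, "[/|]")[[1]]
        if (any(al == ".")) NA_integer_ else sum(al != "0")
    }))
    if (anyNA(counts))
        stop("missing genotype calls are not supported")
    rr <- SummarizedExperiment::rowRanges(vcf)
    colnames(counts) <- names(rr)
    GenotypeData(counts,
                 chrom = as.character(GenomicRanges::seqnames(rr)),
                 pos = GenomicRanges::start(rr),
                 chromOrder = chromOrder)
}

#' Write genotypes as TSV matrix or minimal VCF
#'
#' The TSV writer emits the lines x markers count matrix plus a
#' \code{<path>.markers.tsv} sidecar map; the VCF writer emits a minimal
#' GT-only VCF with synthetic REF/ALT alleles, diploid calls (0 -> 0/0,
#' 1 -> 0/1, 2 -> 1/1) and one sample column per line.
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param path output file.
#' @param format "tsv" or "vcf".
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(x, path, format = c("tsv", "vcf")) {
    format <- match.arg(format)
    rr <- markerRanges(x)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    if (format == "tsv") {
        a <- genoCounts(x)
        tab <- data.frame(line_id = rownames(a), a, check.names = FALSE)
        write.table(tab, path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        map <- data.frame(marker_id = markerIds(x), chrom = chrom,
                          pos = pos)
        write.table(map, paste0(path, ".markers.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    } else {
        a <- genoCounts(x)
        gtcode <- c("0/0", "0/1", "1/1")
        body <- vapply(seq_len(ncol(a)), function(j) {
            paste(c(chrom[j], pos[j], markerIds(x)[j], "A", "T", ".",
                    "PASS", ".", "GT", gtcode[a[, j] + 1L]),
                  collapse = "\t")
        }, character(1))
        hdr <- c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", rownames(a)),
                       collapse = "\t"))
        writeLines(c(hdr, body), path)
    }
    invisible(path)
}

#' Read a gene table from BED or GFF3
#'
#' BED input (0-based half-open) and GFF3 input (1-based inclusive) are
#' both normalized to the package's internal 1-based inclusive
#' convention. The gene identifier is taken from the BED name column or
#' the GFF3 \code{ID} attribute.
#'
#' @param path input file.
#' @param format "bed" or "gff3".
#' @return A \code{GRanges} with metadata column \code{gene_id}.
#' @export
readGenes <- function(path, format = c("bed", "gff3")) {
    format <- match.arg(format)
    if (format == "bed") {
        tab <- read.delim(path, header = FALSE)
        gr <- GenomicRanges::GRanges(
            seqnames = as.character(tab[[1]]),
            ranges = IRanges::IRanges(start = tab[[2]] + 1L,
                                      end = tab[[3]]),
            gene_id = as.character(tab[[4]]))
    } else {
        lines <- readLines(path)
        lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
        f <- strsplit(lines, "\t")
        f <- f[vapply(f, length, 1L) >= 9L]
        ids <- vapply(f, function(v)
            sub(".*ID=([^;]+).*", "\\1", v[9]), character(1))
        gr <- GenomicRanges::GRanges(
            seqnames = vapply(f, `[`, character(1), 1L),
            ranges = IRanges::IRanges(
                start = as.integer(vapply(f, `[`, character(1), 4L)),
                end = as.integer(vapply(f, `[`, character(1), 5L))),
            gene_id = ids)
    }
    if (anyDuplicated(gr$gene_id))
        stop("duplicated gene ids in ", path)
    gr
}

#' Write a gene table as BED
#'
#' @param genes a \code{GRanges} with \code{gene_id} (internal 1-based
#'   inclusive coordinates; written 0-based half-open).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGenesBed <- function(genes, path) {
    tab <- data.frame(as.character(GenomicRanges::seqnames(genes)),
                      GenomicRanges::start(genes) - 1L,
                      GenomicRanges::end(genes),
                      genes$gene_id)
    write.table(tab, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read / write a gene-to-GO membership table
#'
#' Three-column TSV: gene_id, go_id, class (BP/MF/CC).
#'
#' @param path file path.
#' @return data.frame with those columns.
#' @export
readGoTable <- function(path) {
    tab <- read.delim(path)
    need <- c("gene_id", "go_id", "class")
    if (!all(need %in% names(tab)))
        stop("GO table must have columns: ", paste(need, collapse = ", "))
    tab[need]
}

#' @rdname readGoTable
#' @param go data.frame to write.
#' @export
writeGoTable <- function(go, path) {
    write.table(go, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write replicated phenotype records
#'
#' CSV with columns line_id, rep, trait, value and the model covariates
#' (wolbachia, inv1..inv5, block).
#'
#' @param path file path.
#' @return data.frame.
#' @export
readPhenotypes <- function(path) read.csv(path)

#' @rdname readPhenotypes
#' @param pheno data.frame to write.
#' @export
writePhenotypes <- function(pheno, path) {
    write.csv(pheno, path, row.names = FALSE)
    invisible(path)
}

#' Map SNPs to genes within a window
#'
#' A marker is assigned to a gene when its position lies within
#' \code{gene.start - windowBp} and \code{gene.end + windowBp},
#' boundaries inclusive. A marker may map to several genes.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param genes a \code{GRanges} with \code{gene_id}.
#' @param windowBp flanking window in bp (default 5000).
#' @return Named list: per gene_id, the sorted integer indices of its
#'   markers in genome order. Genes without markers get an empty vector.
#' @export
mapSnpsToGenes <- function(geno, genes, windowBp = 5000L) {
    rr <- markerRanges(geno)
    gchr <- unique(as.character(GenomicRanges::seqnames(genes)))
    mchr <- unique(as.character(GenomicRanges::seqnames(rr)))
    orphan <- setdiff(gchr, mchr)
    if (length(orphan))
        stop("gene chromosomes absent from genotype data: ",
             paste(orphan, collapse = ", "))
    ext <- GenomicRanges::resize(genes,
                                 GenomicRanges::width(genes) + 2L * windowBp,
                                 fix = "center")
    hits <- GenomicRanges::findOverlaps(ext, rr, ignore.strand = TRUE)
    out <- rep(list(integer(0)), length(genes))
    names(out) <- genes$gene_id
    sp <- split(S4Vectors::subjectHits(hits),
                S4Vectors::queryHits(hits))
    for (q in names(sp))
        out[[as.integer(q)]] <- sort(unique(sp[[q]]))
    out
}

#' Build the GO SNP-set catalog
#'
#' Groups gene-level marker lists into GO SNP-sets and applies the
#' retention filters: a set is kept only when it contains more than
#' \code{minGenes - 1} member genes with at least one marker, and its
#' deduplicated marker union holds at least \code{minMarkers} markers
#' (defaults: more than 10 genes and more than 199 markers). Markers
#' shared by several member genes are counted once.
#'
#' @param geneMap gene -> marker indices list from
#'   \code{\link{mapSnpsToGenes}}.
#' @param go data.frame (gene_id, go_id, class); rows referencing genes
#'   absent from \code{geneMap} are ignored with a message.
#' @param nMarkersTotal total marker count of the genotype matrix the
#'   map was built from.
#' @param minGenes minimum number of genes (kept when n_genes >=
#'   minGenes; default 11, i.e. more than 10).
#' @param minMarkers minimum number of distinct markers (default 200,
#'   i.e. more than 199).
#' @param verbose report per-class retention counts.
#' @return A \linkS4class{SnpSetCatalog}.
#' @export
buildSnpSets <- function(geneMap, go, nMarkersTotal,
                         minGenes = 11L, minMarkers = 200L,
                         verbose = TRUE) {
    unknown <- setdiff(unique(go$gene_id), names(geneMap))
    if (length(unknown)) {
        message(length(unknown),
                " GO-table gene ids absent from the gene map; ignored")
        go <- go[go$gene_id %in% names(geneMap), , drop = FALSE]
    }
    go <- go[order(go$go_id, go$gene_id), , drop = FALSE]
    byset <- split(go$gene_id, go$go_id)
    classOf <- vapply(split(go$class, go$go_id), function(v)
        as.character(v[1L]), character(1))
    ids <- character(0); cls <- character(0)
    genes <- list(); markers <- list()
    dropped <- 0L
    for (sid in names(byset)) {
        memberGenes <- unique(byset[[sid]])
        withMarkers <- memberGenes[lengths(geneMap[memberGenes]) > 0L]
        ix <- sort(unique(unlist(geneMap[withMarkers], use.names = FALSE)))
        if (length(withMarkers) < minGenes || length(ix) < minMarkers) {
            dropped <- dropped + 1L
            next
        }
        ids <- c(ids, sid); cls <- c(cls, classOf[[sid]])
        genes <- c(genes, list(withMarkers))
        markers <- c(markers, list(as.integer(ix)))
    }
    if (length(ids) == 0L)
        stop("no SNP-set passes the filters (minGenes = ", minGenes,
             ", minMarkers = ", minMarkers, ")")
    if (verbose)
        message(length(ids), " SNP-sets retained (",
                paste(sprintf("%s: %d", names(table(cls)),
                              as.integer(table(cls))), collapse = ", "),
                "); ", dropped, " dropped")
    methods::new("SnpSetCatalog", setIds = ids, setClass = cls,
                 genes = genes, markers = markers,
                 nMarkersTotal = as.integer(nMarkersTotal),
                 provenance = list(minGenes = minGenes,
                                   minMarkers = minMarkers,
                                   nDropped = dropped))
}

#' Accessors for SnpSetCatalog
#'
#' @param x a \linkS4class{SnpSetCatalog}.
#' @return \code{setIds}: character vector of GO ids; \code{setClasses}:
#'   their BP/MF/CC classes; \code{setMarkers}: named list of marker
#'   index vectors; \code{setGenes}: named list of member gene ids.
#' @rdname snpset-accessors
#' @export
setIds <- function(x) x@setIds

#' @rdname snpset-accessors
#' @export
setClasses <- function(x) stats::setNames(x@setClass, x@setIds)

#' @rdname snpset-accessors
#' @export
setMarkers <- function(x) stats::setNames(x@markers, x@setIds)

#' @rdname snpset-accessors
#' @export
setGenes <- function(x) stats::setNames(x@genes, x@setIds)
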