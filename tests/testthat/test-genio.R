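toyGeno <- function() {
    a <- matrix(c(0, 2, 2,
                  2, 2, 0,
                  0, 0, 2,
                  2, 0, 0), nrow = 3,
                dimnames = list(c("l1", "l2", "l3"),
                                c("mA", "mB", "mC", "mD")))
    GenotypeData(a, chrom = c("2L", "2L", "2R", "X"),
                 pos = c(100L, 900L, 50L, 10L))
}

test_that("counts are re-oriented to the sample minor allele", {
    ## raw counts [2,2,0]: raw allele freq 2/3 > 0.5, so orientation
    ## flips to [0,0,2] and p = 1/3
    a <- matrix(c(2, 2, 0), ncol = 1,
                dimnames = list(NULL, "m1"))
    g <- GenotypeData(a, chrom = "2L", pos = 5L)
    expect_equal(as.numeric(genoCounts(g)), c(0, 0, 2))
    expect_equal(markerMAF(g), 1 / 3)
    expect_true(markerRanges(g)$flipped)
})

test_that("TSV round-trip preserves the genotype matrix", {
    g <- toyGeno()
    path <- withr::local_tempfile(fileext = ".tsv")
    writeGenotypes(g, path, format = "tsv")
    g2 <- readGenotypes(path, format = "tsv")
    expect_identical(genoCounts(g2), genoCounts(g))
    expect_identical(markerIds(g2), markerIds(g))
    expect_equal(GenomicRanges::start(markerRanges(g2)),
                 GenomicRanges::start(markerRanges(g)))
})

test_that("VCF round-trip works and heterozygous calls count 1", {
    skip_if_not_installed("VariantAnnotation")
    a <- matrix(c(0, 1, 2, 2, 0, 0), nrow = 3,
                dimnames = list(c("l1", "l2", "l3"), c("m1", "m2")))
    g <- GenotypeData(a, chrom = c("2L", "2R"), pos = c(10L, 20L))
    path <- withr::local_tempfile(fileext = ".vcf")
    writeGenotypes(g, path, format = "vcf")
    expect_true(any(grepl("0/1", readLines(path))))
    g2 <- readGenotypes(path, format = "vcf")
    expect_equal(unname(genoCounts(g2)), unname(genoCounts(g)))
})

test_that("markers are genome-sorted in the fixed arm order", {
    a <- matrix(rep(c(0, 2, 2), 3), nrow = 3)
    colnames(a) <- c("x1", "x2", "x3")
    g <- GenotypeData(a, chrom = c("X", "2L", "2L"),
                      pos = c(5L, 300L, 100L))
    expect_identical(markerIds(g), c("x3", "x2", "x1"))
})

test_that("filterMarkers removes monomorphic and rare markers", {
    ## 10 markers over 25 lines: 3 monomorphic, one at MAF 0.04,
    ## six clean ones survive a 0.05 threshold
    set.seed(1)
    a <- cbind(matrix(rep(c(0, 2), c(12, 13)), 25, 6), # p = 0.48
               matrix(2, 25, 3),                        # monomorphic
               c(1, rep(0, 24)))                        # p = 0.02 < 0.05
    colnames(a) <- paste0("m", 1:10)
    g <- GenotypeData(a, chrom = rep("2L", 10), pos = 1:10 * 100L)
    f <- suppressMessages(filterMarkers(g, mafMin = 0.05))
    expect_equal(ncol(genoCounts(f)), 6)
    ## mafMin = 0 drops only the monomorphic columns
    f0 <- suppressMessages(filterMarkers(g, mafMin = 0))
    expect_equal(ncol(genoCounts(f0)), 7)
    ## idempotence
    f2 <- suppressMessages(filterMarkers(f, mafMin = 0.05))
    expect_identical(genoCounts(f2), genoCounts(f))
    ## total removal errors
    mono <- GenotypeData(matrix(2, 4, 2), chrom = c("2L", "2L"),
                         pos = c(1L, 2L))
    expect_error(filterMarkers(mono), "all markers removed")
})

test_that("SNP-to-gene window is inclusive at exactly 5 kb", {
    a <- matrix(rep(c(0, 2, 2, 0), 3), nrow = 4)
    colnames(a) <- c("in_window", "out_window", "inside")
    g <- GenotypeData(a, chrom = rep("2L", 3),
                      pos = c(7000L, 7001L, 1500L))
    genes <- GenomicRanges::GRanges("2L",
        IRanges::IRanges(start = 1000, end = 2000), gene_id = "gA")
    gm <- mapSnpsToGenes(g, genes, windowBp = 5000L)
    hit <- markerIds(g)[gm$gA]
    expect_true("in_window" %in% hit)   # pos 7000 = end + 5000
    expect_false("out_window" %in% hit) # pos 7001
    expect_true("inside" %in% hit)
})

test_that("a marker inside two overlapping genes maps to both", {
    a <- matrix(c(0, 2), 2, 1, dimnames = list(NULL, "m1"))
    g <- GenotypeData(a, chrom = "2L", pos = 1500L)
    genes <- GenomicRanges::GRanges("2L",
        IRanges::IRanges(start = c(1000, 1400), end = c(2000, 2600)),
        gene_id = c("gA", "gB"))
    gm <- mapSnpsToGenes(g, genes, windowBp = 0L)
    expect_equal(gm$gA, 1L)
    expect_equal(gm$gB, 1L)
})

test_that("chromosome naming mismatches are reported", {
    a <- matrix(c(0, 2), 2, 1, dimnames = list(NULL, "m1"))
    g <- GenotypeData(a, chrom = "2L", pos = 100L)
    genes <- GenomicRanges::GRanges("chr2L",
        IRanges::IRanges(1, 10), gene_id = "gA")
    expect_error(mapSnpsToGenes(g, genes), "chr2L")
})

test_that("BED (0-based) and GFF3 (1-based) readers agree", {
    bed <- withr::local_tempfile(fileext = ".bed")
    writeLines("2L\t999\t2000\tgA", bed)
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
                 "2L\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=gA"), gff)
    gb <- readGenes(bed, "bed")
    gg <- readGenes(gff, "gff3")
    expect_equal(GenomicRanges::start(gb), 1000)
    expect_equal(GenomicRanges::start(gg), 1000)
    expect_equal(GenomicRanges::end(gb), GenomicRanges::end(gg))
    expect_identical(gb$gene_id, gg$gene_id)
})

test_that("buildSnpSets enforces the >10 genes and >199 markers rules", {
    ## 12 genes with 20 markers each, non-overlapping marker ranges
    geneMap <- lapply(0:11, function(i) (i * 20 + 1):(i * 20 + 20))
    names(geneMap) <- paste0("g", 1:12)
    m <- 240L
    mkGo <- function(genes, id = "GO:1")
        data.frame(gene_id = genes, go_id = id, class = "BP")
    ## 10 genes -> dropped regardless of markers
    expect_error(buildSnpSets(mkGo(paste0("g", 1:10)), geneMap = geneMap,
                              nMarkersTotal = m, verbose = FALSE),
                 "no SNP-set")
    ## 11 genes x 20 = 220 markers >= 200 -> kept
    cat11 <- suppressMessages(
        buildSnpSets(geneMap, mkGo(paste0("g", 1:11)), m,
                     verbose = FALSE))
    expect_identical(setIds(cat11), "GO:1")
    expect_equal(lengths(setMarkers(cat11))[["GO:1"]], 220L)
    ## 11 genes but only 199 distinct markers -> dropped
    gm199 <- geneMap
    gm199[["g11"]] <- 201:218  # 18 markers
    gm199[["g1"]] <- 1:1       # union = 1 + 9*20 + 18 = 199 markers
    expect_error(buildSnpSets(gm199, mkGo(paste0("g", 1:11)), m,
                              verbose = FALSE),
                 "no SNP-set")
    gm200 <- gm199
    gm200[["g1"]] <- 1:2       # union = 200 -> kept
    cat200 <- buildSnpSets(gm200, mkGo(paste0("g", 1:11)), m,
                           verbose = FALSE)
    expect_equal(lengths(setMarkers(cat200))[["GO:1"]], 200L)
})

test_that("shared markers are counted once per set", {
    geneMap <- list(gA = 1:10, gB = c(6:10, 11:20))
    go <- data.frame(gene_id = c("gA", "gB"), go_id = "GO:9",
                     class = "MF")
    cat2 <- buildSnpSets(geneMap, go, nMarkersTotal = 25L,
                         minGenes = 2L, minMarkers = 1L,
                         verbose = FALSE)
    expect_equal(setMarkers(cat2)[["GO:9"]], 1:20)
    expect_equal(lengths(setMarkers(cat2))[["GO:9"]], 15L + 5L)
})

test_that("catalog is invariant to GO table row order and stays sorted", {
    set.seed(8)
    geneMap <- lapply(1:30, function(i) sort(sample(500, 30)))
    names(geneMap) <- paste0("g", 1:30)
    go <- data.frame(gene_id = paste0("g", rep(1:30, 2)),
                     go_id = rep(c("GO:1", "GO:2"), each = 30),
                     class = "BP")
    c1 <- buildSnpSets(geneMap, go, 500L, minGenes = 5L,
                       minMarkers = 10L, verbose = FALSE)
    c2 <- buildSnpSets(geneMap, go[sample(nrow(go)), ], 500L,
                       minGenes = 5L, minMarkers = 10L,
                       verbose = FALSE)
    expect_identical(setMarkers(c1), setMarkers(c2))
    for (ix in setMarkers(c1))
        expect_false(is.unsorted(ix, strictly = TRUE))
    ## unknown gene ids are ignored with a message
    goBad <- rbind(go, data.frame(gene_id = "nope", go_id = "GO:1",
                                  class = "BP"))
    expect_message(buildSnpSets(geneMap, goBad, 500L, minGenes = 5L,
                                minMarkers = 10L, verbose = FALSE),
                   "absent")
})
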