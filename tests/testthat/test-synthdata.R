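test_that("generators are deterministic under a fixed seed", {
    cfg <- simConfig(nLines = 12, nMarkersPerChrom = 60, nGenes = 20,
                     geneLen = 500L, intergenicLen = 500L, seed = 42)
    g1 <- simulateGenotypes(cfg)
    g2 <- simulateGenotypes(cfg)
    expect_identical(genoCounts(g1), genoCounts(g2))
    a1 <- simulateAnnotation(cfg)
    a2 <- simulateAnnotation(cfg)
    expect_identical(a1$go, a2$go)
    expect_true(all(a1$genes == a2$genes))
    t1 <- simulateTrait(g1, a1, cfg)
    t2 <- simulateTrait(g2, a2, cfg)
    expect_identical(t1$pheno, t2$pheno)
    expect_identical(t1$truth$true_s, t2$truth$true_s)
})

test_that("inbred genotypes are homozygous and respect the MAF range", {
    cfg <- simConfig(nLines = 20, nMarkersPerChrom = 100,
                     mafRange = c(0.1, 0.4), seed = 7)
    g <- simulateGenotypes(cfg)
    a <- genoCounts(g)
    expect_true(all(a %in% c(0, 2)))
    p <- markerMAF(g)
    expect_true(all(p >= 0.1 & p <= 0.4))
    ghet <- simulateGenotypes(simConfig(nLines = 20,
                                        nMarkersPerChrom = 100,
                                        inbreeding = 0.3, seed = 7))
    expect_true(any(genoCounts(ghet) == 1))
})

test_that("LD blocks give high within-block, null between-block r", {
    cfg <- simConfig(nLines = 200, nMarkersPerChrom = 300,
                     chromNames = "2L", ldBlockLen = 10, seed = 11)
    a <- genoCounts(simulateGenotypes(cfg))
    r <- vapply(seq_len(ncol(a) - 1L),
                function(j) cor(a[, j], a[, j + 1L]), numeric(1))
    within <- r[seq_len(ncol(a) - 1L) %% 10 != 0]
    between <- r[seq_len(ncol(a) - 1L) %% 10 == 0]
    expect_gt(mean(abs(within)), 0.8)
    expect_lt(abs(mean(between)), 0.15)
    ## no-LD generator: adjacent markers essentially uncorrelated
    cfg1 <- simConfig(nLines = 200, nMarkersPerChrom = 500,
                      chromNames = "2L", ldBlockLen = 1, seed = 12)
    a1 <- genoCounts(simulateGenotypes(cfg1))
    r1 <- vapply(seq_len(ncol(a1) - 1L),
                 function(j) cor(a1[, j], a1[, j + 1L]), numeric(1))
    expect_lt(abs(mean(r1)), 0.1)
})

test_that("annotation yields disjoint ordered genes and sized GO sets", {
    cfg <- simConfig(nLines = 10, nMarkersPerChrom = 200,
                     chromNames = "2L", nGenes = 10,
                     nGoSets = c(BP = 3L, MF = 2L, CC = 1L),
                     goSizeRange = c(4L, 4L), seed = 5)
    an <- simulateAnnotation(cfg)
    expect_length(an$genes, 10)
    st <- GenomicRanges::start(an$genes)
    en <- GenomicRanges::end(an$genes)
    expect_true(all(diff(st) > 0))
    expect_true(all(st[-1] > en[-length(en)]))  # disjoint
    sizes <- table(an$go$go_id)
    expect_true(all(sizes == 4))
    expect_setequal(unique(an$go$class), c("BP", "MF", "CC"))
})

test_that("annotation refuses genes that do not fit the chromosomes", {
    cfg <- simConfig(nLines = 10, nMarkersPerChrom = 10,
                     chromNames = "2L", nGenes = 50, seed = 1)
    expect_error(simulateAnnotation(cfg), "exceed")
})

test_that("trait simulation honours the h2 target and ground truth", {
    cfg <- simConfig(nLines = 15, nMarkersPerChrom = 50, nGenes = 30,
                     geneLen = 300L, intergenicLen = 200L,
                     h2Target = 0, seed = 3)
    g <- simulateGenotypes(cfg)
    an <- simulateAnnotation(cfg)
    s0 <- simulateTrait(g, an, cfg)
    expect_true(all(s0$truth$true_s == 0))
    expect_identical(s0$truth$true_h2, 0)
    cfg5 <- simConfig(nLines = 15, nMarkersPerChrom = 50, nGenes = 30,
                      geneLen = 300L, intergenicLen = 200L,
                      h2Target = 0.5, seed = 3)
    s5 <- simulateTrait(g, an, cfg5)
    ## true_g is exactly W %*% true_s (same scaling as downstream)
    sc <- scaleGenotypes(g)
    expect_equal(as.numeric(sc$W %*% s5$truth$true_s),
                 s5$truth$true_g, tolerance = 1e-12)
    ## replicate rows share the line's g: line means of (value - fixed
    ## part) differ between lines when h2 > 0
    expect_gt(s5$truth$true_h2, 0.2)
    expect_lt(s5$truth$true_h2, 0.8)
})

test_that("causal sets restrict true effects to their member markers", {
    cfg <- simConfig(nLines = 15, nMarkersPerChrom = 150, nGenes = 40,
                     nGoSets = c(BP = 4L, MF = 2L, CC = 2L),
                     causalSets = "GO:0000001", h2Target = 0.6,
                     seed = 9)
    g <- simulateGenotypes(cfg)
    an <- simulateAnnotation(cfg)
    st <- simulateTrait(g, an, cfg)
    expect_identical(st$truth$causal_set_ids, "GO:0000001")
    nz <- which(st$truth$true_s != 0)
    expect_true(length(nz) > 0)
    expect_true(all(nz %in% st$truth$causal_markers))
    gm <- mapSnpsToGenes(g, an$genes)
    members <- an$go$gene_id[an$go$go_id == "GO:0000001"]
    inSet <- sort(unique(unlist(gm[members])))
    expect_true(all(nz %in% inSet))
    expect_error(
        simulateTrait(g, an, simConfig(nLines = 15,
                                       nMarkersPerChrom = 150,
                                       causalSets = "GO:9999999",
                                       seed = 9)),
        "not in annotation")
})

test_that("degenerate configurations are rejected or warned about", {
    expect_error(simConfig(nLines = 1), "at least 2")
    expect_error(simConfig(ldBlockLen = 0), "ldBlockLen")
    expect_error(simConfig(h2Target = 1.2), "h2Target")
    expect_error(simConfig(mafRange = c(0, 0.5)), "mafRange")
    cfg <- simConfig(nLines = 10, nMarkersPerChrom = 50, nGenes = 10,
                     h2Target = 1, nRepsPerLine = 3, seed = 2)
    g <- simulateGenotypes(cfg)
    an <- simulateAnnotation(cfg)
    expect_warning(simulateTrait(g, an, cfg), "degenerate")
})

test_that("subsetting lines can create monomorphic markers", {
    cfg <- simConfig(nLines = 30, nMarkersPerChrom = 200,
                     chromNames = "2L", ldBlockLen = 1,
                     mafRange = c(0.05, 0.15), seed = 21)
    g <- simulateGenotypes(cfg)
    gs <- subsetLines(g, 1:5)
    expect_true(any(markerMAF(gs) == 0))
})
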