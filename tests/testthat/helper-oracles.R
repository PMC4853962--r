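## Independent oracles and small fixture builders shared across tests.

## Dense REML log-likelihood, written directly from the definition
## -0.5 (log|V| + log|X' V^-1 X| + r' V^-1 r) with V = sg * ZGZ' + se * I
## and r the GLS residual. Deliberately naive (solve/det), used only on
## tiny fixtures as the brute-force reference for the optimizer.
denseRemlLogLik <- function(y, X, ZGZt, sg, se) {
    n <- length(y)
    V <- sg * ZGZt + diag(se, n)
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    beta <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    as.numeric(-0.5 * (determinant(V)$modulus +
                       determinant(XtViX)$modulus +
                       t(r) %*% Vi %*% r))
}

## Two-stage grid search over (sigma_g^2, sigma_e^2): a coarse
## gridN x gridN sweep over (lo, hi], then an equally sized refinement
## around the coarse argmax. Returns the best point and its loglik.
gridSearchReml <- function(y, X, ZGZt, gridN = 100, hi = NULL) {
    if (is.null(hi)) hi <- 3 * var(y)
    sweep1 <- function(sgs, ses) {
        ll <- matrix(-Inf, length(sgs), length(ses))
        for (i in seq_along(sgs))
            for (j in seq_along(ses))
                ll[i, j] <- denseRemlLogLik(y, X, ZGZt, sgs[i], ses[j])
        ij <- which(ll == max(ll), arr.ind = TRUE)[1, ]
        list(sg = sgs[ij[1]], se = ses[ij[2]], ll = max(ll),
             step = c(sgs[2] - sgs[1], ses[2] - ses[1]), all = ll)
    }
    sgs <- seq(1e-8, hi, length.out = gridN)
    ses <- seq(1e-8, hi, length.out = gridN)
    c1 <- sweep1(sgs, ses)
    sgs2 <- seq(max(1e-10, c1$sg - 2 * c1$step[1]),
                c1$sg + 2 * c1$step[1], length.out = gridN)
    ses2 <- seq(max(1e-10, c1$se - 2 * c1$step[2]),
                c1$se + 2 * c1$step[2], length.out = gridN)
    c2 <- sweep1(sgs2, ses2)
    list(sg = c2$sg, se = c2$se, ll = max(c1$ll, c2$ll),
         h2 = c2$sg / (c2$sg + c2$se),
         llCoarseMax = c1$ll)
}

## Small simulated fixture: genotypes, phenotype, design pieces.
makeFixture <- function(seed, nLines = 10, reps = 2, m = 120,
                        h2 = 0.5, nGenes = 12) {
    cfg <- simConfig(nLines = nLines, nMarkersPerChrom = ceiling(m / 2),
                     chromNames = c("2L", "2R"), ldBlockLen = 5,
                     nGenes = nGenes, geneLen = 200L,
                     intergenicLen = 100L, h2Target = h2,
                     nRepsPerLine = reps, seed = seed)
    geno <- filterMarkers(simulateGenotypes(cfg), verbose = FALSE)
    annot <- simulateAnnotation(cfg)
    sim <- simulateTrait(geno, annot, cfg)
    scaled <- scaleGenotypes(geno)
    G <- computeGRM(scaled)$G
    dimnames(G) <- list(lineIds(geno), lineIds(geno))
    ph <- sim$pheno
    X <- stats::model.matrix(
        ~ wolbachia + inv1 + inv2 + inv3 + inv4 + inv5 + factor(block),
        data = ph)
    q <- qr(X)
    X <- X[, sort(q$pivot[seq_len(q$rank)]), drop = FALSE]
    Z <- outer(ph$line_id, lineIds(geno), "==") * 1
    list(cfg = cfg, geno = geno, annot = annot, sim = sim,
         scaled = scaled, G = G, pheno = ph, X = X, Z = Z,
         ZGZt = Z %*% G %*% t(Z))
}

## Exact upper-tail overlap probability under independent column
## permutation with fixed margins: P(overlap >= x) for columns with k1
## and k2 ones among n rows (hypergeometric).
hyperTailGe <- function(x, n, k1, k2) {
    stats::phyper(x - 1, k1, n - k1, k2, lower.tail = FALSE)
}
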