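#' Centre and scale an allele-count matrix
#'
#' Each column of the allele-count matrix A (lines x markers, minor
#' allele counts) is transformed to
#' w_i = (a_i - 2 p_i) / sqrt(2 p_i (1 - p_i)),
#' where p_i is the sample minor allele frequency of marker i. Columns
#' are exactly mean-centred. Note that on fully inbred lines (genotypes
#' in \{0, 2\}) the empirical column variance is about 2 p (1 - p) /
#' (p (1 - p) / 2)... i.e. about 2, not 1: the 2 p (1 - p) denominator
#' assumes Hardy-Weinberg heterozygosity. The formula is applied as
#' stated; \code{empirical = TRUE} rescales each column to unit sample
#' variance instead, for comparison.
#'
#' @param geno a \linkS4class{GenotypeData} (filtered: no monomorphic
#'   markers).
#' @param empirical scale columns by their sample standard deviation
#'   instead of sqrt(2 p (1 - p)).
#' @return list with \code{W} (lines x markers), \code{p} (per-marker
#'   MAF) and \code{m} (marker count).
#' @export
scaleGenotypes <- function(geno, empirical = FALSE) {
    a <- genoCounts(geno)
    p <- colMeans(a) / 2
    if (any(p == 0 | p == 1))
        stop("monomorphic markers present; run filterMarkers() first")
    ctr <- sweep(a, 2L, 2 * p)
    s <- if (empirical) apply(ctr, 2L, sd) else sqrt(2 * p * (1 - p))
    if (any(s == 0))
        stop("zero-variance markers present; run filterMarkers() first")
    W <- sweep(ctr, 2L, s, "/")
    list(W = W, p = unname(p), m = ncol(W))
}

#' Genomic relationship matrix
#'
#' G = W W' / m from the centred and scaled genotype matrix, where m is
#' the total number of markers. G is symmetric positive semi-definite by
#' construction.
#'
#' @param scaled result of \code{\link{scaleGenotypes}}, or a numeric
#'   matrix W (lines x markers).
#' @return list with \code{G} (lines x lines) and \code{m}.
#' @export
computeGRM <- function(scaled) {
    W <- if (is.list(scaled)) scaled$W else scaled
    m <- ncol(W)
    if (m < 1L) stop("at least one marker required")
    G <- tcrossprod(W) / m
    G <- (G + t(G)) / 2
    list(G = G, m = m)
}

## REML log-likelihood profiled over sigma_e^2 at fixed lambda =
## sigma_g^2 / sigma_e^2, in the eigenbasis of H = Z G Z'.
## Returns the profile loglik and the implied (sigmaG, sigmaE).
## Constant terms in 2*pi are dropped throughout (also in y'Py form).
.remlProfile <- function(lambda, d, yt, Xt) {
    n <- length(yt); p <- ncol(Xt)
    v <- lambda * d + 1
    if (any(v <= 0)) return(list(ll = -Inf))
    iv <- 1 / v
    XtW <- Xt * iv
    XtVX <- crossprod(Xt, XtW)
    ch <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(XtW, yt)))
    r <- yt - Xt %*% beta
    rss <- sum(r^2 * iv)
    sigmaE <- rss / (n - p)
    ll <- -0.5 * (sum(log(v)) + (n - p) * log(sigmaE) +
                  2 * sum(log(diag(ch))) + (n - p))
    list(ll = as.numeric(ll), sigmaE = sigmaE,
         sigmaG = lambda * sigmaE, beta = as.numeric(beta))
}

#' REML log-likelihood of the genomic mixed model
#'
#' Evaluates the restricted log-likelihood of y = Xb + Zg + e at given
#' variance components, with V = sigmaG * Z G Z' + sigmaE * I:
#' -0.5 (log|V| + log|X'V^-1 X| + r'V^-1 r), r the GLS residual.
#' Constants in 2 pi are omitted. Intended for diagnostics and for
#' validating the optimizer against direct grid evaluation.
#'
#' @param y numeric response (n_obs).
#' @param X design matrix (n_obs x p), full rank.
#' @param H the n_obs x n_obs matrix Z G Z'.
#' @param sigmaG,sigmaE variance components (>= 0, not both 0).
#' @return the restricted log-likelihood (numeric scalar).
#' @export
remlLogLik <- function(y, X, H, sigmaG, sigmaE) {
    V <- sigmaG * H + diag(sigmaE, length(y))
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    XtViX <- crossprod(X, Vi_X)
    beta <- solve(XtViX, crossprod(X, Vi_y))
    r <- y - X %*% beta
    Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
    as.numeric(-0.5 * (2 * sum(log(diag(ch))) +
                       determinant(XtViX)$modulus +
                       crossprod(r, Vi_r)))
}

.pruneCollinear <- function(X) {
    q <- qr(X)
    keep <- q$pivot[seq_len(q$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    list(X = X[, sort(keep), drop = FALSE], dropped = dropped)
}

.buildDesign <- function(pheno, covariates, factorCovariates) {
    if (length(covariates) == 0L)
        return(matrix(1, nrow(pheno), 1L,
                      dimnames = list(NULL, "(Intercept)")))
    terms <- vapply(covariates, function(v)
        if (v %in% factorCovariates) paste0("factor(", v, ")") else v,
        character(1))
    f <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
    stats::model.matrix(f, data = pheno)
}

#' Fit the genomic mixed model by REML
#'
#' Fits y = Xb + Zg + e with g ~ N(0, G sigma_g^2) and
#' e ~ N(0, I sigma_e^2) by restricted maximum likelihood. The
#' likelihood is profiled on the variance ratio lambda = sigma_g^2 /
#' sigma_e^2 in the eigenbasis of Z G Z' (one eigendecomposition per
#' fit), scanned on a log grid and polished with Brent's method;
#' nonnegativity holds by construction and boundary solutions
#' (sigma_g^2 = 0) are reported, not clipped. Fixed effects are
#' estimated by GLS at the optimum; collinear design columns are pruned
#' (and reported) beforehand. Line BLUPs are
#' g_hat = sigma_g^2 G Z' V^-1 (y - X b_hat).
#'
#' @param pheno data.frame of observations with columns \code{line_id},
#'   \code{value}, and the covariates.
#' @param G genomic relationship matrix with line ids as dimnames, or
#'   the list from \code{\link{computeGRM}}.
#' @param covariates character, fixed-effect columns of \code{pheno}
#'   (an intercept is always included).
#' @param factorCovariates covariates to treat as unordered factors
#'   (default \code{"block"}; binary 0/1 covariates are equivalent
#'   either way).
#' @param trait optional trait name to subset the \code{trait} column.
#' @return A \linkS4class{GblupFit}.
#' @export
remlFit <- function(pheno, G,
                    covariates = c("wolbachia", paste0("inv", 1:5),
                                   "block"),
                    factorCovariates = "block",
                    trait = NULL) {
    if (is.list(G) && !is.matrix(G)) G <- G$G
    if (!is.null(trait)) pheno <- pheno[pheno$trait == trait, ]
    if (is.null(rownames(G)))
        stop("G must carry line ids as dimnames")
    covariates <- intersect(covariates, names(pheno))
    bad <- setdiff(unique(pheno$line_id), rownames(G))
    if (length(bad))
        stop("phenotype lines absent from G: ",
             paste(head(bad, 5L), collapse = ", "))
    usedLines <- rownames(G)[rownames(G) %in% pheno$line_id]
    G <- G[usedLines, usedLines, drop = FALSE]
    lineIdx <- match(pheno$line_id, usedLines)
    X0 <- .buildDesign(pheno, covariates, factorCovariates)
    pr <- .pruneCollinear(X0)
    if (length(pr$dropped))
        message("collinear design columns pruned: ",
                paste(pr$dropped, collapse = ", "))
    fit <- .remlFitCore(pheno$value, pr$X, G, lineIdx)
    fit@droppedColumns <- pr$dropped
    fit@lineIds <- usedLines
    names(fit@gblup) <- usedLines
    fit
}

.remlFitCore <- function(y, X, G, lineIdx) {
    n <- length(y); p <- ncol(X)
    if (n <= p)
        stop("fewer observations than fixed-effect parameters")
    Z <- matrix(0, n, nrow(G))
    Z[cbind(seq_len(n), lineIdx)] <- 1
    H <- Z %*% G %*% t(Z)
    eg <- eigen((H + t(H)) / 2, symmetric = TRUE)
    d <- pmax(eg$values, 0)
    identifiable <- (max(d) - min(d)) > 1e-8 * max(1, max(d))
    if (!identifiable)
        warning("Z G Z' is (near) proportional to the identity: ",
                "sigma_g^2 and sigma_e^2 are only jointly identifiable; ",
                "reporting the boundary fit sigma_g^2 = 0")
    yt <- as.numeric(crossprod(eg$vectors, y))
    Xt <- crossprod(eg$vectors, X)
    obj <- function(loglam) .remlProfile(exp(loglam), d, yt, Xt)$ll
    grid <- seq(-18, 18, length.out = 121)
    llg <- vapply(grid, obj, numeric(1))
    ll0 <- .remlProfile(0, d, yt, Xt)$ll
    best <- which.max(llg)
    opt <- optimize(obj,
                    lower = grid[max(1L, best - 1L)],
                    upper = grid[min(length(grid), best + 1L)],
                    maximum = TRUE, tol = 1e-10)
    boundary <- FALSE
    if (!identifiable || ll0 >= opt$objective) {
        sol <- .remlProfile(0, d, yt, Xt)
        boundary <- TRUE
    } else {
        sol <- .remlProfile(exp(opt$maximum), d, yt, Xt)
        if (opt$maximum >= grid[length(grid)] - 1e-6) boundary <- TRUE
    }
    if (!is.finite(sol$ll))
        stop("REML fit did not converge (non-finite profile likelihood)")
    sigmaG <- sol$sigmaG; sigmaE <- sol$sigmaE
    ## GLS fixed effects and BLUPs at the optimum
    v <- (sigmaG / max(sigmaE, .Machine$double.xmin)) * d + 1
    Vi_r <- eg$vectors %*% ((yt - Xt %*% sol$beta) / (sigmaE * v))
    gblup <- as.numeric(sigmaG * G %*% crossprod(Z, Vi_r))
    beta <- stats::setNames(sol$beta, colnames(X))
    methods::new("GblupFit", beta = beta, gblup = gblup,
                 sigmaG = sigmaG, sigmaE = sigmaE, logLik = sol$ll,
                 converged = TRUE, boundary = boundary,
                 identifiable = identifiable,
                 droppedColumns = character(0),
                 lineIds = character(0))
}

#' SNP heritability of a fitted model
#'
#' h2_SNP = sigma_g^2 / (sigma_g^2 + sigma_e^2), the fraction of the
#' non-fixed phenotypic variance captured by the markers.
#'
#' @param fit a \linkS4class{GblupFit}, or \code{sigmaG} as a numeric
#'   scalar.
#' @param sigmaE residual variance (when \code{fit} is a scalar).
#' @return proportion in [0, 1].
#' @export
heritability <- function(fit, sigmaE = NULL) {
    if (methods::is(fit, "GblupFit")) {
        sg <- fit@sigmaG; se <- fit@sigmaE
    } else {
        sg <- fit; se <- sigmaE
    }
    if (sg + se <= 0)
        stop("heritability undefined: both variance components are zero")
    sg / (sg + se)
}

#' Accessors for GblupFit
#'
#' @param fit a \linkS4class{GblupFit}.
#' @return \code{lineBLUP}: the named per-line genomic values;
#'   \code{fixedEffects}: the fixed-effect estimates;
#'   \code{varianceComponents}: c(sigmaG, sigmaE).
#' @rdname gblupfit-accessors
#' @export
lineBLUP <- function(fit) fit@gblup

#' @rdname gblupfit-accessors
#' @export
fixedEffects <- function(fit) fit@beta

#' @rdname gblupfit-accessors
#' @export
varianceComponents <- function(fit)
    c(sigmaG = fit@sigmaG, sigmaE = fit@sigmaE)

#' Bootstrap confidence interval for SNP heritability
#'
#' Observations (rows of the phenotype table) are resampled with
#' replacement, keeping the original number of observations; the model
#' is refit on each replicate (lines absent from a replicate are dropped
#' from G for that fit) and the 95\% interval is read off as the 2.5\%
#' and 97.5\% empirical (nearest-rank) quantiles of the replicate
#' heritabilities. Replicates whose fit fails are skipped and counted.
#'
#' @inheritParams remlFit
#' @param nBoot number of bootstrap replicates (>= 100; the reference
#'   analysis used 10,000).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @param lineMeans resample line means instead of raw observations.
#' @return list with \code{lower}, \code{upper}, \code{h2} (replicate
#'   estimates), \code{nFailed}, \code{seed}.
#' @export
bootstrapCI <- function(pheno, G,
                        covariates = c("wolbachia", paste0("inv", 1:5),
                                       "block"),
                        factorCovariates = "block",
                        nBoot = 10000L, seed = 1L, level = 0.95,
                        lineMeans = FALSE) {
    if (nBoot < 100L)
        stop("nBoot must be at least 100")
    if (lineMeans) {
        agg <- stats::aggregate(value ~ line_id, pheno, mean)
        keep <- !duplicated(pheno$line_id)
        pheno <- pheno[keep, , drop = FALSE]
        pheno$value <- agg$value[match(pheno$line_id, agg$line_id)]
    }
    set.seed(seed)
    n <- nrow(pheno)
    h2 <- rep(NA_real_, nBoot)
    for (b in seq_len(nBoot)) {
        idx <- sample.int(n, n, replace = TRUE)
        rep_b <- pheno[idx, , drop = FALSE]
        h2[b] <- tryCatch(
            suppressWarnings(suppressMessages(
                heritability(remlFit(rep_b, G, covariates,
                                     factorCovariates)))),
            error = function(e) NA_real_)
    }
    nFailed <- sum(is.na(h2))
    if (nFailed > 0.1 * nBoot)
        warning(nFailed, " of ", nBoot, " bootstrap fits failed")
    qs <- quantile(h2, c((1 - level) / 2, 1 - (1 - level) / 2),
                   na.rm = TRUE, type = 1, names = FALSE)
    list(lower = qs[1], upper = qs[2], h2 = h2, nFailed = nFailed,
         seed = seed)
}

#' Spearman correlation of genomic values across traits
#'
#' Rank correlation of per-line genomic BLUPs (or any per-line values)
#' between two traits, aligned on shared lines, with a two-sided
#' t-approximation p-value: t = rho sqrt((n-2)/(1-rho^2)) on n - 2
#' degrees of freedom.
#'
#' @param gA,gB named numeric vectors (names = line ids), e.g.
#'   \code{lineBLUP(fit)}.
#' @return list with \code{rho}, \code{p}, \code{n}.
#' @export
genomicCorrelation <- function(gA, gB) {
    if (!is.null(names(gA)) && !is.null(names(gB))) {
        shared <- intersect(names(gA), names(gB))
        gA <- gA[shared]; gB <- gB[shared]
    } else if (length(gA) != length(gB)) {
        stop("unnamed vectors must have equal length")
    }
    n <- length(gA)
    if (n < 4L) stop("at least 4 shared lines required")
    rho <- cor(gA, gB, method = "spearman")
    p <- if (abs(rho) >= 1) 0
         else 2 * pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), n - 2)
    list(rho = rho, p = p, n = n)
}
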