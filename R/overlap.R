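#' Build the SNP-set x trait incidence matrix
#'
#' Binary matrix with one row per SNP-set and one column per trait;
#' entry 1 when that trait's empirical p-value for the set is strictly
#' below \code{threshold} (default 0.05).
#'
#' @param resultsList named list of \code{\link{pathwayTest}} result
#'   data.frames, one per trait, all computed on the same catalog.
#' @param threshold sub-significance threshold.
#' @return binary integer matrix (sets x traits) with dimnames.
#' @export
buildIncidence <- function(resultsList, threshold = 0.05) {
    if (is.null(names(resultsList)))
        names(resultsList) <- paste0("trait_", seq_along(resultsList))
    ids <- resultsList[[1]]$go_id
    for (r in resultsList)
        if (!identical(r$go_id, ids))
            stop("all traits must be tested on the same SNP-set list ",
                 "(set ids differ)")
    inc <- vapply(resultsList, function(r) as.integer(r$p < threshold),
                  integer(length(ids)))
    rownames(inc) <- ids
    inc
}

#' Permutation test for cross-trait overlap of sub-threshold SNP-sets
#'
#' For every pair of traits the observed overlap is the number of
#' SNP-sets flagged (entry 1) in both columns. Under the null of
#' independent association across traits, each column of the incidence
#' matrix is independently permuted \code{nPerm} times (column sums,
#' i.e. per-trait counts, are preserved) and the overlap recorded; the
#' one-tailed empirical p-value is the fraction of permutations whose
#' overlap is greater than or equal to the observed one. With fixed
#' margins this null is Hypergeometric(n, k1, k2), which serves as an
#' analytic cross-check.
#'
#' @param inc binary matrix from \code{\link{buildIncidence}}.
#' @param nPerm number of permutations (default 10,000).
#' @param seed RNG seed.
#' @param alpha level at which an overlap is flagged significant
#'   (default 0.05).
#' @return data.frame with one row per unordered trait pair: traitA,
#'   traitB, k1, k2, observed, n_perm, p, significant.
#' @export
overlapTest <- function(inc, nPerm = 10000L, seed = 1L, alpha = 0.05) {
    if (ncol(inc) < 2L) stop("at least two traits required")
    if (!all(inc %in% c(0L, 1L))) stop("incidence matrix must be binary")
    n <- nrow(inc)
    ks <- colSums(inc)
    zero <- names(ks)[ks == 0L]
    if (length(zero))
        message("trait(s) with no sub-threshold set: ",
                paste(zero, collapse = ", "),
                " (overlaps involving them are 0, p = 1)")
    pairs <- utils::combn(colnames(inc), 2L)
    obs <- apply(pairs, 2L, function(pr)
        sum(inc[, pr[1]] & inc[, pr[2]]))
    set.seed(seed)
    geCount <- integer(ncol(pairs))
    for (b in seq_len(nPerm)) {
        perm <- apply(inc, 2L, sample)
        ov <- apply(pairs, 2L, function(pr)
            sum(perm[, pr[1]] & perm[, pr[2]]))
        geCount <- geCount + (ov >= obs)
    }
    p <- geCount / nPerm
    data.frame(traitA = pairs[1, ], traitB = pairs[2, ],
               k1 = unname(ks[pairs[1, ]]), k2 = unname(ks[pairs[2, ]]),
               observed = as.integer(obs), n_perm = nPerm, p = p,
               significant = p <= alpha, row.names = NULL)
}

#' Expected false-positive and overlap counts under the null
#'
#' Analytic expectations used to judge the per-trait counts of
#' sub-threshold SNP-sets: with n independent sets tested at level
#' alpha, n * alpha sets are expected significant per trait by chance,
#' and n * alpha^2 sets are expected sub-threshold in both traits of a
#' pair. Returned unrounded along with nearest-integer (half away from
#' zero) roundings.
#'
#' @param nSets number of SNP-sets in the class.
#' @param alpha threshold level.
#' @return list with \code{expected_fp}, \code{expected_overlap}, and
#'   rounded \code{expected_fp_int}, \code{expected_overlap_int}.
#' @examples
#' expectedCounts(689, 0.05)  # 34.45 sets, 1.72 overlapping
#' @export
expectedCounts <- function(nSets, alpha) {
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
    fp <- nSets * alpha
    ov <- nSets * alpha^2
    roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)
    list(expected_fp = fp, expected_overlap = ov,
         expected_fp_int = roundHalfUp(fp),
         expected_overlap_int = roundHalfUp(ov))
}
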