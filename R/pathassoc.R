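#' Sum of marker effects within a SNP-set
#'
#' The set summary statistic T_sum: the signed sum of the back-solved
#' marker effects over the (deduplicated) member markers.
#'
#' @param effects numeric vector of genome-ordered marker effects.
#' @param setIdx integer indices (1-based) of the set's markers.
#' @return numeric scalar.
#' @export
tsum <- function(effects, setIdx) {
    if (length(setIdx) == 0L) stop("empty SNP-set")
    sum(effects[setIdx])
}

#' Circular shift of the genome-ordered effect vector
#'
#' Makes element j the first element and wraps the preceding elements to
#' the end: (s_j, s_j+1, ..., s_m, s_1, ..., s_j-1). Rotation preserves
#' the multiset of effects and every adjacency except at the single
#' seam, so local LD correlation among neighbouring effects survives
#' while the link to set membership is broken (set-to-index mappings are
#' kept fixed).
#'
#' @param effects numeric vector (length m).
#' @param j starting index in 1..m; j = 1 is the identity.
#' @return rotated numeric vector.
#' @examples
#' rotateEffects(letters[1:5], 3)  # c d e a b
#' @export
rotateEffects <- function(effects, j) {
    m <- length(effects)
    if (j < 1L || j > m) stop("rotation index out of range [1, m]")
    if (j == 1L) return(effects)
    c(effects[j:m], effects[1:(j - 1L)])
}

#' LD-preserving circular-permutation SNP-set association test
#'
#' For each of \code{nPerm} random rotation offsets the whole effect
#' vector is circularly shifted and T_sum is recomputed for every set
#' against the same rotated vector (one rotation evaluates all sets, so
#' per-rotation set statistics remain jointly comparable across sets and
#' usable by the cross-trait overlap test). The empirical p-value is
#' one-tailed upper: \code{pMode = "proportion"} counts rotations with
#' T_perm strictly greater than T_obs divided by nPerm (this can return
#' 0); the default \code{pMode = "plus_one"} uses
#' (#\{T_perm >= T_obs\} + 1) / (nPerm + 1), which is a valid p-value
#' under exchangeability and is bounded away from 0.
#'
#' @param effects numeric vector of genome-ordered marker effects, or
#'   the list returned by \code{\link{backsolveEffects}}.
#' @param catalog a \linkS4class{SnpSetCatalog}, or a named list of
#'   integer marker-index vectors.
#' @param nPerm number of rotations (default 10,000; < 100 warns).
#' @param seed RNG seed for the offsets.
#' @param pMode "plus_one" or "proportion".
#' @param twoSided use |T| instead of signed T (off by default).
#' @return data.frame with one row per set: go_id, class, n_genes,
#'   n_markers, t_sum, count_exceeding, n_perm, p. The rotation offsets
#'   are attached as \code{attr(, "offsets")}.
#' @export
pathwayTest <- function(effects, catalog, nPerm = 10000L, seed = 1L,
                        pMode = c("plus_one", "proportion"),
                        twoSided = FALSE) {
    pMode <- match.arg(pMode)
    if (is.list(effects) && !is.null(effects$s)) effects <- effects$s
    if (methods::is(catalog, "SnpSetCatalog")) {
        sets <- setMarkers(catalog)
        cls <- setClasses(catalog)
        ngenes <- lengths(setGenes(catalog))
        if (catalog@nMarkersTotal != length(effects))
            stop("effect vector length (", length(effects),
                 ") does not match the catalog's marker count (",
                 catalog@nMarkersTotal, ")")
    } else {
        sets <- catalog
        cls <- rep(NA_character_, length(sets))
        ngenes <- rep(NA_integer_, length(sets))
        if (is.null(names(sets)))
            names(sets) <- paste0("set_", seq_along(sets))
    }
    m <- length(effects)
    if (nPerm < 100L)
        warning("fewer than 100 rotations: empirical p-values are coarse")
    stat <- if (twoSided) function(x) abs(x) else identity
    tObs <- vapply(sets, function(ix) stat(sum(effects[ix])),
                   numeric(1))
    set.seed(seed)
    offsets <- sample.int(m, nPerm, replace = TRUE)
    exceedGt <- integer(length(sets))
    exceedGe <- integer(length(sets))
    for (b in seq_len(nPerm)) {
        rot <- rotateEffects(effects, offsets[b])
        tPerm <- vapply(sets, function(ix) stat(sum(rot[ix])),
                        numeric(1))
        exceedGt <- exceedGt + (tPerm > tObs)
        exceedGe <- exceedGe + (tPerm >= tObs)
    }
    p <- if (pMode == "proportion") exceedGt / nPerm
         else (exceedGe + 1) / (nPerm + 1)
    out <- data.frame(go_id = names(sets),
                      class = unname(cls),
                      n_genes = unname(ngenes),
                      n_markers = lengths(sets),
                      t_sum = unname(tObs),
                      count_exceeding =
                          unname(if (pMode == "proportion") exceedGt
                                 else exceedGe),
                      n_perm = nPerm,
                      p = unname(p),
                      row.names = NULL)
    attr(out, "offsets") <- offsets
    attr(out, "p_mode") <- pMode
    out
}

#' Select significant SNP-sets
#'
#' Strict threshold: sets with p < alpha.
#'
#' @param results data.frame from \code{\link{pathwayTest}}.
#' @param alpha significance level (reference analysis: 0.005).
#' @return the significant rows of \code{results}.
#' @export
significantSets <- function(results, alpha = 0.005) {
    results[results$p < alpha, , drop = FALSE]
}
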