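#' Back-solve per-marker effects from line genomic values
#'
#' Recovers genome-ordered marker effects from the fitted line-level
#' genomic values: s_hat = W' (W W')^-1 g_hat, using the Moore-Penrose
#' pseudoinverse of W W' (= m G) when it is singular. This is the
#' minimum-norm solution of W s = g_hat; when g_hat lies in the row
#' space of W (as BLUPs from G = W W'/m do), the reconstruction
#' W s_hat reproduces g_hat to numerical precision.
#'
#' @param scaled result of \code{\link{scaleGenotypes}} (or a numeric W
#'   matrix, lines x markers) whose rows align with \code{ghat}.
#' @param ghat numeric vector of per-line genomic values (e.g.
#'   \code{lineBLUP(fit)}), in the row order of W.
#' @param tol relative singular-value cutoff for the pseudoinverse;
#'   default \code{.Machine$double.eps * max(dim(W))} times the largest
#'   eigenvalue of W W'.
#' @return list with \code{s} (length-m marker effects in genome order)
#'   and \code{relResidual} = ||W s - g_hat|| / ||g_hat||.
#' @examples
#' W <- matrix(c(1, -1), 2, 1)
#' backsolveEffects(W, c(0.5, -0.5))$s  # 0.5
#' @export
backsolveEffects <- function(scaled, ghat, tol = NULL) {
    W <- if (is.list(scaled)) scaled$W else scaled
    if (nrow(W) != length(ghat))
        stop("length(ghat) must equal nrow(W)")
    WWt <- tcrossprod(W)
    eg <- eigen((WWt + t(WWt)) / 2, symmetric = TRUE)
    if (is.null(tol))
        tol <- .Machine$double.eps * max(dim(W)) * max(eg$values, 0)
    pos <- eg$values > tol
    if (!any(pos))
        stop("W W' is numerically zero")
    Ui <- eg$vectors[, pos, drop = FALSE]
    ## (WW')^+ ghat
    z <- Ui %*% (crossprod(Ui, ghat) / eg$values[pos])
    s <- as.numeric(crossprod(W, z))
    rec <- as.numeric(W %*% s)
    nrm <- sqrt(sum(ghat^2))
    rel <- if (nrm > 0) sqrt(sum((rec - ghat)^2)) / nrm else 0
    list(s = s, relResidual = rel)
}
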