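#' Angular (arcsine-square-root) transform for proportions
#'
#' The standard variance-stabilizing transform for proportion data such
#' as egg-to-adult viability: asin(sqrt(p)), mapping [0, 1] to
#' [0, pi/2] monotonically. A literal squared-arcsine variant
#' (asin(p)^2) is available for sensitivity checks.
#'
#' @param p numeric in [0, 1].
#' @param variant "sqrt" (default, angular transform) or "squared"
#'   (asin(p)^2).
#' @return transformed values in radians (radians squared for
#'   \code{variant = "squared"}).
#' @examples
#' arcsineSqrt(c(0, 0.25, 1))  # 0, asin(0.5), pi/2
#' @export
arcsineSqrt <- function(p, variant = c("sqrt", "squared")) {
    variant <- match.arg(variant)
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("proportions must lie in [0, 1]")
    if (variant == "sqrt") asin(sqrt(p)) else asin(p)^2
}

#' Equalize per-plate means
#'
#' Corrects an assay plate effect by shifting every plate's values so all
#' plates share the grand mean: value + (grand mean - plate mean).
#' Within-plate deviations and the grand mean are preserved exactly.
#'
#' @param values numeric measurements.
#' @param plate plate label per value.
#' @return adjusted values.
#' @examples
#' plateEqualize(c(1, 3, 5, 7), c("A", "A", "B", "B"))  # 3 5 3 5
#' @export
plateEqualize <- function(values, plate) {
    if (length(values) != length(plate))
        stop("values and plate must have equal length")
    plate <- as.character(plate)
    if (length(unique(plate)) == 1L) {
        message("single plate: equalization is the identity")
        return(values)
    }
    pm <- tapply(values, plate, mean)
    as.numeric(values + mean(values) - pm[plate])
}
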