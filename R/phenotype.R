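#' Lignin content from the acetylation assay
#'
#' Converts the OD280 absorbance difference and sample dry weight from the
#' lignin content assay into mg lignin per g dry weight using the kit
#' calibration: \code{lignin (mg/g) = 2.184 * deltaA / W}.
#'
#' @param deltaA Absorbance difference (>= 0).
#' @param dryWeightG Sample dry weight in grams (> 0).
#' @return Lignin content in mg/g (vectorised).
#' @export
#' @examples
#' ligninContent(1, 1)  # 2.184
ligninContent <- function(deltaA, dryWeightG) {
    if (any(dryWeightG <= 0)) stop("dry weight must be > 0")
    if (any(deltaA < 0)) stop("deltaA must be >= 0")
    2.184 * deltaA / dryWeightG
}

#' Pearson correlation with a t-based p-value
#'
#' Sample Pearson correlation and the two-sided p-value from
#' \code{t = r * sqrt((n - 2) / (1 - r^2))} against Student's t with
#' \code{n - 2} degrees of freedom (as computed by \code{stats::cor.test}).
#'
#' @param x,y Numeric vectors of equal length, n >= 3, both with nonzero
#'   variance.
#' @return List with \code{r}, \code{p_value} and \code{n}.
#' @export
pearsonWithP <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3L) stop("need at least 3 observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("zero variance in x or y")
    ct <- stats::cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Height-lignin correlation from a phenotype table
#'
#' Correlates tree height with lignin content either across genotype means
#' (the default: the scale on which the study-level correlation is reported)
#' or across all replicate rows.
#'
#' @param phenotypes data.frame with \code{genotype}, \code{height_cm},
#'   \code{lignin_mg_per_g} (replicate rows allowed).
#' @param mode \code{"means"} (per-genotype means, default) or
#'   \code{"replicates"}.
#' @return List with \code{r}, \code{p_value}, \code{n}, \code{mode}.
#' @export
heightLigninCorrelation <- function(phenotypes, mode = c("means", "replicates")) {
    mode <- match.arg(mode)
    if (mode == "means") {
        h <- tapply(phenotypes$height_cm, phenotypes$genotype, mean)
        l <- tapply(phenotypes$lignin_mg_per_g, phenotypes$genotype, mean)
        res <- pearsonWithP(as.numeric(h), as.numeric(l))
    } else {
        res <- pearsonWithP(phenotypes$height_cm, phenotypes$lignin_mg_per_g)
    }
    c(res, list(mode = mode))
}
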