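#' Normalized fluorescence quenching
#'
#' Tryptophan fluorescence quenching readout of receptor-odorant binding:
#' `dF/F0 (%) = 100 * (f0 - f) / f0`, where `f0` is the intensity of the
#' odorant-untreated nanodiscs and `f` of the treated ones. Unit-free:
#' scaling both intensities together leaves the value unchanged. Values
#' of `f` above `f0` (negative quenching) are allowed and flagged.
#'
#' @param f0 fluorescence intensity without odorant (> 0).
#' @param f fluorescence intensity with odorant (>= 0).
#' @return Quenching percentage(s).
#' @export
quench_norm <- function(f0, f) {
  if (any(!is.finite(f0)) || any(f0 <= 0)) stop("quench_norm: f0 must be > 0")
  if (any(f < 0)) stop("quench_norm: f must be >= 0")
  if (any(f > f0)) warning("quench_norm: f > f0 (negative quenching)")
  100 * (f0 - f) / f0
}

#' Principal component analysis of response patterns
#'
#' Column-mean-centered PCA of a samples-by-channels G_max matrix (no
#' variance scaling by default: all channels share uS units). Components are
#' ordered by decreasing variance and each loading vector's sign is fixed by
#' making its largest-magnitude entry positive, for a reproducible
#' orientation.
#'
#' @param mat numeric matrix, samples x channels (>= 2 of each).
#' @param scale. standardize channels to unit variance first (default FALSE).
#' @return An object of class `pca_result`: `loadings` (orthonormal columns),
#'   `explained` (variance fractions), `scores` (projected samples), `sdev`.
#' @export
pca_responses <- function(mat, scale. = FALSE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2)
    stop("pca_responses: need >= 2 samples and >= 2 channels")
  pc <- stats::prcomp(mat, center = TRUE, scale. = scale.)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  v <- pc$sdev^2
  structure(list(loadings = loadings,
                 explained = v / sum(v),
                 scores = scores,
                 sdev = pc$sdev),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA: explained variance fractions:",
      paste(sprintf("%.3f", x$explained), collapse = ", "), "\n")
  invisible(x)
}

#' 3-sigma/S detection limit
#'
#' Concentration detection floor from a calibration curve: three times the
#' blank noise SD divided by the calibration slope.
#'
#' @param curve a `calibration_curve` from [make_calibration()], or a list
#'   with elements `slope` (uS/ppm, > 0) and `blank_sd` (uS, >= 0).
#' @return Limit of detection (ppm).
#' @export
detection_limit <- function(curve) {
  if (!is.numeric(curve$slope) || curve$slope <= 0)
    stop("detection_limit: undefined for non-positive slope")
  if (curve$blank_sd < 0) stop("detection_limit: blank_sd must be >= 0")
  3 * curve$blank_sd / curve$slope
}

#' Enumerate equimolar mixtures
#'
#' All unordered k-subsets of the odorant list, each as an equimolar
#' composition (fractions 1/k). For the four SCFAs this yields six
#' two-odorant and four three-odorant mixtures.
#'
#' @param odorants odorant identifiers.
#' @param k mixture size, `1 <= k <= length(odorants)`.
#' @return List of named composition vectors.
#' @export
enumerate_mixtures <- function(odorants, k) {
  if (k < 1 || k > length(odorants))
    stop("enumerate_mixtures: k out of range")
  utils::combn(odorants, k,
               FUN = function(s) stats::setNames(rep(1 / k, k), s),
               simplify = FALSE)
}
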