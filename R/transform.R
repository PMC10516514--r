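#' IC50 to normalized binding affinity
#'
#' Maps an IC50 measurement in nM to the unit interval via
#' `1 - log(ic50) / log(50000)`, the convention used by affinity benchmark
#' sets, clamped to \[0, 1\] (so IC50 > 50000 nM maps to 0 and IC50 < 1 nM
#' maps to 1).
#'
#' @param ic50 positive numeric vector, nM.
#' @return numeric vector in \[0, 1\], strictly decreasing on (1, 50000).
#' @export
#' @examples
#' transform_ic50(c(1, 500, 50000))  # 1, 0.4256..., 0
transform_ic50 <- function(ic50) {
  if (!is.numeric(ic50) || any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("ic50 must be finite and strictly positive (nM)", call. = FALSE)
  }
  pmin(1, pmax(0, 1 - log(ic50) / log(50000)))
}

#' Normalized affinity back to IC50 (nM)
#'
#' Algebraic inverse of [transform_ic50()] on the unclamped range.
#'
#' @param affinity numeric vector in \[0, 1\].
#' @return IC50 in nM; `affinity = 0` gives 50000, `affinity = 1` gives 1.
#' @export
inverse_transform <- function(affinity) {
  if (!is.numeric(affinity) || any(!is.finite(affinity)) ||
      any(affinity < 0) || any(affinity > 1)) {
    stop("affinity must lie in [0, 1]", call. = FALSE)
  }
  50000 ^ (1 - affinity)
}

#' Binder classification threshold on the transformed scale
#'
#' The conventional binder cut-off is IC50 < 500 nM; on the transformed scale
#' that is affinity > 1 - log(500)/log(50000) = 0.42562... (0.426 to 3 d.p.).
#' The exact value is used, not the rounded one.
#'
#' @return the threshold as a double.
#' @export
binder_threshold <- function() 1 - log(500) / log(50000)

#' Classify affinities into binders and non-binders
#'
#' A peptide is a binder iff its IC50 is strictly below 500 nM, i.e. its
#' transformed affinity strictly exceeds [binder_threshold()].
#'
#' @param affinity numeric vector in \[0, 1\].
#' @return integer vector of 0/1 labels.
#' @export
#' @examples
#' classify_binder(transform_ic50(c(499, 500)))  # 1, 0
classify_binder <- function(affinity) {
  if (!is.numeric(affinity) || any(affinity < 0 | affinity > 1, na.rm = TRUE)) {
    stop("affinity must lie in [0, 1]", call. = FALSE)
  }
  as.integer(affinity > binder_threshold())
}
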