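## Final-bias reweighting, effective sample size, block-averaged errors.

#' Normalize raw weights to probabilities
#'
#' @param w Non-negative raw weights.
#' @return Weights scaled to sum to 1.
#' @export
normalizeWeights <- function(w) {
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and non-negative")
  s <- sum(w)
  if (s <= 0) stop("weights sum to zero")
  w / s
}

#' Convert final metadynamics bias to frame weights
#'
#' Each frame of the aggregate sampling is reweighted with the bias potential
#' at the end of the run: \eqn{w_i \propto \exp(V_i / k_B T)}. The maximum
#' bias is subtracted before exponentiation for overflow safety, which leaves
#' the normalized weights unchanged (additive-shift invariance).
#'
#' @param biasKJmol Per-frame bias energies, kJ/mol.
#' @param temperatureK Temperature, kelvin.
#' @param sign `+1` (default, last-bias convention) or `-1` to flip the
#'   exponent's sign convention.
#' @return Normalized weight vector.
#' @examples
#' biasToWeights(c(0, 0, 0), 310)                 # uniform
#' w <- biasToWeights(c(5.16, 0), 310)
#' w[1] / w[2]                                     # ~exp(2)
#' @export
biasToWeights <- function(biasKJmol, temperatureK, sign = 1) {
  if (any(!is.finite(biasKJmol))) stop("bias values must be finite")
  if (!sign %in% c(1, -1)) stop("sign must be +1 or -1")
  v <- sign * biasKJmol / thermalEnergy(temperatureK)
  normalizeWeights(exp(v - max(v)))
}

#' Kish effective sample size of a weight vector
#'
#' \eqn{ESS = 1 / \sum_i w_i^2}; equals n for uniform weights and 1 when a
#' single frame carries all weight.
#'
#' @param weights Normalized weight vector.
#' @return Effective number of frames.
#' @export
effectiveSampleSize <- function(weights) {
  weights <- normalizeWeights(weights)
  1 / sum(weights^2)
}

#' Block-averaged weighted mean and standard error
#'
#' The frame series is split into `nBlocks` contiguous blocks (respecting any
#' autocorrelation in trajectory order). Each block's mean is computed with
#' block-local weight renormalization; the estimate is the block-weight
#' weighted mean of block means (identical to the plain weighted mean), and
#' the standard error is the weighted standard error over blocks.
#'
#' @param values Per-frame values of the observable.
#' @param weights Per-frame weights (normalized internally); `NULL` = uniform.
#' @param nBlocks Number of contiguous blocks (>= 2).
#' @return List with `estimate` and `stderr`.
#' @examples
#' blockError(c(1, 1, 0, 0), nBlocks = 2)  # estimate 0.5, stderr 0.5
#' @export
blockError <- function(values, weights = NULL, nBlocks = 5) {
  n <- length(values)
  if (nBlocks < 2) stop("nBlocks must be >= 2")
  if (n < nBlocks) stop("fewer frames (", n, ") than blocks (", nBlocks, ")")
  if (any(!is.finite(values))) stop("values must be finite")
  if (is.null(weights)) weights <- rep(1 / n, n)
  weights <- normalizeWeights(weights)
  block <- ceiling(seq_len(n) / (n / nBlocks))
  Wb <- as.numeric(tapply(weights, block, sum))
  Sb <- as.numeric(tapply(weights * values, block, sum))
  keep <- Wb > 0
  Wb <- Wb[keep]
  mb <- Sb[keep] / Wb
  B <- length(Wb)
  est <- sum(Wb * mb) / sum(Wb)
  se <- if (B > 1) sqrt(sum(Wb * (mb - est)^2) / ((B - 1) * sum(Wb))) else NA_real_
  list(estimate = est, stderr = se)
}
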