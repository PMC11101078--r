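#' Natural-abundance correction matrix
#'
#' Builds the lower-triangular matrix `A` whose entry `(i, j)` (0-based mass
#' shifts) is the probability that a molecule with `j` tracer-labeled
#' carbons is observed at mass shift `i`, given that each of the remaining
#' `n - j` carbons independently carries a natural 13C with probability
#' `p13`:
#' \deqn{A_{ij} = \binom{n-j}{i-j} p_{13}^{\,i-j} (1-p_{13})^{\,n-i},\ i \ge j}
#' Columns sum to 1.
#'
#' @param n_carbons Carbon count of the metabolite.
#' @param p13 Natural 13C abundance fraction (default 0.0107).
#' @return `(n+1) x (n+1)` matrix of class `ppp_corrmat` with attributes
#'   `n_carbons` and `p13`.
#' @examples
#' A <- build_correction_matrix(6)
#' colSums(A)  # all 1
#' @export
build_correction_matrix <- function(n_carbons, p13 = 0.0107) {
  n_carbons <- as.integer(n_carbons)
  if (n_carbons < 1L) stop("n_carbons must be >= 1", call. = FALSE)
  if (!is.finite(p13) || p13 < 0 || p13 >= 1)
    stop("p13 must lie in [0, 1)", call. = FALSE)
  A <- matrix(0, n_carbons + 1L, n_carbons + 1L)
  for (j in 0:n_carbons) {
    k <- 0:(n_carbons - j)  # extra natural labels
    A[j + k + 1L, j + 1L] <- stats::dbinom(k, n_carbons - j, p13)
  }
  dimnames(A) <- list(paste0("m", 0:n_carbons), paste0("m", 0:n_carbons))
  structure(A, n_carbons = n_carbons, p13 = p13,
            class = c("ppp_corrmat", "matrix", "array"))
}

#' Forward natural-abundance convolution
#'
#' Applies the natural-abundance model to a tracer-only MID, producing the
#' isotopologue profile the instrument would measure (the forward model of
#' [correct_mid()]; used by the synthetic-data generator).
#'
#' @param true_mid Numeric MID of length `n + 1`, summing to 1.
#' @param matrix A [build_correction_matrix()] result.
#' @return Numeric vector of measured-isotopologue fractions (sums to 1).
#' @export
apply_natural_abundance <- function(true_mid, matrix) {
  if (length(true_mid) != ncol(matrix))
    stop("MID length does not match correction matrix", call. = FALSE)
  out <- as.numeric(unclass(matrix) %*% as.numeric(true_mid))
  names(out) <- rownames(matrix)
  out
}

#' Correct a measured isotopologue vector for natural abundance
#'
#' Deconvolves the measured vector `y` into the tracer-only MID `x` by
#' solving `A x = y` under `x >= 0` (nonnegativity-constrained least
#' squares, Lawson-Hanson), then renormalizing `x` to sum 1. In the
#' noise-free case this reduces to exact sequential stripping of the
#' natural satellites.
#'
#' @param measured Nonnegative numeric vector of length `n + 1` (raw or
#'   normalized peak areas, or fractions).
#' @param matrix A [build_correction_matrix()] result.
#' @return List of class `ppp_corrected`: `fractions` (corrected MID),
#'   `residual` (residual norm of the fit, on the scale of the normalized
#'   input).
#' @export
correct_mid <- function(measured, matrix) {
  measured <- as.numeric(measured)
  if (length(measured) != ncol(matrix))
    stop("measured vector length does not match correction matrix",
         call. = FALSE)
  if (any(!is.finite(measured)) || any(measured < 0))
    stop("measured intensities must be finite and nonnegative",
         call. = FALSE)
  tot <- sum(measured)
  if (tot <= 0)
    stop("all-zero measured vector cannot be corrected", call. = FALSE)
  y <- measured / tot
  fit <- pracma::lsqnonneg(unclass(matrix), y)
  x <- fit$x
  if (sum(x) <= 0)
    stop("degenerate deconvolution: corrected vector is all zero",
         call. = FALSE)
  x <- x / sum(x)
  names(x) <- colnames(matrix)
  structure(list(fractions = x, residual = sqrt(fit$resid.norm)),
            class = "ppp_corrected")
}

#' @export
print.ppp_corrected <- function(x, ...) {
  cat("Natural-abundance-corrected MID (residual",
      format(x$residual, digits = 3), ")\n")
  print(round(x$fractions, 4))
  invisible(x)
}
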