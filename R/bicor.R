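#' Biweight midcorrelation of two vectors
#'
#' Robust correlation built from Tukey biweights: with
#' `u_i = (x_i - median(x)) / (9 * mad(x))` (raw MAD, no consistency
#' constant), observation weights are `(1 - u_i^2)^2` for `|u_i| < 1` and
#' zero otherwise, and the correlation is the normalized inner product of
#' the weighted, median-centred vectors.  When the MAD of either vector is
#' zero the weights are undefined and the function falls back to Pearson
#' correlation for that vector, which keeps perfectly collinear inputs at
#' +/- 1 instead of erroring.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\].
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("bicor needs at least 3 observations")
  wx <- bicor_weighted(x)
  wy <- bicor_weighted(y)
  denom <- sqrt(sum(wx^2) * sum(wy^2))
  if (denom == 0) return(NA_real_)
  r <- sum(wx * wy) / denom
  max(-1, min(1, r))
}

# median-centred, biweight-weighted version of a vector; Pearson fallback
# (mean-centring, unit weights) when MAD = 0
bicor_weighted <- function(x) {
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  if (mad0 == 0) return(x - mean(x))
  u <- (x - med) / (9 * mad0)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  (x - med) * w
}

#' Biweight midcorrelation matrix
#'
#' Column-wise bicor of a matrix (or cross-correlation of two matrices),
#' the robust analogue of `cor(x, y)`.
#'
#' @param x numeric matrix, observations in rows.
#' @param y optional second matrix with the same number of rows; default
#'   `x`.
#' @return correlation matrix `ncol(x) x ncol(y)`.
#' @export
bicor_matrix <- function(x, y = NULL) {
  x <- as.matrix(x)
  wx <- apply(x, 2, bicor_weighted)
  nx <- sqrt(colSums(wx^2))
  if (is.null(y)) {
    r <- crossprod(wx) / tcrossprod(nx)
    dimnames(r) <- list(colnames(x), colnames(x))
  } else {
    y <- as.matrix(y)
    if (nrow(y) != nrow(x)) stop("x and y must have the same number of rows")
    wy <- apply(y, 2, bicor_weighted)
    ny <- sqrt(colSums(wy^2))
    r <- crossprod(wx, wy) / outer(nx, ny)
    dimnames(r) <- list(colnames(x), colnames(y))
  }
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' Student-t p-value for a correlation
#'
#' Two-sided p-value from the t approximation with n - 2 degrees of
#' freedom, the usual test applied to module-trait correlation tables.
#'
#' @param r correlation value(s).
#' @param n number of observations.
#' @return p-value(s) in \[0, 1\].
#' @export
cor_pvalue <- function(r, n) {
  if (n < 3) stop("need at least 3 observations")
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
}

# significance stars at the conventional 0.05 / 0.01 / 0.001 thresholds
p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}
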