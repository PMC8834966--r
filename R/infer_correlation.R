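new_inference_result <- function(method, stat, pval, symmetric) {
  stopifnot(all(dim(stat) == dim(pval)))
  structure(list(method = method, stat = stat, pval = pval,
                 symmetric = symmetric),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat("inference_result:", x$method, "-", nrow(x$stat), "species",
      if (x$symmetric) "(symmetric)" else "(directed)", "\n")
  invisible(x)
}

#' Correlation-based network inference
#'
#' Pairwise Pearson or Spearman correlation between species time series,
#' with two-sided p-values from the t approximation
#' `t = r sqrt((T - 2) / (1 - r^2))` on `T - 2` degrees of freedom (applied
#' to the rank correlation for Spearman).  Both the statistic and the
#' p-value matrices are symmetric, so these methods cannot represent
#' asymmetric interactions.  Constant series get statistic 0 and p-value 1.
#'
#' @param series numeric matrix, time points by species.
#' @param kind `"pearson"` or `"spearman"`.
#' @return An `inference_result` with `stat` in `[-1, 1]` and `pval` in
#'   `[0, 1]`.
#' @export
correlation_infer <- function(series, kind = c("pearson", "spearman")) {
  kind <- match.arg(kind)
  x <- unclass(series)
  T <- nrow(x)
  if (T < 3) stop("at least 3 time points are required")
  constant <- apply(x, 2, function(v) stats::sd(v) == 0 || !is.finite(sd(v)))
  r <- suppressWarnings(cor(x, method = kind))
  r[!is.finite(r)] <- 0
  r[constant, ] <- 0; r[, constant] <- 0
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((T - 2) / pmax(1 - r^2, .Machine$double.eps))
  pval <- 2 * pt(-abs(tstat), df = T - 2)
  pval[constant, ] <- 1; pval[, constant] <- 1
  diag(r) <- 1; diag(pval) <- 0
  diag(r)[constant] <- 0; diag(pval)[constant] <- 1
  new_inference_result(kind, r, pval, symmetric = TRUE)
}
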