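#' Local similarity analysis configuration
#'
#' @param max_delay largest lag (in samples) considered between two series.
#' @param n_boot permutation replicates for the p-value (0 disables).
#' @return An object of class `lsa_config`.
#' @export
lsa_config <- function(max_delay = 3, n_boot = 2000) {
  stopifnot(max_delay >= 0, n_boot >= 0)
  structure(list(max_delay = as.integer(max_delay),
                 n_boot = as.integer(n_boot)),
            class = "lsa_config")
}

# Rank-to-normal-scores transform: Phi^{-1}(rank / (T + 1)).  Constant
# series map to all-zero scores (every rank is the mid rank).
normal_scores <- function(v) {
  qnorm(rank(v, ties.method = "average") / (length(v) + 1))
}

#' Local similarity analysis (LSA)
#'
#' Detects the strongest contiguous, possibly time-delayed, local
#' association between every pair of series.  Each series is first mapped
#' to normal scores; a dynamic program then finds, over all alignments with
#' delay at most `max_delay` samples, the contiguous window maximizing the
#' absolute sum of score products.  The statistic is that signed sum
#' divided by the series length; the p-value is the fraction of `n_boot`
#' random permutations of one series whose absolute score is at least the
#' observed one.  Output matrices are symmetric: the best alignment over
#' both delay signs is assigned to both directions.
#'
#' @param series numeric matrix, time points by species.
#' @param cfg an [lsa_config()].
#' @param seed optional seed for the permutation stream.
#' @return An `inference_result`.
#' @export
lsa_infer <- function(series, cfg = lsa_config(), seed = NULL) {
  x <- unclass(series)
  T <- nrow(x); n <- ncol(x)
  if (T < 2 * cfg$max_delay + 3) stop("series too short for chosen max_delay")
  z <- apply(x, 2, normal_scores)
  run <- function() {
    stat <- matrix(0, n, n); pval <- matrix(1, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        res <- lsa_pair_cpp(z[, i], z[, j], cfg$max_delay, cfg$n_boot)
        stat[i, j] <- stat[j, i] <- res$score
        p <- if (is.na(res$pval)) 1 else res$pval
        pval[i, j] <- pval[j, i] <- p
      }
    }
    diag(pval) <- 0
    for (i in seq_len(n)) {
      res <- lsa_pair_cpp(z[, i], z[, i], cfg$max_delay, 0L)
      stat[i, i] <- res$score
    }
    new_inference_result("lsa", stat, pval, symmetric = TRUE)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
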