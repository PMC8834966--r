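#' Convergent cross mapping configuration
#'
#' @param E_range candidate embedding dimensions; the dimension of each
#'   predictor series is chosen by maximal univariate leave-one-out simplex
#'   forecasting skill over this range.
#' @param lag embedding lag in samples.
#' @param n_surrogates circular-shift surrogate replicates for the
#'   p-value.  Circular shifts preserve the autocorrelation of the target
#'   series, so the null accounts for predictability inherent in the
#'   target itself (e.g. periodicity).
#' @return An object of class `ccm_config`.
#' @export
ccm_config <- function(E_range = 2:6, lag = 1, n_surrogates = 100) {
  stopifnot(min(E_range) >= 2, lag >= 1, n_surrogates >= 0)
  structure(list(E_range = as.integer(E_range), lag = as.integer(lag),
                 n_surrogates = as.integer(n_surrogates)),
            class = "ccm_config")
}

# Delay embedding: row t holds (v(t), v(t - lag), ..., v(t - (E-1) lag)),
# for t = (E-1)*lag + 1 .. T (1-based).  Returns the matrix and the time
# indices of its rows.
delay_embed <- function(v, E, lag = 1) {
  T <- length(v)
  first <- (E - 1) * lag + 1
  idx <- first:T
  emb <- sapply(0:(E - 1), function(d) v[idx - d * lag])
  list(emb = matrix(emb, length(idx), E), idx = idx)
}

# Simplex-projection weights: for each embedding row, its E+1 nearest
# neighbors (self excluded) with exponential distance weights
# exp(-d / d_min).  Returns an L x L sparse weight matrix W such that
# (W %*% y) is the simplex prediction of any co-registered target y.
simplex_weights <- function(emb, n_neigh) {
  L <- nrow(emb)
  d <- as.matrix(stats::dist(emb))
  diag(d) <- Inf
  W <- matrix(0, L, L)
  for (a in seq_len(L)) {
    nb <- order(d[a, ])[seq_len(n_neigh)]
    dmin <- d[a, nb[1]]
    w <- if (dmin == 0) as.numeric(d[a, nb] == 0) else exp(-d[a, nb] / dmin)
    if (sum(w) == 0) w <- rep(1, length(nb))
    W[a, nb] <- w / sum(w)
  }
  W
}

safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  v <- suppressWarnings(cor(a, b))
  if (!is.finite(v)) 0 else v
}

# Leave-one-out univariate simplex forecast skill of v at dimension E:
# predict v(t + 1) from the E + 1 nearest embedding neighbors.
simplex_skill <- function(v, E, lag = 1) {
  de <- delay_embed(v, E, lag)
  keep <- de$idx + 1 <= length(v)
  emb <- de$emb[keep, , drop = FALSE]
  target <- v[de$idx[keep] + 1]
  if (nrow(emb) < E + 2) return(-Inf)
  W <- simplex_weights(emb, E + 1)
  safe_cor(target, as.vector(W %*% target))
}

# Best embedding dimension of a series by simplex self-forecast skill.
select_embedding_dim <- function(v, E_range, lag = 1) {
  skills <- vapply(E_range, function(E) simplex_skill(v, E, lag), numeric(1))
  E_range[which.max(skills)]
}

#' Convergent cross mapping (CCM)
#'
#' Causality detection by cross-mapped state-space reconstruction.  If
#' species j influences species i, information about x_j is encoded in the
#' history of x_i, so the delay embedding of x_i can reconstruct x_j.  For
#' each predictor series i an embedding dimension is chosen by univariate
#' simplex skill over `E_range`; the target series j is then cross-mapped
#' from the E+1 nearest neighbors in i's reconstructed attractor
#' (leave-one-out, full library), and `stat[i, j]` is the Pearson
#' correlation between the observed and cross-mapped target - the skill of
#' detecting the effect of j on i.  `pval[i, j]` is the fraction of
#' circular-shift surrogates of the target whose skill reaches the
#' observed one.  The output is directed: `stat[i, j]` and `stat[j, i]`
#' generally differ.
#'
#' @param series numeric matrix, time points by species.
#' @param cfg a [ccm_config()].
#' @param seed optional seed for the surrogate stream.
#' @return An `inference_result`.
#' @export
ccm_infer <- function(series, cfg = ccm_config(), seed = NULL) {
  x <- unclass(series)
  T <- nrow(x); n <- ncol(x)
  if (T < 4 * max(cfg$E_range)) stop("series too short for chosen E_range")
  run <- function() {
    stat <- matrix(0, n, n); pval <- matrix(1, n, n)
    for (i in seq_len(n)) {
      v <- x[, i]
      if (sd(v) == 0) next
      E <- select_embedding_dim(v, cfg$E_range, cfg$lag)
      de <- delay_embed(v, E, cfg$lag)
      W <- simplex_weights(de$emb, E + 1)
      shifts <- if (cfg$n_surrogates > 0)
        sample.int(T - 1, cfg$n_surrogates, replace = TRUE) else integer(0)
      for (j in seq_len(n)) {
        if (j == i) {
          stat[i, j] <- simplex_skill(v, E, cfg$lag)
          pval[i, j] <- 0
          next
        }
        y <- x[de$idx, j]
        if (sd(y) == 0) { stat[i, j] <- 0; pval[i, j] <- 1; next }
        obs <- safe_cor(y, as.vector(W %*% y))
        stat[i, j] <- obs
        if (cfg$n_surrogates > 0) {
          cnt <- 0L
          yj <- x[, j]
          for (s in shifts) {
            ys <- c(yj[(s + 1):T], yj[1:s])[de$idx]
            if (safe_cor(ys, as.vector(W %*% ys)) >= obs) cnt <- cnt + 1L
          }
          pval[i, j] <- cnt / cfg$n_surrogates
        }
      }
    }
    new_inference_result("ccm", stat, pval, symmetric = FALSE)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
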