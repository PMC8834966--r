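#' LIMITS configuration
#'
#' @param n_bags bootstrap replicates (the published procedure uses 500).
#' @param vote_threshold fraction of bags in which a predictor must be
#'   selected to count as present (majority vote, default 0.5).
#' @param improvement_tol minimum relative out-of-bag error decrease for a
#'   forward step to be accepted.  The original forward-stepwise rule
#'   accepts any decrease; a small positive tolerance (default 1e-3)
#'   stabilizes the vote on noisy data without affecting clear signals.
#' @param dt_effective time per sample (tau * dt, days); coefficients are
#'   rescaled to the per-day scale.  Detection is invariant to this scale.
#' @param eps abundance floor applied before taking log ratios.
#' @return An object of class `limits_config`.
#' @export
limits_config <- function(n_bags = 500, vote_threshold = 0.5,
                          improvement_tol = 1e-3, dt_effective = 1,
                          eps = 1e-7) {
  stopifnot(n_bags >= 1, vote_threshold > 0, vote_threshold < 1,
            improvement_tol >= 0, dt_effective > 0, eps > 0)
  structure(list(n_bags = as.integer(n_bags),
                 vote_threshold = vote_threshold,
                 improvement_tol = improvement_tol,
                 dt_effective = dt_effective, eps = eps),
            class = "limits_config")
}

# One bag for one focal species: forward stepwise regression on the
# in-bag half, scored by out-of-bag mean squared error.  `self` is always
# in the model (intercept + focal species).  Returns the per-day
# coefficient vector (0 for unselected predictors).
limits_bag <- function(y, P, self, inb, oob, tol, dt_eff) {
  n <- ncol(P)
  included <- self
  design <- function(cols) cbind(1, P[, cols, drop = FALSE])
  fit_err <- function(cols) {
    f <- .lm.fit(design(cols)[inb, , drop = FALSE], y[inb])
    cf <- f$coefficients
    cf[!is.finite(cf)] <- 0
    resid <- y[oob] - design(cols)[oob, , drop = FALSE] %*% cf
    list(coef = cf, err = mean(resid^2))
  }
  cur <- fit_err(included)
  repeat {
    if (cur$err < 1e-25) break  # numerically perfect fit; stop adding
    candidates <- setdiff(seq_len(n), included)
    if (length(candidates) == 0) break
    errs <- vapply(candidates, function(j) fit_err(c(included, j))$err,
                   numeric(1))
    best <- which.min(errs)
    if ((cur$err - errs[best]) / cur$err <= tol) break
    included <- c(included, candidates[best])
    cur <- fit_err(included)
  }
  coefs <- numeric(n)
  coefs[included] <- cur$coef[-1] / dt_eff
  list(selected = included, coefs = coefs)
}

#' LIMITS sparse regression inference
#'
#' Infers a sparse directed interaction matrix from the discrete
#' generalized Lotka-Volterra relation: for each focal species i the
#' response is the log change per sample step,
#' `y_t = ln(x_i(t+1) / x_i(t))`, and the candidate predictors are the
#' abundances `x_j(t)`.  Each of `n_bags` bootstrap replicates splits the
#' transitions into an in-bag and an out-of-bag half, starts from the
#' intercept-plus-self model, and greedily adds the predictor with the
#' largest out-of-bag error decrease while the relative decrease exceeds
#' `improvement_tol`.  A predictor is finally present iff it was selected
#' in more than `vote_threshold` of the bags; its coefficient is the
#' median over the bags that selected it (zero otherwise), giving a sparse
#' statistic matrix.  `pval[i, j]` is the fraction of bags in which the
#' coefficient was zero (one minus the selection frequency), which can be
#' dense.
#'
#' Abundances are floored at `eps` before the log ratio so that zeros from
#' the simulation floor do not produce infinities.
#'
#' @param series numeric matrix, time points by species (strictly positive
#'   after flooring).
#' @param cfg a [limits_config()].
#' @param seed optional seed for the bootstrap stream.
#' @return An `inference_result` with the per-day coefficient matrix as
#'   `stat` (entry (i, j) = effect of species j on species i).
#' @export
limits_infer <- function(series, cfg = limits_config(), seed = NULL) {
  x <- pmax(unclass(series), cfg$eps)
  if (any(!is.finite(x))) stop("non-finite abundances in series")
  T <- nrow(x); n <- ncol(x)
  if (T - 1 < 10) stop("at least 10 transitions are required")
  Tn <- T - 1
  P <- x[seq_len(Tn), , drop = FALSE]
  run <- function() {
    stat <- matrix(0, n, n); pval <- matrix(1, n, n)
    half <- floor(Tn / 2)
    for (i in seq_len(n)) {
      y <- log(x[2:T, i] / x[seq_len(Tn), i])
      sel_count <- numeric(n)
      coef_bags <- matrix(NA_real_, cfg$n_bags, n)
      for (b in seq_len(cfg$n_bags)) {
        inb <- sample.int(Tn, half)
        oob <- setdiff(seq_len(Tn), inb)
        bag <- limits_bag(y, P, i, inb, oob, cfg$improvement_tol,
                          cfg$dt_effective)
        sel_count[bag$selected] <- sel_count[bag$selected] + 1
        coef_bags[b, bag$selected] <- bag$coefs[bag$selected]
      }
      freq <- sel_count / cfg$n_bags
      for (j in seq_len(n)) {
        pval[i, j] <- 1 - freq[j]
        if (freq[j] > cfg$vote_threshold) {
          stat[i, j] <- median(coef_bags[, j], na.rm = TRUE)
        }
      }
    }
    new_inference_result("limits", stat, pval, symmetric = FALSE)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Run one inference method by name
#'
#' Convenience dispatcher used by the benchmark driver and the command
#' line interface.
#'
#' @param series numeric matrix, time points by species.
#' @param method one of `"pearson"`, `"spearman"`, `"lsa"`, `"ccm"`,
#'   `"limits"`.
#' @param cfg optional method configuration object.
#' @param seed optional seed for stochastic methods.
#' @return An `inference_result`.
#' @export
infer_network <- function(series,
                          method = c("pearson", "spearman", "lsa", "ccm",
                                     "limits"),
                          cfg = NULL, seed = NULL) {
  method <- match.arg(method)
  switch(method,
    pearson = correlation_infer(series, "pearson"),
    spearman = correlation_infer(series, "spearman"),
    lsa = lsa_infer(series, cfg %||% lsa_config(), seed = seed),
    ccm = ccm_infer(series, cfg %||% ccm_config(), seed = seed),
    limits = limits_infer(series, cfg %||% limits_config(), seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an inference result as JSON
#'
#' @param res an `inference_result`.
#' @param path file path.
#' @export
write_result_json <- function(res, path) {
  obj <- list(method = res$method, symmetric = res$symmetric,
              stat = res$stat, pval = res$pval)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_result_json
#' @export
read_result_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_inference_result(obj$method, as.matrix(obj$stat), as.matrix(obj$pval),
                       obj$symmetric)
}
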