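#' Discrete generalized Lotka-Volterra fixture
#'
#' Iterates the discrete gLV map
#' `x_i(t+1) = x_i(t) * exp(dt * (b_i + sum_j A_ij x_j(t)) + noise)` with
#' optional Gaussian noise on the log scale.  The ground truth is the
#' nonzero off-diagonal pattern of `A`.  This is the generating model that
#' LIMITS assumes exactly, so noise-free output is its parameter-recovery
#' oracle.
#'
#' @param A square interaction matrix (per-day scale).
#' @param b intrinsic growth-rate vector.
#' @param x0 positive initial abundances.
#' @param n_steps number of iterations.
#' @param dt time per step in days.
#' @param noise_sd standard deviation of the log-scale noise.
#' @return A list with `series` (matrix, `n_steps + 1` rows) and logical
#'   `truth` presence matrix.
#' @export
gen_discrete_glv <- function(A, b, x0, n_steps, dt = 1, noise_sd = 0) {
  n <- nrow(A)
  stopifnot(ncol(A) == n, length(b) == n, length(x0) == n, all(x0 > 0))
  out <- matrix(0, n_steps + 1, n)
  out[1, ] <- x0
  x <- x0
  for (t in seq_len(n_steps)) {
    eta <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
    x <- x * exp(dt * (b + as.vector(A %*% x)) + eta)
    if (any(!is.finite(x)) || any(x > 1e12))
      stop("discrete gLV fixture diverged at step ", t)
    out[t + 1, ] <- x
  }
  truth <- A != 0
  diag(truth) <- FALSE
  list(series = structure(out, class = c("sampled_series", "matrix")),
       truth = truth)
}

#' Unidirectionally coupled logistic maps
#'
#' The canonical cross-mapping benchmark pair:
#' `x(t+1) = x (3.8 - 3.8 x)` drives `y(t+1) = y (3.5 - 3.5 y -
#' coupling * x)`.  The true causal direction is x to y iff
#' `coupling > 0`.  For initial values in (0, 1) both trajectories stay in
#' (0, 1).
#'
#' @param coupling coupling strength (>= 0).
#' @param n_steps number of iterations.
#' @param x0,y0 initial values in (0, 1).
#' @return A list with `series` (two columns, x then y) and
#'   `truth_direction` (`"x->y"` or `"none"`).
#' @export
gen_coupled_logistic <- function(coupling, n_steps, x0 = 0.4, y0 = 0.2) {
  stopifnot(coupling >= 0, x0 > 0, x0 < 1, y0 > 0, y0 < 1)
  x <- numeric(n_steps + 1); y <- numeric(n_steps + 1)
  x[1] <- x0; y[1] <- y0
  for (t in seq_len(n_steps)) {
    x[t + 1] <- x[t] * (3.8 - 3.8 * x[t])
    y[t + 1] <- y[t] * (3.5 - 3.5 * y[t] - coupling * x[t])
  }
  list(series = structure(cbind(x = x, y = y),
                          class = c("sampled_series", "matrix")),
       truth_direction = if (coupling > 0) "x->y" else "none")
}

#' Correlated Gaussian pair
#'
#' Bivariate normal draws with a given correlation, for testing the
#' correlation-based methods against a known effect size.
#'
#' @param rho target correlation, in `[-1, 1]`.
#' @param n number of draws.
#' @return A two-column matrix.
#' @export
gen_correlated_pair <- function(rho, n) {
  stopifnot(abs(rho) <= 1)
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  structure(cbind(x = z1, y = z2), class = c("sampled_series", "matrix"))
}
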