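#' Simulation configuration
#'
#' Settings of the Euler-Maruyama integration.  Defaults match the
#' benchmark design: step size `dt = 0.025` (one step = 0.025 days),
#' `t_max = 10000` steps (250 days), the first `t0 = 2000` steps discarded
#' as transient, noise magnitude `sigma`, and a constant microbe influx
#' `eps = 1e-7` that prevents underflow and allows recovery after a species
#' is floored at zero.
#'
#' The update rule is `x(t+1) = x(t) + F dt + noise + eps`.  The default
#' noise term is `sigma * dt * N(0,1)` (`"additive_dt"`, the model's
#' as-printed scaling); `"additive_sqrt_dt"` gives the canonical
#' Euler-Maruyama diffusion `sigma * sqrt(dt) * N(0,1)` and
#' `"multiplicative"` gives `sigma * x * sqrt(dt) * N(0,1)`, both for
#' sensitivity analysis (see the methods vignette for why the printed
#' scaling is the default).  Chemicals are updated with the same scheme
#' but without the influx; set `noise_on_chemicals = FALSE` to integrate
#' them deterministically.
#'
#' @param dt step size in days.
#' @param t_max number of integration steps.
#' @param t0 transient steps discarded before time averaging.
#' @param sigma noise magnitude.
#' @param eps per-step microbe influx.
#' @param noise_on_chemicals apply the noise term to chemicals too.
#' @param noise_form diffusion-term scaling (see Details).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.025, t_max = 10000, t0 = 2000, sigma = 1,
                       eps = 1e-7, noise_on_chemicals = TRUE,
                       noise_form = c("additive_dt", "additive_sqrt_dt",
                                      "multiplicative")) {
  noise_form <- match.arg(noise_form)
  stopifnot(dt > 0, t0 >= 0, t0 < t_max, sigma >= 0, eps >= 0)
  structure(list(dt = dt, t_max = as.integer(t_max), t0 = as.integer(t0),
                 sigma = sigma, eps = eps,
                 noise_on_chemicals = noise_on_chemicals,
                 noise_form = noise_form),
            class = "sim_config")
}

noise_form_code <- function(form) {
  match(form, c("additive_sqrt_dt", "additive_dt", "multiplicative")) - 1L
}

# Low-level call into the compiled integrator.  Returns the raw list from
# C++ (ok, bad_step, bad_var, xhat, chat, states).
em_integrate_raw <- function(model, params, x0, c0, config, return_states) {
  model <- match.arg(model, MODEL_IDS)
  mediated <- is_mediated_model(model)
  if (mediated) {
    stopifnot(inherits(params, "mediator_params"))
    if (is.null(c0)) c0 <- rep(0, params$m)
    rho <- params$rho_plus - params$rho_minus
    kappa <- params$kappa; alpha <- params$alpha; beta <- params$beta
    A <- matrix(0, 0, 0)
  } else {
    stopifnot(inherits(params, "direct_params"))
    c0 <- numeric(0)
    rho <- kappa <- matrix(0, 0, 0); alpha <- beta <- matrix(0, 0, 0)
    A <- params$A
  }
  stopifnot(length(x0) == params$n, all(x0 >= 0), all(c0 >= 0))
  em_integrate_cpp(match(model, MODEL_IDS) - 1L,
                   params$r, params$K, params$delta,
                   rho, kappa, alpha, beta, A,
                   x0, c0,
                   config$dt, config$t_max, config$t0,
                   config$sigma, config$eps,
                   config$noise_on_chemicals,
                   noise_form_code(config$noise_form),
                   return_states)
}

#' Integrate a stochastic community trajectory
#'
#' Runs the Euler-Maruyama scheme for `t_max` steps from the initial state,
#' flooring every variable at 0 after each step.  Noise draws come from R's
#' random number stream, so a fixed [set.seed()] yields a bit-identical
#' trajectory.
#'
#' @param model one of `"M"`, `"Mprime"`, `"D"`, `"Dprime"`.
#' @param params `mediator_params` or `direct_params`, to match the model.
#' @param x0 initial species abundances.
#' @param c0 initial chemical amounts (mediated models; default all zero).
#' @param config a [sim_config()].
#' @param return_states keep the full state matrix (set `FALSE` to retain
#'   only the post-transient time averages, e.g. inside the community
#'   search).
#' @return An object of class `trajectory` with fields `times` (step
#'   indices 0..t_max), `states` (matrix, one row per step, species columns
#'   then chemical columns), `xhat`/`chat` (time averages over steps
#'   t0+1..t_max), `model_id`, `params`, `config`.
#' @export
integrate_trajectory <- function(model, params, x0, c0 = NULL,
                                 config = sim_config(),
                                 return_states = TRUE) {
  res <- em_integrate_raw(model, params, x0, c0, config, return_states)
  if (!res$ok) {
    stop(sprintf(
      "integration diverged at step %d (state variable %d): non-finite or overflowing value",
      res$bad_step, res$bad_var))
  }
  states <- res$states
  if (!is.null(states)) {
    n <- params$n
    m <- ncol(states) - n
    colnames(states) <- c(paste0("x", seq_len(n)),
                          if (m > 0) paste0("c", seq_len(m)))
  }
  structure(list(times = 0:config$t_max, states = states,
                 xhat = res$xhat, chat = res$chat,
                 model_id = model, params = params, config = config),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", x$model_id, "model,", length(x$times) - 1, "steps,",
      length(x$xhat), "species\n")
  invisible(x)
}

#' Resample the tail of a trajectory into an analysis-ready series
#'
#' Selects `n_points` evenly spaced steps ending exactly at the final step:
#' source steps `t_max - (n_points - 1 - k) * tau` for `k = 0 ..
#' n_points - 1`.  With the default `dt = 0.025`, `tau = 80` spans
#' `99 * 80 * 0.025 = 198` days, i.e. a 200-day observation window sampled
#' every 2 days.  Only species abundances are returned; chemicals are never
#' part of the inference input.
#'
#' @param traj a `trajectory` with states retained.
#' @param tau resampling interval in steps.
#' @param n_points number of samples.
#' @return An object of class `sampled_series`: a matrix of `n_points` rows
#'   by `n` species, with attributes `tau`, `dt` and `steps` (the source
#'   step indices).
#' @export
resample_tail <- function(traj, tau, n_points = 100) {
  stopifnot(inherits(traj, "trajectory"), !is.null(traj$states))
  t_max <- traj$config$t_max
  if (t_max < (n_points - 1) * tau)
    stop("trajectory too short for requested resampling")
  steps <- t_max - (n_points - 1 - seq_len(n_points) + 1) * tau
  n <- traj$params$n
  out <- traj$states[steps + 1, seq_len(n), drop = FALSE]
  structure(out, tau = tau, dt = traj$config$dt, steps = steps,
            class = c("sampled_series", "matrix"))
}

#' Read and write sampled series as TSV
#'
#' One row per time point; first column `step` holds the source step index,
#' then one column per species.  Full trajectories written with
#' [write_series_tsv()] also include the chemical columns.
#'
#' @param series a `sampled_series` or any numeric matrix with a `steps`
#'   attribute (defaults to 0-based row index).
#' @param path file path.
#' @export
write_series_tsv <- function(series, path) {
  steps <- attr(series, "steps")
  if (is.null(steps)) steps <- seq_len(nrow(series)) - 1
  df <- data.frame(step = steps, unclass(series)[, , drop = FALSE],
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_tsv
#' @export
read_series_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  stopifnot(names(df)[1] == "step")
  m <- as.matrix(df[, -1, drop = FALSE])
  structure(m, steps = df$step, class = c("sampled_series", "matrix"))
}
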