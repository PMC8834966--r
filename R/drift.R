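#' Deterministic drift of the community models
#'
#' Evaluates the instantaneous rates of change of species abundances (and
#' chemical amounts, for the mediated models) at a given state.  Four model
#' variants are supported:
#'
#' * `"M"`: per-species logistic growth `r_i (1 - x_i / K) x_i`, plus the
#'   saturating chemical effects
#'   `sum_k (rho_plus - rho_minus)_ik c_k / (c_k + kappa_ik) x_i`, minus
#'   dilution `delta x_i`.  Chemicals follow
#'   `dc_k/dt = sum_i (beta_ki x_i - alpha_ki x_i c_k / (c_k + kappa_ik))
#'   - delta c_k`.
#' * `"Mprime"`: as `"M"` but with a shared logistic term
#'   `r_i (1 - sum_j x_j / (n K)) x_i` modelling competition for a common
#'   nutrient pool (total abundance bounded by `n K`).
#' * `"D"` / `"Dprime"`: the chemical terms are replaced by direct gLV
#'   interactions `sum_j a_ij x_i x_j`; there are no chemical variables.
#'
#' This is the reference R implementation used for testing and for
#' finite-difference checks; stochastic integration uses the compiled
#' equivalent in [integrate_trajectory()].
#'
#' @param model one of `"M"`, `"Mprime"`, `"D"`, `"Dprime"`.
#' @param params `mediator_params` (M/M') or `direct_params` (D/D').
#' @param x species abundance vector (non-negative).
#' @param c chemical amount vector (mediated models only).
#' @return A list with `dx` and (for mediated models) `dc`.
#' @export
drift <- function(model, params, x, c = NULL) {
  model <- match.arg(model, MODEL_IDS)
  if (any(x < 0)) stop("negative species abundance in state")
  n <- length(x)
  if (is_mediated_model(model)) {
    stopifnot(inherits(params, "mediator_params"), !is.null(c))
    if (any(c < 0)) stop("negative chemical amount in state")
    stopifnot(n == params$n, length(c) == params$m)
    # hill[i, k] = c_k / (c_k + kappa_ik)
    hill <- sweep(1 / sweep(params$kappa, 2, c, "+"), 2, c, "*")
    grow <- if (model == "M") {
      params$r * (1 - x / params$K)
    } else {
      params$r * (1 - sum(x) / (n * params$K))
    }
    chem_eff <- rowSums((params$rho_plus - params$rho_minus) * hill)
    dx <- grow * x + chem_eff * x - params$delta * x
    dc <- as.vector(params$beta %*% x) -
      colSums(t(params$alpha) * hill * x) - params$delta * c
    list(dx = dx, dc = dc)
  } else {
    stopifnot(inherits(params, "direct_params"))
    stopifnot(n == params$n)
    grow <- if (model == "D") {
      params$r * (1 - x / params$K)
    } else {
      params$r * (1 - sum(x) / (n * params$K))
    }
    dx <- grow * x + as.vector(params$A %*% x) * x - params$delta * x
    list(dx = dx, dc = NULL)
  }
}
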