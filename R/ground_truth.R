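ZERO_TOL <- 1e-12

#' Analytic Jacobian blocks of the community models
#'
#' Partial derivatives of the drift at a given state, organized as the four
#' blocks of the full Jacobian of the stacked system `(dx/dt, dc/dt)`:
#' `JF_x` (n x n, species on species), `JF_c` (n x m, chemicals on
#' species), `JG_x` (m x n, species on chemicals) and `JG_c` (m x m,
#' chemicals on chemicals).  For the direct models only `JF_x` is nonempty.
#'
#' The derivative of the saturation term `c / (c + kappa)` with respect to
#' `c` is `kappa / (c + kappa)^2`, which drives both `JF_c` and the
#' diagonal of `JG_c`.
#'
#' @param model one of `"M"`, `"Mprime"`, `"D"`, `"Dprime"`.
#' @param params matching parameter object.
#' @param x species abundances at the evaluation state.
#' @param c chemical amounts (mediated models).
#' @return A list of class `jacobian_blocks` with `JF_x`, `JF_c`, `JG_x`,
#'   `JG_c` and the evaluation state.
#' @export
jacobian_blocks <- function(model, params, x, c = NULL) {
  model <- match.arg(model, MODEL_IDS)
  n <- params$n
  if (is_mediated_model(model)) {
    stopifnot(inherits(params, "mediator_params"), !is.null(c))
    m <- params$m
    rho <- params$rho_plus - params$rho_minus
    cm <- matrix(c, n, m, byrow = TRUE)
    hill <- cm / (cm + params$kappa)               # h_ik
    dhill <- params$kappa / (cm + params$kappa)^2  # dh/dc_k
    chem_eff <- rowSums(rho * hill)
    if (model == "M") {
      JF_x <- diag(params$r * (1 - 2 * x / params$K) + chem_eff -
                     params$delta, n, n)
    } else {
      JF_x <- -outer(params$r * x, rep(1, n)) / (n * params$K) +
        diag(params$r * (1 - sum(x) / (n * params$K)) + chem_eff -
               params$delta, n, n)
    }
    JF_c <- rho * x * dhill
    JG_x <- params$beta - params$alpha * t(hill)
    JG_c <- diag(-colSums(t(params$alpha) * dhill * x) - params$delta, m, m)
  } else {
    stopifnot(inherits(params, "direct_params"))
    A <- params$A
    inter <- as.vector(A %*% x)
    if (model == "D") {
      JF_x <- A * x + diag(params$r * (1 - 2 * x / params$K) + inter -
                             params$delta, n, n)
    } else {
      JF_x <- A * x - outer(params$r * x, rep(1, n)) / (n * params$K) +
        diag(params$r * (1 - sum(x) / (n * params$K)) + inter -
               params$delta, n, n)
    }
    JF_c <- matrix(0, n, 0); JG_x <- matrix(0, 0, n); JG_c <- matrix(0, 0, 0)
  }
  structure(list(JF_x = JF_x, JF_c = JF_c, JG_x = JG_x, JG_c = JG_c,
                 eval_state = list(x = x, c = c)),
            class = "jacobian_blocks")
}

new_effective_matrix <- function(values, presence, model_id) {
  diag(presence) <- FALSE
  structure(list(values = values, presence = presence, model_id = model_id),
            class = "effective_matrix")
}

#' Effective interaction matrix of a mediated community
#'
#' For the chemical-mediated models the species-by-species interactions are
#' indirect; the product of Jacobian blocks `A* = JF_c %*% JG_x` (chemical
#' effects on species, times species effects on chemicals) summarizes them
#' as a directed n x n matrix.  Entry (i, j) is the effect of species j on
#' species i.  Entries with magnitude below `1e-12` count as absent.
#'
#' @param model `"M"` or `"Mprime"`.
#' @param params a `mediator_params` object.
#' @param x,c evaluation state (typically the post-transient time averages
#'   of an accepted trajectory).
#' @return An `effective_matrix` with `values`, logical off-diagonal
#'   `presence`, and `model_id`.
#' @export
effective_interaction_matrix <- function(model, params, x, c) {
  model <- match.arg(model, MODEL_IDS)
  if (!is_mediated_model(model))
    stop("effective_interaction_matrix is defined for mediated models; use direct_truth for D/D'")
  jb <- jacobian_blocks(model, params, x, c)
  values <- jb$JF_c %*% jb$JG_x
  new_effective_matrix(values, abs(values) > ZERO_TOL, model)
}

#' State-free structural interaction pattern
#'
#' Species j can affect species i through the chemical pool iff some
#' chemical k is sensed by i (`rho_plus[i,k]` or `rho_minus[i,k]` nonzero)
#' and produced or consumed by j (`beta[k,j]` or `alpha[k,j]` nonzero).
#' This zero-pattern criterion is independent of the state and of parameter
#' magnitudes, so it is immune to accidental cancellations in the
#' state-evaluated effective matrix; it is the default ground truth for the
#' mediated models.
#'
#' @param params a `mediator_params` object.
#' @return Logical n x n matrix; the diagonal is always `FALSE`.
#' @export
structural_presence <- function(params) {
  stopifnot(inherits(params, "mediator_params"))
  sensed <- (params$rho_plus != 0) | (params$rho_minus != 0)   # n x m
  sourced <- (params$beta != 0) | (params$alpha != 0)          # m x n
  pres <- (sensed %*% sourced) > 0
  diag(pres) <- FALSE
  pres
}

#' Ground-truth network of a direct-interaction community
#'
#' For the direct gLV models the interaction matrix `A` itself is the
#' ground truth; presence is its nonzero off-diagonal pattern.
#'
#' @param dparams a `direct_params` object.
#' @return An `effective_matrix`.
#' @export
direct_truth <- function(dparams) {
  stopifnot(inherits(dparams, "direct_params"))
  new_effective_matrix(dparams$A, abs(dparams$A) > ZERO_TOL, "D")
}

#' @export
print.effective_matrix <- function(x, ...) {
  cat("effective_matrix (", x$model_id, "): ", nrow(x$values), " species, ",
      sum(x$presence), " directed interactions\n", sep = "")
  invisible(x)
}

#' Serialize an effective matrix as JSON
#'
#' Writes `values`, `presence` and the orientation convention (entry (i, j)
#' is the effect of species j on species i).
#'
#' @param em an `effective_matrix`.
#' @param path file path.
#' @export
write_truth_json <- function(em, path) {
  obj <- list(model_id = em$model_id,
              convention = "entry (i,j) = effect of species j on species i",
              values = em$values, presence = em$presence * 1L)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  values <- as.matrix(obj$values)
  presence <- matrix(as.logical(as.matrix(obj$presence)), nrow(values))
  new_effective_matrix(values, presence, obj$model_id)
}

# Finite-difference Jacobian of the stacked drift, used as the independent
# oracle against the analytic blocks.
fd_jacobian <- function(model, params, x, c = NULL, h = 1e-6) {
  n <- length(x); m <- length(c)
  f <- function(state) {
    d <- drift(model, params, state[seq_len(n)],
               if (m > 0) state[n + seq_len(m)] else NULL)
    c(d$dx, d$dc)
  }
  s0 <- c(x, c)
  J <- matrix(0, n + m, n + m)
  for (j in seq_len(n + m)) {
    hp <- sp <- s0; hp[j] <- s0[j] + h; sp[j] <- s0[j] - h
    J[, j] <- (f(hp) - f(sp)) / (2 * h)
  }
  J
}
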