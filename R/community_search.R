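#' Search configuration for the evolutionary community search
#'
#' Defaults follow the benchmark design: populations of `Mp = 32`
#' parameter-set/initial-state pairs, `mp = 4` parents kept per generation,
#' `Tmax` generations (60 for M/D, 120 for M'/D'), acceptance threshold
#' `omega = 5` on the community score, major-species threshold
#' `eta = 1e-2`, and initial abundances perturbed by an independent
#' `Uniform(0.8, 1.2)` factor before every simulation.
#'
#' @param Mp population size.
#' @param mp number of parents kept.
#' @param Tmax number of generations.
#' @param omega acceptance threshold on the score.
#' @param eta major-species abundance threshold.
#' @param perturb range of the multiplicative initial-state perturbation.
#' @param restart_cap maximum restarts per accepted community.
#' @param diversity_form `"sqrt"` uses `D = sum(sqrt(p_i))` over major
#'   species (the printed form); `"inv_simpson"` uses `1 / sum(p_i^2)`.
#' @return An object of class `search_config`.
#' @export
search_config <- function(Mp = 32, mp = 4, Tmax = 60, omega = 5, eta = 1e-2,
                          perturb = c(0.8, 1.2), restart_cap = 50,
                          diversity_form = c("sqrt", "inv_simpson")) {
  diversity_form <- match.arg(diversity_form)
  stopifnot(mp < Mp, Mp > 0, Tmax > 0, eta > 0, length(perturb) == 2)
  structure(list(Mp = as.integer(Mp), mp = as.integer(mp),
                 Tmax = as.integer(Tmax), omega = omega, eta = eta,
                 perturb = perturb, restart_cap = as.integer(restart_cap),
                 diversity_form = diversity_form),
            class = "search_config")
}

# Benchmark default: 120 generations for the shared-nutrient models,
# 60 otherwise.
default_Tmax <- function(model) {
  if (model %in% c("Mprime", "Dprime")) 120L else 60L
}

#' Community score
#'
#' Scores a simulated community as `z = S* . D . (4c - 4c^2)` where `S*` is
#' the number of major species (post-transient time-averaged abundance
#' above `eta`), `D = sum(sqrt(xhat_i / sum(xhat_j)))` is a diversity term
#' over the major species, and `c = L / (S* (S* - 1))` is the connectance
#' of the ground-truth network restricted to the major species (`L` =
#' number of present off-diagonal pairs).  The factor `4c - 4c^2` is
#' maximal at connectance 0.5, so the search favours communities with many
#' evenly abundant species and intermediate interaction density.  With at
#' most one major species the connectance is defined as 0 and `z = 0`.
#'
#' @param xhat time-averaged post-transient species abundances.
#' @param presence logical ground-truth presence matrix (full community).
#' @param eta major-species threshold.
#' @param diversity_form see [search_config()].
#' @return An object of class `score_breakdown` with `z`, `S_star`, `D`,
#'   `c`, `L`, `x_hat`, `eta`.
#' @export
community_score <- function(xhat, presence, eta = 1e-2,
                            diversity_form = "sqrt") {
  major <- which(xhat > eta)
  S <- length(major)
  if (S <= 1) {
    D <- if (S == 1) 1 else 0
    out <- list(z = 0, S_star = S, D = D, c = 0, L = 0L,
                x_hat = xhat, eta = eta)
  } else {
    p <- xhat[major] / sum(xhat[major])
    D <- if (diversity_form == "sqrt") sum(sqrt(p)) else 1 / sum(p^2)
    sub <- presence[major, major, drop = FALSE]
    diag(sub) <- FALSE
    L <- sum(sub)
    c <- L / (S * (S - 1))
    out <- list(z = S * D * (4 * c - 4 * c^2), S_star = S, D = D, c = c,
                L = as.integer(L), x_hat = xhat, eta = eta)
  }
  structure(out, class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("score z = %.3f  (S* = %d, D = %.3f, c = %.3f, L = %d)\n",
              x$z, x$S_star, x$D, x$c, x$L))
  invisible(x)
}

#' Mutate a parameter set by value swaps
#'
#' Applies `k ~ Uniform{1, 2, 3, 4}` swaps.  Each swap picks one of the
#' matrices `kappa`, `rho_plus`, `rho_minus`, `alpha`, `beta` uniformly
#' among those with at least one nonzero entry, then exchanges a uniformly
#' chosen nonzero entry with a uniformly chosen other position of the same
#' matrix.  Swaps permute values, so the multiset of entries of every
#' matrix is invariant.  Growth rates and sigma are never mutated.
#'
#' @param params a `mediator_params` object.
#' @param n_swaps number of swaps (default drawn uniformly from 1:4).
#' @return The mutated `mediator_params`.
#' @export
mutate_params <- function(params, n_swaps = sample(1:4, 1)) {
  stopifnot(inherits(params, "mediator_params"))
  fields <- c("kappa", "rho_plus", "rho_minus", "alpha", "beta")
  eligible <- fields[vapply(fields, function(f) any(params[[f]] != 0),
                            logical(1))]
  if (length(eligible) == 0) stop("all mutable matrices are zero")
  for (s in seq_len(n_swaps)) {
    f <- eligible[sample.int(length(eligible), 1)]
    mat <- params[[f]]
    nz <- which(mat != 0)
    a <- nz[sample.int(length(nz), 1)]
    others <- seq_along(mat)[-a]
    b <- others[sample.int(length(others), 1)]
    tmp <- mat[a]; mat[a] <- mat[b]; mat[b] <- tmp
    params[[f]] <- mat
  }
  params
}

# Ground-truth presence used both in the score and downstream evaluation:
# structural pattern for mediated models, nonzero pattern of A for direct.
truth_presence_for <- function(model, params) {
  if (is_mediated_model(model)) structural_presence(params)
  else direct_truth(derive_direct_matrix(params))$presence
}

# Simulation-side parameter object for a candidate under a given model.
sim_params_for <- function(model, params) {
  if (is_mediated_model(model)) params else derive_direct_matrix(params)
}

new_candidate <- function(params, x0) {
  structure(list(params = params, x0 = x0), class = "community_candidate")
}

#' Evolutionary search for a coexisting community
#'
#' Implements the generational search for parameter-set/initial-state
#' pairs.  `Mp` candidates are initialized with random parameters and
#' initial abundances drawn from `Uniform(10 eps, 100 eps)` (chemicals
#' start at zero).  Each generation every candidate's initial abundances
#' are independently perturbed by a `Uniform(0.8, 1.2)` factor, the model
#' is simulated for `t_max` steps, and the candidate is scored with
#' [community_score()]; a diverging simulation scores 0.  The top `mp`
#' candidates survive as parents and the remaining `Mp - mp` slots are
#' filled with mutants ([mutate_params()]) of uniformly chosen parents.
#' After `Tmax` generations the best candidate of the final generation is
#' accepted iff its score exceeds `omega`; otherwise the search reports a
#' rejection and the caller restarts with a fresh seed.
#'
#' The returned acceptance records the per-simulation RNG seed and the
#' perturbed initial state, so the accepted trajectory can be re-simulated
#' bit-identically with [accepted_trajectory()].
#'
#' @param model one of `"M"`, `"Mprime"`, `"D"`, `"Dprime"`.
#' @param sconfig a [search_config()].
#' @param simconfig a [sim_config()]; its `sigma` is the noise magnitude
#'   carried (and never mutated) by every candidate.
#' @param seed integer seed for the whole search.
#' @return On acceptance, a list of class `community_acceptance` with the
#'   winning `candidate`, its `score` breakdown, `sim_seed` and
#'   `perturbed_x0`; on rejection, `NULL`.
#' @export
evolve_community <- function(model, sconfig = search_config(),
                             simconfig = sim_config(), seed = 1L) {
  model <- match.arg(model, MODEL_IDS)
  set.seed(seed)
  n <- 10L
  pop <- lapply(seq_len(sconfig$Mp), function(k) {
    new_candidate(sample_mediator_params(),
                  runif(n, 10 * simconfig$eps, 100 * simconfig$eps))
  })
  best <- NULL
  for (gen in seq_len(sconfig$Tmax)) {
    sim_seeds <- sample.int(.Machine$integer.max, sconfig$Mp)
    scores <- numeric(sconfig$Mp)
    evals <- vector("list", sconfig$Mp)
    for (k in seq_len(sconfig$Mp)) {
      cand <- pop[[k]]
      pert <- runif(n, sconfig$perturb[1], sconfig$perturb[2])
      xp <- cand$x0 * pert
      sp <- sim_params_for(model, cand$params)
      res <- withr::with_seed(sim_seeds[k],
        em_integrate_raw(model, sp, xp, NULL, simconfig,
                         return_states = FALSE))
      if (res$ok) {
        sb <- community_score(res$xhat, truth_presence_for(model, cand$params),
                              sconfig$eta, sconfig$diversity_form)
      } else {
        sb <- community_score(rep(0, n), matrix(FALSE, n, n), sconfig$eta,
                              sconfig$diversity_form)
      }
      scores[k] <- sb$z
      evals[[k]] <- list(score = sb, sim_seed = sim_seeds[k],
                         perturbed_x0 = xp)
    }
    ord <- order(-scores)
    if (gen == sconfig$Tmax) {
      w <- ord[1]
      best <- list(candidate = pop[[w]], score = evals[[w]]$score,
                   sim_seed = evals[[w]]$sim_seed,
                   perturbed_x0 = evals[[w]]$perturbed_x0,
                   model_id = model, sconfig = sconfig,
                   simconfig = simconfig, seed = seed)
      class(best) <- "community_acceptance"
      break
    }
    parents <- pop[ord[seq_len(sconfig$mp)]]
    children <- lapply(seq_len(sconfig$Mp - sconfig$mp), function(s) {
      par <- parents[[sample.int(sconfig$mp, 1)]]
      new_candidate(mutate_params(par$params), par$x0)
    })
    pop <- c(parents, children)
  }
  if (best$score$z > sconfig$omega) best else NULL
}

#' Re-simulate an accepted community with full state output
#'
#' @param acc a `community_acceptance` from [evolve_community()].
#' @return The full `trajectory` of the accepted simulation (bit-identical
#'   to the one scored during the search).
#' @export
accepted_trajectory <- function(acc) {
  stopifnot(inherits(acc, "community_acceptance"))
  sp <- sim_params_for(acc$model_id, acc$candidate$params)
  withr::with_seed(acc$sim_seed,
    integrate_trajectory(acc$model_id, sp, acc$perturbed_x0, NULL,
                         acc$simconfig, return_states = TRUE))
}

#' Search until one community is accepted
#'
#' Repeats [evolve_community()] with fresh derived seeds until a candidate
#' passes the acceptance threshold, up to `restart_cap` restarts.
#'
#' @inheritParams evolve_community
#' @return A `community_acceptance` with an added `n_restarts` field.
#' @export
accepted_community <- function(model, sconfig = search_config(),
                               simconfig = sim_config(), seed = 1L) {
  seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max, sconfig$restart_cap))
  for (i in seq_along(seeds)) {
    acc <- evolve_community(model, sconfig, simconfig, seeds[i])
    if (!is.null(acc)) {
      acc$n_restarts <- i - 1L
      return(acc)
    }
  }
  stop(sprintf("no community accepted for model %s after %d restarts",
               model, sconfig$restart_cap))
}

#' Generate benchmark datasets over the sampling-interval and noise grids
#'
#' Builds the benchmark's eight conditions per model: the accepted
#' sigma = 1 communities resampled at intervals `tau` in {10, 20, 40, 80}
#' (25-, 50-, 100- and 200-day windows of 100 points), plus searches at
#' sigma in {0.5, 2, 4} resampled at tau = 40 (the sigma = 1, tau = 40
#' condition is shared between the two sweeps).  Each dataset entry stores
#' the sampled series, the ground-truth network and the accepted
#' candidate's provenance.
#'
#' @param model one of `"M"`, `"Mprime"`, `"D"`, `"Dprime"`.
#' @param N accepted communities per condition.
#' @param taus resampling intervals for the sigma = 1 sweep.
#' @param sigmas noise magnitudes for the tau = 40 sweep.
#' @param sconfig a [search_config()].
#' @param simconfig a [sim_config()]; its `sigma` field is overridden per
#'   condition.
#' @param seed master seed.
#' @param n_points samples per series.
#' @return A named list of `benchmark_dataset` objects, one per condition
#'   (`"tau<k>_sigma<s>"`).
#' @export
generate_dataset <- function(model, N, taus = c(10, 20, 40, 80),
                             sigmas = c(0.5, 1, 2, 4),
                             sconfig = search_config(),
                             simconfig = sim_config(),
                             seed = 1L, n_points = 100) {
  model <- match.arg(model, MODEL_IDS)
  all_sigmas <- sort(unique(c(1, sigmas)))
  seeds <- withr::with_seed(seed,
    matrix(sample.int(.Machine$integer.max, N * length(all_sigmas)),
           N, length(all_sigmas)))
  communities <- list()
  for (si in seq_along(all_sigmas)) {
    sg <- all_sigmas[si]
    cfg <- simconfig; cfg$sigma <- sg
    communities[[as.character(sg)]] <- lapply(seq_len(N), function(k) {
      acc <- accepted_community(model, sconfig, cfg, seeds[k, si])
      traj <- accepted_trajectory(acc)
      truth <- community_truth(model, acc$candidate$params,
                               traj$xhat, traj$chat)
      list(acc = acc, traj = traj, truth = truth)
    })
  }
  out <- list()
  make_ds <- function(coms, tau, sg) {
    entries <- lapply(seq_along(coms), function(k) {
      com <- coms[[k]]
      list(series = resample_tail(com$traj, tau, n_points),
           truth = com$truth,
           params = com$acc$candidate$params,
           score = com$acc$score,
           seed = com$acc$seed,
           community = k)
    })
    structure(list(model_id = model, tau = tau, sigma = sg,
                   entries = entries),
              class = "benchmark_dataset")
  }
  if (1 %in% all_sigmas) {
    for (tau in taus)
      out[[sprintf("tau%d_sigma1", tau)]] <- make_ds(communities[["1"]],
                                                     tau, 1)
  }
  for (sg in setdiff(sigmas, 1)) {
    out[[sprintf("tau40_sigma%g", sg)]] <-
      make_ds(communities[[as.character(sg)]], 40, sg)
  }
  out
}

# Full ground truth for a community: values plus presence.
community_truth <- function(model, params, xhat, chat) {
  if (is_mediated_model(model)) {
    em <- effective_interaction_matrix(model, params, xhat, chat)
    em$presence <- structural_presence(params)
    em$model_id <- model
    em
  } else {
    dt <- direct_truth(derive_direct_matrix(params))
    dt$model_id <- model
    dt
  }
}

#' @export
print.benchmark_dataset <- function(x, ...) {
  cat("benchmark_dataset:", x$model_id, "model, tau =", x$tau,
      ", sigma =", x$sigma, ",", length(x$entries), "communities\n")
  invisible(x)
}

#' Persist and reload a benchmark dataset directory
#'
#' The layout is `dataset.json` (manifest with model, condition and seeds)
#' plus one `community_<k>/` subdirectory per entry holding `series.tsv`,
#' `truth.json` and `params.json`.
#'
#' @param ds a `benchmark_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(model_id = ds$model_id, tau = ds$tau, sigma = ds$sigma,
                   n_communities = length(ds$entries),
                   seeds = vapply(ds$entries, function(e) e$seed, numeric(1)))
  jsonlite::write_json(manifest, file.path(dir, "dataset.json"),
                       digits = NA, auto_unbox = TRUE)
  for (k in seq_along(ds$entries)) {
    e <- ds$entries[[k]]
    cd <- file.path(dir, sprintf("community_%d", k))
    dir.create(cd, showWarnings = FALSE)
    write_series_tsv(e$series, file.path(cd, "series.tsv"))
    write_truth_json(e$truth, file.path(cd, "truth.json"))
    write_params_json(e$params, file.path(cd, "params.json"), seed = e$seed)
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "dataset.json"),
                                  simplifyVector = TRUE)
  entries <- lapply(seq_len(manifest$n_communities), function(k) {
    cd <- file.path(dir, sprintf("community_%d", k))
    list(series = read_series_tsv(file.path(cd, "series.tsv")),
         truth = read_truth_json(file.path(cd, "truth.json")),
         params = read_params_json(file.path(cd, "params.json")),
         seed = manifest$seeds[k],
         community = k)
  })
  structure(list(model_id = manifest$model_id, tau = manifest$tau,
                 sigma = manifest$sigma, entries = entries),
            class = "benchmark_dataset")
}
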