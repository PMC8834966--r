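# Small hand-built parameter sets reused across test files.

make_params <- function(n, m, r = rep(0.1, n), K = 1, delta = 0.01,
                        kappa = matrix(0.001, n, m),
                        rho_plus = matrix(0, n, m),
                        rho_minus = matrix(0, n, m),
                        alpha = matrix(0, m, n),
                        beta = matrix(0, m, n)) {
  mednetbench:::new_mediator_params(n, m, r, K, delta, kappa,
                                    rho_plus, rho_minus, alpha, beta)
}

# One isolated logistic species, no chemicals coupling.
single_species_params <- function(r = 0.1, delta = 0.01) {
  make_params(1, 1, r = r, delta = delta)
}

# The two-species, one-chemical worked example: species 1 senses the
# chemical (rho_plus = 0.2), species 2 produces it (beta = 0.1).
worked_example_params <- function() {
  make_params(2, 1,
              rho_plus = matrix(c(0.2, 0), 2, 1),
              beta = matrix(c(0, 0.1), 1, 2))
}

# Full Jacobian assembled from the blocks.
stacked_jacobian <- function(jb) {
  rbind(cbind(jb$JF_x, jb$JF_c), cbind(jb$JG_x, jb$JG_c))
}
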