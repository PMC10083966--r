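# shared fixtures: all synthetic, built in code

# reference ground truth (the reported global-fit constants)
gt <- default_ground_truth()

# quiet noise model for exact-recovery tests
no_noise <- noise_model(mobility_rel_scale = 0, teof_rel_scale = 0)

# small design for tests that only need structure, not statistical power
small_design <- function() {
  design_grid(temperatures = c(15, 26, 37), replicates = 1L)
}

# independent algebraic oracle for the two-point binding isotherm:
# eta_mu_i (1 + K c_i) = eta_mu_X + K c_i eta_mu_XL solved for (K, eta_mu_XL)
two_point_isotherm <- function(c1, y1, c2, y2, eta_mu_free) {
  a1 <- (eta_mu_free - y1) / c1
  a2 <- (eta_mu_free - y2) / c2
  K <- (a1 - a2) / (y1 - y2)
  list(K = K, eta_mu_complex = y1 - a1 / K)
}

# random temp_linear_pk for property loops
random_pk <- function() temp_linear_pk(runif(1, -4, 5), runif(1, -0.02, 0.02))
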