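# shared fixtures: loose-tolerance solver options keep unit tests fast;
# acceptance tests use the defaults
quick_opts <- function(tol = 1e-6) {
  solver_options(tol = tol, initial_mesh_size = 20)
}

blood <- function() get_material("blood")
al2o3 <- function() get_material("Al2O3")
copper <- function() get_material("Cu")

# state tibble in the form the residual functions expect, from a profile
# row plus the higher derivatives
residual_state <- function(eta, F, Fp, Fpp, Fppp = NA, theta = NA,
                           thetap = NA, thetapp = NA) {
  tibble::tibble(eta = eta, F = F, Fp = Fp, Fpp = Fpp, Fppp = Fppp,
                 theta = theta, thetap = thetap, thetapp = thetapp)
}
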