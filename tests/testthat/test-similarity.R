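test_that("momentum residual vanishes for known exact states", {
  # the all-zero state is a solution
  z <- residual_state(0.3, 0, 0, 0, Fppp = 0)
  expect_equal(momentum_residual(z, gamma = 0.7, C1 = 0.8, C2 = 1.5), 0)

  # flat-surface exponential profile solves the zero-curvature equation
  eta <- seq(0, 4, by = 0.25)
  cr <- crane_reference(eta)
  expect_equal(momentum_residual(cr, gamma = 0, C1 = 1, C2 = 1),
               rep(0, length(eta)), tolerance = 1e-14)

  # pure-shear state: only -F'^2 survives
  s <- residual_state(1.2, F = 1.2, Fp = 1, Fpp = 0, Fppp = 0)
  expect_equal(momentum_residual(s, gamma = 0, C1 = 1, C2 = 1), -1)
})

test_that("energy residual vanishes and scales as expected", {
  # quiescent fluid at uniform temperature
  s <- residual_state(0.5, 0, 0, 0, Fppp = 0, theta = 0.8, thetap = 0,
                      thetapp = 0)
  expect_equal(energy_residual(s, gamma = 2, pr = 5, C3 = 1.3), 0)

  # theta = F' maps the energy equation onto the momentum equation
  eta <- seq(0, 4, by = 0.5)
  cr <- crane_reference(eta)
  cr$thetapp <- exp(-eta) # theta'' = F''' for the exponential profile
  expect_equal(energy_residual(cr, gamma = 0, pr = 1, C3 = 1),
               rep(0, length(eta)), tolerance = 1e-14)

  # curvature term alone: (1/(Pr C3)) * 2 gamma theta'
  s2 <- residual_state(0.5, 0, 0, 0, Fppp = 0, theta = 0.5, thetap = 1,
                       thetapp = 0)
  expect_equal(energy_residual(s2, gamma = 1, pr = 2, C3 = 1), 1)
})

test_that("boundary residuals encode the three closures", {
  p_lit <- similarity_params(closure = "paper-literal")
  p_str <- similarity_params(closure = "stretching-wall")
  p_qui <- similarity_params(gamma = 0, phi1 = 0, phi2 = 0, eta_edge = 40,
                             closure = "quiescent-edge")

  trivial <- list(F = 0, Fp = 0, Fpp = 0, theta = 1, thetap = 0)
  expect_equal(boundary_residuals(trivial, trivial, p_lit), rep(0, 5))

  zero <- list(F = 0, Fp = 0, Fpp = 0, theta = 0, thetap = 0)
  expect_equal(boundary_residuals(zero, zero, p_str)[2], -1)

  # exponential profile satisfies the far-field closure in the limit
  wall <- crane_reference(0)
  edge <- crane_reference(40)
  expect_equal(boundary_residuals(wall, edge, p_qui), rep(0, 5),
               tolerance = 1e-15)
  expect_equal(boundary_residuals(wall, edge, p_str), rep(0, 5),
               tolerance = 1e-15)

  expect_error(stenoflow:::closure_bc_left("free-slip"), "unknown closure")
})

test_that("parameter constructor validates its domain", {
  expect_error(similarity_params(gamma = -0.1), "gamma")
  expect_error(similarity_params(pr = 0), "pr")
  expect_error(similarity_params(eta_edge = 0), "eta_edge")
  # default edge comes from the stenosis shape at the requested station
  p <- similarity_params(x_tilde = 0, eps = 0.4)
  expect_equal(p$eta_edge, 0.6)
})

test_that("first-order system is algebraically consistent with the residuals", {
  set.seed(11)
  for (rep in 1:20) {
    params <- similarity_params(
      gamma = runif(1, 0, 3), pr = runif(1, 0.5, 8),
      phi1 = runif(1, 0, 0.15), phi2 = runif(1, 0, 0.15),
      eta_edge = runif(1, 0.5, 4)
    )
    rhs <- as_first_order_system(params)
    eta <- runif(5, 0, params$eta_edge)
    Y <- matrix(runif(25, -2, 2), nrow = 5)
    d <- rhs(eta, Y)
    state <- tibble::tibble(eta = eta, F = Y[1, ], Fp = Y[2, ],
                            Fpp = Y[3, ], Fppp = d[3, ],
                            theta = Y[4, ], thetap = Y[5, ],
                            thetapp = d[5, ])
    mom <- momentum_residual(state, params$gamma,
                             params$mixture$C1, params$mixture$C2)
    ene <- energy_residual(state, params$gamma, params$pr,
                           params$mixture$C3)
    expect_lt(max(abs(mom)), 1e-12)
    expect_lt(max(abs(ene)), 1e-12)
    # first three slots chain the derivatives
    expect_equal(d[1, ], Y[2, ])
    expect_equal(d[2, ], Y[3, ])
    expect_equal(d[4, ], Y[5, ])
  }
})

test_that("zero-curvature unit-coefficient system matches the rearranged forms", {
  params <- similarity_params(gamma = 0, pr = 1, phi1 = 0, phi2 = 0,
                              eta_edge = 2)
  rhs <- as_first_order_system(params)
  Y <- matrix(c(0.3, 0.7, -0.2, 0.5, -0.4), nrow = 5)
  d <- rhs(1, Y)
  expect_equal(d[3, ], Y[2, ]^2 - Y[1, ] * Y[3, ])
  expect_equal(d[5, ], Y[2, ] * Y[4, ] - Y[1, ] * Y[5, ])
})
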