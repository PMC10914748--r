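test_that("collocation recovers the exponential stretching-surface solution", {
  params <- similarity_params(gamma = 0, pr = 1, phi1 = 0, phi2 = 0,
                              eta_edge = 8, closure = "quiescent-edge")
  prof <- solve_profile(params, quick_opts())
  # closed form F = 1 - exp(-eta): compare on the solver's own grid
  ref <- crane_reference(prof$profile$eta)
  # agreement is limited by domain truncation (exp(-8) ~ 3e-4), not by
  # the collocation error
  expect_lt(max(abs(prof$profile$F - ref$F)), 5e-3)
  expect_equal(prof$profile$Fpp[1], -1, tolerance = 1e-3)
  expect_true(prof$diagnostics$converged)
})

test_that("literal boundary conditions admit only the trivial state", {
  for (g in c(0, 0.1, 3.4)) {
    params <- similarity_params(gamma = g, pr = 5, phi1 = 0.05, phi2 = 0.05,
                                closure = "paper-literal")
    prof <- solve_profile(params, quick_opts())
    expect_lt(max(abs(prof$profile$F)), 1e-10)
    expect_lt(max(abs(prof$profile$theta - 1)), 1e-10)
  }
})

test_that("temperature collapses onto velocity at the analogy Prandtl number", {
  mix <- hybrid_mixture(0.08, 0.03)
  params <- similarity_params(gamma = 1.2, pr = mix$C1 * mix$C2 / mix$C3,
                              phi1 = 0.08, phi2 = 0.03, eta_edge = 1.5)
  prof <- solve_profile(params, quick_opts(1e-8))
  expect_lt(max(abs(prof$profile$theta - prof$profile$Fp)), 1e-6)
})

test_that("solutions satisfy their boundary conditions and are deterministic", {
  params <- similarity_params(gamma = 0.6, pr = 4, phi1 = 0.05, phi2 = 0.02)
  a <- solve_profile(params, quick_opts())
  b <- solve_profile(params, quick_opts())
  expect_identical(a$profile, b$profile)

  first <- a$profile[1, ]
  last <- a$profile[nrow(a$profile), ]
  bres <- boundary_residuals(first, last, params)
  expect_lt(max(abs(bres)), quick_opts()$tol)
  expect_true(all(diff(a$profile$eta) > 0))
  expect_equal(a$profile$eta[1], 0)
  expect_equal(a$profile$eta[nrow(a$profile)], params$eta_edge)
})

test_that("non-convergence is an explicit classed failure", {
  params <- similarity_params(gamma = 0.3, pr = 3, eta_edge = 12)
  tight <- solver_options(tol = 1e-12, initial_mesh_size = 8,
                          max_nodes = 12, max_refine = 2)
  expect_error(solve_profile(params, tight), class = "stenoflow_bvp_failure")
})

test_that("reference state has the documented endpoint and asymptotic values", {
  r0 <- crane_reference(0)
  expect_equal(c(r0$F, r0$Fp, r0$Fpp), c(0, 1, -1))
  rinf <- crane_reference(30)
  expect_equal(rinf$F, 1, tolerance = 1e-12)
  expect_equal(rinf$Fp, 0, tolerance = 1e-12)
  expect_error(crane_reference(-1), "eta")
})

test_that("wall derivatives settle as the defect tolerance tightens", {
  params <- similarity_params(gamma = 0, pr = 1, phi1 = 0, phi2 = 0,
                              eta_edge = 6, closure = "quiescent-edge")
  study <- convergence_study(params, quick_opts(), tolerances = 10^-(3:6))
  d <- study$dFpp0[-1]
  expect_true(all(diff(d) <= 0) || d[length(d)] < 10 * 1e-6)
  expect_lt(d[length(d)], 10 * 1e-6)
  expect_error(convergence_study(params, tolerances = 1e-4), "at least 2")

  # identical tolerance levels give identical answers (no randomness)
  twice <- convergence_study(params, quick_opts(),
                             tolerances = c(1e-4, 1e-4))
  expect_identical(twice$Fpp0[1], twice$Fpp0[2])
})

test_that("solver options are validated", {
  expect_error(solver_options(tol = 0), "tol")
  expect_error(solver_options(initial_mesh_size = 2), "initial_mesh_size")
  expect_error(solver_options(initial_mesh_size = 50, max_nodes = 50),
               "max_nodes")
})
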