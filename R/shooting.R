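## Shooting solver: independent route to the same BVP, used to
## cross-validate the collocation solver. Integrates the first-order
## system with a high-order explicit integrator (deSolve) and applies a
## damped Newton iteration with forward-difference Jacobian (step 1e-7)
## on the two unknown wall derivatives (F''(0), theta'(0)).

shoot_integrate <- function(s, params, times, rtol, atol) {
  wall_slope <- if (params$closure == "paper-literal") 0 else 1
  y0 <- c(F = 0, Fp = wall_slope, Fpp = s[1], theta = 1, thetap = s[2])
  rhs <- as_first_order_system(params)
  func <- function(t, y, parms) list(as.vector(rhs(t, matrix(y, nrow = 5))))
  deSolve::ode(y = y0, times = times, func = func, parms = NULL,
               method = "ode45", rtol = rtol, atol = atol)
}

shoot_target <- function(s, params, rtol, atol) {
  sol <- shoot_integrate(s, params, c(0, params$eta_edge), rtol, atol)
  yend <- as.numeric(sol[nrow(sol), -1])
  closure_bc_right(params$closure)(yend)
}

#' Solve the similarity BVP by shooting
#'
#' Independent second route to the boundary-value problem of
#' [solve_profile()]: the two unknown wall derivatives are found by Newton
#' iteration on the edge boundary residuals, each evaluation being one
#' initial-value integration with a high-order explicit Runge-Kutta
#' method. Kept deliberately separate from the collocation path so the two
#' can cross-validate each other.
#'
#' @param params a [similarity_params()].
#' @param opts a [solver_options()] (`tol` sets the integrator tolerances).
#' @param n_out number of output grid points for the returned profile.
#' @param max_iter maximum Newton iterations on the unknown slopes.
#' @return an `hnf_profile` (see [solve_profile()]) with
#'   `diagnostics$method = "shooting"`.
#' @export
solve_profile_shooting <- function(params, opts = solver_options(),
                                   n_out = 201, max_iter = 40) {
  stopifnot(inherits(params, "similarity_params"))
  rtol <- min(opts$tol, 1e-9)
  atol <- rtol * 1e-2
  e <- params$eta_edge
  s <- if (params$closure == "paper-literal") c(0, 0) else c(-2 / e, -2 / e)

  g <- shoot_target(s, params, rtol, atol)
  iter <- 0
  fd_step <- 1e-7
  while (max(abs(g)) >= 1e-10 && iter < max_iter) {
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      sp <- s
      dj <- fd_step * (1 + abs(s[j]))
      sp[j] <- sp[j] + dj
      J[, j] <- (shoot_target(sp, params, rtol, atol) - g) / dj
    }
    ds <- tryCatch(solve(J, g), error = function(err) NULL)
    if (is.null(ds) || any(!is.finite(ds))) {
      rlang::abort("shooting: singular Newton system on the wall slopes",
                   class = "stenoflow_bvp_failure")
    }
    lam <- 1
    repeat {
      gn <- shoot_target(s - lam * ds, params, rtol, atol)
      if ((all(is.finite(gn)) && max(abs(gn)) < max(abs(g))) ||
            lam < 1 / 64) break
      lam <- lam / 2
    }
    if (!all(is.finite(gn)) || max(abs(gn)) >= max(abs(g))) break
    s <- s - lam * ds
    g <- gn
    iter <- iter + 1
  }
  if (max(abs(g)) >= 1e-8) {
    rlang::abort(
      sprintf("shooting failed to converge: edge residual %.3e after %d iterations",
              max(abs(g)), iter),
      class = "stenoflow_bvp_failure"
    )
  }

  times <- seq(0, e, length.out = n_out)
  sol <- shoot_integrate(s, params, times, rtol, atol)
  profile <- tibble::tibble(
    eta = sol[, "time"], F = sol[, "F"], Fp = sol[, "Fp"],
    Fpp = sol[, "Fpp"], theta = sol[, "theta"], thetap = sol[, "thetap"]
  )
  structure(
    list(profile = profile, params = params, mixture = params$mixture,
         diagnostics = list(max_defect = NA_real_,
                            newton_residual = max(abs(g)),
                            n_nodes = n_out, refinements = iter,
                            converged = TRUE, method = "shooting")),
    class = "hnf_profile"
  )
}
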