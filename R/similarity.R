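#' Similarity-model parameters
#'
#' Collects the dimensionless parameters of the similarity-reduced
#' boundary-layer problem at one axial station of the stenosed artery:
#' the flow/curvature parameter \eqn{\gamma = \sqrt{\nu_f L_0 / (u_0 R^2)}}
#' (it multiplies the transverse-curvature terms \eqn{(1 + 2\gamma\eta)}),
#' the Prandtl number of the base fluid (conventional convention: momentum
#' over thermal diffusivity), the two nanoparticle volume fractions, the
#' outer edge of the similarity domain, and the boundary-condition closure.
#'
#' Closures (`closure`):
#' \describe{
#'   \item{`"stretching-wall"` (default)}{F(0)=0, F'(0)=1, theta(0)=1 at the
#'     wall; zero shear F''=0 and zero heat-flux gradient theta'=0 at the
#'     edge. The unit wall slope is consistent with the wall velocity scale
#'     \eqn{u_0 x / L_0} of the similarity map.}
#'   \item{`"paper-literal"`}{as above but F'(0)=0. This set admits only
#'     the trivial state F=0, theta=1 (kept so the degeneracy can be
#'     demonstrated rather than silently patched).}
#'   \item{`"quiescent-edge"`}{F(0)=0, F'(0)=1, theta(0)=1 with far-field
#'     decay F'=0, theta=0 at the edge; on a large domain this is the
#'     classical stretching-surface problem with the Crane closed form as
#'     the gamma=0, particle-free limit.}
#' }
#'
#' The edge location defaults to the local dimensionless vessel radius
#' `f(x_tilde)` of the stenosis shape; one boundary-value problem is solved
#' per axial station, the coupling to the geometry being only through this
#' edge value.
#'
#' @param gamma flow/curvature parameter (>= 0).
#' @param pr Prandtl number (> 0).
#' @param phi1,phi2 nanoparticle volume fractions (Al2O3 and Cu by default).
#' @param eta_edge outer boundary of the similarity domain (> 0). Default
#'   `dimensionless_profile(x_tilde, eps)`.
#' @param closure boundary-condition closure, see Details.
#' @param x_tilde,eps axial station and stenosis severity used only to
#'   default `eta_edge`.
#' @param mixture optionally a precomputed [hybrid_mixture()]; by default
#'   built from `phi1`, `phi2` with the built-in materials.
#' @return a list of class `similarity_params`.
#' @examples
#' similarity_params(gamma = 0.1, pr = 3)
#' @export
similarity_params <- function(gamma = 0.1, pr = 3, phi1 = 0.05, phi2 = 0.05,
                              eta_edge = NULL,
                              closure = c("stretching-wall", "paper-literal",
                                          "quiescent-edge"),
                              x_tilde = 0.25, eps = 0.5,
                              mixture = NULL) {
  closure <- match.arg(closure)
  if (!is.finite(gamma) || gamma < 0) rlang::abort("gamma must be >= 0")
  if (!is.finite(pr) || pr <= 0) rlang::abort("pr must be > 0")
  if (is.null(eta_edge)) {
    eta_edge <- dimensionless_profile(x_tilde, eps)
  }
  if (!is.finite(eta_edge) || eta_edge <= 0) {
    rlang::abort("eta_edge must be > 0")
  }
  if (is.null(mixture)) {
    mixture <- hybrid_mixture(phi1, phi2)
  }
  structure(
    list(gamma = gamma, pr = pr, phi1 = phi1, phi2 = phi2,
         eta_edge = eta_edge, closure = closure, mixture = mixture),
    class = "similarity_params"
  )
}

#' @export
print.similarity_params <- function(x, ...) {
  cat("<similarity_params>\n")
  cat(sprintf("  gamma = %g, Pr = %g, phi1 = %g, phi2 = %g\n",
              x$gamma, x$pr, x$phi1, x$phi2))
  cat(sprintf("  eta_edge = %g, closure = %s\n", x$eta_edge, x$closure))
  cat(sprintf("  C1 = %.6f, C2 = %.6f, C3 = %.6f\n",
              x$mixture$C1, x$mixture$C2, x$mixture$C3))
  invisible(x)
}

#' Dimensional flow scales
#'
#' Reference scales needed to map the dimensionless similarity solution
#' back to physical velocity, temperature and wall-flux fields.
#'
#' @param u0 reference axial velocity, m/s (> 0).
#' @param nu_f base-fluid kinematic viscosity, m^2/s (> 0).
#' @param T0 far-field reference temperature, K.
#' @param T1 wall temperature, K (distinct from T0).
#' @param L0 reference axial length, m (> 0).
#' @param R local vessel radius, m (> 0).
#' @param rho_f base-fluid density, kg/m^3 (> 0), used to form mu_f.
#' @param k_f base-fluid conductivity, W m^-1 K^-1 (> 0).
#' @return a list of class `flow_scales`.
#' @export
flow_scales <- function(u0 = 1, nu_f = 1, T0 = 0, T1 = 1, L0 = 1, R = 1,
                        rho_f = 1050, k_f = 0.52) {
  vals <- c(u0 = u0, nu_f = nu_f, L0 = L0, R = R, rho_f = rho_f, k_f = k_f)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    rlang::abort("u0, nu_f, L0, R, rho_f, k_f must be positive")
  }
  if (!is.finite(T0) || !is.finite(T1) || T1 == T0) {
    rlang::abort("T0, T1 must be finite and distinct")
  }
  structure(
    list(u0 = u0, nu_f = nu_f, T0 = T0, T1 = T1, L0 = L0, R = R,
         rho_f = rho_f, k_f = k_f),
    class = "flow_scales"
  )
}

#' Momentum-equation residual
#'
#' Left-hand side of the similarity momentum equation
#' \deqn{\frac{1}{C_1 C_2}\left[(1 + 2\gamma\eta)F''' + 2\gamma F''\right]
#'   + F F'' - F'^2,}
#' evaluated pointwise at supplied states. Zero for an exact solution.
#'
#' @param state data frame with columns `eta`, `F`, `Fp`, `Fpp`, `Fppp`.
#' @param gamma flow/curvature parameter.
#' @param C1,C2 mixture coefficients (see [model_coefficients()]).
#' @return residual vector, one entry per row of `state`.
#' @export
momentum_residual <- function(state, gamma, C1 = 1, C2 = 1) {
  with(state, {
    ((1 + 2 * gamma * eta) * Fppp + 2 * gamma * Fpp) / (C1 * C2) +
      F * Fpp - Fp^2
  })
}

#' Energy-equation residual
#'
#' Left-hand side of the similarity energy equation
#' \deqn{\frac{1}{Pr\,C_3}\left[(1 + 2\gamma\eta)\theta'' +
#'   2\gamma\theta'\right] + F\theta' - F'\theta.}
#'
#' @param state data frame with columns `eta`, `F`, `Fp`, `theta`,
#'   `thetap`, `thetapp`.
#' @param gamma flow/curvature parameter.
#' @param pr Prandtl number.
#' @param C3 mixture coefficient.
#' @return residual vector, one entry per row of `state`.
#' @export
energy_residual <- function(state, gamma, pr, C3 = 1) {
  with(state, {
    ((1 + 2 * gamma * eta) * thetapp + 2 * gamma * thetap) / (pr * C3) +
      F * thetap - Fp * theta
  })
}

closure_bc_left <- function(closure) {
  ## residual functions of the wall state y = (F, Fp, Fpp, theta, thetap)
  switch(closure,
    "paper-literal"   = function(y) c(y[1], y[2], y[4] - 1),
    "stretching-wall" = function(y) c(y[1], y[2] - 1, y[4] - 1),
    "quiescent-edge"  = function(y) c(y[1], y[2] - 1, y[4] - 1),
    rlang::abort(paste0("unknown closure: '", closure, "'"))
  )
}

closure_bc_right <- function(closure) {
  switch(closure,
    "paper-literal"   = function(y) c(y[3], y[5]),
    "stretching-wall" = function(y) c(y[3], y[5]),
    "quiescent-edge"  = function(y) c(y[2], y[4]),
    rlang::abort(paste0("unknown closure: '", closure, "'"))
  )
}

#' Boundary-condition residuals
#'
#' Evaluates the five boundary residuals of the selected closure: three
#' wall conditions at eta = 0 and two edge conditions at eta = eta_edge.
#' All five vanish for a solution satisfying the boundary conditions.
#'
#' @param left,right one-row data frames (or named vectors/lists) with
#'   entries `F`, `Fp`, `Fpp`, `theta`, `thetap` at the wall and edge.
#' @param params a [similarity_params()] (only `closure` is used).
#' @return numeric vector of length 5: wall residuals then edge residuals.
#' @export
boundary_residuals <- function(left, right, params) {
  as_y <- function(s) {
    s <- as.list(s)
    as.numeric(c(s$F, s$Fp, s$Fpp, s$theta, s$thetap))
  }
  c(closure_bc_left(params$closure)(as_y(left)),
    closure_bc_right(params$closure)(as_y(right)))
}

#' First-order ODE system descriptor
#'
#' Reduces the third-order momentum and second-order energy similarity
#' equations to five coupled first-order equations in the state
#' y = (F, F', F'', theta, theta'), solving algebraically for F''' and
#' theta''. The transverse-curvature factor \eqn{1 + 2\gamma\eta} is
#' positive for all \eqn{\gamma, \eta \ge 0}, so the system is regular on
#' the whole domain.
#'
#' @param params a [similarity_params()].
#' @return a function `(eta, Y)` mapping a numeric eta vector and a 5 x n
#'   state matrix (rows F, Fp, Fpp, theta, thetap) to the 5 x n matrix of
#'   derivatives.
#' @export
as_first_order_system <- function(params) {
  gamma <- params$gamma
  c1c2 <- params$mixture$C1 * params$mixture$C2
  prc3 <- params$pr * params$mixture$C3
  function(eta, Y) {
    if (is.null(dim(Y))) Y <- matrix(Y, nrow = 5)
    curv <- 1 + 2 * gamma * eta
    Fppp <- (c1c2 * (Y[2, ]^2 - Y[1, ] * Y[3, ]) - 2 * gamma * Y[3, ]) / curv
    thpp <- (prc3 * (Y[2, ] * Y[4, ] - Y[1, ] * Y[5, ]) -
               2 * gamma * Y[5, ]) / curv
    rbind(Y[2, ], Y[3, ], Fppp, Y[5, ], thpp, deparse.level = 0)
  }
}
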