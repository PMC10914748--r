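check_converged <- function(profile) {
  stopifnot(inherits(profile, "hnf_profile"))
  if (!isTRUE(profile$diagnostics$converged)) {
    rlang::abort("profile did not converge; wall quantities refused")
  }
  invisible(profile)
}

#' Scaled skin-friction coefficient
#'
#' The wall shear group \eqn{Re_x^{1/2} C_f = F''(0) / C_1} with
#' \eqn{C_1 = (1-\phi_1)^{2.5}(1-\phi_2)^{2.5}}. Reported with the sign
#' the computation produces; no sign convention is imposed.
#'
#' @param profile a converged `hnf_profile`.
#' @param mix a [hybrid_mixture()]; defaults to the profile's own.
#' @return dimensionless scaled skin friction.
#' @export
skin_friction <- function(profile, mix = profile$mixture) {
  check_converged(profile)
  profile$profile$Fpp[1] / mix$C1
}

#' Scaled Nusselt number
#'
#' The wall heat-transfer group
#' \eqn{Re_x^{-1/2} Nu_x = -(k_{hnf}/k_f)\,\theta'(0)}, signed as
#' computed.
#'
#' @inheritParams skin_friction
#' @return dimensionless scaled Nusselt number.
#' @export
nusselt <- function(profile, mix = profile$mixture) {
  check_converged(profile)
  -mix$k_ratio * profile$profile$thetap[1]
}

#' Wall-quantity summary of a solved profile
#'
#' @inheritParams skin_friction
#' @return one-row tibble with `Fpp0`, `thetap0`, `cf_scaled`
#'   (\eqn{Re_x^{1/2} C_f}), `nu_scaled` (\eqn{Re_x^{-1/2} Nu_x}).
#' @export
wall_quantities <- function(profile, mix = profile$mixture) {
  check_converged(profile)
  tibble::tibble(
    Fpp0 = profile$profile$Fpp[1],
    thetap0 = profile$profile$thetap[1],
    cf_scaled = skin_friction(profile, mix),
    nu_scaled = nusselt(profile, mix)
  )
}

#' Dimensional wall shear stress and heat flux
#'
#' Maps the dimensionless wall derivatives back to physical units through
#' the similarity transformation. With wall-normal coordinate
#' \eqn{\eta = (r^2 - R^2)/(2R)\sqrt{u_0/(\nu_f L_0)}}, the wall velocity
#' gradient is \eqn{(u_0 x / L_0)\,F''(0)\sqrt{u_0/(\nu_f L_0)}}, so
#' \deqn{\tau_w = \mu_{hnf}\,\frac{u_0 x}{L_0} F''(0)
#'   \sqrt{u_0/(\nu_f L_0)}, \qquad
#'   q_w = -k_{hnf}\,(T_1 - T_0)\,\theta'(0)\sqrt{u_0/(\nu_f L_0)}.}
#'
#' @param profile a converged `hnf_profile`.
#' @param mix a [hybrid_mixture()]; defaults to the profile's own.
#' @param scales a [flow_scales()] (required).
#' @param x axial position, m.
#' @return one-row tibble with `tau_w` (Pa) and `q_w` (W/m^2).
#' @export
dimensional_wall_fluxes <- function(profile, mix = profile$mixture,
                                    scales, x = scales$L0) {
  check_converged(profile)
  if (missing(scales) || !inherits(scales, "flow_scales")) {
    rlang::abort("dimensional wall fluxes need flow_scales")
  }
  grad <- sqrt(scales$u0 / (scales$nu_f * scales$L0))
  mu_f <- scales$rho_f * scales$nu_f
  tau_w <- mu_f * mix$mu_ratio * (scales$u0 * x / scales$L0) *
    profile$profile$Fpp[1] * grad
  q_w <- -scales$k_f * mix$k_ratio * (scales$T1 - scales$T0) *
    profile$profile$thetap[1] * grad
  tibble::tibble(tau_w = tau_w, q_w = q_w)
}

#' Physical velocity and temperature fields at one axial station
#'
#' Maps the similarity solution to dimensional fields sampled on the
#' solver's eta grid. Eta is treated as the nonnegative wall-normal
#' coordinate, so the radial positions satisfy
#' \eqn{r^2 = R^2 + 2R\,\eta\,\sqrt{\nu_f L_0 / u_0}}. Axial velocity is
#' \eqn{u = (u_0 x/L_0) F'(\eta)}, radial velocity
#' \eqn{v = -(R/r)\sqrt{u_0 \nu_f / L_0}\,F(\eta)} and temperature
#' \eqn{T = T_0 + (T_1 - T_0)\theta(\eta)}.
#'
#' @inheritParams dimensional_wall_fluxes
#' @return tibble with columns `eta`, `r`, `u`, `v`, `T`.
#' @export
physical_fields <- function(profile, scales, x = scales$L0) {
  check_converged(profile)
  if (missing(scales) || !inherits(scales, "flow_scales")) {
    rlang::abort("physical fields need flow_scales")
  }
  p <- profile$profile
  eta_dim <- p$eta * sqrt(scales$nu_f * scales$L0 / scales$u0)
  r <- sqrt(scales$R^2 + 2 * scales$R * eta_dim)
  tibble::tibble(
    eta = p$eta,
    r = r,
    u = (scales$u0 * x / scales$L0) * p$Fp,
    v = -(scales$R / r) * sqrt(scales$u0 * scales$nu_f / scales$L0) * p$F,
    T = scales$T0 + (scales$T1 - scales$T0) * p$theta
  )
}
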