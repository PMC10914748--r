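#' Built-in thermophysical material registry
#'
#' Room-temperature constants for the base fluid (whole blood) and the two
#' nanoparticle species used throughout the package: aluminium oxide
#' (Al2O3) and copper (Cu). Densities in kg/m^3, specific heats in
#' J kg^-1 K^-1, thermal conductivities in W m^-1 K^-1.
#'
#' @param extra optional tibble/data frame of user materials with columns
#'   `name`, `rho`, `cp`, `k`; appended to the built-in rows. Built-in names
#'   cannot be overridden.
#' @return a tibble with columns `name`, `rho`, `cp`, `k`.
#' @examples
#' material_registry()
#' @export
material_registry <- function(extra = NULL) {
  base <- tibble::tibble(
    name = c("blood", "Al2O3", "Cu"),
    rho  = c(1050, 3970, 8933),
    cp   = c(3617, 765, 385),
    k    = c(0.52, 40, 400)
  )
  if (is.null(extra)) {
    return(base)
  }
  extra <- tibble::as_tibble(extra)
  required <- c("name", "rho", "cp", "k")
  if (!all(required %in% names(extra))) {
    rlang::abort("extra materials need columns name, rho, cp, k")
  }
  extra <- extra[, required]
  if (any(extra$name %in% base$name)) {
    rlang::abort("built-in materials (blood, Al2O3, Cu) cannot be redefined")
  }
  check_material(extra)
  dplyr::bind_rows(base, extra)
}

check_material <- function(mat) {
  if (any(!is.finite(mat$rho)) || any(mat$rho <= 0) ||
      any(!is.finite(mat$cp)) || any(mat$cp <= 0) ||
      any(!is.finite(mat$k)) || any(mat$k <= 0)) {
    rlang::abort("material properties rho, cp, k must all be positive and finite")
  }
  invisible(mat)
}

#' Look up one material by name
#'
#' @param name material name, e.g. `"blood"`.
#' @param materials a registry tibble, by default [material_registry()].
#' @return a one-row tibble with columns `name`, `rho`, `cp`, `k`.
#' @export
get_material <- function(name, materials = material_registry()) {
  hit <- materials[materials$name == name, ]
  if (nrow(hit) != 1) {
    rlang::abort(paste0("unknown material: '", name, "'"))
  }
  check_material(hit)
}

resolve_material <- function(x, materials = material_registry()) {
  if (is.character(x)) {
    return(get_material(x, materials))
  }
  x <- tibble::as_tibble(x)
  check_material(x)
  x
}

#' Linear mixture density
#'
#' Volume-weighted density of a particle-laden fluid,
#' \eqn{\rho_{nf} = (1-\phi)\rho_f + \phi\rho_s}.
#'
#' @param base,particle material name or one-row material tibble.
#' @param phi particle volume fraction in \[0, 1\].
#' @param materials registry used to resolve names.
#' @return mixture density, kg/m^3.
#' @examples
#' density_mixture("blood", "Cu", 0.1)
#' @export
density_mixture <- function(base, particle, phi, materials = material_registry()) {
  check_fraction(phi, upper_open = FALSE)
  b <- resolve_material(base, materials)
  p <- resolve_material(particle, materials)
  (1 - phi) * b$rho + phi * p$rho
}

#' Linear mixture volumetric heat capacity
#'
#' \eqn{(\rho C_p)_{nf} = (1-\phi)(\rho C_p)_f + \phi(\rho C_p)_s}.
#'
#' @inheritParams density_mixture
#' @return volumetric heat capacity, J m^-3 K^-1.
#' @export
heat_capacity_mixture <- function(base, particle, phi, materials = material_registry()) {
  check_fraction(phi, upper_open = FALSE)
  b <- resolve_material(base, materials)
  p <- resolve_material(particle, materials)
  (1 - phi) * b$rho * b$cp + phi * p$rho * p$cp
}

check_fraction <- function(phi, upper_open = TRUE, arg = "phi") {
  if (any(!is.finite(phi)) || any(phi < 0) ||
      (upper_open && any(phi >= 1)) || (!upper_open && any(phi > 1))) {
    rlang::abort(paste0(
      arg, " must lie in [0, 1", if (upper_open) ")" else "]"
    ))
  }
  invisible(phi)
}

#' Brinkman viscosity ratio for a two-species suspension
#'
#' \eqn{\mu_{hnf}/\mu_f = (1-\phi_1)^{-2.5}(1-\phi_2)^{-2.5}}; each species
#' contributes one Brinkman factor, so the ratio is symmetric in the two
#' fractions. Diverges as either fraction approaches 1 (jamming limit),
#' hence fractions must be strictly below 1.
#'
#' @param phi1,phi2 particle volume fractions in \[0, 1).
#' @return dimensionless viscosity ratio.
#' @examples
#' viscosity_ratio(0.1, 0)
#' @export
viscosity_ratio <- function(phi1, phi2 = 0) {
  check_fraction(phi1, arg = "phi1")
  check_fraction(phi2, arg = "phi2")
  (1 - phi1)^-2.5 * (1 - phi2)^-2.5
}

#' Maxwell two-phase effective conductivity ratio
#'
#' Classical Maxwell (Maxwell-Garnett) formula for spherical inclusions of
#' conductivity `k_part` dispersed at volume fraction `phi` in a continuous
#' phase of conductivity `k_cont`:
#' \deqn{\frac{k_{eff}}{k_{cont}} =
#'   \frac{k_s + 2k_c - 2\phi(k_c - k_s)}{k_s + 2k_c + \phi(k_c - k_s)}.}
#'
#' @param k_cont continuous-phase conductivity, W m^-1 K^-1 (> 0).
#' @param k_part particle conductivity, W m^-1 K^-1 (> 0).
#' @param phi particle volume fraction in \[0, 1\].
#' @return dimensionless ratio of effective to continuous-phase conductivity.
#' @examples
#' maxwell_conductivity_ratio(0.52, 40, 0.05)
#' @export
maxwell_conductivity_ratio <- function(k_cont, k_part, phi) {
  if (any(!is.finite(k_cont)) || any(k_cont <= 0) ||
      any(!is.finite(k_part)) || any(k_part <= 0)) {
    rlang::abort("conductivities must be positive and finite")
  }
  check_fraction(phi, upper_open = FALSE)
  (k_part + 2 * k_cont - 2 * phi * (k_cont - k_part)) /
    (k_part + 2 * k_cont + phi * (k_cont - k_part))
}

#' Effective properties of the hybrid nanofluid
#'
#' Builds the full set of effective thermophysical properties for a base
#' fluid carrying two nanoparticle species, plus the three dimensionless
#' coefficients that enter the similarity-reduced momentum and energy
#' equations:
#' \itemize{
#'   \item density and volumetric heat capacity by two-stage linear mixing
#'     (species 1 into the base, then species 2 into that suspension);
#'   \item viscosity ratio by the product of two Brinkman factors;
#'   \item conductivity ratio by two chained Maxwell factors, where the
#'     continuous phase of the second factor is the mono nanofluid produced
#'     by the first (its conductivity is `k_f` times the first factor);
#'   \item `C1` \eqn{= (1-\phi_1)^{2.5}(1-\phi_2)^{2.5}} (inverse viscosity
#'     ratio), `C2` \eqn{= \rho_{hnf}/\rho_f}, and
#'     `C3` \eqn{= (k_{hnf}/k_f)\,(\rho C_p)_{hnf}/(\rho C_p)_f}.
#' }
#' By default species 1 is Al2O3 and species 2 is Cu; the ordering is
#' configurable and matters only through the chaining of the Maxwell
#' factors (the other mixing laws are symmetric).
#'
#' @param phi1,phi2 volume fractions of species 1 and 2, each in \[0, 1).
#' @param base,particle1,particle2 material names or one-row material
#'   tibbles.
#' @param materials registry used to resolve names.
#' @return a one-row tibble of class `hnf_mixture` with columns
#'   `phi1`, `phi2`, `rho_hnf`, `rhocp_hnf`, `mu_ratio`, `k_ratio`
#'   (hybrid, chained Maxwell), `k_ratio_mono` (species-1-only Maxwell
#'   ratio, exposed because published table headers are ambiguous about
#'   which ratio they scale by), `C1`, `C2`, `C3`.
#' @examples
#' hybrid_mixture(0.05, 0.05)
#' @export
hybrid_mixture <- function(phi1, phi2, base = "blood",
                           particle1 = "Al2O3", particle2 = "Cu",
                           materials = material_registry()) {
  check_fraction(phi1, arg = "phi1")
  check_fraction(phi2, arg = "phi2")
  b <- resolve_material(base, materials)
  p1 <- resolve_material(particle1, materials)
  p2 <- resolve_material(particle2, materials)

  rho_nf <- density_mixture(b, p1, phi1)
  rho_hnf <- (1 - phi2) * rho_nf + phi2 * p2$rho
  rhocp_nf <- heat_capacity_mixture(b, p1, phi1)
  rhocp_hnf <- (1 - phi2) * rhocp_nf + phi2 * p2$rho * p2$cp

  k_ratio_mono <- maxwell_conductivity_ratio(b$k, p1$k, phi1)
  k_nf <- b$k * k_ratio_mono
  k_ratio <- k_ratio_mono * maxwell_conductivity_ratio(k_nf, p2$k, phi2)

  out <- tibble::tibble(
    phi1 = phi1, phi2 = phi2,
    rho_hnf = rho_hnf,
    rhocp_hnf = rhocp_hnf,
    mu_ratio = viscosity_ratio(phi1, phi2),
    k_ratio = k_ratio,
    k_ratio_mono = k_ratio_mono,
    C1 = (1 - phi1)^2.5 * (1 - phi2)^2.5,
    C2 = rho_hnf / b$rho,
    C3 = k_ratio * rhocp_hnf / (b$rho * b$cp)
  )
  class(out) <- c("hnf_mixture", class(out))
  out
}

#' Dimensionless ODE coefficients of a mixture
#'
#' Convenience accessor returning the coefficient triple (C1, C2, C3) used
#' by the momentum and energy similarity equations.
#'
#' @param mix a mixture from [hybrid_mixture()].
#' @return named numeric vector `c(C1, C2, C3)`.
#' @export
model_coefficients <- function(mix) {
  stopifnot(inherits(mix, "hnf_mixture"))
  c(C1 = mix$C1, C2 = mix$C2, C3 = mix$C3)
}
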