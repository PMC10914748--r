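#' Cosine stenosis geometry
#'
#' Describes an axisymmetric artery of unobstructed radius `R0` with a
#' cosine-shaped constriction of maximum depth `lam` spanning the axial
#' interval (-L0/4, L0/4) (total stenosis length L0/2). The severity
#' `eps = lam / R0` is the dimensionless occlusion fraction; `eps = 0` is a
#' healthy vessel and `eps -> 1` total occlusion (disallowed).
#'
#' @param R0 unobstructed radius (length units, > 0).
#' @param L0 reference axial length (> 0); the stenosis occupies L0/2.
#' @param lam maximum occlusion height, in \[0, R0).
#' @return a one-row tibble of class `stenosis_geometry` with columns
#'   `R0`, `L0`, `lam`, `eps`.
#' @examples
#' stenosis_geometry(R0 = 1, L0 = 4, lam = 0.5)
#' @export
stenosis_geometry <- function(R0 = 1, L0 = 1, lam = R0 * 0.5) {
  if (!is.finite(R0) || R0 <= 0 || !is.finite(L0) || L0 <= 0) {
    rlang::abort("R0 and L0 must be positive")
  }
  if (!is.finite(lam) || lam < 0 || lam >= R0) {
    rlang::abort("lam must lie in [0, R0): the artery is never fully occluded")
  }
  out <- tibble::tibble(R0 = R0, L0 = L0, lam = lam, eps = lam / R0)
  class(out) <- c("stenosis_geometry", class(out))
  out
}

#' Dimensional radius profile R(x)
#'
#' Cosine-constricted radius: inside (-L0/4, L0/4),
#' \eqn{R(x) = R_0 - (\lambda/2)(1 + \cos(4\pi x / L_0))}; R0 elsewhere.
#' The two branches agree at x = ±L0/4 (cos = -1), so the profile is
#' continuous with a continuous first derivative.
#'
#' @param x axial position(s), same length units as the geometry.
#' @param geom a [stenosis_geometry()].
#' @return radius at `x` (vectorised).
#' @export
radius_profile <- function(x, geom = stenosis_geometry()) {
  stopifnot(inherits(geom, "stenosis_geometry"))
  inside <- x > -geom$L0 / 4 & x < geom$L0 / 4
  r <- rep(geom$R0, length(x))
  r[inside] <- geom$R0 -
    (geom$lam / 2) * (1 + cos(4 * pi * x[inside] / geom$L0))
  r
}

#' Dimensionless radius profile f(x~)
#'
#' Radius scaled by R0 against the axial coordinate scaled by L0:
#' \eqn{f(\tilde x) = 1 - (\epsilon/2)(1 + \cos(4\pi\tilde x))} for
#' \eqn{|\tilde x| < 1/4}, and 1 otherwise. `f` ranges over \[1 - eps, 1\]
#' with its minimum only at the throat \eqn{\tilde x = 0}. The edge value
#' `f` also sets the default outer boundary of the similarity domain at an
#' axial station (see [similarity_params()]).
#'
#' @param x_tilde dimensionless axial position(s).
#' @param eps stenosis severity in \[0, 1).
#' @return f at `x_tilde` (vectorised).
#' @examples
#' dimensionless_profile(c(-0.5, 0, 0.125, 0.25), eps = 0.4)
#' @export
dimensionless_profile <- function(x_tilde, eps = 0.5) {
  check_fraction(eps, arg = "eps")
  inside <- x_tilde > -0.25 & x_tilde < 0.25
  f <- rep(1, length(x_tilde))
  f[inside] <- 1 - (eps / 2) * (1 + cos(4 * pi * x_tilde[inside]))
  f
}

#' Sampled stenosis shape table
#'
#' @param eps severity in \[0, 1).
#' @param n number of sample points (>= 2).
#' @param range axial range (length-2), default covers one vessel length.
#' @return tibble with columns `x_tilde`, `f`.
#' @export
geometry_table <- function(eps = 0.5, n = 201, range = c(-0.5, 0.5)) {
  stopifnot(n >= 2, length(range) == 2, range[1] < range[2])
  x <- seq(range[1], range[2], length.out = n)
  tibble::tibble(x_tilde = x, f = dimensionless_profile(x, eps))
}
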