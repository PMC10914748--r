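#' Tidy a solved similarity profile
#'
#' Returns the solution grid as a tibble, one row per mesh point.
#'
#' @param x an `hnf_profile`.
#' @param ... unused.
#' @return tibble with columns `eta`, `F`, `Fp`, `Fpp`, `theta`, `thetap`.
#' @method tidy hnf_profile
#' @export
tidy.hnf_profile <- function(x, ...) {
  x$profile
}

#' One-row summary of a solved similarity profile
#'
#' @param x an `hnf_profile`.
#' @param ... unused.
#' @return one-row tibble: the governing parameters, the wall derivatives
#'   `Fpp0` and `thetap0`, the scaled wall groups `cf_scaled` and
#'   `nu_scaled`, and solver diagnostics (`max_defect`, `n_nodes`,
#'   `converged`, `method`).
#' @method glance hnf_profile
#' @export
glance.hnf_profile <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      gamma = x$params$gamma, pr = x$params$pr,
      phi1 = x$params$phi1, phi2 = x$params$phi2,
      eta_edge = x$params$eta_edge, closure = x$params$closure
    ),
    wall_quantities(x),
    tibble::tibble(
      max_defect = x$diagnostics$max_defect,
      n_nodes = x$diagnostics$n_nodes,
      converged = x$diagnostics$converged,
      method = x$diagnostics$method
    )
  )
}
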