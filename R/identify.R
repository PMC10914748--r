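#' Identify the unstated inputs behind a published table
#'
#' The published wall-quantity tables state some inputs per row (gamma
#' and Pr for the Nusselt table; gamma and phi for the skin-friction
#' table) but omit the rest. This utility searches a candidate grid of
#' the omitted inputs exhaustively, re-solving the boundary-value problem
#' for every printed row under every candidate, and returns the
#' assignment minimising the maximum absolute deviation from the printed
#' values, together with the full misfit table for transparency.
#'
#' Ties are broken deterministically: the first candidate in grid order
#' wins and the tie is reported.
#'
#' @param printed tibble of printed rows: per-row stated parameter
#'   columns (any of `gamma`, `pr`, `phi`, `phi1`, `phi2`, `eta_edge`)
#'   plus a `value` column. A `phi` column is expanded to
#'   `phi1 = phi2 = phi`.
#' @param candidates tibble whose columns are the omitted parameters
#'   (same names) and whose rows form the candidate grid; must be
#'   non-empty.
#' @param quantity `"nusselt"` or `"skin_friction"`: which wall group the
#'   printed values are.
#' @param closure,opts passed to the solver.
#' @return list with `best` (one-row tibble: the arg-min candidate and
#'   its `misfit`), `misfits` (all candidates with their misfit, in grid
#'   order), and `tie` (TRUE if another candidate attains the same
#'   minimum).
#' @export
identify_unstated_params <- function(printed, candidates,
                                     quantity = c("nusselt", "skin_friction"),
                                     closure = "stretching-wall",
                                     opts = solver_options()) {
  quantity <- match.arg(quantity)
  candidates <- tibble::as_tibble(candidates)
  printed <- tibble::as_tibble(printed)
  if (nrow(candidates) == 0 || ncol(candidates) == 0) {
    rlang::abort("candidate grid must be non-empty")
  }
  if (!"value" %in% names(printed) || nrow(printed) == 0) {
    rlang::abort("printed rows must be non-empty with a 'value' column")
  }
  overlap <- intersect(names(candidates), setdiff(names(printed), "value"))
  if (length(overlap)) {
    rlang::abort(paste0("parameters both stated and searched: ",
                        paste(overlap, collapse = ", ")))
  }

  fn <- if (quantity == "nusselt") nusselt else skin_friction
  ## duplicate printed rows and candidates that differ only in parameters
  ## the quantity does not depend on are common; cache solves per
  ## parameter tuple for the duration of the call
  cache <- new.env(parent = emptyenv())
  solve_cached <- function(params) {
    ## the momentum block decouples from Pr, so skin friction is cached
    ## across Prandtl candidates
    key <- paste(params$gamma,
                 if (quantity == "nusselt") params$pr else "-",
                 params$phi1, params$phi2,
                 params$eta_edge, params$closure, sep = "|")
    if (is.null(cache[[key]])) {
      cache[[key]] <- fn(solve_profile(params, opts))
    }
    cache[[key]]
  }
  expand_phi <- function(df) {
    if ("phi" %in% names(df)) {
      df$phi1 <- df$phi
      df$phi2 <- df$phi
      df$phi <- NULL
    }
    df
  }

  misfit_of <- function(cand_row) {
    devs <- purrr::map_dbl(seq_len(nrow(printed)), function(i) {
      row <- expand_phi(c(as.list(printed[i, setdiff(names(printed), "value")]),
                          as.list(cand_row)))
      params <- similarity_params(
        gamma = row$gamma %||% 0.1, pr = row$pr %||% 3,
        phi1 = row$phi1 %||% 0.05, phi2 = row$phi2 %||% 0.05,
        eta_edge = row$eta_edge %||% 1, closure = closure
      )
      tryCatch(solve_cached(params) - printed$value[i],
               error = function(e) Inf)
    })
    max(abs(devs))
  }

  misfits <- purrr::map_dbl(seq_len(nrow(candidates)),
                            function(j) misfit_of(as.list(candidates[j, ])))
  best_idx <- which.min(misfits)
  tie <- sum(misfits == misfits[best_idx]) > 1
  if (tie) {
    rlang::warn("identify_unstated_params: tie for the best candidate; first in grid order returned")
  }
  list(
    best = dplyr::bind_cols(candidates[best_idx, ],
                            tibble::tibble(misfit = misfits[best_idx])),
    misfits = dplyr::bind_cols(candidates,
                               tibble::tibble(misfit = misfits)),
    tie = tie
  )
}
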