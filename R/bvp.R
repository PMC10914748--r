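#' Solver options for the collocation BVP solver
#'
#' @param tol maximum permitted scaled collocation defect on any
#'   subinterval (> 0). The defect of the piecewise interpolant is sampled
#'   at the quarter points of every mesh interval and scaled by
#'   `1 + |y'|`; intervals exceeding `tol` are subdivided.
#' @param initial_mesh_size number of mesh intervals to start from (>= 4).
#' @param max_nodes hard cap on mesh points; exceeding it is an explicit
#'   failure, never a silent partial answer.
#' @param max_newton maximum damped-Newton iterations per mesh.
#' @param max_refine maximum mesh-refinement rounds.
#' @return a list of class `solver_options`.
#' @export
solver_options <- function(tol = 1e-8, initial_mesh_size = 50,
                           max_nodes = 2000, max_newton = 25,
                           max_refine = 12) {
  if (!is.finite(tol) || tol <= 0) rlang::abort("tol must be > 0")
  if (initial_mesh_size < 4) rlang::abort("initial_mesh_size must be >= 4")
  if (max_nodes <= initial_mesh_size) {
    rlang::abort("max_nodes must exceed initial_mesh_size")
  }
  structure(
    list(tol = tol, initial_mesh_size = initial_mesh_size,
         max_nodes = max_nodes, max_newton = max_newton,
         max_refine = max_refine),
    class = "solver_options"
  )
}

## deterministic polynomial initial guess satisfying the active wall BCs:
## F'(eta) = (1 - eta/e)^2 for the moving-wall closures (unit wall slope,
## zero slope/shear at the edge), theta = (1 - eta/e)^2; identically zero
## flow and unit temperature for the paper-literal closure.
initial_guess <- function(eta, params) {
  e <- params$eta_edge
  if (params$closure == "paper-literal") {
    rbind(F = 0 * eta, Fp = 0 * eta, Fpp = 0 * eta,
          theta = 1 + 0 * eta, thetap = 0 * eta)
  } else {
    g <- 1 - eta / e
    rbind(F = eta - eta^2 / e + eta^3 / (3 * e^2),
          Fp = g^2, Fpp = -2 * g / e,
          theta = g^2, thetap = -2 * g / e)
  }
}

## three-point Lobatto IIIA (Simpson) collocation residual on the mesh:
## 5 boundary rows then 5 rows per interval.
colloc_residual <- function(eta, Y, rhs, bcl, bcr) {
  n <- length(eta)
  h <- diff(eta)
  f_all <- rhs(eta, Y)
  Yi <- Y[, -n, drop = FALSE]
  Yi1 <- Y[, -1, drop = FALSE]
  fi <- f_all[, -n, drop = FALSE]
  fi1 <- f_all[, -1, drop = FALSE]
  Ymid <- (Yi + Yi1) / 2 + sweep(fi - fi1, 2, h / 8, `*`)
  fmid <- rhs((eta[-n] + eta[-1]) / 2, Ymid)
  res <- Yi1 - Yi - sweep(fi + 4 * fmid + fi1, 2, h / 6, `*`)
  c(bcl(Y[, 1]), bcr(Y[, n]), as.vector(res))
}

## finite-difference Jacobian assembled sparsely with a 2-colour scheme:
## every residual row depends on at most one node of each parity, so ten
## perturbed residual evaluations (2 parities x 5 components) recover the
## full block-bidiagonal structure.
colloc_jacobian <- function(eta, Y, res0, resfun) {
  n <- length(eta)
  m <- 5 * n
  u <- as.vector(Y)
  int_idx <- seq_len(n - 1)
  ti <- tj <- tx <- vector("list", 10)
  slot <- 0
  for (p in 0:1) {
    nodes <- which(seq_len(n) %% 2 == p)
    int_node <- ifelse(int_idx %% 2 == p, int_idx, int_idx + 1)
    row_node <- c(if (1 %% 2 == p) rep(1, 3) else rep(NA, 3),
                  if (n %% 2 == p) rep(n, 2) else rep(NA, 2),
                  rep(int_node, each = 5))
    rows <- which(!is.na(row_node))
    rnode <- row_node[rows]
    for (comp in 1:5) {
      idx <- 5 * (nodes - 1) + comp
      delta <- 1e-7 * (1 + abs(u[idx]))
      up <- u
      up[idx] <- up[idx] + delta
      dres <- resfun(matrix(up, nrow = 5)) - res0
      dmap <- numeric(n)
      dmap[nodes] <- delta
      slot <- slot + 1
      ti[[slot]] <- rows
      tj[[slot]] <- 5 * (rnode - 1) + comp
      tx[[slot]] <- dres[rows] / dmap[rnode]
    }
  }
  Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                       dims = c(m, m))
}

newton_colloc <- function(eta, Y, rhs, bcl, bcr, max_newton, rtol = 1e-11) {
  resfun <- function(Ym) colloc_residual(eta, Ym, rhs, bcl, bcr)
  res0 <- resfun(Y)
  nr0 <- max(abs(res0))
  iter <- 0
  while (nr0 >= rtol && iter < max_newton) {
    J <- colloc_jacobian(eta, Y, res0, resfun)
    du <- tryCatch(as.numeric(Matrix::solve(J, res0)),
                   error = function(e) NULL)
    if (is.null(du) || any(!is.finite(du))) {
      return(list(Y = Y, res = nr0, converged = FALSE, iter = iter))
    }
    lam <- 1
    repeat {
      Ynew <- matrix(as.vector(Y) - lam * du, nrow = 5)
      resn <- resfun(Ynew)
      nrn <- max(abs(resn))
      if ((is.finite(nrn) && nrn < nr0) || lam < 1 / 64) break
      lam <- lam / 2
    }
    if (!is.finite(nrn) || nrn >= nr0) {
      return(list(Y = Y, res = nr0, converged = FALSE, iter = iter))
    }
    Y <- Ynew
    res0 <- resn
    nr0 <- nrn
    iter <- iter + 1
  }
  list(Y = Y, res = nr0, converged = nr0 < rtol, iter = iter)
}

## scaled defect of the cubic Hermite interpolant, sampled at the quarter
## points of each interval (the midpoint defect vanishes identically for
## the Simpson scheme, so it carries no information).
colloc_defect <- function(eta, Y, rhs) {
  n <- length(eta)
  h <- diff(eta)
  f_all <- rhs(eta, Y)
  Yi <- Y[, -n, drop = FALSE]
  Yi1 <- Y[, -1, drop = FALSE]
  fi <- f_all[, -n, drop = FALSE]
  fi1 <- f_all[, -1, drop = FALSE]
  worst <- numeric(n - 1)
  for (tau in c(0.25, 0.75)) {
    h00 <- 2 * tau^3 - 3 * tau^2 + 1
    h10 <- tau^3 - 2 * tau^2 + tau
    h01 <- -2 * tau^3 + 3 * tau^2
    h11 <- tau^3 - tau^2
    d00 <- 6 * tau^2 - 6 * tau
    d10 <- 3 * tau^2 - 4 * tau + 1
    d01 <- -6 * tau^2 + 6 * tau
    d11 <- 3 * tau^2 - 2 * tau
    S <- h00 * Yi + h01 * Yi1 +
      sweep(fi, 2, h * h10, `*`) + sweep(fi1, 2, h * h11, `*`)
    Sp <- sweep(d00 * Yi + d01 * Yi1, 2, h, `/`) +
      d10 * fi + d11 * fi1
    ft <- rhs(eta[-n] + tau * h, S)
    scaled <- abs(Sp - ft) / (1 + abs(ft))
    worst <- pmax(worst, apply(scaled, 2, max))
  }
  worst
}

## insert midpoints into flagged intervals, carrying the solution over via
## the same cubic Hermite interpolant used for the defect estimate.
refine_mesh <- function(eta, Y, rhs, flagged) {
  n <- length(eta)
  f_all <- rhs(eta, Y)
  new_eta <- list()
  new_Y <- list()
  for (i in seq_len(n - 1)) {
    new_eta[[length(new_eta) + 1]] <- eta[i]
    new_Y[[length(new_Y) + 1]] <- Y[, i]
    if (flagged[i]) {
      h <- eta[i + 1] - eta[i]
      tau <- 0.5
      h00 <- 2 * tau^3 - 3 * tau^2 + 1
      h10 <- tau^3 - 2 * tau^2 + tau
      h01 <- -2 * tau^3 + 3 * tau^2
      h11 <- tau^3 - tau^2
      ymid <- h00 * Y[, i] + h01 * Y[, i + 1] +
        h * h10 * f_all[, i] + h * h11 * f_all[, i + 1]
      new_eta[[length(new_eta) + 1]] <- eta[i] + h / 2
      new_Y[[length(new_Y) + 1]] <- ymid
    }
  }
  new_eta[[length(new_eta) + 1]] <- eta[n]
  new_Y[[length(new_Y) + 1]] <- Y[, n]
  list(eta = unlist(new_eta), Y = do.call(cbind, new_Y))
}

#' Solve the similarity boundary-value problem
#'
#' Solves the coupled momentum/energy two-point boundary-value problem on
#' \[0, eta_edge\] by fourth-order collocation: the three-point Lobatto IIIA
#' (Simpson) scheme on an adaptively refined mesh, with a damped Newton
#' iteration on the collocation equations and a sparse finite-difference
#' Jacobian. This is the same scheme class as MATLAB's `bvp4c`,
#' implemented here from scratch. The solve is fully deterministic: the
#' initial guess is a fixed polynomial satisfying the active wall boundary
#' conditions and no randomness enters anywhere.
#'
#' @param params a [similarity_params()].
#' @param opts a [solver_options()].
#' @return an object of class `hnf_profile`: a list with
#'   \describe{
#'     \item{profile}{tibble with columns `eta`, `F`, `Fp`, `Fpp`,
#'       `theta`, `thetap` on the final mesh;}
#'     \item{params, mixture}{the inputs that produced it;}
#'     \item{diagnostics}{list with `max_defect`, `newton_residual`,
#'       `n_nodes`, `refinements`, `converged`, `method`.}
#'   }
#'   Wall derivatives are read off with [glance()] or [wall_quantities()].
#' @examples
#' prof <- solve_profile(similarity_params(gamma = 0.1, pr = 3))
#' glance(prof)
#' @export
solve_profile <- function(params, opts = solver_options()) {
  stopifnot(inherits(params, "similarity_params"))
  stopifnot(inherits(opts, "solver_options"))
  rhs <- as_first_order_system(params)
  bcl <- closure_bc_left(params$closure)
  bcr <- closure_bc_right(params$closure)

  eta <- seq(0, params$eta_edge, length.out = opts$initial_mesh_size + 1)
  Y <- initial_guess(eta, params)
  refinements <- 0
  repeat {
    nwt <- newton_colloc(eta, Y, rhs, bcl, bcr, opts$max_newton)
    if (!nwt$converged) {
      bvp_failure("Newton iteration failed to converge", eta, nwt,
                  refinements)
    }
    Y <- nwt$Y
    defect <- colloc_defect(eta, Y, rhs)
    if (max(defect) <= opts$tol) break
    if (refinements >= opts$max_refine) {
      bvp_failure("defect tolerance not reached within max_refine rounds",
                  eta, nwt, refinements, max(defect))
    }
    flagged <- defect > opts$tol
    if (length(eta) + sum(flagged) > opts$max_nodes) {
      bvp_failure("mesh refinement exceeded max_nodes", eta, nwt,
                  refinements, max(defect))
    }
    ref <- refine_mesh(eta, Y, rhs, flagged)
    eta <- ref$eta
    Y <- ref$Y
    refinements <- refinements + 1
  }

  profile <- tibble::tibble(
    eta = eta, F = Y[1, ], Fp = Y[2, ], Fpp = Y[3, ],
    theta = Y[4, ], thetap = Y[5, ]
  )
  structure(
    list(profile = profile, params = params, mixture = params$mixture,
         diagnostics = list(max_defect = max(defect),
                            newton_residual = nwt$res,
                            n_nodes = length(eta),
                            refinements = refinements,
                            converged = TRUE,
                            method = "collocation")),
    class = "hnf_profile"
  )
}

bvp_failure <- function(msg, eta, nwt, refinements, defect = NA_real_) {
  rlang::abort(
    message = paste0(
      "BVP solve failed: ", msg,
      sprintf(" [nodes = %d, refinements = %d, newton residual = %.3e",
              length(eta), refinements, nwt$res),
      if (is.finite(defect)) sprintf(", max defect = %.3e]", defect) else "]"
    ),
    class = "stenoflow_bvp_failure",
    n_nodes = length(eta), refinements = refinements,
    newton_residual = nwt$res, max_defect = defect
  )
}

#' @export
print.hnf_profile <- function(x, ...) {
  d <- x$diagnostics
  cat("<hnf_profile> ", d$method, " solve, ", d$n_nodes, " nodes\n", sep = "")
  cat(sprintf("  gamma = %g, Pr = %g, phi1 = %g, phi2 = %g, eta_edge = %g (%s)\n",
              x$params$gamma, x$params$pr, x$params$phi1, x$params$phi2,
              x$params$eta_edge, x$params$closure))
  cat(sprintf("  F''(0) = %.6f, theta'(0) = %.6f, max defect = %.2e\n",
              x$profile$Fpp[1], x$profile$thetap[1], d$max_defect))
  invisible(x)
}

#' Classical stretching-surface reference state
#'
#' Closed-form boundary-layer profile \eqn{F = 1 - e^{-\eta}} of the flat
#' stretching surface, which solves the momentum equation exactly in the
#' zero-curvature, particle-free limit with far-field decay, together with
#' the matching exponential temperature profile. Used as the analytic
#' oracle for the numerical solver.
#'
#' @param eta nonnegative similarity coordinate(s).
#' @return tibble with columns `eta`, `F`, `Fp`, `Fpp`, `Fppp`, `theta`,
#'   `thetap`.
#' @export
crane_reference <- function(eta) {
  if (any(eta < 0)) rlang::abort("eta must be >= 0")
  e <- exp(-eta)
  tibble::tibble(eta = eta, F = 1 - e, Fp = e, Fpp = -e, Fppp = e,
                 theta = e, thetap = -e)
}

#' Solver self-consistency under tolerance tightening
#'
#' Re-solves one configuration at a sequence of decreasing defect
#' tolerances and reports the wall derivatives at each level together with
#' the successive differences, which must shrink for a convergent scheme.
#'
#' @param params a [similarity_params()].
#' @param opts base [solver_options()]; each level overrides `tol`.
#' @param tolerances decreasing vector of defect tolerances (>= 2 values).
#' @return tibble with columns `tol`, `Fpp0`, `thetap0`, `n_nodes`,
#'   `dFpp0`, `dthetap0` (absolute successive differences, NA on the first
#'   row) and a `monotone` attribute; a warning is issued if the
#'   differences fail to decrease.
#' @export
convergence_study <- function(params, opts = solver_options(),
                              tolerances = 10^-(4:8)) {
  if (length(tolerances) < 2) {
    rlang::abort("convergence_study needs at least 2 tolerance levels")
  }
  rows <- purrr::map(tolerances, function(tl) {
    o <- opts
    o$tol <- tl
    prof <- solve_profile(params, o)
    tibble::tibble(tol = tl, Fpp0 = prof$profile$Fpp[1],
                   thetap0 = prof$profile$thetap[1],
                   n_nodes = prof$diagnostics$n_nodes)
  })
  out <- dplyr::bind_rows(rows)
  out$dFpp0 <- c(NA, abs(diff(out$Fpp0)))
  out$dthetap0 <- c(NA, abs(diff(out$thetap0)))
  dd <- out$dFpp0[-1]
  monotone <- all(diff(dd[dd > 0]) <= 0) || all(dd < 10 * min(tolerances))
  if (!monotone) {
    rlang::warn("convergence_study: successive differences are not monotone")
  }
  attr(out, "monotone") <- monotone
  out
}
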