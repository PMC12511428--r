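#' Solve the box model to steady state
#'
#' Integrates the three-box model with a stiff ODE solver
#' ([deSolve::lsoda()]) over geometrically growing time chunks until the
#' residual (the largest tracer tendency, expressed as a flux in mol/s
#' and compared against the characteristic gross flux of the final state)
#' falls below `tol`, or `t_max` model seconds have elapsed.
#' Non-convergence is reported through the `converged` flag, never as an
#' error.
#'
#' @param params An [nbox_params()] object.
#' @param init Optional initial state tibble; defaults to [nbox_init()].
#' @param tol Relative residual tolerance: converged when
#'   `max |dC/dt| * V / F_char <= tol` with `F_char` the largest gross
#'   flux (transport or biological) of the final state.
#' @param t_max Maximum integrated model time (s).
#' @param rtol,atol Integrator tolerances passed to [deSolve::lsoda()].
#' @param use_newton Attempt a damped-Newton polish of the steady state
#'   once time integration has brought the residual reasonably close;
#'   this is an exact root-find on the tendency system (with the total-P
#'   constraint replacing one redundant equation in the closed setup) and
#'   typically cuts solve times by an order of magnitude. Set `FALSE` to
#'   integrate all the way down to `tol`.
#' @return An object of class `"nbox_steady"`: a list with the final
#'   `state` tibble, a `result` tibble holding the steady-state summary
#'   (export fluxes, per-box delta-15N, OMZ oxygen, nitrogen budget
#'   fluxes, convergence diagnostics) and the `params` used. Where the
#'   nitrogen pool has collapsed, delta-15N entries are `NA` (undefined),
#'   never NaN.
#' @examples
#' \donttest{
#' fit <- solve_steady_state(nbox_params(U = 0.1))
#' glance(fit)
#' }
#' @export
solve_steady_state <- function(params, init = NULL, tol = 1e-10,
                               t_max = 1e17, rtol = 1e-10, atol = 1e-14,
                               use_newton = TRUE) {
  validate_nbox_params(params)
  if (tol <= 0) abort("`tol` must be positive")
  state <- init %||% nbox_init(params)
  check_state(state)
  y <- state_to_vec(state)

  deriv_fun <- function(t, y, parms) list(nbox_rhs(y, parms)$d)

  elapsed <- 0
  dt <- 1e10
  res <- residual_info(y, params)
  while (res$residual > tol && elapsed < t_max) {
    if (use_newton) {
      pol <- newton_polish(y, params, tol)
      if (!is.null(pol)) {
        y <- pol
        res <- residual_info(y, params)
        if (res$residual <= tol) break
      }
    }
    dt <- min(dt, t_max - elapsed)
    sol <- suppressWarnings(
      deSolve::lsoda(y = y, times = c(0, dt), func = deriv_fun,
                     parms = params, rtol = rtol, atol = atol,
                     maxsteps = 20000)
    )
    y <- pmax(sol[nrow(sol), -1], 0)  # clip integrator noise at zero
    elapsed <- min(elapsed + dt, t_max)
    dt <- dt * 30
    res <- residual_info(y, params)
  }

  build_steady(y, params, converged = res$residual <= tol,
               residual = res$residual, t_elapsed = elapsed)
}

## flux-scale tendency system whose root is the steady state; in the
## closed setup the redundant deep-P equation (conservation makes it a
## linear combination of the others) is replaced by the inventory
## constraint, which also removes the neutral direction from the
## Jacobian.
steady_system <- function(y, params) {
  d <- nbox_rhs(y, params)$d
  V <- c(params$V_surf, params$V_omz, params$V_rest,
         params$V_surf, params$V_surf, params$V_omz, params$V_omz,
         params$V_rest, params$V_rest, params$V_omz, params$V_rest)
  G <- unname(d * V)
  if (params$closed_P) {
    G[3] <- sum(y[1:3] * c(params$V_surf, params$V_omz, params$V_rest)) -
      params$P_inventory
  }
  G
}

newton_polish <- function(y, params, tol, max_iter = 40) {
  n <- length(y)
  floors <- c(rep(1e-7, 9), 1e-5, 1e-5)
  yk <- y
  Fk <- steady_system(yk, params)
  mk <- sum(Fk^2)
  for (k in seq_len(max_iter)) {
    h <- pmax(abs(yk) * 1e-7, floors * 1e-7)
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      yp <- yk; yp[j] <- yk[j] + h[j]
      ym <- yk; ym[j] <- max(yk[j] - h[j], 0)
      J[, j] <- (steady_system(yp, params) - steady_system(ym, params)) /
        (yp[j] - ym[j])
    }
    step <- tryCatch(solve(J, -Fk), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    damp <- 1
    repeat {
      y_try <- yk + damp * step
      if (all(y_try > -1e-12)) {
        y_try <- pmax(y_try, 0)
        F_try <- steady_system(y_try, params)
        if (all(is.finite(F_try)) && sum(F_try^2) < mk) break
      }
      damp <- damp / 2
      if (damp < 1e-4) return(NULL)
    }
    yk <- y_try
    Fk <- F_try
    mk <- sum(Fk^2)
    if (residual_info(yk, params)$residual <= 0.1 * tol) {
      if (is_attracting(yk, params)) return(yk)
      return(NULL)  # genuine root, but not the attracting state
    }
  }
  NULL
}

## local stability of a steady state: all eigenvalues of the dynamics
## Jacobian must have non-positive real part (the closed-P conservation
## mode sits at zero within numerical noise)
is_attracting <- function(y, params, eps_pos = 1e-16) {
  n <- length(y)
  floors <- c(rep(1e-7, 9), 1e-5, 1e-5)
  h <- pmax(abs(y) * 1e-7, floors * 1e-7)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    yp <- y; yp[j] <- y[j] + h[j]
    ym <- y; ym[j] <- max(y[j] - h[j], 0)
    J[, j] <- (nbox_rhs(yp, params)$d - nbox_rhs(ym, params)$d) /
      (yp[j] - ym[j])
  }
  ev <- eigen(J, only.values = TRUE)$values
  max(Re(ev)) <= eps_pos
}

## residual: largest |tendency| as a flux (mol/s), relative to the
## characteristic gross flux of the current state
residual_info <- function(y, params) {
  r <- nbox_rhs(y, params)
  V <- c(params$V_surf, params$V_omz, params$V_rest,
         params$V_surf, params$V_surf, params$V_omz, params$V_omz,
         params$V_rest, params$V_rest, params$V_omz, params$V_rest)
  flux_resid <- max(abs(r$d) * V)
  f <- r$fluxes
  tot <- params$U + params$U_base + params$mix_surf_omz + params$mix_omz_rest
  F_char <- max(f$export_N, f$f_fix, f$f_denit_wc,
                tot * (y[["N14_r"]] + y[["N15_r"]]),
                tot * y[["P_r"]] * params$rNP_uptake,
                tot * params$O2_surf, 1e-12)
  list(residual = flux_resid / F_char, flux_residual = flux_resid, F_char = F_char)
}

build_steady <- function(y, params, converged, residual, t_elapsed) {
  state <- vec_to_state(y, params)
  f <- nbox_rhs(y, params)$fluxes

  n_floor <- 1e-15
  d15 <- function(N15, N14) if (N14 > n_floor) delta15N_from_ratio(N15, N14) else NA_real_
  d15N_surface <- d15(y[["N15_s"]], y[["N14_s"]])
  d15N_omz <- d15(y[["N15_m"]], y[["N14_m"]])
  d15N_deep <- d15(y[["N15_r"]], y[["N14_r"]])
  d15N_export <- if (is.na(d15N_surface)) NA_real_ else d15N_surface - params$eps_assim

  result <- tibble(
    export_P = f$export_P,
    export_N = f$export_N,
    d15N_deep = d15N_deep,
    d15N_omz = d15N_omz,
    d15N_surface = d15N_surface,
    d15N_export = d15N_export,
    O2_omz = y[["O2_m"]],
    f_denit_wc = f$f_denit_wc,
    f_denit_sed = f$f_denit_sed,
    f_fix = f$f_fix,
    f_burial_N = f$f_burial_N,
    f_burial_P = f$f_burial_P,
    converged = converged,
    residual = residual
  )
  structure(
    list(state = state, result = result, params = params,
         fluxes = f, t_elapsed = t_elapsed),
    class = "nbox_steady"
  )
}

#' @export
print.nbox_steady <- function(x, ...) {
  r <- x$result
  cat("<nbox_steady>",
      if (x$params$closed_P) "closed-P" else "open-P",
      "setup, U =", x$params$U / 1e6, "Sv\n")
  cat(sprintf("  converged: %s (residual %.3g)\n", r$converged, r$residual))
  cat(sprintf("  export: %.4g mol P/s;  O2_omz: %.4g mol/m3\n", r$export_P, r$O2_omz))
  cat(sprintf("  d15N deep/OMZ/surface: %.3g / %.3g / %.3g permil\n",
              r$d15N_deep, r$d15N_omz, r$d15N_surface))
  invisible(x)
}

#' Tidy and glance methods for steady-state fits
#'
#' `tidy()` returns the steady-state quantities in long form (one row per
#' quantity with its unit); `glance()` returns the one-row summary table
#' of the fit, which is also the row format used by the sweep functions.
#'
#' @param x An `"nbox_steady"` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.nbox_steady <- function(x, ...) {
  r <- x$result
  tibble(
    quantity = names(r),
    value = as.numeric(r[1, ]),
    unit = c("mol P/s", "mol N/s", rep("permil", 4), "mol/m3",
             rep("mol N/s", 3), "mol N/s", "mol P/s", "", "relative")
  )
}

#' @rdname tidy.nbox_steady
#' @export
glance.nbox_steady <- function(x, ...) {
  x$result
}

#' Total tracer inventories of a state
#'
#' Volume-weighted totals (mol) of P, N14, N15 and total N over the three
#' boxes; used by the conservation checks.
#'
#' @param state State tibble.
#' @param params An [nbox_params()] object.
#' @return A one-row tibble with columns `P`, `N14`, `N15`, `N`.
#' @export
nbox_inventory <- function(state, params) {
  check_state(state)
  V <- setNames(c(params$V_surf, params$V_omz, params$V_rest),
                c("surface", "omz", "rest"))[state$box]
  tibble(
    P = sum(state$P * V),
    N14 = sum(state$N14 * V),
    N15 = sum(state$N15 * V),
    N = sum((state$N14 + state$N15) * V)
  )
}

#' Integrate the box model along a trajectory
#'
#' Time integration of the full tracer system with the same stiff solver
#' used internally by [solve_steady_state()], returning the state at the
#' requested times. Used for conservation diagnostics and transient
#' experiments.
#'
#' @param params An [nbox_params()] object.
#' @param init Optional initial state tibble; defaults to [nbox_init()].
#' @param times Numeric vector of output times (s), starting at 0.
#' @param rtol,atol Integrator tolerances.
#' @return A tibble with one row per output time: `time` plus the state
#'   vector columns (`P_s`, `P_m`, `P_r`, `N14_s`, ..., `O2_r`).
#' @export
nbox_trajectory <- function(params, init = NULL, times,
                            rtol = 1e-10, atol = 1e-14) {
  validate_nbox_params(params)
  state <- init %||% nbox_init(params)
  check_state(state)
  y <- state_to_vec(state)
  sol <- suppressWarnings(
    deSolve::lsoda(y = y, times = times,
                   func = function(t, y, p) list(nbox_rhs(y, p)$d),
                   parms = params, rtol = rtol, atol = atol,
                   maxsteps = 200000)
  )
  out <- as_tibble(as.data.frame(sol))
  names(out)[1] <- "time"
  out
}
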