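#' Sweep the steady state over upwelling transport
#'
#' Solves one steady state per value of the upwelling transport, using
#' continuation (each converged state seeds the next) to stay on one
#' solution branch. The output table has the panel structure of the
#' model's upwelling experiments: export production and delta-15N in the
#' deep ocean and the OMZ as functions of transport, for either P setup.
#'
#' @param params An [nbox_params()] object; its `U` entry is overridden.
#' @param U_grid Non-negative, sorted upwelling transports in Sv.
#' @param ... Passed on to [solve_steady_state()].
#' @return A tibble with class `"nbox_sweep"`: one row per transport with
#'   column `U_Sv` followed by the steady-state summary columns.
#'   Non-converged points are flagged in `converged`; the sweep continues
#'   past them.
#' @examples
#' \donttest{
#' sw <- sweep_upwelling(nbox_params(closed_P = TRUE), c(0.05, 0.15, 0.25))
#' autoplot(sw)
#' }
#' @export
sweep_upwelling <- function(params, U_grid = seq(0, 0.25, by = 0.025), ...) {
  if (any(U_grid < 0)) abort("`U_grid` must be non-negative")
  if (is.unsorted(U_grid)) abort("`U_grid` must be sorted increasing")
  rows <- vector("list", length(U_grid))
  init <- NULL
  for (i in seq_along(U_grid)) {
    p_i <- params
    p_i$U <- U_grid[i] * 1e6
    fit <- solve_steady_state(p_i, init = init, ...)
    if (fit$result$converged) init <- fit$state
    rows[[i]] <- mutate(glance(fit), U_Sv = U_grid[i], .before = 1)
  }
  out <- bind_rows(rows)
  class(out) <- c("nbox_sweep", class(out))
  attr(out, "sweep_var") <- "U_Sv"
  attr(out, "setup") <- if (params$closed_P) "closed" else "open"
  out
}

#' Sweep the steady state over the phosphorus axis
#'
#' For the closed setup (`mode = "inventory"`) the total P inventory is
#' varied at fixed upwelling; export production first rises with P
#' availability and then falls under N limitation, giving an interior
#' maximum which this function locates (grid argmax refined by a local
#' quadratic fit). For the open setup (`mode = "input"`) the weathering
#' input `W` is varied; export is expected to be nearly independent of
#' the input because it is compensated by burial.
#'
#' @param params An [nbox_params()] object with the matching setup flag.
#' @param grid Inventory values in Pmol (`mode = "inventory"`) or P
#'   inputs in mol/s (`mode = "input"`).
#' @param mode `"inventory"` (closed setup) or `"input"` (open setup).
#' @param ... Passed on to [solve_steady_state()].
#' @return A tibble with class `"nbox_sweep"`; first column
#'   `P_inventory_Pmol` or `W_mol_s`. For `mode = "inventory"` the
#'   attribute `"export_max"` holds the refined location and value of the
#'   export maximum.
#' @export
sweep_P <- function(params, grid, mode = c("inventory", "input"), ...) {
  mode <- match.arg(mode)
  if (mode == "inventory" && !params$closed_P) {
    abort("mode = 'inventory' requires a closed-P parameter set")
  }
  if (mode == "input" && params$closed_P) {
    abort("mode = 'input' requires an open-P parameter set")
  }
  if (is.unsorted(grid)) abort("`grid` must be sorted increasing")

  rows <- vector("list", length(grid))
  init <- NULL
  for (i in seq_along(grid)) {
    p_i <- params
    if (mode == "inventory") {
      p_i$P_inventory <- grid[i] * 1e15
      if (!is.null(init)) {
        ## rescale carried-over P field to the new inventory
        inv <- nbox_inventory(init, p_i)$P
        init$P <- init$P * (p_i$P_inventory / inv)
      }
    } else {
      p_i$W <- grid[i]
    }
    fit <- solve_steady_state(p_i, init = init, ...)
    if (fit$result$converged) init <- fit$state
    lab <- if (mode == "inventory") "P_inventory_Pmol" else "W_mol_s"
    rows[[i]] <- mutate(glance(fit), "{lab}" := grid[i], .before = 1)
  }
  out <- bind_rows(rows)
  class(out) <- c("nbox_sweep", class(out))
  attr(out, "sweep_var") <- if (mode == "inventory") "P_inventory_Pmol" else "W_mol_s"
  attr(out, "setup") <- if (params$closed_P) "closed" else "open"
  if (mode == "inventory") {
    attr(out, "export_max") <- locate_max(grid, out$export_P)
  }
  out
}

## parabolic refinement of a grid argmax; falls back to the grid point at
## the edges
locate_max <- function(x, y) {
  ok <- is.finite(y)
  i <- which.max(replace(y, !ok, -Inf))
  if (i == 1 || i == length(x) || !all(ok[(i - 1):(i + 1)])) {
    return(list(x = x[i], y = y[i], interior = !(i %in% c(1, length(x)))))
  }
  x3 <- x[(i - 1):(i + 1)]; y3 <- y[(i - 1):(i + 1)]
  den <- (x3[1] - x3[2]) * (x3[1] - x3[3]) * (x3[2] - x3[3])
  a <- (x3[3] * (y3[2] - y3[1]) + x3[2] * (y3[1] - y3[3]) + x3[1] * (y3[3] - y3[2])) / den
  b <- (x3[3]^2 * (y3[1] - y3[2]) + x3[2]^2 * (y3[3] - y3[1]) + x3[1]^2 * (y3[2] - y3[3])) / den
  if (a >= 0) return(list(x = x[i], y = y[i], interior = TRUE))
  xv <- -b / (2 * a)
  list(x = xv, y = y[i], interior = TRUE)
}

#' Recover upwelling transport from noisy observations
#'
#' Grid-search fit of the upwelling transport to a table of observed
#' (export, deep delta-15N) pairs, such as those produced by
#' [make_boxmodel_observations()]. For each candidate transport the
#' steady state is solved (with continuation) and the sum of squared
#' standardized misfits of both observables is accumulated over the
#' observation rows; the transport minimizing the total misfit is
#' returned.
#'
#' @param obs Tibble with columns `export_P` and `d15N_deep`.
#' @param params An [nbox_params()] object describing the model under
#'   which the observations were generated (its `U` is ignored).
#' @param U_grid Candidate transports in Sv.
#' @param ... Passed on to [solve_steady_state()].
#' @return A list with `U_hat` (Sv), the objective `curve` tibble and the
#'   grid step.
#' @export
recover_upwelling <- function(obs, params, U_grid = seq(0.02, 0.25, by = 0.01), ...) {
  need <- c("export_P", "d15N_deep")
  miss <- setdiff(need, names(obs))
  if (length(miss) > 0) abort(paste0("`obs` is missing column(s): ", paste(miss, collapse = ", ")))
  sw <- sweep_upwelling(params, U_grid, ...)
  s_exp <- max(sd(obs$export_P), 1e-6 * mean(abs(obs$export_P)), 1e-12)
  s_d15 <- max(sd(obs$d15N_deep), 1e-3)
  sse <- vapply(seq_len(nrow(sw)), function(i) {
    sum(((obs$export_P - sw$export_P[i]) / s_exp)^2 +
          ((obs$d15N_deep - sw$d15N_deep[i]) / s_d15)^2)
  }, numeric(1))
  i <- which.min(sse)
  list(
    U_hat = U_grid[i],
    curve = tibble(U_Sv = U_grid, sse = sse),
    grid_step = if (length(U_grid) > 1) min(diff(U_grid)) else NA_real_
  )
}
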