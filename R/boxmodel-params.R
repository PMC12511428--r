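#' Parameters for the three-box N-P-O2 isotope model
#'
#' Builds the full parameter set of the three-box ocean model (surface box,
#' oxygen-minimum-zone box, rest-of-ocean box). Two phosphorus
#' configurations are supported: a *closed* setup in which the total ocean
#' P inventory is fixed and nothing is buried, representing deep-water
#' regions where exported P is completely remineralized; and an *open*
#' setup with a weathering input `W` balanced at steady state by burial,
#' representing shallow regions with significant burial of export
#' production.
#'
#' Transport is a single circulation loop rest -> OMZ -> surface -> rest at
#' volume transport `U`, plus weak background mixing exchanges
#' (surface-OMZ and OMZ-rest) that represent diffusive/eddy ventilation
#' and do not scale with the wind-driven upwelling.
#'
#' Nitrogen is carried as separate 14N and 15N pools so that mass balance
#' is exact; delta-15N is computed only for reporting. Water-column
#' denitrification engages where oxygen falls below `O2_thresh`
#' (fractionation `eps_wc`); sedimentary denitrification is a first-order,
#' non-fractionating sink on deep nitrate, present in both setups.
#' N2-fixation restores nitrogen in proportion to the surface N deficit
#' relative to Redfield demand.
#'
#' @param U Wind-driven upwelling transport in Sverdrup (1 Sv = 1e6
#'   m3/s); the quantity varied in the upwelling experiments.
#' @param U_base Background overturning transport (Sv) running through
#'   the same circulation loop regardless of the wind-driven upwelling;
#'   keeps the deep ocean connected to the OMZ and surface when `U = 0`.
#' @param closed_P Logical; `TRUE` for the closed-P setup (fixed
#'   inventory, no burial), `FALSE` for the open setup (weathering input
#'   `W`, burial output).
#' @param P_inventory Total ocean P in Pmol (1 Pmol = 1e15 mol); used only
#'   when `closed_P = TRUE`.
#' @param W Weathering input of P in mol/s; used only when
#'   `closed_P = FALSE`.
#' @param alpha Burial fraction (0-1): the fraction of exported organic P
#'   that is *not* remineralized either aerobically or through
#'   denitrification which is permanently buried; the unburied remainder
#'   returns to the deep box. Open setup only (the closed setup
#'   remineralizes everything).
#' @param rNP_uptake N:P ratio of primary production (Redfield, 16).
#' @param rNP_burial N:P ratio of buried organic matter.
#' @param rO2P Moles of O2 consumed per mole of P remineralized
#'   aerobically.
#' @param rNO3P Moles of nitrate consumed by denitrification per mole of P
#'   remineralized anaerobically.
#' @param O2_surf Surface oxygen concentration (mol/m3), set by solubility
#'   and held fixed.
#' @param O2_thresh Oxygen concentration below which denitrification
#'   engages (mol/m3). At or above the threshold the denitrification term
#'   is exactly zero.
#' @param o2_ramp_width Width (mol/m3) of the linear ramp *below*
#'   `O2_thresh` over which remineralization shifts from fully aerobic to
#'   fully denitrifying. A small positive width regularizes the hard
#'   switch so a partial-denitrification steady state exists; set it near
#'   zero for a strict step.
#' @param eps_assim Nitrate-assimilation fractionation (permil): exported
#'   N is instantaneously depleted by this amount relative to surface DIN.
#' @param eps_wc Water-column denitrification fractionation (permil).
#' @param eps_fix N2-fixation fractionation (permil); newly fixed N has
#'   delta-15N equal to this value.
#' @param V_surf,V_omz,V_rest Box volumes (m3).
#' @param k_up Surface uptake rate constant (1/s); fast relative to the
#'   circulation so the limiting nutrient is drawn down nearly completely.
#' @param k_fix N2-fixation rate constant (1/s); flux is
#'   `k_fix * max(0, rNP_uptake * P_surf - N_surf) * V_surf`.
#' @param remin_frac_omz Fraction of export whose remineralization demand
#'   falls in the OMZ box; the remainder reaches the deep box/seafloor.
#' @param benthic_eff Fraction of the organic flux reaching the deep
#'   seafloor that is degradable at all; the rest is refractory and joins
#'   the leftover (burial-candidate) stream regardless of oxygen. The
#'   default puts overall burial efficiency at a few percent of export,
#'   the canonical open-ocean value.
#' @param k_sed Rate constant (1/s) for sedimentary (benthic)
#'   denitrification, a first-order sink on deep-ocean nitrate.
#'   Pore-water nitrate consumption is near-complete, so no net isotopic
#'   fractionation is expressed.
#' @param k_scav Optional first-order rate constant (1/s) for authigenic
#'   (apatite-style) burial of dissolved P from the surface/shelf box
#'   (open setup only); default 0. A P sink decoupled from the organic
#'   export stream, exposed as a sensitivity variant.
#' @param mix_surf_omz,mix_omz_rest Background mixing exchanges (m3/s)
#'   between surface and OMZ, and OMZ and rest boxes.
#' @param vent_rest Ventilation exchange (Sv) between the rest-of-ocean
#'   box and the atmosphere. The rest box lumps the remaining surface and
#'   deep ocean, so its oxygen is relaxed toward solubility at this
#'   overturning-scale exchange; it acts on O2 only (nutrients cycled in
#'   the rest-of-ocean surface are re-exported locally and stay in the
#'   box).
#' @param K_N Nitrate half-saturation (mol/m3) of water-column
#'   denitrification; the canonical micromolar-scale value. Organic
#'   matter that neither oxygen nor nitrate can remineralize joins the
#'   leftover stream (burial candidate in the open setup).
#' @param burial_o2_dependent Logical; if `TRUE` the burial fraction
#'   scales with deep-box oxygen as
#'   `alpha * O2_rest / (O2_rest + K_burial_O2)` (P burial efficiency
#'   increasing with oxygenation), the sensitivity variant discussed for
#'   ocean-anoxic-event feedbacks.
#' @param K_burial_O2 Half-saturation (mol/m3) for the oxygen-dependent
#'   burial variant.
#'
#' @return A list with class `"nbox_params"`. Transports are stored in
#'   m3/s and the inventory in mol; the constructor accepts Sv and Pmol.
#' @examples
#' p <- nbox_params(U = 0.1, closed_P = TRUE, P_inventory = 2.42)
#' p$U          # 1e5 m3/s
#' @export
nbox_params <- function(U = 0.1,
                        U_base = 0.05,
                        closed_P = TRUE,
                        P_inventory = 2.42,
                        W = 2,
                        alpha = 0.25,
                        rNP_uptake = 16,
                        rNP_burial = 16,
                        rO2P = 150,
                        rNO3P = 104,
                        O2_surf = 0.22,
                        O2_thresh = 5e-3,
                        o2_ramp_width = 4e-3,
                        eps_assim = 5,
                        eps_wc = 25,
                        eps_fix = 0,
                        V_surf = 1e15,
                        V_omz = 1e16,
                        V_rest = 1.3e18,
                        k_up = 1e-6,
                        k_fix = 5e-11,
                        remin_frac_omz = 0.8,
                        benthic_eff = 0.84,
                        k_sed = 5e-14,
                        k_scav = 0,
                        mix_surf_omz = 0.01,
                        mix_omz_rest = 0.03,
                        vent_rest = 20,
                        K_N = 8e-3,
                        burial_o2_dependent = FALSE,
                        K_burial_O2 = 0.05) {
  p <- list(
    U = U * 1e6, U_base = U_base * 1e6, closed_P = isTRUE(closed_P),
    P_inventory = P_inventory * 1e15, W = W,
    alpha = alpha, rNP_uptake = rNP_uptake, rNP_burial = rNP_burial,
    rO2P = rO2P, rNO3P = rNO3P,
    O2_surf = O2_surf, O2_thresh = O2_thresh,
    o2_ramp_width = o2_ramp_width,
    eps_assim = eps_assim, eps_wc = eps_wc, eps_fix = eps_fix,
    V_surf = V_surf, V_omz = V_omz, V_rest = V_rest,
    k_up = k_up, k_fix = k_fix,
    remin_frac_omz = remin_frac_omz,
    benthic_eff = benthic_eff,
    k_sed = k_sed,
    k_scav = k_scav,
    mix_surf_omz = mix_surf_omz * 1e6,
    mix_omz_rest = mix_omz_rest * 1e6,
    vent_rest = vent_rest * 1e6,
    K_N = K_N,
    burial_o2_dependent = isTRUE(burial_o2_dependent),
    K_burial_O2 = K_burial_O2
  )
  class(p) <- "nbox_params"
  validate_nbox_params(p)
  p
}

validate_nbox_params <- function(p) {
  num <- p[!vapply(p, is.logical, logical(1))]
  bad <- names(num)[!vapply(num, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))]
  if (length(bad) > 0) {
    abort(paste0("non-finite or non-scalar parameter(s): ", paste(bad, collapse = ", ")))
  }
  if (p$alpha < 0 || p$alpha > 1) abort("`alpha` must lie in [0, 1]")
  if (p$U < 0 || p$U_base < 0) abort("`U` and `U_base` must be non-negative")
  if (any(c(p$V_surf, p$V_omz, p$V_rest) <= 0)) abort("box volumes must be positive")
  if (p$remin_frac_omz < 0 || p$remin_frac_omz > 1) abort("`remin_frac_omz` must lie in [0, 1]")
  if (p$benthic_eff < 0 || p$benthic_eff > 1) abort("`benthic_eff` must lie in [0, 1]")
  if (p$k_sed < 0) abort("`k_sed` must be non-negative")
  if (p$closed_P && p$P_inventory <= 0) abort("closed setup needs a positive `P_inventory`")
  if (!p$closed_P && p$W < 0) abort("open setup needs a non-negative `W`")
  if (p$o2_ramp_width < 0 || p$o2_ramp_width > p$O2_thresh) {
    abort("`o2_ramp_width` must lie in [0, O2_thresh]")
  }
  invisible(p)
}

#' @export
print.nbox_params <- function(x, ...) {
  cat("<nbox_params> three-box N-P-O2 model,",
      if (x$closed_P) "closed-P setup\n" else "open-P setup\n")
  cat("  U =", x$U / 1e6, "Sv;",
      if (x$closed_P) paste("P inventory =", x$P_inventory / 1e15, "Pmol")
      else paste("P input W =", x$W, "mol/s"), "\n")
  cat("  alpha =", x$alpha, " eps_assim =", x$eps_assim,
      " eps_wc =", x$eps_wc, " eps_fix =", x$eps_fix, "(permil)\n")
  invisible(x)
}

#' Default initial state for the box model
#'
#' Builds a near-uniform starting state: phosphate spread evenly over the
#' boxes (honouring the closed-setup inventory), nitrate slightly below
#' Redfield balance (N:P of 14, modern-like), a starting delta-15N of
#' 3 permil, and subsurface oxygen at 80% of the surface value.
#'
#' @param params An [nbox_params()] object.
#' @param P_conc Optional uniform phosphate concentration (mol/m3) for the
#'   open setup; ignored in the closed setup where the inventory fixes it.
#' @param d15N_init Initial delta-15N (permil) of all nitrogen pools.
#' @param NP_init Initial N:P ratio of the dissolved pools.
#' @return A tibble with one row per box (`surface`, `omz`, `rest`) and
#'   columns `P`, `N14`, `N15`, `O2` (mol/m3).
#' @export
nbox_init <- function(params, P_conc = NULL, d15N_init = 3, NP_init = 14) {
  V_tot <- params$V_surf + params$V_omz + params$V_rest
  P0 <- if (params$closed_P) params$P_inventory / V_tot else (P_conc %||% 1.8e-3)
  N0 <- NP_init * P0
  R0 <- ratio_from_delta15N(d15N_init)
  N15 <- N0 * R0 / (1 + R0)
  N14 <- N0 - N15
  tibble(
    box = c("surface", "omz", "rest"),
    P = rep(P0, 3),
    N14 = rep(N14, 3),
    N15 = rep(N15, 3),
    O2 = c(params$O2_surf, 0.8 * params$O2_surf, 0.8 * params$O2_surf)
  )
}

## internal: state tibble <-> solver vector -------------------------------

state_to_vec <- function(state) {
  s <- state[match(c("surface", "omz", "rest"), state$box), ]
  c(P_s = s$P[1], P_m = s$P[2], P_r = s$P[3],
    N14_s = s$N14[1], N15_s = s$N15[1],
    N14_m = s$N14[2], N15_m = s$N15[2],
    N14_r = s$N14[3], N15_r = s$N15[3],
    O2_m = s$O2[2], O2_r = s$O2[3])
}

vec_to_state <- function(y, params) {
  tibble(
    box = c("surface", "omz", "rest"),
    P = c(y[["P_s"]], y[["P_m"]], y[["P_r"]]),
    N14 = c(y[["N14_s"]], y[["N14_m"]], y[["N14_r"]]),
    N15 = c(y[["N15_s"]], y[["N15_m"]], y[["N15_r"]]),
    O2 = c(params$O2_surf, y[["O2_m"]], y[["O2_r"]])
  )
}

check_state <- function(state) {
  need <- c("box", "P", "N14", "N15", "O2")
  miss <- setdiff(need, names(state))
  if (length(miss) > 0) abort(paste0("state is missing column(s): ", paste(miss, collapse = ", ")))
  if (!setequal(state$box, c("surface", "omz", "rest"))) {
    abort("state must have exactly the boxes 'surface', 'omz', 'rest'")
  }
  vals <- unlist(state[c("P", "N14", "N15", "O2")])
  if (any(!is.finite(vals))) abort("state contains non-finite values")
  if (any(vals < 0)) abort("state contains negative concentrations")
  invisible(state)
}
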