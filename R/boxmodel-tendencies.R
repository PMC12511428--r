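#' Convert isotopologue amounts to delta-15N
#'
#' `delta15N_from_ratio()` implements the delta definition
#' \eqn{\delta^{15}N = (R_{sample}/R_{AIR} - 1) \times 1000} with
#' \eqn{R = {}^{15}N/{}^{14}N} and the atmospheric reference [R_AIR].
#' `ratio_from_delta15N()` is its exact inverse on the ratio scale.
#'
#' @param N15,N14 Amounts (or concentrations) of the two isotopologues.
#'   Where `N14` is not positive the value is undefined and `NA` is
#'   returned.
#' @param d15N delta-15N in permil vs AIR.
#' @return Numeric vector: permil values (or isotope ratios for the
#'   inverse).
#' @examples
#' delta15N_from_ratio(1.005 * R_AIR, 1)  # 5 permil
#' @export
delta15N_from_ratio <- function(N15, N14) {
  n <- max(length(N15), length(N14))
  N15 <- rep_len(N15, n)
  N14 <- rep_len(N14, n)
  out <- ((N15 / N14) / R_AIR - 1) * 1000
  out[N14 <= 0] <- NA_real_
  out
}

#' @rdname delta15N_from_ratio
#' @export
ratio_from_delta15N <- function(d15N) {
  R_AIR * (1 + d15N / 1000)
}

## delta-space shift of an isotope ratio: the returned ratio corresponds
## to a delta lower by `eps` permil. Used for assimilation and
## water-column denitrification so that delta offsets are exact by
## construction (clamped at zero ratio).
shift_ratio <- function(R, eps) {
  pmax(R - eps * R_AIR / 1000, 0)
}

## 15N fraction of a flux with isotope ratio R
frac15 <- function(R) R / (1 + R)

## aerobic fraction of remineralization as a function of ambient O2:
## exactly 1 at or above O2_thresh (denitrification off), ramping
## linearly to 0 at O2_thresh - width (fully denitrifying).
aerobic_fraction <- function(O2, thresh, width) {
  if (width <= 0) return(as.numeric(O2 >= thresh))
  pmin(1, pmax(0, (O2 - (thresh - width)) / width))
}

#' N2-fixation flux
#'
#' The fixation closure couples the rate of N2-fixation to the surface
#' deficit of N relative to the Redfield demand of primary production:
#' `k_fix * max(0, rNP_uptake * P_surf - N_surf) * V_surf` (mol N/s).
#' Newly fixed N carries delta-15N equal to `eps_fix` (default 0 permil,
#' within the -2 to +2 permil range of marine N2-fixation).
#'
#' @param state State tibble as from [nbox_init()].
#' @param params An [nbox_params()] object.
#' @return Fixation flux in mol N/s.
#' @export
fixation_flux <- function(state, params) {
  check_state(state)
  s <- state[state$box == "surface", ]
  N_s <- s$N14 + s$N15
  params$k_fix * max(0, params$rNP_uptake * s$P - N_s) * params$V_surf
}

## Core right-hand side used by the solver: named state vector in,
## list(derivatives, fluxes) out. Derivatives are d(concentration)/dt in
## mol m^-3 s^-1; fluxes are mol/s.
nbox_rhs <- function(y, p) {
  P_s <- y[["P_s"]]; P_m <- y[["P_m"]]; P_r <- y[["P_r"]]
  N14_s <- y[["N14_s"]]; N15_s <- y[["N15_s"]]
  N14_m <- y[["N14_m"]]; N15_m <- y[["N15_m"]]
  N14_r <- y[["N14_r"]]; N15_r <- y[["N15_r"]]
  O2_m <- y[["O2_m"]]; O2_r <- y[["O2_r"]]
  O2_s <- p$O2_surf

  U <- p$U + p$U_base; Msm <- p$mix_surf_omz; Mmr <- p$mix_omz_rest
  N_s <- N14_s + N15_s; N_m <- N14_m + N15_m; N_r <- N14_r + N15_r

  ## export production: fast Liebig uptake of the limiting nutrient
  uptake_P <- p$k_up * max(0, min(P_s, N_s / p$rNP_uptake)) * p$V_surf
  export_P <- uptake_P
  export_N <- p$rNP_uptake * export_P

  R_s <- if (N14_s > 0) N15_s / N14_s else 0
  R_m <- if (N14_m > 0) N15_m / N14_m else 0
  R_exp <- shift_ratio(R_s, p$eps_assim)
  x_exp <- frac15(R_exp)

  ## remineralization demand per box. Aerobic remineralization is
  ## O2-limited (ramp at the denitrification threshold), denitrification
  ## is nitrate-limited, and of the organic flux reaching the deep
  ## seafloor only a fraction benthic_eff is degradable at all - the
  ## rest is refractory. Organic matter that escapes remineralization
  ## (refractory + anoxia-preserved) is the leftover stream: in the open
  ## setup a fraction alpha of it is buried, the remainder dissolves
  ## back into the deep box; the closed setup remineralizes everything.
  D_m <- p$remin_frac_omz * export_P
  D_r <- (1 - p$remin_frac_omz) * export_P
  D_r_deg <- p$benthic_eff * D_r
  refractory <- (1 - p$benthic_eff) * D_r
  phi_m <- aerobic_fraction(O2_m, p$O2_thresh, p$o2_ramp_width)
  phi_r <- aerobic_fraction(O2_r, p$O2_thresh, p$o2_ramp_width)
  lim_m <- N_m / (N_m + p$K_N)
  lim_r <- N_r / (N_r + p$K_N)
  aer_m <- phi_m * D_m
  aer_r <- phi_r * D_r_deg
  den_m <- (1 - phi_m) * lim_m * D_m   # P remineralized via denitrification
  den_r <- (1 - phi_r) * lim_r * D_r_deg
  leftover <- (D_m - aer_m - den_m) + (D_r_deg - aer_r - den_r) + refractory

  alpha_eff <- if (!p$closed_P) {
    if (p$burial_o2_dependent) p$alpha * O2_r / (O2_r + p$K_burial_O2) else p$alpha
  } else 0
  burial_P_org <- alpha_eff * leftover
  return_left_P <- leftover - burial_P_org     # unburied leftover, to deep box
  burial_N <- min(p$rNP_burial * burial_P_org, p$rNP_uptake * leftover)
  return_left_N <- p$rNP_uptake * leftover - burial_N

  N_return_m <- p$rNP_uptake * (aer_m + den_m)
  N_return_r <- p$rNP_uptake * (aer_r + den_r) + return_left_N

  o2_sink_m <- p$rO2P * aer_m
  o2_sink_r <- p$rO2P * aer_r
  denit_N_m <- p$rNO3P * den_m                 # nitrate consumed, mol N/s
  denit_N_r <- p$rNO3P * den_r
  R_den_m <- shift_ratio(R_m, p$eps_wc)
  R_r <- if (N14_r > 0) N15_r / N14_r else 0
  R_den_r <- shift_ratio(R_r, p$eps_wc)

  ## benthic (sedimentary) denitrification: first-order loss of deep
  ## nitrate, near-complete consumption in pore waters so no net
  ## fractionation is expressed
  sed_denit_N <- p$k_sed * N_r * p$V_rest

  ## N2-fixation and external P cycle
  fix_N <- p$k_fix * max(0, p$rNP_uptake * P_s - N_s) * p$V_surf
  R_fix <- ratio_from_delta15N(p$eps_fix)
  W_in <- if (p$closed_P) 0 else p$W
  ## authigenic (CFA-style) P burial on the productive shelf, first order
  ## in surface dissolved P; a P sink decoupled from the organic export
  ## stream (open setup only)
  scav_P <- if (p$closed_P) 0 else p$k_scav * P_s * p$V_surf

  ## transport (mol/s into each box), loop rest -> omz -> surface -> rest
  ## plus background mixing exchanges
  tr <- function(c_s, c_m, c_r) {
    c(s = U * (c_m - c_s) + Msm * (c_m - c_s),
      m = U * (c_r - c_m) + Msm * (c_s - c_m) + Mmr * (c_r - c_m),
      r = U * (c_s - c_r) + Mmr * (c_m - c_r))
  }
  tP <- tr(P_s, P_m, P_r)
  t14 <- tr(N14_s, N14_m, N14_r)
  t15 <- tr(N15_s, N15_m, N15_r)
  tO2_m <- U * (O2_r - O2_m) + Msm * (O2_s - O2_m) + Mmr * (O2_r - O2_m)
  tO2_r <- U * (O2_s - O2_r) + Mmr * (O2_m - O2_r) + p$vent_rest * (O2_s - O2_r)

  split15 <- function(Ftot, R) {
    f15 <- Ftot * frac15(R)
    c(f14 = Ftot - f15, f15 = f15)
  }
  exp_sp <- split15(export_N, R_exp)
  fix_sp <- split15(fix_N, R_fix)
  den_m_sp <- split15(denit_N_m, R_den_m)
  den_r_sp <- split15(denit_N_r, R_den_r)
  ret_m_sp <- split15(N_return_m, R_exp)
  ret_r_sp <- split15(N_return_r, R_exp)
  sed_sp <- split15(sed_denit_N, R_r)

  d <- c(
    P_s = (tP[["s"]] - uptake_P + W_in - scav_P) / p$V_surf,
    P_m = (tP[["m"]] + aer_m + den_m) / p$V_omz,
    P_r = (tP[["r"]] + aer_r + den_r + return_left_P) / p$V_rest,
    N14_s = (t14[["s"]] - exp_sp[["f14"]] + fix_sp[["f14"]]) / p$V_surf,
    N15_s = (t15[["s"]] - exp_sp[["f15"]] + fix_sp[["f15"]]) / p$V_surf,
    N14_m = (t14[["m"]] + ret_m_sp[["f14"]] - den_m_sp[["f14"]]) / p$V_omz,
    N15_m = (t15[["m"]] + ret_m_sp[["f15"]] - den_m_sp[["f15"]]) / p$V_omz,
    N14_r = (t14[["r"]] + ret_r_sp[["f14"]] - den_r_sp[["f14"]] - sed_sp[["f14"]]) / p$V_rest,
    N15_r = (t15[["r"]] + ret_r_sp[["f15"]] - den_r_sp[["f15"]] - sed_sp[["f15"]]) / p$V_rest,
    O2_m = (tO2_m - o2_sink_m) / p$V_omz,
    O2_r = (tO2_r - o2_sink_r) / p$V_rest
  )

  fluxes <- list(
    export_P = export_P, export_N = export_N,
    f_fix = fix_N,
    f_denit_wc = denit_N_m + denit_N_r,
    f_denit_wc_omz = denit_N_m,
    f_denit_sed = sed_denit_N,
    f_burial_N = burial_N,
    f_burial_P = burial_P_org + scav_P,
    f_burial_P_org = burial_P_org,
    f_scav_P = scav_P,
    W = W_in,
    leftover_P = leftover,
    R_export = R_exp, R_fix = R_fix,
    R_denit_removed_omz = R_den_m, R_denit_removed_rest = R_den_r,
    R_sed_removed = R_r,
    adv_P_r_to_m = U * P_r, adv_P_m_to_s = U * P_m, adv_P_s_to_r = U * P_s,
    phi_omz = phi_m, phi_rest = phi_r
  )
  list(d = d, fluxes = fluxes)
}

#' Per-box time derivatives of the model tracers
#'
#' Evaluates the instantaneous tendencies of phosphate, the two nitrogen
#' isotopologues and oxygen in every box, given a state and a parameter
#' set. The mechanisms are: loop advection at `U` plus background mixing;
#' surface uptake/export with assimilation fractionation; aerobic
#' remineralization consuming O2 above the denitrification threshold and
#' nitrate-consuming denitrification (fractionation `eps_wc`) below it;
#' unfractionated sedimentary denitrification at the deep seafloor;
#' deficit-driven N2-fixation; and, in the open setup, weathering input,
#' organic burial and dissolved-P scavenging. Surface O2 is clamped to
#' `O2_surf` (its tendency is reported as zero).
#'
#' @param state State tibble (one row per box, columns `P`, `N14`, `N15`,
#'   `O2`), e.g. from [nbox_init()].
#' @param params An [nbox_params()] object.
#' @return A tibble of tendencies (mol m^-3 s^-1), one row per box, with
#'   the instantaneous fluxes (mol/s) attached as attribute `"fluxes"`.
#' @examples
#' p <- nbox_params()
#' compute_tendencies(nbox_init(p), p)
#' @export
compute_tendencies <- function(state, params) {
  check_state(state)
  validate_nbox_params(params)
  res <- nbox_rhs(state_to_vec(state), params)
  d <- res$d
  out <- tibble(
    box = c("surface", "omz", "rest"),
    dP = c(d[["P_s"]], d[["P_m"]], d[["P_r"]]),
    dN14 = c(d[["N14_s"]], d[["N14_m"]], d[["N14_r"]]),
    dN15 = c(d[["N15_s"]], d[["N15_m"]], d[["N15_r"]]),
    dO2 = c(0, d[["O2_m"]], d[["O2_r"]])
  )
  attr(out, "fluxes") <- res$fluxes
  out
}
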