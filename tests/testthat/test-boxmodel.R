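test_that("delta15N definition, inverse and undefined marker", {
  expect_equal(delta15N_from_ratio(R_AIR, 1), 0)
  expect_equal(delta15N_from_ratio(1.005 * R_AIR, 1), 5)
  # exact roundtrip through the inverse to 12 significant digits
  d <- c(-30, -5, 0, 3.2, 25)
  r <- ratio_from_delta15N(d)
  expect_equal(delta15N_from_ratio(r, 1), d, tolerance = 1e-12)
  # undefined where the 14N pool is empty
  expect_true(is.na(delta15N_from_ratio(1e-5, 0)))
})

test_that("a motionless, abiotic, uniform ocean has zero tendencies", {
  p <- nbox_params(U = 0, U_base = 0, closed_P = TRUE, k_up = 0, k_fix = 0,
                   mix_surf_omz = 0, mix_omz_rest = 0, vent_rest = 0)
  st <- nbox_init(p)
  st$O2 <- p$O2_surf            # uniform, including subsurface
  td <- compute_tendencies(st, p)
  expect_equal(unlist(td[, c("dP", "dN14", "dN15", "dO2")]),
               setNames(rep(0, 12), names(unlist(td[, c("dP", "dN14", "dN15", "dO2")]))))
})

test_that("advective fluxes follow U times the upstream concentration", {
  # rest-box P of 2 mmol/m3 advected at 0.1 Sv moves 200 mol/s into the OMZ
  p <- nbox_params(U = 0.1, U_base = 0, closed_P = FALSE, W = 0)
  st <- nbox_init(p, P_conc = 1e-3)
  st$P[st$box == "rest"] <- 2e-3
  td <- compute_tendencies(st, p)
  fl <- attr(td, "fluxes")
  expect_equal(fl$adv_P_r_to_m, 0.1e6 * 2e-3)  # 200 mol/s
})

test_that("denitrification is exactly zero wherever oxygen is at or above the threshold", {
  p <- nbox_params()
  st <- nbox_init(p)
  st$O2[st$box == "omz"] <- p$O2_thresh          # exactly at the switch
  td <- compute_tendencies(st, p)
  fl <- attr(td, "fluxes")
  expect_equal(fl$f_denit_wc, 0)

  st$O2[st$box == "omz"] <- p$O2_thresh * 3      # comfortably above
  fl2 <- attr(compute_tendencies(st, p), "fluxes")
  expect_equal(fl2$f_denit_wc, 0)

  st$O2[st$box == "omz"] <- p$O2_thresh - p$o2_ramp_width   # fully below
  fl3 <- attr(compute_tendencies(st, p), "fluxes")
  expect_gt(fl3$f_denit_wc, 0)
})

test_that("fixation follows the deficit closure", {
  p <- nbox_params(k_fix = 1, rNP_uptake = 16, V_surf = 1)
  st <- nbox_init(p)
  set_surface <- function(st, P, N) {
    st$P[st$box == "surface"] <- P
    r <- R_AIR
    st$N14[st$box == "surface"] <- N / (1 + r)
    st$N15[st$box == "surface"] <- N * r / (1 + r)
    st
  }
  # balanced: no deficit
  expect_equal(fixation_flux(set_surface(st, 1, 16), p), 0)
  # N in excess: clamped at zero
  expect_equal(fixation_flux(set_surface(st, 1, 20), p), 0)
  # deficit of 8 with unit rate and volume
  expect_equal(fixation_flux(set_surface(st, 1, 8), p), 8)
})

test_that("invalid states and parameters are rejected", {
  p <- nbox_params()
  st <- nbox_init(p)
  st$P[1] <- -1e-3
  expect_error(compute_tendencies(st, p), "negative")
  expect_error(nbox_params(alpha = 1.2), "alpha")
  expect_error(nbox_params(U = -0.1), "non-negative")
  p_bad <- nbox_params()
  p_bad$eps_wc <- NaN
  expect_error(compute_tendencies(nbox_init(p), p_bad), "eps_wc")
})

test_that("an open ocean with no P input runs down to zero export", {
  p <- nbox_params(closed_P = FALSE, W = 0)
  fit <- quiet_solve(p, t_max = 1e17)
  expect_true(fit$result$converged)
  expect_lt(fit$result$export_P, 1e-6)
  expect_lt(fit$result$f_burial_P, 1e-6)
})

test_that("the closed setup conserves total P to solver tolerance", {
  p <- nbox_params(U = 0.1, closed_P = TRUE, P_inventory = 2.42)
  fit <- quiet_solve(p)
  expect_true(fit$result$converged)
  expect_equal(fit$result$f_burial_P, 0)
  inv <- nbox_inventory(fit$state, p)
  expect_equal(inv$P, 2.42e15, tolerance = 1e-8)
})

test_that("with all fractionations off, steady delta15N is zero in every box", {
  p <- nbox_params(U = 0.1, closed_P = TRUE,
                   eps_assim = 0, eps_wc = 0, eps_fix = 0, rNP_burial = 16)
  fit <- quiet_solve(p)
  expect_true(fit$result$converged)
  d15 <- delta15N_from_ratio(fit$state$N15, fit$state$N14)
  expect_equal(d15, rep(0, 3), tolerance = 1e-6)
})

test_that("the surface-export offset equals the assimilation fractionation identically", {
  for (closed in c(TRUE, FALSE)) {
    fit <- quiet_solve(nbox_params(U = 0.12, closed_P = closed))
    expect_true(fit$result$converged)
    expect_identical(fit$result$d15N_surface - fit$result$d15N_export, 5)
  }
})

test_that("open steady states bury exactly the weathering input", {
  fit <- quiet_solve(nbox_params(U = 0.1, closed_P = FALSE, W = 2))
  expect_true(fit$result$converged)
  expect_equal(fit$result$f_burial_P, 2, tolerance = 1e-6)
})

test_that("nitrogen flux bookkeeping closes along a trajectory and at steady state", {
  p <- nbox_params(U = 0.1, closed_P = TRUE)
  st <- nbox_init(p)
  td <- compute_tendencies(st, p)
  fl <- attr(td, "fluxes")
  V <- c(p$V_surf, p$V_omz, p$V_rest)
  dN_total <- sum((td$dN14 + td$dN15) * V)
  budget <- fl$f_fix - fl$f_denit_wc - fl$f_denit_sed - fl$f_burial_N
  expect_equal(dN_total, budget, tolerance = 1e-6 * max(abs(budget), 1))

  # at steady state the isotope (15N) fluxes balance too
  fit <- quiet_solve(p)
  f <- fit$fluxes
  x <- function(R) R / (1 + R)
  in15 <- f$f_fix * x(f$R_fix)
  out15 <- f$f_denit_wc_omz * x(f$R_denit_removed_omz) +
    (f$f_denit_wc - f$f_denit_wc_omz) * x(f$R_denit_removed_rest) +
    f$f_denit_sed * x(f$R_sed_removed) +
    f$f_burial_N * x(f$R_export)
  expect_equal(in15, out15, tolerance = 1e-6 * in15)
})

test_that("tidy and glance views expose the steady-state summary", {
  fit <- quiet_solve(nbox_params())
  g <- glance(fit)
  expect_s3_class(g, "tbl_df")
  expect_equal(nrow(g), 1)
  td <- generics::tidy(fit)
  expect_true(all(c("quantity", "value", "unit") %in% names(td)))
  expect_equal(nrow(td), ncol(g))
})
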