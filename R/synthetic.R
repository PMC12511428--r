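#' Scenario for synthetic sediment records
#'
#' Describes the statistical structure of a synthetic per-site sediment
#' record: a shared long-term baseline delta-15N curve (piecewise linear
#' in age), site-level AR(1) noise in age order, an independent
#' within-timepoint spread (the up-to-2-permil scatter seen when several
#' samples share an age), a TOC regime, and a per-window coupling sign
#' between delta-15N and organic-carbon accumulation. The default
#' baselines sketch the qualitative shape of the two composite records
#' (deep-margin stable near 3-4 permil over 165 Myr; distal elevated
#' through the Paleogene, converging by the middle Miocene); they are
#' illustrative study conditions, not ground truth.
#'
#' @param environment `"deep-margin"` or `"distal"`.
#' @param age_span Length-2 numeric, record span in Ma.
#' @param density Sampling density (points/Myr).
#' @param baseline Data frame with `age`, `d15N` control points; `NULL`
#'   picks the environment default.
#' @param spread Within-timepoint spread (permil), interpreted as the
#'   full width of the scatter (sampled as Gaussian with sd `spread/4`).
#' @param ar_coef AR(1) coefficient of the site-level noise in age order
#'   (`abs(ar_coef) < 1`).
#' @param ar_sd Innovation standard deviation (permil) of the AR(1)
#'   component.
#' @param toc_mean,toc_trend TOC regime: mean (wt%) and linear trend
#'   (wt% per Myr toward the past).
#' @param sed_rate Sedimentation rate (cm/kyr) of the environment.
#' @param dry_bulk_density Dry bulk density (g/cm3).
#' @param coupling List of coupling windows, each
#'   `list(from, to, sign)` with `sign` in `{-1, 0, 1}` giving the sign
#'   of the imposed association between delta-15N and organic-carbon
#'   accumulation in that age window.
#' @return A list with class `"record_scenario"`.
#' @export
record_scenario <- function(environment = c("deep-margin", "distal"),
                            age_span = NULL,
                            density = 1,
                            baseline = NULL,
                            spread = 2,
                            ar_coef = 0.5,
                            ar_sd = 0.4,
                            toc_mean = NULL,
                            toc_trend = 0,
                            sed_rate = NULL,
                            dry_bulk_density = 1,
                            coupling = NULL) {
  environment <- match.arg(environment)
  if (is.null(age_span)) {
    age_span <- if (environment == "deep-margin") c(0, 165) else c(0, 100)
  }
  if (diff(range(age_span)) <= 0) abort("`age_span` is degenerate")
  if (abs(ar_coef) >= 1) abort("`ar_coef` must satisfy abs(ar_coef) < 1")
  if (spread < 0) abort("`spread` must be non-negative")
  if (is.null(baseline)) {
    baseline <- if (environment == "deep-margin") {
      tibble(age = c(0, 5, 25, 40, 75, 100, 133, 137, 150, 163, 165),
             d15N = c(5.5, 4.5, 3.0, 3.2, 4.0, 3.2, 0.5, 3.0, 3.2, 0.0, 0.5))
    } else {
      tibble(age = c(0, 11, 30, 55, 70, 90, 100),
             d15N = c(5.5, 5.0, 7.0, 9.0, 8.0, 6.0, 5.5))
    }
  }
  if (!all(c("age", "d15N") %in% names(baseline))) {
    abort("`baseline` must have `age` and `d15N` columns")
  }
  if (any(baseline$age < min(age_span) - 1e-9) ||
      any(baseline$age > max(age_span) + 1e-9)) {
    abort("baseline control points must lie within `age_span`")
  }
  if (is.null(toc_mean)) toc_mean <- if (environment == "deep-margin") 1 else 0.3
  if (is.null(sed_rate)) sed_rate <- if (environment == "deep-margin") 2 else 0.7
  structure(
    list(environment = environment, age_span = sort(age_span),
         density = density, baseline = as_tibble(baseline),
         spread = spread, ar_coef = ar_coef, ar_sd = ar_sd,
         toc_mean = toc_mean, toc_trend = toc_trend,
         sed_rate = sed_rate, dry_bulk_density = dry_bulk_density,
         coupling = coupling),
    class = "record_scenario"
  )
}

baseline_at <- function(scenario, age) {
  approx(scenario$baseline$age, scenario$baseline$d15N, xout = age,
         rule = 2, ties = mean)$y
}

#' Generate synthetic sediment records
#'
#' Draws `n_sites` per-site records from a shared baseline curve: each
#' site covers a contiguous, overlapping slice of the scenario's age span
#' (so splice diagnostics are exercised), carries its own AR(1) noise in
#' age order plus independent within-timepoint scatter, and gets TOC and
#' sedimentation-rate columns from the scenario regime, optionally with a
#' signed association between delta-15N and organic-carbon accumulation
#' per coupling window. Output is reproducible bit-for-bit given
#' `(scenario, n_sites, seed)`.
#'
#' @param scenario A [record_scenario()].
#' @param n_sites Number of sites (>= 1).
#' @param seed Integer seed.
#' @return A tibble in the standard record schema: `site`,
#'   `environment`, `age`, `d15N`, `d13c_org`, `TOC`, `sed_rate`,
#'   `dry_bulk_density`, ages strictly increasing within each site.
#' @export
make_records <- function(scenario, n_sites = 3, seed = 1) {
  if (!inherits(scenario, "record_scenario")) abort("`scenario` must be a record_scenario()")
  if (n_sites < 1) abort("`n_sites` must be >= 1")
  span <- scenario$age_span
  width <- diff(span)
  out <- withr::with_seed(seed, {
    purrr::map(seq_len(n_sites), function(s) {
      ## contiguous site windows that tile the span with ~40% overlap
      if (n_sites == 1) {
        lo <- span[1]; hi <- span[2]
      } else {
        step <- width / (n_sites + 0.5)
        lo <- span[1] + (s - 1) * step * 0.9
        hi <- min(span[2], lo + 1.6 * step)
      }
      n_pts <- max(4, round((hi - lo) * scenario$density))
      age <- sort(runif(n_pts, lo, hi))
      age <- age + cumsum(rep(1e-6, n_pts))  # enforce strict monotonicity
      base <- baseline_at(scenario, age)
      innov <- rnorm(n_pts, 0, scenario$ar_sd)
      ar <- as.numeric(stats::filter(innov, scenario$ar_coef, method = "recursive"))
      eps <- rnorm(n_pts, 0, scenario$spread / 4)
      d15N <- base + ar + eps
      toc <- pmax(0.01, scenario$toc_mean + scenario$toc_trend * age +
                    rnorm(n_pts, 0, 0.1 * scenario$toc_mean))
      if (!is.null(scenario$coupling)) {
        z <- scale(d15N)[, 1]
        for (w in scenario$coupling) {
          in_w <- age >= min(w$from, w$to) & age <= max(w$from, w$to)
          toc[in_w] <- pmax(0.01, toc[in_w] * (1 + 0.4 * w$sign * z[in_w]))
        }
      }
      tibble(
        site = sprintf("SYN-%s-%02d", toupper(substr(scenario$environment, 1, 2)), s),
        environment = scenario$environment,
        age = age,
        d15N = d15N,
        d13c_org = -25 + 0.3 * (d15N - mean(d15N)) + rnorm(n_pts, 0, 0.3),
        TOC = toc,
        sed_rate = scenario$sed_rate,
        dry_bulk_density = scenario$dry_bulk_density
      )
    })
  })
  bind_rows(out)
}

#' Scenario for idealized continents and winds
#'
#' Two template families: `"meridional-coast"`, a modern-like
#' north-south landmass whose west-facing coast sits under equatorward
#' trade winds; and `"zonal-coast"`, a Tethys-like landmass whose
#' east-west northern coastline sits in the easterly band. The wind
#' pattern is analytic: easterlies with an equatorward along-shore
#' component within 30 degrees of the equator, westerlies between 30 and
#' 60 degrees.
#'
#' @param template `"meridional-coast"`, `"zonal-coast"` or `"custom"`.
#' @param nlat,nlon Grid size.
#' @param tau0 Zonal stress scale (N/m2).
#' @param tau_merid Meridional (equatorward trade) stress scale (N/m2).
#' @param land_mask Custom logical mask (required for
#'   `template = "custom"`).
#' @param zero_wind If `TRUE` the stress field is identically zero.
#' @return A list with class `"continent_scenario"`.
#' @export
continent_scenario <- function(template = c("meridional-coast", "zonal-coast", "custom"),
                               nlat = 45, nlon = 90,
                               tau0 = 0.08, tau_merid = 0.05,
                               land_mask = NULL, zero_wind = FALSE) {
  template <- match.arg(template)
  if (template == "custom" && is.null(land_mask)) {
    abort("custom template needs a `land_mask`")
  }
  structure(
    list(template = template, nlat = nlat, nlon = nlon,
         tau0 = tau0, tau_merid = tau_merid,
         land_mask = land_mask, zero_wind = isTRUE(zero_wind)),
    class = "continent_scenario"
  )
}

#' Build an idealized wind field from a continent scenario
#'
#' @param scenario A [continent_scenario()].
#' @return A [wind_field()].
#' @export
make_windfield <- function(scenario) {
  if (!inherits(scenario, "continent_scenario")) {
    abort("`scenario` must be a continent_scenario()")
  }
  nlat <- scenario$nlat; nlon <- scenario$nlon
  lat <- seq(-90 + 90 / nlat, 90 - 90 / nlat, length.out = nlat)
  lon <- seq(360 / nlon / 2, 360 - 360 / nlon / 2, length.out = nlon)

  mask <- switch(
    scenario$template,
    "meridional-coast" = outer(lat, lon, function(phi, lam) {
      lam >= 180 & lam <= 220 & abs(phi) <= 60
    }),
    "zonal-coast" = outer(lat, lon, function(phi, lam) {
      lam >= 60 & lam <= 300 & phi >= -45 & phi <= 12
    }),
    "custom" = scenario$land_mask
  )
  mask <- matrix(as.logical(mask), nlat, nlon)
  if (!any(mask) || all(mask)) abort("template produced no coastline")

  if (scenario$zero_wind) {
    tx <- matrix(0, nlat, nlon); ty <- matrix(0, nlat, nlon)
  } else {
    tau_x_lat <- ifelse(abs(lat) <= 30, -scenario$tau0 * cos(pi * lat / 60),
                 ifelse(abs(lat) <= 60, scenario$tau0 * sin(pi * (abs(lat) - 30) / 30), 0))
    tau_y_lat <- ifelse(abs(lat) <= 30,
                        -scenario$tau_merid * sign(lat) * sin(pi * abs(lat) / 30),
                        0)
    tx <- matrix(tau_x_lat, nlat, nlon)
    ty <- matrix(tau_y_lat, nlat, nlon)
  }
  wind_field(lat, lon, tx, ty, mask)
}

#' Noisy steady-state observations for parameter recovery
#'
#' Solves the box model at the given parameters and emits `n_obs`
#' replicate observations of export production and deep-ocean delta-15N
#' with independent Gaussian noise, seed-reproducible. Used to test that
#' the upwelling transport can be recovered by [recover_upwelling()].
#'
#' @param params An [nbox_params()] object.
#' @param noise_sd Length-2 numeric: observation noise sd for
#'   `export_P` (mol P/s) and `d15N_deep` (permil).
#' @param seed Integer seed.
#' @param n_obs Number of replicate observations.
#' @param ... Passed on to [solve_steady_state()].
#' @return Tibble with columns `export_P` and `d15N_deep`; the noiseless
#'   steady state is attached as attribute `"truth"`.
#' @export
make_boxmodel_observations <- function(params, noise_sd = c(2, 0.1),
                                       seed = 1, n_obs = 5, ...) {
  fit <- solve_steady_state(params, ...)
  if (!fit$result$converged) abort("model did not converge; cannot generate observations")
  obs <- withr::with_seed(seed, tibble(
    export_P = fit$result$export_P + rnorm(n_obs, 0, noise_sd[1]),
    d15N_deep = fit$result$d15N_deep + rnorm(n_obs, 0, noise_sd[2])
  ))
  attr(obs, "truth") <- fit$result
  obs
}
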