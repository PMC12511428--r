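#' Gridded wind-stress field container
#'
#' Bundles a rectangular latitude-longitude grid of surface wind stress
#' with a land mask and the physical constants needed by the Ekman
#' diagnostic. Grids are matrices indexed `[lat, lon]`.
#'
#' @param lat,lon Grid-centre coordinates in degrees (strictly monotone;
#'   `abs(lat) <= 90`).
#' @param tau_x,tau_y Zonal (eastward) and meridional (northward) wind
#'   stress (N/m2), matrices of dimension `length(lat) x length(lon)`.
#' @param land_mask Logical matrix, `TRUE` over land.
#' @param rho Seawater density (kg/m3).
#' @param omega Earth rotation rate (rad/s).
#' @param lon_wrap Whether the longitude axis is periodic (global grid).
#' @return A list with class `"wind_field"`.
#' @export
wind_field <- function(lat, lon, tau_x, tau_y, land_mask,
                       rho = 1025, omega = 7.2921e-5, lon_wrap = TRUE) {
  dims <- c(length(lat), length(lon))
  for (nm in c("tau_x", "tau_y", "land_mask")) {
    m <- get(nm)
    if (!identical(dim(m), as.integer(dims))) {
      abort(paste0("`", nm, "` must be a ", dims[1], " x ", dims[2], " matrix"))
    }
  }
  if (any(abs(lat) > 90)) abort("`lat` must lie within [-90, 90]")
  if (is.unsorted(lat) && is.unsorted(rev(lat))) abort("`lat` must be monotone")
  structure(
    list(lat = lat, lon = lon, tau_x = tau_x, tau_y = tau_y,
         land_mask = land_mask, rho = rho, omega = omega,
         lon_wrap = isTRUE(lon_wrap)),
    class = "wind_field"
  )
}

#' @export
print.wind_field <- function(x, ...) {
  cat("<wind_field>", length(x$lat), "x", length(x$lon), "grid,",
      sum(x$land_mask), "land cells\n")
  invisible(x)
}

#' Coriolis parameter
#'
#' `f = 2 * omega * sin(lat)`, in 1/s; antisymmetric about the equator.
#'
#' @param lat Latitude in degrees.
#' @param omega Earth rotation rate (rad/s).
#' @return f in 1/s.
#' @examples
#' coriolis(30)  # 7.2921e-5
#' @export
coriolis <- function(lat, omega = 7.2921e-5) {
  2 * omega * sin(lat * pi / 180)
}

EARTH_RADIUS_M <- 6.371e6

#' Identify coastal ocean cells and their geometry
#'
#' Ocean cells with at least one land neighbour under 4-connectivity.
#' For each, the offshore unit normal is the normalized average of the
#' directions from the adjacent land cells into the ocean cell
#' (x = eastward, y = northward), and the coastline segment length is the
#' summed length of the shared cell edges, from spherical grid metrics at
#' the cell's latitude. Cells whose land neighbours cancel (land on
#' opposite sides) get an undefined normal (`NA`) and are excluded from
#' flux integrals.
#'
#' @param land_mask Logical matrix `[lat, lon]`, `TRUE` over land.
#' @param lat,lon Grid-centre coordinates (degrees).
#' @param lon_wrap Periodic longitude axis?
#' @return Tibble with one row per coastal cell: indices `i` (lat), `j`
#'   (lon), coordinates, normal components `nx`, `ny`, and
#'   `seg_length_m`.
#' @export
coastal_cells <- function(land_mask, lat, lon, lon_wrap = TRUE) {
  nlat <- nrow(land_mask); nlon <- ncol(land_mask)
  if (all(land_mask) || !any(land_mask)) {
    return(tibble(i = integer(), j = integer(), lat = numeric(),
                  lon = numeric(), nx = numeric(), ny = numeric(),
                  seg_length_m = numeric()))
  }
  dlat <- abs(mean(diff(lat)))
  dlon <- abs(mean(diff(lon)))
  merid_edge <- EARTH_RADIUS_M * dlat * pi / 180        # N-S running edge
  zonal_edge <- function(phi) EARTH_RADIUS_M * cos(phi * pi / 180) * dlon * pi / 180

  rows <- list()
  for (i in seq_len(nlat)) {
    for (j in seq_len(nlon)) {
      if (land_mask[i, j]) next
      nx <- 0; ny <- 0; seg <- 0
      ## west / east neighbours (shared edge runs N-S)
      jw <- if (j > 1) j - 1 else if (lon_wrap) nlon else NA
      je <- if (j < nlon) j + 1 else if (lon_wrap) 1 else NA
      if (!is.na(jw) && land_mask[i, jw]) { nx <- nx + 1; seg <- seg + merid_edge }
      if (!is.na(je) && land_mask[i, je]) { nx <- nx - 1; seg <- seg + merid_edge }
      ## south / north neighbours (shared edge runs E-W)
      if (i > 1 && land_mask[i - 1, j] && lat[i - 1] < lat[i]) {
        ny <- ny + 1; seg <- seg + zonal_edge(lat[i])
      }
      if (i > 1 && land_mask[i - 1, j] && lat[i - 1] > lat[i]) {
        ny <- ny - 1; seg <- seg + zonal_edge(lat[i])
      }
      if (i < nlat && land_mask[i + 1, j] && lat[i + 1] > lat[i]) {
        ny <- ny - 1; seg <- seg + zonal_edge(lat[i])
      }
      if (i < nlat && land_mask[i + 1, j] && lat[i + 1] < lat[i]) {
        ny <- ny + 1; seg <- seg + zonal_edge(lat[i])
      }
      if (seg == 0) next
      nrm <- sqrt(nx^2 + ny^2)
      rows[[length(rows) + 1]] <- tibble(
        i = i, j = j, lat = lat[i], lon = lon[j],
        nx = if (nrm > 0) nx / nrm else NA_real_,
        ny = if (nrm > 0) ny / nrm else NA_real_,
        seg_length_m = seg
      )
    }
  }
  bind_rows(rows)
}

#' Coastal Ekman upwelling mass flux
#'
#' For every coastal cell outside the equatorial band, the offshore Ekman
#' mass transport per metre of coastline is the along-shore wind-stress
#' component divided by the Coriolis parameter,
#' `(tau_y * nx - tau_x * ny) / f` (kg s^-1 m^-1, positive offshore =
#' upwelling-favourable), and the cell flux is that transport times the
#' coastline segment length. Only positive cell fluxes enter the global
#' upwelling integral; negative ones are tallied separately as
#' downwelling. Cells within `lat_min` degrees of the equator are skipped
#' and counted.
#'
#' @param field A [wind_field()].
#' @param lat_min Half-width (degrees) of the excluded equatorial band.
#' @return A list of class `"upwelling_flux"` with `cells` (per-cell
#'   tibble incl. `transport_kg_s_m` and `flux_kg_s`) and `totals`, a
#'   one-row tibble with the global upwelling integral in kg/s, 1e9 kg/s
#'   and Sv equivalent (divided by `rho`), the downwelling tally, and the
#'   counts of contributing/skipped cells.
#' @export
coastal_upwelling_flux <- function(field, lat_min = 5) {
  if (!inherits(field, "wind_field")) abort("`field` must be a wind_field()")
  cells <- coastal_cells(field$land_mask, field$lat, field$lon, field$lon_wrap)
  n_equatorial <- 0L
  if (nrow(cells) > 0) {
    in_band <- abs(cells$lat) < lat_min
    n_equatorial <- sum(in_band)
    cells <- cells[!in_band & is.finite(cells$nx), ]
  }
  if (nrow(cells) > 0) {
    f <- coriolis(cells$lat, field$omega)
    tx <- field$tau_x[cbind(cells$i, cells$j)]
    ty <- field$tau_y[cbind(cells$i, cells$j)]
    cells <- cells |>
      mutate(
        f = f,
        tau_along = ty * .data$nx - tx * .data$ny,
        transport_kg_s_m = .data$tau_along / f,
        flux_kg_s = .data$transport_kg_s_m * .data$seg_length_m
      )
  } else {
    cells <- mutate(cells, f = numeric(0), tau_along = numeric(0),
                    transport_kg_s_m = numeric(0), flux_kg_s = numeric(0))
  }
  up <- sum(pmax(cells$flux_kg_s, 0))
  down <- sum(pmin(cells$flux_kg_s, 0))
  totals <- tibble(
    upwelling_kg_s = up,
    upwelling_1e9_kg_s = up / 1e9,
    upwelling_Sv = up / field$rho / 1e6,
    downwelling_kg_s = down,
    n_cells = nrow(cells),
    n_equatorial_skipped = n_equatorial
  )
  structure(list(cells = cells, totals = totals, lat_min = lat_min),
            class = "upwelling_flux")
}

#' @export
print.upwelling_flux <- function(x, ...) {
  t <- x$totals
  cat("<upwelling_flux>", t$n_cells, "coastal cells (",
      t$n_equatorial_skipped, "equatorial skipped )\n")
  cat(sprintf("  global upwelling: %.4g kg/s (%.4g Sv eq.); downwelling tally %.4g kg/s\n",
              t$upwelling_kg_s, t$upwelling_Sv, t$downwelling_kg_s))
  invisible(x)
}

#' @rdname coastal_upwelling_flux
#' @param x An `"upwelling_flux"` object.
#' @param ... Unused.
#' @export
glance.upwelling_flux <- function(x, ...) x$totals

#' @rdname coastal_upwelling_flux
#' @export
tidy.upwelling_flux <- function(x, ...) x$cells
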