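make_island_field <- function(tau_x = 0, tau_y = 0, nlat = 21, nlon = 24) {
  lat <- seq(-80, 80, length.out = nlat)
  lon <- seq(7.5, 352.5, length.out = nlon)
  mask <- matrix(FALSE, nlat, nlon)
  list(lat = lat, lon = lon, mask = mask,
       tx = matrix(tau_x, nlat, nlon), ty = matrix(tau_y, nlat, nlon))
}

test_that("coriolis parameter has the standard value and antisymmetry", {
  expect_equal(coriolis(0), 0)
  expect_equal(coriolis(30), 7.2921e-5, tolerance = 1e-10)  # 2*omega*sin(30) = omega
  lats <- c(-75, -30, -10, 10, 45, 88)
  expect_equal(coriolis(-lats), -coriolis(lats))
})

test_that("a single island yields four coastal cells with outward normals", {
  g <- make_island_field()
  i0 <- 14; j0 <- 10   # island around 24N
  g$mask[i0, j0] <- TRUE
  cc <- coastal_cells(g$mask, g$lat, g$lon)
  expect_equal(nrow(cc), 4)
  # east neighbour gets an eastward normal, etc.
  east <- cc[cc$j == j0 + 1, ]
  expect_equal(c(east$nx, east$ny), c(1, 0))
  west <- cc[cc$j == j0 - 1, ]
  expect_equal(c(west$nx, west$ny), c(-1, 0))
  north <- cc[cc$i == i0 + 1 & cc$j == j0, ]
  expect_equal(c(north$nx, north$ny), c(0, 1))
  south <- cc[cc$i == i0 - 1 & cc$j == j0, ]
  expect_equal(c(south$nx, south$ny), c(0, -1))
})

test_that("a straight meridional coastline has purely zonal normals", {
  g <- make_island_field()
  g$mask[, 12:16] <- TRUE   # full-height continent
  cc <- coastal_cells(g$mask, g$lat, g$lon)
  expect_true(all(cc$ny == 0))
  expect_true(all(abs(cc$nx) == 1))
})

test_that("coastal detection matches a brute-force neighbour scan on a random mask", {
  withr::with_seed(13, {
    nlat <- 20; nlon <- 20
    lat <- seq(-60, 60, length.out = nlat)
    lon <- seq(9, 351, length.out = nlon)
    mask <- matrix(runif(nlat * nlon) < 0.35, nlat, nlon)
    cc <- coastal_cells(mask, lat, lon, lon_wrap = TRUE)

    # independent oracle: explicit double loop over the 4-neighbourhood
    expected <- matrix(FALSE, nlat, nlon)
    for (i in seq_len(nlat)) {
      for (j in seq_len(nlon)) {
        if (mask[i, j]) next
        nb <- list(c(i - 1, j), c(i + 1, j),
                   c(i, if (j == 1) nlon else j - 1),
                   c(i, if (j == nlon) 1 else j + 1))
        for (b in nb) {
          if (b[1] >= 1 && b[1] <= nlat && mask[b[1], b[2]]) expected[i, j] <- TRUE
        }
      }
    }
    got <- matrix(FALSE, nlat, nlon)
    got[cbind(cc$i, cc$j)] <- TRUE
    # cells with cancelling normals are still coastal (listed with NA normal)
    expect_equal(got, expected)
  })
})

test_that("the single-cell Ekman example is reproduced to 4 significant figures", {
  # meridional coast on the east side of an ocean at 30N, equatorward
  # along-shore stress 0.1 N/m2: per-metre transport 0.1/f = 1371.3 kg/s/m
  g <- make_island_field(tau_x = 0, tau_y = -0.1, nlat = 33, nlon = 36)  # 5-degree grid, 30N on it
  i0 <- which.min(abs(g$lat - 30))
  g$mask[, 20] <- TRUE                      # meridional land strip
  fld <- wind_field(g$lat, g$lon, g$tx, g$ty, g$mask)
  res <- coastal_upwelling_flux(fld)
  cell <- res$cells[res$cells$i == i0 & res$cells$j == 19, ]  # ocean west of land
  expect_equal(cell$nx, -1)
  expect_equal(cell$transport_kg_s_m, 1371.347, tolerance = 5e-4)
  # with a 1e5 m segment the flux is 1.3713e8 kg/s
  expect_equal(cell$flux_kg_s / cell$seg_length_m * 1e5, 1.3713e8, tolerance = 5e-4)

  # reversing the wind moves this cell to the downwelling tally
  # (both coasts of the strip swap roles, so the global integral cannot grow)
  fld_rev <- wind_field(g$lat, g$lon, g$tx, -g$ty, g$mask)
  res_rev <- coastal_upwelling_flux(fld_rev)
  expect_lte(res_rev$totals$upwelling_kg_s, res$totals$upwelling_kg_s)
  cell_rev <- res_rev$cells[res_rev$cells$i == i0 & res_rev$cells$j == 19, ]
  expect_equal(cell_rev$flux_kg_s, -cell$flux_kg_s)
  expect_lt(cell_rev$flux_kg_s, 0)
})

test_that("zero wind gives zero flux and the integral is the sum of positive cells", {
  g <- make_island_field(0, 0)
  g$mask[8:14, 5:9] <- TRUE
  fld <- wind_field(g$lat, g$lon, g$tx, g$ty, g$mask)
  res <- coastal_upwelling_flux(fld)
  expect_equal(res$totals$upwelling_kg_s, 0)

  withr::with_seed(21, {
    tx <- matrix(rnorm(21 * 24, 0, 0.05), 21, 24)
    ty <- matrix(rnorm(21 * 24, 0, 0.05), 21, 24)
    fld2 <- wind_field(g$lat, g$lon, tx, ty, g$mask)
    res2 <- coastal_upwelling_flux(fld2)
    expect_equal(res2$totals$upwelling_kg_s,
                 sum(pmax(res2$cells$flux_kg_s, 0)))
  })
})

test_that("fluxes are linear in the stress and mirror across the equator", {
  withr::with_seed(31, {
    nlat <- 20; nlon <- 20
    lat <- seq(-66.5, 66.5, length.out = nlat)   # symmetric grid
    lon <- seq(9, 351, length.out = nlon)
    half <- matrix(runif(nlat / 2 * nlon) < 0.3, nlat / 2, nlon)
    mask <- rbind(half[rev(seq_len(nlat / 2)), ], half)  # equator-symmetric
    tx <- matrix(rnorm(nlat * nlon, 0, 0.06), nlat, nlon)
    ty <- matrix(rnorm(nlat * nlon, 0, 0.06), nlat, nlon)
    fld <- wind_field(lat, lon, tx, ty, mask)
    res <- coastal_upwelling_flux(fld)

    # linearity: scaling the stress scales every flux
    fld3 <- wind_field(lat, lon, 3 * tx, 3 * ty, mask)
    res3 <- coastal_upwelling_flux(fld3)
    expect_equal(res3$cells$flux_kg_s, 3 * res$cells$flux_kg_s)
    expect_equal(res3$totals$upwelling_kg_s, 3 * res$totals$upwelling_kg_s)

    # hemispheric mirror: flip the mask and the meridional stress
    flip <- function(m) m[rev(seq_len(nrow(m))), ]
    fld_m <- wind_field(lat, lon, flip(tx), -flip(ty), flip(mask))
    res_m <- coastal_upwelling_flux(fld_m)
    expect_equal(res_m$totals$upwelling_kg_s, res$totals$upwelling_kg_s,
                 tolerance = 1e-12)
  })
})

test_that("all-ocean and all-land masks give empty coastal sets", {
  g <- make_island_field()
  expect_equal(nrow(coastal_cells(g$mask, g$lat, g$lon)), 0)
  expect_equal(nrow(coastal_cells(!g$mask, g$lat, g$lon)), 0)
})
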