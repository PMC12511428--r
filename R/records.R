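#' Splice per-site sediment records into a composite
#'
#' Concatenates dated per-site records from one depositional environment
#' class into a single age-sorted composite, and reports splice
#' diagnostics for every temporally overlapping pair of sites: the
#' overlap interval, the mean delta-15N offset over the overlap
#' (site a minus site b, each interpolated onto the other's sample ages),
#' the number of points involved, and whether the offset exceeds
#' `overlap_tol`. Offsets are reported, never corrected.
#'
#' @param records Data frame with at least `site`, `environment`, `age`
#'   and `d15N` columns; rows from several sites.
#' @param overlap_tol Flagging threshold (permil) for the absolute mean
#'   offset between overlapping sites.
#' @return A tibble of class `"nbox_composite"`, sorted by age, with
#'   every row traceable to its source site; pairwise diagnostics in
#'   `attr(., "diagnostics")` (also via [splice_diagnostics()]) and the
#'   environment class in `attr(., "environment")`.
#' @export
splice_records <- function(records, overlap_tol = 0.5) {
  need <- c("site", "environment", "age", "d15N")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    abort(paste0("`records` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  env <- unique(records$environment)
  if (length(env) > 1) {
    abort(paste0("records mix environment classes: ", paste(env, collapse = ", ")))
  }
  if (nrow(records) == 0) abort("`records` is empty")

  composite <- records |>
    as_tibble() |>
    arrange(.data$age, .data$site)

  sites <- unique(composite$site)
  diags <- list()
  if (length(sites) > 1) {
    pairs <- utils::combn(sites, 2, simplify = FALSE)
    diags <- purrr::map(pairs, function(pr) {
      a <- composite[composite$site == pr[1], ]
      b <- composite[composite$site == pr[2], ]
      lo <- max(min(a$age), min(b$age))
      hi <- min(max(a$age), max(b$age))
      if (lo >= hi) return(NULL)
      offs <- c(
        a$d15N[a$age >= lo & a$age <= hi] -
          approx(b$age, b$d15N, a$age[a$age >= lo & a$age <= hi], ties = mean)$y,
        approx(a$age, a$d15N, b$age[b$age >= lo & b$age <= hi], ties = mean)$y -
          b$d15N[b$age >= lo & b$age <= hi]
      )
      offs <- offs[is.finite(offs)]
      if (length(offs) == 0) return(NULL)
      tibble(site_a = pr[1], site_b = pr[2],
             overlap_from = lo, overlap_to = hi,
             mean_offset = mean(offs), n = length(offs),
             flagged = abs(mean(offs)) > overlap_tol)
    })
  }
  diags <- bind_rows(diags)
  if (nrow(diags) == 0) {
    diags <- tibble(site_a = character(), site_b = character(),
                    overlap_from = numeric(), overlap_to = numeric(),
                    mean_offset = numeric(), n = integer(),
                    flagged = logical())
  }
  class(composite) <- c("nbox_composite", class(composite))
  attr(composite, "diagnostics") <- diags
  attr(composite, "environment") <- env
  attr(composite, "overlap_tol") <- overlap_tol
  composite
}

#' @rdname splice_records
#' @param composite A composite from [splice_records()].
#' @export
splice_diagnostics <- function(composite) {
  attr(composite, "diagnostics") %||%
    abort("no splice diagnostics: not an object from splice_records()")
}

#' Organic-carbon accumulation rate
#'
#' `(TOC/100) * dry_bulk_density * sed_rate`, i.e. weight-percent organic
#' carbon converted to a burial flux per unit seafloor area.
#'
#' @param TOC Total organic carbon in weight percent.
#' @param sed_rate Sedimentation rate in cm/kyr.
#' @param dry_bulk_density Dry bulk density in g/cm3 (default 1; outputs
#'   computed with the default should be treated as order-of-magnitude).
#' @return Accumulation rate in g C / kyr / cm2.
#' @examples
#' corg_accumulation(1, 1, 1)  # 0.01
#' @export
corg_accumulation <- function(TOC, sed_rate, dry_bulk_density = 1) {
  if (any(TOC < 0, na.rm = TRUE)) abort("`TOC` must be non-negative")
  if (any(sed_rate < 0, na.rm = TRUE)) abort("`sed_rate` must be non-negative")
  if (any(dry_bulk_density < 0, na.rm = TRUE)) abort("`dry_bulk_density` must be non-negative")
  (TOC / 100) * dry_bulk_density * sed_rate
}

#' Delta-15N between distal and deep composite records
#'
#' Interpolates the two composites onto a common age grid and returns
#' `Delta15N = d15N_distal - d15N_deep`, positive when the distal record
#' is isotopically heavier. Grid points outside either record's span, or
#' falling in a data gap wider than `max_gap`, are masked (`NA`) rather
#' than bridged.
#'
#' @param deep,distal Data frames with `age` and `d15N` columns (e.g.
#'   composites from [splice_records()]).
#' @param age_grid Ages (Ma) at which to evaluate the difference;
#'   defaults to a 1-Myr grid over the common span.
#' @param max_gap Maximum data gap (Myr) an interpolation is allowed to
#'   bridge.
#' @return Tibble with columns `age`, `d15N_deep`, `d15N_distal`,
#'   `delta15N`.
#' @export
delta15N_gap <- function(deep, distal, age_grid = NULL, max_gap = 10) {
  for (nm in c("deep", "distal")) {
    d <- get(nm)
    if (!all(c("age", "d15N") %in% names(d))) {
      abort(paste0("`", nm, "` must have `age` and `d15N` columns"))
    }
  }
  lo <- max(min(deep$age), min(distal$age))
  hi <- min(max(deep$age), max(distal$age))
  if (lo >= hi) abort("the two records have no overlapping age span")
  if (is.null(age_grid)) age_grid <- seq(ceiling(lo), floor(hi), by = 1)

  interp_masked <- function(d, x) {
    ages <- sort(unique(d$age))
    y <- approx(d$age, d$d15N, xout = x, ties = mean)$y
    ## mask points bridging a gap wider than max_gap
    idx <- findInterval(x, ages)
    gap_ok <- idx >= 1 & idx < length(ages) &
      (ages[pmin(idx + 1, length(ages))] - ages[pmax(idx, 1)]) <= max_gap
    on_knot <- x %in% ages
    y[!(gap_ok | on_knot)] <- NA_real_
    y
  }
  tibble(
    age = age_grid,
    d15N_deep = interp_masked(deep, age_grid),
    d15N_distal = interp_masked(distal, age_grid),
    delta15N = .data$d15N_distal - .data$d15N_deep
  )
}

#' Nitrate deficit relative to Redfield (N*)
#'
#' `N* = NO3 - 16 * PO4` in mmol N/m3: negative where denitrification has
#' removed fixed N in excess of P (inner-shelf values below -20), positive
#' where nitrate is in excess (about +10 in the open North Atlantic).
#'
#' @param NO3,PO4 Nitrate and phosphate concentrations (mmol/m3).
#' @return N* in mmol N/m3.
#' @export
nstar <- function(NO3, PO4) {
  if (any(NO3 < 0, na.rm = TRUE) || any(PO4 < 0, na.rm = TRUE)) {
    abort("concentrations must be non-negative")
  }
  NO3 - 16 * PO4
}

#' Bin a dated series into fixed age increments
#'
#' Non-overlapping bins of width `bin_width` anchored at age 0. Empty
#' bins inside the data span are emitted with `n = 0`; the standard
#' deviation is `NA` (undefined) for bins with fewer than two points.
#'
#' @param data Data frame with an `age` column and the value column named
#'   by `value`.
#' @param value Name of the value column (default `"value"`).
#' @param bin_width Bin width in Myr (default 5).
#' @return Tibble with `bin_centre`, `mean`, `sd`, `n`.
#' @export
bin_series <- function(data, value = "value", bin_width = 5) {
  if (bin_width <= 0) abort("`bin_width` must be positive")
  if (!"age" %in% names(data)) abort("`data` must have an `age` column")
  if (!value %in% names(data)) abort(paste0("`data` has no column `", value, "`"))
  v <- data[[value]]
  keep <- is.finite(data$age) & is.finite(v)
  age <- data$age[keep]; v <- v[keep]
  if (length(age) == 0) {
    return(tibble(bin_centre = numeric(), mean = numeric(),
                  sd = numeric(), n = integer()))
  }
  idx <- floor(age / bin_width)
  all_bins <- seq(min(idx), max(idx))
  out <- purrr::map(all_bins, function(b) {
    x <- v[idx == b]
    tibble(
      bin_centre = (b + 0.5) * bin_width,
      mean = if (length(x) > 0) mean(x) else NA_real_,
      sd = if (length(x) >= 2) sd(x) else NA_real_,
      n = length(x)
    )
  })
  bind_rows(out)
}

#' Windowed correlation between two dated series
#'
#' Pairs two series by nearest age within `pair_tol`, then computes the
#' Pearson correlation of the pairs falling in each age window. Windows
#' with fewer than four pairs are marked insufficient rather than raising
#' an error. The default windows are the record partition used for the
#' delta-15N vs organic-carbon-accumulation comparison: 165-28 Ma and the
#' last 28 Myr.
#'
#' @param x_series,y_series Data frames with `age` and `value` columns.
#' @param windows List of length-2 numeric vectors `c(from, to)` in Ma
#'   (order irrelevant).
#' @param pair_tol Maximum age difference (Myr) for pairing.
#' @return Tibble with one row per window: `window_from`, `window_to`,
#'   `r`, `n`, `sign`, `insufficient`.
#' @export
windowed_correlation <- function(x_series, y_series,
                                 windows = list(c(28, 165), c(0, 28)),
                                 pair_tol = 2.5) {
  for (nm in c("x_series", "y_series")) {
    d <- get(nm)
    if (!all(c("age", "value") %in% names(d))) {
      abort(paste0("`", nm, "` must have `age` and `value` columns"))
    }
  }
  ys <- y_series[is.finite(y_series$age) & is.finite(y_series$value), ]
  xs <- x_series[is.finite(x_series$age) & is.finite(x_series$value), ]
  if (nrow(xs) == 0 || nrow(ys) == 0) {
    pairs <- tibble(age = numeric(), x = numeric(), y = numeric())
  } else {
    j <- vapply(xs$age, function(a) which.min(abs(ys$age - a)), integer(1))
    ok <- abs(ys$age[j] - xs$age) <= pair_tol
    pairs <- tibble(age = xs$age[ok], x = xs$value[ok], y = ys$value[j][ok])
  }
  purrr::map(windows, function(w) {
    w <- sort(w)
    pw <- pairs[pairs$age >= w[1] & pairs$age <= w[2], ]
    n <- nrow(pw)
    if (n < 4 || sd(pw$x) == 0 || sd(pw$y) == 0) {
      tibble(window_from = w[1], window_to = w[2], r = NA_real_,
             n = n, sign = NA_character_, insufficient = TRUE)
    } else {
      r <- cor(pw$x, pw$y)
      tibble(window_from = w[1], window_to = w[2], r = r, n = n,
             sign = if (r < 0) "negative" else "non-negative",
             insufficient = FALSE)
    }
  }) |>
    bind_rows()
}
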