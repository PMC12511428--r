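test_that("splicing a single record is the identity with empty diagnostics", {
  rec <- two_site_records() |> dplyr::filter(site == "A")
  comp <- splice_records(rec)
  expect_equal(tibble::as_tibble(comp)[names(rec)], rec, ignore_attr = TRUE)
  expect_equal(nrow(splice_diagnostics(comp)), 0)
})

test_that("splice diagnostics measure offsets between overlapping sites", {
  # two records drawn from one curve with modest noise: the mean offset
  # over the overlap stays within 3 standard errors of zero
  noise <- 0.3
  comp <- splice_records(two_site_records(offset_b = 0, noise_sd = noise))
  d <- splice_diagnostics(comp)
  expect_equal(nrow(d), 1)
  se <- noise * sqrt(2) / sqrt(d$n)
  expect_lt(abs(d$mean_offset), 3 * se)
  expect_false(d$flagged)

  # a constructed 2 permil offset gets flagged at overlap_tol = 0.5
  comp2 <- splice_records(two_site_records(offset_b = 2), overlap_tol = 0.5)
  d2 <- splice_diagnostics(comp2)
  expect_true(d2$flagged)
  # offset is reported as site_a minus site_b; B sits 2 permil high
  expect_equal(d2$mean_offset, -2, tolerance = 0.05)

  # mixed environment classes are rejected
  bad <- two_site_records()
  bad$environment[bad$site == "B"] <- "distal"
  expect_error(splice_records(bad), "environment")
})

test_that("splice keeps every row traceable so splitting by site restores the inputs", {
  rec <- two_site_records(noise_sd = 0.2)
  comp <- splice_records(rec)
  back <- tibble::as_tibble(comp) |> dplyr::arrange(site, age)
  expect_equal(back, dplyr::arrange(rec, site, age), ignore_attr = TRUE)
})

test_that("organic carbon accumulation is the TOC-density-rate product", {
  expect_equal(corg_accumulation(1, 1, 1), 0.01)
  expect_equal(corg_accumulation(0, 5, 1.4), 0)
  # margin-like inputs land inside the reported envelope 0.003-0.20
  acc <- corg_accumulation(TOC = c(0.5, 2.5), sed_rate = c(1, 3),
                           dry_bulk_density = c(0.8, 1.2))
  expect_true(all(acc >= 0.003 & acc <= 0.20))
  expect_error(corg_accumulation(-1, 1, 1), "non-negative")
})

test_that("delta15N_gap recovers a constructed offset and masks wide gaps", {
  age <- seq(0, 100, by = 1)
  gap_fun <- function(a) 2 + 0.03 * a          # constructed distal-deep gap
  deep <- tibble::tibble(age = age, d15N = 3 + sin(age / 15))
  distal <- tibble::tibble(age = age, d15N = deep$d15N + gap_fun(age))

  out <- delta15N_gap(deep, distal, age_grid = seq(5, 95, by = 5))
  expect_equal(out$delta15N, gap_fun(out$age), tolerance = 1e-8)

  # identical composites give a zero gap
  same <- delta15N_gap(deep, deep, age_grid = seq(5, 95, by = 5))
  expect_true(all(same$delta15N == 0))

  # antisymmetry under swapping the records
  swapped <- delta15N_gap(distal, deep, age_grid = seq(5, 95, by = 5))
  expect_equal(swapped$delta15N, -out$delta15N)

  # a 30 Myr hole in the deep record is masked, not bridged
  holey <- deep |> dplyr::filter(age <= 30 | age >= 60)
  masked <- delta15N_gap(holey, distal, age_grid = c(20, 45, 80), max_gap = 10)
  expect_false(is.na(masked$delta15N[1]))
  expect_true(is.na(masked$delta15N[2]))
  expect_false(is.na(masked$delta15N[3]))

  # no overlap is an error
  expect_error(
    delta15N_gap(deep, tibble::tibble(age = 200:220, d15N = 5)),
    "overlap"
  )
})

test_that("a well-mixed scenario has mean gap near zero", {
  withr::with_seed(7, {
    age <- seq(0, 100, by = 1)
    deep <- tibble::tibble(age = age, d15N = 3.5 + 0.5 * sin(age / 25))
    distal <- tibble::tibble(age = age, d15N = deep$d15N + rnorm(length(age), 0, 0.3))
    out <- delta15N_gap(deep, distal, age_grid = seq(2, 98, by = 2))
    expect_lt(abs(mean(out$delta15N, na.rm = TRUE)), 3 * 0.3 / sqrt(nrow(out)))
  })
})

test_that("nstar is the Redfield nitrate anomaly", {
  expect_equal(nstar(32, 2), 0)
  expect_equal(nstar(12, 2), -20)   # inner-shelf deficit scale
  expect_equal(nstar(42, 2), 10)    # open North Atlantic scale
  expect_error(nstar(-1, 2), "non-negative")
})

test_that("bin_series matches a brute-force per-point binning", {
  withr::with_seed(11, {
    df <- tibble::tibble(age = runif(200, 0, 63), value = rnorm(200, 5, 2))
    out <- bin_series(df, "value", bin_width = 5)

    # independent oracle: explicit per-point assignment
    idx <- floor(df$age / 5)
    for (b in sort(unique(idx))) {
      x <- df$value[idx == b]
      row <- out[out$bin_centre == (b + 0.5) * 5, ]
      expect_equal(row$mean, mean(x))
      expect_equal(row$sd, sd(x))
      expect_equal(row$n, length(x))
    }
  })
})

test_that("bin_series handles constants, counting, empty bins and singletons", {
  cst <- bin_series(tibble::tibble(age = seq(0, 19, by = 1), value = 4), "value", 5)
  expect_true(all(cst$mean == 4))
  expect_true(all(cst$sd == 0))

  ten <- bin_series(tibble::tibble(age = 0:9, value = 1:10), "value", 5)
  expect_equal(ten$n, c(5L, 5L))

  # a hole in the middle shows up as an n = 0 bin; singleton bins have
  # undefined sd
  holes <- bin_series(tibble::tibble(age = c(1, 2, 3, 12), value = c(1, 2, 3, 9)),
                      "value", 5)
  expect_equal(holes$n, c(3L, 0L, 1L))
  expect_true(is.na(holes$sd[2]) && is.na(holes$sd[3]))

  # bin means are invariant to within-bin permutation of rows
  withr::with_seed(3, {
    df <- tibble::tibble(age = runif(50, 0, 20), value = rnorm(50))
    shuffled <- df[sample(nrow(df)), ]
    expect_equal(bin_series(df, "value", 5), bin_series(shuffled, "value", 5))
  })
})

test_that("windowed correlation recovers constructed sign structure", {
  expect_r <- windowed_correlation(
    tibble::tibble(age = 0:50, value = 0:50),
    tibble::tibble(age = 0:50, value = -(0:50)),
    windows = list(c(0, 25), c(25, 50))
  )
  expect_equal(expect_r$r, c(-1, -1))

  # negative coupling before 28 Ma, positive after, mirroring the
  # record's partition
  withr::with_seed(5, {
    age <- seq(0.5, 160, by = 0.8)
    x <- 3 + sin(age / 12) + rnorm(length(age), 0, 0.2)
    y <- ifelse(age > 28, -1, 1) * (x - 3) + rnorm(length(age), 0, 0.2)
    out <- windowed_correlation(
      tibble::tibble(age = age, value = x),
      tibble::tibble(age = age, value = y),
      windows = list(c(28, 165), c(0, 28))
    )
    expect_equal(out$sign, c("negative", "non-negative"))
  })
})

test_that("independent series show near-zero correlation and sparse windows are marked", {
  withr::with_seed(9, {
    age <- seq(0, 160, length.out = 200)
    out <- windowed_correlation(
      tibble::tibble(age = age, value = rnorm(200)),
      tibble::tibble(age = age, value = rnorm(200)),
      windows = list(c(28, 165), c(0, 28))
    )
    expect_true(all(abs(out$r) < 0.2))
  })
  sparse <- windowed_correlation(
    tibble::tibble(age = c(1, 2), value = c(1, 2)),
    tibble::tibble(age = c(1, 2), value = c(2, 1)),
    windows = list(c(0, 10))
  )
  expect_true(sparse$insufficient)
  expect_true(is.na(sparse$r))
})
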