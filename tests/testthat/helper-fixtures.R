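# Shared helpers: fast parameter sets and small synthetic fixtures built
# in code at test time.

# Steady-state solves in tests use slightly looser residual targets than
# the package default so the suite stays quick; conservation tests tighten
# them again locally.
fast_solve <- function(params, ...) {
  solve_steady_state(params, tol = 1e-9, ...)
}

quiet_solve <- function(params, ...) {
  suppressWarnings(fast_solve(params, ...))
}

# A tiny two-site record pair drawn from one known curve, for splice and
# gap tests.
two_site_records <- function(offset_b = 0, noise_sd = 0, seed = 42) {
  withr::with_seed(seed, {
    curve <- function(age) 3 + 2 * sin(age / 20)
    age_a <- seq(0, 60, by = 2)
    age_b <- seq(40, 100, by = 2)
    dplyr::bind_rows(
      tibble::tibble(site = "A", environment = "deep-margin", age = age_a,
                     d15N = curve(age_a) + rnorm(length(age_a), 0, noise_sd)),
      tibble::tibble(site = "B", environment = "deep-margin", age = age_b,
                     d15N = curve(age_b) + offset_b + rnorm(length(age_b), 0, noise_sd))
    )
  })
}
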