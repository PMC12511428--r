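record_required_cols <- c("site", "environment", "age", "d15N")

#' Read a sediment-record table
#'
#' Reads a CSV in the standard record schema (`site`, `environment`,
#' `age`, `d15N`, optionally `d13c_org`, `TOC`, `sed_rate`,
#' `dry_bulk_density`, ...). Unknown columns are preserved as passthrough
#' metadata. Validates that required columns are present (error names the
#' missing column) and that ages are strictly increasing within each
#' site (error names the site). A column-name shim maps common alternate
#' spellings onto the canonical schema, isolating downstream code from a
#' deposit's header choices.
#'
#' @param path Path to a CSV file.
#' @return A tibble of validated records.
#' @export
read_record_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  shim <- c(
    "Site" = "site", "hole" = "site",
    "Environment" = "environment", "env" = "environment",
    "age_Ma" = "age", "Age" = "age", "Age_Ma" = "age",
    "d15n" = "d15N", "delta15N" = "d15N", "d15N_permil" = "d15N",
    "d13C_org" = "d13c_org", "d13Corg" = "d13c_org",
    "TOC_wt_pct" = "TOC", "toc" = "TOC",
    "sed_rate_cm_kyr" = "sed_rate",
    "dbd" = "dry_bulk_density"
  )
  hit <- names(x) %in% names(shim)
  names(x)[hit] <- shim[names(x)[hit]]
  miss <- setdiff(record_required_cols, names(x))
  if (length(miss) > 0) {
    abort(paste0("record table is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  bad <- x |>
    group_by(.data$site) |>
    summarise(mono = all(diff(.data$age) > 0), .groups = "drop") |>
    dplyr::filter(!.data$mono)
  if (nrow(bad) > 0) {
    abort(paste0("ages are not strictly increasing within site(s): ",
                 paste(bad$site, collapse = ", ")))
  }
  x
}

#' Write a results table with stable formatting
#'
#' Writes a tibble as CSV with a fixed column order (as given), UTF-8,
#' "." decimal separator, empty fields for missing values, and numeric
#' columns formatted to 6 significant digits so that repeated writes of
#' the same data are byte-identical (repeatable diffs).
#'
#' @param table Data frame to write.
#' @param path Output path.
#' @param digits Significant digits for numeric columns.
#' @param allow_empty Permit writing a header-only file for an empty
#'   table.
#' @param manifest If `TRUE`, also write a small JSON run manifest next
#'   to the output (see [run_manifest()]).
#' @return Invisibly, the path written.
#' @export
write_results <- function(table, path, digits = 6, allow_empty = FALSE,
                          manifest = FALSE) {
  if (nrow(table) == 0 && !allow_empty) {
    abort("refusing to write an empty table (set allow_empty = TRUE)")
  }
  out <- as_tibble(table) |>
    mutate(across(where(is.numeric), ~ formatC(.x, digits = digits, format = "g")))
  readr::write_csv(out, path, na = "")
  if (manifest) {
    mf <- run_manifest(command = "write_results", outputs = path)
    writeLines(mf, paste0(path, ".manifest.json"))
  }
  invisible(path)
}

#' Deterministic run manifest
#'
#' A small JSON blob describing a run: command label, package version,
#' seeds, input-file digests (md5, recomputable) and output files.
#' Timestamps are intentionally excluded from the digest-relevant fields
#' so identical runs produce identical manifests apart from the
#' timestamp line.
#'
#' @param command Free-text command label.
#' @param seed Seed(s) used, if any.
#' @param inputs,outputs Character vectors of file paths.
#' @return A JSON string (one element per line).
#' @export
run_manifest <- function(command, seed = NULL, inputs = character(),
                         outputs = character()) {
  digest_one <- function(f) if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
  lines <- c(
    "{",
    paste0('  "command": "', command, '",'),
    paste0('  "package_version": "', as.character(utils::packageVersion("nitrobox")), '",'),
    paste0('  "seed": [', paste(seed, collapse = ", "), '],'),
    paste0('  "inputs": {',
           paste(sprintf('"%s": "%s"', inputs, vapply(inputs, digest_one, character(1))),
                 collapse = ", "), '},'),
    paste0('  "outputs": [', paste(sprintf('"%s"', outputs), collapse = ", "), '],'),
    paste0('  "timestamp": "', format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), '"'),
    "}"
  )
  lines
}

#' Read and write gridded wind fields as long-format CSV
#'
#' Plain-text exchange format for [wind_field()] objects: one row per
#' grid cell with columns `lat`, `lon`, `tau_x`, `tau_y`, `land`
#' (0/1).
#'
#' @param field A [wind_field()].
#' @param path CSV path.
#' @return `write_windfield_csv()` returns the path invisibly;
#'   `read_windfield_csv()` returns a [wind_field()].
#' @export
write_windfield_csv <- function(field, path) {
  grid <- expand.grid(i = seq_along(field$lat), j = seq_along(field$lon))
  df <- tibble(
    lat = field$lat[grid$i], lon = field$lon[grid$j],
    tau_x = field$tau_x[cbind(grid$i, grid$j)],
    tau_y = field$tau_y[cbind(grid$i, grid$j)],
    land = as.integer(field$land_mask[cbind(grid$i, grid$j)])
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_windfield_csv
#' @param rho,omega Constants passed to [wind_field()].
#' @export
read_windfield_csv <- function(path, rho = 1025, omega = 7.2921e-5) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("lat", "lon", "tau_x", "tau_y", "land")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("wind-field CSV is missing column(s): ", paste(miss, collapse = ", ")))
  }
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  shape <- function(v) {
    m <- matrix(NA_real_, length(lat), length(lon))
    m[cbind(match(df$lat, lat), match(df$lon, lon))] <- v
    m
  }
  wind_field(lat, lon, shape(df$tau_x), shape(df$tau_y),
             shape(as.numeric(df$land)) > 0.5, rho = rho, omega = omega)
}
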