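#' @importFrom rlang .data
NULL

# Canonical internal column order for a biomarker battery tibble.
battery_cols <- c("temperature", "density", "day", "replicate",
                  "biomarker", "value", "units")

# Column names used in the on-disk long CSV format.
battery_file_cols <- c(
  temperature = "temperature_C",
  density = "density_cells_per_mL",
  day = "day",
  replicate = "replicate",
  biomarker = "biomarker",
  value = "value",
  units = "units"
)

# Assert that `x` is structurally a battery: required columns, numeric
# fields, unique (treatment, day, replicate, biomarker) keys, and one units
# string per biomarker. Returns the tibble with columns in canonical order.
assert_battery <- function(x, arg = "battery") {
  if (!is.data.frame(x)) {
    rlang::abort(paste0("`", arg, "` must be a data frame."),
                 class = "ibrtox_battery_error")
  }
  missing <- setdiff(battery_cols, names(x))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("`", arg, "` is missing column(s): ", paste(missing, collapse = ", ")),
      class = "ibrtox_battery_error"
    )
  }
  x <- tibble::as_tibble(x)[battery_cols]
  for (col in c("temperature", "density", "day", "replicate", "value")) {
    if (!is.numeric(x[[col]])) {
      rlang::abort(paste0("Column `", col, "` must be numeric."),
                   class = "ibrtox_battery_error")
    }
  }
  key <- paste(x$temperature, x$density, x$day, x$replicate, x$biomarker,
               sep = "\r")
  dup <- anyDuplicated(key)
  if (dup > 0) {
    rlang::abort(
      sprintf(
        "Duplicate record key: temperature=%g, density=%g, day=%g, replicate=%g, biomarker=%s",
        x$temperature[dup], x$density[dup], x$day[dup], x$replicate[dup],
        x$biomarker[dup]
      ),
      class = "ibrtox_duplicate_key_error"
    )
  }
  units_per_bm <- dplyr::distinct(x, .data$biomarker, .data$units) |>
    dplyr::count(.data$biomarker) |>
    dplyr::filter(.data$n > 1)
  if (nrow(units_per_bm) > 0) {
    rlang::abort(
      paste0("Biomarker(s) with more than one units string: ",
             paste(units_per_bm$biomarker, collapse = ", ")),
      class = "ibrtox_battery_error"
    )
  }
  x
}

#' Read a biomarker battery from a long-format CSV file
#'
#' The expected file is a comma-separated, UTF-8, header-first long table
#' with one measured value per row, keyed by treatment (temperature and
#' toxicant density), sampling day, replicate tank, and biomarker name.
#' Default column names are `temperature_C`, `density_cells_per_mL`, `day`,
#' `replicate`, `biomarker`, `value`, `units`; supply `schema` to map other
#' headers onto these roles.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping internal roles
#'   (`temperature`, `density`, `day`, `replicate`, `biomarker`, `value`,
#'   `units`) to column names in the file. Roles omitted from `schema` keep
#'   their default file column name.
#'
#' @return A tibble with columns `temperature`, `density`, `day`,
#'   `replicate`, `biomarker`, `value`, `units` and unique record keys.
#' @seealso [write_battery()], [validate_battery()]
#' @export
read_battery <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    rlang::abort(paste0("File not found: ", path), class = "ibrtox_io_error")
  }
  colmap <- battery_file_cols
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), names(colmap))
    if (length(bad) > 0) {
      rlang::abort(paste0("Unknown schema role(s): ", paste(bad, collapse = ", ")),
                   class = "ibrtox_io_error")
    }
    colmap[names(schema)] <- schema
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(unname(colmap), names(raw))
  if (length(missing) > 0) {
    rlang::abort(paste0("CSV is missing column(s): ", paste(missing, collapse = ", ")),
                 class = "ibrtox_io_error")
  }
  out <- tibble::tibble(
    temperature = parse_num_col(raw[[colmap[["temperature"]]]], colmap[["temperature"]]),
    density = parse_num_col(raw[[colmap[["density"]]]], colmap[["density"]]),
    day = parse_num_col(raw[[colmap[["day"]]]], colmap[["day"]]),
    replicate = parse_num_col(raw[[colmap[["replicate"]]]], colmap[["replicate"]]),
    biomarker = raw[[colmap[["biomarker"]]]],
    value = parse_num_col(raw[[colmap[["value"]]]], colmap[["value"]]),
    units = raw[[colmap[["units"]]]]
  )
  assert_battery(out, arg = "file contents")
}

# Numeric parse with a row-numbered error (header is row 1).
parse_num_col <- function(x, colname) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("Could not parse `%s` as a number in column `%s` (file row %d).",
              x[bad[1]], colname, bad[1] + 1L),
      class = "ibrtox_parse_error"
    )
  }
  if (anyNA(out)) {
    rlang::abort(
      sprintf("Missing value in column `%s` (file row %d).",
              colname, which(is.na(out))[1] + 1L),
      class = "ibrtox_parse_error"
    )
  }
  out
}

#' Write a biomarker battery to the standard long-format CSV
#'
#' Writes the fixed header `temperature_C, density_cells_per_mL, day,
#' replicate, biomarker, value, units`. [read_battery()] applied to the
#' written file recovers the battery exactly.
#'
#' @param battery A battery tibble (see [read_battery()] for the columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_battery <- function(battery, path) {
  battery <- assert_battery(battery)
  out <- battery
  names(out) <- unname(battery_file_cols[names(battery)])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate a battery against a declared design
#'
#' Checks that every design cell (treatment x day x biomarker) carries
#' exactly `n_replicates` measurements and that every value is strictly
#' positive (required by the log-ratio step of the IBR index). This is a
#' reporting operation: it never errors on imbalance.
#'
#' @param battery A battery tibble.
#' @param design A [design_spec()].
#' @return A list of class `battery_validation` with elements
#'   `is_balanced` (TRUE iff no missing cells), `missing_cells` (tibble of
#'   design cells with fewer than `n_replicates` records per biomarker) and
#'   `nonpositive_values` (tibble of offending record keys).
#' @export
validate_battery <- function(battery, design) {
  battery <- assert_battery(battery)
  stopifnot(inherits(design, "design_spec"))
  biomarkers <- sort(unique(battery$biomarker))
  expected <- tidyr::expand_grid(design_cells(design), biomarker = biomarkers)
  counts <- battery |>
    dplyr::count(.data$temperature, .data$density, .data$day, .data$biomarker)
  missing_cells <- expected |>
    dplyr::left_join(counts,
                     by = c("temperature", "density", "day", "biomarker")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::filter(.data$n < design$n_replicates) |>
    dplyr::rename(n_records = "n")
  nonpositive <- battery |>
    dplyr::filter(.data$value <= 0) |>
    dplyr::select(dplyr::all_of(battery_cols))
  structure(
    list(is_balanced = nrow(missing_cells) == 0,
         missing_cells = missing_cells,
         nonpositive_values = nonpositive),
    class = "battery_validation"
  )
}

#' @export
print.battery_validation <- function(x, ...) {
  cat("<battery_validation>\n")
  cat("  balanced:           ", x$is_balanced, "\n")
  cat("  missing cells:      ", nrow(x$missing_cells), "\n")
  cat("  non-positive values:", nrow(x$nonpositive_values), "\n")
  invisible(x)
}

#' Treatment-level means and standard deviations
#'
#' Collapses replicate tanks to one row per (treatment, day, biomarker),
#' with the mean and the sample (n-1 denominator) standard deviation.
#' Single-replicate cells get `sd = NA` and are flagged.
#'
#' @param battery A battery tibble.
#' @return A tibble with columns `temperature`, `density`, `day`,
#'   `biomarker`, `mean`, `sd`, `n_replicates`, `sd_defined`.
#' @export
treatment_means <- function(battery) {
  battery <- assert_battery(battery)
  battery |>
    dplyr::group_by(.data$temperature, .data$density, .data$day, .data$biomarker) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else NA_real_,
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(sd_defined = !is.na(.data$sd)) |>
    dplyr::arrange(.data$temperature, .data$density, .data$day, .data$biomarker)
}
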