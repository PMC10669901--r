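#' Configure an end-to-end analysis run
#'
#' Bundles the input source (a synthetic-generator configuration or a CSV
#' path — exactly one), IBR options, the significance level, the output
#' directory, and the master seed into a single validated object.
#'
#' @param synthetic A [synthetic_config()], or `NULL` when reading a CSV.
#' @param csv Path to a long-format battery CSV, or `NULL` when simulating.
#' @param design A [design_spec()] used for validation; defaults to the
#'   synthetic config's design when simulating (required for CSV input).
#' @param ibr An [ibr_options()] object.
#' @param alpha Significance level in (0, 1) for post hoc letters.
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; the generator substream is derived from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, csv = NULL, design = NULL,
                            ibr = ibr_options(), alpha = 0.05,
                            out_dir, seed = 1L) {
  if (is.null(synthetic) == is.null(csv)) {
    rlang::abort("Exactly one of `synthetic` or `csv` must be supplied.",
                 class = "ibrtox_config_error")
  }
  if (!is.null(synthetic)) {
    stopifnot(inherits(synthetic, "synthetic_config"))
    if (is.null(design)) design <- synthetic$design
  }
  if (!is.null(csv) && is.null(design)) {
    rlang::abort("CSV input requires an explicit `design` for validation.",
                 class = "ibrtox_config_error")
  }
  if (!(length(alpha) == 1 && alpha > 0 && alpha < 1)) {
    rlang::abort("`alpha` must be a single value in (0, 1).",
                 class = "ibrtox_config_error")
  }
  structure(
    list(synthetic = synthetic, csv = csv, design = design, ibr = ibr,
         alpha = alpha, out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full biomarker analysis pipeline
#'
#' Stages: (1) simulate or load the battery; (2) validate it against the
#' design (strict: an unbalanced or non-positive battery halts the run and
#' writes only the validation report); (3) per-biomarker three-way ANOVA
#' tables; (4) per-day Tukey HSD letters for every biomarker; (5) the IBR
#' index with star-plot geometry (CSV + SVG); (6) condition-level PCA
#' (loadings, scores, variance shares, biplot SVG); (7) the Pearson
#' correlation matrix; (8) a JSON manifest with the MD5 checksum of every
#' output. Identical configuration and seed reproduce identical text
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return The manifest, invisibly: a tibble of file paths and checksums.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  files <- character(0)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      rlang::abort(
        sprintf("Pipeline halted at stage `%s`: %s", name, conditionMessage(e)),
        class = "ibrtox_pipeline_error", parent = e
      )
    })
    say("stage %-10s done in %.2fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    res
  }

  battery <- stage("input", {
    if (!is.null(config$synthetic)) {
      cfg <- config$synthetic
      cfg$seed <- config$seed
      generate_battery(cfg)
    } else {
      read_battery(config$csv)
    }
  })
  path_battery <- file.path(out_dir, "battery.csv")
  write_battery(battery, path_battery)
  files <- c(files, path_battery)

  report <- stage("validate", validate_battery(battery, config$design))
  path_validation <- file.path(out_dir, "validation.json")
  jsonlite::write_json(
    list(is_balanced = report$is_balanced,
         missing_cells = report$missing_cells,
         nonpositive_values = report$nonpositive_values),
    path_validation, auto_unbox = TRUE, digits = NA
  )
  files <- c(files, path_validation)
  if (!report$is_balanced || nrow(report$nonpositive_values) > 0) {
    rlang::abort(
      "Pipeline halted at stage `validate`: battery failed validation (see validation.json); no downstream outputs were produced.",
      class = "ibrtox_validation_error"
    )
  }

  biomarkers <- unique(battery$biomarker)
  days <- sort(unique(battery$day))

  stage("anova", {
    for (bm in biomarkers) {
      fit <- fit_three_way_anova(battery, bm)
      p <- file.path(out_dir, paste0("anova_", bm, ".csv"))
      readr::write_csv(tidy(fit), p, progress = FALSE)
      files <- c(files, p)
    }
  })

  stage("posthoc", {
    for (bm in biomarkers) {
      all_pairs <- list(); all_letters <- list()
      for (dy in days) {
        tk <- tukey_hsd(battery, bm, day = dy, alpha = config$alpha)
        all_pairs[[as.character(dy)]] <- dplyr::mutate(tk$pairs, day = dy, .before = 1)
        all_letters[[as.character(dy)]] <- dplyr::mutate(tk$letters, day = dy, .before = 1)
      }
      p1 <- file.path(out_dir, paste0("tukey_pairs_", bm, ".csv"))
      p2 <- file.path(out_dir, paste0("tukey_letters_", bm, ".csv"))
      readr::write_csv(dplyr::bind_rows(all_pairs), p1, progress = FALSE)
      readr::write_csv(dplyr::bind_rows(all_letters), p2, progress = FALSE)
      files <- c(files, p1, p2)
    }
  })

  ibr_res <- stage("ibr", compute_ibr(battery, config$ibr))
  p_scores <- file.path(out_dir, "ibr_scores.csv")
  p_comp <- file.path(out_dir, "ibr_components.csv")
  readr::write_csv(ibr_res$scores, p_scores, progress = FALSE)
  readr::write_csv(ibr_res$components, p_comp, progress = FALSE)
  files <- c(files, p_scores, p_comp)
  star <- ibr_res$scores |>
    dplyr::distinct(.data$temperature, .data$density, .data$day) |>
    purrr::pmap(function(temperature, density, day) {
      star_coordinates(ibr_res, temperature, density, day) |>
        dplyr::mutate(temperature = temperature, density = density,
                      day = day, .before = 1)
    }) |>
    dplyr::bind_rows()
  p_star <- file.path(out_dir, "star_coordinates.csv")
  readr::write_csv(star, p_star, progress = FALSE)
  files <- c(files, p_star)
  p_star_svg <- file.path(out_dir, "ibr_star.svg")
  save_svg(autoplot(ibr_res), p_star_svg, width = 9, height = 7)
  files <- c(files, p_star_svg)

  pca_res <- stage("pca", biomarker_pca(battery))
  for (tp in c("loadings", "scores", "variance")) {
    p <- file.path(out_dir, paste0("pca_", tp, ".csv"))
    readr::write_csv(tidy(pca_res, tp), p, progress = FALSE)
    files <- c(files, p)
  }
  p_biplot <- file.path(out_dir, "pca_biplot.svg")
  save_svg(autoplot(pca_res), p_biplot, width = 7, height = 5)
  files <- c(files, p_biplot)

  pearson <- stage("pearson", pearson_matrix(battery))
  p_pearson <- file.path(out_dir, "pearson_matrix.csv")
  readr::write_csv(tibble::as_tibble(pearson, rownames = "biomarker"),
                   p_pearson, progress = FALSE)
  files <- c(files, p_pearson)

  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    bytes = unname(file.size(files))
  )
  path_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(seed = config$seed, alpha = config$alpha, files = manifest),
    path_manifest, auto_unbox = TRUE, digits = NA
  )
  say("pipeline complete: %d files in %s", nrow(manifest) + 1, out_dir)
  invisible(manifest)
}

# Write a ggplot to SVG via the cairo device.
save_svg <- function(plot, path, width = 7, height = 5) {
  grDevices::svg(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}
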